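#' Configuration for the synthetic burned landscape
#'
#' Defines the study conditions the generator emulates: a local 30 m metric
#' grid, fires burning between 1985 and 2017, planted group-assignment
#' effects, and per-variable noise scales. The defaults describe a landscape
#' of roughly 50,000 burned pixels in which the dominant planted driver of
#' group membership is an anomalously cold post-fire summer.
#'
#' @param grid_rows,grid_cols Grid dimensions in pixels (>= 1).
#' @param pixel_size_m Pixel edge length in metres (> 0), default 30.
#' @param fire_year_range Inclusive calendar-year interval for fire years.
#' @param n_fires Number of fire events (contiguous 8-connected blobs).
#' @param burned_fraction Fraction of the grid burned by all fires together.
#' @param observation_year Calendar year of the structure chronosequence
#'   acquisition; years-since-fire = observation_year - fire_year.
#' @param group_effects Named list of `c(intercept, slope)` coefficients of
#'   the planted logistic (softmax) rules. Each group's slope multiplies its
#'   population-standardized planted predictor: `regrowth_delay` uses
#'   cold-summer anomaly severity (-z of the coldest post-fire summer),
#'   `mixed_growth` uses pre-fire basal area, `conifer_dominant_mixed` uses
#'   the warmest-year anomaly z. The baseline group
#'   (`regenerative_conifer`) has linear predictor 0, so all-zero
#'   coefficients plus zero assignment noise send every pixel to the
#'   baseline. Default intercepts are calibrated so the marginal group
#'   prevalences match the study system (about 38/27/15.3/19.7% for
#'   regenerative conifer / regrowth delay / mixed growth /
#'   conifer-dominant mixed growth).
#' @param noise_scales List of noise standard deviations: `group` scales the
#'   Gumbel assignment noise (1 = softmax sampling; 0 = deterministic
#'   argmax), `spectral` is the additive index noise, `climate_year` and
#'   `climate_local` weight the regional and pixel-level parts of yearly
#'   climate deviations (in units of the variable's interannual SD).
#' @param seed Integer seed fixing all stochastic output.
#' @return A validated `landscape_config` list.
#' @export
landscape_config <- function(grid_rows = 260, grid_cols = 260,
                             pixel_size_m = 30,
                             fire_year_range = c(1985, 2017),
                             n_fires = 25,
                             burned_fraction = 0.75,
                             observation_year = 2022,
                             group_effects = list(
                               regrowth_delay = c(-1.338, 3.0),
                               mixed_growth = c(-1.928, 2.2),
                               conifer_dominant_mixed = c(-1.490, 2.2)
                             ),
                             noise_scales = list(),
                             seed = 1) {
  noise <- modifyList(
    list(group = 1, spectral = 0.02, climate_year = 0.8, climate_local = 0.6),
    noise_scales
  )
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    pixel_size_m = pixel_size_m, fire_year_range = as.integer(fire_year_range),
    n_fires = as.integer(n_fires), burned_fraction = burned_fraction,
    observation_year = as.integer(observation_year),
    group_effects = group_effects, noise_scales = noise, seed = as.integer(seed)
  )
  if (cfg$grid_rows < 1 || cfg$grid_cols < 1) stop("grid dimensions must be >= 1")
  if (cfg$pixel_size_m <= 0) stop("pixel_size_m must be > 0")
  if (length(cfg$fire_year_range) != 2 || cfg$fire_year_range[1] > cfg$fire_year_range[2])
    stop("fire_year_range must be a non-empty year interval")
  if (cfg$burned_fraction <= 0 || cfg$burned_fraction > 1)
    stop("burned_fraction must be in (0, 1]")
  target <- floor(cfg$grid_rows * cfg$grid_cols * cfg$burned_fraction)
  if (cfg$n_fires < 1 || cfg$n_fires > target)
    stop("n_fires exceeds the burnable capacity of the grid")
  need <- c("regrowth_delay", "mixed_growth", "conifer_dominant_mixed")
  if (!all(need %in% names(cfg$group_effects)))
    stop("group_effects must name: ", paste(need, collapse = ", "))
  if (!all(vapply(cfg$group_effects, length, integer(1)) == 2))
    stop("each group_effects entry must be c(intercept, slope)")
  class(cfg) <- "landscape_config"
  cfg
}

# Climate variables, their normals as deterministic functions of elevation
# (6.5 C/km lapse for temperatures) plus smooth noise, interannual SDs, and
# the anomaly extreme kind used for z-scores.
climate_variable_table <- function() {
  data.frame(
    variable = c("MAT", "MAP", "PAS", "CMD",
                 "Summer_avg_T", "Summer_max_T", "Summer_min_T", "Winter_min_T",
                 "Spring_precip", "Summer_precip", "Fall_precip"),
    base = c(3.5, 500, 180, 250, 12.7, 20.7, 5.7, -14, 90, 166, 110),
    elev_coef = c(-6.5e-3, 0.20, 0.15, -0.15,
                  -6.5e-3, -6.5e-3, -6.5e-3, -6.5e-3, 0.03, 0.05, 0.04),
    sd = c(1.1, 70, 45, 55, 1.2, 1.6, 1.4, 2.5, 25, 40, 30),
    anomaly = c("anom_warmest_year", "anom_driest_year", "anom_min_PAS",
                "anom_max_CMD", "anom_coldest_summer_T", "anom_warmest_summer_T",
                "anom_min_summer_T", "anom_coldest_winter_T",
                "anom_min_spring_precip", "anom_min_summer_precip",
                "anom_min_fall_precip"),
    kind = c("max", "min", "min", "max", "min", "max", "min", "min",
             "min", "min", "min"),
    stringsAsFactors = FALSE
  )
}

#' Anomaly extreme kinds for the climate drivers
#'
#' Maps each post-fire climate-anomaly driver to its parent climate normal
#' and the extreme kind (min or max over the first five post-fire years)
#' used for the z-score: warmest year for MAT, driest year for MAP, minimum
#' snow, maximum CMD, coldest summer for the summer mean, and so on.
#'
#' @return Data frame with columns `variable`, `anomaly`, `kind`.
#' @export
anomaly_kind_table <- function() {
  climate_variable_table()[, c("variable", "anomaly", "kind")]
}

# Grow n_fires contiguous 8-connected blobs covering ~total cells.
# Rounds-based frontier growth gives compact, irregular patches.
grow_fires <- function(nr, nc, n_fires, total) {
  fire_id <- matrix(0L, nr, nc)
  w <- rexp(n_fires) + 0.25
  sizes <- pmax(5L, as.integer(round(total * w / sum(w))))
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  neighbours <- function(idx) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    rr <- rep(r, each = 8L) + off_r
    cc <- rep(c, each = 8L) + off_c
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }
  for (f in seq_len(n_fires)) {
    open <- which(fire_id == 0L)
    if (!length(open)) break
    seed_cell <- open[sample.int(length(open), 1L)]
    fire_id[seed_cell] <- f
    grown <- 1L
    frontier <- neighbours(seed_cell)
    frontier <- frontier[fire_id[frontier] == 0L]
    while (grown < sizes[f] && length(frontier)) {
      frontier <- unique(frontier[fire_id[frontier] == 0L])
      if (!length(frontier)) break
      n_take <- min(length(frontier), max(1L, ceiling(length(frontier) * 0.6)),
                    sizes[f] - grown)
      take <- if (n_take == length(frontier)) frontier else
        frontier[sample.int(length(frontier), n_take)]
      fire_id[take] <- f
      grown <- grown + length(take)
      frontier <- c(frontier[!(frontier %in% take)], neighbours(take))
    }
  }
  fire_id
}

#' Generate a synthetic burned landscape with planted ground truth
#'
#' Produces the full synthetic study system: a smoothed elevation field with
#' derived aspect, slope, TPI and flow direction; categorical soil, subzone,
#' pre-fire landcover and species rasters; a smooth pre-fire basal-area
#' raster; contiguous fire blobs each with one fire year (fire years are
#' stratified so every chronosequence epoch is represented); elevation-driven
#' climate normals; per-pixel yearly post-fire climate (normal + regional
#' year offset + local noise); and a truth table assigning every burned pixel
#' a structural recovery group through planted softmax rules on drivers
#' (cold-summer anomaly -> regrowth delay, high pre-fire basal area -> mixed
#' growth, warm annual anomaly -> conifer-dominant mixed growth, baseline ->
#' regenerative conifer).
#'
#' @param config A [landscape_config()].
#' @return A `fire_landscape` list: `config`, `rasters` (matrices/factors),
#'   `fire` (id and year matrices, per-fire years), `climate` (normal
#'   matrices, interannual SDs, per-burned-pixel yearly series for post-fire
#'   years 1..5), and `truth` (pixel_id, row, col, fire_year,
#'   years_since_fire, group, driver_tag, and the planted predictor values).
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  with_seed(config$seed, {
    ## --- terrain -----------------------------------------------------------
    elev_field <- smooth_field(nr, nc, passes = 10)
    elevation <- 600 + 700 * elev_field
    aspect <- aspect_raster(elevation, config$pixel_size_m)
    tpi_m <- tpi_raster(elevation)
    soil_levels <- c("podzol", "luvisol", "brunisol", "organic")
    soil <- matrix(
      soil_levels[findInterval(smooth_field(nr, nc, 8), c(0.35, 0.55, 0.75)) + 1L],
      nr, nc
    )
    subzone_score <- elev_field + 0.2 * smooth_field(nr, nc, 6)
    subzone_levels <- c("SBS-dw", "SBS-mc", "SBPS-xc")
    subzone <- matrix(
      subzone_levels[
        findInterval(subzone_score, quantile(subzone_score, c(1 / 3, 2 / 3))) + 1L],
      nr, nc
    )
    ba_field <- smooth_field(nr, nc, 8)
    prefire_ba <- pmax(0, 4 + 28 * ba_field + rnorm(nr * nc, sd = 1.5))
    dim(prefire_ba) <- c(nr, nc)
    lc_score <- prefire_ba + rnorm(nr * nc, sd = 4)
    landcover_levels <- c("herb", "shrub", "broadleaf", "coniferous")
    prefire_landcover <- matrix(
      landcover_levels[findInterval(lc_score, c(6, 12, 18)) + 1L], nr, nc
    )
    species_levels <- c("lodgepole_pine", "hybrid_spruce", "douglas_fir",
                        "trembling_aspen")
    sp_score <- smooth_field(nr, nc, 6) + 0.3 * runif(nr * nc)
    prefire_species <- matrix(
      species_levels[findInterval(sp_score, c(0.45, 0.75, 0.92)) + 1L], nr, nc
    )

    ## --- fires -------------------------------------------------------------
    total_burn <- floor(nr * nc * config$burned_fraction)
    fire_id <- grow_fires(nr, nc, config$n_fires, total_burn)
    n_fires_grown <- max(fire_id)
    # Fire years: guarantee chronosequence coverage by assigning, first, one
    # fire to each epoch's year set, then uniform years for the rest.
    yr_lo <- config$fire_year_range[1]; yr_hi <- config$fire_year_range[2]
    epoch_year_sets <- lapply(list(5:7, 8:9, 11:12, 15:16, 21), function(ys) {
      cand <- config$observation_year - ys
      cand[cand >= yr_lo & cand <= yr_hi]
    })
    epoch_year_sets <- Filter(length, epoch_year_sets)
    fire_years <- integer(n_fires_grown)
    n_fixed <- min(length(epoch_year_sets), n_fires_grown)
    for (i in seq_len(n_fixed)) {
      ys <- epoch_year_sets[[i]]
      fire_years[i] <- ys[sample.int(length(ys), 1L)]
    }
    if (n_fires_grown > n_fixed) {
      fire_years[(n_fixed + 1):n_fires_grown] <-
        sample(seq(yr_lo, yr_hi), n_fires_grown - n_fixed, replace = TRUE)
    }
    fire_year <- matrix(NA_integer_, nr, nc)
    burned <- fire_id > 0L
    fire_year[burned] <- fire_years[fire_id[burned]]

    ## --- climate -----------------------------------------------------------
    cvt <- climate_variable_table()
    elev_anom <- elevation - mean(elevation)
    normals <- setNames(vector("list", nrow(cvt)), cvt$variable)
    for (i in seq_len(nrow(cvt))) {
      normals[[i]] <- cvt$base[i] + cvt$elev_coef[i] * elev_anom +
        0.15 * cvt$sd[i] * (2 * smooth_field(nr, nc, 6) - 1)
    }
    normal_sd <- setNames(cvt$sd, cvt$variable)

    pix <- which(burned)                      # column-major linear index
    n_b <- length(pix)
    fy <- fire_year[pix]
    cal_years <- seq(min(fy) + 1L, max(fy) + 5L)
    year_offsets <- matrix(
      rnorm(nrow(cvt) * length(cal_years)),
      nrow(cvt), length(cal_years),
      dimnames = list(cvt$variable, as.character(cal_years))
    )
    yearly <- setNames(vector("list", nrow(cvt)), cvt$variable)
    for (i in seq_len(nrow(cvt))) {
      v <- cvt$variable[i]
      dev <- matrix(0, n_b, 5)
      for (k in 1:5) {
        dev[, k] <- config$noise_scales$climate_year * cvt$sd[i] *
          year_offsets[v, as.character(fy + k)] +
          config$noise_scales$climate_local * cvt$sd[i] * rnorm(n_b)
      }
      yearly[[i]] <- normals[[v]][pix] + dev
      colnames(yearly[[i]]) <- paste0("y", 1:5)
    }

    ## --- planted group assignment -----------------------------------------
    z_cold <- climate_anomaly(yearly[["Summer_avg_T"]],
                              normals[["Summer_avg_T"]][pix],
                              normal_sd["Summer_avg_T"], kind = "min")
    z_warm <- climate_anomaly(yearly[["MAT"]],
                              normals[["MAT"]][pix],
                              normal_sd["MAT"], kind = "max")
    ba_b <- prefire_ba[pix]
    ba_sd <- pop_sd(ba_b)
    ba_std <- if (ba_sd > 0) (ba_b - mean(ba_b)) / ba_sd else rep(0, n_b)

    # planted predictors, population-standardized across burned pixels
    std01 <- function(x) {
      s <- pop_sd(x)
      if (s > 0) (x - mean(x)) / s else rep(0, length(x))
    }
    p_rd <- std01(-z_cold)       # colder summers -> larger severity
    p_mg <- ba_std
    p_cdm <- std01(z_warm)
    ge <- config$group_effects
    eta <- matrix(0, n_b, 4L, dimnames = list(NULL, GROUP_LEVELS))
    eta[, "regrowth_delay"] <-
      ge[["regrowth_delay"]][1] + ge[["regrowth_delay"]][2] * p_rd
    eta[, "mixed_growth"] <-
      ge[["mixed_growth"]][1] + ge[["mixed_growth"]][2] * p_mg
    eta[, "conifer_dominant_mixed"] <-
      ge[["conifer_dominant_mixed"]][1] + ge[["conifer_dominant_mixed"]][2] * p_cdm
    score <- eta
    if (config$noise_scales$group > 0)
      score <- score + config$noise_scales$group *
        matrix(rgumbel(n_b * 4L), n_b, 4L)
    g_idx <- max.col(score, ties.method = "first")
    group <- factor(GROUP_LEVELS[g_idx], levels = GROUP_LEVELS)
    tags <- c("baseline", "anom_coldest_summer_T", "Prefire_BA", "anom_warmest_year")
    truth <- data.frame(
      pixel_id = pix,
      row = ((pix - 1L) %% nr) + 1L,
      col = ((pix - 1L) %/% nr) + 1L,
      fire_year = fy,
      years_since_fire = config$observation_year - fy,
      group = group,
      driver_tag = tags[g_idx],
      eta_regrowth_delay = eta[, "regrowth_delay"],
      eta_mixed_growth = eta[, "mixed_growth"],
      eta_conifer_dominant_mixed = eta[, "conifer_dominant_mixed"],
      anom_coldest_summer_T = z_cold,
      anom_warmest_year = z_warm,
      prefire_ba_std = ba_std,
      stringsAsFactors = FALSE
    )

    structure(list(
      config = config,
      rasters = list(
        elevation = elevation, aspect = aspect, tpi = tpi_m,
        soil = soil, subzone = subzone,
        prefire_ba = prefire_ba,
        prefire_landcover = prefire_landcover,
        prefire_species = prefire_species
      ),
      raster_levels = list(
        soil = soil_levels, subzone = subzone_levels,
        prefire_landcover = landcover_levels,
        prefire_species = species_levels
      ),
      fire = list(fire_id = fire_id, fire_year = fire_year, fire_years = fire_years),
      climate = list(normals = normals, sd = normal_sd, yearly = yearly,
                     reference_period = c(1981L, 2010L)),
      planted = list(dominant_driver = "anom_coldest_summer_T"),
      truth = truth
    ), class = "fire_landscape")
  })
}

#' @export
print.fire_landscape <- function(x, ...) {
  cat("fire_landscape:", x$config$grid_rows, "x", x$config$grid_cols,
      "grid,", nrow(x$truth), "burned pixels,",
      max(x$fire$fire_id), "fires,",
      "fire years", min(x$fire$fire_years), "-", max(x$fire$fire_years), "\n")
  print(table(x$truth$group))
  invisible(x)
}

#' Generate per-pixel annual spectral index series for burned pixels
#'
#' Each burned pixel follows its true group's archetype trajectory
#' `value(t) = pre - drop * exp(-rate * t)` for years since fire t >= 0 and a
#' pre-fire plateau at `pre`, with additive Gaussian noise. Series are stored
#' on a relative year axis (fire_year - 1 .. fire_year + 5), which is the
#' window all recovery metrics operate on.
#'
#' @param truth Truth table (`pixel_id`, `fire_year`, `group`), e.g.
#'   `landscape$truth`.
#' @param archetypes Named list of `group_archetype`s covering every group in
#'   `truth`.
#' @param noise_sd Additive index noise SD (0 gives exact trajectories).
#' @param seed Integer seed.
#' @return A `spectral_series_set`.
#' @export
generate_spectral_series <- function(truth, archetypes = default_archetypes(),
                                     noise_sd = 0.02, seed = 1) {
  groups <- unique(as.character(truth$group))
  missing <- setdiff(groups, names(archetypes))
  if (length(missing))
    stop("no archetype for group(s): ", paste(missing, collapse = ", "))
  n <- nrow(truth)
  rel <- -1:5
  with_seed(seed, {
    arrays <- setNames(vector("list", length(SPECTRAL_INDICES)), SPECTRAL_INDICES)
    for (idx in SPECTRAL_INDICES) {
      m <- matrix(NA_real_, n, length(rel), dimnames = list(NULL, as.character(rel)))
      for (g in groups) {
        rows <- which(as.character(truth$group) == g)
        p <- archetypes[[g]]$spectral_params
        p <- p[p$index == idx, ]
        for (j in seq_along(rel)) {
          t_rel <- rel[j]
          m[rows, j] <- if (t_rel < 0) p$pre else p$pre - p$drop * exp(-p$rate * t_rel)
        }
      }
      if (noise_sd > 0) m <- m + matrix(rnorm(n * length(rel), sd = noise_sd), n)
      arrays[[idx]] <- m
    }
    spectral_series_set(truth$pixel_id, truth$fire_year, arrays)
  })
}

#' Sample a space-for-time structure chronosequence
#'
#' Draws structural samples (stems per 900 m2, bare ground %, basal area,
#' conifer proportion) around the archetype means for each group x epoch
#' cell, with truncated Gaussian noise clamped at the variable domains.
#' Mixed growth has no epoch-21 archetype entry, so that cell is always
#' empty. When `truth` is supplied, samples are attached to real pixels whose
#' years-since-fire fall in an epoch (at most `n_per_group_epoch` per
#' group x epoch x cluster cell, where `cluster` is used if present in
#' `truth`); otherwise synthetic rows are fabricated per cell.
#'
#' @param truth Optional data frame with `group`, `years_since_fire` and
#'   optionally `pixel_id`, `cluster`.
#' @param archetypes Named archetype list.
#' @param n_per_group_epoch Samples per cell (>= 1).
#' @param noise List of per-variable SD functions of the mean; see
#'   `structure_noise_defaults()`. Pass SD 0 functions for exact means.
#' @param seed Integer seed.
#' @return Data frame of `StructuralSample` rows: pixel_id, years_since_fire,
#'   epoch, the four structure variables, group, and cluster if available.
#' @export
generate_structure_chronosequence <- function(truth = NULL,
                                              archetypes = default_archetypes(),
                                              n_per_group_epoch = 30,
                                              noise = structure_noise_defaults(),
                                              seed = 1) {
  stopifnot(n_per_group_epoch >= 1)
  epoch_years <- list(`5-7` = 5:7, `8-9` = 8:9, `11-12` = 11:12,
                      `15-16` = 15:16, `21` = 21L)
  draw_cell <- function(a, epoch, n) {
    m <- a$structure_means
    m <- m[m$epoch == epoch, ]
    if (!nrow(m)) return(NULL)                 # e.g. mixed growth at 21
    out <- data.frame(row.names = seq_len(n))
    for (v in STRUCTURE_VARS) {
      mu <- m[[v]]
      sdv <- noise[[v]](mu)
      x <- rnorm(n, mu, sdv)
      x <- switch(v,
        stems_per_900m2 = pmax(x, 0),
        bare_ground_pct = clamp(x, 0, 100),
        basal_area_m2_ha = pmax(x, 0),
        conifer_proportion = clamp(x, 0, 1)
      )
      out[[v]] <- x
    }
    out
  }
  with_seed(seed, {
    rows <- list()
    if (is.null(truth)) {
      for (g in names(archetypes)) {
        for (ep in EPOCH_LEVELS) {
          vals <- draw_cell(archetypes[[g]], ep, n_per_group_epoch)
          if (is.null(vals)) next
          vals$pixel_id <- NA_integer_
          vals$years_since_fire <- epoch_years[[ep]][1]
          vals$epoch <- ep
          vals$group <- g
          rows[[length(rows) + 1L]] <- vals
        }
      }
    } else {
      stopifnot(all(c("group", "years_since_fire") %in% names(truth)))
      truth$epoch <- as.character(assign_epoch(truth$years_since_fire))
      truth <- truth[!is.na(truth$epoch), , drop = FALSE]
      has_cluster <- "cluster" %in% names(truth)
      cell_key <- paste(truth$group, truth$epoch,
                        if (has_cluster) truth$cluster else "", sep = "|")
      for (key in sort(unique(cell_key))) {
        sel <- which(cell_key == key)
        if (length(sel) > n_per_group_epoch)
          sel <- sel[sort(sample.int(length(sel), n_per_group_epoch))]
        g <- as.character(truth$group[sel[1]])
        ep <- truth$epoch[sel[1]]
        if (is.null(archetypes[[g]]))
          stop("no archetype for group: ", g)
        vals <- draw_cell(archetypes[[g]], ep, length(sel))
        if (is.null(vals)) next
        vals$pixel_id <- if ("pixel_id" %in% names(truth))
          truth$pixel_id[sel] else NA_integer_
        vals$years_since_fire <- truth$years_since_fire[sel]
        vals$epoch <- ep
        vals$group <- g
        if (has_cluster) vals$cluster <- truth$cluster[sel]
        rows[[length(rows) + 1L]] <- vals
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(pixel_id = integer(), years_since_fire = integer(),
                        epoch = character(), group = character())
      for (v in STRUCTURE_VARS) out[[v]] <- numeric()
    }
    rownames(out) <- NULL
    front <- c("pixel_id", "years_since_fire", "epoch",
               STRUCTURE_VARS, "group",
               if ("cluster" %in% names(out)) "cluster")
    out[, front]
  })
}
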