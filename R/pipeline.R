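#' Pipeline configuration
#'
#' Single nested configuration for an end-to-end run. Every stochastic
#' stage draws its seed deterministically from `seed`, so one integer fixes
#' the whole run.
#'
#' @param landscape A [landscape_config()]; the demo default is a small
#'   landscape that exercises every stage quickly.
#' @param barc List: `offset`, `scale`, `threshold` of the BARC-A screen.
#' @param cluster List: `k_min`, `k_max`, `n_restarts`, `min_frac`,
#'   optional `k_override` (skip the elbow and force k).
#' @param chrono List: `n_per_group_epoch` structure samples per cell.
#' @param grouping List: `n_permutations`, `alpha`, `correction`.
#' @param plan A [sample_plan()].
#' @param attribution An [attribution_config()].
#' @param stages Character vector of stages to run, in pipeline order
#'   (`synth`, `metrics`, `cluster`, `group`, `drivers`, `attribute`);
#'   execution stops after the last named stage.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(landscape = landscape_config(grid_rows = 80,
                                                         grid_cols = 80,
                                                         n_fires = 12),
                            barc = list(offset = 275, scale = 5, threshold = 130),
                            cluster = list(k_min = 2, k_max = 8,
                                           n_restarts = 5, min_frac = 0.01,
                                           k_override = NULL),
                            chrono = list(n_per_group_epoch = 25),
                            grouping = list(n_permutations = 999, alpha = 0.05,
                                            correction = "none"),
                            plan = sample_plan(fraction = 0.05),
                            attribution = attribution_config(),
                            stages = c("synth", "metrics", "cluster", "group",
                                       "drivers", "attribute"),
                            seed = 1) {
  structure(list(landscape = landscape, barc = barc, cluster = cluster,
                 chrono = chrono, grouping = grouping, plan = plan,
                 attribution = attribution, stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage_csv <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full recovery-grouping pipeline
#'
#' Executes, in order: synthetic landscape generation; spectral metric
#' derivation and BARC-A severity screening; k-means clustering of the
#' standardized 22-metric vectors with rare-cluster exclusion; structural
#' grouping of the clusters via chronosequence PERMANOVA and post-hoc
#' merging; driver derivation; and tiered random-forest attribution. Each
#' stage writes its outputs before the next starts; a JSON manifest with
#' MD5 hashes of every output makes reruns auditable (identical config and
#' seed reproduce identical hashes).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage `results` and the
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  res <- list()
  files <- character(0)
  warns <- character(0)
  note <- function(...) message(sprintf(...))

  ## synth ------------------------------------------------------------------
  note("[synth] generating landscape (seed %d)", config$landscape$seed)
  land <- generate_landscape(config$landscape)
  res$landscape <- land
  files <- c(files, write_stage_csv(land$truth, outdir, "truth.csv"))
  if (!length(setdiff(stages, "synth"))) return(finish_run(config, res, files, outdir, warns))

  ## metrics + screen -------------------------------------------------------
  if ("metrics" %in% stages) {
    note("[metrics] %d burned pixels", nrow(land$truth))
    series <- generate_spectral_series(
      land$truth, default_archetypes(),
      noise_sd = config$landscape$noise_scales$spectral,
      seed = child_seed(config$seed, 2))
    metrics <- compute_metric_matrix(series)
    barc <- to_barc_a(metrics[, "dnbr"], config$barc$offset, config$barc$scale)
    keep <- severity_screen(barc, config$barc$threshold)
    res$metrics <- metrics; res$barc <- barc; res$screen <- keep
    files <- c(files,
               write_stage_csv(data.frame(pixel_id = land$truth$pixel_id,
                                          metrics, check.names = FALSE),
                               outdir, "metrics.csv"),
               write_stage_csv(data.frame(pixel_id = land$truth$pixel_id,
                                          barc = barc, included = keep),
                               outdir, "severity_screen.csv"))
    note("[screen] %d of %d pixels at/above BARC-A %d",
         sum(keep), length(keep), config$barc$threshold)
  }

  ## cluster ----------------------------------------------------------------
  if ("cluster" %in% stages) {
    std <- standardize_metrics(res$metrics[res$screen, , drop = FALSE])
    if (!is.null(config$cluster$k_override)) {
      km <- fit_kmeans(std$scores, config$cluster$k_override,
                       seed = child_seed(config$seed, 3),
                       n_restarts = config$cluster$n_restarts)
      sel <- list(k = km$k, k_grid = km$k, distortions = km$distortion,
                  model = km)
    } else {
      sel <- select_k(std$scores, config$cluster$k_min, config$cluster$k_max,
                      seed = child_seed(config$seed, 3),
                      n_restarts = config$cluster$n_restarts)
    }
    assign <- drop_rare_clusters(sel$model$cluster, config$cluster$min_frac)
    res$standardization <- std; res$k_selection <- sel; res$assignment <- assign
    note("[cluster] chose k = %d; %d pixels excluded as rare",
         sel$k, sum(assign$excluded))
    screened_ids <- land$truth$pixel_id[res$screen]
    files <- c(files, write_stage_csv(
      data.frame(pixel_id = screened_ids, cluster = assign$cluster,
                 excluded = assign$excluded),
      outdir, "clusters.csv"))
  }

  ## group ------------------------------------------------------------------
  if ("group" %in% stages) {
    truth_k <- land$truth[res$screen, , drop = FALSE]
    truth_k$cluster <- res$assignment$cluster
    truth_k <- truth_k[!res$assignment$excluded, , drop = FALSE]
    chron <- generate_structure_chronosequence(
      truth_k, default_archetypes(),
      n_per_group_epoch = config$chrono$n_per_group_epoch,
      seed = child_seed(config$seed, 4))
    d <- structure_dissimilarity(chron)
    pv <- permanova(d, chron$cluster,
                    n_permutations = config$grouping$n_permutations,
                    seed = child_seed(config$seed, 5))
    pw <- posthoc_pairwise(d, chron$cluster,
                           n_permutations = config$grouping$n_permutations,
                           seed = child_seed(config$seed, 6),
                           correction = config$grouping$correction)
    merged <- withCallingHandlers(
      merge_clusters(pw, alpha = config$grouping$alpha),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    res$chronosequence <- chron; res$permanova <- pv
    res$pairwise_p <- pw; res$groups <- merged
    note("[group] PERMANOVA F(%d, %d) = %.2f, p = %.3g; %d clusters -> %d groups",
         pv$df_between, pv$df_within, pv$pseudo_F, pv$p_value,
         length(merged$mapping), length(merged$groups))
    files <- c(files,
               write_stage_csv(chron, outdir, "chronosequence.csv"),
               write_stage_csv(as.data.frame(as.table(pw),
                                             stringsAsFactors = FALSE),
                               outdir, "pairwise_p.csv"),
               write_stage_csv(data.frame(cluster = names(merged$mapping),
                                          group = paste0("group_", merged$mapping)),
                               outdir, "group_mapping.csv"))
    pj <- file.path(outdir, "permanova.json")
    jsonlite::write_json(
      list(pseudo_F = pv$pseudo_F, df_between = pv$df_between,
           df_within = pv$df_within, p_value = pv$p_value,
           n_permutations = pv$n_permutations, seed = pv$seed),
      pj, auto_unbox = TRUE, digits = NA)
    files <- c(files, pj)
  }

  ## drivers ----------------------------------------------------------------
  if ("drivers" %in% stages) {
    drv <- compute_drivers(land)
    res$drivers <- drv
    files <- c(files, write_stage_csv(
      data.frame(pixel_id = land$truth$pixel_id, drv, check.names = FALSE),
      outdir, "drivers.csv"))
    note("[drivers] %d drivers in %d categories", ncol(drv),
         length(unique(attr(drv, "categories"))))
  }

  ## attribute --------------------------------------------------------------
  if ("attribute" %in% stages) {
    keep_rows <- which(res$screen)[!res$assignment$excluded]
    grp <- factor(paste0(
      "group_", res$groups$mapping[as.character(
        res$assignment$cluster[!res$assignment$excluded])]))
    drv_kept <- res$drivers[keep_rows, , drop = FALSE]
    attr(drv_kept, "categories") <- attr(res$drivers, "categories")
    px <- land$config$pixel_size_m
    coords <- cbind(x = land$truth$col[keep_rows] * px,
                    y = land$truth$row[keep_rows] * px)
    rep_att <- withCallingHandlers(
      run_attribution(drv_kept, grp, coords, plan = config$plan,
                      config = config$attribution,
                      seed = child_seed(config$seed, 7)),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    res$attribution <- rep_att
    aj <- file.path(outdir, "attribution.json")
    jsonlite::write_json(list(
      n_train = rep_att$sample$n_train, n_test = rep_att$sample$n_test,
      category_oob = lapply(rep_att$category_models, `[[`, "oob_accuracy"),
      consolidated = rep_att$consolidated,
      global_oob_accuracy = rep_att$global$oob_accuracy,
      external_accuracy = rep_att$global$external$accuracy,
      f_score = as.list(rep_att$global$external$f_score),
      boruta_decision = as.list(rep_att$boruta$decision),
      boruta_importance_0_100 = as.list(rep_att$boruta$importance_0_100)
    ), aj, auto_unbox = TRUE, digits = NA)
    files <- c(files,
               aj,
               write_stage_csv(rep_att$pdp, outdir, "pdp.csv"),
               write_stage_csv(as.data.frame(rep_att$global$external$confusion),
                               outdir, "confusion.csv"))
    note("[attribute] global OOB accuracy %.3f, external %.3f",
         rep_att$global$oob_accuracy, rep_att$global$external$accuracy)
  }

  finish_run(config, res, files, outdir, warns)
}

finish_run <- function(config, res, files, outdir, warns) {
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))),
    warnings = warns
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = res, manifest = manifest, outdir = outdir))
}

#' Validate pipeline input files
#'
#' Report-only schema and domain checks: chronosequence CSVs must carry the
#' four structure variables within their domains, metric CSVs must be fully
#' numeric, and raster CSV matrices must share one shape.
#'
#' @param paths Named list with any of: `chronosequence` (CSV path),
#'   `metrics` (CSV path), `rasters` (character vector of CSV paths).
#' @return Data frame of violations (`file`, `problem`); zero rows when
#'   clean.
#' @export
validate_inputs <- function(paths) {
  bad <- list()
  flag <- function(file, problem)
    bad[[length(bad) + 1L]] <<- data.frame(file = file, problem = problem,
                                           stringsAsFactors = FALSE)
  if (!is.null(paths$chronosequence)) {
    f <- paths$chronosequence
    if (!file.exists(f)) flag(f, "file does not exist") else {
      x <- read.csv(f)
      miss <- setdiff(STRUCTURE_VARS, names(x))
      if (length(miss))
        flag(f, paste("missing columns:", paste(miss, collapse = ", ")))
      if ("bare_ground_pct" %in% names(x) &&
          any(x$bare_ground_pct < 0 | x$bare_ground_pct > 100, na.rm = TRUE))
        flag(f, "bare_ground_pct outside [0, 100]")
      if ("conifer_proportion" %in% names(x) &&
          any(x$conifer_proportion < 0 | x$conifer_proportion > 1, na.rm = TRUE))
        flag(f, "conifer_proportion outside [0, 1]")
      if ("basal_area_m2_ha" %in% names(x) &&
          any(x$basal_area_m2_ha < 0, na.rm = TRUE))
        flag(f, "negative basal_area_m2_ha")
      if ("stems_per_900m2" %in% names(x) &&
          any(x$stems_per_900m2 < 0, na.rm = TRUE))
        flag(f, "negative stems_per_900m2")
    }
  }
  if (!is.null(paths$metrics)) {
    f <- paths$metrics
    if (!file.exists(f)) flag(f, "file does not exist") else {
      x <- read.csv(f)
      nonnum <- names(x)[!vapply(x, is.numeric, logical(1))]
      nonnum <- setdiff(nonnum, "pixel_id")
      if (length(nonnum))
        flag(f, paste("non-numeric metric columns:",
                      paste(nonnum, collapse = ", ")))
    }
  }
  if (!is.null(paths$rasters) && length(paths$rasters) > 1) {
    shapes <- lapply(paths$rasters, function(f) {
      if (!file.exists(f)) { flag(f, "file does not exist"); return(NULL) }
      dim(as.matrix(read.csv(f, header = FALSE)))
    })
    shapes <- Filter(Negate(is.null), shapes)
    if (length(shapes) > 1) {
      ref <- shapes[[1]]
      for (i in seq_along(shapes)[-1]) {
        if (!identical(shapes[[i]], ref))
          flag(paths$rasters[i],
               paste0("raster shape ", paste(shapes[[i]], collapse = "x"),
                      " differs from ", paths$rasters[1], " (",
                      paste(ref, collapse = "x"), ")"))
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(file = character(0), problem = character(0))
}
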