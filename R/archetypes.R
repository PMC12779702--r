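#' Default structural recovery group archetypes
#'
#' Each archetype couples a structural trajectory (per-epoch means for stem
#' density, bare ground, basal area and conifer proportion) with a spectral
#' trajectory family `value(t) = pre - drop * exp(-rate * t)` for every index
#' (`t` = years since fire). Anchor values for the structural means are the
#' group averages reported for this study system: mixed growth 48% deciduous
#' at epoch 5-7 and 7.9% bare ground later on; regrowth delay 75% bare ground
#' at 8-9 and 10,500 stems/ha at 15-16; regenerative conifer 84% conifer
#' cover at 8-9 and 15,035 stems/ha at year 21; conifer-dominant mixed growth
#' 5,500 stems/ha at 15-16 and 0.07 m2/ha basal area at year 21. Stem
#' densities are stored per 900 m2 (stems/ha x 0.09). Cells between anchors
#' are smooth interpolations. Mixed growth has no epoch-21 entry: that group
#' is absent from areas sampled 21 years post-fire.
#'
#' @return Named list of four `group_archetype` objects.
#' @export
default_archetypes <- function() {
  ep <- EPOCH_LEVELS
  sm <- function(stems, bare, ba, con, epochs = ep) {
    data.frame(
      epoch = epochs,
      stems_per_900m2 = stems,
      bare_ground_pct = bare,
      basal_area_m2_ha = ba,
      conifer_proportion = con,
      stringsAsFactors = FALSE
    )
  }
  # Spectral params: per-index pre-fire plateau; drop = pre * 0.75 * severity
  # multiplier except NBR, set explicitly so dNBR clears the BARC-A screen
  # for every group. Regenerative conifer has the fastest expected recovery
  # slope and regrowth delay the slowest; conifer-dominant mixed carries the
  # greatest dNBR burn severity. Severity/rate combinations are spread so
  # the four groups form balanced, spectrally distinct clusters at the
  # default index noise (the planted separation a distortion-elbow scan can
  # recover).
  pre <- c(NDVI = 0.78, NDMI = 0.38, NBR = 0.70, TCB = 0.45,
           TCW = 0.15, TCG = 0.35, TCA = 0.40)
  sp <- function(sev, rate, nbr_drop, nbr_rate = rate) {
    d <- data.frame(
      index = SPECTRAL_INDICES,
      pre = unname(pre[SPECTRAL_INDICES]),
      drop = unname(pre[SPECTRAL_INDICES]) * 0.75 * sev,
      rate = rate,
      stringsAsFactors = FALSE
    )
    d$drop[d$index == "NBR"] <- nbr_drop
    d$rate[d$index == "NBR"] <- nbr_rate
    d
  }
  arch <- list(
    regenerative_conifer = list(
      group_label = "regenerative_conifer",
      structure_means = sm(
        stems = c(400, 700, 950, 1200, 1353),
        bare = c(30, 20, 12, 8, 5),
        ba = c(1, 3, 6, 10, 15),
        con = c(0.70, 0.84, 0.88, 0.90, 0.92)
      ),
      spectral_params = sp(sev = 1.00, rate = 0.60, nbr_drop = 0.80)
    ),
    regrowth_delay = list(
      group_label = "regrowth_delay",
      structure_means = sm(
        stems = c(150, 200, 500, 945, 800),
        bare = c(70, 75, 55, 30, 20),
        ba = c(0.3, 0.8, 2, 5, 8),
        con = c(0.50, 0.60, 0.75, 0.85, 0.90)
      ),
      spectral_params = sp(sev = 0.97, rate = 0.05, nbr_drop = 0.58)
    ),
    mixed_growth = list(
      group_label = "mixed_growth",
      structure_means = sm(
        stems = c(800, 600, 650, 700),
        bare = c(15, 12, 9, 7.9),
        ba = c(2, 4, 7, 11),
        con = c(0.52, 0.55, 0.60, 0.62),
        epochs = ep[ep != "21"]
      ),
      spectral_params = sp(sev = 0.62, rate = 0.18, nbr_drop = 0.62)
    ),
    conifer_dominant_mixed = list(
      group_label = "conifer_dominant_mixed",
      structure_means = sm(
        stems = c(300, 350, 420, 495, 520),
        bare = c(35, 28, 20, 15, 10),
        ba = c(0.02, 0.03, 0.05, 0.06, 0.07),
        con = c(0.60, 0.65, 0.70, 0.72, 0.75)
      ),
      spectral_params = sp(sev = 1.08, rate = 0.32, nbr_drop = 0.68, nbr_rate = 0.14)
    )
  )
  lapply(arch, validate_archetype)
}

validate_archetype <- function(a) {
  stopifnot(
    is.character(a$group_label),
    a$group_label %in% GROUP_LEVELS,
    all(STRUCTURE_VARS %in% names(a$structure_means)),
    all(a$structure_means$epoch %in% EPOCH_LEVELS)
  )
  m <- a$structure_means
  if (any(m$bare_ground_pct < 0 | m$bare_ground_pct > 100))
    stop("bare_ground_pct means outside [0, 100] for ", a$group_label)
  if (any(m$conifer_proportion < 0 | m$conifer_proportion > 1))
    stop("conifer_proportion means outside [0, 1] for ", a$group_label)
  if (any(m$basal_area_m2_ha < 0) || any(m$stems_per_900m2 < 0))
    stop("negative structure means for ", a$group_label)
  want <- if (a$group_label == "mixed_growth") setdiff(EPOCH_LEVELS, "21") else EPOCH_LEVELS
  if (!setequal(m$epoch, want))
    stop("archetype ", a$group_label, " must define epochs: ", paste(want, collapse = ", "))
  if (any(a$spectral_params$drop >= a$spectral_params$pre + 1))
    stop("spectral drop implausibly large for ", a$group_label)
  class(a) <- "group_archetype"
  a
}

#' Closed-form expected recovery metrics for an archetype
#'
#' Under the noise-free trajectory `value(t) = pre - drop * exp(-rate * t)`
#' the recovery metrics have closed forms: year-5 value
#' `pre - drop e^{-5r}`; regrowth magnitude (year-5 minus the post-fire
#' minimum, attained at year 1) `drop (e^{-r} - e^{-5r})`; median yearly slope
#' over post-fire years 1..5 is the median of four decreasing consecutive
#' differences, i.e. the mean of the 2nd and 3rd:
#' `drop (1 - e^{-r}) (e^{-2r} + e^{-3r}) / 2`; and dNBR (pre-fire NBR minus
#' the minimum of post-fire years 1-2) `drop_NBR e^{-r_NBR}`. These serve as
#' independent oracles for the metric implementations.
#'
#' @param archetype A `group_archetype`.
#' @return List with per-index data frame of expected
#'   `magnitude`/`slope`/`year5` and the scalar expected `dnbr`.
#' @export
archetype_expected_metrics <- function(archetype) {
  p <- archetype$spectral_params
  e1 <- exp(-p$rate); e2 <- exp(-2 * p$rate); e3 <- exp(-3 * p$rate); e5 <- exp(-5 * p$rate)
  out <- data.frame(
    index = p$index,
    magnitude = p$drop * (e1 - e5),
    slope = p$drop * (1 - e1) * (e2 + e3) / 2,
    year5 = p$pre - p$drop * e5,
    stringsAsFactors = FALSE
  )
  nbr <- p[p$index == "NBR", ]
  list(metrics = out, dnbr = nbr$drop * exp(-nbr$rate))
}

#' Default chronosequence noise model
#'
#' Per-variable SD functions of the cell mean used by
#' [generate_structure_chronosequence()]. The within-group structural
#' variance is not reported for the study system; these are free parameters
#' chosen to be realistic for lidar-modelled stand structure (roughly 20%
#' CVs, a few percentage points of cover).
#'
#' @return Named list of functions mean -> SD.
#' @export
structure_noise_defaults <- function() {
  list(
    stems_per_900m2 = function(mu) 0.20 * mu + 10,
    bare_ground_pct = function(mu) rep(6, length(mu)),
    basal_area_m2_ha = function(mu) 0.15 * mu + 0.05,
    conifer_proportion = function(mu) rep(0.06, length(mu))
  )
}
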