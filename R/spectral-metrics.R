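#' Burn severity: differenced normalized burn ratio
#'
#' dNBR is the NBR value the year before the fire minus the lowest NBR value
#' in the two subsequent post-fire years; positive when the fire depressed
#' NBR.
#'
#' @param series A `spectral_series_set`.
#' @return Numeric vector, one severity value per pixel.
#' @export
compute_dnbr <- function(series) {
  pre <- series_value(series, "NBR", -1, "compute_dnbr")
  y1 <- series_value(series, "NBR", 1, "compute_dnbr")
  y2 <- series_value(series, "NBR", 2, "compute_dnbr")
  pre - pmin(y1, y2)
}

#' Convert dNBR to a BARC-A severity value
#'
#' Burned Area Reflectance Classification - Adjustable values live on a
#' 0-255 integer scale. The conversion is the common linear rescale
#' `clamp(round((dnbr * 1000 + offset) / scale), 0, 255)`; the defaults
#' (offset 275, scale 5) make a dNBR of 0.375 land exactly on the 130
#' screening threshold. Rounding is half-away-from-zero so results do not
#' depend on floating-point parity.
#'
#' @param dnbr Numeric severity values (finite).
#' @param offset,scale Linear mapping parameters; `scale` must be > 0.
#' @return Integer vector in 0..255.
#' @export
to_barc_a <- function(dnbr, offset = 275, scale = 5) {
  if (scale <= 0) stop("scale must be > 0")
  if (any(!is.finite(dnbr))) stop("dnbr must be finite")
  as.integer(clamp(round_half_up((dnbr * 1000 + offset) / scale), 0, 255))
}

#' High/moderate severity screen on BARC-A values
#'
#' Pixels at or above the minimum BARC-A threshold (default 130) are kept;
#' the threshold is inclusive.
#'
#' @param barc Integer BARC-A values in 0..255.
#' @param threshold Minimum value to include.
#' @return Logical inclusion flags.
#' @export
severity_screen <- function(barc, threshold = 130) {
  if (any(barc < 0 | barc > 255)) stop("BARC-A values must lie in 0..255")
  barc >= threshold
}

#' Regrowth magnitude of one spectral index
#'
#' The index value five years after the fire minus the post-fire minimum
#' over years 1..5: the total spectral recovery achieved in the first five
#' post-fire years.
#'
#' @param series A `spectral_series_set`.
#' @param index One of the seven index names.
#' @return Numeric vector per pixel.
#' @export
regrowth_magnitude <- function(series, index) {
  vals <- vapply(1:5, function(k)
    series_value(series, index, k, "regrowth_magnitude"),
    numeric(length(series$pixel_id)))
  vals <- matrix(vals, ncol = 5)
  vals[, 5] - apply(vals, 1, min)
}

#' Median yearly rate of spectral change
#'
#' Median of the four consecutive first differences of the index over
#' post-fire years 1..5.
#'
#' @inheritParams regrowth_magnitude
#' @return Numeric vector per pixel (index units per year).
#' @export
median_slope <- function(series, index) {
  vals <- vapply(1:5, function(k)
    series_value(series, index, k, "median_slope"),
    numeric(length(series$pixel_id)))
  vals <- matrix(vals, ncol = 5)
  apply(vals[, 2:5, drop = FALSE] - vals[, 1:4, drop = FALSE], 1, median)
}

#' Index value five years post-fire
#'
#' @inheritParams regrowth_magnitude
#' @return Numeric vector per pixel.
#' @export
year5_value <- function(series, index) {
  series_value(series, index, 5, "year5_value")
}

#' Assemble the 22 clustering metrics for every pixel
#'
#' Three metrics (regrowth magnitude, median slope, year-5 value) for each
#' of the seven indices, plus dNBR: 22 columns.
#'
#' @param series A `spectral_series_set`.
#' @return Numeric matrix `n x 22` with rownames the pixel ids.
#' @export
compute_metric_matrix <- function(series) {
  cols <- list()
  for (idx in SPECTRAL_INDICES) {
    cols[[paste0(idx, "_magnitude")]] <- regrowth_magnitude(series, idx)
    cols[[paste0(idx, "_slope")]] <- median_slope(series, idx)
    cols[[paste0(idx, "_year5")]] <- year5_value(series, idx)
  }
  cols[["dnbr"]] <- compute_dnbr(series)
  m <- do.call(cbind, cols)
  rownames(m) <- series$pixel_id
  m
}

#' Standardize metric columns to zero mean and unit population SD
#'
#' Stores the per-feature mean and population SD so the identical transform
#' can be applied to held-out pixels and inverted exactly.
#'
#' @param m Numeric matrix (>= 2 rows).
#' @return List of class `metric_standardization`: `scores` (standardized
#'   matrix, attribute `standardized = TRUE`), `center`, `scale`.
#' @export
standardize_metrics <- function(m) {
  if (nrow(m) < 2) stop("need at least 2 rows to standardize")
  center <- colMeans(m)
  scale <- sqrt(colMeans(sweep(m, 2, center)^2))
  if (any(scale == 0)) {
    bad <- colnames(m)[scale == 0][1]
    stop("feature has zero standard deviation: ", bad)
  }
  z <- sweep(sweep(m, 2, center), 2, scale, "/")
  attr(z, "standardized") <- TRUE
  structure(list(scores = z, center = center, scale = scale),
            class = "metric_standardization")
}

#' Apply (or invert) a stored standardization to new data
#'
#' @param record A `metric_standardization`.
#' @param m Matrix with the same columns as the training data.
#' @param invert If `TRUE`, map standardized scores back to raw units.
#' @return Transformed matrix.
#' @export
standardize_apply <- function(record, m, invert = FALSE) {
  stopifnot(inherits(record, "metric_standardization"))
  m <- m[, names(record$center), drop = FALSE]
  if (invert) {
    sweep(sweep(m, 2, record$scale, "*"), 2, record$center, "+")
  } else {
    z <- sweep(sweep(m, 2, record$center), 2, record$scale, "/")
    attr(z, "standardized") <- TRUE
    z
  }
}
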