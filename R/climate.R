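#' Post-fire climate anomaly z-score
#'
#' Standardizes the extreme (minimum or maximum) of a climate variable over
#' the first five post-fire years against the 1981-2010 normal:
#' `z = (extremum - normal_mean) / normal_sd`. A min-kind anomaly of a
#' series with one very dry/cold year is negative regardless of the other
#' years; the z is invariant to affine unit changes applied consistently to
#' the values and the normal.
#'
#' @param yearly Numeric length-5 vector, or an `n x 5` matrix (rows =
#'   pixels), of the variable's values in post-fire years 1..5.
#' @param normal_mean Climate normal mean (scalar or length-n).
#' @param normal_sd Interannual SD of the normal period; must be > 0.
#' @param kind `"min"` or `"max"`: which extreme the anomaly tracks.
#' @return Numeric z-score(s).
#' @export
climate_anomaly <- function(yearly, normal_mean, normal_sd,
                            kind = c("min", "max")) {
  kind <- match.arg(kind)
  if (any(normal_sd <= 0)) stop("normal_sd must be > 0")
  if (is.matrix(yearly)) {
    if (ncol(yearly) != 5) stop("exactly 5 post-fire years required")
    ext <- if (kind == "min") do.call(pmin, as.data.frame(yearly))
           else do.call(pmax, as.data.frame(yearly))
  } else {
    if (length(yearly) != 5) stop("exactly 5 post-fire years required")
    ext <- if (kind == "min") min(yearly) else max(yearly)
  }
  (ext - normal_mean) / normal_sd
}

#' Mean pre-fire basal area
#'
#' Arithmetic mean of basal area over the five years preceding the fire
#' (fire_year - 5 .. fire_year - 1). Years at or after the fire never enter
#' the mean.
#'
#' @param ba_by_year Numeric vector of BA (m2/ha) named by calendar year.
#' @param fire_year Fire year.
#' @return Mean pre-fire BA (m2/ha).
#' @export
prefire_ba <- function(ba_by_year, fire_year) {
  want <- as.character(seq(fire_year - 5, fire_year - 1))
  missing <- setdiff(want, names(ba_by_year))
  if (length(missing))
    stop("missing pre-fire BA for year(s): ", paste(missing, collapse = ", "))
  mean(ba_by_year[want])
}

#' Modal pre-fire class
#'
#' Most common class over the five pre-fire years; ties break to the class
#' observed in the most recent pre-fire year among the tied classes.
#'
#' @param classes_by_year Character/factor vector named by calendar year.
#' @param fire_year Fire year.
#' @return The modal class (character).
#' @export
prefire_mode <- function(classes_by_year, fire_year) {
  want <- as.character(seq(fire_year - 5, fire_year - 1))
  missing <- setdiff(want, names(classes_by_year))
  if (length(missing))
    stop("missing pre-fire class for year(s): ", paste(missing, collapse = ", "))
  cls <- as.character(classes_by_year[want])
  counts <- table(cls)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1) return(tied)
  for (yr in rev(want)) {                     # most recent year first
    if (cls[match(yr, want)] %in% tied) return(cls[match(yr, want)])
  }
  tied[1]
}
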