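#' Construct a set of per-pixel annual spectral index series
#'
#' Series are stored on a relative year axis spanning fire_year - 1 to
#' fire_year + 5, the window every recovery metric operates on. Values may
#' be `NA`; metric functions fail with the offending year named.
#'
#' @param pixel_id Integer vector of pixel ids.
#' @param fire_year Integer vector of fire years (one per pixel).
#' @param arrays Named list over the seven indices; each element an
#'   `n x 7` numeric matrix with columns named `-1` .. `5` (years relative
#'   to the fire year).
#' @return A `spectral_series_set`.
#' @export
spectral_series_set <- function(pixel_id, fire_year, arrays) {
  rel <- -1:5
  if (!setequal(names(arrays), SPECTRAL_INDICES))
    stop("arrays must cover exactly the indices: ",
         paste(SPECTRAL_INDICES, collapse = ", "))
  n <- length(pixel_id)
  stopifnot(length(fire_year) == n)
  arrays <- arrays[SPECTRAL_INDICES]
  for (idx in SPECTRAL_INDICES) {
    m <- arrays[[idx]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != length(rel))
      stop("index ", idx, ": expected an ", n, " x ", length(rel), " matrix")
    if (is.null(colnames(m)) || !identical(colnames(m), as.character(rel)))
      stop("index ", idx, ": columns must be named ",
           paste(rel, collapse = ", "))
    arrays[[idx]] <- m
  }
  structure(
    list(pixel_id = as.integer(pixel_id), fire_year = as.integer(fire_year),
         rel_years = rel, values = arrays),
    class = "spectral_series_set"
  )
}

#' Construct a single-pixel spectral series from calendar-year values
#'
#' @param pixel_id Pixel id.
#' @param fire_year Calendar fire year.
#' @param values Named list over the seven indices, each a numeric vector
#'   named by calendar year. Years must be contiguous where present; years
#'   outside fire_year - 1 .. fire_year + 5 are ignored, absent years within
#'   the window become `NA` (metric functions then fail naming them).
#' @return A `spectral_series_set` of size one.
#' @export
spectral_series <- function(pixel_id, fire_year, values) {
  rel <- -1:5
  arrays <- setNames(
    lapply(SPECTRAL_INDICES, function(idx) {
      v <- values[[idx]]
      out <- matrix(NA_real_, 1, length(rel),
                    dimnames = list(NULL, as.character(rel)))
      if (!is.null(v)) {
        yrs <- as.integer(names(v))
        if (length(yrs) > 1 && any(diff(sort(yrs)) != 1))
          stop("index ", idx, ": years must be contiguous")
        for (j in seq_along(rel)) {
          hit <- which(yrs == fire_year + rel[j])
          if (length(hit)) out[1, j] <- v[hit]
        }
      }
      out
    }),
    SPECTRAL_INDICES
  )
  spectral_series_set(pixel_id, fire_year, arrays)
}

#' @export
print.spectral_series_set <- function(x, ...) {
  cat("spectral_series_set:", length(x$pixel_id), "pixels,",
      length(SPECTRAL_INDICES), "indices, relative years",
      min(x$rel_years), "..", max(x$rel_years), "\n")
  invisible(x)
}

# Pull the column of relative year k for one index, failing loudly on NA.
series_value <- function(set, index, k, what) {
  m <- set$values[[index]]
  col <- match(as.character(k), colnames(m))
  v <- unname(m[, col])
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop(what, ": missing ", index, " value for year fire_year",
         if (k >= 0) "+" else "", k, " (pixel ", set$pixel_id[bad], ")")
  }
  v
}
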