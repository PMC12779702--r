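#' Topographic position index of a 3x3 window
#'
#' Centre elevation minus the mean of the eight neighbours. Positive on
#' ridges and knolls, negative in depressions, zero on flats and uniform
#' slopes (translation-invariant).
#'
#' @param window 3x3 numeric matrix of elevations (finite).
#' @return TPI in elevation units.
#' @export
tpi <- function(window) {
  stopifnot(is.matrix(window), all(dim(window) == c(3, 3)),
            all(is.finite(window)))
  window[2, 2] - mean(window[-5])
}

#' Topographic position index over a full elevation raster
#'
#' Edge pixels use the available neighbours only and are flagged in the
#' `edge` attribute.
#'
#' @param elev Elevation matrix.
#' @return Matrix of TPI values with a logical `edge` attribute.
#' @export
tpi_raster <- function(elev) {
  nr <- nrow(elev); nc <- ncol(elev)
  s <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    s[rs - dr, cs - dc] <- s[rs - dr, cs - dc] + elev[rs, cs]
    cnt[rs - dr, cs - dc] <- cnt[rs - dr, cs - dc] + 1
  }
  out <- elev - s / cnt
  edge <- matrix(FALSE, nr, nc)
  edge[c(1, nr), ] <- TRUE; edge[, c(1, nc)] <- TRUE
  attr(out, "edge") <- edge
  out
}

#' Transformed aspect (TRASP)
#'
#' Rescales aspect so 0 falls on the coolest (north-north-east, 30 degree)
#' aspects and 1 on the hottest south-south-west aspects:
#' `(1 - cos((aspect - 30) * pi / 180)) / 2`.
#'
#' @param aspect_degrees Aspect in degrees clockwise from north, in
#'   `[0, 360)`; `NA` for flat cells (propagated).
#' @return Values in `[0, 1]`.
#' @export
trasp <- function(aspect_degrees) {
  ok <- is.na(aspect_degrees) |
    (aspect_degrees >= 0 & aspect_degrees < 360)
  if (!all(ok)) stop("aspect must lie in [0, 360)")
  (1 - cos((aspect_degrees - 30) * pi / 180)) / 2
}

#' D8 flow direction of a 3x3 window
#'
#' Steepest-descent direction over the eight neighbours, encoded as powers
#' of two clockwise from east (E=1, SE=2, S=4, SW=8, W=16, NW=32, N=64,
#' NE=128); diagonal drops are divided by sqrt(2). Ties break to the
#' smallest code; a centre with no downhill neighbour (pit or flat) is 0.
#'
#' @param window 3x3 numeric elevation matrix; non-finite neighbours are
#'   ignored (supports grid edges).
#' @return Integer direction code.
#' @export
flow_direction <- function(window) {
  stopifnot(is.matrix(window), all(dim(window) == c(3, 3)))
  centre <- window[2, 2]
  if (!is.finite(centre)) stop("centre elevation must be finite")
  # order = increasing code: E, SE, S, SW, W, NW, N, NE
  nb_r <- c(2, 3, 3, 3, 2, 1, 1, 1)
  nb_c <- c(3, 3, 2, 1, 1, 1, 2, 3)
  codes <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
  dists <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  best <- 0; best_code <- 0L
  for (i in 1:8) {
    nb <- window[nb_r[i], nb_c[i]]
    if (!is.finite(nb)) next
    drop <- (centre - nb) / dists[i]
    if (drop > best) { best <- drop; best_code <- codes[i] }  # strict: ties keep smaller code
  }
  best_code
}

#' D8 flow direction raster
#'
#' @param elev Elevation matrix; cells outside the grid are ignored.
#' @return Integer matrix of D8 codes (0 = pit/flat).
#' @export
flow_direction_raster <- function(elev) {
  nr <- nrow(elev); nc <- ncol(elev)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- elev
  nb_dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
  nb_dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  codes <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
  dists <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  best <- matrix(0, nr, nc)
  out <- matrix(0L, nr, nc)
  for (i in 1:8) {
    nb <- pad[2:(nr + 1) + nb_dr[i], 2:(nc + 1) + nb_dc[i]]
    drop <- (elev - nb) / dists[i]
    better <- !is.na(drop) & drop > best
    best[better] <- drop[better]
    out[better] <- codes[i]
  }
  out
}

#' Aspect raster from elevation (degrees clockwise from north)
#'
#' Central differences with replicated edges; flat cells (negligible
#' gradient) are `NA`.
#'
#' @param elev Elevation matrix (row 1 = north edge).
#' @param cellsize Pixel size in the elevation's horizontal units.
#' @return Matrix of aspect in `[0, 360)` degrees.
#' @export
aspect_raster <- function(elev, cellsize = 30) {
  nr <- nrow(elev); nc <- ncol(elev)
  east <- elev[, c(2:nc, nc)]; west <- elev[, c(1, 1:(nc - 1))]
  south <- elev[c(2:nr, nr), ]; north <- elev[c(1, 1:(nr - 1)), ]
  dzdx <- (east - west) / (2 * cellsize)     # gradient toward east
  dzdy <- (north - south) / (2 * cellsize)   # gradient toward north
  asp <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  asp[abs(dzdx) < 1e-12 & abs(dzdy) < 1e-12] <- NA
  asp
}
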