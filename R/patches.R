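# 8-connected component labelling by iterated neighbour-min propagation.
# Compact fire blobs converge in O(diameter) vectorized passes.
label_patches <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(NA_real_, nr, nc)
  lab[mask] <- which(mask)
  if (!any(mask)) return(lab)
  repeat {
    pad <- matrix(Inf, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- ifelse(is.na(lab), Inf, lab)
    best <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
      upd <- mask & is.finite(nb) & (is.na(best) | nb < best)
      best[upd] <- nb[upd]
    }
    if (identical(best, lab)) break
    lab <- best
  }
  # densify labels in first-occurrence (smallest index) order
  ids <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], ids)
  lab
}

# 1-D squared distance transform (lower envelope of parabolas).
dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Exact squared Euclidean distance (in pixels) to the nearest TRUE cell.
# Felzenszwalb-Huttenlocher two-pass transform; Inf replaced by a large
# finite sentinel so rows without sources still combine correctly.
distance_transform_sq <- function(source) {
  nr <- nrow(source); nc <- ncol(source)
  BIG <- 1e15
  if (nr > 1) {
    up <- matrix(Inf, nr, nc); up[source] <- 0
    for (r in 2:nr) up[r, ] <- pmin(up[r, ], up[r - 1, ] + 1)
    dn <- matrix(Inf, nr, nc); dn[source] <- 0
    for (r in (nr - 1):1) dn[r, ] <- pmin(dn[r, ], dn[r + 1, ] + 1)
    colpix <- pmin(up, dn)
  } else {
    colpix <- matrix(Inf, nr, nc); colpix[source] <- 0
  }
  d <- pmin(colpix^2, BIG)
  for (r in seq_len(nr)) d[r, ] <- dt1d(d[r, ])
  d
}

#' Patch size and distance to live edge for one fire-year mask
#'
#' Patches are the 8-connected components of burned pixels sharing one fire
#' year. Patch size is the component pixel count converted to hectares;
#' distance to the live edge is the exact Euclidean distance from a burned
#' pixel centre to the nearest unburned pixel centre (pixels burned in other
#' fire years count as unburned for this metric).
#'
#' @param mask Logical matrix, `TRUE` = burned in this fire year.
#' @param pixel_size_m Pixel edge length in metres.
#' @return List of matrices aligned with `mask`: `patch_id` (dense component
#'   ids, `NA` off-mask), `patch_ha`, `edge_m` (`Inf`, with a warning, if no
#'   unburned pixel exists).
#' @export
patch_metrics <- function(mask, pixel_size_m = 30) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- label_patches(mask)
  patch_ha <- matrix(NA_real_, nrow(mask), ncol(mask))
  if (any(mask)) {
    counts <- table(lab[mask])
    patch_ha[mask] <- as.numeric(counts[as.character(lab[mask])]) *
      pixel_size_m^2 / 1e4
  }
  edge_m <- matrix(NA_real_, nrow(mask), ncol(mask))
  if (any(mask)) {
    if (all(mask)) {
      warning("mask has no unburned pixel; edge distance is infinite")
      edge_m[mask] <- Inf
    } else {
      d2 <- distance_transform_sq(!mask)
      edge_m[mask] <- sqrt(d2[mask]) * pixel_size_m
    }
  }
  list(patch_id = lab, patch_ha = patch_ha, edge_m = edge_m)
}
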