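# Squared Euclidean distances between n points and k centroids (n x k).
dist2_to_centroids <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d <- matrix(xx, nrow(x), nrow(centers)) -
    2 * tcrossprod(x, centers) +
    matrix(cc, nrow(x), nrow(centers), byrow = TRUE)
  pmax(d, 0)
}

#' k-means++ seeding
#'
#' The first centroid is drawn uniformly from the points; each subsequent
#' centroid is drawn with probability proportional to the squared distance
#' to the nearest centroid chosen so far (D^2 seeding). Deterministic given
#' the seed.
#'
#' @param x Numeric matrix of points (rows).
#' @param k Number of centroids; must not exceed the number of distinct
#'   points.
#' @param seed Integer seed, or `NULL` to draw from the current stream.
#' @return `k x ncol(x)` matrix of initial centroids.
#' @export
kmeanspp_seed <- function(x, k, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > nrow(unique(x)))
    stop("k exceeds the number of distinct points")
  draw <- function() {
    centers <- matrix(NA_real_, k, ncol(x))
    i <- sample.int(n, 1L)
    centers[1, ] <- x[i, ]
    if (k > 1) {
      d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
      for (j in 2:k) {
        i <- sample.int(n, 1L, prob = d2)
        centers[j, ] <- x[i, ]
        d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
      }
    }
    centers
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# One Lloyd descent from given initial centroids. Ties in nearest-centroid
# assignment break to the lowest cluster id; an emptied cluster is re-seeded
# at the point farthest from its assigned centroid.
lloyd <- function(x, centers, tol = 1e-8, max_iter = 100) {
  k <- nrow(centers)
  last_distortion <- Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    d <- dist2_to_centroids(x, centers)
    assign <- max.col(-d, ties.method = "first")
    for (pass in 1:k) {              # empty-cluster policy
      sizes <- tabulate(assign, k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      cur <- d[cbind(seq_len(nrow(x)), assign)]
      far <- which.max(cur)
      centers[empty[1], ] <- x[far, ]
      d <- dist2_to_centroids(x, centers)
      assign <- max.col(-d, ties.method = "first")
    }
    distortion <- sum(d[cbind(seq_len(nrow(x)), assign)])
    if (distortion > last_distortion + 1e-8 * (1 + last_distortion))
      stop("internal error: distortion increased during Lloyd iteration")
    new_centers <- centers
    for (c_id in seq_len(k)) {
      rows <- which(assign == c_id)
      if (length(rows)) new_centers[c_id, ] <- colMeans(x[rows, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol || iter >= max_iter) break
    last_distortion <- distortion
  }
  # final assignment/distortion for the converged centroids
  d <- dist2_to_centroids(x, centers)
  assign <- max.col(-d, ties.method = "first")
  distortion <- sum(d[cbind(seq_len(nrow(x)), assign)])
  list(centers = centers, cluster = assign, distortion = distortion, iter = iter)
}

#' Fit k-means with k-means++ seeding and multiple restarts
#'
#' Runs Lloyd iterations from `n_restarts` independent k-means++ seedings
#' and keeps the fit with the lowest distortion (total within-cluster
#' squared distance). Fully deterministic given `(x, k, seed, n_restarts)`.
#'
#' @param x Numeric matrix of points.
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed.
#' @param n_restarts Number of seeded restarts (default 10).
#' @param tol Centroid-shift convergence tolerance.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return A `spectral_kmeans` list: `k`, `centroids`, `distortion`,
#'   `cluster` (1-based assignments), `sizes`, `seed`, `n_restarts`.
#' @export
fit_kmeans <- function(x, k, seed = 1, n_restarts = 10, tol = 1e-8,
                       max_iter = 100) {
  x <- as.matrix(x)
  stopifnot(k >= 1)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_seed(x, k, seed = child_seed(seed, r))
    fit <- lloyd(x, centers, tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$distortion < best$distortion) best <- fit
  }
  structure(list(
    k = k, centroids = best$centers, distortion = best$distortion,
    cluster = best$cluster, sizes = tabulate(best$cluster, k),
    seed = seed, n_restarts = n_restarts
  ), class = "spectral_kmeans")
}

#' Choose k by the elbow of the distortion curve
#'
#' Fits every k on a grid and picks the elbow: the k maximizing the second
#' difference of the distortion curve. If some k reaches (numerically) zero
#' distortion, the smallest such k is chosen: the data are exactly k
#' distinct points. The full curve is returned so an analyst can audit and
#' override the choice.
#'
#' @param x Numeric matrix of points.
#' @param k_min,k_max Grid bounds (`k_min >= 2`); `k_max` is capped at the
#'   number of distinct points.
#' @param seed Integer seed.
#' @param ... Passed to [fit_kmeans()].
#' @return A `k_selection` list: `k`, `k_grid`, `distortions`, and the
#'   fitted model for the chosen k.
#' @export
select_k <- function(x, k_min = 2, k_max = 10, seed = 1, ...) {
  x <- as.matrix(x)
  stopifnot(k_min >= 2, k_max >= k_min, k_max < nrow(x))
  n_distinct <- nrow(unique(x))
  k_max <- min(k_max, n_distinct)
  k_grid <- seq.int(k_min, k_max)
  fits <- lapply(k_grid, function(k)
    fit_kmeans(x, k, seed = child_seed(seed, 100 + k), ...))
  d <- vapply(fits, `[[`, numeric(1), "distortion")
  if (any(!is.finite(d))) stop("non-finite distortion in k selection")
  eps <- 1e-10 * (d[1] + 1)
  if (any(d <= eps)) {
    k_star <- k_grid[which(d <= eps)[1]]
  } else if (length(k_grid) < 3) {
    k_star <- k_grid[which.min(d)]
  } else {
    inner <- 2:(length(k_grid) - 1)
    second_diff <- d[inner - 1] - 2 * d[inner] + d[inner + 1]
    k_star <- k_grid[inner][which.max(second_diff)]
  }
  structure(list(
    k = k_star, k_grid = k_grid, distortions = d,
    model = fits[[match(k_star, k_grid)]]
  ), class = "k_selection")
}

#' Exclude rare clusters
#'
#' Clusters holding strictly less than `min_frac` of the observations are
#' removed; their pixels are flagged excluded, not reassigned. Retained
#' clusters are relabelled densely (1..m) in decreasing size order (ties by
#' original id).
#'
#' @param cluster Integer vector of cluster assignments.
#' @param min_frac Minimum retained fraction (default 0.01, i.e. 1%).
#' @return A `cluster_assignment` list: `cluster` (new ids, `NA` for
#'   excluded), `excluded` (logical), `sizes` (new id -> count), `dropped`
#'   (original ids removed), `relabel` (original -> new id map).
#' @export
drop_rare_clusters <- function(cluster, min_frac = 0.01) {
  n <- length(cluster)
  ids <- sort(unique(cluster))
  sizes <- vapply(ids, function(i) sum(cluster == i), integer(1))
  rare <- sizes / n < min_frac
  if (all(rare)) stop("all clusters fall below min_frac; degenerate assignment")
  keep <- ids[!rare]
  ord <- keep[order(-sizes[!rare], keep)]
  relabel <- setNames(seq_along(ord), ord)
  new <- relabel[as.character(cluster)]
  excluded <- is.na(new)
  structure(list(
    cluster = unname(new), excluded = unname(excluded),
    sizes = setNames(vapply(seq_along(ord), function(i)
      sum(new == i, na.rm = TRUE), integer(1)), seq_along(ord)),
    dropped = ids[rare], relabel = relabel
  ), class = "cluster_assignment")
}
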