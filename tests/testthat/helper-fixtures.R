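# Shared fixtures and independent oracles for the test suite.

# Build a one-pixel spectral series where every index follows the same
# calendar-year value vector (names = years).
make_series <- function(values_by_year, fire_year = 2000, pixel_id = 1L) {
  v <- setNames(rep(list(values_by_year), length(SPECTRAL_INDICES)),
                SPECTRAL_INDICES)
  spectral_series(pixel_id, fire_year, v)
}

# Series with per-index values (list index -> named numeric by year).
make_series_multi <- function(values, fire_year = 2000, pixel_id = 1L) {
  spectral_series(pixel_id, fire_year, values)
}

SPECTRAL_INDICES <- c("NDVI", "NDMI", "NBR", "TCB", "TCW", "TCG", "TCA")

# Brute-force PERMANOVA pseudo-F from first principles: total and within
# sums of squared distances computed by explicit double loops.
brute_permanova_F <- function(dmat, labels) {
  n <- nrow(dmat)
  labels <- as.character(labels)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + dmat[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx))
        s <- s + dmat[idx[a], idx[b]]^2
    }
    ss_within <- ss_within + s / length(idx)
  }
  a <- length(unique(labels))
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# Exhaustive-permutation PERMANOVA p-value (small n only).
exhaustive_permanova_p <- function(dmat, labels) {
  n <- nrow(dmat)
  stopifnot(n <= 9)
  f_obs <- brute_permanova_F(dmat, labels)
  perms <- all_permutations(n)
  fs <- apply(perms, 1, function(p) brute_permanova_F(dmat, labels[p]))
  mean(fs >= f_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# Brute-force nearest-unburned Euclidean distance (pixel units).
brute_edge_dist <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(NA_real_, nr, nc)
  un <- which(!mask, arr.ind = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    out[i, j] <- if (nrow(un)) sqrt(min((un[, 1] - i)^2 + (un[, 2] - j)^2)) else Inf
  }
  out
}

# Planted Gaussian clusters: centres are scaled coordinate axes so all
# pairwise centre distances equal sep * sqrt(2).
make_planted_clusters <- function(n, k, dim = 22, sep = 3, sd = 0.05,
                                  seed = 1) {
  with_seed(seed, {
    centers <- matrix(0, k, dim)
    for (i in seq_len(k)) centers[i, i] <- sep
    lab <- rep(seq_len(k), length.out = n)
    x <- centers[lab, ] + matrix(rnorm(n * dim, sd = sd), n, dim)
    list(x = x, labels = lab, centers = centers)
  })
}

# Adjusted Rand index (independent of any clustering code under test).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ij <- sum_a * sum_b / n2
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}
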