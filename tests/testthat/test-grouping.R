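test_that("epoch binning follows the chronosequence windows", {
  expect_equal(as.character(assign_epoch(6)), "5-7")
  expect_equal(as.character(assign_epoch(21)), "21")
  expect_true(is.na(assign_epoch(10)))
  expect_true(is.na(assign_epoch(22)))
  expect_true(is.na(assign_epoch(4)))
  expect_equal(as.character(assign_epoch(c(5, 8, 11, 15, 16))),
               c("5-7", "8-9", "11-12", "15-16", "15-16"))
  expect_error(assign_epoch(-1), ">= 0")
})

make_samples <- function(vals, epoch = "5-7") {
  data.frame(
    pixel_id = seq_len(nrow(vals)), years_since_fire = 6, epoch = epoch,
    stems_per_900m2 = vals[, 1], bare_ground_pct = vals[, 2],
    basal_area_m2_ha = vals[, 3], conifer_proportion = vals[, 4]
  )
}

test_that("structural dissimilarity is a metric on within-epoch z-scores", {
  v <- with_seed(4, matrix(abs(rnorm(40, 10, 3)), 10, 4))
  v[, 4] <- v[, 4] / 20
  s <- make_samples(v)
  d <- as.matrix(structure_dissimilarity(s))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)

  # identical samples are at distance zero
  same <- make_samples(matrix(rep(c(10, 20, 5, 0.5), each = 4), 4, 4))
  dd <- structure_dissimilarity(same)
  expect_true(all(as.vector(dd) == 0))

  # two samples differing by one within-epoch SD in one variable -> distance 1
  stems <- c(0, 0, 1, 1, 0.5, 0.5)   # population SD of stems
  sdv <- sqrt(mean((stems - mean(stems))^2))
  v2 <- cbind(stems, 20, 5, 0.5)
  s2 <- make_samples(v2)
  d2 <- as.matrix(structure_dissimilarity(s2))
  expect_equal(d2[1, 3], abs(stems[1] - stems[3]) / sdv)

  expect_error(structure_dissimilarity(make_samples(v[1:3, ],
                                                    epoch = c("5-7", "5-7", "8-9"))),
               "8-9")
})

test_that("pseudo-F matches the brute-force partition and exhaustive p", {
  for (s in 1:4) {
    x <- with_seed(s, matrix(rnorm(12), 6, 2))
    x[4:6, ] <- x[4:6, ] + s %% 3          # varying separation
    dmat <- as.matrix(dist(x))
    labels <- rep(c("A", "B"), each = 3)
    res <- permanova(dmat, labels, n_permutations = 999, seed = s)
    f_brute <- brute_permanova_F(dmat, labels)
    expect_equal(res$pseudo_F, f_brute, tolerance = 1e-10)
    expect_equal(res$ss$total, res$ss$between + res$ss$within,
                 tolerance = 1e-9 * res$ss$total)
    p_exact <- exhaustive_permanova_p(dmat, labels)
    se <- sqrt(p_exact * (1 - p_exact) / 999)
    expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 999)
  }
})

test_that("pseudo-F is invariant to sample order and degenerate input is defined", {
  x <- with_seed(9, matrix(rnorm(40), 20, 2))
  labels <- rep(c("A", "B"), 10)
  dmat <- as.matrix(dist(x))
  r1 <- permanova(dmat, labels, n_permutations = 99, seed = 1)
  perm <- with_seed(2, sample.int(20))
  r2 <- permanova(dmat[perm, perm], labels[perm], n_permutations = 99, seed = 1)
  expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-10)
  expect_equal(r1$df_between, 1L)
  expect_equal(r1$df_within, 18L)

  # identical points: SS_total = 0 -> F := 0, p := 1
  z <- matrix(0, 8, 8)
  rz <- permanova(z, rep(c("A", "B"), 4), n_permutations = 99, seed = 1)
  expect_equal(rz$pseudo_F, 0)
  expect_equal(rz$p_value, 1)
})

test_that("permanova agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  x <- with_seed(7, matrix(rnorm(60), 20, 3))
  x[11:20, 1] <- x[11:20, 1] + 1.5
  labels <- rep(c("A", "B"), each = 10)
  d <- dist(x)
  mine <- permanova(as.matrix(d), labels, n_permutations = 999, seed = 3)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = labels),
                        permutations = 999)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-8)
})

test_that("pairwise post-hoc tests find the planted shifted cluster", {
  found <- 0
  for (s in 1:10) {
    x <- with_seed(s + 50, {
      rbind(matrix(rnorm(60), 30, 2),
            matrix(rnorm(60), 30, 2),
            matrix(rnorm(60, mean = 3), 30, 2))
    })
    labels <- rep(c("1", "2", "3"), each = 30)
    dmat <- as.matrix(dist(x))
    p <- posthoc_pairwise(dmat, labels, n_permutations = 199, seed = s)
    expect_equal(p, t(p))
    expect_true(all(diag(p) == 1))
    if (p["1", "2"] > 0.05 && p["1", "3"] <= 0.05 && p["2", "3"] <= 0.05)
      found <- found + 1
  }
  expect_gte(found, 9)
})

test_that("a pairwise test equals a two-group permanova on the subset", {
  x <- with_seed(21, matrix(rnorm(80), 40, 2))
  labels <- rep(c("1", "2", "3", "4"), each = 10)
  dmat <- as.matrix(dist(x))
  p <- posthoc_pairwise(dmat, labels, n_permutations = 199, seed = 77)
  sel <- labels %in% c("1", "2")
  direct <- permanova(dmat[sel, sel], labels[sel], n_permutations = 199,
                      seed = firestruct:::child_seed(77, 1))
  expect_equal(p["1", "2"], direct$p_value)
})

test_that("Bonferroni correction multiplies pairwise p, capped at one", {
  x <- with_seed(31, matrix(rnorm(60), 30, 2))
  labels <- rep(c("1", "2", "3"), each = 10)
  dmat <- as.matrix(dist(x))
  p_none <- posthoc_pairwise(dmat, labels, n_permutations = 99, seed = 5)
  p_bonf <- posthoc_pairwise(dmat, labels, n_permutations = 99, seed = 5,
                             correction = "bonferroni")
  m <- 3
  expect_equal(p_bonf["1", "2"], min(1, m * p_none["1", "2"]))
  expect_equal(p_bonf["2", "3"], min(1, m * p_none["2", "3"]))
})

test_that("cluster merging is by connected components with logged conflicts", {
  ids <- c("1", "2", "3", "4")
  p <- matrix(0.01, 4, 4, dimnames = list(ids, ids)); diag(p) <- 1
  p["1", "2"] <- p["2", "1"] <- 0.4
  mg <- merge_clusters(p)
  expect_equal(unname(mg$mapping), c(1L, 1L, 2L, 3L))

  p_all <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(p_all) <- 1
  expect_equal(length(merge_clusters(p_all)$groups), 1L)

  # non-transitive chain: 1-2 and 2-3 merge but 1-3 is distinct
  p2 <- matrix(0.01, 3, 3, dimnames = list(ids[1:3], ids[1:3])); diag(p2) <- 1
  p2["1", "2"] <- p2["2", "1"] <- 0.3
  p2["2", "3"] <- p2["3", "2"] <- 0.3
  expect_warning(mg2 <- merge_clusters(p2), "non-transitive")
  expect_equal(unname(mg2$mapping), c(1L, 1L, 1L))
  expect_equal(nrow(mg2$nontransitive), 1L)

  # missing p treated as distinct
  p3 <- matrix(NA_real_, 2, 2, dimnames = list(ids[1:2], ids[1:2])); diag(p3) <- 1
  expect_equal(length(merge_clusters(p3)$groups), 2L)
})
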