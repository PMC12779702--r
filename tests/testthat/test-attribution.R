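test_that("greedy distance thinning follows the stated rule", {
  # three collinear pixels 60 m apart, 90 m minimum, order 1-2-3
  coords <- cbind(c(0, 60, 120), c(0, 0, 0))
  got <- thin_by_distance(coords, order = 1:3, min_distance = 90)
  expect_identical(got, c(1L, 3L))
  # order 2 first blocks both neighbours
  got2 <- thin_by_distance(coords, order = c(2L, 1L, 3L), min_distance = 90)
  expect_identical(got2, 2L)
  # zero distance accepts everything
  expect_length(thin_by_distance(coords, min_distance = 0), 3)
})

test_that("stratified sampling hits targets and respects spacing", {
  set.seed(NULL)
  n <- 2000
  df <- with_seed(8, data.frame(
    group = sample(c("a", "b", "c", "d"), n, replace = TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1)),
    x = runif(n, 0, 6000), y = runif(n, 0, 6000)
  ))
  # inactive distance constraint: proportions match targets exactly
  s0 <- stratified_spatial_sample(df, sample_plan(fraction = 0.1,
                                                  min_distance_m = 0,
                                                  seed = 4))
  for (g in unique(df$group)) {
    got <- sum(df$group[c(s0$train, s0$test)] == g)
    expect_equal(got, round(0.1 * sum(df$group == g)))
  }
  # 70/30 split within stratum (to rounding)
  expect_equal(length(s0$train) + length(s0$test), sum(s0$achieved))
  expect_lt(abs(length(s0$train) / sum(s0$achieved) - 0.7), 0.05)

  # active constraint: all pairwise distances >= 90 m, train/test disjoint
  s1 <- stratified_spatial_sample(df, sample_plan(fraction = 0.05,
                                                  min_distance_m = 90,
                                                  seed = 4))
  sel <- c(s1$train, s1$test)
  expect_length(intersect(s1$train, s1$test), 0)
  dmin <- min(dist(cbind(df$x[sel], df$y[sel])))
  expect_gte(dmin, 90)

  # unfillable stratum warns and fills as far as possible
  df2 <- data.frame(group = "a", x = c(0, 10, 20, 30), y = 0)
  expect_warning(
    s2 <- stratified_spatial_sample(df2, sample_plan(fraction = 1,
                                                     min_distance_m = 90,
                                                     seed = 1)),
    "achieved")
  expect_lt(sum(s2$achieved), 4)
})

test_that("category forests detect a perfect predictor and stay at chance on noise", {
  n <- 800
  dat <- with_seed(3, {
    g <- factor(sample(c("w", "x", "y", "z"), n, replace = TRUE))
    data.frame(group = g,
               perfect = as.numeric(g),
               junk1 = rnorm(n), junk2 = rnorm(n))
  })
  fit <- fit_category_rf(dat, c("perfect", "junk1", "junk2"), seed = 1)
  expect_gt(fit$oob_accuracy, 0.95)
  expect_equal(names(which.max(fit$importance)), "perfect")
  expect_equal(unname(fit$importance_norm["perfect"]), 1)

  noise <- with_seed(4, data.frame(
    group = factor(rep(c("w", "x", "y", "z"), each = n / 4)),
    a = rnorm(n), b = rnorm(n), c = rnorm(n)
  ))
  fitn <- fit_category_rf(noise, c("a", "b", "c"), seed = 1)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(fitn$oob_accuracy - 0.25), 4 * se + 0.02)

  # determinism
  fit2 <- fit_category_rf(dat, c("perfect", "junk1", "junk2"), seed = 1)
  expect_identical(fit$oob_accuracy, fit2$oob_accuracy)
  expect_error(fit_category_rf(data.frame(group = factor("w"), a = 1), "a"),
               "single class")
})

test_that("driver consolidation applies the top-5 and floor rules", {
  imp <- list(
    big = setNames(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3), paste0("b", 1:7)),
    small = setNames(c(0.07, 0.04, 0.06), paste0("s", 1:3))
  )
  sel <- select_top_drivers(imp, max_n = 5, floor = 0.05)
  expect_equal(sum(sel$category == "big"), 5)       # exactly the 5 best
  expect_setequal(sel$feature[sel$category == "big"], paste0("b", 1:5))
  expect_setequal(sel$feature[sel$category == "small"], c("s1", "s3"))
  expect_equal(sel$feature[1], "b1")                # sorted by importance
  # a category with exactly max_n drivers contributes all of them
  imp2 <- list(five = setNames(seq(0.5, 0.1, by = -0.1), paste0("f", 1:5)))
  expect_equal(nrow(select_top_drivers(imp2)), 5)
  expect_error(select_top_drivers(list(empty = numeric(0))), "consolidation")
})

test_that("global forest evaluation reports the arithmetic-mean F-score", {
  n <- 600
  dat <- with_seed(12, {
    g <- factor(sample(c("p", "q", "r", "s"), n, replace = TRUE))
    data.frame(group = g,
               strong = as.numeric(g) + rnorm(n, sd = 0.2),
               weak = rnorm(n))
  })
  idx <- seq_len(400)
  fitg <- fit_global_rf(dat[idx, ], c("strong", "weak"), seed = 2, mtry = 2)
  ev <- evaluate_rf(fitg, dat[-idx, ])
  expect_gt(ev$accuracy, 0.9)
  expect_equal(unname(rowSums(ev$confusion)),
               unname(table(dat$group[-idx])), ignore_attr = TRUE)
  expect_equal(ev$f_score, (ev$precision + ev$recall) / 2)

  # precision 0.8 / recall 0.9 gives F = 0.85 under the arithmetic mean
  expect_equal(unname((0.8 + 0.9) / 2), 0.85)
  conf <- matrix(c(9, 1, 0, 0, 1, 9, 0, 0, 0, 2, 8, 0, 0, 0, 0, 10), 4, 4,
                 byrow = TRUE)
  prec <- diag(conf) / colSums(conf)
  rec <- diag(conf) / rowSums(conf)
  f_arith <- (prec + rec) / 2
  f_harm <- 2 * prec * rec / (prec + rec)
  expect_false(isTRUE(all.equal(f_arith, f_harm)))   # the two differ

  # perfect prediction limit
  perf <- fit_global_rf(dat[idx, ], "strong", seed = 3, mtry = 1,
                        splitrule = "gini", nodesize = 1)
  evp <- evaluate_rf(perf, dat[idx, ])   # resubstitution: sanity ceiling
  expect_gt(evp$accuracy, 0.99)
  expect_true(all(evp$f_score > 0.99))
  expect_true(all(ev$confusion >= 0))
})

test_that("OOB and external accuracy stay close on synthetic data", {
  n <- 1200
  dat <- with_seed(22, {
    g <- factor(sample(c("p", "q", "r", "s"), n, replace = TRUE))
    data.frame(group = g,
               d1 = as.numeric(g) + rnorm(n, sd = 0.8),
               d2 = as.numeric(g) * 0.5 + rnorm(n, sd = 1),
               d3 = rnorm(n), d4 = rnorm(n), d5 = rnorm(n))
  })
  idx <- seq_len(840)
  fitg <- fit_global_rf(dat[idx, ], paste0("d", 1:5), seed = 4)
  ev <- evaluate_rf(fitg, dat[-idx, ])
  expect_gte(fitg$oob_accuracy, ev$accuracy - 0.05)
})

test_that("partial dependence is flat for ignored drivers and conserves probability", {
  n <- 500
  dat <- with_seed(31, {
    g <- factor(sample(c("p", "q", "r"), n, replace = TRUE))
    data.frame(group = g,
               used = as.numeric(g) + rnorm(n, sd = 0.3),
               ignored = rnorm(n))
  })
  fitg <- fit_global_rf(dat, c("used", "ignored"), seed = 5, mtry = 2,
                        splitrule = "gini")
  pd_used <- partial_dependence(fitg, dat, "used", grid_size = 15)
  pd_ign <- partial_dependence(fitg, dat, "ignored", grid_size = 15)
  # probabilities sum to one across groups at every grid point
  sums <- tapply(pd_used$probability, pd_used$value, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # the informative driver moves the curves far more than the noise driver
  rng <- function(pd) max(tapply(pd$probability, pd$group,
                                 function(p) diff(range(p))))
  expect_gt(rng(pd_used), 5 * rng(pd_ign))

  # single-stump oracle: with one driver and depth-1 trees, the PDP value at
  # v must equal the direct prediction of any row with driver = v
  stump_dat <- with_seed(33, data.frame(
    group = factor(rep(c("lo", "hi"), each = 50)),
    x = c(rnorm(50, 0), rnorm(50, 10))
  ))
  stump <- fit_global_rf(stump_dat, "x", seed = 6, mtry = 1,
                         splitrule = "gini", nodesize = 1)
  stump$model <- ranger::ranger(
    dependent.variable.name = ".group",
    data = data.frame(x = stump_dat$x, .group = stump_dat$group),
    num.trees = 1, max.depth = 1, mtry = 1, probability = TRUE,
    seed = 6, num.threads = 1)
  pd <- partial_dependence(stump, stump_dat, "x", grid_size = 8)
  for (v in unique(pd$value)) {
    direct <- predict(stump$model, data = data.frame(x = v),
                      num.threads = 1)$predictions
    got <- pd$probability[pd$value == v]
    names(got) <- pd$group[pd$value == v]
    expect_equal(got[colnames(direct)], direct[1, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("end-to-end attribution is deterministic given the seed", {
  cfg <- landscape_config(grid_rows = 50, grid_cols = 50, n_fires = 8,
                          seed = 17)
  land <- generate_landscape(cfg)
  drv <- compute_drivers(land)
  coords <- cbind(land$truth$col * 30, land$truth$row * 30)
  plan <- sample_plan(fraction = 0.08, seed = 2)
  acfg <- attribution_config(ntree = 100, boruta_max_runs = 25,
                             boruta_ntree = 100, pdp_top = 2, pdp_grid = 5)
  r1 <- suppressWarnings(
    run_attribution(drv, land$truth$group, coords, plan, acfg, seed = 9))
  r2 <- suppressWarnings(
    run_attribution(drv, land$truth$group, coords, plan, acfg, seed = 9))
  expect_identical(r1$global$oob_accuracy, r2$global$oob_accuracy)
  expect_identical(r1$boruta$mean_importance, r2$boruta$mean_importance)
  expect_identical(r1$global$external$confusion, r2$global$external$confusion)
  expect_identical(r1$pdp, r2$pdp)
})
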