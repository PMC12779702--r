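small_cfg <- function(seed = 1, ...) {
  landscape_config(grid_rows = 40, grid_cols = 40, n_fires = 6,
                   burned_fraction = 0.6, seed = seed, ...)
}

test_that("the generator is deterministic and validates its config", {
  l1 <- generate_landscape(small_cfg(3))
  l2 <- generate_landscape(small_cfg(3))
  expect_identical(l1$truth, l2$truth)
  expect_identical(l1$rasters$elevation, l2$rasters$elevation)
  expect_identical(l1$climate$yearly, l2$climate$yearly)

  expect_error(landscape_config(grid_rows = 0), ">= 1")
  expect_error(landscape_config(pixel_size_m = 0), "pixel_size_m")
  expect_error(landscape_config(fire_year_range = c(2010, 2000)), "interval")
  expect_error(landscape_config(grid_rows = 10, grid_cols = 10,
                                n_fires = 500), "capacity")
})

test_that("domain closure holds for every generated field", {
  land <- generate_landscape(small_cfg(7))
  expect_true(all(is.finite(land$rasters$elevation)))
  expect_true(all(land$rasters$prefire_ba >= 0))
  expect_true(all(land$truth$fire_year >= 1985 & land$truth$fire_year <= 2017))
  expect_true(all(as.character(land$truth$group) %in%
                    c("regenerative_conifer", "regrowth_delay",
                      "mixed_growth", "conifer_dominant_mixed")))
  # only burned pixels appear in the truth table
  expect_true(all(!is.na(land$fire$fire_year[land$truth$pixel_id])))
  # every chronosequence epoch is represented among fire years
  ysf <- land$config$observation_year - land$truth$fire_year
  expect_true(all(c("5-7", "8-9", "11-12", "15-16", "21") %in%
                    as.character(assign_epoch(ysf))))
})

test_that("zero effects and zero assignment noise give the baseline group", {
  cfg <- small_cfg(5,
                   group_effects = list(regrowth_delay = c(0, 0),
                                        mixed_growth = c(0, 0),
                                        conifer_dominant_mixed = c(0, 0)),
                   noise_scales = list(group = 0))
  land <- generate_landscape(cfg)
  expect_true(all(as.character(land$truth$group) == "regenerative_conifer"))
})

test_that("a planted cold-summer effect concentrates regrowth delay in cold pixels", {
  cfg <- small_cfg(11,
                   group_effects = list(regrowth_delay = c(0, 6),
                                        mixed_growth = c(-2, 0.5),
                                        conifer_dominant_mixed = c(-2, 0.5)))
  land <- generate_landscape(cfg)
  tr <- land$truth
  cold <- tr$anom_coldest_summer_T < median(tr$anom_coldest_summer_T)
  frac_cold <- mean(tr$group[cold] == "regrowth_delay")
  frac_warm <- mean(tr$group[!cold] == "regrowth_delay")
  expect_gt(frac_cold, frac_warm)
  # per-pixel logistic oracle: the stored linear predictor matches a direct
  # evaluation of the planted rule
  p_rd <- -tr$anom_coldest_summer_T
  p_rd <- (p_rd - mean(p_rd)) / sqrt(mean((p_rd - mean(p_rd))^2))
  expect_equal(tr$eta_regrowth_delay, 0 + 6 * p_rd, tolerance = 1e-10)
})

test_that("planted-effect prevalence is monotone in the coefficient", {
  prev <- vapply(c(0, 2, 4), function(slope) {
    cfg <- small_cfg(13,
                     group_effects = list(regrowth_delay = c(-1, slope),
                                          mixed_growth = c(-2, 1),
                                          conifer_dominant_mixed = c(-2, 1)))
    mean(generate_landscape(cfg)$truth$group == "regrowth_delay")
  }, numeric(1))
  expect_true(all(diff(prev) >= 0))
})

test_that("spectral series generation honours archetypes and fails on gaps", {
  truth <- data.frame(pixel_id = 1:2, fire_year = 2000L,
                      group = c("regrowth_delay", "mixed_growth"))
  expect_error(
    generate_spectral_series(truth, default_archetypes()["regrowth_delay"]),
    "mixed_growth")
  ser <- generate_spectral_series(truth, noise_sd = 0, seed = 1)
  # pre-fire plateau then drop at the fire year
  nbr <- ser$values$NBR
  expect_true(all(nbr[, "-1"] > nbr[, "0"]))
  # expected slope ordering across groups matches the archetype table
  arch <- default_archetypes()
  slopes <- vapply(arch, function(a) {
    e <- archetype_expected_metrics(a)
    mean(e$metrics$slope)
  }, numeric(1))
  t4 <- data.frame(pixel_id = 1:4, fire_year = 2000L,
                   group = names(arch))
  ser4 <- generate_spectral_series(t4, arch, noise_sd = 0, seed = 1)
  obs <- vapply(seq_len(4), function(i) {
    mean(vapply(SPECTRAL_INDICES, function(ix) {
      sub <- ser4
      sub$values <- lapply(sub$values, function(m) m[i, , drop = FALSE])
      sub$pixel_id <- sub$pixel_id[i]; sub$fire_year <- sub$fire_year[i]
      median_slope(sub, ix)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(order(obs), order(slopes))
  # two groups, zero noise: the 22-metric vectors collapse to 2 points
  t2 <- data.frame(pixel_id = 1:40, fire_year = 2000L,
                   group = rep(c("regrowth_delay", "mixed_growth"), 20))
  m2 <- compute_metric_matrix(generate_spectral_series(t2, noise_sd = 0,
                                                       seed = 2))
  expect_equal(nrow(unique(round(m2, 12))), 2)
})

test_that("the chronosequence reproduces archetype means and the epoch gap", {
  arch <- default_archetypes()
  zero_noise <- list(
    stems_per_900m2 = function(mu) rep(0, length(mu)),
    bare_ground_pct = function(mu) rep(0, length(mu)),
    basal_area_m2_ha = function(mu) rep(0, length(mu)),
    conifer_proportion = function(mu) rep(0, length(mu))
  )
  chron <- generate_structure_chronosequence(NULL, arch, 5,
                                             noise = zero_noise, seed = 1)
  for (g in names(arch)) {
    for (ep in unique(chron$epoch[chron$group == g])) {
      mrow <- arch[[g]]$structure_means
      mrow <- mrow[mrow$epoch == ep, ]
      sub <- chron[chron$group == g & chron$epoch == ep, ]
      expect_equal(unique(sub$stems_per_900m2), mrow$stems_per_900m2)
      expect_equal(unique(sub$bare_ground_pct), mrow$bare_ground_pct)
    }
  }
  # mixed growth is never sampled at epoch 21
  expect_equal(nrow(chron[chron$group == "mixed_growth" &
                            chron$epoch == "21", ]), 0)
  tr21 <- data.frame(pixel_id = 1:10, group = "mixed_growth",
                     years_since_fire = 21)
  expect_equal(nrow(generate_structure_chronosequence(tr21, arch, 10,
                                                      seed = 2)), 0)

  # CLT check on an interior cell: sample mean within 3 SE of the mean
  one <- arch["regenerative_conifer"]
  chron_big <- generate_structure_chronosequence(
    data.frame(pixel_id = 1:10000, group = "regenerative_conifer",
               years_since_fire = 15),
    one, n_per_group_epoch = 10000, seed = 3)
  mu <- one[[1]]$structure_means
  mu <- mu[mu$epoch == "15-16", "stems_per_900m2"]
  sdv <- structure_noise_defaults()$stems_per_900m2(mu)
  se <- sdv / sqrt(nrow(chron_big))
  expect_lt(abs(mean(chron_big$stems_per_900m2) - mu), 3 * se)

  # domains are enforced under heavy noise
  big_noise <- list(
    stems_per_900m2 = function(mu) rep(2000, length(mu)),
    bare_ground_pct = function(mu) rep(80, length(mu)),
    basal_area_m2_ha = function(mu) rep(30, length(mu)),
    conifer_proportion = function(mu) rep(1, length(mu))
  )
  noisy <- generate_structure_chronosequence(NULL, arch, 50,
                                             noise = big_noise, seed = 4)
  expect_true(all(noisy$bare_ground_pct >= 0 & noisy$bare_ground_pct <= 100))
  expect_true(all(noisy$conifer_proportion >= 0 & noisy$conifer_proportion <= 1))
  expect_true(all(noisy$stems_per_900m2 >= 0 & noisy$basal_area_m2_ha >= 0))
})
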