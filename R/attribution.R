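#' Configuration of the tiered attribution models
#'
#' @param mtry_category,ntree Category-model forest settings (2 and 500).
#' @param mtry_global,nodesize_global Global-model settings (5 and 5).
#' @param splitrule_global Global split rule (extra trees).
#' @param top_n,importance_floor Driver consolidation rule: top 5 per
#'   category, or importance > 0.05 for categories with fewer drivers.
#' @param boruta_max_runs,boruta_alpha,boruta_ntree Boruta settings.
#' @param pdp_top,pdp_grid Partial dependence: number of most important
#'   drivers and quantile grid size.
#' @return An `attribution_config` list.
#' @export
attribution_config <- function(mtry_category = 2, ntree = 500,
                               mtry_global = 5, nodesize_global = 5,
                               splitrule_global = "extratrees",
                               top_n = 5, importance_floor = 0.05,
                               boruta_max_runs = 100, boruta_alpha = 0.05,
                               boruta_ntree = 500,
                               pdp_top = 6, pdp_grid = 20) {
  structure(as.list(environment()), class = "attribution_config")
}

#' Tiered random-forest attribution of structural groups to drivers
#'
#' Implements the full attribution procedure: a stratified spatial sample of
#' burned pixels (1% per group, 90 m minimum spacing, 70/30 split), one
#' random forest per driver category, consolidation of each category's
#' dominant drivers, a global extra-trees forest on the consolidated set,
#' external validation, Boruta importance over the global driver set, and
#' partial dependence for the most important numeric drivers.
#'
#' @param drivers Driver data frame from [compute_drivers()] (with its
#'   `categories` attribute).
#' @param group Factor of structural group labels, aligned with `drivers`.
#' @param coords Two-column matrix/data frame of pixel x/y in metres.
#' @param plan A [sample_plan()].
#' @param config An [attribution_config()].
#' @param seed Integer seed.
#' @return An `attribution_report` list: `sample` (train/test sizes and
#'   achieved counts), `category_models` (OOB accuracy, held-out accuracy
#'   and importances per category), `consolidated` (driver table),
#'   `global` (OOB accuracy, external evaluation), `boruta`, `pdp`.
#' @export
run_attribution <- function(drivers, group, coords,
                            plan = sample_plan(),
                            config = attribution_config(),
                            seed = 1) {
  categories <- attr(drivers, "categories")
  if (is.null(categories)) stop("drivers must carry a 'categories' attribute")
  df <- data.frame(drivers, check.names = FALSE)
  df$group <- droplevels(factor(group))
  df$x <- coords[, 1]; df$y <- coords[, 2]

  samp <- stratified_spatial_sample(df, plan)
  train <- df[samp$train, , drop = FALSE]
  test <- df[samp$test, , drop = FALSE]

  cat_models <- list()
  importances <- list()
  for (cat_name in unique(categories)) {
    feats <- names(categories)[categories == cat_name]
    fitc <- fit_category_rf(train, feats, "group",
                            mtry = config$mtry_category,
                            ntree = config$ntree,
                            seed = child_seed(seed, match(cat_name, unique(categories))))
    # held-out accuracy alongside OOB for each category model
    pred <- predict(fitc$model, data = test[feats], num.threads = 1)$predictions
    fitc$external_accuracy <- mean(as.character(pred) == as.character(test$group))
    cat_models[[cat_name]] <- fitc
    importances[[cat_name]] <- fitc$importance
  }

  consolidated <- select_top_drivers(importances, max_n = config$top_n,
                                     floor = config$importance_floor)

  global <- fit_global_rf(train, consolidated$feature, "group",
                          mtry = config$mtry_global, ntree = config$ntree,
                          nodesize = config$nodesize_global,
                          splitrule = config$splitrule_global,
                          seed = child_seed(seed, 50))
  external <- evaluate_rf(global, test, "group")

  bor <- boruta_importance(train, consolidated$feature, "group",
                           max_runs = config$boruta_max_runs,
                           alpha = config$boruta_alpha,
                           ntree = config$boruta_ntree,
                           seed = child_seed(seed, 60))

  imp_order <- names(sort(bor$importance_0_100, decreasing = TRUE))
  pdp_drivers <- head(imp_order, config$pdp_top)
  pdp <- do.call(rbind, lapply(pdp_drivers, function(d)
    partial_dependence(global, train, d, grid_size = config$pdp_grid)))

  structure(list(
    sample = list(n_train = nrow(train), n_test = nrow(test),
                  targets = samp$targets, achieved = samp$achieved,
                  warnings = samp$warnings),
    category_models = lapply(cat_models, function(m)
      m[c("oob_accuracy", "external_accuracy", "importance",
          "importance_norm")]),
    consolidated = consolidated,
    global = list(oob_accuracy = global$oob_accuracy,
                  external = external, fit = global),
    boruta = bor,
    pdp = pdp
  ), class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("attribution_report\n")
  cat(sprintf("  sample: %d train / %d test\n", x$sample$n_train, x$sample$n_test))
  for (nm in names(x$category_models))
    cat(sprintf("  category %-14s OOB accuracy %.3f\n", nm,
                x$category_models[[nm]]$oob_accuracy))
  cat(sprintf("  global: %d drivers, OOB accuracy %.3f, external %.3f\n",
              nrow(x$consolidated), x$global$oob_accuracy,
              x$global$external$accuracy))
  cat("  top Boruta drivers:",
      paste(head(names(sort(x$boruta$importance_0_100, decreasing = TRUE)), 3),
            collapse = ", "), "\n")
  invisible(x)
}
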