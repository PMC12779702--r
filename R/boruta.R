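#' Boruta all-relevant feature selection
#'
#' Repeatedly appends shadow features (independent permutations of every
#' active feature), fits a random forest, and records for each undecided
#' real feature whether its permutation importance beats the best shadow.
#' After each run a two-sided binomial test (hit count against Bin(r, 1/2)),
#' Bonferroni-corrected over the features, confirms features that beat the
#' shadows significantly often and rejects those that significantly fail
#' to. Rejected features leave the model; the procedure stops when no
#' feature is left tentative or after `max_runs` runs, at which point
#' remaining tentatives are decided by comparing their median importance to
#' the median best-shadow importance and flagged as such. Mean importances
#' are additionally reported on a 0-100 scale (percent of the maximum).
#'
#' @param data Data frame with features and the response.
#' @param features Feature names to assess.
#' @param response Class-label column name.
#' @param max_runs Maximum forest fits (default 100).
#' @param alpha Significance level of the binomial decisions (default 0.05).
#' @param ntree Trees per forest fit (default 500).
#' @param seed Integer seed.
#' @param early_stop Stop once every feature is decided (default `TRUE`).
#' @return A `boruta_result` list: `decision` (confirmed/rejected per
#'   feature), `flagged` (decided by the fallback median rule), `hits`,
#'   `runs` (per-feature run counts), `mean_importance`,
#'   `importance_0_100`, `importance_history` (runs x features, `NA` once a
#'   feature left the model), `shadow_max`.
#' @export
boruta_importance <- function(data, features, response = "group",
                              max_runs = 100, alpha = 0.05, ntree = 500,
                              seed = 1, early_stop = TRUE) {
  y <- droplevels(factor(data[[response]]))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (min(table(y)) < 5) stop("need at least 5 samples per class")
  nf <- length(features)
  X <- data[features]
  n <- nrow(X)
  decision <- setNames(rep("tentative", nf), features)
  flagged <- setNames(rep(FALSE, nf), features)
  hits <- setNames(integer(nf), features)
  runs <- setNames(integer(nf), features)
  hist_list <- list()
  shadow_max <- numeric(0)
  run <- 0L
  while (run < max_runs) {
    run <- run + 1L
    active <- names(decision)[decision != "rejected"]
    run_seed <- child_seed(seed, run)
    # one shadow per active feature, padded to at least five shadows so the
    # max-shadow reference is stable even for small feature sets
    shadow_src <- active[rep_len(seq_along(active), max(length(active), 5L))]
    sh <- with_seed(run_seed, {
      as.data.frame(lapply(X[shadow_src], function(col) col[sample.int(n)]))
    })
    names(sh) <- paste0(".shadow_", seq_along(shadow_src))
    dat <- data.frame(X[active], sh, .group = y, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".group", data = dat,
      num.trees = ntree, mtry = max(1L, floor(sqrt(ncol(dat) - 1L))),
      importance = "permutation", seed = run_seed, num.threads = 1
    )
    imp <- fit$variable.importance
    sh_best <- max(imp[names(sh)])
    shadow_max <- c(shadow_max, sh_best)
    row <- setNames(rep(NA_real_, nf), features)
    row[active] <- imp[active]
    hist_list[[run]] <- row
    tentative <- names(decision)[decision == "tentative"]
    hits[tentative] <- hits[tentative] + (imp[tentative] > sh_best)
    runs[active] <- runs[active] + 1L
    # two-sided binomial decisions, Bonferroni over the feature set
    for (f in tentative) {
      r <- runs[f]; h <- hits[f]
      p2 <- 2 * min(pbinom(h, r, 0.5), 1 - pbinom(h - 1L, r, 0.5))
      if (min(p2 * nf, 1) < alpha) {
        decision[f] <- if (h > r / 2) "confirmed" else "rejected"
      }
    }
    if (early_stop && !any(decision == "tentative")) break
  }
  if (any(decision == "tentative")) {
    med_shadow <- median(shadow_max)
    hist_mat <- do.call(rbind, hist_list)
    for (f in names(decision)[decision == "tentative"]) {
      med_f <- median(hist_mat[, f], na.rm = TRUE)
      decision[f] <- if (med_f > med_shadow) "confirmed" else "rejected"
      flagged[f] <- TRUE
    }
  }
  hist_mat <- do.call(rbind, hist_list)
  mean_imp <- apply(hist_mat, 2, function(col) {
    if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
  })
  top <- max(mean_imp, na.rm = TRUE)
  imp100 <- if (is.finite(top) && top > 0)
    100 * pmax(mean_imp, 0) / top else mean_imp * 0
  structure(list(
    decision = decision, flagged = flagged, hits = hits, runs = runs,
    n_runs = run, mean_importance = mean_imp, importance_0_100 = imp100,
    importance_history = hist_mat, shadow_max = shadow_max, seed = seed
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("Boruta:", x$n_runs, "runs;",
      sum(x$decision == "confirmed"), "confirmed,",
      sum(x$decision == "rejected"), "rejected",
      if (any(x$flagged)) paste0("(", sum(x$flagged), " by fallback rule)"),
      "\n")
  ord <- order(-x$importance_0_100)
  print(round(x$importance_0_100[ord], 1))
  invisible(x)
}
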