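#' Partial dependence of group probabilities on one driver
#'
#' For a numeric driver, evaluates the model over a quantile grid: at each
#' grid value the driver is set to that value for every training row and the
#' predicted per-group probabilities are averaged. For a categorical driver
#' the same average is computed per level. Probabilities at each grid point
#' sum to one across groups.
#'
#' @param global_fit Result of [fit_global_rf()].
#' @param data Training data frame (rows to average over).
#' @param driver Driver name.
#' @param grid_size Number of quantile grid points (numeric drivers).
#' @return Data frame: `driver`, `value` (numeric grid or level), `group`,
#'   `probability`.
#' @export
partial_dependence <- function(global_fit, data, driver, grid_size = 20) {
  stopifnot(driver %in% global_fit$drivers)
  X <- data[global_fit$drivers]
  x <- X[[driver]]
  grid <- if (is.numeric(x)) {
    unique(unname(quantile(x, probs = seq(0, 1, length.out = grid_size))))
  } else {
    levels(factor(x))
  }
  rows <- lapply(grid, function(v) {
    Xv <- X
    Xv[[driver]] <- if (is.numeric(x)) v else factor(v, levels = levels(factor(x)))
    pr <- predict(global_fit$model, data = Xv, num.threads = 1)$predictions
    colMeans(pr)
  })
  pm <- do.call(rbind, rows)
  out <- data.frame(
    driver = driver,
    value = rep(grid, times = ncol(pm)),
    group = rep(colnames(pm), each = length(grid)),
    probability = as.vector(pm),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
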