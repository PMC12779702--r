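#' Sampling plan for attribution modelling
#'
#' @param fraction Fraction of burned pixels to sample per stratum
#'   (default 0.01, i.e. a 1% stratified sample).
#' @param min_distance_m Minimum pairwise distance between accepted pixels
#'   (default 90 m), limiting spatial autocorrelation.
#' @param split Training fraction of the accepted sample (default 0.7).
#' @param seed Integer seed.
#' @return A validated `sample_plan` list.
#' @export
sample_plan <- function(fraction = 0.01, min_distance_m = 90, split = 0.7,
                        seed = 1) {
  stopifnot(fraction > 0, fraction <= 1, min_distance_m >= 0,
            split > 0, split < 1)
  structure(list(fraction = fraction, min_distance_m = min_distance_m,
                 split = split, seed = as.integer(seed)),
            class = "sample_plan")
}

#' Greedy distance thinning in a fixed candidate order
#'
#' Accepts candidates one by one, keeping a candidate iff it lies at least
#' `min_distance` from every previously accepted point (including points in
#' `accepted`). The accepted set depends on the order, which is why the
#' sampler feeds a seeded shuffle.
#'
#' @param coords Two-column matrix of x/y coordinates (metres).
#' @param order Candidate order (indices into `coords`).
#' @param min_distance Minimum pairwise distance.
#' @param accepted Optional matrix of already-accepted coordinates.
#' @param max_accept Stop after this many acceptances.
#' @return Integer vector of accepted indices (in acceptance order).
#' @export
thin_by_distance <- function(coords, order = seq_len(nrow(coords)),
                             min_distance = 90, accepted = NULL,
                             max_accept = Inf) {
  acc_xy <- if (is.null(accepted)) matrix(numeric(0), 0, 2) else as.matrix(accepted)
  out <- integer(0)
  min2 <- min_distance^2
  for (i in order) {
    if (length(out) >= max_accept) break
    if (min_distance > 0 && nrow(acc_xy)) {
      d2 <- (acc_xy[, 1] - coords[i, 1])^2 + (acc_xy[, 2] - coords[i, 2])^2
      if (any(d2 < min2)) next
    }
    out <- c(out, i)
    acc_xy <- rbind(acc_xy, coords[i, , drop = FALSE])
  }
  out
}

#' Stratified spatial sample of burned pixels
#'
#' Per structural group, targets `round(fraction * stratum size)` pixels,
#' draws stratum candidates in seeded random order and accepts them greedily
#' under the minimum-distance constraint (checked against acceptances across
#' all strata). The accepted set is then split into training and testing
#' subsets within stratum. Strata that cannot reach their target under the
#' distance constraint are filled as far as possible with a warning.
#'
#' @param df Data frame with columns `group`, `x`, `y` (metres).
#' @param plan A [sample_plan()].
#' @return List: `train`, `test` (row indices into `df`), `targets`,
#'   `achieved` (named per stratum), `warnings`.
#' @export
stratified_spatial_sample <- function(df, plan = sample_plan()) {
  stopifnot(all(c("group", "x", "y") %in% names(df)))
  coords <- cbind(df$x, df$y)
  groups <- sort(unique(as.character(df$group)))
  acc_by_g <- list()
  acc_xy <- matrix(numeric(0), 0, 2)
  targets <- achieved <- setNames(integer(length(groups)), groups)
  warns <- character(0)
  with_seed(plan$seed, {
    for (g in groups) {
      rows <- which(as.character(df$group) == g)
      targets[g] <- round(plan$fraction * length(rows))
      ord <- rows[sample.int(length(rows))]
      got <- thin_by_distance(coords, ord, plan$min_distance_m,
                              accepted = acc_xy, max_accept = targets[g])
      achieved[g] <- length(got)
      if (achieved[g] < targets[g])
        warns <- c(warns, sprintf(
          "stratum %s: achieved %d of %d under the %g m constraint",
          g, achieved[g], targets[g], plan$min_distance_m))
      acc_by_g[[g]] <- got
      if (length(got)) acc_xy <- rbind(acc_xy, coords[got, , drop = FALSE])
    }
    train <- test <- integer(0)
    for (g in groups) {
      got <- acc_by_g[[g]]
      if (!length(got)) next
      n_train <- round(plan$split * length(got))
      shuf <- got[sample.int(length(got))]
      train <- c(train, shuf[seq_len(n_train)])
      test <- c(test, shuf[setdiff(seq_along(shuf), seq_len(n_train))])
    }
    for (w in warns) warning(w, call. = FALSE)
    list(train = sort(train), test = sort(test),
         targets = targets, achieved = achieved, warnings = warns)
  })
}
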