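#' Assign years-since-fire to a chronosequence epoch
#'
#' Epochs are the one-to-two-year bins 5-7, 8-9, 11-12, 15-16 and 21 years
#' post-fire; all other (non-negative) years are unassigned (`NA`) and
#' excluded from grouping.
#'
#' @param years_since_fire Non-negative integer vector.
#' @return Factor with levels "5-7", "8-9", "11-12", "15-16", "21";
#'   unassigned years are `NA`.
#' @export
assign_epoch <- function(years_since_fire) {
  if (any(years_since_fire < 0)) stop("years_since_fire must be >= 0")
  out <- rep(NA_character_, length(years_since_fire))
  out[years_since_fire %in% 5:7] <- "5-7"
  out[years_since_fire %in% 8:9] <- "8-9"
  out[years_since_fire %in% 11:12] <- "11-12"
  out[years_since_fire %in% 15:16] <- "15-16"
  out[years_since_fire == 21] <- "21"
  factor(out, levels = EPOCH_LEVELS)
}

#' Structural dissimilarity matrix
#'
#' Euclidean distance on the four structure variables (stems per 900 m2,
#' bare ground %, basal area, conifer proportion) after z-standardization
#' computed within epoch, so that distances compare stands net of
#' time-since-fire. A variable with zero variance within an epoch
#' contributes nothing there. Population SDs are used.
#'
#' @param samples Data frame of structural samples with an `epoch` column
#'   (or `years_since_fire`, from which epochs are derived).
#' @return A `dist` object with an `epoch` attribute carrying the per-sample
#'   strata for downstream permutation tests.
#' @export
structure_dissimilarity <- function(samples) {
  if (nrow(samples) < 2) stop("need at least 2 samples")
  if (!"epoch" %in% names(samples)) {
    samples$epoch <- assign_epoch(samples$years_since_fire)
  }
  ep <- as.character(samples$epoch)
  if (anyNA(ep)) stop("all samples must have an assigned epoch")
  counts <- table(ep)
  if (any(counts < 2))
    stop("epoch with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  z <- matrix(0, nrow(samples), length(STRUCTURE_VARS),
              dimnames = list(NULL, STRUCTURE_VARS))
  for (e in unique(ep)) {
    rows <- which(ep == e)
    for (v in STRUCTURE_VARS) {
      x <- samples[[v]][rows]
      s <- pop_sd(x)
      z[rows, v] <- if (s > 0) (x - mean(x)) / s else 0
    }
  }
  d <- dist(z)
  attr(d, "epoch") <- ep
  d
}

# Sum over groups of (sum of squared within-group distances) / group size.
permanova_ss_within <- function(d2, g, sizes) {
  m <- rowsum(d2, g)
  w <- rowsum(t(m), g)
  sum(diag(w) / (2 * sizes))
}

# Permutation of 1..n restricted within strata (or free if strata NULL).
permute_within_strata <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  perm <- seq_len(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) > 1) perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the sums of squared inter-point distances into between- and
#' within-group components (SS_total = sum of all squared pairwise
#' distances / n; SS_within analogously within groups) and forms the
#' pseudo-F statistic `(SS_b / (a - 1)) / (SS_w / (n - a))`. Significance
#' comes from label permutations, restricted within strata if given, with
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)`. When SS_total is
#' (numerically) zero the statistic is defined as 0 with p = 1.
#'
#' @param d A `dist` or square symmetric matrix of distances.
#' @param labels Group labels covering at least 2 groups.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param strata Optional stratification vector (e.g. epoch): permutations
#'   shuffle labels within strata only. Defaults to the `epoch` attribute of
#'   `d` when present.
#' @return A `permanova_result` list: `pseudo_F`, `df_between`, `df_within`,
#'   `p_value`, `n_permutations`, `seed`, and the `ss` partition.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = 1,
                      strata = attr(d, "epoch")) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8)
    stop("d must be a square symmetric distance matrix")
  n <- nrow(dm)
  labels <- factor(labels)
  if (length(labels) != n) stop("labels length must match the distance matrix")
  sizes <- table(labels)
  if (any(sizes == 0)) stop("empty group after filtering: ",
                            paste(names(sizes)[sizes == 0], collapse = ", "))
  a <- nlevels(labels)
  if (a < 2) stop("labels must cover at least 2 groups")
  d2 <- dm^2
  ss_total <- sum(d2) / (2 * n)
  df_b <- a - 1L
  df_w <- n - a
  g <- as.integer(labels)
  if (ss_total <= 1e-12 * n) {
    return(structure(list(
      pseudo_F = 0, df_between = df_b, df_within = df_w, p_value = 1,
      n_permutations = n_permutations, seed = seed,
      ss = list(total = ss_total, between = 0, within = ss_total)
    ), class = "permanova_result"))
  }
  f_stat <- function(gi) {
    sw <- permanova_ss_within(d2, gi, tabulate(gi, a))
    sb <- ss_total - sw
    (sb / df_b) / (sw / df_w)
  }
  f_obs <- f_stat(g)
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      gp <- g[permute_within_strata(n, strata)]
      if (f_stat(gp) >= f_obs) hits <- hits + 1L
    }
  })
  sw <- permanova_ss_within(d2, g, tabulate(g, a))
  structure(list(
    pseudo_F = f_obs, df_between = df_b, df_within = df_w,
    p_value = (1 + hits) / (1 + n_permutations),
    n_permutations = n_permutations, seed = seed,
    ss = list(total = ss_total, between = ss_total - sw, within = sw)
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA pseudo-F(%d, %d) = %.4g, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Pairwise post-hoc PERMANOVA between clusters
#'
#' Runs a two-group PERMANOVA for every cluster pair on that pair's samples
#' (same strata rule as the omnibus test). A pair involving a singleton
#' cluster gets `NA` (treated as distinct downstream). Optional Holm or
#' Bonferroni correction over the pairs.
#'
#' @param d Distance `dist`/matrix over all samples.
#' @param labels Cluster labels.
#' @param n_permutations,seed As in [permanova()].
#' @param strata Optional strata vector (defaults to `d`'s `epoch`
#'   attribute).
#' @param correction One of "none", "holm", "bonferroni".
#' @return Symmetric matrix of p-values with unit diagonal.
#' @export
posthoc_pairwise <- function(d, labels, n_permutations = 999, seed = 1,
                             strata = attr(d, "epoch"),
                             correction = c("none", "holm", "bonferroni")) {
  correction <- match.arg(correction)
  dm <- as.matrix(d)
  labels <- factor(labels)
  ids <- levels(labels)
  if (length(ids) < 2) stop("need at least 2 clusters")
  p <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(p) <- 1
  pair_idx <- which(upper.tri(p), arr.ind = TRUE)
  for (r in seq_len(nrow(pair_idx))) {
    i <- pair_idx[r, 1]; j <- pair_idx[r, 2]
    sel <- which(labels %in% ids[c(i, j)])
    if (min(table(droplevels(labels[sel]))) < 2) next   # singleton: NA
    sub <- dm[sel, sel, drop = FALSE]
    res <- permanova(sub, droplevels(labels[sel]),
                     n_permutations = n_permutations,
                     seed = child_seed(seed, r),
                     strata = if (!is.null(strata)) strata[sel] else NULL)
    p[i, j] <- p[j, i] <- res$p_value
  }
  if (correction != "none") {
    up <- upper.tri(p)
    vals <- p[up]
    ok <- !is.na(vals)
    vals[ok] <- p.adjust(vals[ok], method = correction)
    p[up] <- vals
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  p
}

#' Merge clusters into structural groups
#'
#' Builds a graph with an edge between clusters whose pairwise p-value
#' exceeds alpha (i.e. the clusters are NOT structurally distinct) and takes
#' connected components as the structural groups. Missing p-values count as
#' distinct. Component labels are assigned deterministically by each
#' component's smallest member cluster id. Pairs inside one component whose
#' p-value is nevertheless <= alpha (non-transitive outcomes) are reported
#' as warnings.
#'
#' @param pairwise_p Symmetric p-value matrix from [posthoc_pairwise()].
#' @param alpha Merge threshold (default 0.05): merge when p > alpha.
#' @return A `group_mapping` list: `mapping` (cluster id -> group id),
#'   `groups` (group id -> member cluster ids), `alpha`,
#'   `nontransitive` (data frame of conflicting pairs).
#' @export
merge_clusters <- function(pairwise_p, alpha = 0.05) {
  ids <- rownames(pairwise_p)
  m <- length(ids)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j && !is.na(pairwise_p[i, j]) && pairwise_p[i, j] > alpha) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(m), find, integer(1))
  comp_ids <- sort(unique(root))
  group_of <- match(root, comp_ids)          # ordered by smallest member
  mapping <- setNames(group_of, ids)
  groups <- split(ids, group_of)
  nontrans <- data.frame(cluster_a = character(), cluster_b = character(),
                         p = numeric(), stringsAsFactors = FALSE)
  for (gmembers in groups) {
    if (length(gmembers) < 2) next
    for (i in seq_along(gmembers)) for (j in seq_along(gmembers)) {
      if (i < j) {
        pv <- pairwise_p[gmembers[i], gmembers[j]]
        if (is.na(pv) || pv <= alpha) {
          nontrans <- rbind(nontrans, data.frame(
            cluster_a = gmembers[i], cluster_b = gmembers[j],
            p = pv, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (nrow(nontrans))
    warning("non-transitive merge: distinct pair(s) joined through a chain: ",
            paste(paste(nontrans$cluster_a, nontrans$cluster_b, sep = "-"),
                  collapse = ", "))
  structure(list(mapping = mapping, groups = groups, alpha = alpha,
                 nontransitive = nontrans),
            class = "group_mapping")
}
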