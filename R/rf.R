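# All forests run single-threaded with an explicit seed so every report
# number is a pure function of (data, config, seed).

#' Fit a per-category random forest
#'
#' Classification forest on one driver category's features only, with the
#' category-model defaults mtry = 2 and ntree = 500. Accuracy is the
#' out-of-bag estimate; per-feature permutation importance (mean accuracy
#' drop) is returned raw and rescaled to [0, 1] by the maximum.
#'
#' @param train Data frame holding the features and the response.
#' @param features Character vector of this category's driver names.
#' @param response Name of the group-label column (factor).
#' @param mtry,ntree Forest parameters (defaults 2 and 500).
#' @param seed Integer seed.
#' @return List: `model`, `oob_accuracy`, `importance` (raw),
#'   `importance_norm`.
#' @export
fit_category_rf <- function(train, features, response = "group",
                            mtry = 2, ntree = 500, seed = 1) {
  y <- factor(train[[response]])
  if (nlevels(droplevels(y)) < 2) stop("training data holds a single class")
  if (!length(features)) stop("category has no drivers")
  dat <- data.frame(train[features], .group = droplevels(y),
                    check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".group", data = dat,
    num.trees = ntree, mtry = min(mtry, length(features)),
    importance = "permutation", seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance[features]
  norm <- if (max(imp) > 0) pmax(imp, 0) / max(imp) else imp * 0
  list(model = fit, oob_accuracy = 1 - fit$prediction.error,
       importance = imp, importance_norm = norm)
}

#' Consolidate the dominant drivers across category models
#'
#' Per category, takes the top `max_n` drivers by raw permutation
#' importance; a category with fewer than `max_n` drivers instead
#' contributes those whose importance exceeds `floor`. The union is ordered
#' by descending importance with the source category retained.
#'
#' @param importances_by_category Named list (category -> named importance
#'   vector) as produced by [fit_category_rf()].
#' @param max_n Top drivers per category (default 5).
#' @param floor Importance floor for small categories (default 0.05).
#' @return Data frame: `feature`, `category`, `importance`, sorted.
#' @export
select_top_drivers <- function(importances_by_category, max_n = 5,
                               floor = 0.05) {
  rows <- list()
  for (cat_name in names(importances_by_category)) {
    imp <- sort(importances_by_category[[cat_name]], decreasing = TRUE)
    keep <- if (length(imp) >= max_n) {
      head(imp, max_n)
    } else {
      imp[imp > floor]
    }
    if (length(keep))
      rows[[cat_name]] <- data.frame(
        feature = names(keep), category = cat_name,
        importance = unname(keep), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no drivers survived consolidation")
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}

#' Fit the global random forest on the consolidated drivers
#'
#' Probability forest with the global-model settings: five candidate
#' variables per split, 500 trees, minimum terminal node size five, and the
#' extra-trees (randomized threshold) split rule. OOB accuracy is the
#' misclassification-based accuracy of the out-of-bag class-probability
#' argmax.
#'
#' @param train Data frame with features and response.
#' @param drivers Consolidated driver names.
#' @param response Group-label column name.
#' @param mtry,ntree,nodesize,splitrule Forest parameters.
#' @param seed Integer seed.
#' @return List: `model` (ranger probability forest), `oob_accuracy`,
#'   `drivers`, `levels`.
#' @export
fit_global_rf <- function(train, drivers, response = "group",
                          mtry = 5, ntree = 500, nodesize = 5,
                          splitrule = "extratrees", seed = 1) {
  y <- droplevels(factor(train[[response]]))
  if (nlevels(y) < 2) stop("training data holds a single class")
  dat <- data.frame(train[drivers], .group = y, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".group", data = dat,
    num.trees = ntree, mtry = min(mtry, length(drivers)),
    min.node.size = nodesize, splitrule = splitrule,
    probability = TRUE, seed = seed, num.threads = 1
  )
  oob <- fit$predictions                 # n x k OOB class probabilities
  pred <- levels(y)[max.col(oob, ties.method = "first")]
  ok <- stats::complete.cases(oob)
  list(model = fit, oob_accuracy = mean(pred[ok] == as.character(y)[ok]),
       drivers = drivers, levels = levels(y))
}

# Class predictions (argmax, ties to the first level) from a probability
# forest.
predict_classes <- function(global_fit, newdata) {
  pr <- predict(global_fit$model, data = newdata,
                num.threads = 1)$predictions
  factor(global_fit$levels[max.col(pr, ties.method = "first")],
         levels = global_fit$levels)
}

#' Evaluate a fitted global forest on held-out data
#'
#' Reports overall accuracy, the confusion matrix, and per-class scores.
#' The F-score is the arithmetic mean of precision and recall (the
#' definition used for this procedure); the harmonic-mean F1 is reported
#' alongside for interoperability.
#'
#' @param global_fit Result of [fit_global_rf()].
#' @param test Held-out data frame (disjoint from training).
#' @param response Group-label column name.
#' @return List: `accuracy`, `confusion` (rows = truth), `precision`,
#'   `recall`, `f_score`, `f1`.
#' @export
evaluate_rf <- function(global_fit, test, response = "group") {
  truth <- factor(test[[response]], levels = global_fit$levels)
  if (anyNA(truth))
    warning("test classes absent from training were scored as errors")
  pred <- predict_classes(global_fit, test[global_fit$drivers])
  conf <- table(truth = truth, predicted = pred)
  acc <- sum(diag(conf)) / sum(conf)
  prec <- diag(conf) / pmax(colSums(conf), 1)
  rec <- diag(conf) / pmax(rowSums(conf), 1)
  list(accuracy = acc, confusion = conf,
       precision = prec, recall = rec,
       f_score = (prec + rec) / 2,
       f1 = ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0))
}
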