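# Carried-vs-ambulation random-forest classifier: grid-search tuning,
# leave-one-subject-out (LOSO) evaluation, impurity-based importances.
#
# Tree induction is delegated to ranger; the bespoke content is the
# binarization contract, the seeded tuning/LOSO protocol, and the report.

#' Binarize a behavior into carried vs ambulation
#'
#' `"carried"` maps to the carried class; `"run"`, `"walk"`, `"crawl"`, and
#' `"climb"` pool into `"ambulation"`. Any other behavior is rejected: only
#' these five are eligible for the binary classification task.
#'
#' @param behavior Character vector of behaviors.
#' @return Factor with levels `carried`, `ambulation`.
#' @examples
#' binarize_behavior(c("walk", "carried"))
#' @export
binarize_behavior <- function(behavior) {
  bad <- setdiff(unique(behavior), classifier_behaviors())
  if (length(bad)) {
    stop("behavior(s) not eligible for carried/ambulation classification: ",
         paste(bad, collapse = ", "))
  }
  factor(ifelse(behavior == "carried", "carried", "ambulation"),
         levels = c("carried", "ambulation"))
}

#' Default random-forest hyperparameter grid
#'
#' Small documented grid: number of trees (100, 300), maximum tree depth
#' (5, 10, unlimited — encoded as 0), and minimum node size (5, 1). Rows
#' are ordered from smallest to largest model; [tune_rf()] breaks CV-accuracy
#' ties in favor of the earliest (smallest) row.
#'
#' @return Data frame with columns `num_trees`, `max_depth`, `min_node`.
#' @export
default_rf_grid <- function() {
  g <- expand.grid(min_node = c(5, 1), max_depth = c(5, 10, 0),
                   num_trees = c(100, 300))
  g[c("num_trees", "max_depth", "min_node")]
}

.fit_rf <- function(x, y, hp, seed, importance = "none") {
  ranger::ranger(
    x = x, y = y,
    num.trees = hp$num_trees,
    max.depth = hp$max_depth,
    min.node.size = hp$min_node,
    importance = importance,
    seed = seed,
    num.threads = 1
  )
}

#' Grid-search hyperparameter tuning by k-fold cross-validation
#'
#' Evaluates every grid point by stratified seeded k-fold cross-validation
#' over the entire data set and returns the point with the highest mean CV
#' accuracy; ties go to the smallest model (the earliest row of the grid,
#' which [default_rf_grid()] orders by size). Fully deterministic for a
#' given seed.
#'
#' @param features Numeric data frame or matrix of predictors.
#' @param labels Factor (or vector) of class labels; both classes must be
#'   present.
#' @param grid Hyperparameter grid, see [default_rf_grid()].
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed.
#' @return List with the chosen `num_trees`, `max_depth`, `min_node`, the
#'   achieved `cv_accuracy`, and the full `grid_results` table.
#' @export
tune_rf <- function(features, labels, grid = default_rf_grid(), folds = 10,
                    seed = 1) {
  features <- as.data.frame(features)
  labels <- as.factor(labels)
  if (any(table(labels) == 0L) || nlevels(droplevels(labels)) < 2L) {
    stop("both classes must be present for tuning")
  }
  n <- nrow(features)
  fold_id <- integer(n)
  local_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  acc <- matrix(NA_real_, nrow(grid), folds)
  for (g in seq_len(nrow(grid))) {
    for (k in seq_len(folds)) {
      test <- fold_id == k
      if (!any(test) || nlevels(droplevels(labels[!test])) < 2L) next
      fit <- .fit_rf(features[!test, , drop = FALSE], labels[!test],
                     grid[g, ], seed = sub_seed(seed, g * folds + k))
      pred <- predict(fit, data = features[test, , drop = FALSE])$predictions
      acc[g, k] <- mean(pred == labels[test])
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  best <- which.max(mean_acc)   # first max = smallest model
  out <- as.list(grid[best, ])
  out$cv_accuracy <- mean_acc[best]
  out$grid_results <- cbind(grid, cv_accuracy = mean_acc)
  out$seed <- seed
  out
}

#' Leave-one-subject-out evaluation
#'
#' Holds out each subject's windows exactly once, trains on the remaining
#' subjects, and pools the held-out predictions into a single confusion
#' matrix with accuracy, per-class and macro-averaged precision/recall,
#' macro F1, a per-fold (per-subject) breakdown, and impurity-based feature
#' importances from a final fit on all data.
#'
#' @param features Numeric data frame or matrix of predictors.
#' @param labels Factor of class labels (see [binarize_behavior()]).
#' @param subjects Subject identifier per row; at least 2 distinct subjects.
#' @param hyper Hyperparameter list (`num_trees`, `max_depth`, `min_node`),
#'   e.g. from [tune_rf()]; defaults to 300 unlimited-depth trees.
#' @param seed Integer seed.
#' @return An object of class `classifier_report`: list with `confusion`
#'   (2x2, truth in rows), `accuracy`, `precision`, `recall` (per class),
#'   `macro_precision`, `macro_recall`, `f1` (macro), `per_fold`,
#'   `importance`, `predictions`, and `tuning`.
#' @export
loso_evaluate <- function(features, labels, subjects, hyper = NULL, seed = 1) {
  features <- as.data.frame(features)
  labels <- as.factor(labels)
  subjects <- as.character(subjects)
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(subjects))
  subj <- unique(subjects)
  if (length(subj) < 2L) stop("LOSO evaluation needs at least 2 subjects")
  if (is.null(hyper)) hyper <- list(num_trees = 300, max_depth = 0, min_node = 1)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  per_fold <- data.frame(subject = subj, n = NA_integer_,
                         accuracy = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(subj)) {
    test <- subjects == subj[i]
    fit <- .fit_rf(features[!test, , drop = FALSE], droplevels(labels[!test]),
                   hyper, seed = sub_seed(seed, i))
    p <- predict(fit, data = features[test, , drop = FALSE])$predictions
    pred[test] <- as.character(p)
    per_fold$n[i] <- sum(test)
    per_fold$accuracy[i] <- mean(p == labels[test])
  }
  confusion <- table(truth = labels, predicted = pred)
  accuracy <- mean(pred == labels)
  recall <- diag(confusion) / rowSums(confusion)
  precision <- diag(confusion) / colSums(confusion)
  precision[is.nan(precision)] <- 0
  f1_class <- ifelse(precision + recall > 0,
                     2 * precision * recall / (precision + recall), 0)
  final <- .fit_rf(features, labels, hyper, seed = sub_seed(seed, 0L),
                   importance = "impurity")
  structure(
    list(
      confusion = confusion,
      accuracy = accuracy,
      precision = precision,
      recall = recall,
      macro_precision = mean(precision),
      macro_recall = mean(recall),
      f1 = mean(f1_class),
      per_fold = per_fold,
      importance = importance_report(final),
      predictions = data.frame(subject = subjects,
                               truth = labels, predicted = pred,
                               stringsAsFactors = FALSE),
      tuning = hyper,
      seed = seed
    ),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  print(x$confusion)
  cat(sprintf("accuracy %.3f | macro precision %.3f | macro recall %.3f | F1 %.3f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$f1))
  cat("top features by importance:\n")
  print(head(x$importance, 5))
  invisible(x)
}

#' Impurity-based feature importances
#'
#' Mean decrease in node impurity per feature from a trained ranger
#' ensemble (fit with `importance = "impurity"`), normalized to sum to 1
#' and sorted descending.
#'
#' @param model A fitted `ranger` object with impurity importances.
#' @return Data frame with columns `feature` and `importance`.
#' @export
importance_report <- function(model) {
  imp <- ranger::importance(model)
  if (!length(imp)) stop("model has no importance values")
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
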