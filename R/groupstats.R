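# Descriptive and comparative statistics: per-behavior count summaries,
# Mann-Whitney comparisons, and d-prime (sensitivity index) feature ranking.

#' Summarize behavior count rates across participants
#'
#' Median, interquartile range (linear-interpolation quantiles, R type 7),
#' and n across participants for each (behavior, measure) cell of a
#' [behavior_count_rate()] table. If the table carries a `site` column, the
#' summary is additionally stratified by site.
#'
#' @param rates Data frame from [behavior_count_rate()] (optionally with a
#'   `site` column, e.g. row-bound across sites).
#' @return Data frame with columns (`site`,) `measure`, `behavior`, `n`,
#'   `median`, `q1`, `q3`.
#' @export
summarize_counts <- function(rates) {
  by_cols <- intersect(c("site", "measure", "behavior"), names(rates))
  if (!nrow(rates)) {
    out <- stats::setNames(
      as.data.frame(rep(list(character(0)), length(by_cols)),
                    stringsAsFactors = FALSE), by_cols)
    out$n <- integer(0); out$median <- out$q1 <- out$q3 <- numeric(0)
    return(out)
  }
  key <- interaction(rates[by_cols], drop = TRUE, sep = "\r")
  pieces <- lapply(split(rates, key), function(d) {
    cbind(d[1L, by_cols, drop = FALSE],
          data.frame(n = nrow(d),
                     median = median(d$rate),
                     q1 = as.numeric(quantile(d$rate, 0.25, type = 7)),
                     q3 = as.numeric(quantile(d$rate, 0.75, type = 7))))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison
#'
#' Two-sided Mann-Whitney test comparing two groups of count rates or
#' feature values. The exact null distribution is used when the combined
#' sample size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' The returned `U` is the Mann-Whitney U statistic for `group_a` (the
#' number of (a, b) pairs with a > b, counting ties as 1/2).
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `U`, `p`, and `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty")
  }
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- (length(group_a) + length(group_b)) <= 20 && !ties
  res <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(U = unname(res$statistic), p = min(1, res$p.value),
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Sensitivity index d-prime between two groups
#'
#' The standardized separation between two empirical distributions:
#' \deqn{d' = |\bar{a} - \bar{b}| / \sqrt{(s_a^2 + s_b^2)/2}}
#' with sample variances — the conventional equal-weight signal-detection
#' form. Symmetric in its arguments and invariant to adding a constant to
#' both groups. Degenerate cases: zero pooled variance yields 0 when the
#' means are equal and `Inf` when they differ.
#'
#' @param values_a,values_b Numeric vectors with at least 2 values each.
#' @return Non-negative scalar (possibly `Inf`).
#' @examples
#' dprime(rnorm(50), rnorm(50, mean = 1))
#' @export
dprime <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("both groups need at least 2 values")
  }
  pooled <- (var(values_a) + var(values_b)) / 2
  delta <- abs(mean(values_a) - mean(values_b))
  if (pooled == 0) {
    return(if (delta == 0) 0 else Inf)
  }
  delta / sqrt(pooled)
}

#' Rank features by d-prime
#'
#' Scores every feature column by [dprime()] between the two classes and
#' returns the full descending ranking (ties broken alphabetically by
#' feature name).
#'
#' @param feature_table Data frame or matrix of feature columns (numeric),
#'   e.g. the feature columns of [extract_features()].
#' @param binary_labels Vector with exactly two distinct values (e.g.
#'   `"carried"` / `"ambulation"`), one per row.
#' @return Data frame of class `dprime_ranking` with columns `rank`,
#'   `feature`, `dprime`, sorted descending by `dprime`.
#' @export
rank_features <- function(feature_table, binary_labels) {
  feature_table <- as.data.frame(feature_table)
  num <- vapply(feature_table, is.numeric, TRUE)
  feature_table <- feature_table[num]
  lev <- unique(binary_labels)
  if (length(lev) != 2L) stop("`binary_labels` must have exactly two classes")
  a <- binary_labels == lev[1L]
  scores <- vapply(feature_table, function(col) dprime(col[a], col[!a]), 0)
  ord <- order(-scores, names(scores))
  out <- data.frame(rank = seq_along(scores),
                    feature = names(scores)[ord],
                    dprime = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- as.character(lev)
  class(out) <- c("dprime_ranking", "data.frame")
  out
}
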