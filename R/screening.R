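# Random-forest feature-importance ranking and threshold screening.

#' Random-forest feature importance
#'
#' Fits a random-forest regressor of the target on all candidate features
#' and reports the mean-decrease-in-impurity importance of each feature,
#' normalized to percentages of the total (so the table sums to 100).
#'
#' @param features Data frame or matrix of candidate features (columns) by
#'   observations (rows); at least 2 features and 10 rows.
#' @param target Numeric response (here: AGB in t/hm2), one per row.
#' @param seed Integer seed for the forest (default 42).
#' @param n_trees Number of trees (default 500).
#' @return Object of class `importance_table`: data frame with columns
#'   `feature` and `importance` (percent, descending), with attributes
#'   `seed` and `n_trees`.
#' @export
rf_importance <- function(features, target, seed = 42L, n_trees = 500L) {
  features <- as.data.frame(features)
  if (ncol(features) < 2L) stop("need at least 2 features", call. = FALSE)
  if (nrow(features) < 10L) stop("need at least 10 rows", call. = FALSE)
  if (length(target) != nrow(features)) {
    stop("target length must match feature rows", call. = FALSE)
  }
  if (stats::var(target) < 1e-14) {
    stop("constant target: importance undefined", call. = FALSE)
  }
  x <- features
  names(x) <- make.names(names(x))
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = target, ntree = n_trees, importance = FALSE))
  raw <- fit$importance[, "IncNodePurity"]
  pct <- 100 * raw / sum(raw)
  out <- data.frame(feature = names(features)[order(pct, decreasing = TRUE)],
                    importance = unname(sort(pct, decreasing = TRUE)),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "n_trees") <- n_trees
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Screen features by importance threshold
#'
#' Drops every feature whose importance falls below `threshold` percent —
#' the overfitting guard applied before model training. The retained set
#' must be non-empty.
#'
#' @param importance An [rf_importance()] table (or data frame with
#'   `feature` and `importance` columns).
#' @param threshold Minimum importance in percent (default 1).
#' @param quiet Suppress the exclusion message.
#' @return Character vector of retained feature names, with attributes
#'   `excluded` (dropped names) and `threshold`.
#' @export
screen_features <- function(importance, threshold = 1.0, quiet = FALSE) {
  check_number(threshold, "threshold", lower = 0)
  keep <- importance$importance >= threshold
  if (!any(keep)) {
    stop("all features fall below the importance threshold", call. = FALSE)
  }
  retained <- importance$feature[keep]
  excluded <- importance$feature[!keep]
  if (length(excluded) && !quiet) {
    message("screened out ", length(excluded), " feature(s): ",
            paste(excluded, collapse = ", "))
  }
  attr(retained, "excluded") <- excluded
  attr(retained, "threshold") <- threshold
  retained
}
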