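# Stage x algorithm x feature-set benchmark of AGB estimation: screening on
# the training split, grid-searched fits, held-out test metrics and the
# saturation diagnostic.

# Default feature-set definitions, intersected with available columns.
.default_feature_sets <- function(cols) {
  aih <- intersect(c("H_5", "H_20", "H_40", "H_60", "H_80", "H_95", "CH"),
                   cols)
  vis <- intersect(vi_names(), cols)
  sets <- list()
  if (length(aih)) sets$AIH <- aih
  if (length(vis)) sets$VIs <- vis
  if (length(aih) && length(vis)) sets$`VIs+AIH` <- c(vis, aih)
  sets
}

#' Benchmark AGB regression algorithms across feature sets and stages
#'
#' For every growth stage and every feature set (structural AIH features,
#' vegetation indices, and their union, by default), the data are split
#' 7:3 into training and test rows, features are screened on the training
#' split by random-forest importance (below-threshold features dropped),
#' each requested algorithm is tuned by grid search with k-fold CV and
#' refitted, and accuracy (R2, RMSE, nRMSE) plus the saturation diagnostic
#' are reported on the held-out test rows. No test row ever enters
#' screening, tuning or fitting.
#'
#' @param features Feature table: `plot_id`, `stage`, AIH columns
#'   (`H_5` ... `H_95`, `CH`) and/or vegetation-index columns.
#' @param truth Data frame with `plot_id`, `stage`, `true_agb` (the measured
#'   response).
#' @param models Algorithms to run (subset of RFR, XGBoost, GBRT, SVR, RR).
#' @param feature_sets Named list of column-name vectors; default builds
#'   AIH / VIs / VIs+AIH from the available columns.
#' @param stages Stage labels to evaluate (default: all present).
#' @param ratio Training fraction for the split (default 0.7).
#' @param seed Run seed; per-stage split seeds and per-model fit seeds are
#'   derived from it by stable name hashing.
#' @param screen_threshold Importance threshold in percent (default 1); set
#'   to 0 to disable screening.
#' @param grids Named list of hyperparameter grids (default
#'   [default_model_grids()]).
#' @param cv_folds CV folds for tuning (default 5).
#' @param top_fraction Tail fraction for [saturation_diagnostic()].
#' @return Object of class `agb_benchmark`: data frame with one row per
#'   stage x model x feature set (`R2`, `RMSE`, `nRMSE`, `saturation`,
#'   `n_train`, `n_test`), with attributes `retained` (screened feature
#'   names per stage/set), `splits` and `seed`.
#' @export
agb_benchmark <- function(features, truth,
                          models = c("RFR", "XGBoost", "GBRT", "SVR", "RR"),
                          feature_sets = NULL,
                          stages = NULL,
                          ratio = 0.7, seed = 42L,
                          screen_threshold = 1.0,
                          grids = default_model_grids(),
                          cv_folds = 5L, top_fraction = 0.2) {
  models <- match.arg(models, several.ok = TRUE)
  data <- merge(features, truth[, c("plot_id", "stage", "true_agb")],
                by = c("plot_id", "stage"))
  if (is.null(stages)) stages <- unique(data$stage)
  if (is.null(feature_sets)) {
    feature_sets <- .default_feature_sets(names(features))
  }
  if (!length(feature_sets)) {
    stop("no usable feature sets: need AIH and/or VI columns",
         call. = FALSE)
  }
  missing_cols <- setdiff(unique(unlist(feature_sets)), names(data))
  if (length(missing_cols)) {
    stop("feature set references absent columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  rows <- list()
  retained_log <- list()
  splits <- list()
  for (s in stages) {
    d <- data[data$stage == s, , drop = FALSE]
    sp <- split_train_test(nrow(d), ratio = ratio,
                           seed = derive_seed(seed, paste(s, "split")))
    splits[[s]] <- sp
    y_train <- d$true_agb[sp$train]
    y_test <- d$true_agb[sp$test]
    for (fs in names(feature_sets)) {
      cols <- feature_sets[[fs]]
      x_train <- d[sp$train, cols, drop = FALSE]
      x_test <- d[sp$test, cols, drop = FALSE]
      keep <- cols
      if (screen_threshold > 0 && length(cols) >= 2L) {
        keep <- tryCatch({
          imp <- rf_importance(x_train, y_train,
                               seed = derive_seed(seed,
                                                  paste(s, fs, "screen")))
          screen_features(imp, threshold = screen_threshold, quiet = TRUE)
        }, error = function(e) {
          warning("screening skipped for ", s, "/", fs, ": ",
                  conditionMessage(e), call. = FALSE)
          cols
        })
      }
      retained_log[[paste(s, fs, sep = "/")]] <- as.character(keep)
      for (mdl in models) {
        fit <- agb_fit(x_train[, keep, drop = FALSE], y_train, method = mdl,
                       grid = grids[[mdl]],
                       seed = derive_seed(seed, paste(s, fs, mdl)),
                       cv_folds = cv_folds)
        pred <- predict(fit, x_test[, keep, drop = FALSE])
        met <- agb_metrics(y_test, pred)
        rows[[length(rows) + 1L]] <- data.frame(
          stage = s, model = mdl, feature_set = fs,
          R2 = met$R2, RMSE = met$RMSE, nRMSE = met$nRMSE,
          saturation = tryCatch(
            saturation_diagnostic(y_test, pred, top_fraction),
            error = function(e) NA_real_),
          n_train = length(y_train), n_test = length(y_test),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "retained") <- retained_log
  attr(out, "splits") <- splits
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("agb_benchmark", "data.frame")
  out
}

#' @export
print.agb_benchmark <- function(x, digits = 3, ...) {
  cat("AGB estimation benchmark (held-out test metrics)\n")
  for (s in unique(x$stage)) {
    cat("\n== stage:", s, "==\n")
    d <- x[x$stage == s, , drop = FALSE]
    wide <- stats::reshape(
      d[, c("model", "feature_set", "R2")],
      idvar = "model", timevar = "feature_set", direction = "wide")
    names(wide) <- sub("^R2\\.", "R2 ", names(wide))
    print(format(wide, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.agb_benchmark <- function(object, ...) {
  agg <- stats::aggregate(cbind(R2, RMSE, nRMSE) ~ model + feature_set,
                          data = object, FUN = stats::median)
  cat("Median test metrics by model x feature set:\n")
  print(format(agg, digits = 3), row.names = FALSE)
  invisible(agg)
}
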