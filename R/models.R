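# The agb_fit modelling core: grid-searched, cross-validated fits of the
# five supported regression algorithms, returned as a classed object with
# the usual methods.

#' Default hyperparameter grids
#'
#' Small documented grids for the five supported algorithms. Each grid is a
#' named list of candidate vectors; the search enumerates their full cross
#' product in `expand.grid()` row order (ties in CV score go to the earlier
#' row).
#'
#' @return Named list of grids for RFR, XGBoost, GBRT, SVR and RR.
#' @export
default_model_grids <- function() {
  list(
    RFR = list(ntree = c(200, 500), nodesize = 5),
    XGBoost = list(eta = c(0.05, 0.1), nrounds = 200, max_depth = 3),
    GBRT = list(shrinkage = c(0.05, 0.1), n_trees = 200, max_depth = 2),
    SVR = list(cost = c(1, 10, 100), epsilon = 0.1),
    RR = list(lambda = 10^seq(-3, 2, by = 1)))
}

#' Random train/test split
#'
#' Uniform random partition of `n` rows into a training set of
#' `floor(ratio * n)` rows and a test set of the remainder.
#'
#' @param n Number of rows (>= 10).
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return Object of class `split_plan`: list with sorted integer vectors
#'   `train` and `test`, plus `ratio` and `seed`.
#' @export
split_train_test <- function(n, ratio = 0.7, seed = 42L) {
  n <- check_count(n, "n", lower = 10L)
  check_number(ratio, "ratio", lower = 1e-9, upper = 1 - 1e-9)
  perm <- with_seed(seed, sample.int(n))
  ntr <- floor(ratio * n + sqrt(.Machine$double.eps))
  structure(list(train = sort(perm[seq_len(ntr)]),
                 test = sort(perm[-seq_len(ntr)]),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_plan")
}

# --- gradient-boosted regression trees (squared loss) -----------------------
# Classic first-order gradient boosting: each shallow regression tree is fit
# to the current residuals and added with shrinkage. The base learner is a
# compact exhaustive-search CART regression tree (variance-reduction splits),
# vectorized so the boosting loop stays fast at benchmark problem sizes.

.reg_tree_fit <- function(X, y, max_depth = 2L, min_node = 5L) {
  nodes <- list()
  grow <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(leaf = TRUE, value = mean(y[idx]))
    n <- length(idx)
    if (depth >= max_depth || n < 2L * min_node) return(id)
    best <- NULL
    best_gain <- 1e-12
    ytot <- sum(y[idx])
    for (j in seq_len(ncol(X))) {
      xo <- X[idx, j]
      ord <- order(xo)
      xs <- xo[ord]
      cl <- cumsum(y[idx][ord])
      k <- seq_len(n - 1L)
      valid <- (xs[k] < xs[k + 1L]) & k >= min_node & (n - k) >= min_node
      if (!any(valid)) next
      gain <- cl[k]^2 / k + (ytot - cl[k])^2 / (n - k) - ytot^2 / n
      gain[!valid] <- -Inf
      bk <- which.max(gain)
      if (gain[bk] > best_gain) {
        best_gain <- gain[bk]
        best <- list(j = j, thr = (xs[bk] + xs[bk + 1L]) / 2,
                     left = idx[ord[seq_len(bk)]],
                     right = idx[ord[-seq_len(bk)]])
      }
    }
    if (is.null(best)) return(id)
    l <- grow(best$left, depth + 1L)
    r <- grow(best$right, depth + 1L)
    nodes[[id]] <<- list(leaf = FALSE, j = best$j, thr = best$thr,
                         left = l, right = r)
    id
  }
  root <- grow(seq_along(y), 0L)
  list(nodes = nodes, root = root)
}

.reg_tree_predict <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(id, idx) {
    nd <- tree$nodes[[id]]
    if (nd$leaf) {
      out[idx] <<- nd$value
      return(invisible(NULL))
    }
    go_l <- X[idx, nd$j] <= nd$thr
    if (any(go_l)) rec(nd$left, idx[go_l])
    if (any(!go_l)) rec(nd$right, idx[!go_l])
  }
  rec(tree$root, seq_len(nrow(X)))
  out
}

.gbrt_train <- function(x, y, n_trees, shrinkage, max_depth) {
  X <- as.matrix(x)
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", n_trees)
  for (m in seq_len(n_trees)) {
    tr <- .reg_tree_fit(X, resid, max_depth = max_depth)
    trees[[m]] <- tr
    resid <- resid - shrinkage * .reg_tree_predict(tr, X)
  }
  list(f0 = f0, trees = trees, shrinkage = shrinkage)
}

.gbrt_predict <- function(model, x) {
  X <- as.matrix(x)
  pred <- rep(model$f0, nrow(X))
  for (tr in model$trees) {
    pred <- pred + model$shrinkage * .reg_tree_predict(tr, X)
  }
  pred
}

# --- per-algorithm fit/predict dispatch --------------------------------------

.fit_engine <- function(method, params, x, y, seed) {
  switch(method,
    RFR = with_seed(seed, randomForest::randomForest(
      x = x, y = y, ntree = params$ntree, nodesize = params$nodesize)),
    XGBoost = xgboost::xgb.train(
      params = list(eta = params$eta, max_depth = params$max_depth,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    GBRT = .gbrt_train(x, y, n_trees = params$n_trees,
                       shrinkage = params$shrinkage,
                       max_depth = params$max_depth),
    SVR = e1071::svm(x = as.matrix(x), y = y, type = "eps-regression",
                     kernel = "radial", cost = params$cost,
                     epsilon = params$epsilon, scale = FALSE),
    RR = {
      df <- as.data.frame(x)
      df$.y <- y
      MASS::lm.ridge(.y ~ ., data = df, lambda = params$lambda)
    },
    stop("unknown model: ", method, call. = FALSE))
}

.predict_engine <- function(method, model, x) {
  switch(method,
    RFR = unname(stats::predict(model, x)),
    XGBoost = unname(stats::predict(model, as.matrix(x))),
    GBRT = .gbrt_predict(model, x),
    SVR = unname(stats::predict(model, as.matrix(x))),
    RR = {
      cf <- stats::coef(model)
      unname(drop(cbind(1, as.matrix(x)) %*% cf))
    })
}

# Algorithms whose inputs are standardized (fit on the training split only).
.needs_scaling <- function(method) method %in% c("SVR", "RR")

#' Fit an AGB regression model with grid-searched hyperparameters
#'
#' The central fitting function. For the requested algorithm it enumerates
#' the hyperparameter grid, scores every combination by k-fold
#' cross-validated RMSE on the training data (folds shuffled once from the
#' seed and shared across the whole grid; ties broken by grid order), then
#' refits the best combination on all rows. Inputs of the scale-sensitive
#' algorithms (SVR, RR) are standardized with training means/sds; tree
#' ensembles are fit on raw features.
#'
#' Supported algorithms: `"RFR"` (random-forest regression), `"XGBoost"`,
#' `"GBRT"` (least-squares gradient boosting over regression trees),
#' `"SVR"` (RBF-kernel support vector regression) and `"RR"` (ridge
#' regression).
#'
#' @param x Data frame or matrix of features (training split).
#' @param y Numeric response (AGB, t/hm2).
#' @param method Algorithm name, see above.
#' @param grid Named list of candidate hyperparameter vectors; defaults to
#'   the matching entry of [default_model_grids()].
#' @param seed Integer seed driving fold shuffling and stochastic fits.
#' @param cv_folds Number of CV folds (default 5).
#' @return Object of class `agb_fit` with elements `method`, `best`
#'   (selected hyperparameters), `cv_rmse` (best mean CV RMSE), `cv_table`
#'   (all grid rows with scores), `model`, `fitted`, and scaling info.
#' @examples
#' x <- data.frame(a = rnorm(40), b = rnorm(40))
#' y <- 2 * x$a + rnorm(40, sd = 0.1)
#' fit <- agb_fit(x, y, "RR", grid = list(lambda = c(0, 1)), seed = 1)
#' coef(fit)
#' @export
agb_fit <- function(x, y, method = c("RFR", "XGBoost", "GBRT", "SVR", "RR"),
                    grid = NULL, seed = 42L, cv_folds = 5L) {
  method <- match.arg(method)
  cv_folds <- check_count(cv_folds, "cv_folds", lower = 2L)
  x <- as.data.frame(x)
  n <- nrow(x)
  if (n < cv_folds) stop("fewer training rows than CV folds", call. = FALSE)
  if (length(y) != n) stop("x and y sizes differ", call. = FALSE)
  if (is.null(grid)) grid <- default_model_grids()[[method]]
  if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)

  feature_names <- names(x)
  xs <- x
  names(xs) <- make.names(feature_names)
  scaling <- NULL
  if (.needs_scaling(method)) {
    ctr <- vapply(xs, mean, numeric(1))
    scl <- vapply(xs, stats::sd, numeric(1))
    scl[scl < 1e-12] <- 1
    xs <- as.data.frame(scale(xs, center = ctr, scale = scl))
    scaling <- list(center = ctr, scale = scl)
  }

  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  fold_of <- with_seed(derive_seed(seed, paste(method, "folds")),
                       sample(rep_len(seq_len(cv_folds), n)))
  cv_scores <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    params <- as.list(combos[ci, , drop = FALSE])
    fold_rmse <- numeric(cv_folds)
    for (fd in seq_len(cv_folds)) {
      hold <- fold_of == fd
      fit <- .fit_engine(method, params, xs[!hold, , drop = FALSE],
                         y[!hold],
                         seed = derive_seed(seed, paste(method, ci, fd)))
      pred <- .predict_engine(method, fit, xs[hold, , drop = FALSE])
      fold_rmse[fd] <- sqrt(mean((y[hold] - pred)^2))
    }
    cv_scores[ci] <- mean(fold_rmse)
  }
  best_i <- which.min(cv_scores)  # first minimum = first-in-grid tie break
  best <- as.list(combos[best_i, , drop = FALSE])
  model <- .fit_engine(method, best, xs, y,
                       seed = derive_seed(seed, paste(method, "final")))
  fitted_vals <- .predict_engine(method, model, xs)

  structure(list(method = method, best = best,
                 cv_rmse = cv_scores[best_i],
                 cv_table = cbind(combos, cv_rmse = cv_scores),
                 model = model, scaling = scaling,
                 feature_names = feature_names,
                 fitted = fitted_vals, y = y,
                 seed = as.integer(seed), cv_folds = cv_folds),
            class = "agb_fit")
}

#' Predict from an agb_fit model
#'
#' @param object An [agb_fit()] object.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.agb_fit <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  xs <- newdata[, object$feature_names, drop = FALSE]
  names(xs) <- make.names(object$feature_names)
  if (!is.null(object$scaling)) {
    xs <- as.data.frame(scale(xs, center = object$scaling$center,
                              scale = object$scaling$scale))
  }
  .predict_engine(object$method, object$model, xs)
}

#' @export
print.agb_fit <- function(x, ...) {
  cat(sprintf("agb_fit: %s on %d features (n = %d)\n", x$method,
              length(x$feature_names), length(x$y)))
  cat("  best hyperparameters: ",
      paste(names(x$best), unlist(x$best), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  CV RMSE (%d-fold): %.4f\n", x$cv_folds, x$cv_rmse))
  invisible(x)
}

#' @export
summary.agb_fit <- function(object, ...) {
  m <- agb_metrics(object$y, object$fitted)
  cat(sprintf("agb_fit summary (%s)\n", object$method))
  cat(sprintf("  training R2 %.3f, RMSE %.3f, nRMSE %.2f%%\n",
              m$R2, m$RMSE, m$nRMSE))
  cat(sprintf("  CV RMSE %.4f over %d grid points\n", object$cv_rmse,
              nrow(object$cv_table)))
  invisible(list(train_metrics = m, cv_table = object$cv_table))
}

#' @export
coef.agb_fit <- function(object, ...) {
  if (object$method != "RR") return(NULL)
  cf <- stats::coef(object$model)
  # translate back to the original (unstandardized) feature scale
  s <- object$scaling
  beta <- cf[-1] / s$scale
  intercept <- cf[1] - sum(cf[-1] * s$center / s$scale)
  stats::setNames(c(intercept, beta),
                  c("(Intercept)", object$feature_names))
}

#' @export
residuals.agb_fit <- function(object, ...) {
  object$y - object$fitted
}

#' @export
fitted.agb_fit <- function(object, ...) {
  object$fitted
}
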