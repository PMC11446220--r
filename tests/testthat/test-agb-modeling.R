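# Splitting, metrics, the agb_fit core, and the benchmark report.

test_that("train/test split is a deterministic 7:3 partition", {
  sp <- split_train_test(180, seed = 3)
  expect_equal(length(sp$train), 126L)
  expect_equal(length(sp$test), 54L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:180)
  expect_identical(sp, split_train_test(180, seed = 3))
  expect_false(identical(sp$train, split_train_test(180, seed = 4)$train))
  expect_error(split_train_test(9), ">= 10")
})

test_that("metrics match their defining formulas to 1e-12", {
  m <- agb_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(m$RMSE, 1, tolerance = 1e-12)
  expect_equal(m$nRMSE, 50, tolerance = 1e-12)

  perfect <- agb_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$RMSE, 0)
  expect_equal(perfect$nRMSE, 0)

  # the null predictor (mean of measured) has R2 exactly 0
  x <- c(4, 7, 2, 9)
  null <- agb_metrics(x, rep(mean(x), 4))
  expect_equal(null$R2, 0, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(20, mean = 6)
    y <- x + rnorm(20)
    got <- agb_metrics(x, y)
    want <- metrics_oracle(x, y)
    expect_equal(got$R2, want$R2, tolerance = 1e-12)
    expect_equal(got$RMSE, want$RMSE, tolerance = 1e-12)
    expect_equal(got$nRMSE, want$nRMSE, tolerance = 1e-12)
  }
  expect_error(agb_metrics(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(agb_metrics(1, 1), "length")
})

test_that("saturation diagnostic flags tail under-prediction", {
  x <- 1:20
  expect_equal(saturation_diagnostic(x, x), 0)
  clipped <- pmin(x, 12)
  expect_gt(saturation_diagnostic(x, clipped), 0)
  expect_equal(saturation_diagnostic(x, clipped, top_fraction = 1),
               mean(x - clipped), tolerance = 1e-12)
  expect_error(saturation_diagnostic(1:5, 1:5, top_fraction = 0.2),
               "fewer than 3")
})

test_that("grid search honors the grid and breaks ties by order", {
  set.seed(41)
  x <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- x$a + rnorm(30, sd = 0.2)
  single <- agb_fit(x, y, "RR", grid = list(lambda = 0.5), seed = 1)
  expect_equal(single$best$lambda, 0.5)
  expect_equal(nrow(single$cv_table), 1L)

  fit <- agb_fit(x, y, "RR", seed = 1)
  expect_true(fit$best$lambda %in% default_model_grids()$RR$lambda)
  # duplicated grid entries tie exactly; the first must win
  tied <- agb_fit(x, y, "RR", grid = list(lambda = c(1, 1)), seed = 1)
  expect_equal(which.min(tied$cv_table$cv_rmse), 1L)
})

test_that("ridge with vanishing penalty recovers a noise-free linear law", {
  set.seed(51)
  x <- data.frame(a = rnorm(40), b = runif(40), c = rnorm(40, sd = 2))
  y <- 3 + 1.5 * x$a - 2 * x$b + 0.25 * x$c
  fit <- agb_fit(x, y, "RR", grid = list(lambda = c(0, 0.1, 1)), seed = 2)
  expect_equal(fit$best$lambda, 0)
  cf <- coef(fit)
  expect_equal(unname(cf), c(3, 1.5, -2, 0.25), tolerance = 1e-6)
  expect_equal(predict(fit, x), y, tolerance = 1e-6)
})

test_that("every algorithm fits, predicts and is seed-deterministic", {
  set.seed(61)
  n <- 60
  x <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  y <- 2 * x$a + sin(3 * x$b) + rnorm(n, sd = 0.1)
  grids <- list(RFR = list(ntree = 100, nodesize = 5),
                XGBoost = list(eta = 0.1, nrounds = 60, max_depth = 3),
                GBRT = list(shrinkage = 0.1, n_trees = 60, max_depth = 2),
                SVR = list(cost = c(1, 10), epsilon = 0.1),
                RR = list(lambda = c(0.01, 1)))
  for (m in names(grids)) {
    f1 <- agb_fit(x, y, m, grid = grids[[m]], seed = 9, cv_folds = 3)
    f2 <- agb_fit(x, y, m, grid = grids[[m]], seed = 9, cv_folds = 3)
    p1 <- predict(f1, x)
    expect_identical(p1, predict(f2, x))
    expect_length(p1, n)
    # each model must beat the null predictor in-sample
    expect_lt(sqrt(mean((y - p1)^2)), sd(y))
    expect_true(all(vapply(names(f1$best), function(nm) {
      f1$best[[nm]] %in% grids[[m]][[nm]]
    }, logical(1))))
  }
  expect_error(predict(agb_fit(x, y, "RR", seed = 1),
                       data.frame(a = 1, b = 2)), "lacks feature")
})

test_that("GBRT captures a nonlinear signal", {
  set.seed(71)
  n <- 120
  x <- data.frame(u = runif(n, -2, 2), v = runif(n, -2, 2))
  y <- x$u^2 + rnorm(n, sd = 0.1)
  fit <- agb_fit(x, y, "GBRT",
                 grid = list(shrinkage = 0.1, n_trees = 150, max_depth = 2),
                 seed = 3, cv_folds = 3)
  r2 <- agb_metrics(y, fitted(fit))$R2
  expect_gt(r2, 0.8)
  expect_equal(residuals(fit), y - fitted(fit))
})

test_that("benchmark report has the full stage x model x set shape", {
  cfg <- tiny_field_config(plots_per_treatment = 30L)
  field <- simulate_field(cfg, stages = c("jointing", "heading"),
                          clouds = FALSE)
  # synthetic AIH-like structural features derived from the truth, so the
  # report shape can be checked without the cloud pipeline
  tr <- field$truth
  set.seed(81)
  feats <- data.frame(plot_id = tr$plot_id, stage = tr$stage,
                      H_60 = 0.8 * tr$true_height + rnorm(nrow(tr), 0, 0.02),
                      H_95 = tr$true_height + rnorm(nrow(tr), 0, 0.02),
                      CH = tr$true_height + rnorm(nrow(tr), 0, 0.02))
  vit <- vi_table(field$reflectance)
  feats <- merge(feats, vit, by = c("plot_id", "stage"))
  grids <- list(RR = list(lambda = c(0.01, 1)),
                GBRT = list(shrinkage = 0.1, n_trees = 40, max_depth = 2))
  bm <- agb_benchmark(feats, tr, models = c("GBRT", "RR"), seed = 13,
                      grids = grids, screen_threshold = 0)
  expect_s3_class(bm, "agb_benchmark")
  expect_equal(nrow(bm), 2 * 3 * 2)  # stages x feature sets x models
  expect_setequal(unique(bm$feature_set), c("AIH", "VIs", "VIs+AIH"))
  expect_setequal(unique(bm$stage), c("jointing", "heading"))
  expect_true(all(bm$RMSE >= 0))
  expect_true(all(bm$R2 <= 1))
  expect_equal(unique(bm$n_train), 42L)  # floor(0.7 * 60)
  expect_equal(unique(bm$n_test), 18L)

  # rerun with the same seed reproduces the report exactly
  bm2 <- agb_benchmark(feats, tr, models = c("GBRT", "RR"), seed = 13,
                       grids = grids, screen_threshold = 0)
  expect_identical(as.data.frame(bm), as.data.frame(bm2))

  # the split is a partition, so no test row reaches the training stage
  sp <- attr(bm, "splits")$jointing
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_len(60))
})

test_that("benchmark rejects feature sets naming absent columns", {
  cfg <- tiny_field_config()
  field <- simulate_field(cfg, stages = "jointing", clouds = FALSE)
  vit <- vi_table(field$reflectance)
  expect_error(
    agb_benchmark(vit, field$truth, models = "RR",
                  feature_sets = list(bad = c("NDVI", "H_95"))),
    "absent columns")
})
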