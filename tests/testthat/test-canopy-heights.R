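# Point-cloud preprocessing, AIH profiles and crop-height estimators.

test_that("denoise removes gross outliers and nothing else", {
  # points on a circle: every k = 2 neighbourhood is congruent, so no point
  # can exceed the mean-distance threshold
  ang <- 2 * pi * (0:19) / 20
  circle <- data.frame(x = cos(ang), y = sin(ang), z = 1)
  expect_identical(denoise(circle, k = 2), circle)

  g <- expand.grid(x = seq(0, 2, 0.2), y = seq(0, 2, 0.2))
  cloud <- data.frame(x = g$x, y = g$y, z = 1)
  spiked <- rbind(cloud, data.frame(x = 1, y = 1, z = 100))
  cleaned <- denoise(spiked, k = 4)
  expect_equal(nrow(cleaned), nrow(cloud))
  expect_true(all(cleaned$z == 1))
  expect_identical(denoise(spiked, k = 4, n_sigma = Inf), spiked)
  small <- cloud[1:3, ]
  expect_warning(out <- denoise(small, k = 5), "smaller than k")
  expect_identical(out, small)
})

test_that("minimum-surface classification separates ground and canopy", {
  flat <- data.frame(x = runif(50), y = runif(50), z = 2)
  expect_true(all(classify_ground(flat)$class == "ground"))

  mixed <- rbind(data.frame(x = runif(40), y = runif(40), z = 0),
                 data.frame(x = runif(40), y = runif(40), z = 0.5))
  cls <- classify_ground(mixed, grid_size = 2)
  expect_true(all(cls$class[mixed$z == 0] == "ground"))
  expect_true(all(cls$class[mixed$z == 0.5] == "vegetation"))

  single <- data.frame(x = 0.3, y = 0.4, z = 7)
  expect_equal(classify_ground(single)$class, "ground")
  expect_error(classify_ground(flat[0, ]), "empty")
})

test_that("normalization subtracts the ground reference and clips", {
  dem <- surface_grid(matrix(5, 4, 4), cell = 0.5, ix0 = 0, iy0 = 0,
                      role = "dem")
  cloud <- data.frame(x = c(0.6, 1.1, 1.4), y = c(0.6, 0.9, 1.2),
                      z = c(5.4, 4.8, 5.0))
  norm <- normalize_heights(cloud, dem)
  expect_equal(norm$heights, c(0.4, 0, 0))  # below-ground clipped to 0

  # planar reference: bilinear interpolation of a plane is exact anywhere
  cc_x <- (0:9 + 0.5) * 0.5
  cc_y <- (0:9 + 0.5) * 0.5
  plane <- function(x, y) 2 + 0.3 * x - 0.2 * y
  dem_p <- surface_grid(outer(cc_x, cc_y, plane), cell = 0.5,
                        ix0 = 0, iy0 = 0, role = "dem")
  set.seed(1)
  px <- runif(30, 0.3, 4.7)
  py <- runif(30, 0.3, 4.7)
  cl <- data.frame(x = px, y = py, z = plane(px, py) + 0.3)
  expect_equal(normalize_heights(cl, dem_p)$heights, rep(0.3, 30),
               tolerance = 1e-12)
})

test_that("normalization rejects disjoint extents and empty clouds", {
  dem <- surface_grid(matrix(5, 2, 2), cell = 0.5, ix0 = 0, iy0 = 0)
  far <- data.frame(x = 100, y = 100, z = 5)
  expect_error(normalize_heights(far, dem), "disjoint")
  expect_error(normalize_heights(far[0, ], dem), "empty")
})

test_that("drop_ground yields a vegetation-only cloud", {
  dem <- surface_grid(matrix(0, 4, 4), cell = 0.5, ix0 = 0, iy0 = 0)
  cloud <- data.frame(x = runif(40, 0, 2), y = runif(40, 0, 2),
                      z = rep(c(0, 0.6), each = 20),
                      source = rep(c("ground", "canopy"), each = 20))
  norm <- normalize_heights(cloud, dem, drop_ground = TRUE)
  expect_equal(norm$n, 20L)
  expect_true(all(norm$heights == 0.6))
})

test_that("AIH profile follows the accumulated-height definition", {
  p <- aih_profile(c(0.1, 0.2, 0.3, 0.4), percentiles = c(5, 50, 100))
  # cumulative sums 0.1, 0.3, 0.6, 1.0; 50% of total (0.5) first reached at
  # the 0.3 point; 5% (0.05) at the first point; 100% at the maximum
  expect_equal(p$heights, c(0.1, 0.3, 0.4))

  uniform <- aih_profile(rep(0.7, 25), percentiles = c(1, 40, 95, 100))
  expect_equal(uniform$heights, rep(0.7, 4))

  zero <- aih_profile(rep(0, 10), percentiles = c(50, 100))
  expect_true(zero$degenerate)
  expect_equal(zero$heights, c(0, 0))

  expect_error(aih_profile(numeric(0)), "empty")
  expect_error(aih_profile(c(0.1, -0.2)), "non-negative")
  expect_error(aih_profile(0.5, percentiles = c(0, 50)), "\\(0, 100\\]")
})

test_that("AIH implementation matches the brute-force oracle exactly", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(1:50, 1)
    h <- round(rexp(n, rate = 2), 3)
    if (rep %% 7 == 0) h[sample(n, ceiling(n / 3))] <- 0
    pct <- sort(sample(c(1:99, 100), sample(3:8, 1)))
    got <- aih_profile(h, percentiles = pct)$heights
    want <- vapply(pct, function(X) aih_oracle(h, X), numeric(1))
    expect_identical(got, want)
  }
})

test_that("AIH is monotone, bounded, and dominates count percentiles", {
  set.seed(202)
  for (rep in 1:60) {
    h <- rexp(sample(5:400, 1))
    pct <- sort(sample(1:100, 12))
    prof <- aih_profile(h, percentiles = pct)
    expect_true(all(diff(prof$heights) >= 0))
    expect_true(all(prof$heights >= min(h) & prof$heights <= max(h)))
    expect_equal(aih_profile(h, percentiles = 100)$heights, max(h))
    cp <- vapply(pct, function(X) count_percentile(h, X), numeric(1))
    expect_true(all(prof$heights >= cp - 1e-12))
  }
})

test_that("heights and estimates are invariant to vertical translation", {
  set.seed(303)
  cloud <- data.frame(x = runif(300, 0, 2), y = runif(300, 0, 4),
                      z = c(rnorm(150, 0, 0.01), runif(150, 0.2, 0.8)))
  dem <- surface_grid(matrix(0, 4, 8), cell = 0.5, ix0 = 0, iy0 = 0)
  plt <- list(origin_x = 0, origin_y = 0, width = 2, length = 4)
  run <- function(shift) {
    cl <- cloud
    cl$z <- cl$z + shift
    dm <- dem
    dm$values <- dm$values + shift
    norm <- normalize_heights(cl, dm)
    prof <- aih_profile(norm, percentiles = c(1, 50, 95, 100))
    dsm <- rasterize_surface(cl, role = "dsm",
                             extent = c(0, 2, 0, 4))
    list(h = norm$heights, prof = prof$heights,
         aih = crop_height_aih(prof),
         chm = crop_height_chm_mean(dsm, dm, plt))
  }
  a <- run(0)
  b <- run(13.7)
  expect_equal(a$h, b$h, tolerance = 1e-9)
  expect_equal(a$prof, b$prof, tolerance = 1e-9)
  expect_equal(a$aih, b$aih, tolerance = 1e-9)
  expect_equal(a$chm, b$chm, tolerance = 1e-9)
})

test_that("AIH-difference crop height behaves per definition", {
  prof <- aih_profile(c(0.1, 0.2, 0.3, 0.4), percentiles = c(5, 100))
  expect_equal(crop_height_aih(prof, upper = 100, baseline = 5), 0.3)
  uniform <- aih_profile(rep(0.5, 30), percentiles = c(1, 95))
  expect_equal(crop_height_aih(uniform, upper = 95, baseline = 1), 0)
  expect_error(crop_height_aih(prof, upper = 95, baseline = 1),
               "not present")
  expect_error(crop_height_aih(prof, upper = 5, baseline = 100),
               "baseline")
})

test_that("rasterization handles flat, planar and gap-filled fields", {
  set.seed(7)
  flat <- data.frame(x = runif(400, 0, 3), y = runif(400, 0, 3), z = 4)
  for (m in c("kriging", "idw")) {
    g <- rasterize_surface(flat, cell = 0.5, role = "dsm", method = m)
    expect_equal(as.vector(g$values), rep(4, g$nx * g$ny))
  }

  plane <- function(x, y) 1 + 0.04 * x - 0.03 * y
  px <- runif(4000, 0, 4)
  py <- runif(4000, 0, 4)
  pl <- data.frame(x = px, y = py, z = plane(px, py))
  g <- rasterize_surface(pl, cell = 0.5, role = "dem", method = "idw",
                         extent = c(0, 4, 0, 4))
  centers_x <- (g$ix0 + seq_len(g$nx) - 0.5) * g$cell
  centers_y <- (g$iy0 + seq_len(g$ny) - 0.5) * g$cell
  want <- outer(centers_x, centers_y, plane)
  # seeds are per-cell minima, offset by at most the in-cell plane range
  expect_lt(max(abs(g$values - want)), 0.04 * 0.5 + 0.03 * 0.5)

  # an empty cell flanked by equal-valued seeds fills to that value
  gap <- data.frame(x = c(0.25, 0.25, 2.25, 2.25, 0.75, 1.75),
                    y = c(0.25, 0.75, 0.25, 0.75, 0.25, 0.75), z = 2)
  for (m in c("kriging", "idw")) {
    gg <- rasterize_surface(gap, cell = 0.5, role = "dsm", method = m,
                            extent = c(0, 2.5, 0, 1))
    expect_equal(as.vector(gg$values), rep(2, gg$nx * gg$ny))
  }
  expect_error(rasterize_surface(flat[0, ]), "empty")
  # empty cells but only two seeded cells: nothing to fit a surface from
  sparse <- data.frame(x = c(0.1, 1.9), y = c(0.1, 0.1), z = c(1, 2))
  expect_error(rasterize_surface(sparse, cell = 0.5,
                                 extent = c(0, 2, 0, 0.5)),
               "fewer than 3")
})

test_that("CHM-mean equals the plot average of DSM minus DEM", {
  dem <- surface_grid(matrix(10, 2, 2), cell = 0.5, ix0 = 0, iy0 = 0,
                      role = "dem")
  plt <- list(origin_x = 0, origin_y = 0, width = 1, length = 1)
  dsm_const <- surface_grid(matrix(10.8, 2, 2), cell = 0.5, ix0 = 0,
                            iy0 = 0)
  expect_equal(crop_height_chm_mean(dsm_const, dem, plt), 0.8)
  expect_equal(crop_height_chm_mean(dem, dem, plt), 0)
  dsm_mix <- surface_grid(matrix(10 + c(0.4, 0.6, 0.5, 0.5), 2, 2),
                          cell = 0.5, ix0 = 0, iy0 = 0)
  expect_equal(crop_height_chm_mean(dsm_mix, dem, plt), 0.5)
  bad <- surface_grid(matrix(10, 2, 2), cell = 0.25, ix0 = 0, iy0 = 0)
  expect_error(crop_height_chm_mean(bad, dem, plt), "misaligned")
})

test_that("per-plot feature extraction recovers the true height", {
  # realistic ground texture (micro-relief + reconstruction noise) is what
  # anchors the low-percentile AIH baseline at ground level
  cfg <- field_config(n_treatments = 1, plots_per_treatment = 1)
  lay <- make_field_layout(cfg)
  tr <- simulate_truth(lay, "filling", cfg, seed = 21)
  pc <- simulate_point_cloud(lay[1, ], tr[1, ], cfg, seed = 21)
  f <- plot_height_features(pc$crop, pc$bare, lay[1, ])
  expect_named(f, c("H_5", "H_20", "H_40", "H_60", "H_80", "H_95", "CH",
                    "chm_mean", "profile"))
  expect_true(all(diff(unlist(f[paste0("H_", c(5, 20, 40, 60, 80, 95))]))
                  >= 0))
  expect_lt(abs(f$CH - tr$true_height[1]), 0.05)
  expect_lt(abs(f$chm_mean - tr$true_height[1]), 0.07)
})
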