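# Synthetic winter-wheat field experiment: layout, ground-truth traits,
# canopy/bare point clouds and band reflectances with known generating
# parameters, so the full height/VI/AGB pipeline can be exercised end to end.

#' Configuration for the synthetic field generator
#'
#' Builds a validated configuration object describing a nitrogen-rate field
#' trial: six fertilizer treatments (300, 240, 180, 120, 60, 0 kg/ha) with 30
#' plots of 1.4 m x 4 m each by default, sampled at three growth stages
#' (jointing, heading, grain filling). Stage-wise trait distributions default
#' to the field statistics of a winter-wheat trial of this design: mean crop
#' height 0.484/0.768/0.836 m with CV 8.74/7.27/8.08 % and mean AGB
#' 2.33/4.96/8.25 t/hm2 with CV 37.72/21.67/15.56 % at jointing, heading and
#' filling respectively. The population CV targets include the between-
#' treatment gradient; the generator calibrates the within-treatment spread
#' accordingly.
#'
#' @param seed Default integer seed for all generator operations.
#' @param n_treatments Number of nitrogen treatments (labels cycle N1..N6).
#' @param plots_per_treatment Plots per treatment.
#' @param nitrogen_rates Nitrogen rates (kg/ha) for treatments N1..N6.
#' @param plot_width,plot_length Plot extent in metres.
#' @param alley Gap between neighbouring plots in the layout (m).
#' @param row_spacing Planting row spacing (m).
#' @param stage_height_params,stage_agb_params Named lists (one entry per
#'   stage) of `c(mean, cv)`; mean in m (height) or t/hm2 (AGB), cv in percent.
#' @param treatment_effect Multiplicative trait gradient across treatments
#'   (recycled to `n_treatments`; mean should be ~1 so stage means are
#'   preserved).
#' @param height_agb_cor Latent correlation between plot height and AGB
#'   deviations (shared "vigor" term).
#' @param ground_point_density,canopy_point_density Point densities (pts/m2).
#' @param ground_roughness_sd Ground micro-relief standard deviation (m).
#' @param point_noise_sd Per-point vertical reconstruction noise (m),
#'   emulating photogrammetric matching error.
#' @param canopy_shape List with `shape1`, `shape2` (beta parameters of the
#'   canopy vertical point distribution; mass concentrated near the top) and
#'   `anchor_top` (logical; rescale so the tallest sampled point equals the
#'   true height, making the canopy top encode the truth exactly).
#' @param row_jitter_sd Lateral scatter of canopy points around their row (m).
#' @param terrain Numeric `c(z0, gx, gy)`: ground plane elevation
#'   `z0 + gx*x + gy*y` (m) of the local terrain.
#' @param reflectance_soil,reflectance_canopy Named band reflectances (B, G,
#'   R, EDGE, NIR) of bare soil and of a closed canopy, each in \[0, 1\].
#' @param saturation_rate Rate (per t/hm2) of the saturating canopy-cover
#'   response `1 - exp(-rate * AGB)` that mixes soil and canopy reflectance.
#' @param band_noise_sd Additive Gaussian reflectance noise per band.
#'
#' @return An object of class `field_config` (a validated list).
#' @examples
#' cfg <- field_config()
#' length(make_field_layout(cfg)$plot_id)
#' @export
field_config <- function(seed = 42L,
                         n_treatments = 6L,
                         plots_per_treatment = 30L,
                         nitrogen_rates = c(300, 240, 180, 120, 60, 0),
                         plot_width = 1.4,
                         plot_length = 4.0,
                         alley = 0.5,
                         row_spacing = 0.15,
                         stage_height_params = list(
                           jointing = c(mean = 0.484, cv = 8.74),
                           heading  = c(mean = 0.768, cv = 7.27),
                           filling  = c(mean = 0.836, cv = 8.08)),
                         stage_agb_params = list(
                           jointing = c(mean = 2.33, cv = 37.72),
                           heading  = c(mean = 4.96, cv = 21.67),
                           filling  = c(mean = 8.25, cv = 15.56)),
                         treatment_effect = c(1.10, 1.06, 1.02,
                                              0.98, 0.94, 0.90),
                         height_agb_cor = 0.7,
                         ground_point_density = 200,
                         canopy_point_density = 250,
                         ground_roughness_sd = 0.01,
                         point_noise_sd = 0.01,
                         canopy_shape = list(shape1 = 6, shape2 = 1.2,
                                             anchor_top = TRUE),
                         row_jitter_sd = 0.02,
                         terrain = c(z0 = 50, gx = 0.005, gy = -0.003),
                         reflectance_soil = c(B = 0.12, G = 0.18, R = 0.20,
                                              EDGE = 0.22, NIR = 0.25),
                         reflectance_canopy = c(B = 0.04, G = 0.10, R = 0.04,
                                                EDGE = 0.35, NIR = 0.80),
                         saturation_rate = 0.25,
                         band_noise_sd = 0.01) {
  n_treatments <- check_count(n_treatments, "n_treatments")
  plots_per_treatment <- check_count(plots_per_treatment,
                                     "plots_per_treatment")
  check_number(plot_width, "plot_width", lower = 1e-9)
  check_number(plot_length, "plot_length", lower = 1e-9)
  check_number(alley, "alley", lower = 0)
  check_number(row_spacing, "row_spacing", lower = 1e-9)
  check_number(height_agb_cor, "height_agb_cor", lower = 0, upper = 1)
  check_number(ground_point_density, "ground_point_density", lower = 1e-9)
  check_number(canopy_point_density, "canopy_point_density", lower = 0)
  check_number(ground_roughness_sd, "ground_roughness_sd", lower = 0)
  check_number(point_noise_sd, "point_noise_sd", lower = 0)
  check_number(saturation_rate, "saturation_rate", lower = 1e-12)
  check_number(band_noise_sd, "band_noise_sd", lower = 0)

  stages <- names(stage_height_params)
  if (is.null(stages) || !identical(stages, names(stage_agb_params))) {
    stop("stage_height_params and stage_agb_params must be named lists over ",
         "the same stages", call. = FALSE)
  }
  for (s in stages) {
    for (p in list(stage_height_params[[s]], stage_agb_params[[s]])) {
      if (length(p) != 2L || any(!is.finite(p)) || p[[1]] <= 0 || p[[2]] < 0)
        stop("stage parameters must be c(mean > 0, cv >= 0) for stage ", s,
             call. = FALSE)
    }
  }
  bands <- c("B", "G", "R", "EDGE", "NIR")
  for (r in list(soil = reflectance_soil, canopy = reflectance_canopy)) {
    if (!all(bands %in% names(r)) || any(r[bands] < 0) || any(r[bands] > 1))
      stop("reflectance baselines must name bands B,G,R,EDGE,NIR with values ",
           "in [0,1]", call. = FALSE)
  }
  if (any(!is.finite(treatment_effect)) || any(treatment_effect <= 0))
    stop("treatment_effect must be positive multipliers", call. = FALSE)
  if (!all(c("shape1", "shape2") %in% names(canopy_shape)) ||
      canopy_shape$shape1 <= 0 || canopy_shape$shape2 <= 0)
    stop("canopy_shape must provide positive shape1 and shape2", call. = FALSE)
  if (is.null(canopy_shape$anchor_top)) canopy_shape$anchor_top <- TRUE

  cfg <- list(
    seed = as.integer(seed),
    n_treatments = n_treatments,
    plots_per_treatment = plots_per_treatment,
    nitrogen_rates = nitrogen_rates,
    plot_width = plot_width, plot_length = plot_length, alley = alley,
    row_spacing = row_spacing,
    stages = stages,
    stage_height_params = stage_height_params,
    stage_agb_params = stage_agb_params,
    treatment_effect = rep_len(treatment_effect, n_treatments),
    height_agb_cor = height_agb_cor,
    ground_point_density = ground_point_density,
    canopy_point_density = canopy_point_density,
    ground_roughness_sd = ground_roughness_sd,
    point_noise_sd = point_noise_sd,
    canopy_shape = canopy_shape,
    row_jitter_sd = row_jitter_sd,
    terrain = terrain,
    reflectance_soil = reflectance_soil[bands],
    reflectance_canopy = reflectance_canopy[bands],
    saturation_rate = saturation_rate,
    band_noise_sd = band_noise_sd)
  class(cfg) <- "field_config"
  cfg
}

#' @export
print.field_config <- function(x, ...) {
  cat("Synthetic field configuration\n")
  cat(sprintf("  %d treatments x %d plots (%.1f m x %.1f m), stages: %s\n",
              x$n_treatments, x$plots_per_treatment, x$plot_width,
              x$plot_length, paste(x$stages, collapse = ", ")))
  cat(sprintf("  densities: ground %g, canopy %g pts/m2; seed %d\n",
              x$ground_point_density, x$canopy_point_density, x$seed))
  invisible(x)
}

#' Lay out the synthetic field
#'
#' Places `n_treatments * plots_per_treatment` rectangular plots on a regular
#' grid in a local metric frame, one column strip per treatment, with an
#' alley between neighbouring plots so extents never overlap. Treatment
#' labels cycle N1..N6 and carry the nitrogen rates 300, 240, 180, 120, 60,
#' 0 kg/ha.
#'
#' @param config A [field_config()].
#' @return A data frame with one row per plot: `plot_id`, `treatment`,
#'   `nitrogen_rate`, `origin_x`, `origin_y`, `width`, `length`.
#' @examples
#' nrow(make_field_layout(field_config()))  # 180
#' @export
make_field_layout <- function(config) {
  stopifnot(inherits(config, "field_config"))
  nt <- config$n_treatments
  np <- config$plots_per_treatment
  ti <- rep(seq_len(nt), each = np)
  pj <- rep(seq_len(np), times = nt)
  lab_idx <- ((ti - 1L) %% 6L) + 1L
  data.frame(
    plot_id = sprintf("N%d_P%02d", lab_idx, pj),
    treatment = sprintf("N%d", lab_idx),
    nitrogen_rate = config$nitrogen_rates[lab_idx],
    origin_x = (ti - 1) * (config$plot_width + config$alley),
    origin_y = (pj - 1) * (config$plot_length + config$alley),
    width = config$plot_width,
    length = config$plot_length,
    stringsAsFactors = FALSE)
}

# Within-treatment CV calibrated so that the population CV (including the
# treatment gradient) matches the configured target.
.within_cv <- function(cv_total, gradient) {
  g <- gradient / mean(gradient)
  sd_g2 <- mean((g - 1)^2)
  sqrt(max(0, (cv_total^2 - sd_g2) / (1 + sd_g2)))
}

#' Simulate ground-truth height and AGB for one growth stage
#'
#' Per-plot true crop height and above-ground biomass are drawn from
#' truncated-at-zero normal distributions with the configured stage mean and
#' CV, scaled by the multiplicative treatment gradient. Height and AGB share
#' a latent plot "vigor" term so the two traits are positively correlated
#' (default correlation 0.7). Every plot uses its own random substream keyed
#' on `plot_id` and stage, so results are independent of row order and fully
#' deterministic given the seed.
#'
#' @param plots Layout data frame from [make_field_layout()].
#' @param stage Stage label; must be configured in `config`.
#' @param config A [field_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Data frame: `plot_id`, `stage`, `true_height` (m), `true_agb`
#'   (t/hm2).
#' @export
simulate_truth <- function(plots, stage, config, seed = config$seed) {
  stopifnot(inherits(config, "field_config"))
  if (!stage %in% config$stages)
    stop("unknown stage label: ", stage, call. = FALSE)
  hp <- config$stage_height_params[[stage]]
  bp <- config$stage_agb_params[[stage]]
  g_all <- config$treatment_effect / mean(config$treatment_effect)
  t_idx <- match(plots$treatment, sprintf("N%d", seq_len(6L)))
  t_idx <- ((t_idx - 1L) %% config$n_treatments) + 1L
  cv_h <- .within_cv(hp[["cv"]] / 100, g_all)
  cv_b <- .within_cv(bp[["cv"]] / 100, g_all)
  a <- sqrt(config$height_agb_cor)

  n <- nrow(plots)
  th <- numeric(n)
  tb <- numeric(n)
  for (i in seq_len(n)) {
    g <- g_all[t_idx[i]]
    sub <- derive_seed(seed, paste(plots$plot_id[i], stage, "truth"))
    draws <- with_seed(sub, {
      for (tries in 1:1000) {
        z <- stats::rnorm(3)
        zh <- a * z[1] + sqrt(1 - a^2) * z[2]
        zb <- a * z[1] + sqrt(1 - a^2) * z[3]
        h <- hp[["mean"]] * g * (1 + cv_h * zh)
        b <- bp[["mean"]] * g * (1 + cv_b * zb)
        if (h > 0 && b >= 0) break
      }
      c(h, max(b, 0))
    })
    th[i] <- draws[1]
    tb[i] <- draws[2]
  }
  data.frame(plot_id = plots$plot_id, stage = stage,
             true_height = th, true_agb = tb, stringsAsFactors = FALSE)
}

.terrain_z <- function(terrain, x, y) {
  terrain[[1]] + terrain[[2]] * x + terrain[[3]] * y
}

#' Simulate the bare-ground and crop point clouds of one plot
#'
#' The bare cloud samples the terrain plane plus Gaussian micro-relief at the
#' ground point density. The crop cloud consists of the same ground points
#' plus canopy points placed along planting rows; canopy heights above the
#' terrain follow a top-weighted scaled beta distribution (mass concentrated
#' near the canopy top, as photogrammetric wheat clouds are), scaled to the
#' plot's true height. With `anchor_top = TRUE` the tallest canopy point
#' equals the true height exactly, so the canopy top encodes the ground
#' truth. All points receive vertical reconstruction noise `point_noise_sd`.
#'
#' @param plot One layout row (data frame row or list with `plot_id`,
#'   `origin_x`, `origin_y`, `width`, `length`).
#' @param truth Matching row of [simulate_truth()] output.
#' @param config A [field_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with elements `crop` (data frame `x`, `y`, `z`, `source` in
#'   \{"ground", "canopy"\}) and `bare` (data frame `x`, `y`, `z`).
#' @export
simulate_point_cloud <- function(plot, truth, config, seed = config$seed) {
  stopifnot(inherits(config, "field_config"))
  w <- plot$width
  l <- plot$length
  if (!is.finite(w * l) || w * l <= 0)
    stop("plot has zero area", call. = FALSE)
  sub <- derive_seed(seed, paste(plot$plot_id, truth$stage, "cloud"))
  cs <- config$canopy_shape
  with_seed(sub, {
    n_g <- stats::rpois(1, config$ground_point_density * w * l)
    gx <- plot$origin_x + stats::runif(n_g) * w
    gy <- plot$origin_y + stats::runif(n_g) * l
    gz <- .terrain_z(config$terrain, gx, gy) +
      stats::rnorm(n_g, 0, config$ground_roughness_sd) +
      stats::rnorm(n_g, 0, config$point_noise_sd)
    bare <- data.frame(x = gx, y = gy, z = gz)

    n_c <- stats::rpois(1, config$canopy_point_density * w * l)
    if (n_c > 0) {
      row_x <- plot$origin_x +
        seq(config$row_spacing / 2, w, by = config$row_spacing)
      cx <- row_x[sample.int(length(row_x), n_c, replace = TRUE)] +
        stats::rnorm(n_c, 0, config$row_jitter_sd)
      cx <- pmin(pmax(cx, plot$origin_x), plot$origin_x + w)
      cy <- plot$origin_y + stats::runif(n_c) * l
      hrel <- stats::rbeta(n_c, cs$shape1, cs$shape2)
      if (isTRUE(cs$anchor_top)) hrel <- hrel / max(hrel)
      cz <- .terrain_z(config$terrain, cx, cy) + truth$true_height * hrel +
        stats::rnorm(n_c, 0, config$point_noise_sd)
      canopy <- data.frame(x = cx, y = cy, z = cz)
    } else {
      canopy <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))
    }
    crop <- rbind(bare, canopy)
    crop$source <- rep(c("ground", "canopy"), c(n_g, n_c))
    list(crop = crop, bare = bare)
  })
}

#' Simulate five-band reflectance for ground-truth plots
#'
#' Band reflectances interpolate between bare-soil and closed-canopy values
#' through the saturating cover term `f = 1 - exp(-saturation_rate * AGB)`:
#' NIR rises and visible bands fall as biomass accumulates, with diminishing
#' sensitivity at high AGB (spectral saturation). Additive Gaussian band
#' noise is applied per plot substream and results are clipped to \[0, 1\].
#'
#' @param truth Data frame from [simulate_truth()] (any number of rows).
#' @param config A [field_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Data frame: `plot_id`, `stage`, `B`, `G`, `R`, `EDGE`, `NIR`.
#' @export
simulate_reflectance <- function(truth, config, seed = config$seed) {
  stopifnot(inherits(config, "field_config"))
  soil <- config$reflectance_soil
  full <- config$reflectance_canopy
  n <- nrow(truth)
  out <- matrix(NA_real_, n, 5, dimnames = list(NULL, names(soil)))
  for (i in seq_len(n)) {
    f <- 1 - exp(-config$saturation_rate * truth$true_agb[i])
    mu <- soil + (full - soil) * f
    sub <- derive_seed(seed, paste(truth$plot_id[i], truth$stage[i], "refl"))
    eps <- with_seed(sub, stats::rnorm(5, 0, config$band_noise_sd))
    out[i, ] <- pmin(pmax(mu + eps, 0), 1)
  }
  cbind(data.frame(plot_id = truth$plot_id, stage = truth$stage,
                   stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper running [make_field_layout()], [simulate_truth()],
#' [simulate_point_cloud()] and [simulate_reflectance()] for the requested
#' stages.
#'
#' @param config A [field_config()].
#' @param stages Stage labels (default: all configured stages).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param clouds Logical; also simulate per-plot point clouds (the expensive
#'   part). If `FALSE`, `clouds` is an empty list.
#' @return An object of class `synthetic_field`: list with `config`, `plots`,
#'   `truth`, `reflectance` and `clouds` (`clouds[[stage]][[plot_id]]` as in
#'   [simulate_point_cloud()]).
#' @export
simulate_field <- function(config = field_config(), stages = config$stages,
                           seed = config$seed, clouds = TRUE) {
  stopifnot(inherits(config, "field_config"))
  plots <- make_field_layout(config)
  truth_list <- list()
  refl_list <- list()
  cloud_list <- list()
  for (s in stages) {
    tr <- simulate_truth(plots, s, config, seed)
    truth_list[[s]] <- tr
    refl_list[[s]] <- simulate_reflectance(tr, config, seed)
    if (clouds) {
      cl <- vector("list", nrow(plots))
      names(cl) <- plots$plot_id
      for (i in seq_len(nrow(plots))) {
        cl[[i]] <- simulate_point_cloud(plots[i, ], tr[i, ], config, seed)
      }
      cloud_list[[s]] <- cl
    }
  }
  out <- list(config = config, plots = plots,
              truth = do.call(rbind, c(truth_list, make.row.names = FALSE)),
              reflectance = do.call(rbind,
                                    c(refl_list, make.row.names = FALSE)),
              clouds = cloud_list)
  class(out) <- "synthetic_field"
  out
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("Synthetic field: %d plots, stages: %s\n", nrow(x$plots),
              paste(unique(x$truth$stage), collapse = ", ")))
  if (length(x$clouds)) {
    npts <- sum(vapply(x$clouds[[1]],
                       function(p) nrow(p$crop), numeric(1)))
    cat(sprintf("  ~%d crop-cloud points per stage\n", npts))
  }
  invisible(x)
}
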