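# Height-above-ground normalization, accumulated-incremental-height (AIH)
# profiles, and per-plot crop-height estimation by the AIH-difference and
# CHM-mean methods.

#' Normalize a point cloud against a ground reference
#'
#' Subtracts the interpolated ground elevation at each point's (x, y) from
#' its z, yielding heights above ground. Negative heights (ground noise below
#' the fitted surface) are clipped to zero. The ground reference is either a
#' DEM [surface_grid()] or a bare-ground cloud, which is rasterized to a DEM
#' first. Ground points are retained by default — under accumulated-height
#' percentiles they carry almost no height mass, and their presence anchors
#' the lower AIH baseline at ground level; set `drop_ground = TRUE` for a
#' vegetation-only cloud (points labelled via a `class`/`source` column or,
#' failing that, [classify_ground()]).
#'
#' @param cloud Data frame with columns `x`, `y`, `z` (optionally
#'   `class`/`source` labels).
#' @param ground A [surface_grid()] with role "dem", or a bare-ground cloud
#'   data frame.
#' @param drop_ground Drop ground-labelled points before returning.
#' @param cell,method Rasterization parameters used when `ground` is a cloud.
#' @return Object of class `normalized_cloud`: list with `heights` (m,
#'   non-negative), `x`, `y` and `n`.
#' @export
normalize_heights <- function(cloud, ground, drop_ground = FALSE,
                              cell = 0.5, method = "kriging") {
  if (nrow(cloud) == 0L) stop("empty cloud", call. = FALSE)
  if (!inherits(ground, "surface_grid")) {
    if (is.data.frame(ground) && nrow(ground) > 0L) {
      ground <- rasterize_surface(ground, cell = cell, role = "dem",
                                  method = method)
    } else {
      stop("`ground` must be a surface_grid or a non-empty cloud",
           call. = FALSE)
    }
  }
  cc <- .grid_centers(ground)
  gx <- range(cc$x) + c(-ground$cell, ground$cell)
  gy <- range(cc$y) + c(-ground$cell, ground$cell)
  if (min(cloud$x) > gx[2] || max(cloud$x) < gx[1] ||
      min(cloud$y) > gy[2] || max(cloud$y) < gy[1]) {
    stop("cloud and ground reference have disjoint xy extents",
         call. = FALSE)
  }
  if (drop_ground) {
    lab <- cloud$class
    if (is.null(lab)) lab <- cloud$source
    if (is.null(lab)) lab <- classify_ground(cloud)$class
    keep <- lab != "ground"
    if (!any(keep)) stop("no vegetation points left after dropping ground",
                         call. = FALSE)
    cloud <- cloud[keep, , drop = FALSE]
  }
  h <- pmax(cloud$z - grid_interp(ground, cloud$x, cloud$y), 0)
  structure(list(heights = h, x = cloud$x, y = cloud$y, n = length(h)),
            class = "normalized_cloud")
}

#' @export
print.normalized_cloud <- function(x, ...) {
  cat(sprintf("normalized_cloud: %d points, height range [%.3f, %.3f] m\n",
              x$n, min(x$heights), max(x$heights)))
  invisible(x)
}

#' Accumulated incremental height (AIH) profile
#'
#' Sorts the normalized heights in ascending order and accumulates them; the
#' AIH at percentile X is the height of the first sorted point at which the
#' running sum reaches X% of the total summed height. No interpolation is
#' applied between points, so the profile is a step function of the sorted
#' heights and AIH(100) equals the maximum height. Because tall points carry
#' more height mass than short ones, AIH(X) always sits at or above the plain
#' count percentile at X.
#'
#' @param norm A `normalized_cloud` or a numeric vector of non-negative
#'   heights.
#' @param percentiles Percentile levels in (0, 100].
#' @return Object of class `aih_profile`: list with `percentiles`, `heights`
#'   (the AIH values, m), `n` (source point count) and `degenerate` (TRUE
#'   when all heights are zero, in which case every AIH is 0).
#' @examples
#' p <- aih_profile(c(0.1, 0.2, 0.3, 0.4), percentiles = c(50, 100))
#' p$heights  # 0.3 (cumsum crosses half the total at the 0.3 point), 0.4
#' @export
aih_profile <- function(norm,
                        percentiles = c(1, 5, 20, 40, 60, 80, 90, 95, 99,
                                        100)) {
  h <- if (inherits(norm, "normalized_cloud")) norm$heights else norm
  if (length(h) == 0L) stop("empty cloud", call. = FALSE)
  if (any(!is.finite(h)) || any(h < 0)) {
    stop("heights must be finite and non-negative", call. = FALSE)
  }
  if (any(percentiles <= 0 | percentiles > 100)) {
    stop("percentiles must lie in (0, 100]", call. = FALSE)
  }
  hs <- sort(h)
  cs <- cumsum(hs)
  total <- cs[length(cs)]
  if (total == 0) {
    out <- list(percentiles = percentiles,
                heights = rep(0, length(percentiles)),
                n = length(h), degenerate = TRUE)
    class(out) <- "aih_profile"
    return(out)
  }
  thr <- percentiles / 100 * total
  # first index whose cumulative sum reaches the threshold
  idx <- findInterval(thr, cs, left.open = TRUE) + 1L
  idx <- pmin(idx, length(hs))
  out <- list(percentiles = percentiles, heights = hs[idx],
              n = length(h), degenerate = FALSE)
  class(out) <- "aih_profile"
  out
}

#' @export
print.aih_profile <- function(x, ...) {
  cat(sprintf("AIH profile over %d points%s\n", x$n,
              if (x$degenerate) " (degenerate: all heights zero)" else ""))
  print(stats::setNames(round(x$heights, 4),
                        paste0("AIH", x$percentiles)))
  invisible(x)
}

#' @export
as.data.frame.aih_profile <- function(x, ...) {
  data.frame(percentile = x$percentiles, height = x$heights)
}

# Look up AIH values at given percentiles, erroring when absent.
.aih_at <- function(profile, p) {
  i <- match(TRUE, abs(profile$percentiles - p) < 1e-9)
  if (is.na(i)) stop("percentile ", p, " not present in AIH profile",
                     call. = FALSE)
  profile$heights[i]
}

#' Crop height from an AIH profile (difference method)
#'
#' The crop height estimate is the AIH at the upper percentile (canopy top,
#' default 95%) minus the AIH at a low baseline percentile (ground level,
#' default 1%), floored at zero.
#'
#' @param profile An [aih_profile()] containing both percentiles.
#' @param upper Upper percentile (default 95).
#' @param baseline Baseline percentile (default 1; must be < `upper`).
#' @return Crop height estimate in metres (numeric scalar).
#' @export
crop_height_aih <- function(profile, upper = 95, baseline = 1) {
  stopifnot(inherits(profile, "aih_profile"))
  if (!(baseline < upper)) stop("baseline must be below upper",
                                call. = FALSE)
  max(.aih_at(profile, upper) - .aih_at(profile, baseline), 0)
}

#' Crop height from a canopy height model (mean method)
#'
#' Computes CHM = DSM - DEM cellwise on aligned grids and averages the CHM
#' over the cells whose centres fall inside the plot rectangle (half-open
#' convention). Negative CHM cells are clipped to zero before averaging.
#'
#' @param dsm,dem [surface_grid()]s with identical cell size (grids are
#'   origin-anchored, so equal cell size implies alignment).
#' @param plot Plot row (list/data frame row with `origin_x`, `origin_y`,
#'   `width`, `length`).
#' @return Mean canopy height over the plot (m).
#' @export
crop_height_chm_mean <- function(dsm, dem, plot) {
  stopifnot(inherits(dsm, "surface_grid"), inherits(dem, "surface_grid"))
  if (abs(dsm$cell - dem$cell) > 1e-12) {
    stop("DSM and DEM grids are misaligned (different cell size)",
         call. = FALSE)
  }
  # intersect the two index ranges
  ix_lo <- max(dsm$ix0, dem$ix0)
  ix_hi <- min(dsm$ix0 + dsm$nx, dem$ix0 + dem$nx)
  iy_lo <- max(dsm$iy0, dem$iy0)
  iy_hi <- min(dsm$iy0 + dsm$ny, dem$iy0 + dem$ny)
  if (ix_hi <= ix_lo || iy_hi <= iy_lo) {
    stop("DSM and DEM grids do not overlap", call. = FALSE)
  }
  ii <- seq(ix_lo, ix_hi - 1L)
  jj <- seq(iy_lo, iy_hi - 1L)
  chm <- dsm$values[ii - dsm$ix0 + 1L, jj - dsm$iy0 + 1L, drop = FALSE] -
    dem$values[ii - dem$ix0 + 1L, jj - dem$iy0 + 1L, drop = FALSE]
  cx <- (ii + 0.5) * dsm$cell
  cy <- (jj + 0.5) * dsm$cell
  in_x <- cx >= plot$origin_x & cx < plot$origin_x + plot$width
  in_y <- cy >= plot$origin_y & cy < plot$origin_y + plot$length
  if (!any(in_x) || !any(in_y)) {
    stop("no grid cells intersect the plot", call. = FALSE)
  }
  cells <- chm[in_x, in_y]
  mean(pmax(cells, 0))
}

#' Height features for one plot
#'
#' Runs the full per-plot height workflow: DEM from the bare cloud, DSM from
#' the crop cloud, CHM-mean crop height, normalization of the crop cloud
#' against the DEM, AIH profile, AIH feature percentiles and the
#' AIH-difference crop height.
#'
#' @param crop,bare Point-cloud data frames for the crop and bare-ground
#'   acquisitions.
#' @param plot Plot row (with `origin_x`, `origin_y`, `width`, `length`).
#' @param cell Grid cell size (m).
#' @param upper,baseline Percentiles for [crop_height_aih()].
#' @param feature_percentiles AIH percentiles exported as features
#'   (H_5 ... H_95 by default).
#' @param method Interpolator for [rasterize_surface()].
#' @param drop_ground Passed to [normalize_heights()].
#' @return Named list: `H_<p>` features, `CH` (AIH crop height), `chm_mean`
#'   (CHM-mean crop height) and `profile` (the [aih_profile()]).
#' @export
plot_height_features <- function(crop, bare, plot, cell = 0.5, upper = 95,
                                 baseline = 1,
                                 feature_percentiles = c(5, 20, 40, 60, 80,
                                                         95),
                                 method = "kriging", drop_ground = FALSE) {
  ext <- c(plot$origin_x, plot$origin_x + plot$width,
           plot$origin_y, plot$origin_y + plot$length)
  dem <- rasterize_surface(bare, cell = cell, role = "dem", method = method,
                           extent = ext)
  dsm <- rasterize_surface(crop, cell = cell, role = "dsm", method = method,
                           extent = ext)
  chm <- crop_height_chm_mean(dsm, dem, plot)
  norm <- normalize_heights(crop, dem, drop_ground = drop_ground)
  pct <- sort(unique(c(baseline, feature_percentiles, upper, 100)))
  prof <- aih_profile(norm, percentiles = pct)
  feats <- lapply(feature_percentiles, function(p) .aih_at(prof, p))
  names(feats) <- paste0("H_", feature_percentiles)
  c(feats, list(CH = crop_height_aih(prof, upper, baseline),
                chm_mean = chm, profile = prof))
}

#' Height estimates and AIH features for a whole synthetic field
#'
#' Applies [plot_height_features()] to every plot and stage of a
#' [simulate_field()] result (clouds must have been generated).
#'
#' @param field A `synthetic_field` with clouds.
#' @param ... Passed to [plot_height_features()].
#' @return Data frame: `plot_id`, `stage`, `H_5` ... `H_95`, `CH` (AIH crop
#'   height) and `chm_mean`.
#' @export
field_heights <- function(field, ...) {
  stopifnot(inherits(field, "synthetic_field"))
  if (!length(field$clouds)) {
    stop("field was simulated without clouds", call. = FALSE)
  }
  rows <- list()
  for (s in names(field$clouds)) {
    for (i in seq_len(nrow(field$plots))) {
      pl <- field$plots[i, ]
      cl <- field$clouds[[s]][[pl$plot_id]]
      f <- plot_height_features(cl$crop, cl$bare, pl, ...)
      f$profile <- NULL
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = pl$plot_id, stage = s, as.data.frame(f),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
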