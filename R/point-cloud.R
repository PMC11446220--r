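# Point-cloud preprocessing and rasterization: statistical outlier removal,
# minimum-surface ground classification, and DSM/DEM gridding with ordinary
# kriging or inverse-distance interpolation of empty cells.

#' Statistical outlier removal for point clouds
#'
#' Removes points whose mean distance to their `k` nearest neighbours exceeds
#' the cloud-wide mean by more than `n_sigma` standard deviations — the usual
#' statistical denoising step applied to photogrammetric clouds before height
#' analysis. Point order is preserved.
#'
#' @param cloud Data frame with columns `x`, `y`, `z`.
#' @param k Neighbour count (>= 1).
#' @param n_sigma Threshold in standard deviations; `Inf` disables removal.
#' @return The retained subset of `cloud`, in input order.
#' @export
denoise <- function(cloud, k = 10, n_sigma = 3) {
  k <- check_count(k, "k")
  n <- nrow(cloud)
  if (n <= k) {
    warning("cloud smaller than k + 1; returned unchanged")
    return(cloud)
  }
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  sq <- rowSums(xyz^2)
  knn_mean <- numeric(n)
  chunk <- max(1L, floor(5e6 / n))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    # squared distances of chunk points to all points
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(xyz[idx, , drop = FALSE],
                                                   xyz)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    knn_mean[idx] <- apply(d, 1L, function(r) mean(sort(r)[2:(k + 1L)]))
  }
  thr <- mean(knn_mean) + n_sigma * stats::sd(knn_mean)
  keep <- is.na(thr) | knn_mean <= thr
  cloud[keep, , drop = FALSE]
}

#' Minimum-surface ground classification
#'
#' A simple grid-based ground filter: within each `grid_size` cell the lowest
#' point defines the local minimum surface, and points within `tol` metres of
#' it are labelled ground; all others are labelled vegetation. This is a
#' documented stand-in for proprietary ground-filtering implementations; on
#' agricultural micro-plots with modest relief it is adequate.
#'
#' @param cloud Data frame with columns `x`, `y`, `z`.
#' @param grid_size Cell size in metres (> 0).
#' @param tol Vertical tolerance above the cell minimum (m).
#' @return `cloud` with an added/overwritten `class` column in
#'   \{"ground", "vegetation"\}.
#' @export
classify_ground <- function(cloud, grid_size = 0.5, tol = 0.1) {
  check_number(grid_size, "grid_size", lower = 1e-9)
  if (nrow(cloud) == 0L) stop("empty cloud", call. = FALSE)
  ci <- paste(floor(cloud$x / grid_size), floor(cloud$y / grid_size))
  zmin <- stats::ave(cloud$z, ci, FUN = min)
  cloud$class <- ifelse(cloud$z <= zmin + tol, "ground", "vegetation")
  cloud
}

# --- surface grids -----------------------------------------------------------

#' Construct a surface grid
#'
#' A regular raster of elevations (DSM/DEM) or heights (CHM) on cells
#' anchored at the coordinate origin: cell (i, j) covers the half-open square
#' `[ (ix0+i-1)*cell, (ix0+i)*cell ) x [ (iy0+j-1)*cell, (iy0+j)*cell )`.
#' Origin anchoring means grids built independently from different clouds
#' with the same cell size are automatically aligned.
#'
#' @param values Numeric matrix (`nx` by `ny`) of cell values.
#' @param cell Cell size in metres.
#' @param ix0,iy0 Integer index of the first cell (i.e. `floor(xmin/cell)`).
#' @param role One of "dsm", "dem", "chm".
#' @return Object of class `surface_grid`.
#' @export
surface_grid <- function(values, cell, ix0, iy0, role = "dsm") {
  stopifnot(is.matrix(values), cell > 0)
  structure(list(values = values, cell = cell,
                 ix0 = as.integer(ix0), iy0 = as.integer(iy0),
                 nx = nrow(values), ny = ncol(values), role = role),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("surface_grid (%s): %d x %d cells of %.2f m, %d missing\n",
              x$role, x$nx, x$ny, x$cell, sum(is.na(x$values))))
  invisible(x)
}

# Cell-centre coordinates of a grid.
.grid_centers <- function(g) {
  list(x = (g$ix0 + seq_len(g$nx) - 0.5) * g$cell,
       y = (g$iy0 + seq_len(g$ny) - 0.5) * g$cell)
}

# Inverse-distance-weighted prediction at (px, py) from seeds (sx, sy, sv).
.idw <- function(px, py, sx, sy, sv, power = 2) {
  vapply(seq_along(px), function(i) {
    d2 <- (sx - px[i])^2 + (sy - py[i])^2
    if (any(d2 == 0)) return(mean(sv[d2 == 0]))
    w <- 1 / d2^(power / 2)
    sum(w * sv) / sum(w)
  }, numeric(1))
}

# Fit an exponential variogram gamma(h) = nugget + psill*(1 - exp(-h/range))
# to seed points by least squares on binned empirical semivariances.
# Returns NULL when fitting is not meaningful (degenerate field).
.fit_exp_variogram <- function(sx, sy, sv, max_pairs = 4e4) {
  n <- length(sv)
  if (n < 3L || stats::var(sv) < 1e-14) return(NULL)
  if (n * (n - 1) / 2 > max_pairs) {
    keep <- sort(sample.int(n, floor(sqrt(2 * max_pairs))))
    sx <- sx[keep]; sy <- sy[keep]; sv <- sv[keep]
    n <- length(sv)
  }
  d <- as.vector(stats::dist(cbind(sx, sy)))
  g <- as.vector(stats::dist(sv))^2 / 2
  brk <- seq(0, max(d), length.out = 12L)
  bin <- cut(d, brk, include.lowest = TRUE)
  dh <- tapply(d, bin, mean)
  gh <- tapply(g, bin, mean)
  ok <- is.finite(dh) & is.finite(gh)
  if (sum(ok) < 3L) return(NULL)
  dh <- dh[ok]; gh <- gh[ok]
  obj <- function(p) {
    mod <- p[1] + p[2] * (1 - exp(-dh / p[3]))
    sum((mod - gh)^2)
  }
  init <- c(nugget = 0, psill = max(stats::var(sv), 1e-12),
            range = max(max(d) / 3, 1e-6))
  fit <- try(stats::optim(init, obj, method = "L-BFGS-B",
                          lower = c(0, 1e-12, 1e-6)), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) return(NULL)
  as.list(fit$par)
}

# Ordinary-kriging prediction with exponential covariance; falls back to IDW
# per point if the kriging system is singular.
.krige <- function(px, py, sx, sy, sv, vg, max_neighbors = 64L) {
  psill <- vg$psill
  rng <- vg$range
  nug <- vg$nugget
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    d2 <- (sx - px[i])^2 + (sy - py[i])^2
    use <- if (length(sv) > max_neighbors) {
      order(d2)[seq_len(max_neighbors)]
    } else seq_along(sv)
    nsx <- sx[use]; nsy <- sy[use]; nsv <- sv[use]
    m <- length(use)
    dd <- as.matrix(stats::dist(cbind(nsx, nsy)))
    K <- psill * exp(-dd / rng)
    diag(K) <- psill + nug
    K <- rbind(cbind(K, 1), c(rep(1, m), 0))
    k0 <- c(psill * exp(-sqrt(d2[use]) / rng), 1)
    w <- try(solve(K, k0), silent = TRUE)
    out[i] <- if (inherits(w, "try-error") || any(!is.finite(w))) {
      .idw(px[i], py[i], nsx, nsy, nsv)
    } else {
      sum(w[seq_len(m)] * nsv)
    }
  }
  out
}

#' Rasterize a point cloud to a DSM or DEM
#'
#' Seeds each origin-anchored cell with the maximum point elevation (DSM,
#' crop cloud) or the minimum (DEM, bare/ground cloud), then fills empty
#' cells by ordinary kriging with an exponential variogram fitted to the
#' seeded cells, or by inverse-distance weighting. When variogram fitting is
#' degenerate (near-constant field or too few cells) the fill falls back to
#' IDW with a warning-free downgrade, so coverage of the requested extent is
#' always complete.
#'
#' @param cloud Data frame with columns `x`, `y`, `z`; for `role = "dem"`
#'   pass the bare-ground acquisition (or ground-classified points).
#' @param cell Cell size in metres (default 0.5).
#' @param role "dsm" (per-cell max seed) or "dem" (per-cell min seed).
#' @param method Interpolator for empty cells: "kriging" or "idw".
#' @param extent Optional numeric `c(xmin, xmax, ymin, ymax)` to force grid
#'   coverage beyond (or within) the cloud's bounding box.
#' @return A [surface_grid()].
#' @export
rasterize_surface <- function(cloud, cell = 0.5, role = c("dsm", "dem"),
                              method = c("kriging", "idw"), extent = NULL) {
  role <- match.arg(role)
  method <- match.arg(method)
  check_number(cell, "cell", lower = 1e-9)
  if (nrow(cloud) == 0L) stop("empty cloud", call. = FALSE)

  if (is.null(extent)) {
    extent <- c(min(cloud$x), max(cloud$x), min(cloud$y), max(cloud$y))
  }
  ix0 <- floor(extent[1] / cell)
  iy0 <- floor(extent[3] / cell)
  nx <- max(floor((extent[2] - 1e-12) / cell) - ix0 + 1L, 1L)
  ny <- max(floor((extent[4] - 1e-12) / cell) - iy0 + 1L, 1L)

  ix <- floor(cloud$x / cell) - ix0 + 1L
  iy <- floor(cloud$y / cell) - iy0 + 1L
  inside <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  ix <- ix[inside]; iy <- iy[inside]; z <- cloud$z[inside]
  if (length(z) == 0L) stop("no points inside the requested extent",
                            call. = FALSE)

  vals <- matrix(NA_real_, nx, ny)
  lin <- (iy - 1L) * nx + ix
  agg <- if (role == "dsm") {
    tapply(z, lin, max)
  } else {
    tapply(z, lin, min)
  }
  vals[as.integer(names(agg))] <- as.numeric(agg)

  miss <- which(is.na(vals))
  if (length(miss)) {
    seeded <- which(!is.na(vals))
    if (length(seeded) < 3L) {
      stop("fewer than 3 seeded cells; cannot interpolate", call. = FALSE)
    }
    cx <- (ix0 + ((seeded - 1L) %% nx)) * cell + cell / 2
    cy <- (iy0 + ((seeded - 1L) %/% nx)) * cell + cell / 2
    sv <- vals[seeded]
    mx <- (ix0 + ((miss - 1L) %% nx)) * cell + cell / 2
    my <- (iy0 + ((miss - 1L) %/% nx)) * cell + cell / 2
    filled <- NULL
    if (method == "kriging") {
      vg <- .fit_exp_variogram(cx, cy, sv)
      if (!is.null(vg)) filled <- .krige(mx, my, cx, cy, sv, vg)
    }
    if (is.null(filled)) filled <- .idw(mx, my, cx, cy, sv)
    vals[miss] <- filled
  }
  surface_grid(vals, cell, ix0, iy0, role)
}

#' Interpolate a surface grid at arbitrary coordinates
#'
#' Bilinear interpolation between cell centres; coordinates outside the
#' centre lattice are clamped to the nearest edge cell (nearest-cell
#' extrapolation).
#'
#' @param grid A [surface_grid()].
#' @param x,y Coordinate vectors.
#' @return Numeric vector of interpolated values.
#' @export
grid_interp <- function(grid, x, y) {
  stopifnot(inherits(grid, "surface_grid"))
  cc <- .grid_centers(grid)
  u <- (x - cc$x[1]) / grid$cell + 1
  v <- (y - cc$y[1]) / grid$cell + 1
  u <- pmin(pmax(u, 1), grid$nx)
  v <- pmin(pmax(v, 1), grid$ny)
  i0 <- pmin(floor(u), grid$nx - 1L); i0[grid$nx == 1L] <- 1L
  j0 <- pmin(floor(v), grid$ny - 1L); j0[grid$ny == 1L] <- 1L
  fu <- u - i0
  fv <- v - j0
  i1 <- pmin(i0 + 1L, grid$nx)
  j1 <- pmin(j0 + 1L, grid$ny)
  V <- grid$values
  V[cbind(i0, j0)] * (1 - fu) * (1 - fv) +
    V[cbind(i1, j0)] * fu * (1 - fv) +
    V[cbind(i0, j1)] * (1 - fu) * fv +
    V[cbind(i1, j1)] * fu * fv
}
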