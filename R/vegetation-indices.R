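# Eighteen visible/multispectral vegetation indices computed from five-band
# reflectance (B, G, R, EDGE, NIR), with zonal (per-plot) aggregation.

#' Names of the supported vegetation indices
#'
#' The 18 indices computed by [compute_vi()]: CI-REG, EVI2, ExG, ExGR, GLI,
#' kNDVI, LCI, NDVI, NGRDI, OSAVI, RDVI, RDVI-REG, RGBVI, RTVI-CORE, RVI,
#' VARI, VDVI, VEG.
#'
#' @return Character vector of length 18.
#' @export
vi_names <- function() {
  c("CI-REG", "EVI2", "ExG", "ExGR", "GLI", "kNDVI", "LCI", "NDVI", "NGRDI",
    "OSAVI", "RDVI", "RDVI-REG", "RGBVI", "RTVI-CORE", "RVI", "VARI", "VDVI",
    "VEG")
}

# Guarded division: NA on (near-)zero denominator instead of +-Inf.
.safe_div <- function(num, den) {
  ifelse(abs(den) < 1e-12, NA_real_, num / den)
}

#' Compute one vegetation index
#'
#' Evaluates the named index from five-band reflectance. Conventions:
#' `alpha = 0.667` (VEG) and `sigma = 0.5 * (NIR + R)` (kNDVI). Any zero
#' denominator or invalid power yields `NA` (a missing value), never an
#' error. Two indices admit alternative renderings, selected by arguments:
#' `kndvi` — `"kernel"` (default) computes `tanh(((NIR - R) / (2 * sigma))^2)`
#' following the kernel-NDVI construction, `"literal"` computes
#' `tanh((NIR - R) / (2 * sigma))^2`; `rdvi` — `"printed"` (default) is
#' `(NIR - R)/(NIR + R)` (numerically identical to NDVI), `"literature"` is
#' the renormalized form `(NIR - R)/sqrt(NIR + R)`.
#'
#' @param sample Named numeric (or single-row data frame) with bands `B`,
#'   `G`, `R`, `EDGE`, `NIR`, each in \[0, 1\].
#' @param index One of [vi_names()].
#' @param kndvi,rdvi Variant selectors, see Details.
#' @return Numeric scalar, or `NA` if undefined for this sample.
#' @examples
#' compute_vi(c(B = 0.05, G = 0.1, R = 0.2, EDGE = 0.3, NIR = 0.6), "NDVI")
#' @export
compute_vi <- function(sample, index, kndvi = c("kernel", "literal"),
                       rdvi = c("printed", "literature")) {
  kndvi <- match.arg(kndvi)
  rdvi <- match.arg(rdvi)
  if (!index %in% vi_names()) stop("unknown index: ", index, call. = FALSE)
  s <- unlist(sample[c("B", "G", "R", "EDGE", "NIR")])
  if (any(is.na(s)) || any(!is.finite(s))) return(NA_real_)
  B <- s[["B"]]; G <- s[["G"]]; R <- s[["R"]]
  EDGE <- s[["EDGE"]]; NIR <- s[["NIR"]]
  alpha <- 0.667
  val <- switch(index,
    "CI-REG" = .safe_div(NIR, EDGE) - 1,
    "EVI2" = .safe_div(2.5 * (NIR - R), 1 + NIR + 2.4 * R),
    "ExG" = 2 * G - R - B,
    "ExGR" = (2 * G - R - B) - (1.4 * R - G),
    "GLI" = .safe_div(2 * G - R - B, 2 * G + R + B),
    "kNDVI" = {
      sigma <- 0.5 * (NIR + R)
      u <- .safe_div(NIR - R, 2 * sigma)
      if (is.na(u)) NA_real_
      else if (kndvi == "kernel") tanh(u^2) else tanh(u)^2
    },
    "LCI" = .safe_div(NIR - EDGE, NIR - R),
    "NDVI" = .safe_div(NIR - R, NIR + R),
    "NGRDI" = .safe_div(G - R, G + R),
    "OSAVI" = 1.6 * .safe_div(NIR - R, NIR + R + 0.16),
    "RDVI" = if (rdvi == "printed") .safe_div(NIR - R, NIR + R)
             else .safe_div(NIR - R, sqrt(NIR + R)),
    "RDVI-REG" = .safe_div(NIR - EDGE, NIR + EDGE),
    "RGBVI" = .safe_div(G^2 - R * B, G^2 + R * B),
    "RTVI-CORE" = 100 * (NIR - EDGE) - 10 * (NIR - G),
    "RVI" = .safe_div(NIR, R),
    "VARI" = .safe_div(G - R, G + R + B),
    "VDVI" = .safe_div(2 * G - (R + B), 2 * G + (R + B)),
    "VEG" = .safe_div(G, R^alpha * B^(1 - alpha)))
  if (!is.na(val) && !is.finite(val)) val <- NA_real_
  unname(val)
}

#' Compute all 18 vegetation indices
#'
#' @inheritParams compute_vi
#' @return Named numeric vector over [vi_names()]; undefined indices are
#'   `NA`.
#' @export
compute_all_vi <- function(sample, kndvi = "kernel", rdvi = "printed") {
  vapply(vi_names(), function(idx) {
    compute_vi(sample, idx, kndvi = kndvi, rdvi = rdvi)
  }, numeric(1))
}

#' Zonal vegetation indices over a plot polygon
#'
#' Computes the per-pixel indices first and then the arithmetic mean across
#' pixels, excluding — index by index — pixels where that index is
#' undefined. When `polygon` is supplied, only pixels whose coordinates fall
#' inside the plot rectangle (half-open) are used.
#'
#' @param pixels Data frame with band columns `B`, `G`, `R`, `EDGE`, `NIR`
#'   and optionally coordinates `x`, `y`.
#' @param polygon Optional plot rectangle (list/row with `origin_x`,
#'   `origin_y`, `width`, `length`); requires `x`, `y` columns.
#' @param ... Passed to [compute_vi()].
#' @return List with `vi` (named means over [vi_names()]) and `n_valid`
#'   (per-index count of pixels entering each mean).
#' @export
zonal_vi <- function(pixels, polygon = NULL, ...) {
  if (!is.null(polygon)) {
    stopifnot(all(c("x", "y") %in% names(pixels)))
    inside <- pixels$x >= polygon$origin_x &
      pixels$x < polygon$origin_x + polygon$width &
      pixels$y >= polygon$origin_y &
      pixels$y < polygon$origin_y + polygon$length
    pixels <- pixels[inside, , drop = FALSE]
  }
  if (nrow(pixels) == 0L) stop("no pixels inside the polygon", call. = FALSE)
  per_pixel <- t(vapply(seq_len(nrow(pixels)), function(i) {
    compute_all_vi(pixels[i, , drop = FALSE], ...)
  }, numeric(length(vi_names()))))
  list(vi = colMeans(per_pixel, na.rm = TRUE),
       n_valid = colSums(!is.na(per_pixel)))
}

#' Vegetation-index feature table
#'
#' Applies [compute_all_vi()] to each row of a plot-level reflectance table.
#'
#' @param reflectance Data frame with columns `plot_id`, `stage` and the five
#'   bands.
#' @param ... Passed to [compute_vi()].
#' @return Data frame: `plot_id`, `stage` and the 18 index columns (names
#'   from [vi_names()], with `-` preserved).
#' @export
vi_table <- function(reflectance, ...) {
  vi <- t(vapply(seq_len(nrow(reflectance)), function(i) {
    compute_all_vi(reflectance[i, , drop = FALSE], ...)
  }, numeric(length(vi_names()))))
  out <- cbind(reflectance[, c("plot_id", "stage")], as.data.frame(vi))
  names(out) <- c("plot_id", "stage", vi_names())
  rownames(out) <- NULL
  out
}
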