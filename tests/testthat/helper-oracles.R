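# Independent oracles and small fixtures shared across the suite.

# Brute-force accumulated-incremental-height: explicit sort + loop, kept
# deliberately naive and separate from the package implementation.
aih_oracle <- function(heights, X) {
  hs <- sort(heights)
  total <- sum(hs)
  if (total == 0) return(0)
  threshold <- X / 100 * total
  acc <- 0
  for (h in hs) {
    acc <- acc + h
    if (acc >= threshold) return(h)
  }
  hs[length(hs)]
}

# Nearest-rank count percentile (the plain quantile AIH dominates).
count_percentile <- function(heights, X) {
  hs <- sort(heights)
  hs[max(1L, ceiling(X / 100 * length(hs)))]
}

# Direct transcription of the three evaluation metrics.
metrics_oracle <- function(x, y) {
  list(R2 = 1 - sum((x - y)^2) / sum((x - mean(x))^2),
       RMSE = sqrt(sum((x - y)^2) / length(x)),
       nRMSE = sqrt(sum((x - y)^2) / length(x)) / mean(x) * 100)
}

# A small, fast field configuration for unit tests (not the study defaults).
tiny_field_config <- function(...) {
  args <- list(...)
  base <- list(n_treatments = 2L, plots_per_treatment = 5L,
               ground_point_density = 60, canopy_point_density = 80)
  base[names(args)] <- args
  do.call(field_config, base)
}

# A generic five-band sample with all bands distinct and interior.
generic_sample <- c(B = 0.07, G = 0.13, R = 0.11, EDGE = 0.28, NIR = 0.61)
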