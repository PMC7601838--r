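fos_feature_names <- c("mean", "median", "sd", "variance", "skewness",
                       "kurtosis", "energy", "entropy", "uniformity",
                       "min", "max", "range", "mad", "rms")

# First-order statistics of a numeric sample plus its level histogram.
# entropy = -sum p log2 p and uniformity = sum p^2 over the G-bin histogram;
# sd/variance use the n-1 denominator; skewness/kurtosis use population
# moments (kurtosis not excess); energy = sum x^2; mad = mean |x - mean|.
fos_from_sample <- function(x, levels, G) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p <- tabulate(levels, nbins = G) / n
  pp <- p[p > 0]
  c(mean       = mu,
    median     = stats::median(x),
    sd         = if (n > 1L) stats::sd(x) else 0,
    variance   = if (n > 1L) stats::var(x) else 0,
    skewness   = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis   = if (m2 > 0) m4 / m2^2 else 0,
    energy     = sum(x^2),
    entropy    = -sum(pp * log2(pp)),
    uniformity = sum(pp^2),
    min        = min(x),
    max        = max(x),
    range      = diff(range(x)),
    mad        = mean(abs(x - mu)),
    rms        = sqrt(mean(x^2)))
}

#' First-order statistics (FOS) radiomic features
#'
#' The 14 first-order features of the ROI intensity distribution: mean,
#' median, SD, variance, skewness, kurtosis, energy (sum of squared
#' intensities), entropy and uniformity (over the G-bin quantized histogram,
#' log base 2), min, max, range, mean absolute deviation, and RMS.
#'
#' @param quantized a [quantize()]d ROI.
#' @return Named numeric vector of length 14.
#' @export
fos_features <- function(quantized) {
  stopifnot(inherits(quantized, "quantized_roi"))
  m <- quantized$mask
  fos_from_sample(quantized$values[m], quantized$levels[m], quantized$G)
}
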