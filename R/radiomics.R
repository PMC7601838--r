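#' All 51 single-parameter radiomic features of one channel
#'
#' Convenience wrapper assembling the full single-channel feature vector:
#' 14 first-order ([fos_features()]), 18 co-occurrence ([glcm_features()]),
#' 11 run-length ([glrlm_features()]), 5 neighborhood gray-tone difference
#' ([ngtdm_features()]), 2 fractal ([fractal_features()]) and 1 convexity
#' ([convexity()]) feature, with prefixed names (`FOS_`, `GLCM_`, `GLRLM_`,
#' `NGTDM_`, `fractal_`, `convexity`).
#'
#' @param channel 3-D numeric array.
#' @param mask logical 3-D array of the same shape (lesion ROI).
#' @param G gray levels (default 64).
#' @param distance GLCM offset in voxels (default 1).
#' @param ngtdm_mode `"2d"` or `"3d"` neighborhood for NGTDM.
#' @return Named numeric vector of 51 features.
#' @export
radiomic_vector <- function(channel, mask, G = 64L, distance = 1L,
                            ngtdm_mode = "2d") {
  q <- quantize(channel, mask, G)
  out <- c(stats_prefix(fos_features(q), "FOS"),
           stats_prefix(glcm_features(q, distance), "GLCM"),
           stats_prefix(glrlm_features(q), "GLRLM"),
           stats_prefix(ngtdm_features(q, ngtdm_mode), "NGTDM"),
           stats_prefix(fractal_features(channel, mask, G), "fractal"),
           convexity = convexity(mask))
  stopifnot(length(out) == 51L)
  out
}

stats_prefix <- function(x, prefix) {
  names(x) <- paste(prefix, names(x), sep = "_")
  x
}
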