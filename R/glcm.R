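glcm_feature_names <- c("autocorrelation", "contrast", "correlation",
                        "cluster_shade", "cluster_prominence", "dissimilarity",
                        "energy", "entropy", "homogeneity1", "homogeneity2",
                        "max_probability", "variance", "sum_average",
                        "sum_variance", "sum_entropy", "difference_entropy",
                        "idn", "idmn")

# Symmetric, normalized co-occurrence probability matrices, one per in-plane
# direction (0/45/90/135 degrees), slice-wise at the given voxel distance.
# Directions with no co-occurring pair are returned as NULL.
glcm_probs <- function(levels, mask, G, distance = 1L) {
  lapply(texture_directions(), function(off) {
    pr <- level_pairs(levels, mask, off[1], off[2], distance)
    if (length(pr$l1) == 0L) return(NULL)
    M <- matrix(tabulate((pr$l2 - 1L) * G + pr$l1, nbins = G * G), nrow = G)
    M <- M + t(M)
    M / sum(M)
  })
}

# The 18 co-occurrence features from one normalized symmetric GLCM.
# `P` may be restricted to the occupied levels, whose gray-level values are
# then given in `lv` (absent levels carry zero probability and contribute
# nothing); `G` is still the full quantization depth used by IDN/IDMN.
glcm_stats <- function(P, G, lv = NULL) {
  if (is.null(lv)) lv <- seq_len(nrow(P))
  L <- length(lv)
  ii <- matrix(lv, L, L)
  jj <- t(ii)
  px <- rowSums(P)
  mu <- sum(lv * px)
  sigma2 <- sum((lv - mu)^2 * px)
  pk_sum  <- rowsum(as.vector(P), group = as.vector(ii + jj))    # k = 2..2G present
  k_sum   <- as.numeric(rownames(pk_sum))
  pk_diff <- rowsum(as.vector(P), group = as.vector(abs(ii - jj)))
  k_diff  <- as.numeric(rownames(pk_diff))
  ent_of <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  sa <- sum(k_sum * pk_sum)
  c(autocorrelation    = sum(ii * jj * P),
    contrast           = sum((ii - jj)^2 * P),
    correlation        = if (sigma2 > .Machine$double.eps) (sum(ii * jj * P) - mu^2) / sigma2 else 1,
    cluster_shade      = sum((ii + jj - 2 * mu)^3 * P),
    cluster_prominence = sum((ii + jj - 2 * mu)^4 * P),
    dissimilarity      = sum(abs(ii - jj) * P),
    energy             = sum(P^2),
    entropy            = ent_of(P),
    homogeneity1       = sum(P / (1 + abs(ii - jj))),
    homogeneity2       = sum(P / (1 + (ii - jj)^2)),
    max_probability    = max(P),
    variance           = sum((ii - mu)^2 * P),
    sum_average        = sa,
    sum_variance       = sum((k_sum - sa)^2 * pk_sum),
    sum_entropy        = ent_of(pk_sum),
    difference_entropy = ent_of(pk_diff),
    idn                = sum(P / (1 + abs(ii - jj) / G)),
    idmn               = sum(P / (1 + (ii - jj)^2 / G^2)))
}

#' Gray-level co-occurrence matrix (GLCM) features
#'
#' Builds a symmetric, normalized co-occurrence matrix per in-plane direction
#' (0, 45, 90, 135 degrees, slice-wise) at the given voxel distance, computes
#' 18 Haralick-style features per direction, and averages them across
#' directions for rotational invariance. Entropies use log base 2; the
#' correlation of a zero-variance (single-level) ROI is defined as 1.
#'
#' @param quantized a [quantize()]d ROI.
#' @param distance co-occurrence offset in voxels (default 1).
#' @return Named numeric vector of 18 direction-averaged features.
#' @export
glcm_features <- function(quantized, distance = 1L) {
  stopifnot(inherits(quantized, "quantized_roi"))
  Ps <- glcm_probs(quantized$levels, quantized$mask, quantized$G, distance)
  Ps <- Filter(Negate(is.null), Ps)
  if (length(Ps) == 0L) stop("no co-occurring voxel pairs in ROI")
  rowMeans(vapply(Ps, function(P) {
    occ <- which(rowSums(P) > 0)
    glcm_stats(P[occ, occ, drop = FALSE], quantized$G, lv = occ)
  }, numeric(18L)))
}
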