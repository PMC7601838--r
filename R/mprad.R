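#' Build the per-voxel tissue-signature field
#'
#' At each ROI voxel the tissue signature is the length-N vector of
#' intensities across the N co-registered channels. Channels are z-score
#' standardized over the ROI before any binning, so every downstream
#' multiparametric feature is invariant to positive affine rescaling of any
#' channel; a constant channel standardizes to zero.
#'
#' @param volumes a [volume_set()] of co-registered channels.
#' @param mask lesion [roi_mask()] (or logical array), non-empty.
#' @return An object of class `tissue_signatures`: list with `S` (voxels x N
#'   matrix of standardized intensities), `coords` (voxel array indices),
#'   `channels`, `mask`, `dim`.
#' @export
build_signatures <- function(volumes, mask) {
  stopifnot(inherits(volumes, "volume_set"))
  mask <- array(as.logical(mask), dim = dim(mask))
  check_mask(volumes, mask)
  coords <- which(mask, arr.ind = TRUE)
  S <- vapply(volumes$channels, function(ch) {
    v <- ch[mask]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }, numeric(sum(mask)))
  S <- matrix(S, nrow = sum(mask),
              dimnames = list(NULL, names(volumes$channels)))
  structure(list(S = S, coords = coords, channels = names(volumes$channels),
                 mask = mask, dim = dim(mask)),
            class = "tissue_signatures")
}

#' @export
print.tissue_signatures <- function(x, ...) {
  cat(sprintf("Tissue-signature field: %d voxels x %d channels (%s)\n",
              nrow(x$S), ncol(x$S), paste(x$channels, collapse = ", ")))
  invisible(x)
}

# Per-channel equal-width binning of the standardized signatures into B bins
# (same floor rule as quantize()); returns voxels x N integer matrix.
signature_bins <- function(field, B) {
  bins <- apply(field$S, 2L, function(v) {
    rng <- range(v)
    if (rng[2] <= rng[1]) return(rep(1L, length(v)))
    q <- floor((v - rng[1]) / (rng[2] - rng[1]) * B) + 1L
    q[q > B] <- B
    as.integer(q)
  })
  if (!is.matrix(bins)) bins <- matrix(bins, nrow = nrow(field$S))
  bins
}

# Occupied cells of the N-dimensional tissue-signature probability matrix:
# returns list(cell = factor of per-voxel cell ids, p = named cell
# probabilities, bins = the bin matrix).
tspm_cells <- function(field, B) {
  bins <- signature_bins(field, B)
  cell <- apply(bins, 1L, paste, collapse = ",")
  tab <- table(cell)
  list(cell = cell, p = as.numeric(tab) / length(cell),
       labels = names(tab), bins = bins)
}

#' Tissue-signature probability matrix (TSPM) features
#'
#' The TSPM is the N-dimensional probability array over per-channel
#' quantization bins (B bins per channel); each occupied cell is one
#' signature configuration. Features: entropy (-sum p log2 p), uniformity
#' (sum p^2), and mutual information, defined as the mean over channel pairs
#' of the MI between their bin indices computed from the TSPM's 2-D
#' marginals (0 for a single channel).
#'
#' @param field a [build_signatures()] field.
#' @param B bins per channel (default 8).
#' @return Named numeric vector `c(entropy, uniformity, mutual_information)`.
#' @export
tspm_features <- function(field, B = 8L) {
  stopifnot(inherits(field, "tissue_signatures"))
  if (B < 2L) stop("B must be >= 2")
  cells <- tspm_cells(field, B)
  p <- cells$p
  N <- ncol(cells$bins)
  mi <- 0
  if (N >= 2L) {
    pairs <- utils::combn(N, 2L)
    mis <- apply(pairs, 2L, function(ij) {
      joint <- table(factor(cells$bins[, ij[1]], levels = seq_len(B)),
                     factor(cells$bins[, ij[2]], levels = seq_len(B)))
      pj <- joint / sum(joint)
      pi_ <- rowSums(pj); pk <- colSums(pj)
      num <- pj / outer(pi_, pk)
      sum(pj[pj > 0] * log2(num[pj > 0]))
    })
    mi <- mean(mis)
  }
  c(entropy = -sum(p * log2(p)), uniformity = sum(p^2),
    mutual_information = mi)
}

#' Tissue-signature first-order statistics (TSFOS)
#'
#' The 14 first-order statistics of the pooled distribution of all
#' standardized intensities across every channel and ROI voxel (a sample of
#' size N x voxels); entropy and uniformity use a 64-bin histogram of the
#' pooled sample.
#'
#' @param field a [build_signatures()] field.
#' @param G histogram bins for entropy/uniformity (default 64).
#' @return Named numeric vector of 14 features.
#' @export
tsfos_features <- function(field, G = 64L) {
  stopifnot(inherits(field, "tissue_signatures"))
  pooled <- as.vector(field$S)
  rng <- range(pooled)
  if (rng[2] > rng[1]) {
    lv <- floor((pooled - rng[1]) / (rng[2] - rng[1]) * G) + 1L
    lv[lv > G] <- G
  } else lv <- rep(1L, length(pooled))
  fos_from_sample(pooled, lv, G)
}

#' Tissue-signature co-occurrence matrix (TSCM) features
#'
#' Signature codewords are the occupied TSPM cells ranked by the mean of
#' their bin tuple (ties broken lexicographically), giving each cell an
#' ordinal level 1..L that orders codewords from "all channels low" to "all
#' channels high". Codeword co-occurrence is accumulated slice-wise at
#' distance 1 over the four in-plane directions, symmetrized and normalized
#' per direction, and GLCM-style features are averaged across directions.
#' The "-I" suffixed names are the first standard formula variant
#' (contrast-I = sum (i-j)^2 p etc.); homogeneity-II is the inverse
#' difference moment; inverse variance is sum_{i != j} p / (i-j)^2; IDN and
#' IDMN normalize by the codeword count L.
#'
#' @param field a [build_signatures()] field.
#' @param B bins per channel (default 8).
#' @param distance co-occurrence offset in voxels (default 1).
#' @return Named numeric vector of 11 features.
#' @export
tscm_features <- function(field, B = 8L, distance = 1L) {
  stopifnot(inherits(field, "tissue_signatures"))
  cells <- tspm_cells(field, B)
  lab_mat <- do.call(rbind, lapply(strsplit(cells$labels, ","), as.integer))
  ord <- do.call(order, c(list(rowMeans(lab_mat)),
                          lapply(seq_len(ncol(lab_mat)), function(j) lab_mat[, j])))
  rank_of <- integer(length(cells$labels))
  rank_of[ord] <- seq_along(ord)
  code <- rank_of[match(cells$cell, cells$labels)]
  L <- length(cells$labels)

  arr <- array(NA_integer_, dim = field$dim)
  arr[field$mask] <- code
  Ps <- Filter(Negate(is.null), glcm_probs(arr, field$mask, L, distance))
  if (length(Ps) == 0L) stop("no adjacent ROI voxels under the offset set")
  per_dir <- vapply(Ps, function(P) {
    g <- glcm_stats(P, L)
    ii <- matrix(seq_len(L), L, L); jj <- t(ii)
    off <- ii != jj
    inv_var <- sum(P[off] / (ii[off] - jj[off])^2)
    c(contrast1 = unname(g["contrast"]),
      autocorrelation1 = unname(g["autocorrelation"]),
      variance1 = unname(g["variance"]),
      dissimilarity1 = unname(g["dissimilarity"]),
      homogeneity2 = unname(g["homogeneity2"]),
      idn = unname(g["idn"]),
      idmn = unname(g["idmn"]),
      inverse_variance = inv_var,
      sum_variance = unname(g["sum_variance"]),
      energy = unname(g["energy"]),
      entropy = unname(g["entropy"]))
  }, numeric(11L))
  rowMeans(per_dir)
}

#' All multiparametric (mpRad) tissue-signature features
#'
#' Assembles the TSPM, TSFOS and TSCM feature families with prefixed names.
#'
#' @param volumes a [volume_set()].
#' @param mask lesion mask.
#' @param B bins per channel for TSPM/TSCM (default 8).
#' @param distance TSCM co-occurrence offset (default 1).
#' @return Named numeric vector (3 TSPM + 14 TSFOS + 11 TSCM features).
#' @export
mprad_features <- function(volumes, mask, B = 8L, distance = 1L) {
  field <- build_signatures(volumes, mask)
  c(stats_prefix(tspm_features(field, B), "TSPM"),
    stats_prefix(tsfos_features(field), "TSFOS"),
    stats_prefix(tscm_features(field, B, distance), "TSCM"))
}
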