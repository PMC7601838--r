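glrlm_feature_names <- c("sre", "lre", "gln", "rln", "rp",
                         "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge")

# Gray-level runs along one in-plane direction of one slice. Runs are maximal
# stretches of equal level among consecutive in-mask voxels along the
# direction line; a mask gap breaks a run. Returns a two-column matrix
# (level, run length), one row per run.
runs_in_slice <- function(lv, direction) {
  nr <- nrow(lv); nc <- ncol(lv)
  idx <- switch(direction,
    `0`   = split(seq_len(nr * nc), rep(seq_len(nr), times = nc)),       # along columns (left-right)
    `90`  = split(seq_len(nr * nc), rep(seq_len(nc), each = nr)),        # along rows (up-down)
    `45`  = {  # direction (-1,+1): constant i+j anti-diagonals, ordered by increasing j
      ii <- rep(seq_len(nr), times = nc); jjv <- rep(seq_len(nc), each = nr)
      ord <- order(ii + jjv, jjv)
      split(ord, (ii + jjv)[ord])
    },
    `135` = {  # direction (-1,-1): constant i-j diagonals, ordered by decreasing j
      ii <- rep(seq_len(nr), times = nc); jjv <- rep(seq_len(nc), each = nr)
      ord <- order(ii - jjv, -jjv)
      split(ord, (ii - jjv)[ord])
    },
    stop("unknown direction"))
  out <- vector("list", length(idx))
  for (q in seq_along(idx)) {
    line <- lv[idx[[q]]]
    if (all(is.na(line))) next
    r <- rle(ifelse(is.na(line), -1L, line))
    keep <- r$values != -1L
    if (any(keep))
      out[[q]] <- cbind(level = r$values[keep], len = r$lengths[keep])
  }
  do.call(rbind, out)
}

# Run-length feature vector from a run table (level, len) with n_vox ROI voxels.
glrlm_stats <- function(runs, n_vox) {
  i <- runs[, "level"]; r <- runs[, "len"]
  nr <- nrow(runs)
  by_level <- rowsum(rep(1, nr), i)
  by_len   <- rowsum(rep(1, nr), r)
  c(sre   = sum(1 / r^2) / nr,
    lre   = sum(r^2) / nr,
    gln   = sum(by_level^2) / nr,
    rln   = sum(by_len^2) / nr,
    rp    = nr / n_vox,
    lgre  = sum(1 / i^2) / nr,
    hgre  = sum(i^2) / nr,
    srlge = sum(1 / (i^2 * r^2)) / nr,
    srhge = sum(i^2 / r^2) / nr,
    lrlge = sum(r^2 / i^2) / nr,
    lrhge = sum(i^2 * r^2) / nr)
}

#' Gray-level run-length matrix (GLRLM) features
#'
#' Runs of equal gray level are extracted slice-wise along the four in-plane
#' directions (0, 45, 90, 135 degrees); the 11 run-length features (SRE, LRE,
#' GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE) are computed per
#' direction and averaged across directions.
#'
#' @param quantized a [quantize()]d ROI.
#' @return Named numeric vector of 11 direction-averaged features.
#' @export
glrlm_features <- function(quantized) {
  stopifnot(inherits(quantized, "quantized_roi"))
  lev <- quantized$levels
  n_vox <- sum(quantized$mask)
  d3 <- dim(lev)[3]
  feats <- vapply(names(texture_directions()), function(dir) {
    runs <- do.call(rbind, lapply(seq_len(d3), function(k)
      runs_in_slice(lev[, , k], dir)))
    glrlm_stats(runs, n_vox)
  }, numeric(11L))
  rowMeans(feats)
}
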