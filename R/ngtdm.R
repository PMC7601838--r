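ngtdm_feature_names <- c("coarseness", "contrast", "busyness",
                         "complexity", "strength")

# Per-level neighborhood gray-tone sums: for every ROI voxel whose full
# 8-neighborhood (2-D, slice-wise) or 26-neighborhood (3-D) lies inside the
# mask, accumulate |level - mean(neighbor levels)| into s[level] and count
# occurrences n[level].
ngtdm_accumulate <- function(levels, mask, G, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  d <- dim(levels)
  offs <- if (mode == "2d") {
    o <- expand.grid(a = -1:1, b = -1:1, c = 0L)
    o[!(o$a == 0 & o$b == 0), ]
  } else {
    o <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
    o[!(o$a == 0 & o$b == 0 & o$c == 0), ]
  }
  # interior region where every offset stays in bounds
  r1 <- 2:(d[1] - 1); c1 <- 2:(d[2] - 1)
  s1 <- if (mode == "2d") seq_len(d[3]) else 2:(d[3] - 1)
  if (d[1] < 3 || d[2] < 3 || (mode == "3d" && d[3] < 3))
    return(list(s = numeric(G), n = integer(G)))
  valid <- mask[r1, c1, s1, drop = FALSE]
  nb_sum <- array(0, dim = dim(valid))
  for (q in seq_len(nrow(offs))) {
    a <- offs$a[q]; b <- offs$b[q]; cc <- offs$c[q]
    valid <- valid & mask[r1 + a, c1 + b, s1 + cc, drop = FALSE]
    nb_sum <- nb_sum + ifelse(is.na(levels[r1 + a, c1 + b, s1 + cc, drop = FALSE]),
                              0, levels[r1 + a, c1 + b, s1 + cc, drop = FALSE])
  }
  k <- nrow(offs)
  lev_c <- levels[r1, c1, s1, drop = FALSE][valid]
  abar  <- nb_sum[valid] / k
  s <- numeric(G); n <- integer(G)
  if (length(lev_c) > 0L) {
    dev <- abs(lev_c - abar)
    tmp <- rowsum(dev, lev_c)
    s[as.integer(rownames(tmp))] <- tmp[, 1L]
    n <- tabulate(lev_c, nbins = G)
  }
  list(s = s, n = n)
}

#' Neighborhood gray-tone difference matrix (NGTDM) features
#'
#' Amadasun-King texture features (coarseness, contrast, busyness,
#' complexity, strength) from the per-level sums of absolute differences
#' between a voxel's level and the mean level of its complete neighborhood:
#' the 8-neighborhood slice-wise in 2-D mode (default) or the 26-neighborhood
#' in 3-D mode. Only voxels whose full neighborhood lies inside the ROI
#' contribute. A single-level ROI has contrast, busyness, complexity and
#' strength 0 and infinite coarseness.
#'
#' @param quantized a [quantize()]d ROI.
#' @param mode `"2d"` (slice-wise 8-neighborhood) or `"3d"` (26-neighborhood).
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(quantized, mode = c("2d", "3d")) {
  stopifnot(inherits(quantized, "quantized_roi"))
  acc <- ngtdm_accumulate(quantized$levels, quantized$mask, quantized$G,
                          match.arg(mode))
  if (sum(acc$n) == 0L) stop("no ROI voxel has a complete neighborhood")
  ngtdm_stats(acc$s, acc$n)
}

ngtdm_stats <- function(s, n) {
  N <- sum(n)
  p <- n / N
  pres <- which(n > 0L)
  Ng <- length(pres)
  psum <- sum(p * s)
  lev <- pres
  pi_ <- p[pres]; si_ <- s[pres]
  dmat <- outer(lev, lev, "-")
  contrast <- if (Ng > 1)
    (sum(outer(pi_, pi_) * dmat^2) / (Ng * (Ng - 1))) * (sum(s) / N) else 0
  bus_den <- sum(abs(outer(lev * pi_, lev * pi_, "-")))
  busyness <- if (bus_den > 0) psum / bus_den else 0
  cx <- outer(pi_ * si_, pi_ * si_, "+") / outer(pi_, pi_, "+")
  complexity <- sum(abs(dmat) * cx) / N
  str_num <- sum(outer(pi_, pi_, "+") * dmat^2)
  strength <- if (sum(s) > 0) str_num / sum(s) else 0
  c(coarseness = if (psum > 0) 1 / psum else Inf,
    contrast   = contrast,
    busyness   = busyness,
    complexity = complexity,
    strength   = strength)
}
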