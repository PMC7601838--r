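laplacian_kernel <- function() {
  matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
}

log_kernel <- function(sigma = 1, size = 2L * ceiling(3 * sigma) + 1L) {
  h <- (size - 1L) / 2L
  x <- matrix(rep(-h:h, size), size, size)
  y <- t(x)
  k <- (x^2 + y^2 - 2 * sigma^2) / sigma^4 * exp(-(x^2 + y^2) / (2 * sigma^2))
  k - mean(k)   # zero-sum so flat and linear fields respond 0
}

# Slice-wise 2-D convolution by kernel shifting; voxels whose kernel support
# leaves the image are NA.
convolve_slice <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kh <- (nrow(kernel) - 1L) / 2L
  out <- matrix(NA_real_, nr, nc)
  if (nr < nrow(kernel) || nc < ncol(kernel)) return(out)
  rr <- (kh + 1L):(nr - kh); cc <- (kh + 1L):(nc - kh)
  acc <- matrix(0, length(rr), length(cc))
  for (a in -kh:kh) for (b in -kh:kh) {
    w <- kernel[a + kh + 1L, b + kh + 1L]
    if (w != 0) acc <- acc + w * img[rr + a, cc + b]
  }
  out[rr, cc] <- acc
  out
}

#' Radiomic feature maps (RFM)
#'
#' Recomputes a named first-order or co-occurrence feature in a sliding
#' in-plane window centered on every ROI voxel (window voxels outside the ROI
#' are excluded; quantized levels are taken from the ROI-wide quantization so
#' window maps are comparable across the lesion), plus Laplacian and
#' Laplacian-of-Gaussian filter maps. Each map is aggregated over the ROI to
#' a scalar named `RFM_<feature>`: the plain ROI mean for windowed features
#' and the mean absolute response for the two filter maps.
#'
#' @param channel 3-D numeric array.
#' @param mask logical 3-D array of the same shape.
#' @param features character vector of map names: any of
#'   `paste0("fos_", fos_feature_names)`, `paste0("glcm_", glcm_feature_names)`,
#'   `"laplacian"`, `"log"`.
#' @param window odd window side length >= 3 (default 5).
#' @param G gray levels for the ROI-wide quantization (default 64).
#' @param distance GLCM offset within the window (default 1).
#' @param log_sigma Gaussian scale of the LoG filter in voxels (default 1).
#' @return List with `maps` (named list of 3-D arrays, `NA` where undefined)
#'   and `means` (named numeric vector of `RFM_<feature>` scalars).
#' @export
rfm_maps <- function(channel, mask,
                     features = c("fos_entropy", "fos_uniformity",
                                  "glcm_entropy", "glcm_energy",
                                  "laplacian", "log"),
                     window = 5L, G = 64L, distance = 1L, log_sigma = 1) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  d <- dim(channel)
  if (window > max(d[1], d[2])) stop("window larger than ROI extent")
  q <- quantize(channel, mask, G)
  h <- (window - 1L) %/% 2L
  vox <- which(mask, arr.ind = TRUE)

  fos_sel  <- grep("^fos_",  features, value = TRUE)
  glcm_sel <- grep("^glcm_", features, value = TRUE)
  bad <- setdiff(features, c(fos_sel, glcm_sel, "laplacian", "log"))
  if (length(bad)) stop("unknown RFM feature(s): ", paste(bad, collapse = ", "))
  fos_idx  <- match(sub("^fos_", "", fos_sel), fos_feature_names)
  glcm_idx <- match(sub("^glcm_", "", glcm_sel), glcm_feature_names)
  if (anyNA(fos_idx) || anyNA(glcm_idx)) stop("unknown FOS/GLCM feature name")

  maps <- lapply(features, function(f) array(NA_real_, dim = d))
  names(maps) <- features

  if (length(fos_sel) || length(glcm_sel)) {
    for (v in seq_len(nrow(vox))) {
      i <- vox[v, 1]; j <- vox[v, 2]; k <- vox[v, 3]
      rr <- max(1L, i - h):min(d[1], i + h)
      cc <- max(1L, j - h):min(d[2], j + h)
      wm <- mask[rr, cc, k, drop = FALSE]
      if (!any(wm)) next
      if (length(fos_sel)) {
        vals <- q$values[rr, cc, k, drop = FALSE][wm]
        lv   <- q$levels[rr, cc, k, drop = FALSE][wm]
        fv <- fos_from_sample(vals, lv, G)
        for (s in seq_along(fos_sel))
          maps[[fos_sel[s]]][i, j, k] <- fv[fos_idx[s]]
      }
      if (length(glcm_sel)) {
        lw <- array(q$levels[rr, cc, k], dim = c(length(rr), length(cc), 1L))
        mw <- array(wm, dim = dim(lw))
        Ps <- Filter(Negate(is.null), glcm_probs(lw, mw, G, distance))
        if (length(Ps)) {
          gv <- rowMeans(vapply(Ps, function(P) {
            occ <- which(rowSums(P) > 0)
            glcm_stats(P[occ, occ, drop = FALSE], G, lv = occ)
          }, numeric(18L)))
          for (s in seq_along(glcm_sel))
            maps[[glcm_sel[s]]][i, j, k] <- gv[glcm_idx[s]]
        }
      }
    }
  }

  for (f in intersect(c("laplacian", "log"), features)) {
    kern <- if (f == "laplacian") laplacian_kernel() else log_kernel(log_sigma)
    for (k in seq_len(d[3])) {
      if (!any(mask[, , k])) next
      maps[[f]][, , k] <- convolve_slice(channel[, , k], kern)
    }
    maps[[f]][!mask] <- NA_real_
  }

  means <- vapply(features, function(f) {
    x <- maps[[f]][mask]
    x <- x[is.finite(x)]
    if (length(x) == 0L) return(NA_real_)
    if (f %in% c("laplacian", "log")) mean(abs(x)) else mean(x)
  }, numeric(1L))
  names(means) <- paste0("RFM_", features)
  list(maps = maps, means = means)
}
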