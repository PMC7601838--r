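#' Quantize ROI intensities to discrete gray levels
#'
#' Equal-width min-max binning of the ROI intensities into `G` levels:
#' level = floor((x - min) / (max - min) * G) + 1, clipped to `[1, G]` so the
#' maximum maps to level `G`. A constant (zero-range) ROI maps to level 1
#' everywhere.
#'
#' @param channel 3-D numeric array of intensities.
#' @param mask logical 3-D array (or [roi_mask()]) of the same shape; must be
#'   non-empty.
#' @param G number of gray levels (default 64).
#' @return An object of class `quantized_roi`: list with `levels` (integer
#'   3-D array, `NA` outside the ROI), `values` (raw intensities, `NA`
#'   outside), `mask`, `G`.
#' @export
quantize <- function(channel, mask, G = 64L) {
  if (!identical(dim(channel), dim(mask))) stop("mask shape does not match channel")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("empty mask")
  G <- as.integer(G)
  if (G < 2L) stop("G must be >= 2")
  v <- channel[mask]
  if (!all(is.finite(v))) stop("non-finite intensities inside ROI")
  rng <- range(v)
  lev <- array(NA_integer_, dim = dim(channel))
  if (rng[2] > rng[1]) {
    q <- floor((v - rng[1]) / (rng[2] - rng[1]) * G) + 1L
    q[q > G] <- G
  } else {
    q <- rep(1L, length(v))      # zero-range convention
  }
  lev[mask] <- as.integer(q)
  vals <- array(NA_real_, dim = dim(channel))
  vals[mask] <- v
  structure(list(levels = lev, values = vals, mask = mask, G = G),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("Quantized ROI: %d voxels, %d gray levels (%d occupied)\n",
              sum(x$mask), x$G, length(unique(x$levels[x$mask]))))
  invisible(x)
}

# In-plane direction offsets (dim1, dim2) for 0, 45, 90, 135 degrees.
texture_directions <- function() {
  list(`0`   = c(0L,  1L),
       `45`  = c(-1L, 1L),
       `90`  = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

# Co-occurring level pairs for one in-plane offset (a, b) at a given distance,
# slice-wise; both voxels must lie in the mask. Returns list(l1, l2).
level_pairs <- function(levels, mask, a, b, distance = 1L) {
  a <- a * distance; b <- b * distance
  d <- dim(levels)
  r1 <- max(1L, 1L - a):min(d[1], d[1] - a)
  c1 <- max(1L, 1L - b):min(d[2], d[2] - b)
  if (length(r1) < 1L || length(c1) < 1L) return(list(l1 = integer(0), l2 = integer(0)))
  m1 <- mask[r1, c1, , drop = FALSE]
  m2 <- mask[r1 + a, c1 + b, , drop = FALSE]
  sel <- m1 & m2
  list(l1 = levels[r1, c1, , drop = FALSE][sel],
       l2 = levels[r1 + a, c1 + b, , drop = FALSE][sel])
}
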