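# Box sizes used for box-counting slopes. Boundary counts start at size 1;
# the intensity relief (differential box counting) starts at size 2 because
# a single-voxel box carries no intensity span.
box_sizes <- function(extent, from = 1L) {
  top <- max(from + 1L, floor(extent / 2))
  s <- unique(round(exp(seq(log(from), log(top), length.out = 4L))))
  as.integer(pmax(from, s))
}

# 2-D box count of a set of (row, col) points at box size s.
count_boxes <- function(pts, s) {
  if (nrow(pts) == 0L) return(0L)
  nrow(unique(cbind(floor((pts[, 1] - 1) / s), floor((pts[, 2] - 1) / s))))
}

# Boundary voxels of a slice mask (4-connectivity): in-mask voxels with at
# least one 4-neighbor outside the mask or outside the image.
boundary_slice <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
           pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(core & !inner, arr.ind = TRUE)
}

#' Fractal dimension features of a masked lesion
#'
#' Two box-counting estimates computed slice-wise and pooled across slices:
#' the boundary fractal dimension (box counts of the 4-connectivity boundary
#' voxels versus box size; a smooth closed contour gives a slope near 1) and
#' the intensity-surface fractal dimension by differential box counting on
#' the quantized intensity relief over the ROI.
#'
#' @param channel 3-D numeric array.
#' @param mask logical 3-D array of the same shape, non-degenerate (more than
#'   one voxel).
#' @param G gray levels used for the intensity relief (default 64).
#' @return Named numeric vector `c(intensity_fd, boundary_fd)`.
#' @export
fractal_features <- function(channel, mask, G = 64L) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (sum(mask) < 2L) stop("degenerate (single-voxel) mask")
  q <- quantize(channel, mask, G)
  d <- dim(mask)
  ext <- max(d[1], d[2])
  b_sizes <- box_sizes(ext, from = 1L)
  i_sizes <- box_sizes(ext, from = 2L)

  bnd_counts <- numeric(length(b_sizes))
  int_counts <- numeric(length(i_sizes))
  for (k in seq_len(d[3])) {
    m <- mask[, , k]
    if (!any(m)) next
    bpts <- boundary_slice(m)
    lv <- q$levels[, , k]
    rpts <- which(m, arr.ind = TRUE)
    for (si in seq_along(b_sizes))
      bnd_counts[si] <- bnd_counts[si] + count_boxes(bpts, b_sizes[si])
    for (si in seq_along(i_sizes)) {
      # differential box counting: per s x s column, span of levels / box height
      s <- i_sizes[si]
      h <- max(1, s * G / ext)
      cell <- cbind(floor((rpts[, 1] - 1) / s), floor((rpts[, 2] - 1) / s))
      key <- factor(paste(cell[, 1], cell[, 2], sep = ","))
      vals <- lv[rpts]
      lo <- tapply(vals, key, min)
      hi <- tapply(vals, key, max)
      int_counts[si] <- int_counts[si] + sum(floor(hi / h) - floor(lo / h) + 1)
    }
  }
  slope_fd <- function(counts, sizes) {
    keep <- counts > 0
    if (sum(keep) < 2L) return(NA_real_)
    -stats::coef(stats::lm(log(counts[keep]) ~ log(sizes[keep])))[[2L]]
  }
  c(intensity_fd = slope_fd(int_counts, i_sizes),
    boundary_fd = slope_fd(bnd_counts, b_sizes))
}

# Signed test of grid points against a convex polygon (vertices in order):
# a point counts as inside when it lies on the inner side of every edge,
# with a small tolerance so boundary points are included.
points_in_convex <- function(px, py, vx, vy, tol = 1e-9) {
  nv <- length(vx)
  if (nv == 1L) return(abs(px - vx) < tol & abs(py - vy) < tol)
  # ensure counter-clockwise orientation (shoelace)
  area2 <- sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)
  if (area2 < 0) { vx <- rev(vx); vy <- rev(vy) }
  inside <- rep(TRUE, length(px))
  for (e in seq_len(nv)) {
    e2 <- if (e == nv) 1L else e + 1L
    cr <- (vx[e2] - vx[e]) * (py - vy[e]) - (vy[e2] - vy[e]) * (px - vx[e])
    inside <- inside & cr >= -tol
  }
  # degenerate (collinear) polygons: restrict to the bounding box
  inside & px >= min(vx) - tol & px <= max(vx) + tol &
           py >= min(vy) - tol & py <= max(vy) + tol
}

#' Convexity of a lesion mask
#'
#' Ratio of the ROI volume to the volume of its convex hull, computed
#' slice-wise: per slice the 2-D convex hull of the in-mask voxel centers is
#' rasterized (a voxel belongs to the hull if its center lies inside or on
#' the hull polygon) and the ratio of total ROI voxels to total hull voxels
#' is returned, clipped to (0, 1]. Convex shapes score 1 within
#' discretization; concave shapes score below 1.
#'
#' @param mask logical 3-D array, non-degenerate.
#' @return Convexity ratio in (0, 1].
#' @export
convexity <- function(mask) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (sum(mask) < 2L) stop("degenerate (single-voxel) mask")
  d <- dim(mask)
  n_roi <- 0L; n_hull <- 0L
  grid <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]))
  for (k in seq_len(d[3])) {
    m <- mask[, , k]
    if (!any(m)) next
    pts <- which(m, arr.ind = TRUE)
    n_roi <- n_roi + nrow(pts)
    if (nrow(pts) <= 2L) { n_hull <- n_hull + nrow(pts); next }
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    inside <- points_in_convex(grid$r, grid$c,
                               pts[hull, 1], pts[hull, 2])
    n_hull <- n_hull + sum(inside)
  }
  min(1, n_roi / n_hull)
}
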