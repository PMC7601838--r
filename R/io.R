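#' Construct a multiparametric volume set
#'
#' Bundles N co-registered 3-D intensity volumes (e.g. T2, ADC, Ktrans map,
#' post-contrast DCE) sharing one voxel grid. The per-voxel vector of
#' intensities across the channels is the tissue signature used by the
#' multiparametric radiomics ([build_signatures()]).
#'
#' @param channels named list of 3-D numeric arrays, all with identical
#'   dimensions. Names are the parameter names.
#' @param spacing numeric length-3 voxel spacing in mm per axis.
#' @param units optional character vector of physical units, one per channel.
#' @return An object of class `volume_set`.
#' @export
volume_set <- function(channels, spacing = c(1, 1, 1), units = NULL) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("'channels' must be a non-empty named list of 3-D arrays")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("all channels must be 3-D arrays")
  ref <- dims[[1L]]
  for (d in dims)
    if (!identical(d, ref)) stop("channel grid shapes differ")
  for (ch in channels)
    if (!all(is.finite(ch))) stop("channel intensities must be finite")
  if (is.null(units)) units <- rep("a.u.", length(channels))
  structure(list(channels = channels, spacing = as.numeric(spacing),
                 units = units),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("Multiparametric volume set: %d channel(s), grid %s, spacing %s mm\n",
              length(x$channels), paste(d, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param mask logical or 0/1 3-D array.
#' @param label one of `"lesion"` or `"glandular"`.
#' @return An object of class `roi_mask` (a logical array with a label
#'   attribute).
#' @export
roi_mask <- function(mask, label = c("lesion", "glandular")) {
  label <- match.arg(label)
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  m <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(m)) stop("mask must not contain NA")
  structure(m, label = label, class = "roi_mask")
}

check_mask <- function(volumes, mask, require_nonempty = TRUE) {
  if (!identical(dim(volumes$channels[[1L]]), dim(mask)))
    stop("mask shape does not match channel grid")
  if (require_nonempty && !any(mask)) stop("mask is empty")
  invisible(TRUE)
}

#' Read a set of co-registered volumes from NIfTI files
#'
#' @param paths character vector of NIfTI file paths.
#' @param names parameter names, one per path.
#' @param units optional units, one per path.
#' @return A [volume_set()].
#' @export
read_volume_set <- function(paths, names, units = NULL) {
  if (length(paths) == 0L) stop("empty channel list")
  if (length(paths) != length(names)) stop("'paths' and 'names' differ in length")
  imgs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    RNifti::readNifti(p)
  })
  spacing <- RNifti::pixdim(imgs[[1L]])[1:3]
  channels <- lapply(imgs, function(im) array(as.numeric(im), dim = dim(im)))
  names(channels) <- names
  volume_set(channels, spacing = spacing, units = units)
}

#' Write a volume set to NIfTI files
#'
#' @param volumes a [volume_set()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return Invisibly, the written file paths (named by channel).
#' @export
write_volume_set <- function(volumes, dir, prefix = "vol") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(volumes$channels))
  names(paths) <- names(volumes$channels)
  for (i in seq_along(volumes$channels)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, names(volumes$channels)[i]))
    im <- RNifti::asNifti(volumes$channels[[i]])
    RNifti::pixdim(im) <- volumes$spacing
    RNifti::writeNifti(im, p)
    paths[i] <- p
  }
  invisible(paths)
}

#' Read an ROI mask from a NIfTI file
#'
#' Voxels with value > 0.5 are inside the ROI.
#'
#' @param path NIfTI file path.
#' @param label mask label, `"lesion"` or `"glandular"`.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, label = c("lesion", "glandular")) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(im) > 0.5, dim = dim(im)), label = match.arg(label))
}

#' Write an ROI mask to a NIfTI file
#' @param mask an [roi_mask()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim = dim(mask))), path)
  invisible(path)
}

#' Write / read a patient feature table
#'
#' Plain-CSV persistence for the patients-by-parameters matrix consumed by the
#' embedding, network and classification stages. Missing values are written as
#' `NA` and flagged on read.
#'
#' @param table data.frame of features, one row per patient.
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data.frame with an attribute
#'   `missing_flags` marking NA cells.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(names(table))) stop("duplicate column names")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(tab))) stop("duplicate column names")
  attr(tab, "missing_flags") <- is.na(tab)
  tab
}

#' Fit apparent diffusion coefficient maps from diffusion-weighted signals
#'
#' Per-voxel monoexponential fit S(b) = S0 * exp(-b * ADC), estimated by
#' ordinary least squares of log-signal against b-value. With exactly two
#' b-values this reduces to the analytic two-point formula
#' ADC = log(S1/S2) / (b2 - b1). Voxels with any non-positive signal cannot be
#' log-transformed and are returned as `NA` (flagged invalid, excluded from
#' ROI statistics).
#'
#' @param signals numeric array of diffusion-weighted intensities whose last
#'   dimension indexes b-values: a matrix (voxels x b) or a 4-D array
#'   (x,y,z,b).
#' @param bvalues numeric vector of b-values in s/mm^2 (>= 2 distinct).
#' @return ADC in mm^2/s, shaped like one b-volume of the input.
#' @export
fit_adc <- function(signals, bvalues) {
  bvalues <- as.numeric(bvalues)
  if (length(unique(bvalues)) < 2L) stop("need >= 2 distinct b-values")
  dm <- dim(signals)
  if (is.null(dm)) dm <- c(length(signals) / length(bvalues), length(bvalues))
  nb <- dm[length(dm)]
  if (nb != length(bvalues)) stop("last dimension must match length(bvalues)")
  vox_dim <- dm[-length(dm)]
  S <- matrix(as.numeric(signals), ncol = nb)
  valid <- rowSums(S <= 0) == 0L
  adc <- rep(NA_real_, nrow(S))
  if (any(valid)) {
    # OLS slope of -log S on b: ADC = -cov(b, logS)/var(b)
    b_c <- bvalues - mean(bvalues)
    denom <- sum(b_c^2)
    logS <- log(S[valid, , drop = FALSE])
    adc[valid] <- -as.vector(logS %*% b_c) / denom
  }
  if (length(vox_dim) > 1L) array(adc, dim = vox_dim) else adc
}

#' Normalized ADC ratio (lesion over glandular tissue)
#'
#' @param lesion_mean mean lesion ADC (mm^2/s).
#' @param glandular_mean mean glandular-tissue ADC (mm^2/s), must be > 0.
#' @return `lesion_mean / glandular_mean`.
#' @export
normalized_adc <- function(lesion_mean, glandular_mean) {
  if (any(glandular_mean <= 0)) stop("glandular mean ADC must be positive")
  lesion_mean / glandular_mean
}

#' ROI summary statistics
#'
#' Mean and standard deviation of a channel over the valid (finite) voxels of
#' an ROI.
#'
#' @param channel 3-D numeric array.
#' @param mask an [roi_mask()] (or logical array) of the same shape.
#' @return list with `mean`, `sd`, `n` (valid voxels used).
#' @export
roi_stats <- function(channel, mask) {
  if (!identical(dim(channel), dim(mask))) stop("mask shape does not match channel")
  v <- channel[as.logical(mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no valid voxels in ROI")
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}
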