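#' Project nuisance regressors out of region time courses
#'
#' Each row of `x` is replaced by the residual of its least-squares fit on an
#' intercept plus the supplied regressors (multiple linear regression). This
#' is the standard removal of non-neuronal signal sources: typical regressors
#' are the mean time course of high-variance out-of-brain voxels, the mean
#' cerebrospinal-fluid signal and the mean white-matter signal, but any
#' finite `r x n` matrix is accepted.
#'
#' @param x `p x n` matrix of region time courses.
#' @param regressors `r x n` matrix, one nuisance series per row.
#' @return `p x n` matrix of residuals; every row is orthogonal to every
#'   regressor and has zero mean.
#' @export
nuisance_regress <- function(x, regressors) {
  x <- as.matrix(x)
  regressors <- as.matrix(regressors)
  if (ncol(regressors) != ncol(x))
    stop("regressors and data must share the number of timepoints")
  if (!all(is.finite(regressors))) stop("regressors must be finite")
  if (nrow(regressors) >= ncol(x))
    stop("need fewer regressors than timepoints")
  d <- cbind(1, t(regressors))            # n x (r+1) design
  qd <- qr(d)
  if (qd$rank < ncol(d)) {
    drop_cols <- setdiff(seq_len(ncol(d)), qd$pivot[seq_len(qd$rank)])
    stop(sprintf("rank-deficient regressor set: collinear column(s) %s",
                 paste(drop_cols - 1L, collapse = ", ")))
  }
  res <- t(qr.resid(qd, t(x)))
  dimnames(res) <- dimnames(x)
  res
}

# discrete-cosine drift basis: columns cos(pi*(t - 1/2)*j/n), j = 1..order
.dct_basis <- function(n, order) {
  t_idx <- seq_len(n) - 0.5
  sapply(seq_len(order), function(j) cos(pi * t_idx * j / n))
}

#' High-pass filter by removing a discrete-cosine drift basis
#'
#' Removes slow drifts with period at or above `cutoff_period` by regressing
#' each row on an intercept plus the discrete cosine transform (DCT) basis
#' functions whose frequencies fall below `1 / cutoff_period`. This is the
#' drift model commonly used for fMRI high-pass filtering; a 140 s cutoff
#' reproduces the conventional preprocessing choice for narrative stimuli.
#'
#' @param x `p x n` matrix of region time courses.
#' @param cutoff_period drift period in seconds; components slower than this
#'   are removed (including the constant term).
#' @param tr sampling interval in seconds.
#' @return Filtered `p x n` matrix with zero-mean rows.
#' @export
highpass <- function(x, cutoff_period, tr) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (cutoff_period <= 2 * tr)
    stop("cutoff period must exceed twice the sampling interval (Nyquist)")
  # DCT component j has frequency j / (2 n tr); keep drifts below 1/cutoff
  order <- floor(2 * n * tr / cutoff_period)
  xc <- x - rowMeans(x)
  if (order >= 1L) {
    b <- .dct_basis(n, order)
    qb <- qr(b)
    xc <- t(qr.resid(qb, t(xc)))
  }
  dimnames(xc) <- dimnames(x)
  xc
}

#' Average voxel time courses within regions of interest
#'
#' Collapses a 4-D volume (x, y, z, time) to a `p x n` matrix by averaging,
#' at each timepoint, the voxels belonging to each ROI. ROIs are given as
#' voxel-index sets (linear indices into a single volume, or `nvox x 3`
#' integer coordinate matrices) and must be non-empty and mutually disjoint.
#' A NIfTI file path is accepted when the RNifti package is available.
#'
#' @param volume_4d 4-D numeric array or path to a NIfTI-1 file.
#' @param rois named list of ROI voxel index vectors (linear indices) or
#'   `nvox x 3` coordinate matrices.
#' @return `p x n` matrix, one averaged time course per ROI.
#' @export
extract_roi_timeseries <- function(volume_4d, rois) {
  if (is.character(volume_4d)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI volumes requires the RNifti package")
    volume_4d <- as.array(RNifti::readNifti(volume_4d))
  }
  if (length(dim(volume_4d)) != 4L)
    stop("'volume_4d' must be a 4-D (x, y, z, time) array")
  dm <- dim(volume_4d)
  nvox <- prod(dm[1:3])
  n <- dm[4L]
  idx_list <- lapply(rois, function(r) {
    if (is.matrix(r)) {
      if (ncol(r) != 3L) stop("ROI coordinate matrices must have 3 columns")
      r <- r[, 1L] + (r[, 2L] - 1L) * dm[1L] + (r[, 3L] - 1L) * dm[1L] * dm[2L]
    }
    r <- as.integer(r)
    if (length(r) == 0L) stop("ROI with no voxels")
    if (any(r < 1L | r > nvox)) stop("ROI voxel outside the volume grid")
    r
  })
  all_idx <- unlist(idx_list)
  if (anyDuplicated(all_idx))
    stop("ROIs must be mutually disjoint")
  flat <- matrix(volume_4d, nrow = nvox, ncol = n)
  out <- t(vapply(idx_list, function(ii) colMeans(flat[ii, , drop = FALSE]),
                  numeric(n)))
  rownames(out) <- names(rois)
  out
}
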