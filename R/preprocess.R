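#' Gaussian filter width (in volumes) for a frequency cutoff
#'
#' The running-mean Gaussian temporal filters are parameterized by a
#' sigma in volumes: sigma = 1 / (2 f TR). At TR 2.5 s this gives 22.2
#' volumes for the 0.009 Hz high-pass cutoff and 2.5 volumes for the
#' 0.08 Hz low-pass cutoff.
#'
#' @param f_hz cutoff frequency in Hz (> 0).
#' @param tr_seconds repetition time in seconds.
#' @return sigma in volumes.
#' @export
sigma_from_cutoff <- function(f_hz, tr_seconds) {
  stopifnot(f_hz > 0, tr_seconds > 0)
  if (f_hz >= 1 / (2 * tr_seconds))
    warning("cutoff at or above Nyquist frequency")
  1 / (2 * f_hz * tr_seconds)
}

#' Band-pass filter specification
#'
#' @param f_low_hz high-pass cutoff (Hz); fluctuations slower than this are
#'   removed (scanner drift).
#' @param f_high_hz low-pass cutoff (Hz); fluctuations faster than this are
#'   removed (cardiac/respiratory-band noise).
#' @param tr_seconds repetition time.
#' @return list of class `filter_spec` with the two cutoffs, TR, and the
#'   derived Gaussian sigmas in volumes (`sigma_highpass_vols` for the
#'   low-frequency cutoff, `sigma_lowpass_vols` for the high-frequency one).
#' @export
filter_spec <- function(f_low_hz = 0.009, f_high_hz = 0.08, tr_seconds = 2.5) {
  stopifnot(f_low_hz > 0, f_high_hz > f_low_hz)
  if (f_high_hz >= 1 / (2 * tr_seconds))
    stop("f_high_hz must be below Nyquist")
  structure(list(
    f_low_hz = f_low_hz, f_high_hz = f_high_hz, tr_seconds = tr_seconds,
    sigma_highpass_vols = sigma_from_cutoff(f_low_hz, tr_seconds),
    sigma_lowpass_vols = sigma_from_cutoff(f_high_hz, tr_seconds)),
    class = "filter_spec")
}

# T x T Gaussian running-mean weight matrix with renormalized truncated
# weights at the series edges (each row sums to 1).
gaussian_running_mean_matrix <- function(n, sigma_vols) {
  idx <- seq_len(n)
  w <- exp(-outer(idx, idx, "-")^2 / (2 * sigma_vols^2))
  w / rowSums(w)
}

# Band-pass columns of a T x V matrix: high-pass (series minus Gaussian
# running mean at sigma_highpass) then Gaussian low-pass at sigma_lowpass.
bandpass_matrix <- function(x, fs) {
  n <- nrow(x)
  hp <- x - gaussian_running_mean_matrix(n, fs$sigma_highpass_vols) %*% x
  gaussian_running_mean_matrix(n, fs$sigma_lowpass_vols) %*% hp
}

#' Temporal band-pass filter of a BOLD series
#'
#' Voxelwise Gaussian-weighted running-line filtering: the high-pass step
#' subtracts a Gaussian running mean (sigma = 1/(2 f_low TR) volumes), the
#' low-pass step smooths with a Gaussian of sigma = 1/(2 f_high TR)
#' volumes. Edge weights are renormalized (truncated Gaussian). The
#' operator is linear and maps constant series to (numerically) zero.
#'
#' @param b a [bold_series()].
#' @param fs a [filter_spec()]; its TR must match the series.
#' @return filtered `bold_series`.
#' @export
bandpass_temporal <- function(b, fs) {
  stopifnot(inherits(b, "bold_series"), inherits(fs, "filter_spec"))
  if (abs(fs$tr_seconds - b$tr_seconds) > 1e-9)
    stop("filter_spec TR does not match series TR")
  nt <- n_volumes(b)
  if (nt < 3 * fs$sigma_lowpass_vols)
    warning("series shorter than 3 sigma of the low-pass kernel")
  d <- dim(b$data)
  x <- t(matrix(b$data, prod(d[1:3]), d[4]))      # T x V
  y <- bandpass_matrix(x, fs)
  bold_series(array(t(y), dim = d), b$tr_seconds)
}

#' Discard initial volumes
#'
#' Removes the first `n` time points (magnet-stabilization volumes) from
#' the BOLD series and, if supplied, the matching rows of the motion
#' parameters.
#'
#' @param b a [bold_series()].
#' @param n volumes to discard (default 4).
#' @param motion optional per-volume motion parameter matrix (rows = volumes).
#' @return the trimmed `bold_series`, or `list(bold, motion)` when motion
#'   is supplied.
#' @export
drop_initial_volumes <- function(b, n = 4, motion = NULL) {
  stopifnot(inherits(b, "bold_series"), n >= 0)
  nt <- n_volumes(b)
  if (nt <= n) stop("cannot discard ", n, " of ", nt, " volumes")
  keep <- (n + 1L):nt
  out <- new_bold_series(b$data[, , , keep, drop = FALSE], b$tr_seconds)
  if (is.null(motion)) return(out)
  stopifnot(nrow(motion) == nt)
  list(bold = out, motion = motion[keep, , drop = FALSE])
}

# n x n symmetric-boundary (reflective) Gaussian convolution matrix;
# preserves constants (rows sum to 1) and totals (columns sum to 1).
gaussian_reflect_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  taps <- (-r):r
  w <- exp(-taps^2 / (2 * sigma_vox^2)); w <- w / sum(w)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + taps
    # reflect about the edges (half-sample symmetric)
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    j <- ifelse(j < 1L, 1L - j, j)   # second fold for very wide kernels
    for (k in seq_along(taps)) m[i, j[k]] <- m[i, j[k]] + w[k]
  }
  m
}

# multiply matrix M (n_axis x n_axis) along one axis of a 3D/4D array
apply_axis <- function(a, m, axis) {
  d <- dim(a); nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  x <- aperm(a, perm)
  dx <- dim(x)
  y <- m %*% matrix(x, d[axis], prod(dx[-1]))
  dim(y) <- dx
  aperm(y, order(perm))
}

#' Spatial Gaussian smoothing of a BOLD series
#'
#' Per-volume separable 3D Gaussian convolution with
#' sigma_mm = FWHM / (2 sqrt(2 ln 2)), reflective boundary handling
#' (volume totals and constants are preserved).
#'
#' @param b a [bold_series()] (or 3D array).
#' @param fwhm_mm kernel full width at half maximum in mm (default 6).
#' @param voxel_mm isotropic voxel size in mm.
#' @return smoothed object of the same type.
#' @export
smooth_spatial <- function(b, fwhm_mm = 6, voxel_mm) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  arr <- if (inherits(b, "bold_series")) b$data else b
  d3 <- dim(arr)[1:3]
  for (ax in 1:3)
    arr <- apply_axis(arr, gaussian_reflect_matrix(d3[ax], sigma_vox), ax)
  if (inherits(b, "bold_series")) new_bold_series(arr, b$tr_seconds) else arr
}

# 4x4 rigid transform from 3 rotations (radians, about x/y/z) and 3
# translations (mm)
rigid_transform <- function(rot, trans) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  m <- diag(4)
  m[1:3, 1:3] <- rx %*% ry %*% rz
  m[1:3, 4] <- trans
  m
}

#' Mean absolute displacement between consecutive volumes
#'
#' For each consecutive volume pair, the RMS displacement of the relative
#' rigid-body transform averaged over a solid sphere of the given radius
#' (Jenkinson's formulation): with M - I = \[A b; 0 0\],
#' d = sqrt(R^2/5 tr(A'A) + b'b). Returns the mean across pairs, in mm.
#' Only relative motion contributes; a constant offset applied to every
#' volume cancels.
#'
#' @param m motion matrix, one row per volume: 3 rotations (radians) then
#'   3 translations (mm).
#' @param radius_mm sphere radius (default 80 mm).
#' @return mean displacement in mm.
#' @export
mean_abs_displacement <- function(m, radius_mm = 80) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 volumes to measure displacement")
  stopifnot(ncol(m) == 6)
  d <- numeric(nrow(m) - 1)
  prev <- rigid_transform(m[1, 1:3], m[1, 4:6])
  for (i in 2:nrow(m)) {
    cur <- rigid_transform(m[i, 1:3], m[i, 4:6])
    rel <- cur %*% solve(prev)
    a <- rel[1:3, 1:3] - diag(3)
    b <- rel[1:3, 4]
    d[i - 1] <- sqrt(radius_mm^2 / 5 * sum(a * a) + sum(b * b))
    prev <- cur
  }
  mean(d)
}

#' Mean time course over a mask
#'
#' @param b a [bold_series()].
#' @param mask logical 3D array on the same grid, nonempty.
#' @return numeric vector of length n_volumes.
#' @export
extract_mean_timecourse <- function(b, mask) {
  stopifnot(inherits(b, "bold_series"))
  if (!any(mask)) stop("mask is empty")
  d <- dim(b$data)
  if (!all(dim(mask) == d[1:3])) stop("mask grid does not match series")
  x <- matrix(b$data, prod(d[1:3]), d[4])
  colMeans(x[as.vector(mask), , drop = FALSE])
}

#' Assemble the first-level design matrix
#'
#' Columns: seed regressor, WM mean, CSF mean, the 6 motion parameters,
#' and an intercept. All non-intercept columns are mean-centered, and the
#' design is checked for full column rank.
#'
#' @param seed_tc,wm_tc,csf_tc time courses of equal length.
#' @param motion motion matrix (rows = time points, 6 columns).
#' @return design matrix with column names
#'   `seed, wm, csf, rot_x..trans_z, intercept`.
#' @export
build_first_level_design <- function(seed_tc, wm_tc, csf_tc, motion) {
  motion <- as.matrix(motion)
  nt <- length(seed_tc)
  stopifnot(length(wm_tc) == nt, length(csf_tc) == nt,
            nrow(motion) == nt, ncol(motion) == 6)
  x <- cbind(seed = seed_tc, wm = wm_tc, csf = csf_tc, motion,
             intercept = 1)
  colnames(x)[4:9] <- c("rot_x", "rot_y", "rot_z",
                        "trans_x", "trans_y", "trans_z")
  x[, 1:9] <- sweep(x[, 1:9, drop = FALSE], 2,
                    colMeans(x[, 1:9, drop = FALSE]))
  assert_full_rank(x)
  x
}

assert_full_rank <- function(x) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(x)
}
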