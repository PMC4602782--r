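#' Preprocessing configuration
#'
#' Defaults follow common practice for 3 T resting-state acquisitions:
#' discard the first 10 volumes, exclude subjects moving more than 1 mm or
#' 1 degree, smooth with an 8 mm FWHM isotropic Gaussian, regress the six
#' motion parameters plus CSF/white-matter/global mean signals, and band-pass
#' to the 0.01-0.08 Hz low-frequency fluctuation band.
#'
#' @param n_discard initial volumes to discard.
#' @param translation_limit_mm,rotation_limit_deg motion-exclusion limits;
#'   exceedance is strict (`>`), so a subject at exactly the limit is kept.
#' @param smooth_fwhm_mm isotropic smoothing kernel FWHM in mm.
#' @param band_low_hz,band_high_hz pass band in Hz; must satisfy
#'   `band_low_hz < band_high_hz < 1/(2 TR)`.
#' @param nuisance_set named logical flags: `motion`, `csf`, `wm`, `global`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(n_discard = 10,
                              translation_limit_mm = 1.0,
                              rotation_limit_deg = 1.0,
                              smooth_fwhm_mm = 8,
                              band_low_hz = 0.01,
                              band_high_hz = 0.08,
                              nuisance_set = c(motion = TRUE, csf = TRUE,
                                               wm = TRUE, global = TRUE)) {
  dmn_assert(band_low_hz > 0 && band_low_hz < band_high_hz,
             "bad_params", "need 0 < band_low_hz < band_high_hz")
  dmn_assert(smooth_fwhm_mm > 0, "bad_params", "smooth_fwhm_mm must be > 0")
  structure(list(n_discard = as.integer(n_discard),
                 translation_limit_mm = translation_limit_mm,
                 rotation_limit_deg = rotation_limit_deg,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 nuisance_set = nuisance_set),
            class = "preprocess_config")
}

#' Discard initial volumes
#'
#' Drops the first `n` volumes of a BOLD series (steady-state magnetization
#' settling) and marks the series as discarded; applying it twice is refused.
#'
#' @param bold a [bold_series()].
#' @param n number of initial volumes to drop.
#' @return The shortened [bold_series()] with `discarded = TRUE`.
#' @export
discard_initial <- function(bold, n) {
  dmn_assert(!bold$discarded, "already_discarded",
             "initial volumes were already discarded from this series")
  nt <- dim(bold$data)[4]
  dmn_assert(n >= 0 && n < nt, "bad_discard",
             sprintf("cannot discard %d of %d volumes", n, nt))
  params <- acq_params(bold$params$tr_seconds, bold$params$n_volumes,
                       n_discard = n, voxel_size_mm = bold$params$voxel_size_mm)
  data <- bold$data[, , , seq.int(n + 1L, nt), drop = FALSE]
  bold_series(data, bold$affine, params, discarded = TRUE)
}

#' Screen a motion trace against exclusion limits
#'
#' A subject is excluded when any volume's absolute translation exceeds the
#' translation limit or any absolute rotation exceeds the rotation limit.
#' Exceedance is strict: values exactly at the limit are retained.
#'
#' @param trace a [motion_trace()].
#' @param config a [preprocess_config()].
#' @return A list with `excluded` (logical), `max_translation_mm`,
#'   `max_rotation_deg`, and the limits applied.
#' @export
screen_motion <- function(trace, config = preprocess_config()) {
  max_t <- max(abs(trace$translations_mm))
  max_r <- max(abs(trace$rotations_deg))
  list(excluded = max_t > config$translation_limit_mm ||
         max_r > config$rotation_limit_deg,
       max_translation_mm = max_t, max_rotation_deg = max_r,
       translation_limit_mm = config$translation_limit_mm,
       rotation_limit_deg = config$rotation_limit_deg)
}

# --- Gaussian smoothing -----------------------------------------------------

# 1-D truncated, row-normalized Gaussian smoothing matrix for an axis of
# length n; sigma in voxel units. Rows sum to one, so constants are
# preserved and edge voxels renormalize over the in-bounds window.
gauss_smooth_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- exp(-((j - i)^2) / (2 * sigma_vox^2))
    S[i, j] <- w / sum(w)
  }
  S
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Apply separable smoothing along the three spatial axes of a 3-D or 4-D
# array. kernels: list of the three smoothing matrices.
smooth_separable <- function(x, kernels) {
  d <- dim(x)
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  rest <- prod(d) / (n1 * n2 * n3)
  dim(x) <- c(n1, n2 * n3 * rest)
  x <- kernels[[1]] %*% x
  dim(x) <- c(n1, n2, n3 * rest)
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(n2, n1 * n3 * rest)
  x <- kernels[[2]] %*% x
  dim(x) <- c(n2, n1, n3, rest)
  x <- aperm(x, c(3, 2, 1, 4))
  dim(x) <- c(n3, n1 * n2 * rest)
  x <- kernels[[3]] %*% x
  dim(x) <- c(n3, n1, n2, rest)
  x <- aperm(x, c(2, 3, 1, 4))
  dim(x) <- d
  x
}

smoothing_kernels <- function(shape, voxel_size_mm, fwhm_mm) {
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  lapply(1:3, function(a) gauss_smooth_matrix(shape[a], sig[a]))
}

#' Spatial Gaussian smoothing
#'
#' Convolves each volume with a separable isotropic Gaussian of the given
#' FWHM (sigma = FWHM / (2 sqrt(2 ln 2)) per axis, converted from mm to
#' voxels per axis). The kernel is truncated at 4 sigma and renormalized, so
#' constant volumes are unchanged and interior intensity is conserved.
#'
#' @param bold a [bold_series()].
#' @param fwhm_mm kernel full width at half maximum in mm (> 0).
#' @return The smoothed [bold_series()].
#' @export
smooth_bold <- function(bold, fwhm_mm) {
  dmn_assert(is.numeric(fwhm_mm) && fwhm_mm > 0, "bad_params",
             "fwhm_mm must be positive")
  shape <- dim(bold$data)[1:3]
  ker <- smoothing_kernels(shape, bold$params$voxel_size_mm, fwhm_mm)
  out <- smooth_separable(bold$data, ker)
  bold_series(out, bold$affine, bold$params, discarded = bold$discarded)
}

# --- Nuisance regression ----------------------------------------------------

# time x voxel matrix view of a 4-D lattice (column-major voxel order)
bold_ts_matrix <- function(bold) {
  d <- dim(bold$data)
  t(matrix(bold$data, prod(d[1:3]), d[4]))
}

matrix_to_bold <- function(Y, template) {
  d <- dim(template$data)
  bold_series(array(t(Y), dim = d), template$affine, template$params,
              discarded = template$discarded)
}

mask_mean_series <- function(bold, mask) {
  d <- dim(bold$data)
  keep <- as.vector(mask$data)
  dmn_assert(any(keep), "empty_mask", "mask selects no voxels")
  M <- matrix(bold$data, prod(d[1:3]), d[4])
  colMeans(M[keep, , drop = FALSE])
}

#' Regress nuisance signals out of a BOLD series
#'
#' Ordinary least squares per voxel on a design of intercept, the six motion
#' parameters, and mean time series from CSF, white matter, and the whole
#' brain, per the configured `nuisance_set`. The returned series holds the
#' residuals, which are orthogonal to every regressor.
#'
#' @param bold a discarded [bold_series()] (post [discard_initial()]).
#' @param trace the subject's full-length [motion_trace()]; the retained
#'   volumes are selected to match the series.
#' @param csf_mask,wm_mask,brain_mask [binary_mask()] objects on the series
#'   grid.
#' @param config a [preprocess_config()].
#' @return The residual [bold_series()].
#' @export
regress_nuisance <- function(bold, trace, csf_mask, wm_mask, brain_mask,
                             config = preprocess_config()) {
  nt <- dim(bold$data)[4]
  X <- matrix(1, nt, 1)
  cn <- "intercept"
  ns <- config$nuisance_set
  if (isTRUE(ns[["motion"]])) {
    m <- cbind(trace$translations_mm, trace$rotations_deg)
    dmn_assert(nrow(m) >= nt, "bad_motion",
               "motion trace shorter than the BOLD series")
    m <- m[seq.int(nrow(m) - nt + 1L, nrow(m)), , drop = FALSE]
    X <- cbind(X, m)
    cn <- c(cn, paste0("motion_", c("tx", "ty", "tz", "rx", "ry", "rz")))
  }
  if (isTRUE(ns[["csf"]])) {
    X <- cbind(X, mask_mean_series(bold, csf_mask)); cn <- c(cn, "csf_mean")
  }
  if (isTRUE(ns[["wm"]])) {
    X <- cbind(X, mask_mean_series(bold, wm_mask)); cn <- c(cn, "wm_mean")
  }
  if (isTRUE(ns[["global"]])) {
    X <- cbind(X, mask_mean_series(bold, brain_mask)); cn <- c(cn, "global_mean")
  }
  colnames(X) <- cn
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    offending <- cn[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    dmn_stop("collinear_design",
             paste("nuisance design is rank deficient; offending column(s):",
                   paste(offending, collapse = ", ")))
  }
  Y <- bold_ts_matrix(bold)
  Q <- qr.Q(qx)
  E <- Y - Q %*% crossprod(Q, Y)
  matrix_to_bold(E, bold)
}

# --- Band-pass filtering ----------------------------------------------------

# Zero-phase frequency-domain band-pass gains for an N-point series sampled
# at interval tr. Ideal window with a raised-cosine transition of width
# `transition` Hz centred on each band edge; DC is always removed.
bandpass_gains <- function(n, tr, low, high, transition = 0.005) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr)
  ramp_up <- function(f, edge) {
    lo <- max(edge - transition / 2, 0); hi <- edge + transition / 2
    g <- (f - lo) / (hi - lo)
    pmin(pmax(g, 0), 1)
  }
  up <- ramp_up(f, low)
  down <- 1 - ramp_up(f, high)
  g <- 0.5 * (1 - cos(pi * up)) * 0.5 * (1 - cos(pi * down))
  g[f == 0] <- 0
  g
}

# The filter is a fixed linear operator per (n, tr, band); materializing it
# once and applying it as a single matrix product is much faster than
# repeated FFTs across thousands of voxel columns.
.bandpass_cache <- new.env(parent = emptyenv())

bandpass_operator <- function(n, tr, low, high) {
  key <- paste(n, tr, low, high, sep = "|")
  op <- .bandpass_cache[[key]]
  if (is.null(op)) {
    g <- bandpass_gains(n, tr, low, high)
    Yf <- stats::mvfft(diag(n))
    op <- Re(stats::mvfft(Yf * g, inverse = TRUE)) / n
    .bandpass_cache[[key]] <- op
  }
  op
}

bandpass_matrix <- function(Y, tr, low, high) {
  bandpass_operator(nrow(Y), tr, low, high) %*% Y
}

#' Temporal band-pass filter
#'
#' Zero-phase frequency-domain filter retaining the low-frequency fluctuation
#' band. Components outside `[low_hz, high_hz]` are attenuated through a
#' raised-cosine transition of width 0.005 Hz; the DC component is removed.
#'
#' @param bold a [bold_series()].
#' @param low_hz,high_hz band edges in Hz; `0 < low < high < 1/(2 TR)`.
#' @return The filtered [bold_series()] (same length as the input).
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  tr <- bold$params$tr_seconds
  nyq <- 1 / (2 * tr)
  dmn_assert(low_hz > 0 && low_hz < high_hz && high_hz < nyq, "bad_band",
             sprintf("band must satisfy 0 < low < high < Nyquist (%.3f Hz)", nyq))
  Y <- bold_ts_matrix(bold)
  matrix_to_bold(bandpass_matrix(Y, tr, low_hz, high_hz), bold)
}

#' Run the per-subject preprocessing chain
#'
#' Applies, in order: initial-volume discard, Gaussian smoothing, nuisance
#' regression, band-pass filtering. Motion screening is the caller's
#' responsibility ([screen_motion()]) since excluded subjects are never
#' preprocessed.
#'
#' @inheritParams regress_nuisance
#' @return The preprocessed [bold_series()].
#' @export
preprocess_subject <- function(bold, trace, csf_mask, wm_mask, brain_mask,
                               config = preprocess_config()) {
  dmn_assert(!bold$discarded, "already_discarded",
             "initial volumes were already discarded from this series")
  # fused implementation of discard -> smooth -> regress -> filter; it is
  # checked against the staged operations in the test suite
  d <- dim(bold$data)
  n <- config$n_discard
  dmn_assert(n >= 0 && n < d[4], "bad_discard",
             sprintf("cannot discard %d of %d volumes", n, d[4]))
  x <- bold$data[, , , seq.int(n + 1L, d[4]), drop = FALSE]
  ker <- smoothing_kernels(d[1:3], bold$params$voxel_size_mm,
                           config$smooth_fwhm_mm)
  x <- smooth_separable(x, ker)
  nt <- dim(x)[4]
  n_vox <- prod(d[1:3])
  M <- matrix(x, n_vox, nt)

  X <- matrix(1, nt, 1)
  cn <- "intercept"
  ns <- config$nuisance_set
  if (isTRUE(ns[["motion"]])) {
    m <- cbind(trace$translations_mm, trace$rotations_deg)
    dmn_assert(nrow(m) >= nt, "bad_motion",
               "motion trace shorter than the BOLD series")
    X <- cbind(X, m[seq.int(nrow(m) - nt + 1L, nrow(m)), , drop = FALSE])
    cn <- c(cn, paste0("motion_", c("tx", "ty", "tz", "rx", "ry", "rz")))
  }
  for (tk in c("csf", "wm", "global")) {
    if (!isTRUE(ns[[tk]])) next
    msk <- switch(tk, csf = csf_mask, wm = wm_mask, global = brain_mask)
    keep <- as.vector(msk$data)
    dmn_assert(any(keep), "empty_mask", "tissue mask selects no voxels")
    X <- cbind(X, colMeans(M[keep, , drop = FALSE]))
    cn <- c(cn, paste0(tk, "_mean"))
  }
  colnames(X) <- cn
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    offending <- cn[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    dmn_stop("collinear_design",
             paste("nuisance design is rank deficient; offending column(s):",
                   paste(offending, collapse = ", ")))
  }
  Q <- qr.Q(qx)
  Y <- t(M)
  E <- Y - Q %*% crossprod(Q, Y)
  tr <- bold$params$tr_seconds
  nyq <- 1 / (2 * tr)
  dmn_assert(config$band_high_hz < nyq, "bad_band",
             sprintf("band edge above Nyquist (%.3f Hz)", nyq))
  E <- bandpass_matrix(E, tr, config$band_low_hz, config$band_high_hz)
  params <- acq_params(tr, bold$params$n_volumes, n,
                       voxel_size_mm = bold$params$voxel_size_mm)
  bold_series(array(t(E), dim = c(d[1:3], nt)), bold$affine, params,
              discarded = TRUE)
}
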