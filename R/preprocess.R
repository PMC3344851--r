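# Temporal detrending / high-pass filtering and spatial Gaussian smoothing.
#
# The high-pass is a projection onto the orthogonal complement of a slow
# regressor set (intercept, linear trend, discrete-cosine terms with
# frequencies up to the cutoff), the standard fMRI drift model.  Projection
# (rather than Fourier masking) avoids wraparound artifacts and makes the
# operation exactly idempotent.

#' Preprocessing parameters
#'
#' @param highpass_hz high-pass cutoff in Hz (frequencies below are removed);
#'   default 0.005.
#' @param fwhm_mm full width at half maximum of the spatial Gaussian smoother
#'   in mm; default 8.
#' @param detrend remove a per-voxel linear trend; default TRUE.
#' @return list of class \code{preproc_params}.
#' @export
preproc_params <- function(highpass_hz = 0.005, fwhm_mm = 8, detrend = TRUE) {
  .assert(is.numeric(highpass_hz) && highpass_hz >= 0, "highpass_hz must be >= 0")
  .assert(is.numeric(fwhm_mm) && fwhm_mm >= 0, "fwhm_mm must be >= 0")
  structure(list(highpass_hz = highpass_hz, fwhm_mm = fwhm_mm,
                 detrend = isTRUE(detrend)), class = "preproc_params")
}

# Drift design matrix: intercept [+ linear] [+ DCT cosines below cutoff].
drift_design <- function(n, tr_seconds, highpass_hz, detrend) {
  cols <- list(rep(1, n))
  if (detrend) cols <- c(cols, list(seq_len(n) - (n + 1) / 2))
  if (highpass_hz > 0) {
    K <- floor(2 * n * tr_seconds * highpass_hz)
    if (K >= 1) {
      tt <- seq_len(n) - 0.5
      for (k in seq_len(K)) cols <- c(cols, list(cos(pi * k * tt / n)))
    }
  }
  do.call(cbind, cols)
}

#' Remove linear trend and slow frequency content from a BOLD run
#'
#' Per in-mask voxel, regresses out an intercept, a linear trend (if
#' \code{detrend}) and discrete-cosine regressors spanning all frequencies
#' below \code{highpass_hz}; keeps the residual.  Voxel means are removed;
#' out-of-mask voxels are untouched.
#'
#' @param run a \code{\link{bold_run}}.
#' @param params a \code{\link{preproc_params}}.
#' @return a filtered \code{bold_run}.
#' @export
detrend_highpass <- function(run, params = preproc_params()) {
  .assert(inherits(run, "bold_run"), "run must be a bold_run")
  n <- n_volumes(run)
  nyq <- 1 / (2 * run$tr_seconds)
  .assert(params$highpass_hz < nyq,
          "highpass cutoff (%g Hz) must be below Nyquist (%g Hz)", params$highpass_hz, nyq)
  X <- drift_design(n, run$tr_seconds, params$highpass_hz, params$detrend)
  qx <- qr(X)
  M <- run_matrix(run)                       # t x v
  resid <- M - qr.fitted(qx, M)
  matrix_to_run(resid, run)
}

#' Spatially smooth each volume of a BOLD run
#'
#' Convolves every volume with an isotropic-in-mm Gaussian kernel
#' (\eqn{\sigma = FWHM / \sqrt{8 \ln 2}}, converted to voxels per axis using
#' that axis's voxel size), separably with replicate-edge boundary handling
#' inside the mask bounding box.  Out-of-box voxels are untouched.
#'
#' @inheritParams detrend_highpass
#' @return a smoothed \code{bold_run}.
#' @export
smooth_gaussian <- function(run, params = preproc_params()) {
  .assert(inherits(run, "bold_run"), "run must be a bold_run")
  if (params$fwhm_mm <= 0) return(run)
  d <- dim(run$data)
  bb <- lapply(1:3, function(a) {
    pr <- apply(run$mask, a, any)
    range(which(pr))
  })
  ix <- bb[[1]][1]:bb[[1]][2]; iy <- bb[[2]][1]:bb[[2]][2]; iz <- bb[[3]][1]:bb[[3]][2]
  sub <- run$data[ix, iy, iz, , drop = FALSE]
  ds <- dim(sub)
  sig <- fwhm_to_sigma(params$fwhm_mm) / run$voxel_mm
  # separable convolution applied to all volumes at once, one axis at a time
  for (a in 1:3) {
    S <- smoothing_matrix_1d(ds[a], sig[a])
    perm <- c(a, setdiff(1:4, a))
    sp <- aperm(sub, perm)
    sp <- array(S %*% matrix(sp, ds[a]), dim(sp))
    sub <- aperm(sp, order(perm))
  }
  out <- run$data
  out[ix, iy, iz, ] <- sub
  bold_run(out, run$tr_seconds, run$mask, run$voxel_mm)
}

#' Run both preprocessing steps (filter, then smooth)
#'
#' @inheritParams detrend_highpass
#' @return a preprocessed \code{bold_run}.
#' @export
preprocess_run <- function(run, params = preproc_params()) {
  smooth_gaussian(detrend_highpass(run, params), params)
}
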