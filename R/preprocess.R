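## Canonical temporal-preprocessing order; each operation refuses to run
## twice and refuses to run after a later stage has already been applied.
.pp_steps <- c("drop_initial", "smooth", "bandpass", "regress", "scrub")

assert_step <- function(run, step) {
  applied <- sub(":.*", "", run$history)
  if (step %in% applied)
    stop("step '", step, "' has already been applied to this run")
  later <- .pp_steps[seq_along(.pp_steps) > match(step, .pp_steps)]
  done_later <- intersect(later, applied)
  if (length(done_later))
    stop("cannot apply '", step, "' after '", done_later[1], "'")
  invisible(TRUE)
}

#' Drop initial volumes of a run
#'
#' Removes the first `n` frames so magnetization reaches equilibrium
#' before any frame enters the analysis (10 frames by convention at
#' TR = 2 s).  The caller is responsible for trimming the motion trace in
#' lockstep (see [preprocess_run()]).
#'
#' @param run a [bold_run()].
#' @param n number of initial frames to drop.
#' @return the trimmed run with updated history.
#' @export
drop_initial <- function(run, n = 10L) {
  assert_step(run, "drop_initial")
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  if (n_frames(run) <= n)
    stop("run has ", n_frames(run), " frames; cannot drop ", n)
  if (n > 0L) run$data <- run$data[, -seq_len(n), drop = FALSE]
  run$history <- c(run$history, sprintf("drop_initial:%d", n))
  run
}

## 1D Gaussian convolution matrix with half-sample reflective boundaries;
## the operator is symmetric, so both image mass and constant volumes are
## preserved exactly.
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    pos <- j + (-r:r)
    pos <- ifelse(pos < 1L, 1L - pos, pos)
    pos <- ifelse(pos > n, 2L * n + 1L - pos, pos)
    pos <- pmin(pmax(pos, 1L), n)
    for (t in seq_along(pos)) m[pos[t], j] <- m[pos[t], j] + w[t]
  }
  m
}

#' Spatial Gaussian smoothing
#'
#' Convolves every volume with an isotropic Gaussian kernel of the given
#' full width at half maximum (sigma = FWHM / (2 sqrt(2 ln 2)) per axis,
#' in voxel units), using separable 1D convolutions with reflective
#' boundary handling.
#'
#' @param run a [bold_run()].
#' @param fwhm_mm kernel FWHM in mm (0 for identity).
#' @return the smoothed run.
#' @export
smooth_spatial <- function(run, fwhm_mm = 8) {
  assert_step(run, "smooth")
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  d <- run$grid$dims
  if (fwhm_mm > 0) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / run$grid$voxel_mm
    r <- max(1L, ceiling(4 * sigma))
    w <- exp(-(-r:r)^2 / (2 * sigma^2))
    run$data <- .gauss_smooth_frames(run$data, d[1], d[2], d[3], w / sum(w))
  }
  run$history <- c(run$history, sprintf("smooth:%g", fwhm_mm))
  run
}

## Cache of zero-phase band-pass operator matrices keyed by
## (frames, band, order, sampling rate).
.bp_cache <- new.env(parent = emptyenv())

#' Zero-phase Butterworth band-pass operator
#'
#' Builds the exact linear operator of: remove mean, mirror-pad, filter
#' forward and backward with a Butterworth band-pass of the given order,
#' trim.  Cached, so repeated runs of the same length reuse it.
#'
#' @param n_frames series length.
#' @param low_hz,high_hz pass-band edges in Hz.
#' @param fs sampling rate in Hz (1 / TR).
#' @param order Butterworth section order (2 gives a 4-pole band-pass).
#' @return an n x n matrix applied as `M %*% x`.
#' @export
bandpass_operator <- function(n_frames, low_hz, high_hz, fs, order = 2L) {
  key <- paste(n_frames, low_hz, high_hz, fs, order, sep = "|")
  if (!is.null(.bp_cache[[key]])) return(.bp_cache[[key]])
  ny <- fs / 2
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < ny))
    stop("band must satisfy 0 <= low < high < Nyquist (", ny, " Hz)")
  if (n_frames < 12L) stop("run too short for the band-pass filter")
  bf <- signal::butter(order, c(low_hz, high_hz) / ny, type = "pass")
  pad <- n_frames - 1L
  one_col <- function(x) {
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n_frames] - rev(x[(n_frames - pad):(n_frames - 1)]))
    y <- signal::filtfilt(bf, xp)
    y[(pad + 1):(pad + n_frames)]
  }
  M <- apply(diag(n_frames), 2L, one_col)
  ## compose with mean removal (linear, so the operator stays exact)
  M <- M %*% (diag(n_frames) - matrix(1 / n_frames, n_frames, n_frames))
  .bp_cache[[key]] <- M
  M
}

#' Temporal band-pass filtering
#'
#' Zero-phase (forward-backward) Butterworth band-pass of every voxel
#' series; the DC component is removed.
#'
#' @param run a [bold_run()].
#' @param low_hz,high_hz pass band in Hz.
#' @param order Butterworth section order.
#' @return the filtered run.
#' @export
bandpass <- function(run, low_hz = 0.008, high_hz = 0.08, order = 2L) {
  assert_step(run, "bandpass")
  M <- bandpass_operator(n_frames(run), low_hz, high_hz, 1 / run$tr, order)
  run$data <- run$data %*% t(M)
  run$history <- c(run$history, sprintf("bandpass:%g-%g", low_hz, high_hz))
  run
}

#' Build the nuisance design matrix for a run
#'
#' White-matter mean, CSF mean, global (whole-brain) mean, the six motion
#' parameters and an intercept.
#'
#' @param run a [bold_run()].
#' @param motion a [motion_trace()] aligned to the run's frames.
#' @param global include the global-signal regressor (GSR)?
#' @return numeric frames x p matrix with named columns.
#' @export
nuisance_design <- function(run, motion, global = TRUE) {
  stopifnot(nrow(motion$params) == n_frames(run))
  X <- cbind(intercept = 1,
             wm = colMeans(run$data[run$masks$wm, , drop = FALSE]),
             csf = colMeans(run$data[run$masks$csf, , drop = FALSE]),
             motion$params)
  if (global)
    X <- cbind(X, global = colMeans(run$data[run$masks$brain, , drop = FALSE]))
  X
}

#' Nuisance regression
#'
#' Replaces every voxel series with its least-squares residual against the
#' regressor columns; residuals are orthogonal to the (retained) design.
#' Collinear columns are dropped with a warning.
#'
#' @param run a [bold_run()].
#' @param regressors frames x p numeric matrix with named columns.
#' @return the residualized run.
#' @export
regress_nuisance <- function(run, regressors) {
  assert_step(run, "regress")
  X <- as.matrix(regressors)
  if (nrow(X) != n_frames(run))
    stop("regressor rows (", nrow(X), ") do not match run length (",
         n_frames(run), ")")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    warning("rank-deficient nuisance design; dropped: ",
            paste(dropped, collapse = ", "))
  }
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  run$data <- run$data - (run$data %*% Q) %*% t(Q)
  run$history <- c(run$history, sprintf("regress:p%d", qrx$rank))
  run
}

#' Frame-wise motion and global-signal metrics
#'
#' Fills the derived series of a motion trace: framewise displacement
#' `FD(t) = sum |delta translations| + 50 mm * sum |delta rotations|`
#' (Power-style, 50 mm rotation radius, frame 1 = 0), and global-signal
#' percent change `|GS(t) - GS(t-1)| / mean(GS) * 100` computed over the
#' brain mask.  Intended to run after smoothing and before band-pass
#' filtering, while the signal still carries its mean level.
#'
#' @param run a [bold_run()].
#' @param motion a [motion_trace()] aligned to the run.
#' @param rotation_radius_mm lever arm converting rotations to mm.
#' @return the motion trace with `fd` and `gs_change` filled.
#' @export
compute_frame_metrics <- function(run, motion, rotation_radius_mm = 50) {
  stopifnot(nrow(motion$params) == n_frames(run))
  gs <- colMeans(run$data[run$masks$brain, , drop = FALSE])
  mgs <- mean(gs)
  if (abs(mgs) < 1e-12) stop("mean global signal is zero")
  motion$gs_change <- c(0, abs(diff(gs)) / mgs * 100)
  dp <- abs(diff(motion$params))
  motion$fd <- c(0, rowSums(dp[, 1:3, drop = FALSE]) +
                   rotation_radius_mm * rowSums(dp[, 4:6, drop = FALSE]))
  motion
}

#' Motion scrubbing (volume censoring)
#'
#' Flags every frame at which BOTH the global-signal percent change and
#' the framewise displacement reach their thresholds, removes each
#' flagged frame together with the one before and the two after
#' (windows clipped at run bounds, overlaps merged), and marks the run
#' excluded when more than `exclusion_n` frames were removed.
#'
#' @param run a [bold_run()].
#' @param metrics a [compute_frame_metrics()] trace.
#' @param gs_thresh global-signal change threshold (percent BOLD).
#' @param disp_thresh displacement threshold (mm).
#' @param exclusion_n removed-volume count above which the run is excluded.
#' @return list with the censored `run`, the trimmed `metrics`, and a
#'   `report` (class `scrub_report`) with flagged/removed/kept indices.
#' @export
scrub <- function(run, metrics, gs_thresh = 0.5, disp_thresh = 0.5,
                  exclusion_n = 60L) {
  assert_step(run, "scrub")
  T <- n_frames(run)
  if (is.null(metrics$fd) || is.null(metrics$gs_change))
    stop("metrics not filled; run compute_frame_metrics() first")
  stopifnot(length(metrics$fd) == T)
  flagged <- which(metrics$gs_change >= gs_thresh & metrics$fd >= disp_thresh)
  removed <- integer(0)
  for (f in flagged) removed <- c(removed, max(1L, f - 1L):min(T, f + 2L))
  removed <- sort(unique(removed))
  kept <- setdiff(seq_len(T), removed)
  if (length(removed)) run$data <- run$data[, kept, drop = FALSE]
  run$history <- c(run$history, sprintf("scrub:%d", length(removed)))
  metrics$params <- metrics$params[kept, , drop = FALSE]
  metrics$fd <- metrics$fd[kept]
  metrics$gs_change <- metrics$gs_change[kept]
  report <- structure(list(flagged = flagged, removed = removed, kept = kept,
                           n_removed = length(removed),
                           excluded = length(removed) > exclusion_n),
                      class = "scrub_report")
  list(run = run, metrics = metrics, report = report)
}

#' @export
print.scrub_report <- function(x, ...) {
  cat(sprintf("<scrub_report: %d flagged, %d removed%s>\n",
              length(x$flagged), x$n_removed,
              if (x$excluded) ", RUN EXCLUDED" else ""))
  invisible(x)
}

#' Full temporal preprocessing of one run
#'
#' Applies the canonical chain: initial-volume drop, spatial smoothing,
#' frame-metric computation, band-pass filtering, nuisance regression
#' (WM/CSF/global/6 motion parameters; global optional), and motion
#' scrubbing.  The motion trace is trimmed in lockstep with the data.
#'
#' @param run a [bold_run()].
#' @param motion the run's [motion_trace()].
#' @param drop_n initial frames to drop.
#' @param fwhm_mm smoothing kernel FWHM.
#' @param low_hz,high_hz band-pass edges.
#' @param gsr include global-signal regression?
#' @param gs_thresh,disp_thresh,exclusion_n scrubbing parameters.
#' @return list with `run`, `metrics`, `report` (scrubbing) and `design`.
#' @export
preprocess_run <- function(run, motion, drop_n = 10L, fwhm_mm = 8,
                           low_hz = 0.008, high_hz = 0.08, gsr = TRUE,
                           gs_thresh = 0.5, disp_thresh = 0.5,
                           exclusion_n = 60L) {
  run <- drop_initial(run, drop_n)
  if (drop_n > 0L) motion$params <- motion$params[-seq_len(drop_n), , drop = FALSE]
  run <- smooth_spatial(run, fwhm_mm)
  motion <- compute_frame_metrics(run, motion)
  ## nuisance series are extracted from (and motion regressors filtered
  ## with) the band-passed data, so the regression removes exactly the
  ## frequency content the voxel series still carry.  Because the mean
  ## of filtered data is the filtered mean, the design can be built
  ## before the (large) filtering matrix product, and the band-pass and
  ## regression collapse into a single frames x frames operator.
  T <- n_frames(run)
  M <- bandpass_operator(T, low_hz, high_hz, 1 / run$tr)
  gs <- function(vox) as.numeric(M %*% colMeans(run$data[vox, , drop = FALSE]))
  X <- cbind(intercept = 1, wm = gs(run$masks$wm), csf = gs(run$masks$csf),
             M %*% motion$params)
  if (gsr) X <- cbind(X, global = gs(run$masks$brain))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    warning("rank-deficient nuisance design; dropped: ",
            paste(dropped, collapse = ", "))
  }
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  op <- t(M) - (t(M) %*% Q) %*% t(Q)     # band-pass then residualize
  run$data <- run$data %*% op
  run$history <- c(run$history, sprintf("bandpass:%g-%g", low_hz, high_hz),
                   sprintf("regress:p%d", qrx$rank))
  out <- scrub(run, motion, gs_thresh, disp_thresh, exclusion_n)
  out$design <- X
  out
}
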