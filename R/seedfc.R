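#' Seed specification
#'
#' @param center_mm sphere centre in world mm (default: posterior
#'   cingulate, MNI 0, -53, 26).
#' @param radius_mm sphere radius in mm.
#' @return list of class `seed_spec`.
#' @export
seed_spec <- function(center_mm = c(0, -53, 26), radius_mm = 8) {
  stopifnot(radius_mm > 0, length(center_mm) == 3L)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm)), class = "seed_spec")
}

#' Mean time course of a spherical seed
#'
#' Unweighted mean over all in-brain voxels whose centres lie within the
#' seed radius of the seed centre.
#'
#' @param run a preprocessed [bold_run()].
#' @param seed a [seed_spec()].
#' @return numeric vector of length `n_frames(run)`.
#' @export
extract_seed_timecourse <- function(run, seed) {
  vox <- intersect(sphere_voxels(run$grid, seed$center_mm, seed$radius_mm),
                   run$masks$brain)
  if (!length(vox)) stop("seed sphere does not intersect the brain mask")
  colMeans(run$data[vox, , drop = FALSE])
}

#' Voxelwise correlation with a seed time course
#'
#' Pearson correlation of every in-mask voxel series with the seed
#' series.  Constant voxel series yield r = 0; their count is recorded in
#' the `n_constant` attribute.
#'
#' @param run a preprocessed [bold_run()].
#' @param seed_tc numeric seed time course.
#' @param mask voxel indices to correlate (default: the brain mask).
#' @return numeric vector of correlations named by `mask`, with attribute
#'   `n_constant`.
#' @export
voxelwise_correlation <- function(run, seed_tc, mask = run$masks$brain) {
  T <- n_frames(run)
  if (T < 3L) stop("fewer than 3 surviving frames")
  stopifnot(length(seed_tc) == T)
  s <- seed_tc - mean(seed_tc)
  ns <- sqrt(sum(s^2))
  if (ns == 0) stop("seed time course is constant")
  x <- run$data[mask, , drop = FALSE]
  x <- x - rowMeans(x)
  nx <- sqrt(rowSums(x^2))
  const <- nx == 0
  nx[const] <- 1
  r <- as.numeric((x %*% s) / (nx * ns))
  r[const] <- 0
  if (any(const)) attr(r, "n_constant") <- sum(const)
  r
}

#' Fisher-Z transform
#'
#' `z = atanh(r)`; correlations at +-1 are clipped to `1 - 1e-7` in
#' magnitude (with a warning) so the transform stays finite.
#'
#' @param r correlations in `[-1, 1]`.
#' @return Fisher-Z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1")
  if (any(abs(r) >= 1, na.rm = TRUE))
    warning("correlations at |r| = 1 clipped to 1 - 1e-7")
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Benjamini-Yekutieli / Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure: reject the `i` smallest p-values for the largest
#' `i` with `p_(i) <= i q / (m c(m))`, where `c(m) = sum_{j<=m} 1/j`
#' for the Benjamini-Yekutieli variant (valid under arbitrary
#' dependence) and `c(m) = 1` for Benjamini-Hochberg.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param q target false-discovery rate.
#' @param method `"BY"` (default) or `"BH"`.
#' @return logical rejection mask aligned with `p_values`.
#' @export
fdr_correct <- function(p_values, q = 0.05, method = c("BY", "BH")) {
  method <- match.arg(method)
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  p.adjust(p_values, method = method) <= q
}

#' Group significance map for one state
#'
#' One-sample t-test of the subjects' Fisher-Z values against zero at
#' every voxel, two-tailed p, FDR correction across the mask.  The
#' state's network map (used for the union mask downstream) is the set of
#' significant voxels with positive t; significant negative voxels are
#' reported separately.
#'
#' @param z_maps numeric matrix voxels x subjects of Fisher-Z values
#'   (rows aligned with `mask`).
#' @param mask voxel indices the rows refer to.
#' @param state state label.
#' @param q FDR level.
#' @param method FDR variant passed to [fdr_correct()].
#' @return an object of class `group_state_map` with `t`, `p`,
#'   `significant` (positive-t mask voxels), `significant_negative`,
#'   `mask`, `state`, `n`.
#' @export
group_significance <- function(z_maps, mask, state = "R1", q = 0.05,
                               method = "BY") {
  z_maps <- as.matrix(z_maps)
  n <- ncol(z_maps)
  if (n < 2L) stop("need at least 2 subjects")
  stopifnot(nrow(z_maps) == length(mask))
  m <- rowMeans(z_maps)
  s <- sqrt(rowSums((z_maps - m)^2) / (n - 1))
  zero_var <- s == 0
  s[zero_var] <- 1
  tt <- m / (s / sqrt(n))
  p <- 2 * pt(abs(tt), df = n - 1, lower.tail = FALSE)
  if (any(zero_var)) {
    warning(sum(zero_var), " voxel(s) with zero variance across subjects")
    p[zero_var] <- ifelse(m[zero_var] != 0, 0, 1)
    tt[zero_var] <- ifelse(m[zero_var] != 0, Inf * sign(m[zero_var]), 0)
  }
  rej <- fdr_correct(p, q = q, method = method)
  structure(list(state = state, t = tt, p = p, mask = mask, n = n,
                 q = q, method = method,
                 significant = mask[rej & tt > 0],
                 significant_negative = mask[rej & tt < 0]),
            class = "group_state_map")
}

#' @export
print.group_state_map <- function(x, ...) {
  cat(sprintf("<group_state_map %s: n=%d, %d sig+ / %d sig- of %d voxels (FDR %s q=%g)>\n",
              x$state, x$n, length(x$significant),
              length(x$significant_negative), length(x$mask), x$method, x$q))
  invisible(x)
}

#' Per-subject seed connectivity map
#'
#' Convenience wrapper: seed time course, voxelwise correlation over the
#' brain mask, Fisher-Z transform.
#'
#' @param run a preprocessed [bold_run()].
#' @param seed a [seed_spec()].
#' @return list with `z` (named by mask voxel), `mask`, `subject`, `state`.
#' @export
connectivity_map <- function(run, seed = seed_spec()) {
  stc <- extract_seed_timecourse(run, seed)
  r <- voxelwise_correlation(run, stc)
  list(z = fisher_z(r), mask = run$masks$brain,
       subject = run$subject, state = run$state)
}
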