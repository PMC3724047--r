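#' BOLD run container
#'
#' One subject-by-state 4D time series, stored as a voxels x time matrix on
#' the scenario grid, together with grid geometry, mask references, the
#' repetition time and an append-only history of applied preprocessing
#' steps.
#'
#' @param data numeric matrix, voxels x frames (full-grid rows in linear
#'   voxel order).
#' @param grid a [make_grid()] object.
#' @param tr repetition time in seconds.
#' @param subject subject identifier.
#' @param state state label (`R1`, `T1`, `T2`, `R2`).
#' @param masks list of integer voxel-index vectors `brain`, `wm`, `csf`.
#' @return an object of class `bold_run`.
#' @export
bold_run <- function(data, grid, tr, subject, state, masks) {
  stopifnot(is.matrix(data), nrow(data) == n_voxels(grid), ncol(data) >= 1L)
  structure(list(data = data, grid = grid, tr = as.numeric(tr),
                 subject = subject, state = state, masks = masks,
                 history = character(0)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run %s/%s: %d voxels x %d frames, TR %gs>\n",
              x$subject, x$state, nrow(x$data), ncol(x$data), x$tr))
  if (length(x$history)) cat("  history:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of frames in a run
#' @param run a [bold_run()].
#' @return integer frame count.
#' @export
n_frames <- function(run) ncol(run$data)

#' Motion trace container
#'
#' Six rigid-body parameters per frame (3 translations in mm, 3 rotations
#' in radians); the derived framewise displacement and global-signal
#' percent-change series are filled by [compute_frame_metrics()].
#'
#' @param params numeric frames x 6 matrix.
#' @return an object of class `motion_trace`.
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6L)
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(list(params = params, fd = NULL, gs_change = NULL),
            class = "motion_trace")
}

## Stationary AR(1) filter applied row-wise to standardized innovations.
## Same coefficient for every channel, so lag-zero cross-correlations of
## the innovations are preserved exactly in the stationary output.  The
## recursion x_t = phi x_{t-1} + sqrt(1 - phi^2) e_t (x_1 = e_1) is a
## lower-triangular Toeplitz operator, cached per (length, phi) so wide
## matrices go through one BLAS call.
.ar1_cache <- new.env(parent = emptyenv())

ar1_operator <- function(n, phi) {
  key <- paste(n, phi, sep = "|")
  if (!is.null(.ar1_cache[[key]])) return(.ar1_cache[[key]])
  i <- matrix(seq_len(n), n, n)
  d <- i - t(i)
  A <- ifelse(d >= 0, phi^d, 0) * sqrt(1 - phi^2)
  A[, 1] <- phi^(seq_len(n) - 1)
  .ar1_cache[[key]] <- A
  A
}

ar1_filter <- function(innov, phi) {
  if (phi == 0) return(innov)
  innov %*% t(ar1_operator(ncol(innov), phi))
}

## Draw one subject's block-level connectivity deviations (Fisher-Z scale):
## a common offset shared by all states of a block plus independent
## state-specific offsets.
subject_deviations <- function(scenario) {
  blocks <- default_block_targets()$block
  common <- setNames(rnorm(length(blocks), 0, scenario$subject_sd_common), blocks)
  state <- matrix(rnorm(length(blocks) * 4L, 0, scenario$subject_sd),
                  length(blocks), 4L, dimnames = list(blocks, dmn_states()))
  list(common = common, state = state)
}

## Subject-specific latent correlation matrix for one state: group value
## plus the subject's block deviation, applied on the Fisher-Z scale and
## mapped back through tanh (so perturbed correlations stay in (-1, 1)).
## Eigenvalues are floored if the perturbation breaks positive
## semi-definiteness.
subject_state_matrix <- function(scenario, dev, state) {
  regs <- signal_regions(scenario)
  systems <- vapply(regs, `[[`, "", "system")
  key <- outer(systems, systems, pair_block)
  m <- scenario$state_covariance[[state]]
  z <- atanh(pmin(pmax(m, -1 + 1e-7), 1 - 1e-7))
  kv <- as.vector(key)
  shift <- matrix(dev$common[kv] + dev$state[cbind(kv, rep(state, length(kv)))],
                  nrow(m), ncol(m))
  out <- tanh(z + shift)
  diag(out) <- 1
  if (!is_psd(out, tol = 1e-10)) out <- repair_correlation(out, floor = 1e-6)
  out
}

## Latent block-level connectivity value (Pearson r) for one subject,
## block and state: all pairs of a block share it by construction.
latent_block_value <- function(scenario, dev, block, state) {
  g <- scenario$block_targets[block, state]
  tanh(atanh(g) + dev$common[block] + dev$state[block, state])
}

## Poisson-placed spike frames with a minimum separation.
draw_spike_frames <- function(n_frames, rate, min_gap) {
  n <- rpois(1L, rate)
  if (n == 0L) return(integer(0))
  frames <- integer(0)
  candidates <- seq_len(n_frames)
  for (i in seq_len(n)) {
    ok <- candidates[vapply(candidates, function(f)
      !length(frames) || min(abs(frames - f)) >= min_gap, TRUE)]
    if (!length(ok)) break
    frames <- c(frames, if (length(ok) == 1L) ok else sample(ok, 1L))
  }
  sort(frames)
}

## Simulate one run's voxel data and motion trace for a given subject
## deviation set.  Returns list(run, motion, latents, spikes).
simulate_run <- function(scenario, dev, state, subject_id, seed,
                         mover = TRUE) {
  set.seed(seed)
  grid <- scenario$grid
  V <- n_voxels(grid)
  T <- scenario$n_volumes
  nm <- scenario$noise_model
  regs <- signal_regions(scenario)
  k <- length(regs)

  ## latent signals: correlated innovations -> AR(1); after the k region
  ## channels come the background-network channels (equicorrelated at
  ## bg_rho, independent of the regions) and the WM, CSF and global
  ## physiological components (independent).
  bg_regions <- Filter(function(r) r$system == "background",
                       scenario$region_layout)
  nb <- length(bg_regions)
  sigma <- subject_state_matrix(scenario, dev, state)
  innov <- matrix(rnorm((k + nb + 4L) * T), k + nb + 4L, T)
  innov[1:k, ] <- psd_factor(sigma) %*% innov[1:k, , drop = FALSE]
  if (nb > 0L) {
    sig_bg <- matrix(nm$bg_rho, nb, nb); diag(sig_bg) <- 1
    innov[k + 1:nb, ] <- psd_factor(sig_bg) %*% innov[k + 1:nb, , drop = FALSE]
  }
  lat <- ar1_filter(innov, nm$ar1)
  latents <- lat[1:k, , drop = FALSE]
  bg_lat <- lat[k + seq_len(nb), , drop = FALSE]
  wm_sig <- lat[k + nb + 1L, ]; csf_sig <- lat[k + nb + 2L, ]
  physio <- lat[k + nb + 3L, ]
  gfield <- lat[k + nb + 4L, ]

  ## voxel-private AR(1) noise, slow out-of-band drift (one 0.003 Hz
  ## component with random per-voxel amplitude and phase, two rank-one
  ## terms), brain-wide physiological component and baseline; only brain
  ## voxels carry signal, the rest of the grid stays zero.
  brain <- scenario$masks$brain
  Vb <- length(brain)
  base <- ar1_filter(matrix(rnorm(Vb * T), Vb, T), nm$ar1) * nm$sd
  if (nm$drift_amp > 0) {
    tt <- 2 * pi * 0.003 * scenario$tr * (seq_len(T) - 1)
    ab <- matrix(rnorm(2L * Vb, 0, nm$drift_amp / sqrt(2)), Vb, 2L)
    base <- base + ab %*% rbind(sin(tt), cos(tt))
  }
  base <- base + tcrossprod(rep(nm$physio_amp, Vb), physio) + nm$baseline
  data <- matrix(0, V, T)
  data[brain, ] <- base

  ## diffuse non-DMN field: widespread coherent activity away from the
  ## planted systems (dominates the global mean alongside the
  ## physiological component)
  if (nm$gfield_amp > 0 && length(scenario$masks$field))
    data[scenario$masks$field, ] <- data[scenario$masks$field, ] +
      tcrossprod(rep(nm$gfield_amp, length(scenario$masks$field)), gfield)

  amp_r <- nm$region_amp %||% 1
  for (r in regs) data[r$voxels, ] <- data[r$voxels, ] +
    rep(amp_r, length(r$voxels)) %o% latents[r$latent, ]
  for (r in bg_regions) data[r$voxels, ] <- data[r$voxels, ] +
    rep(nm$bg_amp, length(r$voxels)) %o% bg_lat[r$latent, ]
  ## WM/CSF compartments: their own nuisance signal plus an elevated
  ## physiological loading (the reason such compartment regressors clean
  ## shared physiological fluctuations in real pipelines)
  extra_phys <- (nm$nuisance_physio %||% nm$physio_amp) - nm$physio_amp
  data[scenario$masks$wm, ] <- data[scenario$masks$wm, ] +
    rep(nm$nuisance_amp, length(scenario$masks$wm)) %o% wm_sig +
    rep(extra_phys, length(scenario$masks$wm)) %o% physio
  data[scenario$masks$csf, ] <- data[scenario$masks$csf, ] +
    rep(nm$nuisance_amp, length(scenario$masks$csf)) %o% csf_sig +
    rep(extra_phys, length(scenario$masks$csf)) %o% physio

  ## motion: slow random walk plus spikes that exceed BOTH scrubbing
  ## thresholds at the spike frame only (the translation steps and stays;
  ## the image takes a one-frame global intensity impulse).
  mot <- scenario$motion
  params <- apply(matrix(rnorm(T * 6L, 0, mot$walk_sd), T, 6L), 2L, cumsum)
  params[, 4:6] <- params[, 4:6] / 50
  rate <- scenario$motion_spike_rate[[state]] * (if (mover) 1 else 0)
  spikes <- draw_spike_frames(T, rate, mot$spike_gap)
  for (f in spikes) {
    if (f > 1L) params[f:T, 1L] <- params[f:T, 1L] + mot$spike_translation_mm
    data[brain, f] <- data[brain, f] +
      nm$baseline * mot$spike_gs_pct / 100 + rnorm(length(brain), 0, 2 * nm$sd)
  }

  list(run = bold_run(data, grid, scenario$tr, subject_id, state,
                      scenario$masks),
       motion = motion_trace(params),
       latents = latents, spikes = spikes)
}

#' Simulate all four runs of one subject
#'
#' Draws the subject's block-level connectivity deviations from the
#' scenario's heterogeneity model, then generates the four state runs
#' (voxel data plus motion traces) from the subject's perturbed latent
#' correlation matrices.  Fully deterministic given `(scenario,
#' subject_index, base_seed)`.
#'
#' @param scenario a [make_scenario()] object.
#' @param subject_index subject number in `1:n_subjects`.
#' @param base_seed integer seed of the cohort draw (defaults to the
#'   scenario seed).
#' @return list with elements `runs` and `motion` (named by state),
#'   `deviations`, `spikes`, and `subject`.
#' @export
simulate_subject <- function(scenario, subject_index,
                             base_seed = scenario$seed) {
  if (is.null(base_seed)) stop("an explicit RNG seed is required")
  stopifnot(subject_index >= 1L, subject_index <= scenario$n_subjects)
  subject_id <- sprintf("sub%02d", subject_index)
  set.seed(substream_seed(base_seed, subject_index, 0L))
  dev <- subject_deviations(scenario)
  ## a subject is a "mover" (subject to the configured spike rates) with
  ## probability mover_frac; motion-heavy cohorts are typically bimodal,
  ## with a few severely moving subjects and the rest clean
  mover <- runif(1) < scenario$motion$mover_frac
  runs <- list(); motion <- list(); spikes <- list()
  for (si in seq_along(scenario$states)) {
    st <- scenario$states[si]
    sim <- simulate_run(scenario, dev, st, subject_id,
                        substream_seed(base_seed, subject_index, si),
                        mover = mover)
    runs[[st]] <- sim$run
    motion[[st]] <- sim$motion
    spikes[[st]] <- sim$spikes
  }
  list(subject = subject_id, runs = runs, motion = motion,
       deviations = dev, spikes = spikes)
}

#' Latent (generator-truth) dFC table of a cohort
#'
#' Per-subject change of the latent block-level connectivity from R1 to
#' each task state, for the stable-decreasing and stable-increasing
#' system pairs — the quantity the behavioural model couples to.
#'
#' @param scenario a [make_scenario()] object.
#' @param deviations list of per-subject deviation draws.
#' @return data.frame with columns `subject`, `pair`, `state`, `dfc`.
#' @export
latent_dfc_table <- function(scenario, deviations) {
  out <- expand.grid(subject = seq_along(deviations),
                     pair = c("stable_decreasing", "stable_increasing"),
                     state = c("T1", "T2"), stringsAsFactors = FALSE)
  out$dfc <- mapply(function(s, p, st) {
    dev <- deviations[[s]]
    latent_block_value(scenario, dev, p, st) -
      latent_block_value(scenario, dev, p, "R1")
  }, out$subject, out$pair, out$state)
  out
}

#' Simulate behavioural records coupled to latent connectivity change
#'
#' Reaction time at each task state is coupled to that subject's latent
#' dFC(stable, decreasing) and accuracy to dFC(stable, increasing): each
#' measure is `state mean + sd * (rho * z + sqrt(1 - rho^2) * noise)`
#' where `z` is the standardized latent dFC, so the population correlation
#' equals the configured coupling.  Accuracy is clipped to `[0, 100]`.
#'
#' @param scenario a [make_scenario()] object.
#' @param latent_dfc data.frame from [latent_dfc_table()] (one value per
#'   subject per pair per task state).
#' @param seed RNG seed for the behavioural noise.
#' @return data.frame with columns `subject`, `state`, `rt_ms`,
#'   `accuracy_pct`.
#' @export
simulate_behavior <- function(scenario, latent_dfc, seed = scenario$seed) {
  set.seed(substream_seed(seed, 999L))
  subjects <- sort(unique(latent_dfc$subject))
  n <- length(subjects)
  beh <- scenario$behavior; coup <- scenario$behavior_coupling
  pull <- function(pair, st) {
    x <- latent_dfc$dfc[latent_dfc$pair == pair & latent_dfc$state == st]
    if (length(x) != n) stop("latent dFC table incomplete for ", pair, "/", st)
    x[order(latent_dfc$subject[latent_dfc$pair == pair &
                                 latent_dfc$state == st])]
  }
  out <- NULL
  for (st in c("T1", "T2")) {
    zd <- as.numeric(scale(pull("stable_decreasing", st)))
    zi <- as.numeric(scale(pull("stable_increasing", st)))
    rho_rt <- coup$rt[[st]]; rho_ac <- coup$accuracy[[st]]
    rt <- beh$rt_mean[[st]] + beh$rt_sd[[st]] *
      (rho_rt * zd + sqrt(1 - rho_rt^2) * rnorm(n))
    rt <- pmax(rt, 1)
    acc <- beh$acc_mean[[st]] + beh$acc_sd[[st]] *
      (rho_ac * zi + sqrt(1 - rho_ac^2) * rnorm(n))
    acc <- pmin(pmax(acc, 0), 100)
    out <- rbind(out, data.frame(subject = sprintf("sub%02d", subjects),
                                 state = st, rt_ms = rt, accuracy_pct = acc,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Simulate a cohort's metadata (deviations, latent dFC, behaviour)
#'
#' Voxel data is large, so a cohort object stores the per-subject
#' deviation draws and behavioural table; runs are regenerated on demand
#' with [simulate_subject()] (deterministic for a given seed).
#'
#' @param scenario a [make_scenario()] object.
#' @param seed cohort seed (defaults to the scenario seed).
#' @return an object of class `synth_cohort`.
#' @export
simulate_cohort <- function(scenario, seed = scenario$seed) {
  deviations <- lapply(seq_len(scenario$n_subjects), function(i) {
    set.seed(substream_seed(seed, i, 0L))
    subject_deviations(scenario)
  })
  ldfc <- latent_dfc_table(scenario, deviations)
  behavior <- simulate_behavior(scenario, ldfc, seed)
  structure(list(scenario = scenario, seed = seed, deviations = deviations,
                 latent_dfc = ldfc, behavior = behavior),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort: %d subjects, seed %d>\n",
              x$scenario$n_subjects, x$seed))
  invisible(x)
}

#' Region-level fast path: simulate mean region time courses directly
#'
#' Generates the latent region signals of one subject-state run plus the
#' region-averaged private noise (white-noise SD divided by the square
#' root of the region size), skipping the voxel stage.  Used for
#' experiments that only need system-level connectivity, where the voxel
#' pipeline's region means are well approximated by this construction.
#'
#' @param scenario a [make_scenario()] object.
#' @param dev one subject's deviation draw.
#' @param state state label.
#' @param seed RNG seed.
#' @return matrix regions x frames of region mean time courses.
#' @export
simulate_region_timecourses <- function(scenario, dev, state, seed) {
  set.seed(seed)
  regs <- signal_regions(scenario)
  k <- length(regs)
  T <- scenario$n_volumes
  nm <- scenario$noise_model
  sigma <- subject_state_matrix(scenario, dev, state)
  innov <- psd_factor(sigma) %*% matrix(rnorm(k * T), k, T)
  lat <- ar1_filter(innov, nm$ar1)
  vsize <- vapply(regs, function(r) length(r$voxels), 1L)
  noise <- ar1_filter(matrix(rnorm(k * T), k, T), nm$ar1) *
    (nm$sd / sqrt(vsize))
  tc <- (nm$region_amp %||% 1) * lat + noise
  rownames(tc) <- vapply(regs, `[[`, "", "name")
  tc
}
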