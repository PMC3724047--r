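#' Experimental states of the four-stage design
#'
#' Pre-task rest (R1), relaxed-pace task (T1), speeded task (T2) and
#' post-task rest (R2), in run order.
#' @export
dmn_states <- function() c("R1", "T1", "T2", "R2")

#' Planted region
#'
#' A named set of voxels driven by one latent signal, tagged with the
#' system it belongs to: `stable` regions keep their seed connectivity
#' across states, `decreasing` regions lose it during task states,
#' `increasing` regions gain it, and `background` carries noise only.
#'
#' @param name region label.
#' @param system one of `"stable"`, `"decreasing"`, `"increasing"`,
#'   `"background"`.
#' @param voxels integer vector of linear voxel indices (non-empty).
#' @param latent index of the latent-signal row driving the region.
#' @return an object of class `planted_region`.
#' @export
planted_region <- function(name, system, voxels, latent) {
  system <- match.arg(system,
                      c("stable", "decreasing", "increasing", "background"))
  voxels <- sort(unique(as.integer(voxels)))
  if (length(voxels) < 1L) stop("planted region '", name, "' has no voxels")
  structure(list(name = as.character(name), system = system,
                 voxels = voxels, latent = as.integer(latent)),
            class = "planted_region")
}

#' Default planted-region layout
#'
#' Fourteen block-shaped regions on the default grid, mirroring the
#' three-system organisation recovered in four-state DMN experiments: six
#' stable DMN regions (the seed-bearing posterior-cingulate block plus
#' five others), four regions whose seed connectivity decreases during
#' task states (precuneus/angular/vermis-like), and four whose
#' connectivity increases (salience-network-like).  Region names carry the
#' conventional anatomical shorthand purely as labels; the layout is
#' schematic, with blocks separated so that spatial smoothing does not mix
#' neighbouring systems.
#'
#' @param grid the scenario grid (must be the default 24 x 28 x 24 grid).
#' @return list of [planted_region()] objects, seed-bearing region first.
#' @export
default_region_layout <- function(grid) {
  stopifnot(identical(grid$dims, c(24L, 36L, 24L)))
  blk <- function(name, system, corner, size = 4L) {
    planted_region(name, system, block_voxels(grid, corner, size), NA_integer_)
  }
  ## systems are segregated by x-lane (cross-system gaps of 5+ voxels,
  ## outside the reach of the 8 mm kernel, so smoothing never mixes
  ## systems) and spread in a checkerboard within each lane (same-class
  ## gaps of 10+ voxels, so detected clusters cannot merge)
  layout <- list(
    blk("PCC",    "stable",     c(11L, 12L, 10L), 5L),
    blk("MPFC",   "stable",     c(11L, 3L,  3L)),
    blk("IPL_L",  "stable",     c(11L, 3L,  17L)),
    blk("IPL_R",  "stable",     c(11L, 21L, 3L)),
    blk("LTC_L",  "stable",     c(11L, 21L, 17L)),
    blk("LTC_R",  "stable",     c(11L, 30L, 10L)),
    blk("PCS",    "decreasing", c(2L,  3L,  3L)),
    blk("ANG_L",  "decreasing", c(2L,  3L,  17L)),
    blk("ANG_R",  "decreasing", c(2L,  21L, 3L)),
    blk("VER",    "decreasing", c(2L,  21L, 17L)),
    blk("IIFC_L", "increasing", c(20L, 3L,  3L)),
    blk("IIFC_R", "increasing", c(20L, 3L,  17L)),
    blk("ACC",    "increasing", c(20L, 21L, 3L)),
    blk("MCC",    "increasing", c(20L, 21L, 17L))
  )
  for (i in seq_along(layout)) layout[[i]]$latent <- i

  ## background networks: the rest of the cortex is not silent — blocks of
  ## mutually correlated signal unrelated to the seeded systems occupy the
  ## free lattice slots (also what keeps global-signal regression from
  ## projecting DMN structure out of the data, as in real brains where the
  ## global mean is dominated by non-DMN fluctuations)
  slots <- as.matrix(expand.grid(x = c(2L, 11L, 20L), y = c(3L, 12L, 21L, 30L),
                                 z = c(3L, 10L, 17L)))
  used <- rbind(do.call(rbind, lapply(layout, function(r)
    index_to_ijk(grid, r$voxels[1]))), c(2L, 12L, 3L), c(20L, 12L, 3L))
  free <- slots[!apply(slots, 1L, function(s)
    any(rowSums(abs(sweep(used, 2L, s, "-"))) == 0)), , drop = FALSE]
  for (b in seq_len(nrow(free))) {
    ## 2^3 patches centred in their slots: >= 4 voxels from any planted
    ## region, outside the reach of the 8 mm smoothing kernel
    reg <- blk(sprintf("bg%02d", b), "background", free[b, ] + 1L, 2L)
    reg$latent <- b
    layout[[length(layout) + 1L]] <- reg
  }
  layout
}

#' Default system-level correlation targets across states
#'
#' The between-system means are the group values a four-state DMN
#' experiment reports for stable-decreasing and stable-increasing mean
#' functional connectivity over (R1, T1, T2, R2); within-system and
#' decreasing-increasing levels complete the block structure with a
#' plausible profile (stable regions tightly coupled throughout, the
#' changing systems desynchronizing/synchronizing in step with their
#' coupling to the stable core).
#'
#' @return a data.frame with one row per region-pair block and one column
#'   per state, values on the Pearson r scale.
#' @export
default_block_targets <- function() {
  out <- data.frame(
    block = c("stable", "decreasing", "increasing",
              "stable_decreasing", "stable_increasing",
              "decreasing_increasing"),
    R1 = c(0.60, 0.46, 0.12, 0.43, 0.05, 0.02),
    T1 = c(0.60, 0.36, 0.32, 0.35, 0.30, 0.10),
    T2 = c(0.60, 0.26, 0.36, 0.24, 0.34, 0.12),
    R2 = c(0.60, 0.46, 0.10, 0.45, 0.03, 0.02),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$block
  out
}

## Block key for a pair of systems ("stable"+"decreasing" ->
## "stable_decreasing" etc.); within-system pairs map to the system name.
pair_block <- function(sys_a, sys_b) {
  lev <- c("stable", "decreasing", "increasing")
  ia <- match(sys_a, lev); ib <- match(sys_b, lev)
  ifelse(ia == ib, lev[ia],
         paste(lev[pmin(ia, ib)], lev[pmax(ia, ib)], sep = "_"))
}

#' Expand block correlation targets into full latent correlation matrices
#'
#' The between-system pair values are not uniform: the seed-bearing
#' stable region's coupling to the changing systems modulates more
#' strongly across states than the other stable regions' (the pattern
#' seen in seed-based four-state experiments, where the posterior
#' cingulate's coupling to increasing regions starts near zero or
#' negative at rest and rises sharply during task, while e.g. parietal
#' stable regions change less).  Each pair trajectory is the block mean
#' trajectory with its state modulation scaled by `seed_gain` for seed
#' pairs and by `(n_stable - seed_gain) / (n_stable - 1)` for the
#' remaining stable regions, so the block average over all pairs equals
#' the printed system-level trajectory exactly.
#'
#' @param layout list of [planted_region()] (background regions excluded).
#' @param blocks data.frame as returned by [default_block_targets()].
#' @param seed_gain modulation amplification of the seed region's pairs
#'   with the changing systems.
#' @param seed_name name of the seed-bearing stable region.
#' @return named list of one correlation matrix per state, with one
#'   row/column per region in `layout` order.
#' @export
expand_block_correlations <- function(layout, blocks = default_block_targets(),
                                      seed_gain = 2.5, seed_name = "PCC") {
  systems <- vapply(layout, `[[`, "", "system")
  nms <- vapply(layout, `[[`, "", "name")
  n <- length(layout)
  key <- outer(systems, systems, pair_block)
  n_stable <- sum(systems == "stable")
  gain <- matrix(1, n, n)
  if (seed_gain != 1 && seed_name %in% nms && n_stable > 1L) {
    oth_gain <- (n_stable - seed_gain) / (n_stable - 1)
    is_seed <- nms == seed_name
    is_chg <- systems %in% c("decreasing", "increasing")
    is_oth_stable <- systems == "stable" & !is_seed
    gain[is_seed, is_chg] <- seed_gain
    gain[is_chg, is_seed] <- seed_gain
    gain[is_oth_stable, is_chg] <- oth_gain
    gain[is_chg, is_oth_stable] <- oth_gain
  }
  block_mean <- rowMeans(as.matrix(blocks[, dmn_states()]))
  out <- lapply(dmn_states(), function(st) {
    base <- matrix(blocks[key, st], n, n)
    centre <- matrix(block_mean[key], n, n)
    m <- centre + gain * (base - centre)
    diag(m) <- 1
    dimnames(m) <- list(nms, nms)
    m
  })
  names(out) <- dmn_states()
  out
}

#' Build and validate a synthetic-cohort scenario
#'
#' A scenario fixes everything the generator needs: the grid, the planted
#' region layout, one latent inter-region correlation matrix per state,
#' the between-subject heterogeneity of those correlations, the noise
#' model, the motion-spike model and the behaviour coupling.  With no
#' arguments it returns the packaged default scenario calibrated to the
#' group means, subject SEMs and brain-behavior effect sizes of the
#' four-state DMN study design (19 subjects, 150 volumes at TR = 2 s).
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param voxel_mm voxel size in mm.
#' @param n_subjects number of subjects in a cohort.
#' @param n_volumes frames per run (>= 11 so the initial-volume drop
#'   leaves data).
#' @param tr repetition time in seconds.
#' @param region_layout list of [planted_region()]; `NULL` for the default
#'   layout (requires the default grid).
#' @param state_covariance named list of latent correlation matrices, one
#'   per state in [dmn_states()]; `NULL` expands `block_targets`.
#' @param block_targets block-level correlation table used when
#'   `state_covariance` is `NULL`.
#' @param subject_sd between-subject SD (Fisher-Z scale) of the
#'   state-specific part of each planted block correlation.
#' @param subject_sd_common between-subject SD (Fisher-Z scale) of the
#'   subject offset shared by all four states of a block (a subject with
#'   tight coupling is tight in every state); the study design only pins
#'   the total between-subject spread, so the split is a calibration
#'   choice.
#' @param noise_model list with elements `ar1` (AR(1) coefficient of all
#'   stochastic signals), `sd` (voxel-private white-noise SD relative to
#'   unit-variance latents), `drift_amp` (amplitude of a slow
#'   out-of-band drift), `physio_amp` (amplitude of a brain-wide
#'   physiological/scanner component, independent of the latents, that
#'   global-signal regression is meant to remove), `baseline` (mean BOLD
#'   intensity added to brain voxels) and `nuisance_amp` (amplitude of the
#'   WM/CSF compartment signals).
#' @param motion_spike_rate expected number of flagged frames per run;
#'   scalar or named per-state vector.
#' @param motion list of motion-trace parameters (`walk_sd`, `spike_gap`,
#'   `spike_translation_mm`, `spike_gs_pct`).
#' @param behavior_coupling list with `rt` and `accuracy`, each a named
#'   (T1, T2) vector: the population correlation between the latent
#'   per-subject dFC and the behavioural measure the generator enforces.
#' @param behavior list of behavioural population parameters (`rt_mean`,
#'   `rt_sd`, `acc_mean`, `acc_sd`, each named over T1/T2).
#' @param masks optional list with integer voxel-index vectors `brain`,
#'   `wm`, `csf`; by default the brain is the grid minus a one-voxel
#'   border and small WM/CSF compartments sit in region-free corners.
#' @param seed integer RNG seed of the scenario.
#' @param repair if `TRUE`, repair non-PSD state matrices by eigenvalue
#'   clipping instead of raising an error.
#' @return an object of class `synth_scenario`.
#' @export
make_scenario <- function(grid_shape = c(24L, 36L, 24L),
                          voxel_mm = 3,
                          n_subjects = 19L,
                          n_volumes = 150L,
                          tr = 2,
                          region_layout = NULL,
                          state_covariance = NULL,
                          block_targets = default_block_targets(),
                          subject_sd = 0.12,
                          subject_sd_common = 0.12,
                          noise_model = list(),
                          motion_spike_rate = 0,
                          motion = list(),
                          behavior_coupling = NULL,
                          behavior = NULL,
                          masks = NULL,
                          seed = 1L,
                          repair = FALSE) {
  grid <- make_grid(grid_shape, voxel_mm,
                    origin_mm = c(-36, -92, -7))
  if (n_volumes < 11L) stop("n_volumes must be >= 11 (initial-volume drop)")
  if (is.null(region_layout)) region_layout <- default_region_layout(grid)

  systems <- vapply(region_layout, `[[`, "", "system")
  bad <- setdiff(systems, c("stable", "decreasing", "increasing", "background"))
  if (length(bad)) stop("unknown system label(s): ", paste(bad, collapse = ", "))
  all_vox <- unlist(lapply(region_layout, `[[`, "voxels"))
  if (anyDuplicated(all_vox)) stop("region layout has overlapping regions")
  if (max(all_vox) > n_voxels(grid)) stop("region voxels outside the grid")

  signal_regions <- region_layout[systems != "background"]
  if (is.null(state_covariance)) {
    state_covariance <- expand_block_correlations(signal_regions, block_targets)
  }
  if (!setequal(names(state_covariance), dmn_states())) {
    stop("state_covariance must have matrices named ",
         paste(dmn_states(), collapse = ", "))
  }
  state_covariance <- state_covariance[dmn_states()]
  k <- length(signal_regions)
  for (st in dmn_states()) {
    m <- state_covariance[[st]]
    if (!is.matrix(m) || nrow(m) != k || ncol(m) != k)
      stop("state_covariance[['", st, "']] must be ", k, " x ", k)
    if (max(abs(m - t(m))) > 1e-10)
      stop("state_covariance[['", st, "']] is not symmetric")
    if (max(abs(diag(m) - 1)) > 1e-10)
      stop("state_covariance[['", st, "']] must have unit diagonal")
    if (!is_psd(m)) {
      if (!repair)
        stop("state_covariance[['", st, "']] is not positive semi-definite ",
             "(pass repair = TRUE to clip eigenvalues)")
      state_covariance[[st]] <- repair_correlation(m)
    }
  }

  noise <- utils::modifyList(
    list(ar1 = 0.4, sd = 0.6, region_amp = 1.5, drift_amp = 1.0,
         physio_amp = 0, baseline = 1000, nuisance_amp = 1.0,
         nuisance_physio = 0, bg_amp = 2, bg_rho = 0.5, gfield_amp = 1.2),
    noise_model)
  mot <- utils::modifyList(
    list(walk_sd = 0.01, spike_gap = 5L,
         spike_translation_mm = 1.2, spike_gs_pct = 1.5, mover_frac = 1),
    motion)
  rate <- motion_spike_rate
  if (length(rate) == 1L && is.null(names(rate)))
    rate <- setNames(rep(as.numeric(rate), 4L), dmn_states())
  stopifnot(setequal(names(rate), dmn_states()), all(rate >= 0))

  beh <- utils::modifyList(
    list(rt_mean = c(T1 = 1864, T2 = 1310),
         rt_sd = c(T1 = 152.8, T2 = 65.6) * sqrt(19),
         acc_mean = c(T1 = 97.8, T2 = 94.5),
         acc_sd = c(T1 = 0.46, T2 = 0.99) * sqrt(19)),
    behavior %||% list())
  ## generative couplings between latent dFC and behaviour; calibrated so
  ## that the PIPELINE-MEASURED dFC-behaviour correlations land at the
  ## study's reported effect sizes (0.60/0.57 for RT, 0.49/0.59 for
  ## accuracy) after estimation attenuation of the measured dFC
  ## (~0.73-0.77 at 140 band-limited frames) and accuracy clipping
  coup <- utils::modifyList(
    list(rt = c(T1 = 0.82, T2 = 0.79),
         accuracy = c(T1 = 0.65, T2 = 0.79)),
    behavior_coupling %||% list())

  ## masks: brain = grid minus a one-voxel border; small WM and CSF
  ## compartments tucked into region-free corners of the brain.
  if (is.null(masks)) {
    d <- grid$dims
    ijk <- index_to_ijk(grid, seq_len(n_voxels(grid)))
    brain <- which(ijk[, 1] > 1L & ijk[, 1] < d[1] & ijk[, 2] > 1L &
                     ijk[, 2] < d[2] & ijk[, 3] > 1L & ijk[, 3] < d[3])
    wm_corner <- pmin(c(2L, 12L, 3L), d - 3L)
    csf_corner <- pmin(c(d[1] - 4L, 12L, 3L), d - 3L)
    masks <- list(brain = brain,
                  wm = block_voxels(grid, pmax(wm_corner, 1L), 3L),
                  csf = block_voxels(grid, pmax(csf_corner, 1L), 3L))
  }
  stopifnot(all(c("brain", "wm", "csf") %in% names(masks)))
  if (length(intersect(c(masks$wm, masks$csf), all_vox)))
    stop("WM/CSF compartments overlap planted regions")
  if (!all(all_vox %in% masks$brain))
    stop("planted regions must lie inside the brain mask")

  ## diffuse-field support: brain voxels at Chebyshev distance > 3 from
  ## every signal region (a moat keeps the field and its smoothed tail
  ## out of the planted regions and their detection shells)
  sig_vox <- unlist(lapply(region_layout[systems != "background"],
                           `[[`, "voxels"))
  inmoat <- logical(n_voxels(grid))
  if (length(sig_vox)) {
    ijk_sig <- index_to_ijk(grid, sig_vox)
    lo <- pmax(t(t(ijk_sig) - 3L), 1L)
    hi <- t(pmin(t(ijk_sig) + 3L, grid$dims))
    for (v in seq_len(nrow(ijk_sig))) {
      ijk_box <- as.matrix(expand.grid(lo[v, 1]:hi[v, 1], lo[v, 2]:hi[v, 2],
                                       lo[v, 3]:hi[v, 3]))
      inmoat[ijk_to_index(grid, ijk_box)] <- TRUE
    }
  }
  ## the WM/CSF compartments are kept out of the field so their nuisance
  ## regressors stay field-free
  masks$field <- setdiff(masks$brain, c(which(inmoat), masks$wm, masks$csf))

  structure(list(
    grid = grid, n_subjects = as.integer(n_subjects),
    n_volumes = as.integer(n_volumes), tr = as.numeric(tr),
    states = dmn_states(),
    region_layout = region_layout,
    state_covariance = state_covariance,
    block_targets = block_targets,
    subject_sd = as.numeric(subject_sd),
    subject_sd_common = as.numeric(subject_sd_common),
    noise_model = noise,
    motion_spike_rate = rate[dmn_states()],
    motion = mot,
    behavior_coupling = coup,
    behavior = beh,
    masks = masks,
    seed = as.integer(seed)
  ), class = "synth_scenario")
}

#' @export
print.synth_scenario <- function(x, ...) {
  sys <- table(vapply(x$region_layout, `[[`, "", "system"))
  cat(sprintf("<synth_scenario: %d subjects x 4 states, %d volumes @ TR %gs>\n",
              x$n_subjects, x$n_volumes, x$tr))
  cat("  grid: ", paste(x$grid$dims, collapse = " x "),
      " @ ", x$grid$voxel_mm, " mm\n", sep = "")
  cat("  regions:", paste(names(sys), sys, sep = "=", collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Regions carrying latent signal, in latent-index order
#' @param scenario a [make_scenario()] object.
#' @return list of [planted_region()] objects excluding background.
#' @export
signal_regions <- function(scenario) {
  regs <- Filter(function(r) r$system != "background", scenario$region_layout)
  regs[order(vapply(regs, `[[`, 1L, "latent"))]
}

#' The packaged default seed specification
#'
#' An 8 mm-radius sphere centred on the posterior cingulate seed
#' coordinate (MNI 0, -53, 26), which falls at the centre of the
#' seed-bearing stable region of the default layout.
#' @return list with `center_mm` and `radius_mm`.
#' @export
default_seed_spec <- function() list(center_mm = c(0, -53, 26), radius_mm = 8)
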