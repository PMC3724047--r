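#' Region set of the planted ground truth
#'
#' Wraps a scenario's planted layout as a `region_set`, e.g. to compare
#' detected regions against truth or to run the system-level stage
#' directly on known regions.
#'
#' @param scenario a [make_scenario()] object.
#' @return a `region_set`.
#' @export
planted_region_set <- function(scenario) {
  regs <- list()
  sphere <- sphere_voxels(scenario$grid, default_seed_spec()$center_mm,
                          default_seed_spec()$radius_mm)
  for (r in signal_regions(scenario)) {
    regs[[r$name]] <- list(name = r$name, class = r$system,
                           voxels = r$voxels,
                           seed_region = length(intersect(r$voxels,
                                                          sphere)) > 0)
  }
  structure(list(regions = regs, grid = scenario$grid), class = "region_set")
}

#' End-to-end seed-based pipeline on one synthetic cohort
#'
#' Simulates every subject, applies the temporal preprocessing chain,
#' computes seed connectivity maps, runs the group statistics (per-state
#' significance, union mask, repeated-measures ANOVA over subjects with
#' all four usable states, cluster filtering, retrospective
#' classification, region assembly), then the system-level stage
#' (connectomes, system means, transition tests) and, optionally, the
#' brain-behavior panel.
#'
#' @param scenario a [make_scenario()] object.
#' @param seed cohort seed.
#' @param q FDR level used throughout.
#' @param method FDR variant (`"BY"` by default).
#' @param gsr include global-signal regression?
#' @param min_cluster cluster-extent threshold (exclusive).
#' @param connectivity cluster adjacency (26 or 6).
#' @param do_behavior run the behaviour panel?
#' @param n_boot bootstrap resamples for the behaviour panel.
#' @param seed_region the [seed_spec()] to use (default: the packaged
#'   posterior-cingulate sphere).
#' @param keep_runs keep the preprocessed runs in the result (large).
#' @return list with the stage outputs (`cohort`, `maps`, `union`,
#'   `anova`, `clusters`, `labels`, `region_set`, `connectomes`,
#'   `summaries`, `transitions`, `behavior`, `scrub`, `complete`).
#' @export
run_seed_pipeline <- function(scenario, seed = scenario$seed, q = 0.05,
                              method = "BY", gsr = TRUE, min_cluster = 5L,
                              connectivity = 26L, do_behavior = TRUE,
                              n_boot = 1000L, seed_region = seed_spec(),
                              keep_runs = FALSE) {
  cohort <- simulate_cohort(scenario, seed)
  sp <- seed_region
  n <- scenario$n_subjects
  runs_pp <- vector("list", n)
  zmaps <- vector("list", n)
  scrub_reports <- vector("list", n)
  usable <- matrix(TRUE, n, 4L, dimnames = list(NULL, dmn_states()))
  for (i in seq_len(n)) {
    sub <- simulate_subject(scenario, i, seed)
    runs_pp[[i]] <- list(); zmaps[[i]] <- list(); scrub_reports[[i]] <- list()
    for (st in dmn_states()) {
      pp <- preprocess_run(sub$runs[[st]], sub$motion[[st]], gsr = gsr)
      scrub_reports[[i]][[st]] <- pp$report
      if (pp$report$excluded) {
        usable[i, st] <- FALSE
        next
      }
      runs_pp[[i]][[st]] <- pp$run
      zmaps[[i]][[st]] <- connectivity_map(pp$run, sp)$z
    }
  }
  complete <- which(rowSums(usable) == 4L)
  if (length(complete) < 2L) stop("fewer than 2 subjects with all four states")
  brain <- scenario$masks$brain

  maps <- list()
  for (st in dmn_states()) {
    zm <- vapply(complete, function(i) zmaps[[i]][[st]],
                 numeric(length(brain)))
    maps[[st]] <- group_significance(zm, brain, st, q = q, method = method)
  }
  un <- union_mask(maps)
  rows <- match(un$voxels, brain)
  z_by_state <- lapply(dmn_states(), function(st) {
    m <- vapply(complete, function(i) zmaps[[i]][[st]][rows],
                numeric(length(rows)))
    if (length(rows) == 1L) m <- matrix(m, 1L)
    m
  })
  names(z_by_state) <- dmn_states()
  if (length(un$voxels)) {
    anova <- voxelwise_rm_anova(z_by_state, un$voxels, q = q, method = method)
  } else {
    anova <- list(F = numeric(0), p = numeric(0), significant = integer(0),
                  voxels = integer(0))
  }
  clusters <- cluster_filter(anova$significant, scenario$grid, min_cluster,
                             connectivity)
  labels <- classify_voxels(z_by_state, un$voxels, clusters)
  rs <- define_regions(labels, un, anova$significant, scenario$grid, sp,
                       connectivity)

  connectomes <- list(); summaries <- NULL; transitions <- NULL
  behavior <- NULL
  if (length(rs$regions)) {
    for (i in seq_len(n)) {
      sts <- dmn_states()[usable[i, ]]
      if (!length(sts)) next
      cn <- pairwise_fc(runs_pp[[i]][sts], rs)
      connectomes[[sprintf("sub%02d", i)]] <- cn
      summaries <- rbind(summaries, system_means(cn))
    }
    keep <- intersect(sprintf("sub%02d", complete), names(connectomes))
    transitions <- state_transition_tests(
      summaries[summaries$subject %in% keep, ],
      connectomes = connectomes[keep], q = q, method = method)
    if (do_behavior)
      behavior <- behavior_panel(summaries, cohort$behavior, n_boot = n_boot,
                                 seed = substream_seed(seed, 17L), q = q,
                                 method = method)
  }
  out <- list(cohort = cohort, maps = maps, union = un, anova = anova,
              clusters = clusters, labels = labels, region_set = rs,
              connectomes = connectomes, summaries = summaries,
              transitions = transitions, behavior = behavior,
              scrub = scrub_reports, usable = usable, complete = complete)
  if (keep_runs) out$runs <- runs_pp
  out
}

#' Band-pass preprocess a set of region time courses
#'
#' The temporal part of the preprocessing chain for region-level data:
#' initial-volume drop and zero-phase band-pass.
#'
#' @param tc regions x frames matrix.
#' @param tr repetition time (s).
#' @param drop_n initial frames to drop.
#' @param low_hz,high_hz pass band.
#' @return filtered regions x frames matrix.
#' @export
preprocess_timecourses <- function(tc, tr, drop_n = 10L, low_hz = 0.008,
                                   high_hz = 0.08) {
  stopifnot(ncol(tc) > drop_n)
  if (drop_n > 0L) tc <- tc[, -seq_len(drop_n), drop = FALSE]
  M <- bandpass_operator(ncol(tc), low_hz, high_hz, 1 / tr)
  tc %*% t(M)
}

#' System-level fast path on one cohort
#'
#' Runs the system-level stage directly on the planted regions: region
#' mean time courses from the generator's fast path, temporal
#' preprocessing, connectomes, system means and (optionally) the
#' behaviour panel.  This skips voxelwise detection, so it measures the
#' connectivity-estimation and behaviour stages in isolation.
#'
#' @param scenario a [make_scenario()] object.
#' @param seed cohort seed.
#' @param do_behavior run the behaviour panel?
#' @param n_boot bootstrap resamples.
#' @param q FDR level.
#' @param method FDR variant.
#' @return list with `cohort`, `summaries`, `connectomes`, `behavior`.
#' @export
run_system_experiment <- function(scenario, seed = scenario$seed,
                                  do_behavior = TRUE, n_boot = 1000L,
                                  q = 0.05, method = "BY") {
  cohort <- simulate_cohort(scenario, seed)
  regs <- signal_regions(scenario)
  classes <- setNames(vapply(regs, `[[`, "", "system"),
                      vapply(regs, `[[`, "", "name"))
  connectomes <- list(); summaries <- NULL
  for (i in seq_len(scenario$n_subjects)) {
    r <- list(); z <- list()
    for (si in seq_along(dmn_states())) {
      st <- dmn_states()[si]
      tc <- simulate_region_timecourses(cohort$scenario, cohort$deviations[[i]],
                                        st, substream_seed(seed, i, si, 55L))
      tc <- preprocess_timecourses(tc, scenario$tr)
      cm <- cor(t(tc))
      r[[st]] <- cm
      zc <- cm; diag(zc) <- 0
      zc <- fisher_z(zc)
      z[[st]] <- zc
    }
    cn <- structure(list(subject = sprintf("sub%02d", i), r = r, z = z,
                         classes = classes), class = "subject_connectome")
    connectomes[[cn$subject]] <- cn
    summaries <- rbind(summaries, system_means(cn))
  }
  behavior <- NULL
  if (do_behavior)
    behavior <- behavior_panel(summaries, cohort$behavior, n_boot = n_boot,
                               seed = substream_seed(seed, 17L), q = q,
                               method = method)
  list(cohort = cohort, summaries = summaries, connectomes = connectomes,
       behavior = behavior)
}

#' Group mean system connectivity of a pipeline result
#'
#' @param summaries a row-bound [system_means()] table.
#' @return data.frame measure x state of group mean `fc_r`.
#' @export
group_mean_fc <- function(summaries) {
  measures <- c("stable_decreasing", "stable_increasing", "stable",
                "decreasing", "increasing")
  out <- matrix(NA_real_, length(measures), 4L,
                dimnames = list(measures, dmn_states()))
  for (ms in measures) for (st in dmn_states()) {
    v <- summaries$fc_r[summaries$measure == ms & summaries$state == st]
    v <- v[is.finite(v)]
    if (length(v)) out[ms, st] <- mean(v)
  }
  out
}

#' Match detected regions against the planted truth
#'
#' Greedy best-overlap matching of detected decreasing/increasing
#' regions to planted regions of the same class, with Jaccard overlap
#' and planted-coverage (sensitivity) per match.
#'
#' @param region_set detected `region_set`.
#' @param scenario the generating scenario.
#' @return data.frame with one row per planted changing region:
#'   `planted`, `class`, `detected`, `jaccard`, `coverage`.
#' @export
region_recovery <- function(region_set, scenario) {
  out <- NULL
  for (cls in c("decreasing", "increasing")) {
    planted <- Filter(function(r) r$system == cls, signal_regions(scenario))
    detected <- regions_of(region_set, cls)
    for (p in planted) {
      best <- NA_character_; bj <- 0; bc <- 0
      for (d in detected) {
        inter <- length(intersect(p$voxels, d$voxels))
        if (!inter) next
        j <- inter / length(union(p$voxels, d$voxels))
        if (j > bj) { bj <- j; bc <- inter / length(p$voxels); best <- d$name }
      }
      out <- rbind(out, data.frame(planted = p$name, class = cls,
                                   detected = best, jaccard = bj,
                                   coverage = bc, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Replicated end-to-end calibration experiment
#'
#' Runs the full seed pipeline on `n_cohorts` independently seeded
#' cohorts and collects the group mean system connectivity per state and
#' the detected changing-region counts per cohort.
#'
#' @param scenario a [make_scenario()] object.
#' @param n_cohorts number of replicate cohorts.
#' @param base_seed seed from which cohort seeds are derived.
#' @param ... passed to [run_seed_pipeline()].
#' @return list with `mean_fc` (average of the per-cohort group-mean
#'   tables), `per_cohort_fc`, `region_counts` (cohorts x 2), and
#'   `recovery` (list of [region_recovery()] tables).
#' @export
replicate_calibration <- function(scenario, n_cohorts = 25L, base_seed = 1L,
                                  ...) {
  fc <- list(); counts <- NULL; recovery <- list()
  for (c_i in seq_len(n_cohorts)) {
    res <- run_seed_pipeline(scenario, seed = substream_seed(base_seed, c_i),
                             do_behavior = FALSE, ...)
    fc[[c_i]] <- group_mean_fc(
      res$summaries[res$summaries$subject %in%
                      sprintf("sub%02d", res$complete), ])
    cls <- vapply(res$region_set$regions, `[[`, "", "class")
    counts <- rbind(counts, c(decreasing = sum(cls == "decreasing"),
                              increasing = sum(cls == "increasing")))
    recovery[[c_i]] <- region_recovery(res$region_set, scenario)
  }
  arr <- simplify2array(fc)
  mean_fc <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  list(mean_fc = mean_fc, per_cohort_fc = fc, region_counts = counts,
       recovery = recovery)
}

#' Replicated behaviour-coupling experiment (fast path)
#'
#' Runs the system-level fast path on `n_cohorts` cohorts and collects
#' the behaviour panel of each, summarising the mean correlation per
#' (measure, state, behaviour) cell and the per-cohort significance
#' pattern.
#'
#' @param scenario a [make_scenario()] object.
#' @param n_cohorts replicate cohorts.
#' @param base_seed seed for cohort-seed derivation.
#' @param n_boot bootstrap resamples per panel (kept small here; the
#'   panel's CI is not the target of this experiment).
#' @param ... passed to [run_system_experiment()].
#' @return list with `mean_r` (aggregated panel), `panels` (list).
#' @export
replicate_behavior <- function(scenario, n_cohorts = 200L, base_seed = 1L,
                               n_boot = 200L, ...) {
  panels <- vector("list", n_cohorts)
  for (c_i in seq_len(n_cohorts)) {
    res <- run_system_experiment(scenario,
                                 seed = substream_seed(base_seed, c_i, 7L),
                                 n_boot = n_boot, ...)
    p <- res$behavior
    p$cohort <- c_i
    panels[[c_i]] <- p
  }
  all <- do.call(rbind, panels)
  mean_r <- aggregate(cbind(r, significant) ~ measure + state + behavior,
                      data = all, FUN = mean)
  names(mean_r)[names(mean_r) == "significant"] <- "sig_rate"
  list(mean_r = mean_r, panels = panels)
}
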