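#' Mean time course of a region
#'
#' @param run a preprocessed [bold_run()].
#' @param voxels integer voxel indices of the region (non-empty, inside
#'   the brain mask).
#' @return numeric vector over frames.
#' @export
region_timecourse <- function(run, voxels) {
  if (!length(voxels)) stop("empty region")
  if (!all(voxels %in% run$masks$brain))
    stop("region extends outside the brain mask")
  colMeans(run$data[voxels, , drop = FALSE])
}

#' Region-by-region connectivity of one subject
#'
#' Pearson correlations between all region mean time courses, per state,
#' with the Fisher-Z matrix alongside.
#'
#' @param runs named list of the subject's four preprocessed
#'   [bold_run()]s (any subset of states is accepted).
#' @param region_set a [define_regions()] result.
#' @return object of class `subject_connectome`: `r` and `z` are named
#'   lists of region x region matrices.
#' @export
pairwise_fc <- function(runs, region_set) {
  regs <- region_set$regions
  if (!length(regs)) stop("empty region set")
  r <- list(); z <- list()
  for (st in names(runs)) {
    run <- runs[[st]]
    if (n_frames(run) < 3L) stop("fewer than 3 surviving frames in ", st)
    tc <- vapply(regs, function(reg) region_timecourse(run, reg$voxels),
                 numeric(n_frames(run)))
    cm <- cor(tc)
    dimnames(cm) <- list(names(regs), names(regs))
    r[[st]] <- cm
    zc <- cm
    diag(zc) <- 0          # transform off-diagonals only
    zc <- fisher_z(zc)
    z[[st]] <- zc
  }
  structure(list(subject = runs[[1]]$subject, r = r, z = z,
                 classes = vapply(regs, `[[`, "", "class")),
            class = "subject_connectome")
}

## All (row, col) index pairs contributing to one system aggregate.
system_pairs <- function(classes, measure) {
  idx <- seq_along(classes)
  if (measure %in% c("stable", "decreasing", "increasing")) {
    members <- idx[classes == measure]
    if (length(members) < 2L) return(NULL)
    pairs <- t(utils::combn(members, 2L))
  } else {
    other <- sub("stable_", "", measure)
    a <- idx[classes == "stable"]; b <- idx[classes == other]
    if (!length(a) || !length(b)) return(NULL)
    pairs <- as.matrix(expand.grid(a, b))
  }
  pairs
}

#' System-level mean connectivity of one subject
#'
#' Averages the pairwise correlations into the five system aggregates:
#' stable-decreasing and stable-increasing between-system means (all
#' pairs of one stable and one changing region) and the three
#' within-system means (unordered distinct pairs).  Means are reported on
#' the r scale; the Fisher-Z mean is carried alongside for inference.
#'
#' @param connectome a [pairwise_fc()] result.
#' @return data.frame with `subject`, `state`, `measure`, `fc_r`, `fc_z`,
#'   `n_pairs`.
#' @export
system_means <- function(connectome) {
  classes <- connectome$classes
  measures <- c("stable_decreasing", "stable_increasing",
                "stable", "decreasing", "increasing")
  out <- NULL
  for (st in names(connectome$r)) {
    for (ms in measures) {
      pairs <- system_pairs(classes, ms)
      if (is.null(pairs)) {
        out <- rbind(out, data.frame(subject = connectome$subject, state = st,
                                     measure = ms, fc_r = NA_real_,
                                     fc_z = NA_real_, n_pairs = 0L))
        next
      }
      out <- rbind(out, data.frame(
        subject = connectome$subject, state = st, measure = ms,
        fc_r = mean(connectome$r[[st]][pairs]),
        fc_z = mean(connectome$z[[st]][pairs]),
        n_pairs = nrow(pairs), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Consecutive-state transition tests
#'
#' Paired t-tests (on the Fisher-Z scale) between consecutive states
#' (R1 vs T1, T1 vs T2, T2 vs R2) plus the R1 vs R2 null check, for each
#' of the five system aggregates and, when connectomes are supplied, for
#' every region pair entering those aggregates.  One FDR pass (BY by
#' default) is applied across the whole family.
#'
#' @param summaries row-bound [system_means()] tables of all subjects.
#' @param connectomes optional named/indexed list of
#'   [pairwise_fc()] results, to add region-pair level tests.
#' @param q FDR level.
#' @param method FDR variant.
#' @return data.frame with `level`, `measure`, `contrast`, `n`,
#'   `mean_diff_r`, `t`, `p`, `significant`.
#' @export
state_transition_tests <- function(summaries, connectomes = NULL, q = 0.05,
                                   method = "BY") {
  contrasts <- list(c("R1", "T1"), c("T1", "T2"), c("T2", "R2"),
                    c("R1", "R2"))
  rows <- list()
  paired_t <- function(a, b) {
    d <- b - a
    d <- d[is.finite(d)]
    n <- length(d)
    if (n < 2L) return(c(n = n, t = NA, p = NA))
    m <- mean(d); s <- sd(d)
    if (s == 0) return(c(n = n, t = if (m == 0) 0 else Inf * sign(m),
                         p = if (m == 0) 1 else 0))
    tt <- m / (s / sqrt(n))
    c(n = n, t = tt, p = 2 * pt(abs(tt), n - 1, lower.tail = FALSE))
  }
  for (ms in unique(summaries$measure)) {
    sub <- summaries[summaries$measure == ms, ]
    wide_z <- tapply(sub$fc_z, list(sub$subject, sub$state), identity)
    wide_r <- tapply(sub$fc_r, list(sub$subject, sub$state), identity)
    for (ct in contrasts) {
      if (!all(ct %in% colnames(wide_z))) next
      ok <- is.finite(wide_z[, ct[1]]) & is.finite(wide_z[, ct[2]])
      res <- paired_t(wide_z[ok, ct[1]], wide_z[ok, ct[2]])
      rows[[length(rows) + 1L]] <- data.frame(
        level = "system", measure = ms,
        contrast = paste(ct, collapse = "-"), n = res["n"],
        mean_diff_r = mean(wide_r[ok, ct[2]] - wide_r[ok, ct[1]]),
        t = res["t"], p = res["p"], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(connectomes) && length(connectomes)) {
    classes <- connectomes[[1]]$classes
    nm <- names(classes)
    measures <- c("stable_decreasing", "stable_increasing",
                  "stable", "decreasing", "increasing")
    for (ms in measures) {
      pairs <- system_pairs(classes, ms)
      if (is.null(pairs)) next
      for (pi in seq_len(nrow(pairs))) {
        a <- pairs[pi, 1]; b <- pairs[pi, 2]
        for (ct in contrasts) {
          za <- vapply(connectomes, function(cn)
            if (all(ct %in% names(cn$z))) cn$z[[ct[1]]][a, b] else NA_real_, 1)
          zb <- vapply(connectomes, function(cn)
            if (all(ct %in% names(cn$z))) cn$z[[ct[2]]][a, b] else NA_real_, 1)
          ok <- is.finite(za) & is.finite(zb)
          res <- paired_t(za[ok], zb[ok])
          rows[[length(rows) + 1L]] <- data.frame(
            level = "pair", measure = paste(nm[a], nm[b], sep = "|"),
            contrast = paste(ct, collapse = "-"), n = res["n"],
            mean_diff_r = mean(tanh(zb[ok]) - tanh(za[ok])),
            t = res["t"], p = res["p"], stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- FALSE
  ok <- is.finite(out$p)
  if (any(ok)) out$significant[ok] <- fdr_correct(out$p[ok], q = q,
                                                  method = method)
  out
}
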