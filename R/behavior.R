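#' Per-subject connectivity change from rest to task
#'
#' `dFC_i = meanFC_i(task state) - meanFC_i(R1)` for one system
#' aggregate, on the r scale (the baseline is R1, not the R1/R2 average,
#' so subjects without a usable R2 run still contribute).
#'
#' @param summaries row-bound [system_means()] tables.
#' @param task_state `"T1"` or `"T2"`.
#' @param measure system aggregate name (e.g. `"stable_decreasing"`).
#' @return named numeric vector of per-subject dFC values.
#' @export
compute_dfc <- function(summaries, task_state, measure) {
  stopifnot(task_state %in% c("T1", "T2"))
  sub <- summaries[summaries$measure == measure, ]
  wide <- tapply(sub$fc_r, list(sub$subject, sub$state), identity)
  if (!all(c("R1", task_state) %in% colnames(wide)))
    stop("missing state ", task_state, " or R1 in summaries")
  wide[, task_state] - wide[, "R1"]
}

#' Pearson correlation with significance
#'
#' `r`, `R^2 = r^2` and the two-tailed p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y aligned numeric vectors, `n >= 3`, both non-constant.
#' @return list with `r`, `r2`, `p`, `n`.
#' @export
correlate_behavior <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, r2 = r^2, p = 0, n = n))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, r2 = r^2, p = 2 * pt(abs(tt), n - 2, lower.tail = FALSE), n = n)
}

#' Percentile bootstrap confidence interval for a correlation
#'
#' Resamples subject pairs with replacement, recomputes the correlation
#' each time and returns the percentile interval.  Degenerate resamples
#' (constant x or y) are redrawn, up to a cap.
#'
#' @param x,y aligned numeric vectors.
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed RNG seed.
#' @param max_redraw cap on redraws of degenerate resamples.
#' @return list with `lower`, `upper`, `boot_r` (the resampled
#'   correlations), `n_redrawn`.
#' @export
bootstrap_ci <- function(x, y, n_boot = 1000L, level = 0.95, seed = 1L,
                         max_redraw = 10L * n_boot) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  set.seed(seed)
  boot_r <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(x[idx]) > 0 && sd(y[idx]) > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > max_redraw)
        stop("too many degenerate bootstrap resamples")
    }
    boot_r[b] <- cor(x[idx], y[idx])
  }
  if (redrawn > 0L)
    warning(redrawn, " degenerate bootstrap resample(s) redrawn")
  a <- (1 - level) / 2
  ci <- unname(quantile(boot_r, c(a, 1 - a), type = 6))
  list(lower = ci[1], upper = ci[2], boot_r = boot_r, n_redrawn = redrawn)
}

#' Brain-behavior correlation panel
#'
#' The full grid of dFC-behaviour tests: the two between-system
#' aggregates (stable-decreasing, stable-increasing) and the three
#' within-system aggregates, against mean RT and accuracy, at both task
#' states; Pearson correlation, bootstrap CI, and one FDR pass across
#' the family.
#'
#' @param summaries row-bound [system_means()] tables.
#' @param behavior_table data.frame with `subject`, `state`, `rt_ms`,
#'   `accuracy_pct` (one row per subject per task state).
#' @param n_boot bootstrap resamples per test.
#' @param seed RNG seed for the bootstrap.
#' @param q FDR level.
#' @param method FDR variant.
#' @param measures system aggregates to test.
#' @return data.frame of class `dfc_result` rows: `measure`, `state`,
#'   `behavior`, `n`, `r`, `r2`, `p`, `ci_lower`, `ci_upper`,
#'   `significant`.
#' @export
behavior_panel <- function(summaries, behavior_table, n_boot = 1000L,
                           seed = 1L, q = 0.05, method = "BY",
                           measures = c("stable_decreasing",
                                        "stable_increasing", "stable",
                                        "decreasing", "increasing")) {
  rows <- list()
  for (ms in measures) {
    for (st in c("T1", "T2")) {
      dfc <- compute_dfc(summaries, st, ms)
      if (!any(is.finite(dfc))) next    # aggregate unavailable (no pairs)
      beh <- behavior_table[behavior_table$state == st, ]
      beh <- beh[match(names(dfc), beh$subject), ]
      if (anyNA(beh$subject)) stop("behaviour table does not cover subjects")
      for (bv in c("rt_ms", "accuracy_pct")) {
        y <- beh[[bv]]
        cb <- correlate_behavior(dfc, y)
        ci <- bootstrap_ci(dfc, y, n_boot = n_boot,
                           seed = substream_seed(seed, match(ms, measures),
                                                 match(st, c("T1", "T2")),
                                                 match(bv, c("rt_ms",
                                                             "accuracy_pct"))))
        rows[[length(rows) + 1L]] <- data.frame(
          measure = ms, state = st, behavior = bv, n = cb$n, r = cb$r,
          r2 = cb$r2, p = cb$p, ci_lower = ci$lower, ci_upper = ci$upper,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) < 1L) stop("no tests requested")
  out <- do.call(rbind, rows)
  out$significant <- fdr_correct(out$p, q = q, method = method)
  class(out) <- c("dfc_result", class(out))
  out
}
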