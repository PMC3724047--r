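# Temporal preprocessing: initial drop, smoothing, band-pass, nuisance
# regression, frame metrics and scrubbing.

test_that("initial-volume drop trims frames and validates bounds", {
  run <- matrix_run(matrix(rnorm(216 * 150), 216, 150))
  out <- drop_initial(run, 10L)
  expect_equal(n_frames(out), 140L)
  expect_equal(out$data, run$data[, 11:150])
  same <- drop_initial(run, 0L)
  expect_equal(same$data, run$data)
  short <- matrix_run(matrix(rnorm(216 * 5), 216, 5))
  expect_error(drop_initial(short, 10L), "cannot drop")
  expect_error(drop_initial(out, 10L), "already been applied")
})

test_that("Gaussian smoothing matches the closed-form kernel on an impulse", {
  dims <- c(17L, 17L, 17L)
  V <- prod(dims)
  data <- matrix(0, V, 1L)
  grid <- make_grid(dims, 3)
  centre <- ijk_to_index(grid, matrix(c(9L, 9L, 9L), 1L))
  data[centre, 1L] <- 1
  run <- bold_run(data, grid, 2, "s", "R1",
                  list(brain = seq_len(V), wm = 1:2, csf = 3:4))
  sm <- smooth_spatial(run, 8)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1L, ceiling(4 * sigma))
  w1 <- exp(-(-r:r)^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  # analytic separable profile at selected offsets (far from boundary)
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(1, 1, 1))) {
    idx <- ijk_to_index(grid, matrix(c(9L, 9L, 9L) + off, 1L))
    expected <- prod(w1[r + 1 + off])
    expect_lt(abs(sm$data[idx, 1] - expected), 1e-4)
  }
  # discrete peak is close to the continuous normalization constant
  expect_lt(abs(sm$data[centre, 1] - (1 / (sqrt(2 * pi) * sigma))^3), 1e-3)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)  # mass preserved
})

test_that("smoothing equals the separable reflective convolution operator", {
  dims <- c(13L, 12L, 14L)
  V <- prod(dims)
  set.seed(11)
  data <- matrix(rnorm(V * 3), V, 3)
  grid <- make_grid(dims, 3)
  run <- bold_run(data, grid, 2, "s", "R1",
                  list(brain = seq_len(V), wm = 1:2, csf = 3:4))
  sm <- smooth_spatial(run, 8)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  S <- lapply(dims, dmndyn:::gauss_conv_matrix, sigma_vox = sigma)
  # oracle: explicit Kronecker-structured operator application
  oracle <- apply(data, 2L, function(col) {
    a <- array(col, dims)
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      a[i, j, ] <- S[[3]] %*% a[i, j, ]
    for (i in seq_len(dims[1])) for (kk in seq_len(dims[3]))
      a[i, , kk] <- S[[2]] %*% a[i, , kk]
    for (j in seq_len(dims[2])) for (kk in seq_len(dims[3]))
      a[, j, kk] <- S[[1]] %*% a[, j, kk]
    as.numeric(a)
  })
  expect_equal(sm$data, oracle, tolerance = 1e-12)
  # constant volume is unchanged; fwhm 0 is the identity
  const <- bold_run(matrix(5, V, 2), grid, 2, "s", "R1", run$masks)
  expect_equal(smooth_spatial(const, 8)$data, const$data, tolerance = 1e-9)
  expect_equal(smooth_spatial(run, 0)$data, run$data)
  expect_error(smooth_spatial(run, -1), "non-negative")
})

test_that("band-pass keeps in-band sinusoids and rejects stop-band ones", {
  T <- 140L
  tr <- 2
  tt <- seq_len(T) * tr
  amp_ratio <- function(freq) {
    x <- sin(2 * pi * freq * tt)
    run <- matrix_run(matrix(x, 216, T, byrow = TRUE))
    out <- bandpass(run)
    # FFT oracle: amplitude at the signal bin before vs after
    bin <- which.max(Mod(fft(x))[2:(T / 2)])
    Mod(fft(out$data[1, ]))[bin + 1] / Mod(fft(x))[bin + 1]
  }
  expect_gt(amp_ratio(0.04), 0.95)
  expect_lt(amp_ratio(0.04), 1.05)
  expect_lt(amp_ratio(0.2), 0.1)
  # constant series maps to zero (DC removed)
  run <- matrix_run(matrix(7, 216, T))
  expect_lt(max(abs(bandpass(run)$data)), 1e-8)
  expect_error(bandpass(matrix_run(matrix(rnorm(216 * T), 216, T)),
                        low_hz = 0.1, high_hz = 0.3), "Nyquist")
  expect_error(bandpass(matrix_run(matrix(rnorm(216 * 8), 216, 8))),
               "too short")
})

test_that("nuisance regression returns exact least-squares residuals", {
  T <- 80L
  set.seed(3)
  X <- cbind(intercept = 1, wm = rnorm(T), csf = rnorm(T), g = rnorm(T))
  # voxel equal to a regressor -> zero residual
  data <- rbind(X[, "g"], rnorm(T) + 5)
  run <- matrix_run(rbind(data, matrix(rnorm(214 * T), 214, T)))
  out <- regress_nuisance(run, X)
  expect_lt(max(abs(out$data[1, ])), 1e-10)
  # intercept removes the mean
  expect_lt(abs(mean(out$data[2, ])), 1e-10)
  # signal + 0.7 * wm with wm orthogonalized against the signal:
  s <- sin(2 * pi * (1:T) / 16)
  wm <- rnorm(T)
  wm <- wm - s * sum(wm * s) / sum(s * s)   # exact orthogonality
  X2 <- cbind(intercept = 1, wm = wm)
  run2 <- matrix_run(rbind(s + 0.7 * wm, matrix(rnorm(215 * T), 215, T)))
  out2 <- regress_nuisance(run2, X2)
  demeaned <- s - mean(s)
  expect_lt(max(abs(out2$data[1, ] - demeaned)), 1e-8)
  # residuals orthogonal to every design column (skip all-zero residuals)
  rn <- sqrt(rowSums(out$data^2))
  keep <- rn > 1e-6
  G <- out$data[keep, ] %*% X
  norms <- outer(rn[keep], sqrt(colSums(X^2)))
  expect_lt(max(abs(G / norms)), 1e-8)
  # rank deficiency warns and reports the dropped column
  X3 <- cbind(X, dup = X[, "wm"])
  expect_warning(regress_nuisance(matrix_run(matrix(rnorm(216 * T), 216, T)),
                                  X3), "dup")
  expect_error(regress_nuisance(matrix_run(matrix(rnorm(216 * 10), 216, 10)),
                                X), "do not match")
})

test_that("frame metrics implement the displacement and GS-change formulas", {
  T <- 30L
  data <- matrix(100, 216, T)
  run <- matrix_run(data)
  mot <- motion_trace(matrix(0, T, 6))
  met <- compute_frame_metrics(run, mot)
  expect_equal(met$fd, rep(0, T))
  expect_equal(met$gs_change, rep(0, T))
  # 0.5 mm translation step between frames 9 and 10
  p <- matrix(0, T, 6); p[10:T, 1] <- 0.5
  met <- compute_frame_metrics(run, motion_trace(p))
  expect_equal(met$fd[10], 0.5)
  expect_equal(met$fd[11], 0)
  # rotations use the 50 mm lever arm
  p2 <- matrix(0, T, 6); p2[5:T, 4] <- 0.01
  expect_equal(compute_frame_metrics(run, motion_trace(p2))$fd[5], 0.5)
  # GS step 100 -> 101 gives |delta|/mean * 100
  data2 <- data; data2[, 20:T] <- 101
  run2 <- matrix_run(data2)
  met2 <- compute_frame_metrics(run2, mot)
  gs <- c(rep(100, 19), rep(101, 11))
  expect_equal(met2$gs_change[20], 1 / mean(gs) * 100)
  expect_error(compute_frame_metrics(matrix_run(matrix(0, 216, T)), mot),
               "zero")
})

test_that("scrubbing removes the flagged window under the AND rule", {
  T <- 150L
  mk_metrics <- function(flags) {
    m <- motion_trace(matrix(0, T, 6))
    m$fd <- rep(0, T); m$gs_change <- rep(0, T)
    m$fd[flags] <- 0.6; m$gs_change[flags] <- 0.7
    m
  }
  run <- matrix_run(matrix(rnorm(216 * T), 216, T))
  out <- scrub(run, mk_metrics(50L))
  expect_equal(out$report$flagged, 50L)
  expect_equal(out$report$removed, 49:52)
  expect_equal(n_frames(out$run), T - 4L)
  expect_equal(out$run$data, run$data[, -(49:52)])

  # one metric over threshold is not enough
  m <- mk_metrics(integer(0)); m$fd[30] <- 0.6; m$gs_change[30] <- 0.1
  expect_equal(scrub(run, m)$report$n_removed, 0L)

  # windows are clipped at run bounds and merged when overlapping
  expect_equal(scrub(run, mk_metrics(1L))$report$removed, 1:3)
  expect_equal(scrub(run, mk_metrics(T))$report$removed, (T - 1):T)
  expect_equal(scrub(run, mk_metrics(c(40L, 42L)))$report$removed, 39:44)

  # 17 flags spaced >= 5 frames apart remove 68 > 60 volumes -> excluded
  flags <- seq(5L, by = 8L, length.out = 17L)
  out17 <- scrub(run, mk_metrics(flags))
  expect_equal(out17$report$n_removed, 68L)
  expect_true(out17$report$excluded)
  # enumerated window oracle
  oracle <- sort(unique(unlist(lapply(flags, function(f)
    max(1, f - 1):min(T, f + 2)))))
  expect_equal(out17$report$removed, oracle)

  # idempotence: re-scrubbing with the surviving metrics removes nothing
  # (history reset so the arithmetic property can be exercised directly)
  out17$run$history <- character(0)
  out2 <- scrub(out17$run, out17$metrics)
  expect_equal(out2$report$n_removed, 0L)
  expect_equal(out2$run$data, out17$run$data)
})

test_that("the pipeline order contract is enforced through history", {
  run <- matrix_run(matrix(rnorm(216 * 60), 216, 60))
  a <- smooth_spatial(run, 4)
  expect_error(smooth_spatial(a, 4), "already been applied")
  b <- bandpass(a)
  expect_error(smooth_spatial(b, 4), "already been applied")
  expect_error(drop_initial(b, 5L), "cannot apply")
  expect_match(b$history, "smooth", all = FALSE)
})

test_that("full preprocessing chain runs and records its history", {
  tr <- tiny_run()
  pp <- preprocess_run(tr$sub$runs$R1, tr$sub$motion$R1)
  expect_equal(sub(":.*", "", pp$run$history),
               c("drop_initial", "smooth", "bandpass", "regress", "scrub"))
  expect_equal(n_frames(pp$run), tiny_scenario()$n_volumes - 10L)
  expect_equal(nrow(pp$metrics$params), n_frames(pp$run))
  # residuals orthogonal to the design (normalized dot products)
  vox <- tr$scenario$masks$brain[1:50]
  G <- pp$run$data[vox, ] %*% pp$design
  norms <- outer(sqrt(rowSums(pp$run$data[vox, ]^2)),
                 sqrt(colSums(pp$design^2)))
  expect_lt(max(abs(G / norms)), 1e-8)
})
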