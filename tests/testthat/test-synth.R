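# Generator: scenario validation, latent-correlation fidelity, behaviour
# coupling, determinism.

test_that("scenario validation enforces PSD, disjointness and state labels", {
  grid <- make_grid(c(10L, 10L, 10L), 3)
  regs <- list(
    planted_region("A", "stable", block_voxels(grid, c(2L, 2L, 2L), 2L), 1L),
    planted_region("B", "decreasing", block_voxels(grid, c(6L, 6L, 6L), 2L), 2L))
  masks <- list(brain = seq_len(1000L),
                wm = block_voxels(grid, c(8L, 2L, 2L), 2L),
                csf = block_voxels(grid, c(2L, 8L, 2L), 2L))
  near_one <- matrix(c(1, 0.99, 0.99, 1), 2)
  cov_ok <- list(R1 = near_one, T1 = near_one, T2 = near_one, R2 = near_one)
  expect_no_error(make_scenario(grid_shape = c(10L, 10L, 10L),
                                region_layout = regs, state_covariance = cov_ok,
                                masks = masks))
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  cov_bad <- list(R1 = bad, T1 = near_one, T2 = near_one, R2 = near_one)
  expect_error(make_scenario(grid_shape = c(10L, 10L, 10L),
                             region_layout = regs, state_covariance = cov_bad,
                             masks = masks),
               "positive semi-definite")
  expect_no_error(make_scenario(grid_shape = c(10L, 10L, 10L),
                                region_layout = regs, state_covariance = cov_bad,
                                masks = masks, repair = TRUE))
  # eigenvalue oracle agrees with the accept/reject decision
  expect_true(min(eigen(near_one, symmetric = TRUE)$values) >= 0)
  expect_true(min(eigen(bad, symmetric = TRUE)$values) < 0)

  overlapping <- list(
    planted_region("A", "stable", block_voxels(grid, c(2L, 2L, 2L), 2L), 1L),
    planted_region("B", "decreasing", block_voxels(grid, c(2L, 2L, 2L), 2L), 2L))
  expect_error(make_scenario(grid_shape = c(10L, 10L, 10L),
                             region_layout = overlapping,
                             state_covariance = cov_ok, masks = masks),
               "overlapping")
  expect_error(planted_region("X", "sideways", 1:3, 1L))
  expect_error(make_scenario(n_volumes = 10L), "n_volumes")
  expect_error(make_scenario(grid_shape = c(10L, 10L, 10L),
                             region_layout = regs,
                             state_covariance = cov_ok[c(1, 2, 3)],
                             masks = masks))
})

test_that("identity state covariance plants zero inter-region correlation", {
  sc <- tiny_scenario()
  id <- diag(3)
  sc0 <- make_scenario(grid_shape = sc$grid$dims,
                       region_layout = sc$region_layout,
                       state_covariance = list(R1 = id, T1 = id, T2 = id,
                                               R2 = id),
                       masks = sc$masks, subject_sd = 0, subject_sd_common = 0)
  for (st in dmn_states())
    expect_equal(sc0$state_covariance[[st]][upper.tri(id)], rep(0, 3))
  # empirically: latent region time courses are uncorrelated on average
  rs <- replicate(40, {
    tc <- simulate_region_timecourses(sc0, subject_deviations_null(),
                                      "R1", sample.int(1e6, 1))
    cor(tc["A", ], tc["B", ])
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("packaged default scenario carries the calibrated state profile", {
  sc <- make_scenario()
  bt <- sc$block_targets
  expect_equal(unlist(bt["stable_decreasing", dmn_states()]),
               c(R1 = 0.43, T1 = 0.35, T2 = 0.24, R2 = 0.45))
  expect_equal(unlist(bt["stable_increasing", dmn_states()]),
               c(R1 = 0.05, T1 = 0.30, T2 = 0.34, R2 = 0.03))
  # expanded matrices carry the same block values
  regs <- signal_regions(sc)
  sys <- vapply(regs, `[[`, "", "system")
  m <- sc$state_covariance$T2
  expect_equal(mean(m[sys == "stable", sys == "decreasing"]), 0.24)
  expect_equal(mean(m[sys == "stable", sys == "increasing"]), 0.34)
  expect_equal(sc$n_volumes, 150L)
  expect_equal(sc$tr, 2)
  expect_equal(sc$n_subjects, 19L)
})

test_that("noise-free generator reproduces planted correlations exactly at r = 1", {
  grid <- make_grid(c(10L, 10L, 10L), 3)
  regs <- list(
    planted_region("A", "stable", block_voxels(grid, c(2L, 2L, 2L), 2L), 1L),
    planted_region("B", "decreasing", block_voxels(grid, c(6L, 6L, 6L), 2L), 2L))
  one <- matrix(1, 2, 2)
  masks <- list(brain = seq_len(1000L),
                wm = block_voxels(grid, c(8L, 2L, 2L), 2L),
                csf = block_voxels(grid, c(2L, 8L, 2L), 2L))
  sc <- make_scenario(grid_shape = c(10L, 10L, 10L), region_layout = regs,
                      state_covariance = list(R1 = one, T1 = one, T2 = one,
                                              R2 = one),
                      masks = masks, subject_sd = 0, subject_sd_common = 0,
                      noise_model = list(sd = 0, drift_amp = 0,
                                         physio_amp = 0, bg_amp = 0),
                      n_volumes = 40L)
  sub <- simulate_subject(sc, 1L, 5L)
  run <- sub$runs$R1
  a <- colMeans(run$data[regs[[1]]$voxels, ])
  b <- colMeans(run$data[regs[[2]]$voxels, ])
  expect_equal(cor(a, b), 1, tolerance = 1e-6)
})

test_that("planted r = 0.5 is recovered by the generator within Monte-Carlo error", {
  sc <- tiny_scenario(subject_sd = 0, subject_sd_common = 0,
                      n_volumes = 150L,
                      noise_model = list(sd = 0))
  dev0 <- subject_deviations_null()
  rs <- vapply(1:300, function(i) {
    tc <- simulate_region_timecourses(sc, dev0, "R1", 1000L + i)
    tc <- tc[, -(1:10)]    # generator alone: initial drop, no filtering
    cor(tc["A", ], tc["B", ])
  }, 1)
  expect_lt(abs(mean(rs) - 0.5), 0.02)
})

test_that("generator fidelity holds across a sweep of PSD targets", {
  # property: for random PSD latent targets, noise-free latents reproduce
  # the planted pairwise correlation within Monte-Carlo error
  set.seed(42)
  for (rep in 1:4) {
    r_ab <- runif(1, -0.8, 0.8)
    sc <- tiny_scenario(subject_sd = 0, subject_sd_common = 0,
                        noise_model = list(sd = 0), n_volumes = 150L)
    m <- diag(3); m[1, 2] <- m[2, 1] <- r_ab
    sc$state_covariance$R1 <- m
    rs <- vapply(1:100, function(i) {
      tc <- simulate_region_timecourses(sc, subject_deviations_null(), "R1",
                                        rep * 10000L + i)
      cor(tc["A", ], tc["B", ])
    }, 1)
    expect_lt(abs(mean(rs) - r_ab), 3 / sqrt(sc$n_volumes))
  }
})

test_that("identical scenario and seed reproduce a subject bit-for-bit", {
  sc <- tiny_scenario()
  a <- simulate_subject(sc, 2L, 99L)
  b <- simulate_subject(sc, 2L, 99L)
  expect_identical(a$runs$T1$data, b$runs$T1$data)
  expect_identical(a$motion$R2$params, b$motion$R2$params)
  c <- simulate_subject(sc, 2L, 100L)
  expect_false(identical(a$runs$T1$data, c$runs$T1$data))
  expect_error(simulate_subject(sc, 2L, base_seed = NULL), "seed")
})

test_that("zero spike rate yields no frames over both scrubbing thresholds", {
  sc <- tiny_scenario(motion_spike_rate = 0)
  sub <- simulate_subject(sc, 1L, 3L)
  for (st in dmn_states()) {
    run <- drop_initial(sub$runs[[st]])
    mot <- sub$motion[[st]]
    mot$params <- mot$params[-(1:10), , drop = FALSE]
    met <- compute_frame_metrics(run, mot)
    expect_equal(sum(met$fd >= 0.5 & met$gs_change >= 0.5), 0L)
  }
})

test_that("motion spikes exceed both thresholds and respect the spacing", {
  sc <- tiny_scenario(motion_spike_rate = 4)
  hit <- 0L
  for (i in 1:4) {
    sub <- simulate_subject(sc, i, 31L)
    for (st in dmn_states()) {
      spikes <- sub$spikes[[st]]
      if (length(spikes) > 1L) expect_true(min(diff(spikes)) >= 5L)
      run <- drop_initial(sub$runs[[st]], 0L)  # keep frame indexing
      met <- compute_frame_metrics(run, sub$motion[[st]])
      over <- which(met$fd >= 0.5 & met$gs_change >= 0.5)
      expect_true(all(over %in% spikes))
      # spikes after frame 1 must be flagged (frame 1 has no predecessor)
      expect_true(all(setdiff(spikes, 1L) %in% over))
      hit <- hit + length(spikes)
    }
  }
  expect_gt(hit, 0L)
})

test_that("null behaviour coupling leaves RT uncorrelated with latent dFC", {
  sc <- make_scenario(behavior_coupling = list(rt = c(T1 = 0, T2 = 0),
                                               accuracy = c(T1 = 0, T2 = 0)))
  rs <- vapply(1:200, function(i) {
    cohort <- simulate_cohort(sc, seed = i)
    d <- cohort$latent_dfc
    x <- d$dfc[d$pair == "stable_decreasing" & d$state == "T1"]
    y <- cohort$behavior$rt_ms[cohort$behavior$state == "T1"]
    cor(x, y)
  }, 1)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("configured behaviour coupling is recovered across cohorts", {
  sc <- make_scenario(behavior_coupling = list(rt = c(T1 = 0.6, T2 = 0.6),
                                               accuracy = c(T1 = 0.6,
                                                            T2 = 0.6)))
  rs <- vapply(1:300, function(i) {
    cohort <- simulate_cohort(sc, seed = 5000L + i)
    d <- cohort$latent_dfc
    x <- d$dfc[d$pair == "stable_decreasing" & d$state == "T1"]
    y <- cohort$behavior$rt_ms[cohort$behavior$state == "T1"]
    cor(x, y)
  }, 1)
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("simulated group behaviour matches the configured population means", {
  sc <- make_scenario(n_subjects = 1000L)
  cohort <- simulate_cohort(sc, seed = 12L)
  beh <- cohort$behavior
  rt_t1 <- mean(beh$rt_ms[beh$state == "T1"])
  expect_lt(abs(rt_t1 - 1864) / 1864, 0.02)
  rt_t2 <- mean(beh$rt_ms[beh$state == "T2"])
  expect_lt(abs(rt_t2 - 1310) / 1310, 0.02)
  acc_t1 <- mean(beh$accuracy_pct[beh$state == "T1"])
  expect_lt(abs(acc_t1 - 97.8), 1)
  expect_true(all(beh$accuracy_pct <= 100 & beh$accuracy_pct >= 0))
  expect_true(all(beh$rt_ms > 0))
})

test_that("behaviour simulation rejects incomplete latent dFC tables", {
  sc <- make_scenario(n_subjects = 4L)
  cohort <- simulate_cohort(sc, 1L)
  broken <- cohort$latent_dfc[-1, ]
  expect_error(simulate_behavior(sc, broken), "incomplete")
})
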