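# Region detection: union mask, repeated-measures ANOVA, cluster
# filtering, classification, region assembly.

fake_map <- function(voxels, state = "R1", all_mask = 1:500) {
  structure(list(state = state, mask = all_mask, n = 8,
                 significant = voxels, significant_negative = integer(0)),
            class = "group_state_map")
}

test_that("union mask is the elementwise OR of the four state maps", {
  m <- list(R1 = fake_map(1:10), T1 = fake_map(11:20), T2 = fake_map(21:30),
            R2 = fake_map(31:40))
  u <- union_mask(m)
  expect_equal(u$voxels, 1:40)
  expect_equal(colSums(u$membership), c(R1 = 10L, T1 = 10L, T2 = 10L,
                                        R2 = 10L))
  same <- list(R1 = fake_map(5:15), T1 = fake_map(5:15), T2 = fake_map(5:15),
               R2 = fake_map(5:15))
  expect_equal(union_mask(same)$voxels, 5:15)
  # random overlapping masks equal a brute-force OR
  set.seed(8)
  rnd <- lapply(dmn_states(), function(s) fake_map(sample(500, 60), s))
  names(rnd) <- dmn_states()
  u2 <- union_mask(rnd)
  oracle <- sort(unique(unlist(lapply(rnd, `[[`, "significant"))))
  expect_equal(u2$voxels, oracle)
  for (st in dmn_states())
    expect_equal(u2$voxels[u2$membership[, st]],
                 sort(rnd[[st]]$significant))
  expect_error(union_mask(rnd[1:3]), "four")
})

test_that("RM-ANOVA matches the textbook sum-of-squares decomposition", {
  # 3 subjects x 4 states, one voxel, hand-checkable
  tab <- matrix(c(1.0, 1.2, 0.8,
                  0.7, 0.9, 0.6,
                  0.5, 0.6, 0.4,
                  1.1, 1.3, 0.9), nrow = 3)
  z <- lapply(1:4, function(j) matrix(tab[, j], 1L))
  names(z) <- dmn_states()
  res <- voxelwise_rm_anova(z, voxels = 42L, q = 0.05)
  # brute-force oracle
  grand <- mean(tab)
  ss_state <- 3 * sum((colMeans(tab) - grand)^2)
  ss_subj <- 4 * sum((rowMeans(tab) - grand)^2)
  ss_err <- sum((tab - outer(rowMeans(tab), colMeans(tab), `+`) + grand)^2)
  F_oracle <- (ss_state / 3) / (ss_err / 6)
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$df, c(3, 6))
  # independent route: stats::aov with subject error stratum
  df <- data.frame(y = as.numeric(tab),
                   subj = factor(rep(1:3, 4)),
                   state = factor(rep(dmn_states(), each = 3)))
  fit <- summary(stats::aov(y ~ state + Error(subj), data = df))
  F_aov <- fit[["Error: Within"]][[1]]["state", "F value"]
  expect_equal(res$F, F_aov, tolerance = 1e-8)
  p_aov <- fit[["Error: Within"]][[1]]["state", "Pr(>F)"]
  expect_equal(res$p, p_aov, tolerance = 1e-8)
})

test_that("RM-ANOVA returns F = 0, p = 1 when states are identical", {
  z1 <- matrix(rnorm(5 * 6), 5, 6)
  z <- list(R1 = z1, T1 = z1, T2 = z1, R2 = z1)
  res <- voxelwise_rm_anova(z, voxels = 1:5)
  expect_equal(res$F, rep(0, 5))
  expect_equal(res$p, rep(1, 5))
  expect_equal(length(res$significant), 0L)
})

test_that("the calibrated state profile is detected with high power at n = 16", {
  # profile of the stable-decreasing trajectory, subject SD 0.1, against
  # 50 state-constant voxels; FDR across the mask
  # a union-mask-like mixture: 10 voxels carry the trajectory, 41 are
  # state-constant
  means <- c(0.43, 0.35, 0.24, 0.45)
  set.seed(21)
  hits <- vapply(1:200, function(i) {
    z <- lapply(1:4, function(j)
      rbind(matrix(rnorm(10 * 16, means[j], 0.1), 10, 16),
            matrix(rnorm(41 * 16, 0.4, 0.1), 41, 16)))
    names(z) <- dmn_states()
    res <- voxelwise_rm_anova(z, voxels = 1:51)
    1L %in% res$significant
  }, TRUE)
  expect_gt(mean(hits), 0.95)
})

test_that("Greenhouse-Geisser correction bounds epsilon and deflates p", {
  set.seed(30)
  z <- lapply(1:4, function(j) matrix(rnorm(10 * 8, j / 10, 0.2), 10, 8))
  names(z) <- dmn_states()
  plain <- voxelwise_rm_anova(z, 1:10)
  gg <- voxelwise_rm_anova(z, 1:10, gg = TRUE)
  expect_true(all(gg$epsilon >= 1 / 3 - 1e-9 & gg$epsilon <= 1 + 1e-9))
  # the correction is conservative where the effect is non-trivial
  big <- plain$F > 2
  expect_true(all(gg$p[big] >= plain$p[big] - 1e-12))
  expect_equal(gg$F, plain$F)
})

test_that("cluster filtering retains only components larger than the threshold", {
  grid <- make_grid(c(12L, 12L, 12L), 3)
  blob5 <- block_voxels(grid, c(2L, 2L, 2L), c(5L, 1L, 1L))
  blob6 <- block_voxels(grid, c(2L, 8L, 8L), c(6L, 1L, 1L))
  out <- cluster_filter(c(blob5, blob6), grid)
  expect_equal(length(out), 1L)
  expect_equal(sort(out[[1]]), sort(blob6))
  expect_equal(cluster_filter(integer(0), grid), list())
  # vertex-touching blobs: one cluster under 26-connectivity, two under 6
  a <- block_voxels(grid, c(2L, 2L, 2L), 2L)
  b <- block_voxels(grid, c(4L, 4L, 4L), 2L)
  expect_equal(length(cluster_filter(c(a, b), grid, min_size = 5L,
                                     connectivity = 26L)), 1L)
  expect_equal(length(cluster_filter(c(a, b), grid, min_size = 5L,
                                     connectivity = 6L)), 2L)
})

test_that("connected components equal an exhaustive flood-fill oracle", {
  flood_oracle <- function(voxels, grid, connectivity) {
    off <- dmndyn:::neighbour_offsets(connectivity)
    remaining <- voxels
    comps <- list()
    while (length(remaining)) {
      queue <- remaining[1]
      comp <- integer(0)
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!(v %in% remaining)) next
        remaining <- setdiff(remaining, v)
        comp <- c(comp, v)
        nb <- sweep(off, 2L, index_to_ijk(grid, v), "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= grid$dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= grid$dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= grid$dims[3]
        cand <- ijk_to_index(grid, nb[ok, , drop = FALSE])
        queue <- c(queue, intersect(cand, remaining))
      }
      comps[[length(comps) + 1L]] <- sort(comp)
    }
    comps[order(-lengths(comps), vapply(comps, min, 1L))]
  }
  grid <- make_grid(c(8L, 8L, 8L), 3)
  set.seed(17)
  for (conn in c(6L, 26L)) for (i in 1:5) {
    vox <- sort(sample(512L, 60L))
    got <- dmndyn:::connected_components(vox, grid, conn)
    got <- lapply(got, sort)
    got <- got[order(-lengths(got), vapply(got, min, 1L))]
    expect_equal(got, flood_oracle(vox, grid, conn))
  }
})

test_that("retrospective classification separates decreasing and increasing", {
  n <- 12L
  mk <- function(profile, sdv = 0.02) lapply(1:4, function(j)
    matrix(rnorm(2 * n, profile[j], sdv), 2, n))
  z <- mk(c(0.5, 0.3, 0.3, 0.5))
  names(z) <- dmn_states()
  lab <- classify_voxels(z, voxels = 1:2, clusters = list(1:2))
  expect_equal(lab$label, c("decreasing", "decreasing"))
  z2 <- mk(c(0.05, 0.30, 0.34, 0.03))
  names(z2) <- dmn_states()
  lab2 <- classify_voxels(z2, voxels = 1:2, clusters = list(1:2))
  expect_equal(lab2$label, c("increasing", "increasing"))
  # task mean equal to rest mean for every subject -> unclassified
  z3 <- lapply(1:4, function(j) matrix(seq_len(n) / 10, 1L, n, byrow = TRUE))
  names(z3) <- dmn_states()
  expect_warning(lab3 <- classify_voxels(z3, voxels = 1L,
                                         clusters = list(1L)),
                 "unclassified")
  expect_equal(lab3$label, "unclassified")
  # deterministic sign: task exactly rest - 0.2
  z4 <- list(R1 = matrix(rnorm(n), 1L), T1 = NULL, T2 = NULL, R2 = NULL)
  z4$R2 <- z4$R1
  z4$T1 <- z4$R1 - 0.2
  z4$T2 <- z4$R1 - 0.2
  lab4 <- classify_voxels(z4, 1L, list(1L))
  expect_equal(lab4$label, "decreasing")
})

test_that("region assembly enforces the stable-region definition", {
  grid <- make_grid(c(12L, 12L, 12L), 3)
  blockA <- block_voxels(grid, c(2L, 2L, 2L), 2L)   # in all four maps
  blockB <- block_voxels(grid, c(8L, 8L, 8L), 2L)   # in three maps only
  maps <- list(R1 = fake_map(c(blockA, blockB)), T1 = fake_map(c(blockA, blockB)),
               T2 = fake_map(c(blockA, blockB)), R2 = fake_map(blockA))
  u <- union_mask(maps)
  labels <- data.frame(voxel = integer(0), t = numeric(0), p = numeric(0),
                       label = character(0))
  rs <- define_regions(labels, u, anova_sig = integer(0), grid,
                       seed = seed_spec(center_mm = voxel_to_mm(
                         grid, matrix(c(2, 2, 2), 1)), radius_mm = 3))
  stab <- regions_of(rs, "stable")
  expect_equal(length(stab), 1L)
  expect_equal(sort(stab[[1]]$voxels), sort(blockA))   # B is not stable
  expect_true(stab[[1]]$seed_region)
  # an ANOVA-significant voxel never lands in a stable region
  rs2 <- define_regions(labels, u, anova_sig = blockA[1:2], grid,
                        seed = seed_spec(center_mm = c(0, 0, 0),
                                         radius_mm = 3))
  stab2 <- regions_of(rs2, "stable")
  expect_false(any(blockA[1:2] %in% unlist(lapply(stab2, `[[`, "voxels"))))
  # classified clusters become regions of their class
  labels3 <- data.frame(voxel = blockB, t = -3, p = 0.01,
                        label = "decreasing", stringsAsFactors = FALSE)
  rs3 <- define_regions(labels3, u, anova_sig = blockB, grid,
                        seed = seed_spec(center_mm = c(0, 0, 0),
                                         radius_mm = 3))
  dec <- regions_of(rs3, "decreasing")
  expect_equal(length(dec), 1L)
  expect_equal(sort(dec[[1]]$voxels), sort(blockB))
})
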