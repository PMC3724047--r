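# Shared fixtures: small scenarios so unit tests stay fast.  All data is
# generated in code at test time.

# A compact three-region scenario on a small grid: one "stable" seed-like
# region, one whose coupling to it drops during task states, one whose
# coupling rises.  State matrices mirror the shape of the default
# calibration at reduced size.
tiny_scenario <- function(n_subjects = 4L, n_volumes = 60L, seed = 7L, ...) {
  grid <- make_grid(c(14L, 14L, 14L), 3, origin_mm = c(-36, -86, -28))
  regs <- list(
    planted_region("A", "stable", block_voxels(grid, c(3L, 3L, 3L), 3L), 1L),
    planted_region("B", "decreasing", block_voxels(grid, c(9L, 3L, 9L), 3L), 2L),
    planted_region("C", "increasing", block_voxels(grid, c(3L, 9L, 9L), 3L), 3L)
  )
  cov_of <- function(ab, ac) {
    m <- diag(3)
    m[1, 2] <- m[2, 1] <- ab
    m[1, 3] <- m[3, 1] <- ac
    m[2, 3] <- m[3, 2] <- 0.05
    m
  }
  ijk <- index_to_ijk(grid, seq_len(n_voxels(grid)))
  brain <- which(apply(ijk, 1L, function(v) all(v > 1L & v < 14L)))
  masks <- list(brain = brain,
                wm = block_voxels(grid, c(9L, 9L, 3L), 2L),
                csf = block_voxels(grid, c(12L, 9L, 3L), 2L))
  make_scenario(grid_shape = c(14L, 14L, 14L), n_subjects = n_subjects,
                n_volumes = n_volumes, region_layout = regs,
                state_covariance = list(R1 = cov_of(0.5, 0.05),
                                        T1 = cov_of(0.35, 0.3),
                                        T2 = cov_of(0.25, 0.35),
                                        R2 = cov_of(0.5, 0.05)),
                masks = masks, seed = seed, ...)
}

# One small preprocessable run with known content.
tiny_run <- function(n_volumes = 60L, seed = 7L, subject_sd = 0.05) {
  sc <- tiny_scenario(n_volumes = n_volumes, subject_sd = subject_sd)
  sub <- simulate_subject(sc, 1L, seed)
  list(scenario = sc, sub = sub)
}

# Deterministic synthetic run built directly from a matrix (no generator),
# for preprocessing-operation oracles.
matrix_run <- function(data, dims = c(6L, 6L, 6L), tr = 2,
                       brain = seq_len(prod(dims))) {
  grid <- make_grid(dims, 3)
  bold_run(data, grid, tr, "subX", "R1",
           masks = list(brain = brain, wm = brain[1:2], csf = brain[3:4]))
}

expect_no_error <- function(expr) expect_error(expr, NA)

# end-to-end pipeline on the tiny scenario, seeded at region A's centre
run_seed_pipeline_tiny <- function(sc, seed, ...) {
  centre <- colMeans(voxel_to_mm(sc$grid, index_to_ijk(
    sc$grid, sc$region_layout[[1]]$voxels)))
  run_seed_pipeline(sc, seed = seed,
                    seed_region = seed_spec(center_mm = centre,
                                            radius_mm = 5), ...)
}

# all-zero subject deviations (generator truth = group values)
subject_deviations_null <- function() {
  blocks <- default_block_targets()$block
  list(common = setNames(rep(0, 6), blocks),
       state = matrix(0, 6, 4, dimnames = list(blocks, dmn_states())))
}
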