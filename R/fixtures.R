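## NIfTI export of a voxels x frames matrix on a dmn_grid.
run_to_nifti <- function(data, grid) {
  arr <- array(data, c(grid$dims, ncol(data)))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, rep(grid$voxel_mm, 3))
  RNifti::`sform<-`(img, structure(grid_affine(grid), code = 2L))
}

## Logical volume for a voxel-index mask.
mask_to_nifti <- function(voxels, grid) {
  vol <- numeric(n_voxels(grid))
  vol[voxels] <- 1
  run_to_nifti(matrix(vol, ncol = 1L), grid)
}

#' Serialize a scenario to YAML
#'
#' Matrices become nested lists; [read_scenario_yaml()] restores an
#' equivalent scenario.
#'
#' @param scenario a [make_scenario()] object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_scenario_yaml <- function(scenario, path) {
  regs <- lapply(scenario$region_layout, function(r)
    list(name = r$name, system = r$system, latent = r$latent,
         voxels = as.integer(r$voxels)))
  obj <- list(
    grid_shape = as.integer(scenario$grid$dims),
    voxel_mm = scenario$grid$voxel_mm,
    n_subjects = scenario$n_subjects,
    n_volumes = scenario$n_volumes,
    tr = scenario$tr,
    subject_sd = scenario$subject_sd,
    subject_sd_common = scenario$subject_sd_common,
    noise_model = scenario$noise_model,
    motion_spike_rate = as.list(scenario$motion_spike_rate),
    motion = scenario$motion,
    behavior_coupling = lapply(scenario$behavior_coupling, as.list),
    behavior = lapply(scenario$behavior, as.list),
    seed = scenario$seed,
    masks = lapply(scenario$masks, as.integer),
    region_layout = regs,
    state_covariance = lapply(scenario$state_covariance, function(m)
      apply(unname(m), 1L, as.list, simplify = FALSE))
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  regs <- lapply(obj$region_layout, function(r)
    planted_region(r$name, r$system, unlist(r$voxels), r$latent))
  cov <- lapply(obj$state_covariance, function(m) {
    mm <- do.call(rbind, lapply(m, unlist))
    (mm + t(mm)) / 2
  })
  make_scenario(grid_shape = unlist(obj$grid_shape), voxel_mm = obj$voxel_mm,
                n_subjects = obj$n_subjects, n_volumes = obj$n_volumes,
                tr = obj$tr, region_layout = regs, state_covariance = cov,
                subject_sd = obj$subject_sd,
                subject_sd_common = obj$subject_sd_common,
                noise_model = obj$noise_model,
                motion_spike_rate = unlist(obj$motion_spike_rate),
                motion = obj$motion,
                behavior_coupling = lapply(obj$behavior_coupling, unlist),
                behavior = lapply(obj$behavior, unlist),
                masks = lapply(obj$masks, function(v) as.integer(unlist(v))),
                seed = obj$seed)
}

#' Write a cohort to disk as analysis-ready fixtures
#'
#' One gzipped NIfTI per subject and state (double precision, so
#' re-reading reproduces the arrays exactly), one 6-column whitespace-
#' delimited motion file per run, the brain/WM/CSF masks, the behaviour
#' TSV, the scenario YAML, and a manifest with MD5 checksums.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest (`file`, `md5`), invisibly written to
#'   `manifest.tsv` as well.
#' @export
write_fixtures <- function(cohort, out_dir) {
  scenario <- cohort$scenario
  if (scenario$n_subjects < 1L) stop("empty cohort")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir)
  files <- character(0)
  for (i in seq_len(scenario$n_subjects)) {
    sub <- simulate_subject(scenario, i, cohort$seed)
    for (st in dmn_states()) {
      base <- sprintf("%s_%s", sub$subject, st)
      nii <- file.path(out_dir, paste0(base, "_bold.nii.gz"))
      RNifti::writeNifti(run_to_nifti(sub$runs[[st]]$data, scenario$grid),
                         nii, datatype = "double")
      mot <- file.path(out_dir, paste0(base, "_motion.txt"))
      write.table(format(sub$motion[[st]]$params, digits = 17),
                  mot, row.names = FALSE, col.names = FALSE,
                  quote = FALSE)
      files <- c(files, nii, mot)
    }
  }
  for (mk in names(scenario$masks)) {
    f <- file.path(out_dir, sprintf("mask_%s.nii.gz", mk))
    RNifti::writeNifti(mask_to_nifti(scenario$masks[[mk]], scenario$grid), f,
                       datatype = "uint8")
    files <- c(files, f)
  }
  beh <- file.path(out_dir, "behavior.tsv")
  bt <- cohort$behavior
  names(bt) <- c("subject", "state", "rt_ms", "accuracy_pct")
  write.table(bt, beh, sep = "\t", row.names = FALSE, quote = FALSE)
  yml <- file.path(out_dir, "scenario.yaml")
  write_scenario_yaml(scenario, yml)
  files <- c(files, beh, yml)
  if (anyDuplicated(files)) stop("manifest collision")
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read one fixture run back as a `bold_run`
#'
#' @param path NIfTI file written by [write_fixtures()].
#' @param scenario the scenario (grid and masks).
#' @param subject,state labels to attach.
#' @return list with `run` ([bold_run()]) and `motion`
#'   ([motion_trace()]); the motion file is located next to the image.
#' @export
read_fixture_run <- function(path, scenario, subject, state) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  data <- matrix(arr, prod(dim(arr)[1:3]), dim(arr)[4])
  run <- bold_run(data, scenario$grid, scenario$tr, subject, state,
                  scenario$masks)
  mot_path <- sub("_bold\\.nii\\.gz$", "_motion.txt", path)
  motion <- motion_trace(as.matrix(read.table(mot_path)))
  list(run = run, motion = motion)
}
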