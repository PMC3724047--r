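#!/usr/bin/env Rscript

# Temporal preprocessing of the demonstration subjects written by
# 01_simulate_cohort.R: drop the first 10 volumes, smooth at 8 mm FWHM,
# band-pass 0.008-0.08 Hz, regress WM/CSF/global/6 motion parameters,
# and censor frames whose global-signal change and framewise
# displacement both reach their thresholds (0.5% / 0.5 mm), removing the
# frame before and the two after each flagged frame.

library(dmndyn)

scenario <- read_scenario_yaml("results/cohort/scenario.yaml")
scenario$n_subjects <- 2L
dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)

rows <- NULL
for (i in 1:2) {
  for (st in dmn_states()) {
    f <- sprintf("results/cohort/demo_subjects/sub%02d_%s_bold.nii.gz", i, st)
    fx <- read_fixture_run(f, scenario, sprintf("sub%02d", i), st)
    pp <- preprocess_run(fx$run, fx$motion)
    rep <- pp$report
    jsonlite::write_json(
      list(subject = fx$run$subject, state = st,
           flagged = rep$flagged, removed = rep$removed,
           n_removed = rep$n_removed, excluded = rep$excluded),
      sprintf("results/preprocess/sub%02d_%s_scrub.json", i, st),
      auto_unbox = TRUE)
    rows <- rbind(rows, data.frame(
      subject = fx$run$subject, state = st,
      frames_in = scenario$n_volumes, frames_out = n_frames(pp$run),
      n_flagged = length(rep$flagged), n_removed = rep$n_removed,
      excluded = rep$excluded))
  }
}
write.table(rows, "results/preprocess/scrub_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Scrubbing summary:\n")
print(rows)
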