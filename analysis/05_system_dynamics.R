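#!/usr/bin/env Rscript

# System-level connectivity dynamics: per-subject mean FC within and
# between the stable/decreasing/increasing systems at each state, and
# paired t-tests between consecutive states (plus the R1-R2 null check),
# FDR-corrected in one family.

library(dmndyn)

res <- readRDS("scratch/pipeline_state.rds")
dir.create("results/systems", showWarnings = FALSE, recursive = TRUE)

comp <- sprintf("sub%02d", res$complete)
gm <- group_mean_fc(res$summaries[res$summaries$subject %in% comp, ])
write.table(data.frame(measure = rownames(gm), round(gm, 4)),
            "results/systems/group_mean_fc.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(res$summaries, "results/systems/subject_summaries.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
tt <- res$transitions
write.table(tt, "results/systems/transition_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Group mean system FC by state:\n")
print(round(gm, 3))
cat("\nSystem-level transition tests:\n")
print(tt[tt$level == "system", ], row.names = FALSE)
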