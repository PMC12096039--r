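#!/usr/bin/env Rscript
# Variance partitioning and condition statistics on a small synthetic
# cohort: unique contributions (delta r) of music, self, other and
# coordination via full-vs-reduced generic prediction, electrode selection
# (delta r > 0), and the 2x2 repeated-measures ANOVA with Bonferroni
# correction across the four regressors.

suppressPackageStartupMessages(library(dyadtrf))
dir.create("results", showWarnings = FALSE)

cfg <- session_config(duration_s = 20, blocks = 2)  # scaled-down cohort
cat("Simulating and fitting 3 dyads (6 participants),",
    "full + 4 reduced models per participant and condition ...\n")
sessions <- lapply(derive_seeds(31, 3), function(s)
  standardize_session(make_session(cfg, s)))
participants <- unlist(lapply(sessions, `[[`, "participants"),
                       recursive = FALSE)
part <- trf_partition(participants, sessions[[1]]$conditions,
                      reduced_sets = list(music = "music", self = "self",
                                          other = "other",
                                          coordination = "coordination"))

an <- partition_anovas(part)
lay <- sessions[[1]]$layout
tab <- do.call(rbind, lapply(names(an), function(rg) {
  cbind(regressor = rg, n_electrodes = length(an[[rg]]$channels),
        an[[rg]]$anova$effects)
}))
cat("\n2x2 RM-ANOVA on electrode-averaged delta r (Bonferroni x4):\n")
print(tab, row.names = FALSE)
cat("\nThe key pattern is the coordination row: strong vision and music",
    "\nmain effects plus their interaction, because the coordination kernel",
    "\nis gated off without visual contact and damped under different music.",
    "\nAt this small demo scale other rows can also reach significance:",
    "\nwith only 6 participants the F tests are noisy, and the self",
    "\ncontribution genuinely varies with coupling (a visible partner moves",
    "\nin phase with the self, so the two velocity regressors share",
    "\nvariance and the unique self share shrinks).\n")
write.table(tab, "results/anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

dr_mean <- apply(part$delta_r, c(1, 3, 4), mean)   # channel x cond x reg
long <- expand.grid(channel = lay$label, condition = part$conditions,
                    regressor = dimnames(part$delta_r)[[4]],
                    KEEP.OUT.ATTRS = FALSE)
long$delta_r <- as.vector(dr_mean)
write.table(long, "results/delta_r_grand_average.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/anova.tsv and results/delta_r_grand_average.tsv\n")
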