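#!/usr/bin/env Rscript
# Fit full mTRF models on a small synthetic cohort (2 dyads) and read the
# recovered response waveforms at the channels of interest: Fz (music),
# C3/C4 average (self-movement), Oz (other-movement and coordination).

suppressPackageStartupMessages(library(dyadtrf))
dir.create("results", showWarnings = FALSE)

cat("Fitting subject TRFs for 2 dyads (4 participants), full model,",
    "leave-one-trial lambda selection ...\n")
cohort <- cohort_subject_trfs(n_dyads = 2, config = session_config(),
                              seed = 7, progress = TRUE)
win <- cohort$window
lay <- cohort$layout
vis <- c("yes/same", "yes/different")

wave <- function(conds, reg, labels) {
  g <- grand_average_trf(cohort, conds)
  rowMeans(trf_weights(g, reg)[, match(labels, lay$label), drop = FALSE])
}
tab <- data.frame(
  lag_ms = win$lag_ms,
  music_fz = wave(cohort$conditions, "music", "Fz"),
  self_c3c4 = wave(cohort$conditions, "self", c("C3", "C4")),
  other_oz = wave(vis, "other", "Oz"),
  coordination_oz = wave("yes/same", "coordination", "Oz"))
write.table(tab, "results/trf_waveforms.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

lat <- kernel_latency_report(cohort)
cat("\nRecovered TRF peak latencies (ms):\n")
print(round(lat))
cat("\nGround-truth kernel peaks: music +60/+120/+200, self -100/0/+80,",
    "\nother +70/+160, coordination -180/-90/+30/+160 ms.\n")
write.table(data.frame(regressor = names(lat), latency_ms = unname(lat)),
            "results/trf_latencies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/trf_waveforms.tsv and results/trf_latencies.tsv\n")
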