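#!/usr/bin/env Rscript
# Simulate one synthetic dyad session under the 2x2 (visual contact x
# musical input) design and summarize its structure: trial balance,
# coordination episode counts per condition, and regressor scales.

suppressPackageStartupMessages(library(dyadtrf))
dir.create("results", showWarnings = FALSE)

cfg <- session_config()
sess <- make_session(cfg, seed = 1)
cat("Simulated session:", nrow(sess$conditions), "trials x 2 participants,",
    cfg$duration_s, "s at", cfg$fs, "Hz\n")

cond <- paste(sess$conditions$vision, sess$conditions$music, sep = "/")
cat("Trials per condition:\n")
print(table(cond))

eps <- vapply(sess$participants[[1]], function(tr)
  coordination_episode_count(tr$regressors$coordination, cfg$fs), numeric(1))
summ <- aggregate(data.frame(episodes = eps), by = list(condition = cond),
                  FUN = mean)
cat("\nMean in-/anti-phase episode transitions per 40 s trial:\n")
print(summ, row.names = FALSE)
cat("\nWith visual contact and shared music the dyad alternates deliberately",
    "\nbetween coordination states; with different music the pair entrains at",
    "\na stable offset, and without vision the phases drift freely.\n")

write.table(data.frame(trial = sess$conditions$trial, condition = cond,
                       episodes = eps),
            "results/session_structure.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sd_tab <- as.data.frame(standardize_session(sess)$scales)
sd_tab$participant <- 1:2
write.table(sd_tab, "results/regressor_sd.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nWrote results/session_structure.tsv and results/regressor_sd.tsv\n")
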