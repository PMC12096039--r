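#!/usr/bin/env Rscript
# Event-related potentials from one synthetic session: music ERPs at Fz
# split into loud vs soft acoustic onsets (prestimulus baseline), and
# coordination ERPs at Oz split into changes to in-phase vs anti-phase
# (whole-epoch baseline), each with a cluster-based permutation contrast.

suppressPackageStartupMessages(library(dyadtrf))
dir.create("results", showWarnings = FALSE)

cfg <- session_config()
win <- lag_window()
cat("Simulating", 4, "dyads for per-participant ERP averages ...\n")
sessions <- lapply(derive_seeds(21, 4), function(s) make_session(cfg, s))
lay <- sessions[[1]]$layout
fz <- match("Fz", lay$label); oz <- match("Oz", lay$label)

erp_groups <- function(trials, channel, detect, baseline, split) {
  lo <- NULL; hi <- NULL
  for (tr in trials) {
    on <- detect(tr)
    if (nrow(on) < 10) next
    g <- split(on)
    ep <- epoch_eeg(tr$eeg[, channel], on$sample, win, baseline)
    keep <- function(idx) {
      sel <- which(ep$kept %in% idx)
      if (length(sel)) apply(ep$epochs[sel, , 1, drop = FALSE], 2, mean)
    }
    lo <- rbind(lo, keep(g$low)); hi <- rbind(hi, keep(g$high))
  }
  list(low = colMeans(lo), high = colMeans(hi))
}

rows <- list(); participant_means <- list(low = NULL, high = NULL)
for (si in seq_along(sessions)) for (p in 1:2) {
  trials <- sessions[[si]]$participants[[p]]
  g <- erp_groups(trials, fz,
                  detect = function(tr) detect_onsets(tr$regressors$music,
                                                      cfg$fs, salience_sd = 3),
                  baseline = "prestim",
                  split = function(on) split_extremes(on$amplitude))
  participant_means$low <- rbind(participant_means$low, g$low)
  participant_means$high <- rbind(participant_means$high, g$high)
}
res <- cluster_perm_test(participant_means$high, participant_means$low,
                         n_perm = 1000, seed = 3, lag_ms = win$lag_ms)
cat("Music ERP (Fz), loud vs soft onsets:", nrow(res$clusters),
    "cluster(s);")
if (nrow(res$clusters))
  cat(" strongest p =", round(min(res$clusters$p), 4),
      "spanning", res$clusters$start_ms[which.max(abs(res$clusters$mass))],
      "to", res$clusters$end_ms[which.max(abs(res$clusters$mass))], "ms")
cat("\n")
write.table(data.frame(lag_ms = win$lag_ms,
                       loud = colMeans(participant_means$high),
                       soft = colMeans(participant_means$low)),
            "results/erp_music_fz.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (nrow(res$clusters))
  write.table(res$clusters, "results/erp_music_clusters.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)

# coordination ERPs: changes to in-phase vs anti-phase at Oz
inph <- NULL; anti <- NULL
for (si in seq_along(sessions)) for (p in 1:2) {
  trials <- sessions[[si]]$participants[[p]]
  cond <- sessions[[si]]$conditions
  keep <- cond$vision == "yes" & cond$music == "same"
  mi <- NULL; ma <- NULL
  for (tr in trials[keep]) {
    trn <- coordination_transitions(tr$regressors$coordination,
                                    tr$regressors$velocity_sign_self,
                                    tr$regressors$velocity_sign_other, cfg$fs)
    ep <- epoch_eeg(tr$eeg[, oz], trn$sample, win, "whole_epoch")
    lab <- trn$transition[ep$kept]
    if (any(lab == "to_inphase"))
      mi <- rbind(mi, apply(ep$epochs[lab == "to_inphase", , 1,
                                      drop = FALSE], 2, mean))
    if (any(lab == "to_antiphase"))
      ma <- rbind(ma, apply(ep$epochs[lab == "to_antiphase", , 1,
                                      drop = FALSE], 2, mean))
  }
  inph <- rbind(inph, colMeans(mi)); anti <- rbind(anti, colMeans(ma))
}
res2 <- cluster_perm_test(inph, anti, n_perm = 1000, seed = 4,
                          lag_ms = win$lag_ms)
cat("Coordination ERP (Oz), in-phase vs anti-phase (vision+same music):",
    nrow(res2$clusters), "cluster(s)\n")
write.table(data.frame(lag_ms = win$lag_ms, to_inphase = colMeans(inph),
                       to_antiphase = colMeans(anti)),
            "results/erp_coordination_oz.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/erp_music_fz.tsv and results/erp_coordination_oz.tsv\n")
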