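#!/usr/bin/env Rscript
# Stage 5 -- statistical calibration of the whole chain.
#
# Two simulation checks at reduced size: (a) the cluster-level
# false-positive rate of the full pipeline on null cohorts (no injected
# effect) should be compatible with the nominal alpha = 0.05; (b) the
# injected central-frontal entropy decrease at the power-oracle magnitude
# (0.12) should be recovered in at least 80% of runs. The acceptance
# script repeats (a) with 200 runs; here 50 keep the stage quick.

source("analysis/00_config.R")

n_null <- 50
n_eff <- 25

run_null <- function(s) {
  cfg <- study_config(n_subjects = 8, conditions = "rest1",
                      features = "entropy",
                      eeg = eeg_sim_config(duration = 4, fs_native = 256),
                      seed = s)
  ct <- run_study(cfg)$eeg[["entropy:rest1"]]
  any(vapply(ct$clusters, function(cl) cl$p_value < 0.05, logical(1)))
}
fp <- vapply(seq_len(n_null), function(i) run_null(MASTER_SEED + i),
             logical(1))
ci <- binom.test(sum(fp), n_null, 0.05)$conf.int
cat(sprintf("null cluster FP rate: %.3f (%d/%d runs; 95%% CI %.3f-%.3f; nominal 0.05)\n",
            mean(fp), sum(fp), n_null, ci[1], ci[2]))

grp <- c("Fz", "FC1", "FC2", "Cz", "F3", "F4", "C3", "C4")
run_effect <- function(s) {
  ef <- list(effect_spec("entropy", grp, direction = -1, magnitude = 0.12))
  cfg <- study_config(n_subjects = 8, conditions = "rest1",
                      features = "entropy",
                      eeg = eeg_sim_config(duration = 6, fs_native = 256),
                      effects = ef, seed = s)
  ct <- run_study(cfg)$eeg[["entropy:rest1"]]
  any(vapply(ct$clusters, function(cl) cl$polarity < 0 && cl$p_value < 0.05,
             logical(1)))
}
rec <- vapply(seq_len(n_eff), function(i) run_effect(MASTER_SEED + 500 + i),
              logical(1))
cat(sprintf("entropy-effect recovery: %.0f%% (%d/%d runs; target >= 80%%)\n",
            100 * mean(rec), sum(rec), n_eff))

write.csv(data.frame(
  check = c("null_fp_rate", "entropy_effect_recovery"),
  value = c(mean(fp), mean(rec)),
  n_runs = c(n_null, n_eff)),
  file.path(RESULTS_DIR, "calibration.csv"), row.names = FALSE)
cat("wrote", file.path(RESULTS_DIR, "calibration.csv"), "\n")
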