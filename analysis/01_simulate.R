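#!/usr/bin/env Rscript
# Stage 1 -- synthetic cohort and behavioral data.
#
# Generates the paired baseline/follow-up cohort (EEG per condition, with
# injected artifacts and the configured follow-up effect), the Simon-task
# trial streams, recall counts for the two memory tasks, and the
# neuropsychological score table. Writes sample files and summary tables
# under results/simulated/.

source("analysis/00_config.R")

out <- file.path(RESULTS_DIR, "simulated")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- generate_subject_cohort(study_cfg$n_subjects, study_cfg$effects,
                                  study_cfg$eeg,
                                  conditions = study_cfg$conditions)

n_rec <- study_cfg$n_subjects * length(study_cfg$conditions) * 2
cat(sprintf("cohort: %d subjects x %d conditions x 2 sessions = %d recordings\n",
            study_cfg$n_subjects, length(study_cfg$conditions), n_rec))

# one recording round-tripped to EDF as a format sample, plus its ground
# truth artifact annotations
sample_rec <- cohort$subjects[[1]]$rest1$baseline
write_edf(sample_rec, file.path(out, "subject01_rest1_baseline.edf"))
write_annotations(cohort$subjects[[1]]$rest1$truth_baseline,
                  file.path(out, "subject01_rest1_baseline_truth.json"))

truth_counts <- table(unlist(lapply(cohort$subjects, function(su) {
  unlist(lapply(su, function(cond) {
    vapply(c(cond$truth_baseline, cond$truth_followup), `[[`,
           character(1), "reason")
  }))
})))
cat("injected artifact events by kind:\n")
print(truth_counts)

# behavioral streams (same seeds the study pipeline derives)
beh_seed <- study_cfg$seed + 500009L
simon_rows <- do.call(rbind, lapply(seq_len(study_cfg$n_subjects),
                                    function(s) {
  do.call(rbind, lapply(c(baseline = 1, followup = 2), function(sess) {
    tab <- generate_simon_session(
      congruency_effect_ms = study_cfg$behavior$congruency_effect_ms,
      seed = beh_seed + s * 7L + sess)
    tab$subject <- s
    tab$session <- names(c(baseline = 1, followup = 2))[sess]
    tab
  }))
}))
write.csv(simon_rows, file.path(out, "simon_trials.csv"), row.names = FALSE)

wp <- generate_recall_counts("wp", study_cfg$n_subjects, item_total = 60,
                             base_p = 0.36, seed = beh_seed + 101L)
vr <- generate_recall_counts("vr", study_cfg$n_subjects, item_total = 50,
                             base_p = 0.62, seed = beh_seed + 102L)
write.csv(rbind(wp, vr), file.path(out, "recall_counts.csv"),
          row.names = FALSE)
scores <- generate_score_table(default_score_measures(),
                               study_cfg$n_subjects, seed = beh_seed + 103L)
write.csv(scores, file.path(out, "score_table.csv"), row.names = FALSE)

cat(sprintf("simon: %d trials (%.0f%% congruent)\n",
            sum(simon_rows$session == "baseline" & simon_rows$subject == 1),
            100 * mean(simon_rows$condition == "congruent")))
cat(sprintf("recall medians: wp %.1f/%.1f, vr %.1f/%.1f (baseline/follow-up)\n",
            median(wp$baseline), median(wp$followup),
            median(vr$baseline), median(vr$followup)))
cat("wrote", out, "\n")
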