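# Shared desk-scale study configuration for the numbered analysis scripts.
# Sourced by 01-05. Edit here to change the whole workflow.

library(qeegpipe)

MASTER_SEED <- 20260101L

study_cfg <- study_config(
  n_subjects = 8,                      # cognitive-condition sample size
  conditions = c("rest1", "rest2", "wp_learning", "wp_recall",
                 "vr_learning", "simon"),
  features = c("hjorth_activity", "hjorth_mobility", "hjorth_complexity",
               "brain_rate", "entropy", "power"),
  eeg = eeg_sim_config(
    duration = 15,                     # seconds per condition recording
    fs_native = 256,                   # simulate at the analysis rate
    alpha_peak_hz = 10, alpha_amp_uv = 20, noise_amp_uv = 10,
    # one event of each kind per recording at this duration
    artifact_rates = c(blink = 4, muscle = 4, step = 4, flatline = 4)
  ),
  # the treatment hypothesis injected at follow-up: a central-frontal
  # entropy decrease at the magnitude chosen by the power oracle
  effects = list(
    effect_spec("entropy",
                c("Fz", "FC1", "FC2", "Cz", "F3", "F4", "C3", "C4"),
                direction = -1, magnitude = 0.12)
  ),
  seed = MASTER_SEED
)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)
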