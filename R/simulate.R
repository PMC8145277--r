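# Synthetic paired-session EEG generator.
#
# Recordings are composed in the frequency domain: 1/f (pink) background
# noise per channel, a posterior-weighted narrowband alpha rhythm, and
# optional session effects applied as band-power multipliers, whole-channel
# gain, or burst amplitude modulation. Everything is a pure function of
# (config, seed).

#' Simulation configuration
#'
#' @param duration Recording length in seconds.
#' @param fs_native Sampling rate in Hz (acquisition hardware default
#'   2500 Hz; simulations for fast tests may generate directly at 256 Hz —
#'   the downstream contract is rate-agnostic).
#' @param alpha_peak_hz Center of the background alpha rhythm (Hz).
#' @param alpha_amp_uv RMS amplitude of the alpha component on the most
#'   posterior channels (microvolt).
#' @param noise_amp_uv RMS amplitude of the 1/f background noise (microvolt).
#' @param pink_slope Spectral exponent of the background noise (power ~
#'   1/f^slope).
#' @param artifact_rates Named numeric, events per minute for each artifact
#'   kind: `blink`, `muscle`, `step`, `flatline`.
#' @param seed Integer RNG seed.
#' @return An `eeg_sim_config` list.
#' @export
eeg_sim_config <- function(duration = 60, fs_native = 2500,
                           alpha_peak_hz = 10, alpha_amp_uv = 20,
                           noise_amp_uv = 10, pink_slope = 1,
                           artifact_rates = c(blink = 0, muscle = 0,
                                              step = 0, flatline = 0),
                           seed = 1L) {
  stopifnot(duration > 0, fs_native >= 256,
            alpha_peak_hz > 0, alpha_amp_uv >= 0, noise_amp_uv >= 0,
            all(artifact_rates >= 0))
  rates <- c(blink = 0, muscle = 0, step = 0, flatline = 0)
  rates[names(artifact_rates)] <- artifact_rates
  structure(
    list(duration = duration, fs_native = fs_native,
         alpha_peak_hz = alpha_peak_hz, alpha_amp_uv = alpha_amp_uv,
         noise_amp_uv = noise_amp_uv, pink_slope = pink_slope,
         artifact_rates = rates, seed = as.integer(seed)),
    class = "eeg_sim_config"
  )
}

#' Session effect specification
#'
#' Describes one hypothesized treatment effect injected into follow-up
#' recordings. Effects act in the generative domain (band-power or waveform
#' manipulation), never on computed feature values, so the feature code is
#' exercised honestly.
#'
#' @param feature_name One of `hjorth_activity`, `hjorth_mobility`,
#'   `hjorth_complexity`, `brain_rate`, `entropy`, `power`.
#' @param electrode_group Non-empty subset of montage labels.
#' @param direction +1 or -1.
#' @param magnitude Non-negative fraction of the baseline feature scale.
#' @param frequency_band Length-2 Hz range; required for `power`.
#' @export
effect_spec <- function(feature_name, electrode_group, direction = 1,
                        magnitude = 0.1, frequency_band = NULL) {
  feature_name <- match.arg(feature_name,
                            c("hjorth_activity", "hjorth_mobility",
                              "hjorth_complexity", "brain_rate", "entropy",
                              "power"))
  stopifnot(length(electrode_group) >= 1, magnitude >= 0,
            direction %in% c(-1, 1))
  if (feature_name == "power" && is.null(frequency_band)) {
    stop("power effects need a frequency_band")
  }
  structure(
    list(feature_name = feature_name,
         electrode_group = as.character(electrode_group),
         direction = direction, magnitude = magnitude,
         frequency_band = frequency_band),
    class = "effect_spec"
  )
}

# Posterior weighting of the alpha rhythm: strongest over occipital/parietal
# sites, weak frontally.
.alpha_weights <- function(montage) {
  y <- montage$positions[, "y"]
  w <- 0.2 + 0.8 * pmax(0, -y)
  stats::setNames(w, montage$labels)
}

# Frontal coupling map for ocular (blink) activity.
.blink_weights <- function(montage) {
  y <- montage$positions[, "y"]
  z <- montage$positions[, "z"]
  w <- pmax(0, y)^2 * pmax(0.2, 1 - z)
  w <- w / max(w)
  stats::setNames(w, montage$labels)
}

# Narrowband or 1/f random process via frequency-domain synthesis.
# Returns a length-n series with approximately the requested RMS.
.fft_noise <- function(n, fs, amp_fun, rms) {
  freqs <- seq(0, fs / 2, by = fs / n)
  nf <- length(freqs)
  mag <- amp_fun(freqs)
  mag[1] <- 0
  phases <- stats::runif(nf, 0, 2 * pi)
  spec <- mag * exp(1i * phases)
  # hermitian completion
  if (n %% 2 == 0) {
    full <- c(spec, Conj(rev(spec[2:(nf - 1)])))
  } else {
    full <- c(spec, Conj(rev(spec[2:nf])))
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x * (rms / s)
  x
}

# Translate feature-level effect specs into generative manipulations:
# per-channel band multipliers (applied to the noise spectrum), channel
# gain, alpha gain, and burst-AM depth.
.effect_plan <- function(effects, labels) {
  plan <- list(
    band_mult = list(),   # list of list(channels, band, mult)
    gain = stats::setNames(rep(1, length(labels)), labels),
    alpha_gain = stats::setNames(rep(1, length(labels)), labels),
    burst = stats::setNames(rep(0, length(labels)), labels)
  )
  for (ef in effects) {
    stopifnot(inherits(ef, "effect_spec"))
    ch <- intersect(ef$electrode_group, labels)
    if (length(ch) == 0) stop("effect electrode_group not in montage")
    d <- ef$direction
    m <- ef$magnitude
    switch(ef$feature_name,
      power = {
        plan$band_mult[[length(plan$band_mult) + 1]] <-
          list(channels = ch, band = ef$frequency_band, mult = 1 + d * m)
      },
      hjorth_activity = {
        plan$gain[ch] <- plan$gain[ch] * sqrt(pmax(0.05, 1 + d * m))
      },
      hjorth_mobility = ,
      brain_rate = {
        # shift spectral mass toward (d = +1) or away from high frequencies
        plan$band_mult[[length(plan$band_mult) + 1]] <-
          list(channels = ch, band = c(13, 45), mult = pmax(0.05, 1 + d * m))
        plan$band_mult[[length(plan$band_mult) + 1]] <-
          list(channels = ch, band = c(0.5, 5), mult = pmax(0.05, 1 - d * m))
      },
      hjorth_complexity = {
        # widen (+) or narrow (-) the occupied bandwidth around alpha
        plan$band_mult[[length(plan$band_mult) + 1]] <-
          list(channels = ch, band = c(0.5, 4), mult = pmax(0.05, 1 + d * m))
        plan$band_mult[[length(plan$band_mult) + 1]] <-
          list(channels = ch, band = c(25, 45), mult = pmax(0.05, 1 + d * m))
        plan$alpha_gain[ch] <- plan$alpha_gain[ch] * pmax(0.05, 1 - d * m / 2)
      },
      entropy = {
        if (d < 0) {
          # burst amplitude modulation concentrates the amplitude histogram
          plan$burst[ch] <- pmax(plan$burst[ch], 6 * m)
        } else {
          # more broadband, Gaussian-like signal raises binned entropy
          plan$band_mult[[length(plan$band_mult) + 1]] <-
            list(channels = ch, band = c(0.5, 45), mult = 1 + m)
          plan$alpha_gain[ch] <- plan$alpha_gain[ch] * pmax(0.05, 1 - m)
        }
      }
    )
  }
  plan
}

# Apply band multipliers to one channel series in the frequency domain
# (multiplies amplitude by sqrt(mult) so power scales by mult).
.apply_band_mults <- function(x, fs, mults) {
  if (length(mults) == 0) return(x)
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # mirror for negative frequencies
  for (bm in mults) {
    sel <- freqs >= bm$band[1] & freqs < bm$band[2]
    X[sel] <- X[sel] * sqrt(bm$mult)
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Piecewise-constant burst envelope: mostly 1, occasional 0.25-s segments
# with gain (1 + depth). Sub-epoch bursts make the per-epoch amplitude
# distribution a leptokurtic scale mixture: the range (hence the bin grid)
# stretches while most samples stay in the central bins, lowering the
# binned entropy.
.burst_envelope <- function(n, fs, depth, duty = 0.25) {
  seg <- max(1L, as.integer(round(fs / 4)))
  nseg <- ceiling(n / seg)
  gains <- ifelse(stats::runif(nseg) < duty, 1 + depth, 1)
  rep(gains, each = seg)[seq_len(n)]
}

#' Generate a continuous synthetic EEG recording
#'
#' @param montage A `montage_spec`.
#' @param config An `eeg_sim_config`.
#' @param effects Optional list of `effect_spec` applied to this recording
#'   (used for follow-up sessions of a cohort).
#' @param subject_scale Optional named list with `alpha` and `noise`
#'   multipliers modelling stable subject-level variation.
#' @return A `raw_recording`: list with `data` (channels x samples matrix,
#'   microvolt; rows = 29 scalp labels plus the EOG channel), `fs`, `labels`,
#'   `montage`, `annotations` (empty list).
#' @export
generate_recording <- function(montage, config, effects = list(),
                               subject_scale = list(alpha = 1, noise = 1)) {
  stopifnot(inherits(montage, "montage_spec"),
            inherits(config, "eeg_sim_config"))
  fs <- config$fs_native
  n <- as.integer(round(config$duration * fs))
  labels <- c(montage$labels, montage$eog_label)
  plan <- .effect_plan(effects, montage$labels)
  aw <- .alpha_weights(montage)
  set.seed(config$seed)

  slope <- config$pink_slope
  pink_amp <- function(f) ifelse(f > 0, f^(-slope / 2), 0)
  alpha_amp <- function(f) exp(-(f - config$alpha_peak_hz)^2 / (2 * 0.6^2))

  data <- matrix(0, nrow = length(labels), ncol = n,
                 dimnames = list(labels, NULL))
  for (ch in montage$labels) {
    noise <- .fft_noise(n, fs, pink_amp,
                        config$noise_amp_uv * subject_scale$noise)
    noise <- .apply_band_mults(
      noise, fs, Filter(function(bm) ch %in% bm$channels, plan$band_mult))
    alpha <- .fft_noise(n, fs, alpha_amp,
                        config$alpha_amp_uv * aw[[ch]] *
                          subject_scale$alpha * plan$alpha_gain[[ch]])
    x <- (noise + alpha) * plan$gain[[ch]]
    if (plan$burst[[ch]] > 0) {
      x <- x * .burst_envelope(n, fs, plan$burst[[ch]])
    }
    data[ch, ] <- x
  }
  # quiet ocular channel baseline; blink transients are added by
  # inject_artifacts
  data[montage$eog_label, ] <- .fft_noise(n, fs, pink_amp, 3)

  structure(
    list(data = data, fs = fs, labels = labels, montage = montage,
         annotations = list()),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2), " s), ",
      length(x$annotations), " annotations\n", sep = "")
  invisible(x)
}

# One artifact annotation. Intervals are half-open sample ranges [start, end)
# with 0-based indices (time t = index / fs).
artifact_annotation <- function(start, end, channels, reason) {
  stopifnot(start < end, is.character(channels))
  list(start = as.integer(start), end = as.integer(end),
       channels = channels, reason = reason)
}

#' Inject stereotyped artifacts with ground truth
#'
#' Adds blink transients (400-ms raised cosine, frontally weighted and
#' mirrored on the EOG channel), broadband muscle bursts (>20 Hz), step
#' transients, and flatline segments at the per-minute rates in `config`,
#' and returns the exact ground-truth annotation of every event.
#'
#' @param rec A `raw_recording` at its native rate.
#' @param config The `eeg_sim_config` (uses `artifact_rates` and `seed`).
#' @return List with `recording` (modified copy) and `truth` (list of
#'   annotations, each `list(start, end, channels, reason)` in half-open
#'   0-based samples).
#' @export
inject_artifacts <- function(rec, config) {
  stopifnot(inherits(rec, "raw_recording"), inherits(config, "eeg_sim_config"))
  fs <- rec$fs
  n <- ncol(rec$data)
  rates <- config$artifact_rates
  minutes <- n / fs / 60
  counts <- vapply(rates, function(r) as.integer(round(r * minutes)),
                   integer(1))
  durations <- c(blink = 0.4, muscle = 0.5, step = 0.3, flatline = 2.0)
  total_needed <- sum(counts * (durations[names(counts)] + 0.5))
  if (total_needed > n / fs) {
    stop("artifact rates produce more events than fit in the recording")
  }
  if (sum(counts) == 0) {
    return(list(recording = rec, truth = list()))
  }

  set.seed(config$seed + 104729L)
  montage <- rec$montage
  bw <- .blink_weights(montage)
  scalp <- montage$labels
  temporal <- intersect(c("T7", "T8", "F7", "F8", "FC5", "FC6", "TP9", "TP10"),
                        scalp)
  truth <- list()
  # lay events on a jittered grid so they never overlap
  n_events <- sum(counts)
  kinds <- rep(names(counts), counts)
  kinds <- sample(kinds)
  slot_len <- floor(n / n_events)
  data <- rec$data
  for (i in seq_len(n_events)) {
    kind <- kinds[i]
    dur <- as.integer(round(durations[[kind]] * fs))
    slot0 <- (i - 1L) * slot_len
    margin <- slot_len - dur - 1L
    if (margin < 1L) stop("artifact rates produce overlapping events")
    start <- slot0 + sample.int(margin, 1)  # 0-based
    idx <- (start + 1L):(start + dur)
    chans <- switch(kind,
      blink = {
        tmpl <- 250 * 0.5 * (1 - cos(2 * pi * seq_len(dur) / dur))
        affected <- names(bw)[bw > 0.1]
        for (ch in affected) data[ch, idx] <- data[ch, idx] + bw[[ch]] * tmpl
        data[montage$eog_label, idx] <- data[montage$eog_label, idx] + tmpl
        affected
      },
      muscle = {
        ch <- sample(temporal, min(2, length(temporal)))
        for (cc in ch) {
          burst <- .fft_noise(dur, fs,
                              function(f) as.numeric(f >= 20 & f <= min(90, fs / 2 - 1)),
                              90)
          data[cc, idx] <- data[cc, idx] + burst
        }
        ch
      },
      step = {
        ch <- sample(scalp, 1)
        data[ch, idx] <- data[ch, idx] + 300
        ch
      },
      flatline = {
        ch <- sample(scalp, 1)
        data[ch, idx] <- data[ch, idx[1]]
        ch
      })
    truth[[length(truth) + 1]] <-
      artifact_annotation(start, start + dur, chans, kind)
  }
  rec$data <- data
  rec$annotations <- truth
  list(recording = rec, truth = truth)
}

# Deterministic seed-splitting rule: each subject owns a disjoint block of
# seeds, so adding subjects never perturbs earlier ones.
.subject_seed <- function(master, subject, session, slot) {
  as.integer((master %% 100000L) * 20011L + subject * 1009L +
               session * 211L + slot)
}

#' Generate a paired baseline/follow-up cohort
#'
#' Per subject and EEG condition, generates one baseline and one follow-up
#' recording. Subject-level variation (stable alpha and noise gain) is shared
#' across both sessions of a pair; small session-level gain jitter creates
#' within-pair variability. Follow-up recordings carry the injected
#' `effects`; with `effects = list()` the cohort is a true null.
#'
#' @param n_subjects Integer >= 2.
#' @param effects List of `effect_spec` applied at follow-up.
#' @param config An `eeg_sim_config`; its `seed` is the master seed.
#' @param conditions Character vector of EEG conditions.
#' @return A `cohort` list: per subject, per condition, `baseline` and
#'   `followup` `raw_recording`s (artifacts injected at the configured
#'   rates), plus the per-event ground truth.
#' @export
generate_subject_cohort <- function(n_subjects, effects, config,
                                    conditions = c("rest1", "rest2",
                                                   "wp_learning", "wp_recall",
                                                   "vr_learning", "simon")) {
  stopifnot(n_subjects >= 2, inherits(config, "eeg_sim_config"))
  if (length(conditions) == 0) stop("condition list must be non-empty")
  montage <- generate_montage()
  master <- config$seed
  cohort <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(.subject_seed(master, s, 0L, 0L))
    subj <- list(alpha = exp(stats::rnorm(1, 0, 0.15)),
                 noise = exp(stats::rnorm(1, 0, 0.10)))
    per_cond <- list()
    for (ci in seq_along(conditions)) {
      sessions <- list()
      for (sess in 1:2) {
        set.seed(.subject_seed(master, s, sess, ci))
        jitter <- exp(stats::rnorm(1, 0, 0.05))
        cfg <- config
        cfg$seed <- .subject_seed(master, s, sess, 100L + ci)
        scale <- list(alpha = subj$alpha * jitter, noise = subj$noise * jitter)
        ef <- if (sess == 2) effects else list()
        rec <- generate_recording(montage, cfg, effects = ef,
                                  subject_scale = scale)
        inj <- inject_artifacts(rec, cfg)
        sessions[[sess]] <- inj
      }
      per_cond[[conditions[ci]]] <- list(baseline = sessions[[1]]$recording,
                                         followup = sessions[[2]]$recording,
                                         truth_baseline = sessions[[1]]$truth,
                                         truth_followup = sessions[[2]]$truth)
    }
    cohort[[s]] <- per_cond
  }
  structure(list(subjects = cohort, conditions = conditions,
                 n_subjects = n_subjects, master_seed = master),
            class = "cohort")
}
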