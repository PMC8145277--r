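# Synthetic behavioral data: Simon-task trial streams, recall counts for the
# two memory tasks, and paired neuropsychological score tables.

#' Generate one Simon-task session
#'
#' Trials come in blocks with an exact (count-based, not expected)
#' congruent/incongruent split, randomized within block. Reaction times
#' follow a shifted lognormal with an additive congruency effect, so the
#' incongruent - congruent median difference equals `congruency_effect_ms`
#' in expectation.
#'
#' @param n_trials Total trials (default 400).
#' @param block_size Trials per block (default 100).
#' @param p_congruent Proportion congruent per block (default 0.6); must
#'   yield an integer count per block.
#' @param congruency_effect_ms Additive slowdown for incongruent trials (ms).
#' @param rt_shift_ms,rt_meanlog,rt_sdlog Shifted-lognormal RT parameters:
#'   RT = shift + lognormal(meanlog, sdlog) (+ effect if incongruent).
#'   Defaults give a congruent median near 462 ms.
#' @param p_correct Named accuracy probabilities for `congruent` and
#'   `incongruent` trials.
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `task`, `trial_index`, `block`,
#'   `condition`, `rt_ms`, `correct`.
#' @export
generate_simon_session <- function(n_trials = 400, block_size = 100,
                                   p_congruent = 0.6,
                                   congruency_effect_ms = 48,
                                   rt_shift_ms = 200,
                                   rt_meanlog = log(262), rt_sdlog = 0.3,
                                   p_correct = c(congruent = 0.99,
                                                 incongruent = 0.96),
                                   seed = 1L) {
  stopifnot(n_trials > 0, block_size > 0, p_congruent > 0, p_congruent < 1)
  if (n_trials %% block_size != 0) {
    stop("n_trials must be divisible by block_size")
  }
  n_con <- p_congruent * block_size
  if (abs(n_con - round(n_con)) > 1e-9) {
    stop("p_congruent * block_size must be an integer")
  }
  n_con <- as.integer(round(n_con))
  n_blocks <- n_trials %/% block_size
  set.seed(seed)
  condition <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(c("congruent", "incongruent"),
               c(n_con, block_size - n_con)))
  }))
  inc <- condition == "incongruent"
  rt <- rt_shift_ms + stats::rlnorm(n_trials, rt_meanlog, rt_sdlog) +
    ifelse(inc, congruency_effect_ms, 0)
  correct <- stats::runif(n_trials) <
    ifelse(inc, p_correct[["incongruent"]], p_correct[["congruent"]])
  data.frame(
    task = "simon",
    trial_index = seq_len(n_trials),
    block = rep(seq_len(n_blocks), each = block_size),
    condition = condition,
    rt_ms = rt,
    correct = correct,
    stringsAsFactors = FALSE
  )
}

#' Generate paired recall counts for a memory task
#'
#' Counts are binomial with a stable subject-level recall probability
#' (logit-normal across subjects) shared between sessions; a session effect
#' shifts the follow-up probability by `effect` items in expectation.
#'
#' @param task Identifier, e.g. `"wp"` (word pairs, 60 items) or `"vr"`
#'   (virtual-town details).
#' @param n_subjects Number of paired subjects.
#' @param item_total Maximum recallable items.
#' @param effect Expected follow-up minus baseline count (items; may be
#'   negative).
#' @param base_p Population mean recall probability.
#' @param subject_sd SD of subject effects on the logit scale.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `task`, `subject`, `baseline`,
#'   `followup`; all counts in `[0, item_total]`.
#' @export
generate_recall_counts <- function(task = "wp", n_subjects = 12,
                                   item_total = 60, effect = 0,
                                   base_p = 0.36, subject_sd = 0.5,
                                   seed = 1L) {
  stopifnot(item_total > 0, n_subjects >= 1)
  set.seed(seed)
  p_subj <- stats::plogis(stats::qlogis(base_p) +
                            stats::rnorm(n_subjects, 0, subject_sd))
  p_follow <- pmin(1, pmax(0, p_subj + effect / item_total))
  data.frame(
    task = task,
    subject = seq_len(n_subjects),
    baseline = stats::rbinom(n_subjects, item_total, p_subj),
    followup = stats::rbinom(n_subjects, item_total, p_follow),
    stringsAsFactors = FALSE
  )
}

#' Generate paired neuropsychological score tables
#'
#' Emulates a battery of paired integer scales (screening instruments and
#' subscales) at the summary level the statistics consume: a stable subject
#' latent score plus independent session noise, rounded and clipped to the
#' scale range.
#'
#' @param measures data.frame with columns `measure`, `minimum`, `maximum`,
#'   `mean`, `sd_between`, `sd_within`, and optional `effect` (expected
#'   follow-up shift in scale units).
#' @param n_subjects Number of paired subjects.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `measure`, `subject`, `baseline`,
#'   `followup` (integers within each scale range).
#' @export
generate_score_table <- function(measures, n_subjects = 12, seed = 1L) {
  stopifnot(is.data.frame(measures), n_subjects >= 1)
  if (is.null(measures$effect)) measures$effect <- 0
  set.seed(seed)
  rows <- lapply(seq_len(nrow(measures)), function(i) {
    m <- measures[i, ]
    latent <- stats::rnorm(n_subjects, m$mean, m$sd_between)
    clip <- function(x) pmin(m$maximum, pmax(m$minimum, round(x)))
    data.frame(
      measure = m$measure,
      subject = seq_len(n_subjects),
      baseline = clip(latent + stats::rnorm(n_subjects, 0, m$sd_within)),
      followup = clip(latent + m$effect +
                        stats::rnorm(n_subjects, 0, m$sd_within)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Default neuropsychological battery for simulation
#'
#' A compact stand-in for the screening battery (adverse events, executive
#' screening, verbal memory, mood, impulsiveness): plausible scale ranges
#' and variabilities for paired integer scores, all with zero true effect
#' unless overridden.
#'
#' @return data.frame accepted by [generate_score_table()].
#' @export
default_score_measures <- function() {
  data.frame(
    measure = c("aep_total", "epitrack_total", "vlmt_learning",
                "hads_anxiety", "hads_depression", "bsi_total"),
    minimum = c(0, 0, 0, 0, 0, 30),
    maximum = c(88, 49, 75, 21, 21, 120),
    mean = c(36, 32, 52, 5, 2, 60),
    sd_between = c(8, 5, 9, 3, 1.5, 10),
    sd_within = c(4, 2.5, 5, 1.5, 1, 5),
    stringsAsFactors = FALSE
  )
}
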