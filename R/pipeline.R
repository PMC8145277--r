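# Study orchestration: generate (or load) a paired cohort, preprocess every
# recording, extract features, run every feature x condition cluster
# contrast and the behavioral Wilcoxon/Benjamini-Hochberg table.

#' Study configuration
#'
#' @param n_subjects Paired subjects in the cohort (default 8, the cognitive
#'   EEG sample size; resting contrasts in the original design use 10).
#' @param conditions EEG conditions to simulate and analyze. `simon` is
#'   automatically split into congruent/incongruent at the feature stage.
#' @param features Feature families for the EEG contrasts.
#' @param eeg An `eeg_sim_config` for the cohort generator (desk-scale
#'   default: 20-s recordings generated directly at 256 Hz).
#' @param effects List of `effect_spec` injected at follow-up (empty = null
#'   cohort).
#' @param stats List with `cluster_alpha`, `alpha`, `max_exact_n`.
#' @param behavior List with `congruency_effect_ms`, `recall_effect`,
#'   `score_effect`.
#' @param seed Master seed; every stochastic stage derives from it.
#' @return A `study_config`.
#' @export
study_config <- function(n_subjects = 8,
                         conditions = c("rest1", "rest2", "wp_learning",
                                        "wp_recall", "vr_learning", "simon"),
                         features = c("hjorth_activity", "hjorth_mobility",
                                      "hjorth_complexity", "brain_rate",
                                      "entropy"),
                         eeg = NULL, effects = list(),
                         stats = list(cluster_alpha = 0.05, alpha = 0.05,
                                      max_exact_n = 14),
                         behavior = list(congruency_effect_ms = 48,
                                         recall_effect = 0,
                                         score_effect = 0),
                         seed = 1L) {
  if (length(conditions) == 0) stop("condition list must be non-empty")
  if (is.null(eeg)) {
    eeg <- eeg_sim_config(duration = 20, fs_native = 256, seed = seed)
  }
  eeg$seed <- as.integer(seed)
  structure(
    list(n_subjects = n_subjects, conditions = conditions,
         features = features, eeg = eeg, effects = effects, stats = stats,
         behavior = behavior, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Split Simon-task epochs by trial congruency
#'
#' Maps each 1-s epoch to a trial of the session's trial stream (epoch i to
#' trial `(i - 1) mod n_trials + 1`) and splits the epoch set into
#' congruent and incongruent subsets before feature averaging.
#'
#' @param epochs An `epoch_set` from the Simon condition.
#' @param trials A trial table from [generate_simon_session()].
#' @return Named list of two `epoch_set`s: `simon_congruent`,
#'   `simon_incongruent`.
#' @export
split_simon_epochs <- function(epochs, trials) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- dim(epochs$epochs)[1]
  cond <- trials$condition[((seq_len(n_ep) - 1) %% nrow(trials)) + 1]
  out <- lapply(c(congruent = "congruent", incongruent = "incongruent"),
                function(cc) {
    sel <- which(cond == cc)
    sub <- epochs
    sub$epochs <- epochs$epochs[sel, , , drop = FALSE]
    sub$epoch_starts <- epochs$epoch_starts[sel]
    sub$condition <- paste0("simon_", cc)
    sub
  })
  names(out) <- c("simon_congruent", "simon_incongruent")
  out
}

# subject x electrode (or electrode@freq) matrix for one feature/condition/
# session from the tidy feature table
.feature_matrix <- function(tab, feature, condition, session, nodes) {
  sel <- tab[tab$feature == feature & tab$condition == condition &
               tab$session == session, ]
  subjects <- sort(unique(sel$subject))
  node_of <- if (feature == "power") {
    paste0(sel$electrode, "@", sel$freq)
  } else {
    sel$electrode
  }
  m <- matrix(NA_real_, nrow = length(subjects), ncol = length(nodes),
              dimnames = list(subjects, nodes))
  m[cbind(match(sel$subject, subjects), match(node_of, nodes))] <- sel$value
  m
}

#' Run the full desk-scale study
#'
#' Generates the paired cohort, preprocesses every recording, extracts the
#' configured features, runs a cluster-based permutation test for every
#' feature x EEG-condition contrast (baseline vs follow-up), and computes
#' the behavioral Wilcoxon/Benjamini-Hochberg table. Fully reproducible
#' from `(config, seed)`.
#'
#' @param config A `study_config`.
#' @param verbose Log stage boundaries with epoch/interval counts.
#' @return A `study_report`: list with `feature_table`, `eeg` (named list of
#'   `cluster_test`s, one per feature x condition), `behavioral`
#'   (Table-style data.frame), `provenance`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_subject_cohort(config$n_subjects, config$effects,
                                    config$eeg,
                                    conditions = config$conditions)
  graph <- build_neighbor_graph(generate_montage())

  # behavioral streams: paired Simon sessions (stable subject speed,
  # identical congruency effect in both sessions), recall counts, scores
  beh_seed <- config$seed + 500009L
  simon <- lapply(seq_len(config$n_subjects), function(s) {
    set.seed(beh_seed + s)
    subj_meanlog <- log(262) + stats::rnorm(1, 0, 0.08)
    lapply(c(baseline = 1, followup = 2), function(sess) {
      generate_simon_session(
        congruency_effect_ms = config$behavior$congruency_effect_ms,
        rt_meanlog = subj_meanlog,
        seed = beh_seed + s * 7L + sess)
    })
  })
  wp <- generate_recall_counts("wp", config$n_subjects, item_total = 60,
                               effect = config$behavior$recall_effect,
                               base_p = 0.36, seed = beh_seed + 101L)
  vr <- generate_recall_counts("vr", config$n_subjects, item_total = 50,
                               effect = config$behavior$recall_effect,
                               base_p = 0.62, seed = beh_seed + 102L)
  measures <- default_score_measures()
  measures$effect <- config$behavior$score_effect
  scores <- generate_score_table(measures, config$n_subjects,
                                 seed = beh_seed + 103L)

  # preprocess + features
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    for (cond in config$conditions) {
      pair <- cohort$subjects[[s]][[cond]]
      for (sess in c("baseline", "followup")) {
        pp <- preprocess_recording(pair[[sess]], condition = cond,
                                   verbose = verbose)
        sets <- if (cond == "simon") {
          split_simon_epochs(pp$epochs, simon[[s]][[sess]])
        } else {
          stats::setNames(list(pp$epochs), cond)
        }
        for (es in sets) {
          if (dim(es$epochs)[1] == 0) next
          ft <- condition_features(es, features = config$features)
          ft$subject <- s
          ft$session <- sess
          rows[[length(rows) + 1]] <- ft
        }
      }
    }
  }
  feature_table <- do.call(rbind, rows)

  # EEG contrasts
  eeg_conditions <- unique(feature_table$condition)
  eeg <- list()
  for (feat in config$features) {
    for (cond in eeg_conditions) {
      nodes <- if (feat == "power") {
        freqs <- sort(unique(feature_table$freq[
          feature_table$feature == "power"]))
        g <- expand_graph_frequency(graph, freqs)
        g$nodes
      } else {
        g <- graph
        graph$nodes
      }
      a <- .feature_matrix(feature_table, feat, cond, "baseline", nodes)
      b <- .feature_matrix(feature_table, feat, cond, "followup", nodes)
      ok <- stats::complete.cases(a) & stats::complete.cases(b)
      if (sum(ok) < 2) next
      ct <- cluster_permutation_test(
        b[ok, , drop = FALSE], a[ok, , drop = FALSE], g,
        cluster_alpha = config$stats$cluster_alpha,
        alpha = config$stats$alpha,
        max_exact_n = config$stats$max_exact_n,
        monte_carlo = TRUE, seed = config$seed + 900L)
      eeg[[paste(feat, cond, sep = ":")]] <- ct
      if (verbose) {
        message(sprintf("[stats] %s x %s: %s, %d permutations, %d clusters",
                        feat, cond, ct$scheme, ct$n_permutations,
                        length(ct$clusters)))
      }
    }
  }

  behavioral <- behavioral_contrasts(simon, list(wp = wp, vr = vr), scores)

  provenance <- list(
    package = "qeegpipe",
    version = as.character(utils::packageVersion("qeegpipe")),
    r_version = as.character(getRversion()),
    master_seed = config$seed,
    n_subjects = config$n_subjects,
    conditions = config$conditions,
    features = config$features,
    eeg_config = unclass(config$eeg),
    stats = config$stats,
    behavior = config$behavior,
    n_effects = length(config$effects)
  )
  structure(
    list(feature_table = feature_table, eeg = eeg, behavioral = behavioral,
         provenance = provenance),
    class = "study_report"
  )
}

# one Wilcoxon row (helper for the behavioral table); positive z means the
# second argument tends above the first
.contrast_row <- function(measure, first, second) {
  wt <- suppressWarnings(wilcoxon_signed_rank(second, first))
  data.frame(
    measure = measure,
    median_a = stats::median(first), median_b = stats::median(second),
    w = wt$statistic, z = wt$z, p = wt$p,
    r = effect_size_r(wt$z, length(first)),
    n_pairs = length(first),
    stringsAsFactors = FALSE
  )
}

#' Behavioral contrast table
#'
#' Builds the full behavioral table: Simon reaction-time and accuracy
#' contrasts (congruent vs incongruent within each session; baseline vs
#' follow-up within each congruency), recall counts for the two memory
#' tasks, and every simulated neuropsychological measure. All rows get a
#' Wilcoxon signed-rank z and effect size r; p-values are
#' Benjamini-Hochberg adjusted as one family.
#'
#' @param simon List (per subject) of lists with `baseline` and `followup`
#'   trial tables.
#' @param recall Named list of recall-count data.frames (columns `baseline`,
#'   `followup`).
#' @param scores Score table from [generate_score_table()] (or `NULL`).
#' @return data.frame with `measure`, `median_a`, `median_b`, `w`, `z`, `p`,
#'   `p_adjusted`, `r`, `n_pairs`.
#' @export
behavioral_contrasts <- function(simon, recall = list(), scores = NULL) {
  med_rt <- function(tab, cc) stats::median(tab$rt_ms[tab$condition == cc])
  acc <- function(tab, cc) 100 * mean(tab$correct[tab$condition == cc])
  stat_of <- function(fun, sess, cc) {
    vapply(simon, function(su) fun(su[[sess]], cc), numeric(1))
  }
  rows <- list(
    .contrast_row("simon_rt_congruent_b_vs_m",
                  stat_of(med_rt, "baseline", "congruent"),
                  stat_of(med_rt, "followup", "congruent")),
    .contrast_row("simon_rt_incongruent_b_vs_m",
                  stat_of(med_rt, "baseline", "incongruent"),
                  stat_of(med_rt, "followup", "incongruent")),
    .contrast_row("simon_rt_c_vs_ic_baseline",
                  stat_of(med_rt, "baseline", "congruent"),
                  stat_of(med_rt, "baseline", "incongruent")),
    .contrast_row("simon_rt_c_vs_ic_followup",
                  stat_of(med_rt, "followup", "congruent"),
                  stat_of(med_rt, "followup", "incongruent")),
    .contrast_row("simon_acc_congruent_b_vs_m",
                  stat_of(acc, "baseline", "congruent"),
                  stat_of(acc, "followup", "congruent")),
    .contrast_row("simon_acc_incongruent_b_vs_m",
                  stat_of(acc, "baseline", "incongruent"),
                  stat_of(acc, "followup", "incongruent")),
    .contrast_row("simon_acc_c_vs_ic_baseline",
                  stat_of(acc, "baseline", "congruent"),
                  stat_of(acc, "baseline", "incongruent")),
    .contrast_row("simon_acc_c_vs_ic_followup",
                  stat_of(acc, "followup", "congruent"),
                  stat_of(acc, "followup", "incongruent"))
  )
  for (nm in names(recall)) {
    rc <- recall[[nm]]
    rows[[length(rows) + 1]] <-
      .contrast_row(paste0(nm, "_recall"), rc$baseline, rc$followup)
  }
  if (!is.null(scores)) {
    for (nm in unique(scores$measure)) {
      sc <- scores[scores$measure == nm, ]
      rows[[length(rows) + 1]] <-
        .contrast_row(nm, sc$baseline, sc$followup)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- benjamini_hochberg(out$p)
  out[, c("measure", "median_a", "median_b", "w", "z", "p", "p_adjusted",
          "r", "n_pairs")]
}

#' Write a study report to disk
#'
#' Behavioral table and feature table as CSV, cluster results and
#' provenance as JSON.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$behavioral, file.path(dir, "behavioral.csv"),
                   row.names = FALSE)
  utils::write.csv(report$feature_table, file.path(dir, "features.csv"),
                   row.names = FALSE)
  clusters <- lapply(report$eeg, function(ct) {
    list(scheme = ct$scheme, n_permutations = ct$n_permutations,
         n_subjects = ct$n_subjects,
         clusters = lapply(ct$clusters, function(cl) {
           list(members = cl$members, mass = cl$mass,
                polarity = cl$polarity, p_value = cl$p_value,
                significant = cl$significant)
         }))
  })
  jsonlite::write_json(clusters, file.path(dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  # flat cluster summary
  flat <- do.call(rbind, lapply(names(report$eeg), function(key) {
    ct <- report$eeg[[key]]
    if (length(ct$clusters) == 0) {
      return(data.frame(contrast = key, scheme = ct$scheme,
                        n_permutations = ct$n_permutations, mass = NA,
                        polarity = NA, p_value = NA, n_nodes = 0))
    }
    do.call(rbind, lapply(ct$clusters, function(cl) {
      data.frame(contrast = key, scheme = ct$scheme,
                 n_permutations = ct$n_permutations, mass = cl$mass,
                 polarity = cl$polarity, p_value = cl$p_value,
                 n_nodes = length(cl$members))
    }))
  }))
  utils::write.csv(flat, file.path(dir, "cluster_summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", x$provenance$n_subjects, " subjects, ",
      length(x$eeg), " EEG contrasts, ", nrow(x$behavioral),
      " behavioral rows\n", sep = "")
  invisible(x)
}
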