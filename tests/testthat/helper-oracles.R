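# Test helpers: fixture builders and independent brute-force oracles.
# The oracles deliberately share no code with the implementation.

# wrap a channels x samples matrix (or a single series replicated over all
# scalp channels) as a raw_recording
make_recording <- function(data, fs = 256, montage = generate_montage(),
                           with_eog = TRUE) {
  if (is.vector(data)) {
    labs <- c(montage$labels, if (with_eog) montage$eog_label)
    data <- matrix(rep(data, length(labs)), nrow = length(labs),
                   byrow = TRUE)
    rownames(data) <- labs
  }
  structure(
    list(data = data, fs = fs, labels = rownames(data), montage = montage,
         annotations = list()),
    class = "raw_recording"
  )
}

# neighbor_graph for a simple path a - b - c - ...
path_graph <- function(labels) {
  k <- length(labels)
  adj <- stats::setNames(vector("list", k), labels)
  for (i in seq_len(k)) {
    adj[[i]] <- labels[c(i - 1, i + 1)[c(i - 1, i + 1) >= 1 &
                                         c(i - 1, i + 1) <= k]]
  }
  edges <- cbind(from = labels[-k], to = labels[-1])
  structure(list(nodes = labels, edges = edges, adjacency = adj),
            class = "neighbor_graph")
}

# Brute-force cluster permutation p-values: enumerates every sign vector
# with nested loops, recomputes t by the textbook formula, finds connected
# components by repeated neighbor expansion. Returns the permutation
# distribution of max |cluster mass| and p per observed cluster.
brute_cluster_oracle <- function(A, B, adjacency, cluster_alpha = 0.05) {
  D <- A - B
  n <- nrow(D)
  labels <- colnames(A)
  tcrit <- qt(1 - cluster_alpha / 2, df = n - 1)
  tmap <- function(D) {
    vapply(seq_len(ncol(D)), function(j) {
      d <- D[, j]
      s <- sd(d)
      if (s == 0) 0 else mean(d) / (s / sqrt(n))
    }, numeric(1))
  }
  clusters_of <- function(t) {
    out <- list()
    for (sgn in c(1, -1)) {
      supra <- labels[sgn * t > tcrit]
      while (length(supra) > 0) {
        comp <- supra[1]
        repeat {
          grow <- unique(unlist(lapply(comp, function(l) adjacency[[l]])))
          grow <- intersect(grow, supra)
          if (all(grow %in% comp)) break
          comp <- union(comp, grow)
        }
        out[[length(out) + 1]] <- list(members = comp,
                                       mass = sum(t[match(comp, labels)]),
                                       polarity = sgn)
        supra <- setdiff(supra, comp)
      }
    }
    out
  }
  t_obs <- tmap(D)
  names(t_obs) <- labels
  obs_clusters <- clusters_of(t_obs)
  maxima <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(code, 2^(seq_len(n) - 1)) > 0, -1, 1)
    tperm <- tmap(D * signs)
    cls <- clusters_of(tperm)
    maxima[code + 1] <- if (length(cls) == 0) 0 else
      max(vapply(cls, function(cl) abs(cl$mass), numeric(1)))
  }
  for (i in seq_along(obs_clusters)) {
    obs_clusters[[i]]$p <- mean(maxima >= abs(obs_clusters[[i]]$mass) - 1e-12)
  }
  list(clusters = obs_clusters, maxima = maxima, t_obs = t_obs)
}

# Brute-force two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# assignments of the ranked magnitudes (same average-rank convention).
brute_signrank_p <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  ws <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    pos <- bitwAnd(code, 2^(seq_len(n) - 1)) > 0
    ws[code + 1] <- sum(rk[pos])
  }
  lower <- mean(ws <= W + 1e-12)
  upper <- mean(ws >= W - 1e-12)
  min(1, 2 * min(lower, upper))
}
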