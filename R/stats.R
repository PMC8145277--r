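# Within-subject inference: paired t-maps, cluster-based permutation tests
# with exact sign-flip enumeration over the electrode(/frequency) neighbor
# graph, Wilcoxon signed-rank with effect size r, and Benjamini-Hochberg
# correction.

#' Paired t-statistic map
#'
#' Per node (electrode, or electrode x frequency), the dependent-samples
#' t-statistic of the per-subject differences `d = A - B`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, df = n - 1.
#'
#' @param values_a,values_b Subject x node matrices with identical shape,
#'   subject order and column names.
#' @return Named numeric vector of t-values (0, with a warning, for nodes
#'   with zero difference variance).
#' @export
paired_t_map <- function(values_a, values_b) {
  stopifnot(is.matrix(values_a), identical(dim(values_a), dim(values_b)),
            nrow(values_a) >= 2)
  d <- values_a - values_b
  n <- nrow(d)
  m <- colMeans(d)
  v <- apply(d, 2, stats::var)
  t <- numeric(length(m))
  zero <- v == 0
  if (any(zero)) {
    warning("zero difference variance at ", sum(zero),
            " node(s); t set to 0")
  }
  t[!zero] <- m[!zero] / sqrt(v[!zero] / n)
  names(t) <- colnames(values_a)
  t
}

# adjacency as list of integer indices in node order
.adjacency_index <- function(nodes, adjacency) {
  lapply(nodes, function(lab) match(adjacency[[lab]], nodes))
}

# connected components of the active node subset; returns list of integer
# vectors
.components <- function(active, adj_idx) {
  comps <- list()
  seen <- !active
  for (s in which(active)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, v)
      for (w in adj_idx[[v]]) {
        if (!is.na(w) && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- members
  }
  comps
}

# maximal |cluster mass| of one t-map under the threshold/graph
.max_cluster_mass <- function(t, thresh, adj_idx) {
  best <- 0
  for (sgn in c(1, -1)) {
    active <- sgn * t > thresh
    if (!any(active)) next
    for (comp in .components(active, adj_idx)) {
      best <- max(best, abs(sum(t[comp])))
    }
  }
  best
}

#' Expand a spatial graph across frequency bins
#'
#' For spectral features clustered over electrode x frequency: nodes are
#' `electrode@freq`, adjacent when spatially neighboring at the same
#' frequency or on the same electrode within +/- 1 bin.
#'
#' @param graph A `neighbor_graph` over electrodes.
#' @param freqs Ordered numeric frequency bins.
#' @return A `neighbor_graph` over the product nodes.
#' @export
expand_graph_frequency <- function(graph, freqs) {
  stopifnot(inherits(graph, "neighbor_graph"), length(freqs) >= 1)
  nodes <- as.vector(outer(graph$nodes, freqs,
                           function(e, f) paste0(e, "@", f)))
  adjacency <- stats::setNames(vector("list", length(nodes)), nodes)
  for (e in graph$nodes) {
    nb <- graph$adjacency[[e]]
    for (k in seq_along(freqs)) {
      node <- paste0(e, "@", freqs[k])
      spat <- paste0(nb, "@", freqs[k])
      spec <- character(0)
      if (k > 1) spec <- c(spec, paste0(e, "@", freqs[k - 1]))
      if (k < length(freqs)) spec <- c(spec, paste0(e, "@", freqs[k + 1]))
      adjacency[[node]] <- c(spat, spec)
    }
  }
  edges <- do.call(rbind, lapply(nodes, function(a) {
    to <- adjacency[[a]]
    to <- to[to > a]  # each pair once
    if (length(to)) cbind(from = a, to = to) else NULL
  }))
  structure(list(nodes = nodes, edges = edges, adjacency = adjacency),
            class = "neighbor_graph")
}

# all 2^n sign assignments as a (2^n) x n matrix of +/- 1
.sign_matrix <- function(n) {
  stopifnot(n <= 20)
  m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  dimnames(m) <- NULL
  m
}

#' Cluster-based permutation test for paired data
#'
#' Thresholds the observed paired t-map two-sided at the critical value for
#' `cluster_alpha` (df = n - 1), groups suprathreshold nodes into connected
#' components per polarity under the neighbor graph, and scores each
#' cluster's mass (sum of member t-values) against the permutation
#' distribution of the maximal |cluster mass| under sign flips of the
#' subject differences. All `2^n` unique sign assignments are enumerated
#' when `n <= max_exact_n`; beyond that a seeded Monte-Carlo scheme (with
#' the observed assignment included) is used when enabled.
#'
#' @param values_a,values_b Subject x node matrices (columns named with the
#'   graph's nodes).
#' @param graph A `neighbor_graph` covering the columns.
#' @param cluster_alpha Cluster-forming alpha for the two-sided t threshold
#'   (default 0.05).
#' @param alpha Cluster significance level (default 0.05).
#' @param max_exact_n Largest n for exact enumeration (default 14).
#' @param monte_carlo Allow Monte-Carlo fallback above `max_exact_n`.
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed Seed for the Monte-Carlo scheme.
#' @return A `cluster_test` object: list with `clusters` (each with
#'   `members`, `mass`, `polarity`, `p_value`, `significant`), `t_obs`,
#'   `scheme` (`"exact"` or `"monte_carlo"`), `n_permutations`.
#' @export
cluster_permutation_test <- function(values_a, values_b, graph,
                                     cluster_alpha = 0.05, alpha = 0.05,
                                     max_exact_n = 14, monte_carlo = FALSE,
                                     n_draws = 1000, seed = 1L) {
  stopifnot(inherits(graph, "neighbor_graph"),
            is.matrix(values_a), identical(dim(values_a), dim(values_b)))
  nodes <- colnames(values_a)
  if (!setequal(nodes, graph$nodes)) {
    stop("graph nodes must match the feature's columns")
  }
  values_a <- values_a[, graph$nodes, drop = FALSE]
  values_b <- values_b[, graph$nodes, drop = FALSE]
  d <- values_a - values_b
  n <- nrow(d)
  p <- ncol(d)
  if (n > max_exact_n && !monte_carlo) {
    stop("n = ", n, " exceeds max_exact_n = ", max_exact_n,
         " and the Monte-Carlo fallback is disabled")
  }
  adj_idx <- .adjacency_index(graph$nodes, graph$adjacency)
  thresh <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  t_obs <- suppressWarnings(paired_t_map(values_a, values_b))

  # observed clusters
  clusters <- list()
  for (sgn in c(1, -1)) {
    active <- sgn * t_obs > thresh
    if (!any(active)) next
    for (comp in .components(active, adj_idx)) {
      clusters[[length(clusters) + 1]] <-
        list(members = graph$nodes[comp], mass = sum(t_obs[comp]),
             polarity = sgn)
    }
  }

  exact <- n <= max_exact_n
  if (exact) {
    S <- .sign_matrix(n)
  } else {
    set.seed(seed)
    S <- matrix(sample(c(1, -1), n_draws * n, replace = TRUE),
                nrow = n_draws)
    S <- rbind(rep(1, n), S)  # observed assignment included
  }
  R <- nrow(S)
  # vectorized t-maps for all sign assignments: sum(d_i^2) is flip-invariant
  M <- (S %*% d) / n
  ss <- matrix(colSums(d^2), nrow = R, ncol = p, byrow = TRUE)
  V <- (ss - n * M^2) / (n - 1)
  Tmat <- matrix(0, R, p)
  ok <- V > 0
  Tmat[ok] <- M[ok] / sqrt(V[ok] / n)
  maxima <- vapply(seq_len(R), function(r) {
    .max_cluster_mass(Tmat[r, ], thresh, adj_idx)
  }, numeric(1))

  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    cl$p_value <- mean(maxima >= abs(cl$mass) - 1e-12)
    cl$significant <- cl$p_value < alpha
    clusters[[i]] <- cl
  }
  structure(
    list(clusters = clusters, t_obs = t_obs,
         scheme = if (exact) "exact" else "monte_carlo",
         n_permutations = R, cluster_alpha = cluster_alpha, alpha = alpha,
         n_subjects = n),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> n = ", x$n_subjects, ", ", x$scheme, " scheme, ",
      x$n_permutations, " permutations, ", length(x$clusters),
      " cluster(s)\n", sep = "")
  for (cl in x$clusters) {
    cat(sprintf("  %s mass %.3f, p = %.4g%s (%d nodes)\n",
                if (cl$polarity > 0) "+" else "-", cl$mass, cl$p_value,
                if (cl$significant) " *" else "", length(cl$members)))
  }
  invisible(x)
}

# exact distribution of W+ (sum of positive signed ranks) by convolution
.signrank_distribution <- function(ranks) {
  maxw <- sum(ranks)
  probs <- c(1, rep(0, maxw))
  for (r in ranks) {
    shifted <- c(rep(0, r), probs[seq_len(maxw + 1 - r)])
    probs <- (probs + shifted) / 2
  }
  probs  # P(W+ = 0..maxw)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' `W` is the sum of positive signed ranks of `x - y` (average ranks for
#' tied magnitudes, zero differences dropped). The two-sided p-value is
#' exact (full sign-assignment enumeration) for n <= 15 without ties,
#' otherwise from the normal approximation with tie correction. The
#' standardized statistic z is always reported from the normal
#' approximation, signed so that positive z means `x` tends above `y`.
#'
#' @param x,y Paired numeric vectors.
#' @return A `rank_test` list: `statistic` (W), `z`, `p`, `n_pairs`
#'   (non-zero differences), `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences zero")
    return(structure(list(statistic = 0, z = 0, p = 1, n_pairs = 0,
                          exact = TRUE), class = "rank_test"))
  }
  a <- abs(d)
  rk <- rank(a)
  W <- sum(rk[d > 0])
  ties <- anyDuplicated(a) > 0
  mu <- n * (n + 1) / 4
  tie_counts <- table(a)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_counts^3 - tie_counts) / 48
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  exact <- n <= 15 && !ties
  if (exact) {
    probs <- .signrank_distribution(as.integer(rk))
    lower <- sum(probs[seq_len(W + 1)])           # P(W+ <= W)
    upper <- sum(probs[(W + 1):length(probs)])    # P(W+ >= W)
    p <- min(1, 2 * min(lower, upper))
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(statistic = W, z = z, p = p, n_pairs = n, exact = exact),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> W = %.1f, z = %.3f, p = %.4g (%s, n = %d)\n",
              x$statistic, x$z, x$p,
              if (x$exact) "exact" else "normal approx.", x$n_pairs))
  invisible(x)
}

#' Effect size r for a rank test
#'
#' `r = z / sqrt(N)` with `N = 2 * n_pairs` observations (both measurement
#' occasions of the paired design).
#'
#' @param z Standardized rank statistic.
#' @param n_pairs Number of pairs.
#' @return Effect size in [-1, 1].
#' @export
effect_size_r <- function(z, n_pairs) {
  stopifnot(n_pairs > 0)
  z / sqrt(2 * n_pairs)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `p_adj(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, order-preserving.
#'
#' @param p_values Numeric vector in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
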