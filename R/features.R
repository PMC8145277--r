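# Quantitative EEG features on 1-s epochs: Hjorth parameters, brain-rate
# (spectrum-weighted mean frequency), binned Shannon entropy, and normalized
# power spectra; plus per-condition aggregation.

#' Hjorth parameters of one epoch
#'
#' Activity is the signal variance (microvolt^2). Mobility is
#' `sqrt(var(x') / var(x))` with the derivative realized as the first
#' difference scaled by `fs`, a mean-frequency proxy in rad/s; for a pure
#' sinusoid well below Nyquist it approaches the angular frequency.
#' Complexity is `mobility(x') / mobility(x)`, a bandwidth proxy equal to 1
#' for an ideal sine.
#'
#' @param x Numeric epoch (one channel).
#' @param fs Sampling rate in Hz (default 256).
#' @return List with `activity`, `mobility`, `complexity`.
#' @export
hjorth_parameters <- function(x, fs = 256) {
  v0 <- stats::var(x)
  if (v0 == 0) {
    stop("degenerate (constant) epoch: mobility and complexity undefined",
         call. = FALSE)
  }
  d1 <- diff(x) * fs
  d2 <- diff(d1) * fs
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  list(activity = v0, mobility = mob,
       complexity = sqrt(v2 / v1) / mob)
}

#' Brain-rate frequency bands
#'
#' The five canonical bands with fixed center frequencies 2, 4, 6, 10 and
#' 18 Hz. The center set is standard; the edges are a design choice of this
#' package (delta, theta, low-alpha, alpha/low-beta, beta) and are exposed
#' here for configuration.
#'
#' @param edges Optional 5 x 2 matrix of half-open Hz intervals.
#' @return A `brainrate_bands` list with `centers` and `edges`.
#' @export
brainrate_bands <- function(edges = NULL) {
  centers <- c(2, 4, 6, 10, 18)
  if (is.null(edges)) {
    edges <- rbind(c(0.5, 3), c(3, 5), c(5, 7.5), c(7.5, 13), c(13, 30))
  }
  stopifnot(nrow(edges) == 5, all(edges[, 2] > edges[, 1]),
            all(diff(as.vector(t(edges))) >= 0))
  structure(list(centers = centers, edges = edges), class = "brainrate_bands")
}

#' Spectrum-weighted mean frequency (brain-rate)
#'
#' `fb = sum(f_i * p_i) / sum(p_i)` where `p_i` is the mean power inside
#' band i and `f_i` its center frequency; an arousal index bounded by the
#' outer band centers (2 and 18 Hz). Invariant to global spectrum scaling.
#'
#' @param spectrum A `spectrum` object (see [power_spectrum()]) or a list
#'   with `freqs` and `power` (vector over freqs).
#' @param bands A `brainrate_bands` object.
#' @return Brain-rate in Hz.
#' @export
brain_rate <- function(spectrum, bands = brainrate_bands()) {
  freqs <- spectrum$freqs
  power <- spectrum$power
  p <- vapply(seq_along(bands$centers), function(i) {
    sel <- freqs >= bands$edges[i, 1] & freqs < bands$edges[i, 2]
    if (!any(sel)) stop("spectrum does not cover band ", i)
    mean(power[sel])
  }, numeric(1))
  if (sum(p) <= 0) stop("all-zero spectrum: brain-rate undefined")
  sum(bands$centers * p) / sum(p)
}

#' Freedman-Diaconis bin count
#'
#' Bin width `2 * IQR * n^(-1/3)` (type-7 linear-interpolation quantiles),
#' count `ceiling(range / width)`. Used to recompute a cohort-level bin
#' count the way the fixed default of 15 was derived; scale-invariant.
#'
#' @param x Numeric samples (n >= 4 for a meaningful estimate).
#' @return Integer bin count (1, with a warning, when the IQR is zero).
#' @export
fd_bin_count <- function(x) {
  rng <- max(x) - min(x)
  if (rng == 0) return(1L)
  iqr <- stats::IQR(x, type = 7)
  if (iqr == 0) {
    warning("zero IQR: falling back to a single bin")
    return(1L)
  }
  width <- 2 * iqr * length(x)^(-1 / 3)
  as.integer(ceiling(rng / width))
}

#' Binned Shannon entropy of one epoch
#'
#' Amplitudes are binned into `n_bins` equal-width bins spanning the
#' epoch's own [min, max]; `H = -sum(p * log2(p))` with `0 log 0 = 0`.
#' Bounded by `log2(n_bins)`; 0 for a constant epoch.
#'
#' @param x Numeric epoch.
#' @param n_bins Number of amplitude bins (default 15, the cohort-level
#'   Freedman-Diaconis grand average used for all entropy calculations).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x, n_bins = 15) {
  stopifnot(n_bins >= 1)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(.bincode(x, breaks, include.lowest = TRUE),
                     nbins = n_bins)
  p <- counts / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized power spectrum of one epoch
#'
#' Demeans the epoch, applies a Hanning taper, takes the FFT, and keeps the
#' analysis band at the epoch's native 1-Hz resolution. When `normalize` is
#' `TRUE`, power is divided by its mean over the analysis band (band mean
#' exactly 1).
#'
#' @param x Numeric epoch (`fs` samples, 1 s).
#' @param fs Sampling rate (default 256).
#' @param band Analysis band in Hz, inclusive (default `c(1, 40)`: exactly
#'   40 one-Hz bins; `c(0.5, 45)` is supported and keeps bins 1..45).
#' @param normalize Divide by the band mean power.
#' @return A `spectrum` list: `freqs`, `power`, `normalized`.
#' @export
power_spectrum <- function(x, fs = 256, band = c(1, 40), normalize = TRUE) {
  n <- length(x)
  if (all(x == 0)) stop("all-zero epoch: normalization undefined")
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))  # periodic Hanning
  X <- stats::fft(x * w)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  power <- Mod(X[keep])^2
  freqs <- freqs[keep]
  if (normalize) {
    m <- mean(power)
    if (m <= 0) stop("zero band power: normalization undefined")
    power <- power / m
  }
  structure(list(freqs = freqs, power = power, normalized = normalize),
            class = "spectrum")
}

#' Per-condition feature aggregation
#'
#' Computes the selected features on every epoch and channel and averages
#' arithmetically over epochs (per electrode, and per frequency bin for
#' power).
#'
#' @param epochs An `epoch_set`.
#' @param features Character subset of `hjorth_activity`, `hjorth_mobility`,
#'   `hjorth_complexity`, `brain_rate`, `entropy`, `power`.
#' @param entropy_bins Bin count for the entropy feature (default 15).
#' @param band Analysis band for power (default `c(1, 40)`).
#' @param bands `brainrate_bands` for the brain-rate feature.
#' @return Tidy data.frame: `condition`, `feature`, `electrode`, `freq`
#'   (NA for univariate features), `value`.
#' @export
condition_features <- function(epochs,
                               features = c("hjorth_activity",
                                            "hjorth_mobility",
                                            "hjorth_complexity",
                                            "brain_rate", "entropy", "power"),
                               entropy_bins = 15, band = c(1, 40),
                               bands = brainrate_bands()) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- dim(epochs$epochs)[1]
  if (n_ep < 1) stop("empty epoch set")
  features <- match.arg(features, several.ok = TRUE,
                        choices = c("hjorth_activity", "hjorth_mobility",
                                    "hjorth_complexity", "brain_rate",
                                    "entropy", "power"))
  fs <- epochs$fs
  labels <- epochs$labels
  need_spec <- any(c("brain_rate", "power") %in% features)
  rows <- list()
  add_row <- function(feature, electrode, freq, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      condition = epochs$condition, feature = feature, electrode = electrode,
      freq = freq, value = value, stringsAsFactors = FALSE)
  }
  for (ci in seq_along(labels)) {
    mat <- t(epochs$epochs[, ci, , drop = FALSE][, 1, ])  # samples x epochs
    if (n_ep == 1) mat <- matrix(epochs$epochs[1, ci, ], ncol = 1)
    hj <- if (any(startsWith(features, "hjorth"))) {
      vals <- apply(mat, 2, hjorth_parameters, fs = fs)
      list(activity = mean(vapply(vals, `[[`, numeric(1), "activity")),
           mobility = mean(vapply(vals, `[[`, numeric(1), "mobility")),
           complexity = mean(vapply(vals, `[[`, numeric(1), "complexity")))
    }
    if ("hjorth_activity" %in% features) {
      add_row("hjorth_activity", labels[ci], NA_real_, hj$activity)
    }
    if ("hjorth_mobility" %in% features) {
      add_row("hjorth_mobility", labels[ci], NA_real_, hj$mobility)
    }
    if ("hjorth_complexity" %in% features) {
      add_row("hjorth_complexity", labels[ci], NA_real_, hj$complexity)
    }
    if ("entropy" %in% features) {
      add_row("entropy", labels[ci], NA_real_,
              mean(apply(mat, 2, shannon_entropy, n_bins = entropy_bins)))
    }
    if (need_spec) {
      specs <- lapply(seq_len(n_ep), function(e) {
        power_spectrum(mat[, e], fs = fs, band = band, normalize = TRUE)
      })
      if ("brain_rate" %in% features) {
        add_row("brain_rate", labels[ci], NA_real_,
                mean(vapply(specs, brain_rate, numeric(1), bands = bands)))
      }
      if ("power" %in% features) {
        pw <- rowMeans(vapply(specs, `[[`,
                              numeric(length(specs[[1]]$freqs)), "power"))
        freqs <- specs[[1]]$freqs
        for (k in seq_along(freqs)) {
          add_row("power", labels[ci], freqs[k], pw[k])
        }
      }
    }
  }
  do.call(rbind, rows)
}
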