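# Preprocessing chain: zero-phase band-pass + notch, downsampling to 256 Hz,
# regression-based ocular correction, threshold artifact detection, channel
# and interval interpolation, interval exclusion, TP9/TP10 removal,
# common-average re-referencing and 1-s epoching.
#
# Fixed pipeline order: filter -> downsample -> ocular correction -> detect
# -> channel repair -> interval interpolate/exclude -> exclude TP9/TP10 ->
# segment + re-reference.

# Second-order IIR notch (RBJ biquad); no notch designer ships with
# r-signal, so the coefficients are computed directly.
.notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# squared magnitude response |B(e^-iw)/A(e^-iw)|^2 of a digital filter on a
# frequency grid in Hz
.mag_sq_response <- function(b, a, freqs, fs) {
  w <- 2 * pi * freqs / fs
  ew <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- ew %*% b
  ew_a <- exp(-1i * outer(w, seq_along(a) - 1))
  den <- ew_a %*% a
  as.vector(Mod(num / den)^2)
}

# Zero-phase application of a cascade of IIR designs to a channels x samples
# matrix: the forward-backward response |H|^2 is applied in the frequency
# domain on a mirror-padded copy (pad 3 s or the signal length, whichever is
# shorter), one matrix FFT for all channels.
.zero_phase_apply <- function(data, fs, designs) {
  n <- ncol(data)
  pad <- min(n - 1L, as.integer(round(3 * fs)))
  xp <- cbind(data[, (pad + 1):2, drop = FALSE], data,
              data[, (n - 1):(n - pad), drop = FALSE])
  np <- ncol(xp)
  fk <- (seq_len(np) - 1) * fs / np
  fk <- pmin(fk, fs - fk)
  gain <- rep(1, np)
  for (d in designs) {
    gain <- gain * .mag_sq_response(d$b, d$a, fk, fs)
  }
  Y <- stats::mvfft(t(xp))
  out <- Re(stats::mvfft(Y * gain, inverse = TRUE)) / np
  t(out)[, (pad + 1):(pad + n), drop = FALSE]
}

#' Zero-phase band-pass and line-noise notch filter
#'
#' 4th-order Butterworth band-pass applied forward-backward (zero phase;
#' combined asymptotic roll-off 48 dB/oct) plus a zero-phase second-order
#' IIR notch at the line frequency. The forward-backward response
#' (magnitude squared, zero phase) is applied spectrally on mirror-padded
#' data, which processes all channels in one transform.
#'
#' @param rec A `raw_recording`.
#' @param low,high Band edges in Hz (defaults 0.5 and 100).
#' @param notch Line frequency in Hz (default 50); `NA` disables the notch.
#' @param notch_q Notch quality factor (default 35).
#' @return The filtered `raw_recording`.
#' @export
bandpass_and_notch <- function(rec, low = 0.5, high = 100, notch = 50,
                               notch_q = 35) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  if (fs <= 200 || high >= fs / 2) {
    stop("sampling rate too low for the requested band")
  }
  bp <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  designs <- list(list(b = bp$b, a = bp$a))
  if (!is.na(notch)) {
    designs <- c(designs, list(.notch_coefficients(notch, fs, notch_q)))
  }
  rec$data <- .zero_phase_apply(rec$data, fs, designs)
  rec
}

#' Downsample a recording to 256 Hz
#'
#' Anti-alias low-pass (8th-order Butterworth at 0.4 x target rate, applied
#' zero-phase) followed by cubic-spline evaluation on the target sample
#' grid. Duration is preserved within one sample.
#'
#' @param rec A `raw_recording` with `fs >= 256`.
#' @param fs_out Target rate (default 256 Hz).
#' @return The resampled `raw_recording`.
#' @export
resample_to_256 <- function(rec, fs_out = 256) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  if (fs < fs_out) stop("cannot upsample: fs below the target rate")
  if (fs == fs_out) return(rec)
  n_in <- ncol(rec$data)
  n_out <- as.integer(floor(n_in * fs_out / fs))
  t_in <- (seq_len(n_in) - 1) / fs
  t_out <- (seq_len(n_out) - 1) / fs_out
  aa <- signal::butter(8, 0.8 * (fs_out / 2) / (fs / 2), type = "low")
  filtered <- .zero_phase_apply(rec$data, fs, list(list(b = aa$b, a = aa$a)))
  out <- matrix(0, nrow = nrow(rec$data), ncol = n_out,
                dimnames = list(rownames(rec$data), NULL))
  for (i in seq_len(nrow(rec$data))) {
    out[i, ] <- stats::spline(t_in, filtered[i, ], xout = t_out,
                              method = "fmm")$y
  }
  rec$data <- out
  rec$fs <- fs_out
  rec
}

#' Regression-based ocular correction
#'
#' Removes the EOG-correlated component from every scalp channel by
#' least-squares regression on the ocular channel (deterministic stand-in
#' for component-based blink removal; see the methods vignette).
#'
#' @param rec A `raw_recording` containing the ocular channel.
#' @param eog_channel Ocular channel label (default: the montage's).
#' @return The corrected `raw_recording` (EOG channel left untouched).
#' @export
ocular_correction <- function(rec, eog_channel = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  if (is.null(eog_channel)) eog_channel <- rec$montage$eog_label
  if (!eog_channel %in% rec$labels) {
    stop("ocular channel '", eog_channel, "' not present in the recording")
  }
  eog <- rec$data[eog_channel, ]
  v <- stats::var(eog)
  if (v == 0) return(rec)
  scalp <- setdiff(rec$labels, eog_channel)
  eog_c <- eog - mean(eog)
  for (ch in scalp) {
    beta <- sum((rec$data[ch, ] - mean(rec$data[ch, ])) * eog_c) /
      sum(eog_c^2)
    rec$data[ch, ] <- rec$data[ch, ] - beta * eog
  }
  rec
}

# windowed running range (max - min) over all windows of w samples,
# van Herk block prefix/suffix scan, O(n); returns length n - w + 1
.running_extreme <- function(x, w, fun) {
  n <- length(x)
  nw <- n - w + 1L
  nb <- ceiling(n / w)
  pad <- nb * w - n
  xp <- c(x, rep(x[n], pad))
  m <- matrix(xp, nrow = w)
  prefix <- as.vector(apply(m, 2, fun))
  suffix <- as.vector(apply(m[w:1, , drop = FALSE], 2, fun)[w:1, ,
                                                            drop = FALSE])
  fun2 <- if (identical(fun, cummax)) pmax else pmin
  fun2(suffix[seq_len(nw)], prefix[seq_len(nw) + w - 1L])
}

.running_range <- function(x, w) {
  .running_extreme(x, w, cummax) - .running_extreme(x, w, cummin)
}

# flag all samples covered by any violating window (starts: logical over
# window start indices), windows of w samples
.flag_windows <- function(starts, w, n) {
  idx <- which(starts)
  if (length(idx) == 0) return(logical(n))
  delta <- integer(n + 1L)
  dd <- tabulate(idx, nbins = n)
  delta[seq_len(n)] <- dd
  ends <- pmin(idx + w, n + 1L)
  delta_end <- tabulate(ends, nbins = n + 1L)
  cumsum(delta - delta_end)[seq_len(n)] > 0
}

.runs_to_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])  # 0-based half-open
}

#' Threshold-based artifact detection
#'
#' Flags, per scalp channel: gradient violations (absolute consecutive-sample
#' difference above `max_gradient` microvolt/ms), amplitude violations
#' (peak-to-peak range above `max_diff` microvolt within any `diff_window`
#' seconds), and flatline (peak-to-peak below `min_diff` microvolt within
#' any `flat_window` seconds). Windows slide at one-sample stride; flagged
#' samples are dilated by `guard` seconds on each side and merged into
#' maximal intervals.
#'
#' @param rec A `raw_recording` (nominally at 256 Hz).
#' @param max_gradient microvolt per millisecond (default 50).
#' @param max_diff,diff_window Amplitude criterion: microvolt, seconds
#'   (defaults 200, 0.2).
#' @param min_diff,flat_window Flatline criterion: microvolt, seconds
#'   (defaults 0.5, 0.1).
#' @param guard Guard margin added around flagged samples, seconds
#'   (default 0.1).
#' @param guard_flat Guard margin for flatline flags, seconds (default 1):
#'   the upstream zero-phase high-pass (0.5 Hz, time constant about 0.3 s)
#'   smears residual ripple about a second into a dead segment, so the
#'   detectable flat interior underestimates the dead stretch by roughly
#'   this much on each side.
#' @return List of annotations `list(start, end, channels, reason)` with
#'   half-open 0-based sample intervals; reasons are `gradient`, `amplitude`
#'   or `flatline` (priority in that order when criteria overlap).
#' @export
detect_artifacts <- function(rec, max_gradient = 50, max_diff = 200,
                             diff_window = 0.2, min_diff = 0.5,
                             flat_window = 0.1, guard = 0.1,
                             guard_flat = 1) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  n <- ncol(rec$data)
  w_amp <- max(2L, as.integer(round(diff_window * fs)))
  w_flat <- max(2L, as.integer(round(flat_window * fs)))
  g <- as.integer(round(guard * fs))
  g_flat <- as.integer(round(guard_flat * fs))
  dilate <- function(flag, margin) {
    if (!any(flag)) return(flag)
    iv <- .runs_to_intervals(flag)
    iv[, "start"] <- pmax(0L, iv[, "start"] - margin)
    iv[, "end"] <- pmin(n, iv[, "end"] + margin)
    out <- logical(n)
    for (r in seq_len(nrow(iv))) {
      out[(iv[r, "start"] + 1L):iv[r, "end"]] <- TRUE
    }
    out
  }
  grad_thresh <- max_gradient * 1000 / fs  # microvolt per sample step
  scalp <- intersect(rec$montage$labels, rec$labels)
  annotations <- list()
  for (ch in scalp) {
    x <- rec$data[ch, ]
    flags <- list()
    gd <- abs(diff(x)) > grad_thresh
    fg <- logical(n)
    fg[which(gd)] <- TRUE
    fg[which(gd) + 1L] <- TRUE
    flags$gradient <- fg
    flags$amplitude <- if (max(x) - min(x) > max_diff) {
      .flag_windows(.running_range(x, w_amp) > max_diff, w_amp, n)
    } else {
      logical(n)  # no window can exceed the global range
    }
    flags$flatline <- .flag_windows(.running_range(x, w_flat) < min_diff,
                                    w_flat, n)
    any_flag <- dilate(flags$gradient | flags$amplitude, g) |
      dilate(flags$flatline, g_flat)
    if (!any(any_flag)) next
    iv <- .runs_to_intervals(any_flag)
    for (r in seq_len(nrow(iv))) {
      span <- (iv[r, "start"] + 1L):iv[r, "end"]
      reason <- if (any(flags$gradient[span])) "gradient"
      else if (any(flags$amplitude[span])) "amplitude"
      else "flatline"
      annotations[[length(annotations) + 1]] <-
        artifact_annotation(iv[r, "start"], iv[r, "end"], ch, reason)
    }
  }
  annotations
}

# merge overlapping/touching [start, end) intervals; matrix in, matrix out
.merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  o <- order(iv[, "start"])
  iv <- iv[o, , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (r in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv[r, "start"] <= out[last, "end"]) {
      out[last, "end"] <- max(out[last, "end"], iv[r, "end"])
    } else {
      out <- rbind(out, iv[r, , drop = FALSE])
    }
  }
  out
}

#' Interpolate broken channels from their neighbors
#'
#' Replaces each bad channel, over the whole recording, by the unweighted
#' mean of its non-bad neighboring electrodes.
#'
#' @param rec A `raw_recording`.
#' @param bad_labels Channels to repair.
#' @param graph Optional `neighbor_graph`; defaults to the full-montage
#'   graph (no exclusions).
#' @return The repaired `raw_recording`.
#' @export
repair_bad_channels <- function(rec, bad_labels, graph = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  if (length(bad_labels) == 0) return(rec)
  if (is.null(graph)) {
    graph <- build_neighbor_graph(rec$montage, exclusions = character(0))
  }
  src <- rec$data
  for (ch in bad_labels) {
    nb <- setdiff(graph$adjacency[[ch]], bad_labels)
    nb <- intersect(nb, rec$labels)
    if (length(nb) == 0) {
      stop("channel '", ch, "' has no clean neighbors; unrecoverable")
    }
    rec$data[ch, ] <- colMeans(src[nb, , drop = FALSE])
  }
  rec
}

#' Interpolate narrow artifacts, mark the rest for exclusion
#'
#' Overlapping annotations are merged into events. Events touching at most
#' two channels are repaired in place (neighbor averaging restricted to the
#' interval); events on three or more channels are returned for exclusion.
#'
#' @param rec A `raw_recording`.
#' @param annotations List of annotations (as from [detect_artifacts()]).
#' @param graph Optional `neighbor_graph` for the interval repair.
#' @param max_interpolated_channels Events with up to this many channels are
#'   repaired (default 2).
#' @return List with `recording` and `exclusions` (matrix of half-open
#'   0-based `start`/`end` sample intervals; zero rows when nothing is
#'   excluded).
#' @export
interpolate_or_exclude <- function(rec, annotations, graph = NULL,
                                   max_interpolated_channels = 2) {
  stopifnot(inherits(rec, "raw_recording"))
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (length(annotations) == 0) {
    return(list(recording = rec, exclusions = empty))
  }
  if (is.null(graph)) {
    graph <- build_neighbor_graph(rec$montage, exclusions = character(0))
  }
  # merge overlapping annotations (any channel) into events
  starts <- vapply(annotations, `[[`, integer(1), "start")
  o <- order(starts)
  events <- list()
  for (i in o) {
    a <- annotations[[i]]
    last <- if (length(events)) events[[length(events)]] else NULL
    if (!is.null(last) && a$start <= last$end) {
      last$end <- max(last$end, a$end)
      last$channels <- union(last$channels, a$channels)
      events[[length(events)]] <- last
    } else {
      events[[length(events) + 1]] <- list(start = a$start, end = a$end,
                                           channels = a$channels)
    }
  }
  exclusions <- empty
  for (ev in events) {
    idx <- (ev$start + 1L):ev$end
    if (length(ev$channels) <= max_interpolated_channels) {
      src <- rec$data
      ok <- TRUE
      for (ch in ev$channels) {
        nb <- setdiff(graph$adjacency[[ch]], ev$channels)
        nb <- intersect(nb, rec$labels)
        if (length(nb) == 0) { ok <- FALSE; break }
        rec$data[ch, idx] <- colMeans(src[nb, idx, drop = FALSE])
      }
      if (!ok) {
        exclusions <- rbind(exclusions, c(start = ev$start, end = ev$end))
      }
    } else {
      exclusions <- rbind(exclusions, c(start = ev$start, end = ev$end))
    }
  }
  if (nrow(exclusions) > 1) exclusions <- .merge_intervals(exclusions)
  list(recording = rec, exclusions = exclusions)
}

#' Drop excluded electrodes and intervals, re-reference, and epoch
#'
#' Removes the configured electrodes (TP9/TP10 by default, leaving 27), cuts
#' the excluded intervals, tiles every remaining contiguous segment with
#' non-overlapping 1-s epochs anchored at the segment start (remainder
#' shorter than 1 s discarded), and applies the common-average reference per
#' epoch across the retained channels.
#'
#' @param rec A `raw_recording` at 256 Hz (any rate works; epochs are
#'   `fs` samples).
#' @param exclusions Matrix of half-open 0-based `start`/`end` intervals.
#' @param drop_labels Electrodes removed before epoching.
#' @param condition Condition identifier carried on the output.
#' @return An `epoch_set`: list with `condition`, `epochs` (epoch x channel
#'   x sample array, microvolt), `fs`, `labels`. Empty (0 epochs, with a
#'   warning) if less than 1 s survives.
#' @export
exclude_reference_and_segment <- function(rec, exclusions = NULL,
                                          drop_labels = c("TP9", "TP10"),
                                          condition = "unspecified") {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  n <- ncol(rec$data)
  len <- as.integer(round(fs))
  keep_labels <- setdiff(intersect(rec$montage$labels, rec$labels),
                         drop_labels)
  keep <- rep(TRUE, n)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    for (r in seq_len(nrow(exclusions))) {
      s <- max(0L, exclusions[r, "start"])
      e <- min(n, exclusions[r, "end"])
      if (e > s) keep[(s + 1L):e] <- FALSE
    }
  }
  seg <- .runs_to_intervals(keep)
  epoch_starts <- integer(0)  # 0-based
  if (nrow(seg) > 0) {
    for (r in seq_len(nrow(seg))) {
      k <- (seg[r, "end"] - seg[r, "start"]) %/% len
      if (k > 0) {
        epoch_starts <- c(epoch_starts,
                          seg[r, "start"] + (seq_len(k) - 1L) * len)
      }
    }
  }
  n_ep <- length(epoch_starts)
  if (n_ep == 0) {
    warning("no full 1-s epoch survives interval exclusion")
    epochs <- array(numeric(0), dim = c(0, length(keep_labels), len))
  } else {
    epochs <- array(0, dim = c(n_ep, length(keep_labels), len))
    for (e in seq_len(n_ep)) {
      idx <- (epoch_starts[e] + 1L):(epoch_starts[e] + len)
      block <- rec$data[keep_labels, idx, drop = FALSE]
      block <- sweep(block, 2, colMeans(block))  # common average per sample
      epochs[e, , ] <- block
    }
  }
  structure(
    list(condition = condition, epochs = epochs, fs = fs,
         labels = keep_labels, epoch_starts = epoch_starts),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> '", x$condition, "': ", dim(x$epochs)[1], " epochs x ",
      dim(x$epochs)[2], " channels x ", dim(x$epochs)[3], " samples @ ",
      x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Full preprocessing chain for one recording
#'
#' Applies, in fixed order: band-pass + notch filter, downsampling to
#' 256 Hz, ocular correction, artifact detection, bad-channel repair,
#' interval interpolation/exclusion, electrode exclusion, and common-average
#' 1-s epoching.
#'
#' @param rec A `raw_recording` at its native rate.
#' @param bad_channels Channels to interpolate over the whole length.
#' @param condition Condition identifier for the output.
#' @param drop_labels Electrodes excluded from analysis (default TP9/TP10).
#' @param verbose Log per-stage counts (epochs and excluded intervals are
#'   the main silent-failure modes).
#' @param ... Threshold overrides passed to [detect_artifacts()].
#' @return List with `epochs` (an `epoch_set`), `annotations`, `exclusions`.
#' @export
preprocess_recording <- function(rec, bad_channels = character(0),
                                 condition = "unspecified",
                                 drop_labels = c("TP9", "TP10"),
                                 verbose = FALSE, ...) {
  rec <- bandpass_and_notch(rec)
  rec <- resample_to_256(rec)
  rec <- ocular_correction(rec)
  ann <- detect_artifacts(rec, ...)
  if (length(bad_channels) > 0) {
    rec <- repair_bad_channels(rec, bad_channels)
    ann <- Filter(function(a) !all(a$channels %in% bad_channels), ann)
  }
  ie <- interpolate_or_exclude(rec, ann)
  eps <- exclude_reference_and_segment(ie$recording, ie$exclusions,
                                       drop_labels = drop_labels,
                                       condition = condition)
  if (verbose) {
    message(sprintf(
      "[%s] %d annotations, %d excluded intervals, %d epochs",
      condition, length(ann), nrow(ie$exclusions), dim(eps$epochs)[1]))
  }
  list(epochs = eps, annotations = ann, exclusions = ie$exclusions)
}
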