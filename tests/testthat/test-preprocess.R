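fs <- 256

test_that("band-pass removes DC and passes the mid-band without distortion", {
  n <- fs * 10
  t <- (0:(n - 1)) / fs
  r_dc <- bandpass_and_notch(make_recording(rep(5, n)))
  expect_lt(max(abs(r_dc$data["Fp1", ])), 0.05)  # < 1% of the offset

  r_10 <- bandpass_and_notch(make_recording(sin(2 * pi * 10 * t)))
  mid <- (2 * fs):(8 * fs)
  amp <- sqrt(2) * sd(r_10$data["Fp1", mid])
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)
  # zero phase: cross-correlation with the input peaks at lag 0
  cc <- ccf(r_10$data["Fp1", mid], sin(2 * pi * 10 * t)[mid],
            lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("the 50 Hz notch attenuates line noise by at least 20 dB", {
  n <- fs * 10
  t <- (0:(n - 1)) / fs
  r <- bandpass_and_notch(make_recording(sin(2 * pi * 50 * t)))
  amp <- sqrt(2) * sd(r$data["Fp1", (2 * fs):(8 * fs)])
  expect_lt(amp, 10^(-20 / 20))
})

test_that("filtering rejects rates too low for the band", {
  r <- make_recording(rnorm(150 * 4), fs = 150)
  expect_error(bandpass_and_notch(r), "too low")
})

test_that("downsampling preserves duration, tones, and rejects upsampling", {
  n <- 2500 * 10
  t <- (0:(n - 1)) / 2500
  r <- make_recording(sin(2 * pi * 10 * t), fs = 2500)
  out <- resample_to_256(r)
  expect_equal(out$fs, 256)
  expect_lte(abs(ncol(out$data) - 2560), 1)
  pg <- stats::spec.pgram(out$data["Fp1", ], plot = FALSE, taper = 0)
  expect_lt(abs(pg$freq[which.max(pg$spec)] * 256 - 10), 0.2)
  expect_error(resample_to_256(make_recording(rnorm(100), fs = 128)),
               "upsample")
})

test_that("components above the output Nyquist guard band are suppressed", {
  n <- 2500 * 10
  t <- (0:(n - 1)) / 2500
  r <- make_recording(sin(2 * pi * 120 * t), fs = 2500)
  out <- resample_to_256(r)
  x <- out$data["Fp1", (2 * 256):(8 * 256)]
  tt <- (seq_along(x) - 1) / 256
  fit <- lm(x ~ sin(2 * pi * 120 * tt) + cos(2 * pi * 120 * tt))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(amp, 10^(-20 / 20))
})

test_that("ocular regression removes a known admixture", {
  m <- generate_montage()
  n <- fs * 8
  set.seed(5)
  eog <- 100 * pmax(0, sin(2 * pi * 0.7 * (0:(n - 1)) / fs))^4 + rnorm(n)
  clean <- matrix(rnorm(29 * n, sd = 10), nrow = 29,
                  dimnames = list(m$labels, NULL))
  mixed <- rbind(clean + matrix(rep(0.5 * eog, 29), nrow = 29, byrow = TRUE),
                 EOG = eog)
  rec <- make_recording(mixed, fs = fs)
  out <- ocular_correction(rec)
  resid <- out$data[m$labels, ] - clean
  expect_lt(mean(resid^2), 0.1 * mean((0.5 * eog)^2))
})

test_that("ocular regression leaves uncorrelated data essentially unchanged", {
  m <- generate_montage()
  n <- fs * 8
  set.seed(6)
  data <- matrix(rnorm(30 * n, sd = 10), nrow = 30,
                 dimnames = list(c(m$labels, "EOG"), NULL))
  rec <- make_recording(data, fs = fs)
  out <- ocular_correction(rec)
  rel <- sqrt(mean((out$data[m$labels, ] - data[m$labels, ])^2)) /
    sqrt(mean(data[m$labels, ]^2))
  expect_lt(rel, 0.05)
  # zero regressor: identity
  data["EOG", ] <- 0
  rec0 <- make_recording(data, fs = fs)
  expect_identical(ocular_correction(rec0)$data, data)
  rec_no <- rec
  rec_no$data <- data[m$labels, ]
  rec_no$labels <- m$labels
  expect_error(ocular_correction(rec_no), "not present")
})

test_that("a step transient trips the gradient and amplitude criteria", {
  n <- fs * 4
  x <- rep(0, n)
  x[(2 * fs):n] <- 300
  ann <- detect_artifacts(make_recording(x))
  expect_gt(length(ann), 0)
  reasons <- vapply(ann, `[[`, character(1), "reason")
  expect_true("gradient" %in% reasons)
  a <- ann[[1]]
  expect_lte(a$start, 2 * fs)
  expect_gte(a$end, 2 * fs)
})

test_that("a constant recording is flagged as flatline over its full extent", {
  n <- fs * 3
  ann <- detect_artifacts(make_recording(rep(1.5, n)))
  per_ch <- ann[vapply(ann, function(a) a$channels == "Cz", logical(1))]
  expect_length(per_ch, 1)
  expect_equal(per_ch[[1]]$start, 0)
  expect_equal(per_ch[[1]]$end, n)
  expect_equal(per_ch[[1]]$reason, "flatline")
})

test_that("a moderate alpha-band sine passes all three criteria", {
  # analytic margins: gradient ~1.9 uV/ms, 200-ms range 60 uV,
  # 100-ms range >= 30 uV
  n <- fs * 4
  t <- (0:(n - 1)) / fs
  ann <- detect_artifacts(make_recording(30 * sin(2 * pi * 10 * t)))
  expect_length(ann, 0)
})

test_that("the detector is translation-equivariant", {
  n <- fs * 6
  base <- 30 * sin(2 * pi * 10 * (0:(n - 1)) / fs)  # passes all criteria
  mk <- function(shift) {
    x <- base
    x[(2 * fs + shift):(2 * fs + shift + 10)] <- x[(2 * fs + shift):
                                                     (2 * fs + shift + 10)] + 300
    make_recording(x)
  }
  a0 <- detect_artifacts(mk(0))
  a64 <- detect_artifacts(mk(64))
  expect_equal(length(a0), length(a64))
  expect_equal(a64[[1]]$start - a0[[1]]$start, 64)
  expect_equal(a64[[1]]$end - a0[[1]]$end, 64)
})

test_that("bad channels are replaced by their neighbor average", {
  m <- generate_montage()
  n <- fs * 2
  data <- matrix(0, nrow = 30, ncol = n,
                 dimnames = list(c(m$labels, "EOG"), NULL))
  for (ch in c("T7", "FC1", "FC5")) data[ch, ] <- 1
  for (ch in c("Cz", "CP1", "CP5")) data[ch, ] <- 3
  data["C3", ] <- 99
  rec <- make_recording(data, fs = fs)
  out <- repair_bad_channels(rec, "C3")
  expect_equal(unname(out$data["C3", ]), rep(2, n))
  # fixed point: a channel already at the neighbor mean stays put
  out2 <- repair_bad_channels(out, "C3")
  expect_equal(out$data, out2$data)
})

test_that("channel repair is idempotent on arbitrary data", {
  m <- generate_montage()
  set.seed(9)
  data <- matrix(rnorm(30 * fs), nrow = 30,
                 dimnames = list(c(m$labels, "EOG"), NULL))
  rec <- make_recording(data, fs = fs)
  r1 <- repair_bad_channels(rec, c("C3", "O1"))
  r2 <- repair_bad_channels(r1, c("C3", "O1"))
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("an isolated bad channel raises an unrecoverable error", {
  m <- generate_montage()
  rec <- make_recording(matrix(rnorm(30 * fs), nrow = 30,
                               dimnames = list(c(m$labels, "EOG"), NULL)),
                        fs = fs)
  bad <- c("C3", build_neighbor_graph(m, character(0))$adjacency[["C3"]])
  expect_error(repair_bad_channels(rec, bad), "no clean neighbors")
})

test_that("narrow artifacts are repaired in place, wide ones excluded", {
  m <- generate_montage()
  set.seed(10)
  rec <- make_recording(matrix(rnorm(30 * fs * 4), nrow = 30,
                               dimnames = list(c(m$labels, "EOG"), NULL)),
                        fs = fs)
  two <- list(artifact_annotation(100, 200, c("C3", "C4"), "amplitude"))
  out <- interpolate_or_exclude(rec, two)
  expect_equal(nrow(out$exclusions), 0)
  expect_false(identical(out$recording$data["C3", 101:200],
                         rec$data["C3", 101:200]))
  # untouched outside the interval
  expect_identical(out$recording$data["C3", 1:100], rec$data["C3", 1:100])

  three <- list(artifact_annotation(100, 200, c("C3", "C4", "Cz"),
                                    "amplitude"))
  out3 <- interpolate_or_exclude(rec, three)
  expect_equal(nrow(out3$exclusions), 1)
  expect_identical(out3$recording$data, rec$data)

  out0 <- interpolate_or_exclude(rec, list())
  expect_identical(out0$recording$data, rec$data)
  expect_equal(nrow(out0$exclusions), 0)
})

test_that("epoch tiling follows the half-open arithmetic", {
  set.seed(11)
  rec <- make_recording(rnorm(fs * 300))
  es <- exclude_reference_and_segment(rec, condition = "rest1")
  expect_equal(dim(es$epochs)[1], 300)
  expect_length(es$labels, 27)
  expect_false(any(c("TP9", "TP10", "EOG") %in% es$labels))

  rec10 <- make_recording(rnorm(fs * 10))
  excl <- cbind(start = as.integer(4 * fs), end = as.integer(6.5 * fs))
  es10 <- exclude_reference_and_segment(rec10, excl)
  expect_equal(dim(es10$epochs)[1], 7)  # 4 + floor(3.5)
  # no epoch overlaps the excluded interval
  expect_true(all(es10$epoch_starts + fs <= 4 * fs |
                    es10$epoch_starts >= 6.5 * fs))

  short <- make_recording(rnorm(fs))
  expect_warning(
    es0 <- exclude_reference_and_segment(short,
                                         cbind(start = 0L,
                                               end = as.integer(fs))),
    "no full")
  expect_equal(dim(es0$epochs)[1], 0)
})

test_that("epochs are common-average referenced per sample", {
  set.seed(12)
  m <- generate_montage()
  rec <- make_recording(matrix(rnorm(30 * fs * 5), nrow = 30,
                               dimnames = list(c(m$labels, "EOG"), NULL)),
                        fs = fs)
  es <- exclude_reference_and_segment(rec)
  for (e in seq_len(dim(es$epochs)[1])) {
    expect_lt(max(abs(colMeans(es$epochs[e, , ]))), 1e-9)
  }
})

test_that("injected artifacts end up repaired or excluded end to end", {
  m <- generate_montage()
  cfg <- eeg_sim_config(duration = 600, fs_native = 256, seed = 13,
                        artifact_rates = c(muscle = 3, step = 2,
                                           flatline = 1))
  inj <- inject_artifacts(generate_recording(m, cfg), cfg)
  expect_gte(length(inj$truth), 50)
  pp <- preprocess_recording(inj$recording)
  n <- ncol(inj$recording$data)
  handled <- logical(n)
  for (a in pp$annotations) handled[(a$start + 1):a$end] <- TRUE
  if (nrow(pp$exclusions) > 0) {
    for (r in seq_len(nrow(pp$exclusions))) {
      handled[(pp$exclusions[r, "start"] + 1):pp$exclusions[r, "end"]] <- TRUE
    }
  }
  truth_flag <- logical(n)
  for (a in inj$truth) truth_flag[(a$start + 1):a$end] <- TRUE
  coverage <- mean(handled[truth_flag])
  expect_gte(coverage, 0.95)
})
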