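fs <- 256
t1 <- (0:(fs - 1)) / fs

test_that("Hjorth parameters recover the analytic sine limits", {
  for (f0 in c(5, 10, 20)) {
    a <- 2.5
    hj <- hjorth_parameters(a * sin(2 * pi * f0 * t1), fs)
    expect_equal(hj$activity, a^2 / 2, tolerance = 0.01)
    expect_equal(hj$mobility, 2 * pi * f0, tolerance = 0.02)
    expect_equal(hj$complexity, 1, tolerance = 0.02)
  }
})

test_that("white noise is more complex than a sine", {
  set.seed(3)
  hj <- hjorth_parameters(rnorm(fs), fs)
  expect_gt(hj$complexity, 1)
})

test_that("constant epochs are rejected as degenerate", {
  expect_error(hjorth_parameters(rep(2, fs), fs), "degenerate")
})

test_that("Hjorth scaling laws hold", {
  set.seed(4)
  x <- rnorm(fs)
  h1 <- hjorth_parameters(x, fs)
  h3 <- hjorth_parameters(3 * x, fs)
  expect_equal(h3$activity, 9 * h1$activity, tolerance = 1e-12)
  expect_equal(h3$mobility, h1$mobility, tolerance = 1e-12)
  expect_equal(h3$complexity, h1$complexity, tolerance = 1e-12)
})

test_that("brain-rate reproduces the weighted-mean closed forms", {
  b <- brainrate_bands()
  grid <- seq(0.5, 29.5, by = 0.5)
  flat <- list(freqs = grid, power = rep(1, length(grid)))
  expect_equal(brain_rate(flat, b), 8)

  alpha_only <- list(freqs = grid,
                     power = as.numeric(grid >= 7.5 & grid < 13))
  expect_equal(brain_rate(alpha_only, b), 10)

  # band mean powers 1..5 -> (2+8+18+40+90)/15
  pw <- numeric(length(grid))
  for (i in 1:5) {
    sel <- grid >= b$edges[i, 1] & grid < b$edges[i, 2]
    pw[sel] <- i
  }
  expect_equal(brain_rate(list(freqs = grid, power = pw), b), 158 / 15)
  expect_error(brain_rate(list(freqs = grid, power = numeric(length(grid))),
                          b), "all-zero")
})

test_that("brain-rate is scale invariant and converges for narrowband input", {
  b <- brainrate_bands()
  set.seed(5)
  sp <- power_spectrum(rnorm(fs), fs, normalize = FALSE)
  expect_equal(brain_rate(sp, b),
               brain_rate(list(freqs = sp$freqs, power = 7 * sp$power), b))
  for (f0 in c(4, 10, 18)) {
    sp <- power_spectrum(sin(2 * pi * f0 * t1), fs, normalize = FALSE)
    expect_lt(abs(brain_rate(sp, b) - f0), 0.5)
  }
})

test_that("the Freedman-Diaconis count matches a direct evaluation", {
  x <- 0:255
  # independent evaluation of the rule on this sequence
  width <- 2 * (quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)) *
    length(x)^(-1 / 3)
  expected <- as.integer(ceiling((max(x) - min(x)) / width))
  expect_identical(fd_bin_count(x), expected)
  expect_identical(fd_bin_count(10 * x), expected)  # scale invariance
  expect_identical(fd_bin_count(rep(3, 100)), 1L)
  expect_warning(out <- fd_bin_count(c(rep(0, 50), 100)), "single bin")
  expect_identical(out, 1L)
})

test_that("binned entropy hits its closed-form anchors", {
  # exactly uniform occupancy over 15 bins
  u <- rep(seq(0.5, 14.5, by = 1), each = 10) / 15
  expect_equal(shannon_entropy(u, 15), log2(15), tolerance = 1e-9)
  expect_equal(shannon_entropy(rep(c(0, 1), each = 50), 2), 1)
  expect_equal(shannon_entropy(rep(1, 100), 15), 0)
})

test_that("entropy is bounded by log2 of the bin count", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(fs)
    expect_lte(shannon_entropy(x, 15), log2(15))
    expect_gte(shannon_entropy(x, 15), 0)
  }
})

test_that("normalized spectra have unit band mean and locate tones", {
  sp <- power_spectrum(sin(2 * pi * 10 * t1), fs)
  expect_equal(mean(sp$power), 1, tolerance = 1e-9)
  expect_equal(sp$freqs[which.max(sp$power)], 10)
  expect_equal(sp$freqs, 1:40)
  sp45 <- power_spectrum(sin(2 * pi * 10 * t1), fs, band = c(0.5, 45))
  expect_equal(length(sp45$freqs), 45)
  expect_error(power_spectrum(rep(0, fs), fs), "all-zero")
  expect_true(all(sp$power >= 0))
})

test_that("two-tone power ratio survives the Hanning taper", {
  a <- 3
  x <- a * sin(2 * pi * 6 * t1) + 2 * a * sin(2 * pi * 12 * t1)
  sp <- power_spectrum(x, fs, normalize = FALSE)
  ratio <- sp$power[sp$freqs == 12] / sp$power[sp$freqs == 6]
  expect_equal(ratio, 4, tolerance = 0.02)
})

test_that("condition averaging equals the brute-force epoch loop", {
  set.seed(7)
  n_ep <- 5
  labels <- c("C3", "C4", "Cz")
  arr <- array(rnorm(n_ep * 3 * fs, sd = 10), dim = c(n_ep, 3, fs))
  es <- structure(list(condition = "rest1", epochs = arr, fs = fs,
                       labels = labels), class = "epoch_set")
  ft <- condition_features(es, features = c("entropy", "hjorth_activity",
                                            "brain_rate"))
  for (ci in seq_along(labels)) {
    ent <- mean(sapply(seq_len(n_ep),
                       function(e) shannon_entropy(arr[e, ci, ], 15)))
    act <- mean(sapply(seq_len(n_ep),
                       function(e) var(arr[e, ci, ])))
    br <- mean(sapply(seq_len(n_ep), function(e) {
      brain_rate(power_spectrum(arr[e, ci, ], fs))
    }))
    expect_equal(ft$value[ft$feature == "entropy" &
                            ft$electrode == labels[ci]], ent)
    expect_equal(ft$value[ft$feature == "hjorth_activity" &
                            ft$electrode == labels[ci]], act)
    expect_equal(ft$value[ft$feature == "brain_rate" &
                            ft$electrode == labels[ci]], br)
  }
  # identical epochs: average equals the single-epoch value
  arr1 <- array(rep(arr[1, , ], each = 2), dim = c(2, 3, fs))
  es1 <- structure(list(condition = "x", epochs = arr1, fs = fs,
                        labels = labels), class = "epoch_set")
  ft1 <- condition_features(es1, features = "entropy")
  expect_equal(ft1$value[1], shannon_entropy(arr1[1, 1, ], 15))
  es_empty <- structure(list(condition = "x",
                             epochs = array(0, c(0, 3, fs)), fs = fs,
                             labels = labels), class = "epoch_set")
  expect_error(condition_features(es_empty), "empty")
})
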