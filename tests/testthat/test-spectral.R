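cfg <- spectral_config()

test_that("window enumeration matches direct counting", {
  # 300 s at 512 Hz, 4 s windows, 50% overlap: floor((300 - 4)/2) + 1
  rec <- af_recording(matrix(0, 1, 300 * 512), 512, "a", "atrial-node")
  expect_equal(nrow(window_segments(rec, cfg)), 149L)
  # boundaries
  rec4 <- af_recording(matrix(0, 1, 4 * 512), 512, "a", "atrial-node")
  expect_equal(nrow(window_segments(rec4, cfg)), 1L)
  rec39 <- af_recording(matrix(0, 1, round(3.9 * 512)), 512, "a",
                        "atrial-node")
  expect_warning(w <- window_segments(rec39, cfg), "shorter")
  expect_equal(nrow(w), 0L)
  # every window is exactly window_s * fs samples
  w <- window_segments(rec, cfg)
  expect_true(all(w$end - w$start + 1L == 2048L))
})

test_that("spectra live on an exact 0.05 Hz grid and locate tone peaks", {
  t <- seq_len(2048) / 512
  spec <- compute_spectrum(cos(2 * pi * 6 * t), 512, cfg)
  expect_equal(unique(round(diff(spec$freqs), 10)), 0.05)
  expect_equal(spec$freqs[which.max(spec$power)], 6)
  expect_true(all(spec$power >= 0))
  # amplitude ordering between two tones
  two <- compute_spectrum(cos(2 * pi * 5 * t) + 2 * cos(2 * pi * 7 * t),
                          512, cfg)
  p_at <- function(s, f) s$power[which.min(abs(s$freqs - f))]
  expect_gt(p_at(two, 7), p_at(two, 5))
  expect_error(compute_spectrum(c(NaN, t[-1]), 512, cfg), "non-finite")
  expect_error(compute_spectrum(t[1:100], 512, cfg), "samples")
})

test_that("tone peaks land on the tone bin across the whole DF band", {
  t <- seq_len(2048) / 512
  for (est in c("welch", "fft")) {
    cfg_e <- spectral_config(estimator = est)
    for (f in seq(4, 10, by = 0.25)) {
      spec <- compute_spectrum(cos(2 * pi * f * t + 0.7), 512, cfg_e)
      expect_equal(spec$freqs[which.max(spec$power)], f)
    }
  }
})

test_that("dominant frequency respects the band and tie-breaks low", {
  s <- make_spectrum(power_at = 7.35, value = 5, base = 1)
  expect_equal(find_df(s, c(4, 10))$df, 7.35)
  s2 <- make_spectrum(power_at = c(3, 6), value = c(9, 5), base = 1)
  expect_equal(find_df(s2, c(4, 10))$df, 6)
  flat <- make_spectrum(base = 1)
  expect_equal(find_df(flat, c(4, 10))$df, 4)
  expect_error(find_df(flat, c(40, 50)), "outside")
})

test_that("dominant frequency equals an exhaustive scan on random spectra", {
  set.seed(21)
  freqs <- seq(0, 30, by = 0.05)
  for (i in 1:50) {
    power <- runif(length(freqs))
    spec <- list(freqs = freqs, power = power)
    got <- find_df(spec, c(4, 10))
    # oracle: plain loop over all bins
    best_f <- NA; best_p <- -Inf
    for (j in seq_along(freqs)) {
      if (freqs[j] >= 4 && freqs[j] <= 10 && power[j] > best_p) {
        best_p <- power[j]; best_f <- freqs[j]
      }
    }
    expect_identical(got$df, best_f)
    expect_identical(got$peak_power, best_p)
  }
})

test_that("organization index handles the canonical constructions", {
  # all power inside the DF window
  s1 <- make_spectrum(power_at = c(5.95, 6, 6.05), value = 3)
  expect_equal(organization_index(s1, 6, cfg), 1.0)
  # flat spectrum: 3 windows x 0.75 Hz over a 20 Hz band
  flat <- make_spectrum(base = 1)
  oi_flat <- organization_index(flat, 6, cfg)
  expect_equal(oi_flat, 2.25 / 20, tolerance = 1 / 401 / (2.25 / 20))
  # exactly half the power inside DF + harmonic windows
  s3 <- make_spectrum(power_at = c(6, 12), value = c(3, 1), base = 0)
  s3$power[which.min(abs(s3$freqs - 2))] <- 4   # outside any window
  expect_equal(organization_index(s3, 6, cfg), 0.5)
  # zero denominator
  z <- make_spectrum(base = 0)
  z$power[which.min(abs(z$freqs - 25))] <- 1    # power only above f_h
  expect_error(organization_index(z, 6, cfg), "undefined")
})

test_that("organization index equals brute-force summation on random spectra", {
  set.seed(33)
  freqs <- seq(0, 30, by = 0.05)
  worst <- 0
  for (i in 1:200) {
    power <- rexp(length(freqs))
    df <- sample(seq(4, 10, by = 0.05), 1)
    got <- organization_index(list(freqs = freqs, power = power), df, cfg)
    want <- oracle_oi(freqs, power, df)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-12)
})

test_that("organization index is scale-invariant and bounded", {
  set.seed(8)
  freqs <- seq(0, 30, by = 0.05)
  power <- rexp(length(freqs))
  spec <- list(freqs = freqs, power = power)
  oi <- organization_index(spec, 7.5, cfg)
  expect_true(oi >= 0 && oi <= 1)
  scaled <- list(freqs = freqs, power = power * 1e6)
  expect_equal(organization_index(scaled, 7.5, cfg), oi, tolerance = 1e-12)
})

test_that("organization index grows as power moves into the DF windows", {
  freqs <- seq(0, 30, by = 0.05)
  base <- rep(1, length(freqs))
  ois <- vapply(c(0, 5, 20, 100), function(extra) {
    p <- base
    p[which.min(abs(freqs - 6))] <- 1 + extra
    organization_index(list(freqs = freqs, power = p), 6, cfg)
  }, numeric(1))
  expect_true(all(diff(ois) > 0))
})

test_that("F-ratio test matches its constructions and critical value", {
  flat <- make_spectrum(base = 1)
  ft <- f_ratio_test(flat, 7, cfg)
  expect_equal(ft$f_ratio, 1.0)
  expect_false(ft$significant)
  expect_equal(ft$n_freqs, 21L)

  pk <- make_spectrum(power_at = 7, value = 10, base = 1)
  ft2 <- f_ratio_test(pk, 7, cfg)
  expect_equal(ft2$f_ratio, 10.0)
  expect_true(ft2$significant)

  # ratio exactly 3.0 sits below the critical value 3.23
  pk3 <- make_spectrum(power_at = 7, value = 3, base = 1)
  ft3 <- f_ratio_test(pk3, 7, cfg)
  expect_equal(ft3$f_ratio, 3.0)
  expect_false(ft3$significant)
  expect_equal(ft3$f_crit, qf(0.95, 2, 40))

  # two-level spectra scale as peak/baseline
  pk4 <- make_spectrum(power_at = 7, value = 14, base = 2)
  expect_equal(f_ratio_test(pk4, 7, cfg)$f_ratio, 7.0)
})

test_that("F-ratio neighbors truncate with a warning at the grid edge", {
  s <- make_spectrum(base = 1, max_freq = 11)
  expect_warning(ft <- f_ratio_test(s, 10, cfg), "truncated")
  expect_lt(ft$n_freqs, 21L)
})

test_that("harmonic classification separates driver and cardiac multiples", {
  # 2nd harmonic of a 4.5 Hz fibrillatory driver
  s1 <- make_spectrum(power_at = c(4.5, 9), value = c(5, 3), base = 0.01)
  cl1 <- classify_harmonic(s1, 9, cfg)
  expect_equal(cl1$status, "af-harmonic")
  expect_equal(cl1$fundamental, 4.5)
  # 3rd multiple of a 2.5 Hz cardiac rate, below the 4 Hz search floor
  s2 <- make_spectrum(power_at = c(2.5, 7.5), value = c(5, 3), base = 0.01)
  cl2 <- classify_harmonic(s2, 7.5, cfg)
  expect_equal(cl2$status, "cardiac-harmonic")
  expect_equal(cl2$fundamental, 2.5)
  # isolated bump, nothing below
  s3 <- make_spectrum(power_at = c(7.95, 8, 8.05), value = c(2, 3, 2),
                      base = 0.01)
  expect_equal(classify_harmonic(s3, 8, cfg)$status, "none")
})

test_that("per-channel analysis table carries coherent metrics", {
  rec <- tone_recording(c(6, 7.5, 9), fs = 512, dur = 12)
  tab <- analyze_recording(rec, cfg)
  expect_equal(sort(unique(tab$channel)), c("ch01", "ch02", "ch03"))
  expect_equal(max(tab$window), 5)
  expect_equal(unname(tapply(tab$df, tab$channel, unique)),
               c(6, 7.5, 9), ignore_attr = TRUE)
  expect_true(all(tab$oi >= 0 & tab$oi <= 1))
  expect_true(all(tab$significant))
  expect_true(all(tab$harmonic_status == "none"))
})
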