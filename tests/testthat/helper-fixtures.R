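# in-code fixtures shared across test files

# single- or multi-tone recording; amps recycled over freqs
tone_recording <- function(freqs, fs = 512, dur = 4, amps = 1,
                           roles = "atrial-node", phase = 0) {
  t <- seq_len(round(dur * fs)) / fs
  amps <- rep(amps, length.out = length(freqs))
  phase <- rep(phase, length.out = length(freqs))
  samples <- t(vapply(seq_along(freqs), function(i)
    amps[i] * cos(2 * pi * freqs[i] * t + phase[i]), numeric(length(t))))
  af_recording(samples, fs = fs,
               labels = sprintf("ch%02d", seq_along(freqs)), roles = roles)
}

# constructed spectrum on the standard 0.05 Hz grid up to max_freq
make_spectrum <- function(power_at = numeric(0), value = 1, base = 0,
                          max_freq = 30, bin_width = 0.05) {
  freqs <- seq(0, max_freq, by = bin_width)
  power <- rep(base, length(freqs))
  value <- rep(value, length.out = length(power_at))
  for (i in seq_along(power_at)) {
    power[which.min(abs(freqs - power_at[i]))] <- value[i]
  }
  structure(list(freqs = freqs, power = power), class = "window_spectrum")
}

# independent brute-force organization index: plain loops, no shared code
# with the implementation
oracle_oi <- function(freqs, power, df, k = 0.375, f_l = 0, f_h = 20) {
  in_window <- function(f) {
    if (abs(f - df) <= k + 1e-9) return(TRUE)
    n <- 2
    while (n * df + k <= f_h + 1e-9) {
      if (abs(f - n * df) <= k + 1e-9) return(TRUE)
      n <- n + 1
    }
    FALSE
  }
  num <- 0; den <- 0
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    if (f >= f_l - 1e-9 && f <= f_h + 1e-9) {
      den <- den + power[i]
      if (in_window(f)) num <- num + power[i]
    }
  }
  num / den
}

# small scenario sized for test runtime; scientific defaults otherwise
test_scenario <- function(...) {
  args <- list(...)
  defaults <- list(n_atrial_nodes = 48, n_torso_electrodes = 24,
                   duration_s = 20, seed = 11L)
  do.call(synthetic_scenario, utils::modifyList(defaults, args))
}

# memoized noiseless driver-frequency sweep reused by several tests
.sweep_cache <- new.env(parent = emptyenv())
driver_sweep_results <- function(freqs = c(6.5, 7.5, 8.5, 9.5)) {
  key <- paste(freqs, collapse = ",")
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  res <- lapply(freqs, function(f) {
    scn <- test_scenario(driver_freq = f, noise_sigma = 0, mains_amp = 0)
    # the OI-0.5 arm may legitimately be empty on the torso side
    suppressWarnings(run_pipeline(pipeline_config(scenario = scn)))
  })
  names(res) <- as.character(freqs)
  .sweep_cache[[key]] <- res
  res
}
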