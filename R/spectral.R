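#' Spectral analysis configuration
#'
#' Parameters of the per-window spectral estimator and of the derived
#' metrics (dominant frequency, organization index, F-ratio peak test).
#'
#' Each analysis window of `window_s` seconds receives its own spectrum
#' on a zero-padded grid with spacing exactly `bin_width`. With the
#' `"welch"` estimator the window is split into Hamming-tapered
#' sub-segments of half the window length at 50% overlap whose
#' periodograms are averaged; `"fft"` uses a single tapered periodogram
#' of the whole window.
#'
#' The F-ratio compares power at a spectral peak with the mean power of
#' `n_neighbors` frequencies on each side. Zero-padded bins are strongly
#' correlated, so neighbors are sampled at the native pre-padding
#' resolution (`neighbor_spacing`, default `1/window_s` Hz) rather than
#' at adjacent padded bins; set `neighbor_spacing = bin_width` for
#' contiguous padded bins. `f_crit` defaults to the upper 5% point of
#' the F distribution with 2 and 2(F-1) degrees of freedom, where
#' F = 2*n_neighbors + 1 is the number of frequencies entering the test
#' (3.23 for the default 21).
#'
#' @param window_s Analysis window length in seconds.
#' @param overlap_frac Overlap fraction between consecutive analysis
#'   windows.
#' @param taper Taper name; only `"hamming"` is implemented.
#' @param bin_width Spectral grid spacing in Hz after zero padding.
#' @param df_band Numeric length-2, dominant-frequency search band in Hz.
#' @param oi_halfwidth Half-width k in Hz of the spectral window around
#'   the DF and each harmonic in the organization index.
#' @param oi_band Numeric length-2 `(f_l, f_h)`: denominator band of the
#'   organization index in Hz.
#' @param n_neighbors Neighbor frequencies per side in the F-ratio test.
#' @param f_crit Critical value of the F-ratio test, or `NULL` to derive
#'   it from the F distribution at alpha = 0.05.
#' @param estimator `"welch"` or `"fft"`.
#' @param neighbor_spacing Spacing in Hz between F-ratio neighbor
#'   frequencies, or `NULL` for `1/window_s`.
#' @param max_freq Highest frequency retained on the stored grid, Hz.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 4, overlap_frac = 0.5,
                            taper = "hamming", bin_width = 0.05,
                            df_band = c(4, 10), oi_halfwidth = 0.375,
                            oi_band = c(0, 20), n_neighbors = 10,
                            f_crit = NULL, estimator = c("welch", "fft"),
                            neighbor_spacing = NULL, max_freq = 30) {
  estimator <- match.arg(estimator)
  if (bin_width <= 0) stop("bin_width must be positive")
  if (oi_halfwidth <= 0) stop("oi_halfwidth must be positive")
  if (n_neighbors < 1) stop("n_neighbors must be at least 1")
  if (!(overlap_frac >= 0 && overlap_frac < 1)) {
    stop("overlap_frac must lie in [0, 1)")
  }
  if (taper != "hamming") stop("only the Hamming taper is implemented")
  if (is.null(neighbor_spacing)) neighbor_spacing <- 1 / window_s
  n_freqs <- 2L * n_neighbors + 1L
  if (is.null(f_crit)) f_crit <- stats::qf(0.95, 2, 2 * (n_freqs - 1L))
  if (max_freq < max(oi_band[2], df_band[2] + n_neighbors * neighbor_spacing)) {
    stop("max_freq too small for the configured OI band / F-ratio neighbors")
  }
  structure(list(window_s = window_s, overlap_frac = overlap_frac,
                 taper = taper, bin_width = bin_width, df_band = df_band,
                 oi_halfwidth = oi_halfwidth, oi_band = oi_band,
                 n_neighbors = n_neighbors, f_crit = f_crit,
                 estimator = estimator, neighbor_spacing = neighbor_spacing,
                 max_freq = max_freq),
            class = "spectral_config")
}

#' Enumerate analysis windows of a recording
#'
#' Splits the recording timeline into windows of `window_s` seconds with
#' hop `window_s * (1 - overlap_frac)`; a trailing partial window is
#' dropped.
#'
#' @param rec An [af_recording].
#' @param cfg A [spectral_config].
#' @return Data frame with columns `window` (1-based index), `start`,
#'   `end` (inclusive sample indices, each window `window_s * fs` samples
#'   long). Zero rows, with a warning, when the recording is shorter than
#'   one window.
#' @export
window_segments <- function(rec, cfg = spectral_config()) {
  n_win <- round(cfg$window_s * rec$fs)
  hop <- round(cfg$window_s * (1 - cfg$overlap_frac) * rec$fs)
  n <- n_samples(rec)
  if (n < n_win) {
    warning("recording shorter than one analysis window")
    return(data.frame(window = integer(0), start = integer(0),
                      end = integer(0)))
  }
  starts <- seq.int(1L, n - n_win + 1L, by = hop)
  data.frame(window = seq_along(starts), start = starts,
             end = starts + n_win - 1L)
}

hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

# power spectra for a matrix of segments (samples x channels) on the
# zero-padded grid; returns list(freqs, power[nbins x nchan])
power_matrix <- function(seg, fs, cfg) {
  n <- nrow(seg)
  nfft <- round(fs / cfg$bin_width)
  if (abs(nfft * cfg$bin_width - fs) > 1e-6) {
    stop("fs must be an integer multiple of bin_width")
  }
  if (cfg$estimator == "welch") {
    sub_len <- floor(n / 2)
    hop <- floor(sub_len / 2)
    starts <- seq.int(1L, n - sub_len + 1L, by = hop)
  } else {
    sub_len <- n
    starts <- 1L
  }
  w <- hamming(sub_len)
  scale <- 1 / (fs * sum(w^2))
  keep <- seq_len(floor(cfg$max_freq / cfg$bin_width) + 1L)
  acc <- NULL
  for (s in starts) {
    x <- seg[s:(s + sub_len - 1L), , drop = FALSE] * w
    xp <- rbind(x, matrix(0, nfft - sub_len, ncol(x)))
    P <- Mod(stats::mvfft(xp)[keep, , drop = FALSE])^2 * scale
    acc <- if (is.null(acc)) P else acc + P
  }
  list(freqs = (keep - 1L) * cfg$bin_width, power = acc / length(starts))
}

#' Power spectrum of one channel-window
#'
#' Estimates the power spectrum of a single analysis window on a uniform
#' zero-padded grid with spacing `cfg$bin_width` (0.05 Hz by default).
#'
#' @param segment Numeric vector, exactly `window_s * fs` samples.
#' @param fs Sampling rate in Hz.
#' @param cfg A [spectral_config].
#' @return A list of class `window_spectrum` with `freqs` (Hz, uniform,
#'   from 0 to `cfg$max_freq`) and non-negative `power`.
#' @export
compute_spectrum <- function(segment, fs, cfg = spectral_config()) {
  if (!all(is.finite(segment))) stop("segment contains non-finite samples")
  n_expect <- round(cfg$window_s * fs)
  if (length(segment) != n_expect) {
    stop(sprintf("segment must be %d samples (window_s * fs), got %d",
                 n_expect, length(segment)))
  }
  pm <- power_matrix(matrix(segment, ncol = 1), fs, cfg)
  structure(list(freqs = pm$freqs, power = as.numeric(pm$power)),
            class = "window_spectrum")
}

#' Dominant frequency of a spectrum
#'
#' The DF is the frequency of maximum power within the closed band
#' (4-10 Hz by default); ties break toward the lowest frequency.
#'
#' @param spec A `window_spectrum` (or any list with `freqs`, `power`).
#' @param band Numeric length-2 search band in Hz.
#' @return List with `df` (Hz) and `peak_power`.
#' @export
find_df <- function(spec, band = c(4, 10)) {
  sel <- which(spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9)
  if (!length(sel)) stop("DF band lies outside the spectral grid")
  i <- sel[which.max(spec$power[sel])]
  list(df = spec$freqs[i], peak_power = spec$power[i])
}

# bin mask of the DF window plus harmonic windows, each bin counted once
oi_numerator_mask <- function(freqs, df, k, f_l, f_h, refine = FALSE,
                              power = NULL) {
  centers <- df
  n <- 2L
  repeat {
    h <- n * df
    if (h + k > f_h + 1e-9) break
    if (refine && !is.null(power)) {
      sel <- which(abs(freqs - h) <= k + 1e-9)
      if (length(sel)) h <- freqs[sel[which.max(power[sel])]]
    }
    centers <- c(centers, h)
    n <- n + 1L
  }
  mask <- rep(FALSE, length(freqs))
  for (h in centers) mask <- mask | (abs(freqs - h) <= k + 1e-9)
  mask & freqs >= f_l - 1e-9 & freqs <= f_h + 1e-9
}

#' Organization index of a spectrum
#'
#' Ratio of the spectral power inside the DF window `[df - k, df + k]`
#' plus the windows around each harmonic `n * df` (n = 2, 3, ... while
#' `n * df + k` stays within the band) to the total power over the
#' reference band `(f_l, f_h)` (0-20 Hz by default). Overlapping windows
#' are counted once, so the index always lies in [0, 1]. Values near 1
#' indicate a highly periodic signal dominated by the DF.
#'
#' @param spec A `window_spectrum`.
#' @param df Dominant frequency in Hz (on the grid).
#' @param cfg A [spectral_config] supplying `oi_halfwidth` (k) and
#'   `oi_band`.
#' @param refine_harmonics If `TRUE`, each harmonic window is re-centered
#'   on the local power maximum within +/- k of the exact multiple.
#' @return Organization index in [0, 1].
#' @export
organization_index <- function(spec, df, cfg = spectral_config(),
                               refine_harmonics = FALSE) {
  k <- cfg$oi_halfwidth
  f_l <- cfg$oi_band[1]; f_h <- cfg$oi_band[2]
  if (f_h > max(spec$freqs) + 1e-9) {
    stop("spectral grid does not cover the OI band")
  }
  inband <- spec$freqs >= f_l - 1e-9 & spec$freqs <= f_h + 1e-9
  den <- sum(spec$power[inband])
  if (den <= 0) stop("organization index undefined: zero total power in band")
  mask <- oi_numerator_mask(spec$freqs, df, k, f_l, f_h,
                            refine = refine_harmonics, power = spec$power)
  min(max(sum(spec$power[mask]) / den, 0), 1)
}

#' F-ratio significance test of a spectral peak
#'
#' Compares power at the peak frequency with the mean power of
#' `n_neighbors` frequencies above and below it, sampled at
#' `neighbor_spacing` (the native pre-padding resolution by default).
#' The peak is significant when the ratio exceeds the critical value of
#' the F test with 2 and 2(F-1) degrees of freedom, F being the total
#' number of frequencies in the test (21 by default, critical value
#' 3.23).
#'
#' @param spec A `window_spectrum`.
#' @param peak Peak frequency in Hz (on the grid).
#' @param cfg A [spectral_config].
#' @return List with `f_ratio`, `significant`, `n_freqs` (frequencies
#'   used, peak included) and `f_crit`.
#' @export
f_ratio_test <- function(spec, peak, cfg = spectral_config()) {
  ip <- which.min(abs(spec$freqs - peak))
  step <- round(cfg$neighbor_spacing / cfg$bin_width)
  if (step < 1L) stop("neighbor_spacing must be at least one bin")
  offs <- seq_len(cfg$n_neighbors) * step
  idx <- c(ip - rev(offs), ip + offs)
  ok <- idx >= 1L & idx <= length(spec$freqs)
  if (!all(ok)) {
    warning("F-ratio neighbors truncated at the grid edge")
    idx <- idx[ok]
  }
  baseline <- mean(spec$power[idx])
  f_ratio <- if (baseline > 0) spec$power[ip] / baseline else Inf
  list(f_ratio = f_ratio, significant = f_ratio > cfg$f_crit,
       n_freqs = length(idx) + 1L, f_crit = cfg$f_crit)
}

#' Classify a non-significant peak as a possible harmonic
#'
#' Applied when the F-ratio test fails: searches for a stronger
#' fundamental below the peak, in `[1 Hz, hdf)` (harmonics of the
#' ventricular/cardiac cycle rate) and in `[4 Hz, hdf)` (harmonics of a
#' slower fibrillatory driver). The peak is labelled a harmonic of a
#' candidate fundamental `g` when `hdf` lies within one OI half-width
#' `k` of an integer multiple `n * g` (n >= 2) and `g` carries at least
#' as much power as the peak.
#'
#' @param spec A `window_spectrum`.
#' @param hdf Peak frequency under test, Hz.
#' @param cfg A [spectral_config].
#' @return List with `status` (`"none"`, `"cardiac-harmonic"` or
#'   `"af-harmonic"`) and `fundamental` (Hz or `NA`).
#' @export
classify_harmonic <- function(spec, hdf, cfg = spectral_config()) {
  k <- cfg$oi_halfwidth
  p_hdf <- spec$power[which.min(abs(spec$freqs - hdf))]
  probe <- function(f_min) {
    sel <- which(spec$freqs >= f_min - 1e-9 & spec$freqs < hdf - 1e-9)
    if (!length(sel)) return(NULL)
    g <- spec$freqs[sel[which.max(spec$power[sel])]]
    p_g <- spec$power[sel[which.max(spec$power[sel])]]
    n <- round(hdf / g)
    if (n >= 2 && abs(hdf - n * g) <= k + 1e-9 && p_g >= p_hdf) g else NULL
  }
  if (hdf <= 1) return(list(status = "none", fundamental = NA_real_))
  g4 <- probe(4)
  if (!is.null(g4)) return(list(status = "af-harmonic", fundamental = g4))
  g1 <- probe(1)
  if (!is.null(g1)) return(list(status = "cardiac-harmonic", fundamental = g1))
  list(status = "none", fundamental = NA_real_)
}

#' Per-channel, per-window spectral metrics of a recording
#'
#' Runs the full spectral stage over every valid channel and every
#' analysis window: spectrum estimation, dominant frequency, peak power,
#' organization index, F-ratio significance, and — for non-significant
#' peaks — harmonic classification.
#'
#' @param rec An [af_recording]; only channels with `valid_mask == TRUE`
#'   are analyzed.
#' @param cfg A [spectral_config].
#' @param roles Optional character vector restricting analysis to
#'   channels with these role tags.
#' @return Data frame with one row per channel-window: `channel`,
#'   `window`, `df`, `peak_power`, `oi`, `f_ratio`, `significant`,
#'   `harmonic_status`, `fundamental`.
#' @export
analyze_recording <- function(rec, cfg = spectral_config(), roles = NULL) {
  keep <- rec$valid_mask
  if (!is.null(roles)) keep <- keep & rec$roles %in% roles
  labels <- rec$labels[keep]
  if (!length(labels)) stop("no valid channels to analyze")
  wins <- window_segments(rec, cfg)
  out <- vector("list", nrow(wins))
  samp <- rec$samples[keep, , drop = FALSE]
  for (wi in seq_len(nrow(wins))) {
    seg <- t(samp[, wins$start[wi]:wins$end[wi], drop = FALSE])
    pm <- power_matrix(seg, rec$fs, cfg)
    rows <- lapply(seq_along(labels), function(ci) {
      spec <- list(freqs = pm$freqs, power = pm$power[, ci])
      pk <- find_df(spec, cfg$df_band)
      oi <- organization_index(spec, pk$df, cfg)
      ft <- f_ratio_test(spec, pk$df, cfg)
      if (ft$significant) {
        status <- "none"; fund <- NA_real_
      } else {
        cl <- classify_harmonic(spec, pk$df, cfg)
        status <- cl$status; fund <- cl$fundamental
      }
      data.frame(channel = labels[ci], window = wins$window[wi],
                 df = pk$df, peak_power = pk$peak_power, oi = oi,
                 f_ratio = ft$f_ratio, significant = ft$significant,
                 harmonic_status = status, fundamental = fund,
                 stringsAsFactors = FALSE)
    })
    out[[wi]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
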