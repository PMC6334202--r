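#' Preprocessing configuration
#'
#' Bundles the signal-conditioning parameters applied before spectral
#' analysis: the common resampling rate, the band-pass edges of the
#' zero-phase moving-average filter, and the mains quality-control rule
#' (channels whose power around the mains frequency exceeds the given
#' fraction of total spectral power are discarded).
#'
#' @param target_fs Common sampling rate after resampling, Hz.
#' @param bandpass Length-2 numeric, band-pass (low, high) corner
#'   frequencies in Hz.
#' @param mains_freq Mains interference frequency in Hz (50 in the UK/EU).
#' @param mains_frac_threshold Maximum tolerated fraction of total spectral
#'   power within `mains_freq` +/- 0.5 Hz before a channel is rejected.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 512, bandpass = c(2, 50),
                              mains_freq = 50, mains_frac_threshold = 0.005) {
  stopifnot(length(bandpass) == 2L)
  if (!(0 < bandpass[1] && bandpass[1] < bandpass[2] &&
        bandpass[2] < target_fs / 2)) {
    stop("require 0 < low < high < target_fs/2")
  }
  if (!(mains_frac_threshold > 0 && mains_frac_threshold < 1)) {
    stop("mains_frac_threshold must lie in (0, 1)")
  }
  structure(list(target_fs = target_fs, bandpass = bandpass,
                 mains_freq = mains_freq,
                 mains_frac_threshold = mains_frac_threshold),
            class = "preprocess_config")
}

# integer p/q with p/q == a/b for possibly non-integer rates (e.g. 2034.5)
rational_rate <- function(target_fs, fs) {
  for (k in c(1, 2, 10, 100, 1000)) {
    p <- target_fs * k; q <- fs * k
    if (abs(p - round(p)) < 1e-9 && abs(q - round(q)) < 1e-9) {
      p <- round(p); q <- round(q)
      g <- pracma_gcd(p, q)
      return(c(p / g, q / g))
    }
  }
  stop("cannot express target_fs/fs as a small rational ratio")
}

pracma_gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Resample a recording to a new rate
#'
#' Polyphase rational resampling (via an anti-aliasing FIR low-pass) of
#' every channel to `target_fs`. Tones below both Nyquist rates are
#' preserved in frequency, which is what the downstream 0.05 Hz spectral
#' grid relies on.
#'
#' @param rec An [af_recording].
#' @param target_fs Desired sampling rate in Hz.
#' @return A resampled `af_recording` with
#'   `round(n_samples * target_fs / fs)` samples per channel.
#' @export
resample_recording <- function(rec, target_fs) {
  if (!is.numeric(target_fs) || target_fs <= 0) {
    stop("target_fs must be positive")
  }
  if (target_fs == rec$fs) return(rec)
  pq <- rational_rate(target_fs, rec$fs)
  n_out <- round(n_samples(rec) * target_fs / rec$fs)
  out <- matrix(0, nrow = n_channels(rec), ncol = n_out)
  for (i in seq_len(n_channels(rec))) {
    y <- signal::resample(rec$samples[i, ], pq[1], pq[2])
    out[i, ] <- y[seq_len(n_out)]
  }
  af_recording(out, fs = target_fs, labels = rec$labels, roles = rec$roles,
               coords = rec$coords, valid_mask = rec$valid_mask)
}

# centered moving average, zero phase, reflection-padded at the edges
moving_average <- function(x, len) {
  if (len %% 2L == 0L) len <- len + 1L
  if (len <= 1L) return(x)
  h <- (len - 1L) %/% 2L
  n <- length(x)
  xp <- c(rev(x[2:(h + 1L)]), x, rev(x[(n - h):(n - 1L)]))
  y <- stats::filter(xp, rep(1 / len, len), sides = 2)
  as.numeric(y)[(h + 1L):(h + n)]
}

#' Zero-phase moving-average band-pass filter
#'
#' Band-pass filtering implemented as a cascade of centered moving
#' averages: a short moving average (window ~ `fs/high` samples) acts as
#' the low-pass, and the running baseline estimated by a long moving
#' average (window ~ `fs/low` samples) of the low-passed signal is
#' subtracted to remove DC and drift. Both stages are symmetric FIRs, so
#' the cascade is exactly zero-phase and window indices stay aligned
#' across simultaneously recorded streams. The measured -3 dB points for
#' the default (2, 50) Hz band at 512 Hz are reported in the package
#' vignette.
#'
#' @param rec An [af_recording].
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @return A filtered `af_recording`.
#' @export
bandpass_filter <- function(rec, low = 2, high = 50) {
  fs <- rec$fs
  if (!(0 < low && low < high && high < fs / 2)) {
    stop("require 0 < low < high < fs/2")
  }
  len_hi <- max(3L, round(fs / high))
  len_lo <- max(3L, round(fs / low))
  out <- rec$samples
  for (i in seq_len(nrow(out))) {
    lp <- moving_average(out[i, ], len_hi)
    out[i, ] <- lp - moving_average(lp, len_lo)
  }
  af_recording(out, fs = fs, labels = rec$labels, roles = rec$roles,
               coords = rec$coords, valid_mask = rec$valid_mask)
}

# full-record one-sided periodogram: power per FFT bin and bin frequencies
record_periodogram <- function(x, fs) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  nh <- n %/% 2L + 1L
  list(freq = (seq_len(nh) - 1L) * fs / n, power = P[seq_len(nh)])
}

#' Reject channels contaminated by mains interference
#'
#' Computes each channel's full-record periodogram and invalidates the
#' channel when the power summed over `mains_freq` +/- `tol` Hz exceeds
#' `frac` of the total spectral power. Samples are untouched; only the
#' quality-control mask is updated, so the operation is idempotent.
#'
#' @param rec An [af_recording].
#' @param mains_freq Mains frequency in Hz; must be below `fs/2`.
#' @param frac Power-fraction threshold (default 0.005, i.e. 0.5%).
#' @param tol Half-width of the mains band in Hz.
#' @return The updated logical `valid_mask` (with attribute `mains_frac`
#'   holding each channel's measured power fraction).
#' @export
reject_mains_channels <- function(rec, mains_freq = 50, frac = 0.005,
                                  tol = 0.5) {
  if (mains_freq >= rec$fs / 2) stop("mains_freq must be below fs/2")
  nch <- n_channels(rec)
  ratio <- numeric(nch)
  for (i in seq_len(nch)) {
    pg <- record_periodogram(rec$samples[i, ], rec$fs)
    total <- sum(pg$power)
    if (total <= 0) { ratio[i] <- 0; next }
    inband <- abs(pg$freq - mains_freq) <= tol
    ratio[i] <- sum(pg$power[inband]) / total
  }
  mask <- rec$valid_mask & (ratio <= frac)
  if (!any(mask)) message("reject_mains_channels: no channels survive QC")
  attr(mask, "mains_frac") <- ratio
  mask
}

#' Time-align two recordings on a shared reference lead
#'
#' Finds the integer sample lag maximizing the normalized
#' cross-correlation of a reference channel (e.g. ECG lead I) present in
#' both recordings. A positive offset means `b` lags `a`: dropping the
#' first `offset` samples of `b` (or prepending to `a`) brings the
#' reference leads into coincidence at their common R peaks.
#'
#' @param a,b Two [af_recording]s resampled to the same rate.
#' @param ref_label Label of the shared reference channel.
#' @param min_corr Minimum acceptable peak normalized cross-correlation;
#'   below it the alignment is considered failed.
#' @return Integer sample offset (attribute `peak_corr` holds the peak
#'   normalized correlation).
#' @export
align_recordings <- function(a, b, ref_label, min_corr = 0.5) {
  if (a$fs != b$fs) stop("recordings must share one sampling rate")
  xa <- channel(a, ref_label); xb <- channel(b, ref_label)
  xa <- xa - mean(xa); xb <- xb - mean(xb)
  na <- length(xa); nb <- length(xb)
  nfft <- stats::nextn(na + nb, 2)
  cc <- Re(stats::fft(Conj(stats::fft(c(xa, rep(0, nfft - na)))) *
                      stats::fft(c(xb, rep(0, nfft - nb))), inverse = TRUE)) / nfft
  denom <- sqrt(sum(xa^2) * sum(xb^2))
  if (denom <= 0) stop("alignment failed: reference channel has zero variance")
  cc <- cc / denom
  # circular layout: lags 0..nb-1 at the front, -(na-1)..-1 wrapped at the end
  vals <- c(cc[seq_len(nb)], cc[(nfft - na + 2L):nfft])
  lags <- c(0:(nb - 1L), -(na - 1L):-1L)
  i <- which.max(vals)
  peak <- vals[i]
  if (peak < min_corr) {
    stop(sprintf(
      "alignment failed: peak normalized cross-correlation %.3f < %.2f",
      peak, min_corr))
  }
  offset <- lags[i]
  attr(offset, "peak_corr") <- peak
  offset
}

#' Apply an alignment offset to a pair of recordings
#'
#' Trims both recordings to the overlapping span implied by the offset
#' from [align_recordings], so that sample `t` in each output refers to
#' the same instant.
#'
#' @param a,b Two [af_recording]s at the same rate.
#' @param offset Integer sample offset (`b` lags `a` by `offset`).
#' @return List with elements `a` and `b`, trimmed to equal length.
#' @export
apply_alignment <- function(a, b, offset) {
  offset <- as.integer(offset)
  if (offset > 0) {
    b$samples <- b$samples[, -seq_len(offset), drop = FALSE]
  } else if (offset < 0) {
    a$samples <- a$samples[, -seq_len(-offset), drop = FALSE]
  }
  n <- min(ncol(a$samples), ncol(b$samples))
  a$samples <- a$samples[, seq_len(n), drop = FALSE]
  b$samples <- b$samples[, seq_len(n), drop = FALSE]
  list(a = a, b = b)
}
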