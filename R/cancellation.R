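#' Detect R peaks on a reference ECG channel
#'
#' Simple energy-based QRS detector: the signal is differentiated,
#' squared and smoothed over 150 ms, local maxima of this detection
#' function above an adaptive threshold (a fraction of its upper
#' quantile) are kept under a 200 ms refractory period, and each
#' detection is refined to the maximum of the raw signal within
#' +/- 50 ms. Intended for the relatively clean reference leads used to
#' anchor QRS-T cancellation, not as a general-purpose clinical detector.
#'
#' @param ecg Numeric vector, one reference ECG channel.
#' @param fs Sampling rate in Hz.
#' @param qrst_span Numeric length-2, (pre, post) extent of the QRS-T
#'   complex around each R peak in ms; stored in the annotation and used
#'   by [subtract_qrst_template].
#' @param threshold_frac Fraction of the 99th percentile of the smoothed
#'   detection energy used as detection threshold.
#' @return A list of class `beat_annotation`: `r_peaks` (strictly
#'   increasing sample indices) and `qrst_span`.
#' @export
detect_r_peaks <- function(ecg, fs, qrst_span = c(100, 450),
                           threshold_frac = 0.4) {
  if (length(ecg) < 2 * fs) stop("need at least 2 s of signal")
  if (any(qrst_span <= 0)) stop("qrst_span entries must be positive")
  d <- c(0, diff(ecg))
  e <- moving_average(d^2, max(3L, round(0.15 * fs)))
  thr <- threshold_frac * stats::quantile(e, 0.99, names = FALSE)
  ann <- structure(list(r_peaks = integer(0), qrst_span = qrst_span),
                   class = "beat_annotation")
  if (!is.finite(thr) || thr <= 0) {
    warning("no beats detected (flat or empty detection energy)")
    return(ann)
  }
  refr <- round(0.2 * fs)
  half <- round(0.06 * fs)
  n <- length(ecg)
  # candidate per contiguous above-threshold run: the run's energy maximum,
  # refined to the raw-signal maximum nearby
  runs <- rle(e > thr)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- integer(0)
  for (j in which(runs$values)) {
    seg <- starts[j]:ends[j]
    i <- seg[which.max(e[seg])]
    lo <- max(1L, i - half); hi <- min(n, i + half)
    p <- lo + which.max(ecg[lo:hi]) - 1L
    if (length(peaks) && p - peaks[length(peaks)] < refr) next
    peaks <- c(peaks, p)
  }
  peaks <- sort(unique(peaks))
  if (!length(peaks)) warning("no beats detected above threshold")
  ann$r_peaks <- peaks
  ann
}

# cosine-tapered window covering one QRS-T span; ramp_s seconds each edge
qrst_taper <- function(len, fs, ramp_s = 0.02) {
  nr <- min(round(ramp_s * fs), floor(len / 2))
  w <- rep(1, len)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / (nr + 1)))
    w[seq_len(nr)] <- ramp
    w[(len - nr + 1):len] <- rev(ramp)
  }
  w
}

#' Remove ventricular far-field activity by average-beat subtraction
#'
#' Classic QRS-T cancellation: for each channel, the beat waveform is
#' averaged over all annotated QRS-T spans and this template — tapered
#' with a 20 ms cosine ramp at both edges to avoid subtraction steps —
#' is subtracted at every beat occurrence, leaving the atrial component.
#' Samples outside all annotated spans are never modified. With fewer
#' than 3 usable beats the signal is passed through unchanged with a
#' warning.
#'
#' @param rec An [af_recording].
#' @param beats A `beat_annotation` from [detect_r_peaks] (indices on
#'   `rec`'s timeline).
#' @return An `af_recording` with the average beat removed per channel.
#' @export
subtract_qrst_template <- function(rec, beats) {
  fs <- rec$fs
  pre <- round(beats$qrst_span[1] / 1000 * fs)
  post <- round(beats$qrst_span[2] / 1000 * fs)
  len <- pre + post + 1L
  n <- n_samples(rec)
  r <- beats$r_peaks
  r <- r[r - pre >= 1L & r + post <= n]
  if (length(r) < 3L) {
    warning("fewer than 3 usable beats: QRS-T cancellation skipped")
    return(rec)
  }
  w <- qrst_taper(len, fs)
  out <- rec$samples
  idx <- vapply(r, function(p) (p - pre):(p + post), integer(len))
  for (ch in seq_len(nrow(out))) {
    segs <- matrix(out[ch, idx], nrow = len)
    template <- rowMeans(segs) * w
    for (j in seq_along(r)) {
      out[ch, idx[, j]] <- out[ch, idx[, j]] - template
    }
  }
  af_recording(out, fs = fs, labels = rec$labels, roles = rec$roles,
               coords = rec$coords, valid_mask = rec$valid_mask)
}
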