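# run code under a temporary RNG state derived from `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic Fibonacci-lattice points on a spherical cap (half-angle in
# radians, cap centered on +z), scaled by radius
fibonacci_cap <- function(n, half_angle = pi, radius = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - cos(half_angle)) * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  radius * cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Synthetic atrial-source and torso scenario
#'
#' Describes a synthetic study condition: quasi-periodic harmonic-series
#' oscillators on atrial nodes (a compact fast "driver" patch over a
#' slower large-area background), a distance-based volume-conductor
#' projection onto torso electrodes, a shared ventricular far-field beat
#' train, mains contamination and white noise. Node frequencies, driver
#' membership and beat times are returned as ground truth so every
#' pipeline stage can be verified against known answers.
#'
#' @param n_atrial_nodes Number of atrial nodes on a unit-sphere cap.
#' @param n_torso_electrodes Number of electrodes on a surrounding shell.
#' @param background_freq Background fibrillatory rate, Hz.
#' @param driver_freq Driver-patch rate, Hz (`background < driver`, both
#'   within 4-10 Hz).
#' @param driver_area_frac Fraction of atrial nodes in the driver patch.
#' @param harmonic_amps Relative amplitudes of the source fundamental and
#'   its harmonics.
#' @param leadfield_exponent Inverse-distance power of the volume
#'   conductor weights.
#' @param leadfield_smoothing Spatial smoothing radius over the node
#'   neighborhood, in coordinate units (unit-sphere atrium).
#' @param ventricular_rate Mean ventricular beat rate, Hz (< 3).
#' @param ventricular_amp Far-field amplitude relative to the unit atrial
#'   sources.
#' @param rr_jitter_s Standard deviation of the seeded RR-interval
#'   jitter, s. Fibrillation conducts irregularly to the ventricles, and
#'   an exactly periodic beat train phase-locked to the atrial rate would
#'   let average-beat cancellation absorb coherent atrial signal.
#' @param mains_amp Amplitude of the added mains sinusoid.
#' @param mains_freq Mains frequency, Hz.
#' @param noise_sigma Standard deviation of the additive white noise.
#' @param freq_jitter Peak deviation of the slow frequency modulation of
#'   each source, Hz (cycle-length jitter).
#' @param phase_jitter Standard deviation of the per-node phase
#'   perturbation, radians.
#' @param duration_s Recording length, s.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; a fixed seed reproduces the scenario
#'   byte-identically.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_atrial_nodes = 256, n_torso_electrodes = 64,
                               background_freq = 6.0, driver_freq = 9.0,
                               driver_area_frac = 0.05,
                               harmonic_amps = c(1, 0.4, 0.15),
                               leadfield_exponent = 2,
                               leadfield_smoothing = 0.3,
                               ventricular_rate = 1.0, ventricular_amp = 1.0,
                               rr_jitter_s = 0.05,
                               mains_amp = 0.02, mains_freq = 50,
                               noise_sigma = 0.05, freq_jitter = 0.02,
                               phase_jitter = 0.2, duration_s = 60,
                               fs = 512, seed = 1L) {
  if (!(4 <= background_freq && background_freq < driver_freq &&
        driver_freq <= 10)) {
    stop("require 4 <= background_freq < driver_freq <= 10")
  }
  if (!(driver_area_frac >= 0 && driver_area_frac < 0.5)) {
    stop("driver_area_frac must lie in [0, 0.5)")
  }
  if (ventricular_rate >= 3) stop("ventricular_rate must be below 3 Hz")
  structure(as.list(environment()), class = "synthetic_scenario")
}

atrial_geometry <- function(scn) {
  fibonacci_cap(scn$n_atrial_nodes, half_angle = 70 * pi / 180, radius = 1)
}

torso_geometry <- function(scn) {
  fibonacci_cap(scn$n_torso_electrodes, half_angle = pi, radius = 2.5)
}

# driver patch: the nodes geodesically closest to a fixed patch center
driver_patch <- function(scn, nodes) {
  n_drv <- round(scn$driver_area_frac * scn$n_atrial_nodes)
  if (n_drv == 0L) return(integer(0))
  center <- c(sin(0.4), 0, cos(0.4))
  score <- nodes %*% center
  order(score, decreasing = TRUE)[seq_len(n_drv)]
}

#' Simulate atrial node sources
#'
#' Each atrial node emits a harmonic-series oscillator at its assigned
#' rate — `driver_freq` inside the compact driver patch, otherwise
#' `background_freq` — with a smooth spatial phase gradient, small
#' seeded phase perturbations and slow seeded frequency modulation
#' (cycle-length jitter). The harmonic structure matches what the
#' organization index assumes: a dominant fundamental with decaying
#' harmonics.
#'
#' @param scn A [synthetic_scenario].
#' @return List with `recording` (an [af_recording] of atrial-node
#'   channels with node coordinates) and `truth` (data frame `label`,
#'   `freq`, `is_driver`).
#' @export
simulate_atrial_sources <- function(scn) {
  nodes <- atrial_geometry(scn)
  n <- scn$n_atrial_nodes
  drv <- driver_patch(scn, nodes)
  freqs <- rep(scn$background_freq, n)
  freqs[drv] <- scn$driver_freq
  t <- seq_len(round(scn$duration_s * scn$fs)) / scn$fs
  fm_rate <- 0.1                                  # Hz, slow cycle-length drift
  samples <- with_local_seed(scn$seed, {
    theta <- acos(pmin(pmax(nodes[, 3], -1), 1))  # polar angle
    phase0 <- 0.5 * theta + stats::rnorm(n, 0, scn$phase_jitter)
    phase0[drv] <- stats::rnorm(length(drv), 0, scn$phase_jitter / 2)
    fm_phase <- stats::runif(n, 0, 2 * pi)
    amp <- stats::runif(n, 0.9, 1.1)
    out <- matrix(0, nrow = n, ncol = length(t))
    beta <- if (fm_rate > 0) scn$freq_jitter / fm_rate else 0
    for (i in seq_len(n)) {
      ph <- 2 * pi * freqs[i] * t + beta * sin(2 * pi * fm_rate * t +
                                               fm_phase[i]) + phase0[i]
      x <- 0
      for (h in seq_along(scn$harmonic_amps)) {
        x <- x + scn$harmonic_amps[h] * cos(h * ph)
      }
      out[i, ] <- amp[i] * x
    }
    out
  })
  labels <- sprintf("N%03d", seq_len(n))
  rec <- af_recording(samples, fs = scn$fs, labels = labels,
                      roles = "atrial-node", coords = nodes)
  truth <- data.frame(label = labels, freq = freqs,
                      is_driver = seq_len(n) %in% drv,
                      stringsAsFactors = FALSE)
  list(recording = rec, truth = truth)
}

#' Volume-conductor lead field
#'
#' Builds the torso-electrode by atrial-node weight matrix of the
#' forward model: weights proportional to inverse distance to the power
#' `leadfield_exponent`, rows normalized to sum one, then spatially
#' smoothed over each node's neighborhood (radius
#' `leadfield_smoothing`) and re-normalized. The smoothing is what makes
#' the projection a spatial low-pass: a compact fast patch contributes
#' only its blurred, area-weighted share to every electrode.
#'
#' @param scn A [synthetic_scenario].
#' @param nodes,electrodes Optional coordinate matrices overriding the
#'   scenario geometry.
#' @return Electrode x node weight matrix with non-negative entries and
#'   unit row sums.
#' @export
build_leadfield <- function(scn, nodes = NULL, electrodes = NULL) {
  if (is.null(nodes)) nodes <- atrial_geometry(scn)
  if (is.null(electrodes)) electrodes <- torso_geometry(scn)
  eps <- 1e-6
  d2 <- outer(rowSums(electrodes^2), rowSums(nodes^2), "+") -
    2 * electrodes %*% t(nodes)
  d <- sqrt(pmax(d2, eps^2))
  W <- 1 / d^scn$leadfield_exponent
  W <- W / rowSums(W)
  if (scn$leadfield_smoothing > 0) {
    nd2 <- outer(rowSums(nodes^2), rowSums(nodes^2), "+") -
      2 * nodes %*% t(nodes)
    S <- (sqrt(pmax(nd2, 0)) <= scn$leadfield_smoothing) * 1
    S <- S / rowSums(S)
    W <- W %*% t(S)
    W <- W / rowSums(W)
  }
  W
}

#' Project atrial sources to the torso
#'
#' Applies the lead field as a memoryless linear spatial mixing: each
#' torso sample is the weighted sum of all atrial node samples at the
#' same instant.
#'
#' @param atrial An [af_recording] of atrial-node channels.
#' @param leadfield Electrode x node weight matrix whose columns match
#'   the atrial channels.
#' @param electrodes Optional electrode coordinate matrix to attach.
#' @return An `af_recording` of torso-electrode channels.
#' @export
forward_project <- function(atrial, leadfield, electrodes = NULL) {
  if (ncol(leadfield) != n_channels(atrial)) {
    stop("leadfield columns must match atrial channel count")
  }
  samples <- leadfield %*% atrial$samples
  af_recording(samples, fs = atrial$fs,
               labels = sprintf("T%03d", seq_len(nrow(leadfield))),
               roles = "torso-electrode", coords = electrodes)
}

# stylized QRS-T waveform sampled at fs over [-pre, post] ms around R
qrst_waveform <- function(fs, pre_ms = 100, post_ms = 450) {
  t <- seq(-pre_ms / 1000, post_ms / 1000, by = 1 / fs)
  r <- exp(-(t / 0.012)^2)
  q <- -0.15 * exp(-((t + 0.040) / 0.015)^2)
  s <- -0.25 * exp(-((t - 0.040) / 0.015)^2)
  tw <- 0.35 * exp(-((t - 0.300) / 0.070)^2)
  list(wave = q + r + s + tw, r_index = which.min(abs(t)))
}

#' Add a ventricular far-field beat train
#'
#' Superimposes a shared, stylized QRS-T beat train — scaled per channel
#' by a seeded factor — on every channel, and appends a clean
#' reference-ecg channel (`"ECG_I"`) carrying the same beats for R-peak
#' detection and alignment. Ground-truth R-peak sample indices are
#' attached as attribute `"r_peaks"`.
#'
#' @param rec An [af_recording].
#' @param rate Mean beat rate in Hz (< 3).
#' @param amplitude Far-field amplitude; 0 returns the recording with
#'   only the (silent) reference channel appended.
#' @param rr_jitter_s Standard deviation of the seeded RR-interval
#'   jitter, s; 0 gives an exactly periodic train.
#' @param seed Integer seed for the per-channel scaling and RR jitter.
#' @param ref_label Label of the appended reference channel.
#' @return An `af_recording` with the far field added and the reference
#'   channel appended.
#' @export
add_ventricular_farfield <- function(rec, rate = 1.0, amplitude = 1.0,
                                     rr_jitter_s = 0, seed = 1L,
                                     ref_label = "ECG_I") {
  if (rate >= 3) stop("rate must be below 3 Hz")
  fs <- rec$fs; n <- n_samples(rec)
  qw <- qrst_waveform(fs)
  n_max <- ceiling(n * rate / fs) + 2L
  rr <- with_local_seed(seed + 1L, {
    pmax(1 / rate + stats::rnorm(n_max, 0, rr_jitter_s), 0.35)
  })
  if (rr_jitter_s == 0) rr <- rep(1 / rate, n_max)
  beat_starts <- round(0.25 * fs) + round(cumsum(c(0, rr)) * fs)
  beat_starts <- beat_starts[beat_starts <= n - length(qw$wave)]
  train <- numeric(n)
  for (b in beat_starts) {
    idx <- b:(b + length(qw$wave) - 1L)
    train[idx] <- train[idx] + qw$wave
  }
  r_peaks <- beat_starts + qw$r_index - 1L
  nch <- n_channels(rec)
  scales <- with_local_seed(seed, stats::runif(nch, 0.6, 1.4)) * amplitude
  samples <- rec$samples + outer(scales, train)
  samples <- rbind(samples, train)
  coords <- if (!is.null(rec$coords)) rbind(rec$coords, c(0, 0, 0))
  out <- af_recording(samples, fs = fs, labels = c(rec$labels, ref_label),
                      roles = c(rec$roles, "reference-ecg"), coords = coords,
                      valid_mask = c(rec$valid_mask, TRUE))
  attr(out, "r_peaks") <- r_peaks
  out
}

#' Add white noise and mains contamination
#'
#' Adds seeded Gaussian white noise and a mains sinusoid (random phase
#' per channel) to every channel. With `sigma = 0` and `mains_amp = 0`
#' the recording is returned unchanged.
#'
#' @param rec An [af_recording].
#' @param sigma White-noise standard deviation.
#' @param mains_amp Mains sinusoid amplitude (may be a per-channel
#'   vector).
#' @param mains_freq Mains frequency, Hz.
#' @param seed Integer seed.
#' @return The noisy `af_recording`.
#' @export
add_noise <- function(rec, sigma = 0, mains_amp = 0, mains_freq = 50,
                      seed = 1L) {
  if (all(sigma == 0) && all(mains_amp == 0)) return(rec)
  nch <- n_channels(rec); n <- n_samples(rec)
  t <- seq_len(n) / rec$fs
  rec$samples <- with_local_seed(seed, {
    x <- rec$samples
    if (any(sigma > 0)) {
      x <- x + matrix(stats::rnorm(nch * n, 0, sigma), nrow = nch)
    }
    if (any(mains_amp > 0)) {
      amp <- rep(mains_amp, length.out = nch)
      ph <- stats::runif(nch, 0, 2 * pi)
      for (i in seq_len(nch)) {
        if (amp[i] > 0) {
          x[i, ] <- x[i, ] + amp[i] * sin(2 * pi * mains_freq * t + ph[i])
        }
      }
    }
    x
  })
  rec
}

#' Simulate a complete paired recording set
#'
#' Runs the whole generative model of a scenario: atrial sources, lead
#' field, torso projection, ventricular far field on both recordings
#' (with a shared beat train and clean reference leads), then mains and
#' white noise. All randomness derives from the scenario seed, so a
#' fixed scenario reproduces identical recordings.
#'
#' @param scn A [synthetic_scenario].
#' @return List with `atrial` and `torso` recordings (each including an
#'   `"ECG_I"` reference channel), `truth` (node frequency map, driver
#'   flags, R-peak indices) and `leadfield`.
#' @export
simulate_scenario <- function(scn) {
  src <- simulate_atrial_sources(scn)
  W <- build_leadfield(scn)
  torso <- forward_project(src$recording, W, electrodes = torso_geometry(scn))
  atrial <- add_ventricular_farfield(src$recording, scn$ventricular_rate,
                                     amplitude = 0.5 * scn$ventricular_amp,
                                     rr_jitter_s = scn$rr_jitter_s,
                                     seed = scn$seed + 101L)
  torso <- add_ventricular_farfield(torso, scn$ventricular_rate,
                                    amplitude = scn$ventricular_amp,
                                    rr_jitter_s = scn$rr_jitter_s,
                                    seed = scn$seed + 101L)
  r_peaks <- attr(atrial, "r_peaks")
  atrial <- add_noise(atrial, scn$noise_sigma, scn$mains_amp, scn$mains_freq,
                      seed = scn$seed + 103L)
  torso <- add_noise(torso, scn$noise_sigma, scn$mains_amp, scn$mains_freq,
                     seed = scn$seed + 104L)
  list(atrial = atrial, torso = torso,
       truth = list(nodes = src$truth, r_peaks = r_peaks),
       leadfield = W)
}
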