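# Compact EDF/BDF reader and writer. EDF stores 16-bit little-endian
# samples, BDF (BioSemi) 24-bit; both share the same fixed-width ASCII
# header layout. Annotation channels are not supported: every signal is
# treated as a regular data channel and all signals must share one rate.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Read an EDF or BDF recording
#'
#' Reads all data signals from a European Data Format (EDF, 16-bit) or
#' BioSemi Data Format (BDF, 24-bit) file into an [af_recording]. The
#' format is auto-detected from the file's identification byte. Samples
#' are returned in physical units using the per-signal digital/physical
#' calibration from the header. All signals must share one sampling rate.
#'
#' @param path Path to the `.edf` / `.bdf` file.
#' @return An `af_recording` with roles set to `"atrial-node"` (override
#'   via a sidecar or [select_channels]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id0 <- readBin(con, "raw", n = 1L)
  id <- rawToChar(readBin(con, "raw", n = 7L))
  is_bdf <- id0 == as.raw(255L)
  if (!is_bdf && !(rawToChar(id0) %in% c("0", " "))) {
    stop("not an EDF/BDF file: ", path)
  }
  readBin(con, "raw", n = 160L)                        # patient + recording id
  readBin(con, "raw", n = 16L)                         # start date/time
  hdr_bytes <- as.integer(rawToChar(readBin(con, "raw", n = 8L)))
  readBin(con, "raw", n = 44L)                         # reserved
  n_rec <- as.integer(rawToChar(readBin(con, "raw", n = 8L)))
  rec_dur <- as.numeric(rawToChar(readBin(con, "raw", n = 8L)))
  ns <- as.integer(rawToChar(readBin(con, "raw", n = 4L)))
  rd_fields <- function(width) {
    vapply(seq_len(ns), function(i)
      trimws(rawToChar(readBin(con, "raw", n = width))), character(1))
  }
  labels <- rd_fields(16L)
  rd_fields(80L)                                       # transducer
  rd_fields(8L)                                        # physical dimension
  phys_min <- as.numeric(rd_fields(8L))
  phys_max <- as.numeric(rd_fields(8L))
  dig_min <- as.numeric(rd_fields(8L))
  dig_max <- as.numeric(rd_fields(8L))
  rd_fields(80L)                                       # prefiltering
  nsamp <- as.integer(rd_fields(8L))
  rd_fields(32L)                                       # reserved
  if (length(unique(nsamp)) != 1L) {
    stop("signals with differing per-record sample counts are not supported")
  }
  seek(con, hdr_bytes)
  bps <- if (is_bdf) 3L else 2L
  raw_all <- readBin(con, "raw", n = n_rec * sum(nsamp) * bps)
  if (length(raw_all) < n_rec * sum(nsamp) * bps) stop("truncated EDF/BDF data")
  if (is_bdf) {
    m <- matrix(as.integer(raw_all), nrow = 3L)
    dig <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    dig <- ifelse(dig >= 8388608, dig - 16777216, dig)
  } else {
    dig <- readBin(raw_all, "integer", n = length(raw_all) / 2L,
                   size = 2L, signed = TRUE, endian = "little")
  }
  # record-major layout: record 1 signal 1..ns, record 2 signal 1..ns, ...
  dig <- array(dig, dim = c(nsamp[1], ns, n_rec))
  samples <- matrix(0, nrow = ns, ncol = nsamp[1] * n_rec)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (s in seq_len(ns)) {
    samples[s, ] <- as.numeric(dig[, s, ]) * gain[s] +
      (phys_min[s] - dig_min[s] * gain[s])
  }
  af_recording(samples, fs = nsamp[1] / rec_dur,
               labels = make.unique(labels), roles = "atrial-node")
}

#' Write a recording as EDF or BDF
#'
#' Writes an [af_recording] to the 16-bit EDF or 24-bit BDF format, one
#' data record per second (`fs` must therefore be a positive integer).
#' Per-channel physical ranges are taken from the data; digital ranges
#' use the full signed 16/24-bit span, so the round trip quantizes each
#' channel to its range over 2^15 (EDF) or 2^23 (BDF) steps.
#'
#' @param rec An `af_recording` with integer `fs`.
#' @param path Output file path.
#' @param type `"edf"` or `"bdf"`.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path, type = c("edf", "bdf")) {
  type <- match.arg(type)
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF/BDF writer requires integer fs")
  ns <- n_channels(rec)
  n_rec <- floor(n_samples(rec) / fs)
  if (n_rec < 1L) stop("recording shorter than one 1 s data record")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  dmax <- if (type == "bdf") 8388607L else 32767L
  dmin <- -dmax - 1L
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmax[flat] <- pmin[flat] + 1
  # digitize against the values as actually written into the 8-char header
  # fields, so reader and writer use the identical calibration
  as_field <- function(v) as.numeric(formatC(v, format = "g", digits = 5))
  pmin <- as_field(pmin - abs(pmin) * 1e-4)
  pmax <- as_field(pmax + abs(pmax) * 1e-4)
  con <- file(path, "wb")
  on.exit(close(con))
  if (type == "bdf") {
    writeBin(as.raw(255L), con)
    writeChar("BIOSEMI", con, nchars = 7, eos = NULL)
  } else {
    writeChar(pad_field("0", 8), con, eos = NULL)
  }
  writeChar(pad_field("X", 80), con, eos = NULL)       # patient id
  writeChar(pad_field("X", 80), con, eos = NULL)       # recording id
  writeChar("01.01.0001.00.01", con, eos = NULL)       # start date + time
  hdr_bytes <- 256L + 256L * ns
  writeChar(pad_field(hdr_bytes, 8), con, eos = NULL)
  res44 <- if (type == "bdf") "24BIT" else ""
  writeChar(pad_field(res44, 44), con, eos = NULL)
  writeChar(pad_field(n_rec, 8), con, eos = NULL)
  writeChar(pad_field(1, 8), con, eos = NULL)          # record duration 1 s
  writeChar(pad_field(ns, 4), con, eos = NULL)
  wr <- function(vals, width) {
    for (v in vals) writeChar(pad_field(v, width), con, eos = NULL)
  }
  wr(rec$labels, 16); wr(rep("", ns), 80); wr(rep("uV", ns), 8)
  wr(pmin, 8); wr(pmax, 8)
  wr(rep(dmin, ns), 8); wr(rep(dmax, ns), 8)
  wr(rep("", ns), 80); wr(rep(fs, ns), 8); wr(rep("", ns), 32)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- x[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((seg - pmin[s]) / gain[s]) + dmin)
      dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
      if (type == "bdf") {
        u <- ifelse(dig < 0, dig + 16777216L, dig)
        b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
        writeBin(as.raw(b), con)
      } else {
        writeBin(dig, con, size = 2L, endian = "little")
      }
    }
  }
  invisible(path)
}
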