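#' Multichannel recording container
#'
#' An `af_recording` holds a time-aligned channel-by-sample matrix of
#' potentials together with its sampling rate and per-channel metadata.
#' It is the common container for endocardial (virtual electrogram) node
#' signals, torso body-surface electrode signals and reference ECG leads.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param labels Character vector of unique channel identifiers, one per row.
#' @param roles Character vector of per-channel role tags; each must be one
#'   of `"atrial-node"`, `"torso-electrode"` or `"reference-ecg"`. A single
#'   value is recycled.
#' @param coords Optional numeric matrix of per-channel 3D positions
#'   (channels x 3, arbitrary length units), or `NULL`.
#' @param valid_mask Logical vector of per-channel quality-control status;
#'   defaults to all `TRUE`.
#'
#' @return An object of class `af_recording`: a list with elements
#'   `samples`, `fs`, `labels`, `roles`, `coords`, `valid_mask`.
#' @export
#' @examples
#' x <- matrix(rnorm(3 * 512), nrow = 3)
#' rec <- af_recording(x, fs = 512, labels = c("a", "b", "c"),
#'                     roles = "atrial-node")
#' n_samples(rec)
af_recording <- function(samples, fs, labels, roles,
                         coords = NULL, valid_mask = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x time)")
  }
  nch <- nrow(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive finite scalar (Hz)")
  }
  labels <- as.character(labels)
  if (length(labels) != nch) stop("`labels` length must equal channel count")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  roles <- as.character(roles)
  if (length(roles) == 1L) roles <- rep(roles, nch)
  if (length(roles) != nch) stop("`roles` length must equal channel count")
  ok_roles <- c("atrial-node", "torso-electrode", "reference-ecg")
  if (!all(roles %in% ok_roles)) {
    stop("roles must be one of: ", paste(ok_roles, collapse = ", "))
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nch || ncol(coords) != 3L) {
      stop("`coords` must be a channels x 3 matrix")
    }
  }
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, nch)
  if (length(valid_mask) != nch || !is.logical(valid_mask)) {
    stop("`valid_mask` must be logical with one entry per channel")
  }
  rownames(samples) <- labels
  structure(
    list(samples = samples, fs = fs, labels = labels, roles = roles,
         coords = coords, valid_mask = valid_mask),
    class = "af_recording"
  )
}

#' @export
print.af_recording <- function(x, ...) {
  cat(sprintf("<af_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  tb <- table(x$roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("  valid channels: %d/%d\n", sum(x$valid_mask), length(x$valid_mask)))
  invisible(x)
}

#' Number of samples per channel
#' @param rec An `af_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' Number of channels
#' @param rec An `af_recording`.
#' @return Integer channel count.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' Subset channels of a recording
#'
#' @param rec An `af_recording`.
#' @param which Logical, integer or character index of channels to keep.
#' @return A new `af_recording` with the selected channels.
#' @export
select_channels <- function(rec, which) {
  if (is.character(which)) which <- match(which, rec$labels)
  if (anyNA(which)) stop("unknown channel label")
  af_recording(rec$samples[which, , drop = FALSE], rec$fs,
               rec$labels[which], rec$roles[which],
               coords = if (!is.null(rec$coords)) rec$coords[which, , drop = FALSE],
               valid_mask = rec$valid_mask[which])
}

#' Extract one channel as a numeric vector
#' @param rec An `af_recording`.
#' @param label Channel label.
#' @return Numeric vector of samples.
#' @export
channel <- function(rec, label) {
  i <- match(label, rec$labels)
  if (is.na(i)) stop("channel not found: ", label)
  rec$samples[i, ]
}

#' Read a multichannel recording
#'
#' Loads a recording from either the canonical delimited-matrix format
#' (channels as rows, one row per channel, whitespace/comma separated)
#' with a YAML metadata sidecar, or from an EDF/BDF file. The sidecar
#' carries `fs`, `labels`, `roles` and optional `coords`; for EDF/BDF the
#' rate and labels come from the file header and the sidecar (if given)
#' may supply roles and coordinates.
#'
#' @param path Path to the data file.
#' @param format One of `"matrix"`, `"edf"`, `"bdf"`.
#' @param sidecar Path to the YAML sidecar; required for `"matrix"`,
#'   optional for EDF/BDF.
#' @return An `af_recording` with all channels initially valid.
#' @export
load_recording <- function(path, format = c("matrix", "edf", "bdf"),
                           sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix") {
    if (is.null(sidecar)) stop("matrix format requires a YAML sidecar")
    meta <- yaml::read_yaml(sidecar)
    if (is.null(meta$fs) || is.null(meta$labels)) {
      stop("sidecar must provide `fs` and `labels`")
    }
    samples <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(samples) <- NULL
    if (length(meta$labels) != nrow(samples)) {
      stop(sprintf("sidecar lists %d channels but file has %d rows",
                   length(meta$labels), nrow(samples)))
    }
    roles <- if (is.null(meta$roles)) "atrial-node" else unlist(meta$roles)
    coords <- if (!is.null(meta$coords)) {
      do.call(rbind, lapply(meta$coords, as.numeric))
    }
    af_recording(samples, fs = meta$fs, labels = unlist(meta$labels),
                 roles = roles, coords = coords)
  } else {
    rec <- read_edf(path)
    if (!is.null(sidecar)) {
      meta <- yaml::read_yaml(sidecar)
      if (!is.null(meta$labels) && length(meta$labels) != n_channels(rec)) {
        stop(sprintf("sidecar lists %d channels but file has %d",
                     length(meta$labels), n_channels(rec)))
      }
      if (!is.null(meta$roles)) rec$roles <- rep(unlist(meta$roles),
                                                 length.out = n_channels(rec))
      if (!is.null(meta$coords)) {
        rec$coords <- do.call(rbind, lapply(meta$coords, as.numeric))
      }
    }
    rec
  }
}

#' Write a recording in the canonical matrix + sidecar format
#'
#' @param rec An `af_recording`.
#' @param path Output path for the delimited sample matrix (channels as
#'   rows, tab separated).
#' @param sidecar Output path for the YAML metadata sidecar.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, sidecar) {
  utils::write.table(rec$samples, path, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  meta <- list(fs = rec$fs, labels = as.list(rec$labels),
               roles = as.list(rec$roles))
  if (!is.null(rec$coords)) {
    meta$coords <- lapply(seq_len(nrow(rec$coords)),
                          function(i) as.numeric(rec$coords[i, ]))
  }
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}
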