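#' Highest dominant frequency of one window
#'
#' For one dataset (endocardial nodes or body-surface electrodes) and one
#' analysis window, the HDF is the maximum DF over channels whose
#' organization index exceeds `oi_threshold`; channels whose DF lies
#' within 0.25 Hz below the HDF form the HDF-hosting area. With no
#' eligible channel the HDF is undefined for the window.
#'
#' @param df_results Data frame rows from [analyze_recording] for one
#'   window of one dataset.
#' @param oi_threshold Organization-index threshold in [0, 1]; a channel
#'   is eligible only if its OI strictly exceeds it.
#' @param area_hz Width of the hosting band below the HDF, Hz.
#' @return A list of class `hdf_window`: `window`, `hdf` (Hz or `NA`),
#'   `hosting_nodes` (character), `peak_channel` (channel attaining the
#'   HDF), `harmonic_status` (of the peak channel), `oi_threshold`,
#'   `excluded`, `exclusion_reason`.
#' @export
hdf_for_window <- function(df_results, oi_threshold = 0, area_hz = 0.25) {
  if (!nrow(df_results)) stop("df_results is empty")
  if (length(unique(df_results$window)) != 1L) {
    stop("df_results mixes several window indices")
  }
  win <- df_results$window[1]
  elig <- df_results[df_results$oi > oi_threshold, , drop = FALSE]
  if (!nrow(elig)) {
    return(structure(list(window = win, hdf = NA_real_,
                          hosting_nodes = character(0),
                          peak_channel = NA_character_,
                          harmonic_status = NA_character_,
                          oi_threshold = oi_threshold, excluded = TRUE,
                          exclusion_reason = "no-node-above-threshold"),
                     class = "hdf_window"))
  }
  hdf <- max(elig$df)
  hosts <- elig$channel[elig$df >= hdf - area_hz - 1e-9]
  ipk <- which(elig$df == hdf)[1]
  structure(list(window = win, hdf = hdf, hosting_nodes = hosts,
                 peak_channel = elig$channel[ipk],
                 harmonic_status = elig$harmonic_status[ipk],
                 oi_threshold = oi_threshold, excluded = FALSE,
                 exclusion_reason = "none"),
            class = "hdf_window")
}

#' HDF results for every window of one dataset
#'
#' @param df_table Full output of [analyze_recording] for one dataset.
#' @param oi_threshold Organization-index threshold.
#' @param area_hz Width of the hosting band below the HDF, Hz.
#' @return List of `hdf_window` objects indexed by window.
#' @export
hdf_by_window <- function(df_table, oi_threshold = 0, area_hz = 0.25) {
  lapply(split(df_table, df_table$window), hdf_for_window,
         oi_threshold = oi_threshold, area_hz = area_hz)
}

#' Pair endocardial and body-surface windows, excluding harmonics
#'
#' Builds the window-by-window pairing of the two datasets and excludes
#' from further analysis every window in which the HDF-hosting peak of
#' either dataset was classified as a possible harmonic, as well as
#' windows where either HDF is undefined.
#'
#' @param vegm,bsm Lists of `hdf_window` objects (same windows) from
#'   [hdf_by_window] for the endocardial and body-surface datasets.
#' @return Data frame with one row per window: `window`, `vegm_hdf`,
#'   `bsm_hdf`, `vegm_hosts`, `bsm_hosts` (list columns of channel ids),
#'   `excluded`, `exclusion_reason`.
#' @export
exclude_harmonic_windows <- function(vegm, bsm) {
  wv <- vapply(vegm, `[[`, numeric(1), "window")
  wb <- vapply(bsm, `[[`, numeric(1), "window")
  common <- intersect(wv, wb)
  rows <- lapply(common, function(w) {
    v <- vegm[[match(w, wv)]]; b <- bsm[[match(w, wb)]]
    reason <- "none"
    if (v$excluded || b$excluded) {
      reason <- "no-node-above-threshold"
    } else if ((!is.na(v$harmonic_status) && v$harmonic_status != "none") ||
               (!is.na(b$harmonic_status) && b$harmonic_status != "none")) {
      reason <- "harmonic"
    }
    data.frame(window = w, vegm_hdf = v$hdf, bsm_hdf = b$hdf,
               vegm_hosts = I(list(v$hosting_nodes)),
               bsm_hosts = I(list(b$hosting_nodes)),
               excluded = reason != "none", exclusion_reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

iqr_range <- function(x) {
  if (!length(x)) return(c(NA_real_, NA_real_))
  stats::quantile(x, c(0.25, 0.75), names = FALSE)
}

#' Sweep the organization-index threshold
#'
#' Recomputes window HDFs for every OI threshold on the grid (0 to 1 in
#' steps of 0.1 by default) and reports, per threshold, the percentage
#' of windows with a defined HDF — both over all analyzable windows and
#' over the windows surviving harmonic exclusion. At `compare_threshold`
#' it additionally compares each window's HDF-hosting node set against
#' the unthresholded one: percentage of valid nodes hosting the HDF
#' before and after, percentage of original HDF nodes persisting, and
#' percentage of post-threshold HDF nodes that are new.
#'
#' @param df_table Output of [analyze_recording] for one dataset.
#' @param thresholds Numeric vector of OI thresholds in [0, 1].
#' @param compare_threshold Threshold used for the node-set comparison.
#' @param area_hz Width of the hosting band below the HDF, Hz.
#' @return A list of class `oi_sweep`: `curve` (data frame `threshold`,
#'   `pct_windows_defined`, `pct_windows_defined_nonharmonic`),
#'   `node_comparison` (per-window data frame with hosting percentages,
#'   persisting and new node percentages), and `summary` (median and
#'   interquartile range of each percentage across windows).
#' @export
oi_threshold_sweep <- function(df_table, thresholds = seq(0, 1, by = 0.1),
                               compare_threshold = 0.5, area_hz = 0.25) {
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]")
  }
  base <- hdf_by_window(df_table, 0, area_hz)
  harmonic_win <- vapply(base, function(h) {
    !is.na(h$harmonic_status) && h$harmonic_status != "none"
  }, logical(1))
  n_win <- length(base)
  curve <- do.call(rbind, lapply(thresholds, function(th) {
    hs <- hdf_by_window(df_table, th, area_hz)
    defined <- vapply(hs, function(h) !h$excluded, logical(1))
    data.frame(
      threshold = th,
      pct_windows_defined = 100 * sum(defined) / n_win,
      pct_windows_defined_nonharmonic = if (any(!harmonic_win)) {
        100 * sum(defined & !harmonic_win) / sum(!harmonic_win)
      } else NA_real_)
  }))
  n_nodes <- length(unique(df_table$channel))
  after <- hdf_by_window(df_table, compare_threshold, area_hz)
  comp <- do.call(rbind, lapply(seq_along(base), function(i) {
    b <- base[[i]]$hosting_nodes; a <- after[[i]]$hosting_nodes
    data.frame(
      window = base[[i]]$window,
      pct_hosting_before = 100 * length(b) / n_nodes,
      pct_hosting_after = 100 * length(a) / n_nodes,
      pct_persisting = if (length(b)) 100 * length(intersect(b, a)) / length(b)
                       else NA_real_,
      pct_new = if (length(a)) 100 * length(setdiff(a, b)) / length(a)
                else NA_real_)
  }))
  rownames(comp) <- NULL
  summ <- lapply(comp[-1], function(x) {
    x <- x[is.finite(x)]
    list(median = stats::median(x), iqr = iqr_range(x))
  })
  structure(list(curve = curve, node_comparison = comp, summary = summ,
                 compare_threshold = compare_threshold),
            class = "oi_sweep")
}

#' Paired body-surface minus endocardial HDF differences
#'
#' For every paired, non-excluded window computes the HDF difference
#' (body surface minus endocardial) and groups the records into 0.5 Hz
#' bins of the endocardial HDF with edges on integer and half-integer Hz
#' (half-open `[x.0, x.5)`, bin centers at x.25 / x.75). Reports per-bin
#' median, interquartile range and count.
#'
#' @param paired Data frame from [exclude_harmonic_windows].
#' @return A list of class `hdf_difference_table`: `records` (window,
#'   vegm_hdf, bsm_hdf, diff, bin_center) and `bins` (bin_center, median,
#'   q25, q75, n). Empty, with a warning, when no window survives.
#' @export
hdf_difference_analysis <- function(paired) {
  keep <- paired[!paired$excluded & is.finite(paired$vegm_hdf) &
                   is.finite(paired$bsm_hdf), , drop = FALSE]
  if (!nrow(keep)) {
    warning("no paired windows survive exclusion")
    return(structure(list(records = data.frame(), bins = data.frame()),
                     class = "hdf_difference_table"))
  }
  rec <- data.frame(window = keep$window, vegm_hdf = keep$vegm_hdf,
                    bsm_hdf = keep$bsm_hdf,
                    diff = keep$bsm_hdf - keep$vegm_hdf)
  rec$bin_center <- floor(rec$vegm_hdf * 2) / 2 + 0.25
  bins <- do.call(rbind, lapply(split(rec, rec$bin_center), function(g) {
    q <- iqr_range(g$diff)
    data.frame(bin_center = g$bin_center[1],
               median = stats::median(g$diff),
               q25 = q[1], q75 = q[2], n = nrow(g))
  }))
  bins <- bins[order(bins$bin_center), ]
  rownames(bins) <- NULL
  structure(list(records = rec, bins = bins),
            class = "hdf_difference_table")
}

#' Exponential fit of the HDF difference-versus-frequency curve
#'
#' Fits the per-bin median differences against bin center with the
#' exponentially decaying model
#' `d(f) = -a * exp(b * (f - f0)) + c`,
#' `f0` fixed at the lowest bin center, by Levenberg-Marquardt nonlinear
#' least squares. Starting values come from a log-linearization of the
#' residual `c - d`; a small set of deterministically scaled restarts
#' guards against poor initialization. Asymptotic 95% confidence
#' intervals and the coefficient of determination against the bin
#' medians are returned.
#'
#' @param diff_table An `hdf_difference_table` (or a data frame with
#'   columns `bin_center` and `median`).
#' @param min_bins Minimum number of bins with defined medians.
#' @return A list of class `exp_fit`: `params` (a, b, c), `f0`, `ci95`
#'   (2 x 3 matrix), `r_squared`, `fitted`, `residuals`, `degenerate`.
#' @export
fit_exponential <- function(diff_table, min_bins = 4) {
  bins <- if (inherits(diff_table, "hdf_difference_table")) {
    diff_table$bins
  } else diff_table
  bins <- bins[is.finite(bins$median), , drop = FALSE]
  if (nrow(bins) < min_bins) {
    stop(sprintf("need at least %d bins with defined medians, have %d",
                 min_bins, nrow(bins)))
  }
  f <- bins$bin_center; y <- bins$median
  f0 <- min(f)
  if (stats::sd(y) < 1e-12) {
    # constant medians: the decay branch is unidentifiable; report the
    # constant model, exact by construction
    ci <- matrix(NA_real_, 2, 3,
                 dimnames = list(c("lo", "hi"), c("a", "b", "c")))
    return(structure(list(params = c(a = 0, b = 0, c = mean(y)), f0 = f0,
                          ci95 = ci, r_squared = 1, fitted = rep(mean(y),
                          length(y)), residuals = y - mean(y),
                          degenerate = TRUE),
                     class = "exp_fit"))
  }
  c0 <- max(y) + 0.05 * diff(range(y)) + 1e-9
  z <- log(pmax(c0 - y, 1e-12))
  lin <- stats::lm(z ~ I(f - f0))
  a0 <- exp(unname(stats::coef(lin)[1])); b0 <- unname(stats::coef(lin)[2])
  dat <- data.frame(f = f, y = y)
  best <- NULL
  for (sc in c(1, 0.5, 2, 0.25, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ -a * exp(b * (f - f0)) + c, data = dat,
        start = list(a = a0 * sc, b = b0 * sc, c = c0),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) stop("exponential fit failed to converge")
  fit <- best$fit
  est <- stats::coef(fit)
  fitted <- as.numeric(stats::fitted(fit))
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - best$sse / sstot else 1
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  tq <- stats::qt(0.975, max(length(y) - 3L, 1L))
  ci <- rbind(lo = est - tq * se, hi = est + tq * se)
  colnames(ci) <- c("a", "b", "c")
  structure(list(params = c(a = unname(est["a"]), b = unname(est["b"]),
                            c = unname(est["c"])),
                 f0 = f0, ci95 = ci, r_squared = r2, fitted = fitted,
                 residuals = y - fitted, degenerate = FALSE),
            class = "exp_fit")
}

#' Compare atrial HDF-area distributions for concordant vs discordant windows
#'
#' Partitions the paired windows into those where the body-surface HDF
#' matched the endocardial HDF within 0.5 Hz ("same") and the rest
#' ("different"), computes each window's atrial HDF area as the
#' percentage of valid atrial nodes hosting the HDF, and compares the
#' two area distributions with a Mann-Whitney rank-sum test.
#'
#' @param paired Data frame from [exclude_harmonic_windows].
#' @param n_atrial_nodes Number of valid atrial channels (denominator of
#'   the area percentage).
#' @param same_hz Concordance tolerance in Hz.
#' @param breaks Histogram breaks for the normalized area distributions
#'   (percent of atrium).
#' @return A list of class `area_comparison`: `same_areas`,
#'   `diff_areas` (percent), `hist_same`, `hist_diff` (normalized
#'   histograms or `NULL` for an empty partition), `p_value`.
#' @export
area_distribution_comparison <- function(paired, n_atrial_nodes,
                                         same_hz = 0.5,
                                         breaks = seq(0, 100, by = 2)) {
  keep <- paired[!paired$excluded, , drop = FALSE]
  if (!nrow(keep)) stop("no paired windows to compare")
  area <- 100 * vapply(keep$vegm_hosts, length, integer(1)) / n_atrial_nodes
  same <- abs(keep$bsm_hdf - keep$vegm_hdf) <= same_hz + 1e-9
  norm_hist <- function(x) {
    if (!length(x)) return(NULL)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(mids = h$mids, ratio = h$counts / length(x))
  }
  if (!any(same) || all(same)) {
    warning("one HDF-concordance partition is empty")
    p <- NA_real_
  } else {
    p <- stats::wilcox.test(area[same], area[!same], exact = FALSE)$p.value
  }
  structure(list(same_areas = area[same], diff_areas = area[!same],
                 hist_same = norm_hist(area[same]),
                 hist_diff = norm_hist(area[!same]), p_value = p),
            class = "area_comparison")
}
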