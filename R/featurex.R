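# Window segmentation and the 78 window features (30 time-domain,
# 48 frequency-domain).
#
# Axis naming follows the actigraphy convention for feature names:
# x = horizontal (device axis 2), y = vertical (axis 1),
# z = perpendicular (axis 3). VM is the per-sample vector magnitude.
#
# Frequency features are computed on the magnitude spectrum of the
# mean-detrended signal (scaled so a sinusoid of amplitude A contributes a
# bin magnitude of about A), over the non-DC bins up to Nyquist. With 5-s
# windows at 30 Hz the bin resolution is 0.2 Hz; "bin 1..10" span
# 0.2-2.0 Hz. The weighted mean is the spectral centroid
# sum(f * |S(f)|) / sum(|S(f)|).

.axis_letters <- c(axis2 = "x", axis1 = "y", axis3 = "z")

#' Canonical feature names
#'
#' Names and order of the 78 window features: for each axis x/y/z the seven
#' time-domain statistics (mean, SD, median, min, max, skewness, kurtosis),
#' six statistics of the per-sample vector magnitude (mean, median, min,
#' max, skewness, kurtosis), three pairwise zero-lag cross-correlations
#' (xy, yz, xz), then per axis the six spectral statistics (mean, SD,
#' median, min, max, weighted mean/centroid) and the first ten non-DC FFT
#' bin magnitudes.
#'
#' @param domain `"all"`, `"time"`, or `"freq"`.
#' @return Character vector of feature names (78, 30, or 48).
#' @examples
#' length(feature_names())
#' @export
feature_names <- function(domain = c("all", "time", "freq")) {
  domain <- match.arg(domain)
  ax <- c("x", "y", "z")
  tstats <- c("mean", "sd", "median", "min", "max", "skew", "kurt")
  time_nm <- c(
    as.vector(t(outer(ax, tstats, function(a, s) paste0(s, "_", a)))),
    paste0(c("mean", "median", "min", "max", "skew", "kurt"), "_vm"),
    c("corr_xy", "corr_yz", "corr_xz")
  )
  fstats <- c("fft_mean", "fft_sd", "fft_median", "fft_min", "fft_max",
              "fft_wmean")
  freq_nm <- as.vector(vapply(ax, function(a) {
    c(paste0(fstats, "_", a), sprintf("fft_bin%02d_%s", 1:10, a))
  }, character(16L)))
  switch(domain, time = time_nm, freq = freq_nm, all = c(time_nm, freq_nm))
}

#' @rdname feature_names
#' @details `spectral_shape_features()` returns the nine spectral-shape
#'   summaries (SD, max, and weighted mean of the magnitude spectrum, per
#'   axis) — the features expected to separate low-pass-smoothed "carried"
#'   signals from broadband ambulation, since foot-strike transients raise
#'   spectral spread while an adult's damped gait concentrates energy below
#'   3 Hz.
#' @export
spectral_shape_features <- function() {
  as.vector(outer(c("fft_sd", "fft_max", "fft_wmean"), c("x", "y", "z"),
                  paste, sep = "_"))
}

# Column-wise moments for a samples-in-columns matrix; constant columns get
# skewness 0 and excess kurtosis 0 by convention.
.col_moments <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  cm <- sweep(m, 2L, mu)
  m2 <- colMeans(cm^2)
  s <- sqrt(colSums(cm^2) / (n - 1))
  skew <- ifelse(m2 > 0, colMeans(cm^3) / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, colMeans(cm^4) / m2^2 - 3, 0)
  list(mean = mu, sd = s, median = apply(m, 2L, median),
       min = apply(m, 2L, min), max = apply(m, 2L, max),
       skew = skew, kurt = kurt, centered = cm)
}

.col_cor <- function(ca, cb) {
  sa <- sqrt(colSums(ca^2))
  sb <- sqrt(colSums(cb^2))
  r <- colSums(ca * cb) / (sa * sb)
  r[!is.finite(r)] <- 0   # a constant axis has no defined correlation
  r
}

# Vectorized feature core: `axes` is a list of three n x m matrices
# (axis1, axis2, axis3), each column one window. Returns an m x 78 matrix.
.compute_features <- function(axes, sample_rate) {
  n <- nrow(axes[[1L]])
  m <- ncol(axes[[1L]])
  x <- axes[[2L]]  # horizontal
  y <- axes[[1L]]  # vertical
  z <- axes[[3L]]  # perpendicular
  mx <- .col_moments(x)
  my <- .col_moments(y)
  mz <- .col_moments(z)
  vm <- sqrt(x^2 + y^2 + z^2)
  mv <- .col_moments(vm)
  tstats <- c("mean", "sd", "median", "min", "max", "skew", "kurt")
  time_block <- cbind(
    do.call(cbind, mx[tstats]),
    do.call(cbind, my[tstats]),
    do.call(cbind, mz[tstats]),
    do.call(cbind, mv[c("mean", "median", "min", "max", "skew", "kurt")]),
    .col_cor(mx$centered, my$centered),
    .col_cor(my$centered, mz$centered),
    .col_cor(mx$centered, mz$centered)
  )
  nb <- n %/% 2L                       # non-DC bins up to Nyquist
  freq_hz <- (1:nb) * sample_rate / n
  spec_block <- lapply(list(x, y, z), function(a) {
    sp <- mvfft(sweep(a, 2L, colMeans(a)))
    mag <- 2 * Mod(sp[1L + (1:nb), , drop = FALSE]) / n
    tot <- colSums(mag)
    wmean <- ifelse(tot > 0, colSums(mag * freq_hz) / tot, 0)
    cbind(colMeans(mag), sqrt(colSums(sweep(mag, 2L, colMeans(mag))^2) / (nb - 1)),
          apply(mag, 2L, median), apply(mag, 2L, min), apply(mag, 2L, max),
          wmean, t(mag[1:10, , drop = FALSE]))
  })
  out <- cbind(time_block, do.call(cbind, spec_block))
  dimnames(out) <- list(NULL, feature_names())
  out
}

#' Segment synchronized data into single-behavior windows
#'
#' Tiles each label's trimmed interval (first and last second excluded)
#' with non-overlapping windows of `window_s` seconds, starting at the
#' trimmed start. Windows never straddle a label boundary and any trailing
#' partial window is discarded, so every window describes 100% of a single
#' behavior. A 14-s label trims to 12 s and yields two 5-s windows; a 5-s
#' label trims to 3 s and yields none.
#'
#' @param trace An [accel_trace()] synchronized with `track`.
#' @param track A [label_track()].
#' @param window_s Window length in seconds (default 5).
#' @param behaviors Behaviors eligible for windowing (default the five
#'   classification behaviors: carried, run, walk, crawl, climb).
#' @return A list of windows, each a list with `samples` (matrix
#'   `window_s * sample_rate` x 3), `behavior`, `participant`, `start`.
#' @export
segment_windows <- function(trace, track, window_s = 5,
                            behaviors = classifier_behaviors()) {
  sr <- trace$sample_rate
  wlen <- window_s * sr
  if (wlen != round(wlen)) {
    stop("window length times sample rate must be a whole number of samples")
  }
  wlen <- as.integer(wlen)
  track <- track[track$behavior %in% behaviors, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(track))) {
    a <- track$start[i] + 1
    b <- track$end[i] - 1
    n_win <- max(0, floor((b - a) / window_s))
    for (w in seq_len(n_win)) {
      t0 <- a + (w - 1) * window_s
      i0 <- round((t0 - trace$start_time) * sr) + 1L
      if (i0 < 1L || i0 + wlen - 1L > nrow(trace$samples)) next
      out[[length(out) + 1L]] <- list(
        samples = trace$samples[i0:(i0 + wlen - 1L), , drop = FALSE],
        behavior = track$behavior[i],
        participant = track$participant[i],
        site = trace$site,
        start = t0
      )
    }
  }
  out
}

#' Time-domain features of one window
#'
#' The 30 time-domain features: mean, SD, median, min, max, skewness, and
#' excess kurtosis of each axis (x = horizontal, y = vertical,
#' z = perpendicular); mean, median, min, max, skewness, and kurtosis of
#' the per-sample vector magnitude; and the zero-lag cross-correlation of
#' each axis pair. Skewness and kurtosis of a constant signal are defined
#' as 0.
#'
#' @param window A window from [segment_windows()], or a samples matrix.
#' @param sample_rate Sample rate in Hz (used only by the frequency
#'   features; accepted here for symmetry).
#' @return Named numeric vector of length 30.
#' @export
time_domain_features <- function(window, sample_rate = 30) {
  .single_window_features(window, sample_rate)[feature_names("time")]
}

#' Frequency-domain features of one window
#'
#' The 48 frequency-domain features: per axis, the mean, SD, median, min,
#' max, and weighted mean (spectral centroid) of the magnitude spectrum of
#' the mean-detrended signal, plus the first ten non-DC bin magnitudes
#' (0.2 Hz resolution for 5-s windows at 30 Hz, so bins 1-10 span
#' 0.2-2.0 Hz).
#'
#' @inheritParams time_domain_features
#' @return Named numeric vector of length 48.
#' @export
freq_domain_features <- function(window, sample_rate = 30) {
  .single_window_features(window, sample_rate)[feature_names("freq")]
}

.single_window_features <- function(window, sample_rate) {
  samples <- if (is.list(window) && !is.null(window$samples)) {
    window$samples
  } else {
    as.matrix(window)
  }
  axes <- list(matrix(samples[, 1L]), matrix(samples[, 2L]),
               matrix(samples[, 3L]))
  drop(.compute_features(axes, sample_rate))
}

#' Extract the feature table for a batch of windows
#'
#' One row per window with provenance columns (`participant`, `behavior`,
#' `site`, `window_start`) followed by the 78 feature columns in the stable
#' canonical order of [feature_names()]. An empty window list yields an
#' empty table with the full 82-column header.
#'
#' @param windows A list of windows from [segment_windows()].
#' @param sample_rate Sample rate in Hz.
#' @return A `data.frame` with 4 + 78 columns.
#' @export
extract_features <- function(windows, sample_rate = 30) {
  meta_cols <- c("participant", "behavior", "site", "window_start")
  if (!length(windows)) {
    empty <- c(
      stats::setNames(rep(list(character(0)), 3L), meta_cols[1:3]),
      list(window_start = numeric(0)),
      stats::setNames(rep(list(numeric(0)), 78L), feature_names())
    )
    return(as.data.frame(empty, stringsAsFactors = FALSE, optional = TRUE))
  }
  axes <- lapply(1:3, function(j) {
    vapply(windows, function(w) w$samples[, j], numeric(nrow(windows[[1L]]$samples)))
  })
  feats <- .compute_features(axes, sample_rate)
  meta <- data.frame(
    participant = vapply(windows, function(w) w$participant %||% NA_character_, ""),
    behavior = vapply(windows, function(w) w$behavior %||% NA_character_, ""),
    site = vapply(windows, function(w) w$site %||% NA_character_, ""),
    window_start = vapply(windows, function(w) w$start %||% NA_real_, 0),
    stringsAsFactors = FALSE
  )
  cbind(meta, as.data.frame(feats))
}
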