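# Open activity-count algorithm and cut-point utilities.
#
# Proprietary ActiLife counts are emulated with a documented open pipeline:
# per axis, band-pass 0.25-2.5 Hz (Butterworth order 3, zero-phase),
# decimate to 10 Hz, rectify, apply a dead-band, clip, quantize, and sum
# per epoch. Absolute values approximate commercial counts; analyses built
# on them here are ordinal or arithmetic.

.count_filter_band <- c(0.25, 2.5)   # Hz
.count_rate <- 10                     # Hz internal rate after decimation
.count_deadband <- 0.05               # g
.count_lsb <- 0.05                    # g per count unit
.count_peak <- 2.5                    # g clip before quantization

#' Compute per-epoch activity counts from a raw trace
#'
#' Converts a raw triaxial trace to non-negative integer activity counts per
#' epoch for each axis. The algorithm band-pass filters each axis at
#' 0.25–2.5 Hz (removing gravity and high-frequency noise), decimates to
#' 10 Hz, rectifies, zeroes samples below a 0.05 g dead-band, clips at
#' 2.5 g, quantizes at 0.05 g per unit, and sums within each epoch.
#' Quantization precedes the epoch sum, so counts are exactly additive
#' across epoch lengths: 1-s counts summed in groups of five equal 5-s
#' counts. A trailing partial epoch is dropped.
#'
#' @param trace An [accel_trace()]. Its sample rate must be a multiple of
#'   10 Hz (e.g. 30 Hz).
#' @param epoch_length_s Epoch length in seconds.
#' @return An [epoch_counts()] data frame (one row per complete epoch) with
#'   derived vector-magnitude column `vm`.
#' @examples
#' tr <- simulate_bout("walk", 20, "hip", seed = 1)
#' compute_counts(tr, 5)
#' @export
compute_counts <- function(trace, epoch_length_s = 5) {
  stopifnot(inherits(trace, "accel_trace"))
  assert_scalar_number(epoch_length_s, "epoch_length_s", min = 1e-9)
  sr <- trace$sample_rate
  if (sr %% .count_rate != 0) {
    stop(sprintf(
      "unsupported sample rate %g Hz: the count filter supports multiples of %d Hz (e.g. 10, 30, 100)",
      sr, .count_rate))
  }
  x <- trace$samples
  n <- nrow(x)
  bf <- signal::butter(3, .count_filter_band / (sr / 2), type = "pass")
  dec <- seq(1L, n, by = sr / .count_rate)
  q <- matrix(0, length(dec), 3L)
  for (j in 1:3) {
    # remove the gravity DC offset first: the band-pass kills it anyway, but
    # doing so avoids filter edge transients leaking above the dead-band
    xc <- x[, j] - mean(x[, j])
    f <- if (n > 24L) signal::filtfilt(bf, xc) else xc
    r <- abs(f[dec])
    r[r < .count_deadband] <- 0
    r[r > .count_peak] <- .count_peak
    q[, j] <- floor(r / .count_lsb)
  }
  per_epoch <- .count_rate * epoch_length_s
  if (per_epoch != round(per_epoch)) {
    stop("epoch length must be a whole number of 0.1-s steps")
  }
  n_epochs <- floor(nrow(q) / per_epoch)
  if (n_epochs < 1L) stop("trace shorter than one epoch")
  idx <- rep(seq_len(n_epochs), each = per_epoch)
  sums <- rowsum(q[seq_along(idx), , drop = FALSE], idx)
  epoch_counts(sums, epoch_length_s, trace$start_time)
}

#' Per-behavior count rates (counts per 5 s)
#'
#' Aggregates epoch counts over labeled behavior time. Each label's first
#' and last second are trimmed (a label `[10:00:00, 10:00:05)` contributes
#' data from 10:00:01 to 10:00:04 only) so that only unambiguous
#' single-behavior time contributes. For each (participant, behavior), the
#' counts accumulated over all trimmed label time are divided by total
#' trimmed seconds and multiplied by five, for each of axis1, axis2, axis3,
#' and vector magnitude.
#'
#' @param counts An [epoch_counts()] at 1-s epochs (second-resolution labels
#'   require 1-s count epochs).
#' @param labels A [label_track()]; normally pre-filtered with
#'   [filter_labels()].
#' @return A data frame with columns `participant`, `behavior`, `measure`
#'   (axis1/axis2/axis3/vm), `rate` (counts per 5 s), and `seconds` (trimmed
#'   seconds contributing).
#' @export
behavior_count_rate <- function(counts, labels) {
  stopifnot(inherits(counts, "epoch_counts"))
  if (attr(counts, "epoch_length") != 1) {
    stop("behavior_count_rate() requires 1-s epoch counts")
  }
  if (!nrow(labels)) {
    return(data.frame(participant = character(0), behavior = character(0),
                      measure = character(0), rate = numeric(0),
                      seconds = numeric(0)))
  }
  t_lo <- min(counts$epoch_start)
  t_hi <- max(counts$epoch_start) + 1
  sums <- list()
  secs <- list()
  for (i in seq_len(nrow(labels))) {
    if (labels$start[i] < t_lo || labels$end[i] > t_hi) {
      stop(sprintf(
        "label \"%s\" [%g, %g) lies outside the count time range [%g, %g)",
        labels$behavior[i], labels$start[i], labels$end[i], t_lo, t_hi))
    }
    a <- labels$start[i] + 1
    b <- labels$end[i] - 1
    if (b <= a) next
    sel <- counts$epoch_start >= a & counts$epoch_start < b
    key <- paste(labels$participant[i], labels$behavior[i], sep = "\r")
    m <- colSums(counts[sel, c("axis1", "axis2", "axis3", "vm"), drop = FALSE])
    sums[[key]] <- (sums[[key]] %||% c(axis1 = 0, axis2 = 0, axis3 = 0, vm = 0)) + m
    secs[[key]] <- (secs[[key]] %||% 0) + (b - a)
  }
  if (!length(sums)) {
    return(data.frame(participant = character(0), behavior = character(0),
                      measure = character(0), rate = numeric(0),
                      seconds = numeric(0)))
  }
  keys <- names(sums)
  parts <- vapply(strsplit(keys, "\r", fixed = TRUE), `[`, "", 1L)
  behs <- vapply(strsplit(keys, "\r", fixed = TRUE), `[`, "", 2L)
  out <- do.call(rbind, lapply(seq_along(keys), function(i) {
    data.frame(participant = parts[i], behavior = behs[i],
               measure = c("axis1", "axis2", "axis3", "vm"),
               rate = as.numeric(sums[[i]]) / secs[[i]] * 5,
               seconds = secs[[i]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rescale a count cut-point to a different epoch length
#'
#' Count thresholds published for one epoch length are converted to another
#' by linear scaling with rounding to the nearest integer (419 counts/15 s
#' becomes 140 counts/5 s; 1756 counts/min becomes 146 counts/5 s).
#'
#' @param threshold_counts Published threshold, counts per `from_epoch_s`.
#' @param from_epoch_s,to_epoch_s Source and target epoch lengths, seconds.
#' @return Integer threshold in counts per `to_epoch_s`.
#' @examples
#' convert_cutpoint(419, 15, 5)
#' @export
convert_cutpoint <- function(threshold_counts, from_epoch_s, to_epoch_s) {
  if (from_epoch_s <= 0 || to_epoch_s <= 0) {
    stop("epoch lengths must be positive")
  }
  if (any(threshold_counts < 0)) stop("thresholds must be non-negative")
  as.integer(round(threshold_counts * to_epoch_s / from_epoch_s))
}

#' Cut-point sets
#'
#' Returns a cut-point set normalized to a given epoch length. The
#' `"toddler_hip_va"` set uses the toddler MVPA bound of 419 vertical-axis
#' counts/15 s (140 counts/5 s); its light-activity lower bound of 6
#' counts/5 s is this package's operational quiescence ceiling (standing,
#' sitting, and stroller time register below ~5 counts/5 s).
#'
#' @param name Set name; currently `"toddler_hip_va"`.
#' @param epoch_s Target epoch length in seconds.
#' @return A data frame of class `cutpoint_set` with columns `class` and
#'   `lower` (inclusive lower bound, counts per epoch), ordered by `lower`.
#' @export
cutpoint_set <- function(name = "toddler_hip_va", epoch_s = 5) {
  name <- match.arg(name)
  base <- data.frame(
    class = c("sedentary", "light", "mvpa"),
    lower = c(0, convert_cutpoint(6, 5, epoch_s),
              convert_cutpoint(419, 15, epoch_s)),
    stringsAsFactors = FALSE
  )
  if (any(diff(base$lower) <= 0)) stop("cut-point bounds must increase")
  attr(base, "epoch_length") <- epoch_s
  attr(base, "name") <- name
  class(base) <- c("cutpoint_set", "data.frame")
  base
}

#' Classify a count rate into an intensity class
#'
#' Returns the intensity class of the highest cut-point lower bound not
#' exceeding the rate; a rate equal to a bound belongs to the higher class
#' (">=" cut-point convention).
#'
#' @param rate_per_epoch Count rate(s), counts per the cut-point set's epoch.
#' @param cutpoints A [cutpoint_set()].
#' @return Character vector of intensity classes.
#' @examples
#' classify_intensity(c(0, 49, 144), cutpoint_set())
#' @export
classify_intensity <- function(rate_per_epoch, cutpoints = cutpoint_set()) {
  if (any(rate_per_epoch < 0)) stop("count rates must be non-negative")
  idx <- findInterval(rate_per_epoch, cutpoints$lower)
  cutpoints$class[idx]
}
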