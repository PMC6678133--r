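# Core data containers: triaxial traces, label tracks, epoch counts.

#' Behavior vocabularies
#'
#' `toddler_behaviors()` returns the nine prescribed toddler behaviors used
#' throughout the package. `behavior_vocabulary()` additionally includes the
#' auxiliary labels coders use for unprescribed movement
#' (`"bounce"`, `"transition"`, `"other"`). `ambulation_behaviors()` returns
#' the four behaviors pooled into the "ambulation" class, and
#' `classifier_behaviors()` those four plus `"carried"` — the five behaviors
#' eligible for window-based classification.
#'
#' @return Character vector of behavior names.
#' @examples
#' toddler_behaviors()
#' @export
toddler_behaviors <- function() {
  c("run", "walk", "crawl", "climb", "ride_on_toy",
    "stand", "sit", "stroller", "carried")
}

#' @rdname toddler_behaviors
#' @export
behavior_vocabulary <- function() {
  c(toddler_behaviors(), "bounce", "transition", "other")
}

#' @rdname toddler_behaviors
#' @export
ambulation_behaviors <- function() c("run", "walk", "crawl", "climb")

#' @rdname toddler_behaviors
#' @export
classifier_behaviors <- function() c(ambulation_behaviors(), "carried")

#' Construct a triaxial acceleration trace
#'
#' An `accel_trace` is a uniformly sampled triaxial acceleration stream for
#' one wear site, in units of g. Axis 1 is the device vertical axis, axis 2
#' horizontal, axis 3 perpendicular (the ActiGraph convention).
#'
#' @param samples Numeric matrix with 3 columns (axis1, axis2, axis3), one
#'   row per sample.
#' @param sample_rate Sampling frequency in Hz.
#' @param site Wear site, `"hip"` or `"wrist"`.
#' @param start_time Session-clock time of the first sample, in seconds.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(samples, sample_rate = 30, site = c("hip", "wrist"),
                        start_time = 0) {
  site <- match.arg(site)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("`samples` must have 3 columns (axis1..axis3)")
  if (nrow(samples) == 0L) stop("`samples` must be non-empty")
  assert_scalar_number(sample_rate, "sample_rate", min = 1e-9)
  colnames(samples) <- c("axis1", "axis2", "axis3")
  structure(
    list(samples = samples, sample_rate = sample_rate, site = site,
         start_time = start_time),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> site=%s  %d samples @ %g Hz  (%.1f s)\n",
              x$site, nrow(x$samples), x$sample_rate, trace_duration(x)))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param trace An [accel_trace()].
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) nrow(trace$samples) / trace$sample_rate

#' Construct a behavior label track
#'
#' A label track is an ordered set of behavior annotations for one
#' participant and coder, with start/end times at whole-second resolution
#' (session-clock seconds). Intervals are half-open `[start, end)`.
#'
#' @param participant Participant identifier (recycled).
#' @param behavior Character vector of behaviors from [behavior_vocabulary()].
#' @param start,end Integer-valued start and end times in seconds.
#' @param coder Coder identifier (recycled).
#' @return A `data.frame` of class `label_track` with columns
#'   `participant`, `coder`, `behavior`, `start`, `end`.
#' @export
label_track <- function(participant, behavior, start, end, coder = "truth") {
  behavior <- as.character(behavior)
  bad <- setdiff(unique(behavior), behavior_vocabulary())
  if (length(bad)) {
    stop("unknown behavior(s): ", paste(bad, collapse = ", "))
  }
  if (any(start != round(start)) || any(end != round(end))) {
    stop("label times must be whole seconds")
  }
  if (any(end <= start)) stop("label end times must exceed start times")
  out <- data.frame(
    participant = rep_len(as.character(participant), length(behavior)),
    coder = rep_len(as.character(coder), length(behavior)),
    behavior = behavior,
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  per_coder <- split(out, out$coder)
  for (tr in per_coder) {
    if (nrow(tr) > 1L && any(tr$start[-1L] < tr$end[-nrow(tr)])) {
      stop("labels overlap within one coder's track")
    }
  }
  class(out) <- c("label_track", "data.frame")
  out
}

label_duration <- function(track) track$end - track$start

#' Construct per-epoch activity counts
#'
#' @param counts Integer matrix with columns axis1..axis3, one row per epoch.
#' @param epoch_length Epoch length in seconds.
#' @param start_time Session-clock time of the first epoch, seconds.
#' @return A `data.frame` of class `epoch_counts` with columns
#'   `epoch_start`, `axis1`, `axis2`, `axis3`, `vm` (vector magnitude,
#'   derived as `sqrt(axis1^2 + axis2^2 + axis3^2)`).
#' @export
epoch_counts <- function(counts, epoch_length, start_time = 0) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 3L) stop("`counts` must have 3 columns")
  if (any(counts < 0)) stop("counts must be non-negative")
  out <- data.frame(
    epoch_start = start_time + epoch_length * (seq_len(nrow(counts)) - 1L),
    axis1 = as.numeric(counts[, 1L]),
    axis2 = as.numeric(counts[, 2L]),
    axis3 = as.numeric(counts[, 3L])
  )
  out$vm <- sqrt(out$axis1^2 + out$axis2^2 + out$axis3^2)
  attr(out, "epoch_length") <- epoch_length
  class(out) <- c("epoch_counts", "data.frame")
  out
}
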