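# Behavior-annotation handling: synchronization, filtering, inter-coder
# agreement, and label summaries.

#' Synchronize a label track to a trace's clock
#'
#' Shifts label times by a (whole-second) offset into the trace clock and
#' clips labels extending beyond the trace, flagging clipped labels in a
#' `clipped` column. Labels falling entirely outside the trace are dropped;
#' if no label overlaps the trace an error is raised.
#'
#' @param trace An [accel_trace()].
#' @param track A [label_track()].
#' @param offset_s Clock offset in seconds added to label times (rounded to
#'   whole seconds).
#' @return The aligned [label_track()] with a logical `clipped` column.
#' @export
synchronize <- function(trace, track, offset_s = 0) {
  offset_s <- round(offset_s)
  dur <- floor(trace_duration(trace))
  t0 <- trace$start_time
  start <- track$start + offset_s
  end <- track$end + offset_s
  keep <- end > t0 & start < t0 + dur
  if (!any(keep)) stop("label track lies entirely outside the trace")
  start <- start[keep]
  end <- end[keep]
  clipped <- start < t0 | end > t0 + dur
  start <- pmax(start, t0)
  end <- pmin(end, t0 + dur)
  out <- label_track(track$participant[keep], track$behavior[keep],
                     start, end, coder = track$coder[keep])
  out$clipped <- clipped[order(start)]
  out
}

#' Filter labels by behavior and minimum duration
#'
#' Retains only labels of the named behaviors lasting at least
#' `min_duration_s` consecutive seconds — the selection applied before any
#' count aggregation or windowing (unprescribed labels such as
#' `"transition"` and sub-threshold bouts are excluded).
#'
#' @param track A [label_track()].
#' @param min_duration_s Minimum label duration in seconds (default 5).
#' @param behaviors Behaviors to keep (default the nine prescribed toddler
#'   behaviors).
#' @return The filtered [label_track()] (possibly empty). Idempotent.
#' @export
filter_labels <- function(track, min_duration_s = 5,
                          behaviors = toddler_behaviors()) {
  keep <- track$behavior %in% behaviors &
    (track$end - track$start) >= min_duration_s
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(track)
  out
}

#' Inter-coder percent agreement
#'
#' Matches two coders' labels for the same session by interval overlap
#' (two labels match when their overlap exceeds `min_overlap` of the shorter
#' label's duration; matching is greedy by descending overlap, one-to-one)
#' and counts a matched pair as concordant when the behaviors agree.
#' Unmatched labels on either side count toward the total as discordant,
#' so the total is the union of matched pairs and unmatched labels. The
#' reported percent is rounded to the nearest integer; the raw fraction is
#' also returned. Symmetric in its arguments.
#'
#' @param track_a,track_b [label_track()]s covering the same session.
#' @param min_overlap Matching threshold as a fraction of the shorter
#'   label's duration (default 0.5).
#' @return A list with `concordant`, `total`, `percent` (rounded), and
#'   `fraction`.
#' @export
percent_agreement <- function(track_a, track_b, min_overlap = 0.5) {
  if (!nrow(track_a) || !nrow(track_b)) {
    stop("both label tracks must be non-empty")
  }
  na <- nrow(track_a)
  nb <- nrow(track_b)
  ov <- outer(seq_len(na), seq_len(nb), function(i, j) {
    pmax(0, pmin(track_a$end[i], track_b$end[j]) -
           pmax(track_a$start[i], track_b$start[j]))
  })
  shorter <- outer(track_a$end - track_a$start, track_b$end - track_b$start,
                   pmin)
  ov[ov <= min_overlap * shorter] <- 0
  matched <- 0L
  concordant <- 0L
  while (any(ov > 0)) {
    ij <- arrayInd(which.max(ov), dim(ov))
    matched <- matched + 1L
    if (track_a$behavior[ij[1L]] == track_b$behavior[ij[2L]]) {
      concordant <- concordant + 1L
    }
    ov[ij[1L], ] <- 0
    ov[, ij[2L]] <- 0
  }
  total <- na + nb - matched
  c(list(concordant = concordant, total = total),
    agreement_percent(concordant, total))
}

#' Percent agreement from concordant/total counts
#'
#' Reporting arithmetic shared with [percent_agreement()]: 3175 concordant
#' labels of 3308 give 96 percent.
#'
#' @param concordant,total Non-negative counts, `total > 0`.
#' @return List with `percent` (rounded to nearest integer) and `fraction`.
#' @examples
#' agreement_percent(3175, 3308)$percent
#' @export
agreement_percent <- function(concordant, total) {
  if (total <= 0 || concordant < 0 || concordant > total) {
    stop("need 0 <= concordant <= total with total > 0")
  }
  list(percent = round(100 * concordant / total),
       fraction = concordant / total)
}

#' Summarize behavior labels
#'
#' Per-behavior label frequencies and duration statistics, plus the mean
#' number of labels per behavior class (total divided by the number of
#' classes, default 9) and per participant, both rounded to the nearest
#' integer for reporting.
#'
#' @param track A [label_track()] (typically filtered; may pool
#'   participants).
#' @param n_classes Number of behavior classes for the per-behavior mean
#'   (default 9).
#' @param n_participants Number of participants; defaults to the number of
#'   distinct participants in `track`.
#' @return A list with `per_behavior` (data frame: behavior, n,
#'   mean_duration_s, median_duration_s), `total`, `labels_per_behavior`,
#'   and `labels_per_participant`.
#' @export
label_summary <- function(track, n_classes = 9,
                          n_participants = length(unique(track$participant))) {
  if (!nrow(track)) {
    return(list(
      per_behavior = data.frame(behavior = character(0), n = integer(0),
                                mean_duration_s = numeric(0),
                                median_duration_s = numeric(0)),
      total = 0L, labels_per_behavior = 0L, labels_per_participant = 0L))
  }
  dur <- track$end - track$start
  per <- do.call(rbind, lapply(split(dur, track$behavior), function(d) {
    data.frame(n = length(d), mean_duration_s = mean(d),
               median_duration_s = median(d))
  }))
  per <- data.frame(behavior = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  total <- nrow(track)
  list(
    per_behavior = per,
    total = total,
    labels_per_behavior = round(total / n_classes),
    labels_per_participant = if (n_participants > 0) {
      round(total / n_participants)
    } else 0L
  )
}

#' Reference toddler behavior-label frequencies
#'
#' Published frequencies and mean/median annotated durations of the nine
#' prescribed behaviors from a video-annotated free-play study of 21
#' toddlers (664 labels of at least 5 s), useful as a realistic target for
#' schedule generation and as printed-input arithmetic checks.
#'
#' @return Data frame with columns `behavior`, `frequency`,
#'   `mean_duration_s`, `median_duration_s`.
#' @export
toddler_label_reference <- function() {
  data.frame(
    behavior = c("run", "walk", "crawl", "climb", "ride_on_toy",
                 "stand", "sit", "stroller", "carried"),
    frequency = c(20L, 244L, 29L, 47L, 40L, 129L, 84L, 36L, 35L),
    mean_duration_s = c(7.5, 7.3, 6.8, 8.3, 10.3, 6.9, 14.5, 12.0, 9.9),
    median_duration_s = c(5.0, 6.0, 5.0, 8.0, 10.7, 5.0, 9.5, 10.5, 14.0),
    stringsAsFactors = FALSE
  )
}

#' Read and write behavior-label CSV files
#'
#' The label CSV format has columns `participant,coder,behavior,start,end`
#' (times in whole session seconds). Lines starting with `#` are treated as
#' a provenance/comment preamble. `write_labels()` round-trips bit-exactly
#' through `read_labels()`.
#'
#' @param track A [label_track()].
#' @param path File path.
#' @param provenance Optional character vector written as `#`-prefixed
#'   header lines.
#' @return `read_labels()` returns a [label_track()]; `write_labels()`
#'   returns `path` invisibly.
#' @export
write_labels <- function(track, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  write.csv(as.data.frame(track)[c("participant", "coder", "behavior",
                                   "start", "end")],
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("participant", "coder", "behavior", "start", "end")
  if (!all(req %in% names(df))) {
    stop("label CSV must have columns: ", paste(req, collapse = ", "))
  }
  label_track(df$participant, df$behavior, df$start, df$end, coder = df$coder)
}
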