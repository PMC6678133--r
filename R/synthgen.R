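# Seeded synthetic generator of hip/wrist triaxial signals and label tracks
# for nine toddler behaviors (plus "bounce" and "transition").
#
# Signal model per bout: a sum-of-harmonics gait oscillation (fundamental +
# two harmonics) at a behavior-specific cadence and amplitude, broadband
# foot-strike impact transients for ambulatory behaviors, a static gravity
# vector rotated by the behavior's trunk pitch, and white sensor noise.
# "Carried" is an adult-cadence oscillation low-pass filtered at 3 Hz (the
# child's body damps the adult's impacts) plus a slow carrier sway, so its
# spectrum is confined below 3 Hz while ambulation keeps broadband content.
# "Ride-on toy" has two modes (bouncing vs quiet feet), picked per bout.

.behavior_param <- function(freq, vamp, hamp, harmonics = c(1, 0.4, 0.2),
                            pitch = 0, noise = 0.03, impact = 0,
                            smoothing = NA_real_, sway_freq = NA_real_,
                            sway_amp = 0) {
  list(freq = freq, vamp = vamp, hamp = hamp, harmonics = harmonics,
       pitch = pitch, noise = noise, impact = impact, smoothing = smoothing,
       sway_freq = sway_freq, sway_amp = sway_amp)
}

#' Default simulation parameters
#'
#' Returns the complete parameter set driving [simulate_bout()] and
#' [simulate_session()]: per-behavior cadence (`freq`, Hz), vertical and
#' horizontal oscillation amplitudes (`vamp`, `hamp`, g), harmonic weights,
#' trunk pitch relative to gravity (`pitch`, degrees; 90 for crawling, i.e.
#' trunk horizontal), sensor noise SD (g), foot-strike impact amplitude (g),
#' and, for "carried", a low-pass smoothing cutoff (Hz) plus carrier-sway
#' parameters. Global settings: `sample_rate` 30 Hz, `clip_range` 6 g
#' (device dynamic range), wrist coupling (`gain` of the hip dynamic signal
#' transmitted to the wrist, plus independent arm-motion amplitude), and the
#' default inter-bout `transition_s`.
#'
#' Amplitudes were fixed once so that emulated hip vertical-axis count
#' medians respect the qualitative ordering observed in toddlers:
#' stand/sit/stroller (quiescent) < walk < carried < crawl, with running and
#' bouncing highest.
#'
#' @return A named list of class `sim_params`.
#' @examples
#' p <- default_sim_params()
#' p$sample_rate
#' names(p$behaviors)
#' @export
default_sim_params <- function() {
  behaviors <- list(
    run         = .behavior_param(2.8, 0.55, 0.35, noise = 0.04, impact = 0.30),
    walk        = .behavior_param(2.0, 0.16, 0.10, noise = 0.03, impact = 0.15),
    crawl       = .behavior_param(1.5, 0.55, 0.25, harmonics = c(1, 0.35, 0.15),
                                  pitch = 90, noise = 0.04, impact = 0.20),
    climb       = .behavior_param(1.8, 0.30, 0.22, pitch = 10, noise = 0.04,
                                  impact = 0.18),
    ride_on_toy = .behavior_param(1.2, 0.45, 0.20, noise = 0.03, impact = 0.10),
    stand       = .behavior_param(0, 0, 0, noise = 0.02),
    sit         = .behavior_param(0, 0, 0, pitch = 15, noise = 0.02),
    stroller    = .behavior_param(0, 0, 0, pitch = 20, noise = 0.025),
    carried     = .behavior_param(1.9, 0.33, 0.18, noise = 0.03, impact = 0,
                                  smoothing = 3, sway_freq = 0.4,
                                  sway_amp = 0.05),
    bounce      = .behavior_param(2.2, 1.10, 0.40, harmonics = c(1, 0.3, 0.1),
                                  noise = 0.05, impact = 0.35),
    transition  = .behavior_param(0.8, 0.08, 0.08, harmonics = c(1, 0, 0),
                                  noise = 0.06)
  )
  structure(
    list(
      sample_rate = 30,
      clip_range = 6,
      transition_s = 1,
      # quiet-feet mode for ride_on_toy (bout-level mixture, p = 0.5)
      ride_quiet = .behavior_param(1.0, 0.04, 0.10, noise = 0.03,
                                   impact = 0.02),
      wrist = list(gain = 0.6, arm_amp = 0.15, arm_cutoff = 5, pitch = 45),
      behaviors = behaviors
    ),
    class = "sim_params"
  )
}

# Damped 8 Hz oscillation kernel emulating a foot-strike transient.
.impact_kernel <- function(sr) {
  t <- (0:(round(sr / 2) - 1)) / sr
  exp(-t / 0.04) * cos(2 * pi * 8 * t)
}

# Hip-frame dynamic (gravity-free) signal for one bout; consumes RNG.
.bout_dynamic <- function(behavior, n, params) {
  sr <- params$sample_rate
  beh <- params$behaviors[[behavior]]
  if (behavior == "ride_on_toy" && runif(1) < 0.5) {
    pitch <- beh$pitch
    beh <- params$ride_quiet
    beh$pitch <- pitch
  }
  t <- (seq_len(n) - 1) / sr
  dyn <- matrix(0, n, 3L)
  if (beh$freq > 0 && (beh$vamp > 0 || beh$hamp > 0)) {
    ph <- runif(3, 0, 2 * pi)
    w <- beh$harmonics
    v <- numeric(n)
    for (k in seq_along(w)) {
      v <- v + w[k] * sin(2 * pi * k * beh$freq * t + ph[1] + (k - 1) * 0.7)
    }
    dyn[, 1L] <- beh$vamp * v
    dyn[, 2L] <- beh$hamp * (sin(2 * pi * beh$freq * t + ph[2]) +
                               0.3 * sin(2 * pi * 2 * beh$freq * t + ph[2] + 0.9))
    dyn[, 3L] <- 0.6 * beh$hamp * sin(2 * pi * beh$freq * t + ph[3])
  }
  if (beh$impact > 0 && beh$freq > 0) {
    step_period <- sr / beh$freq
    offset <- runif(1, 0, step_period)
    idx <- round(seq(1 + offset, n, by = step_period))
    idx <- idx[idx >= 1 & idx <= n]
    train <- numeric(n)
    train[idx] <- beh$impact * runif(length(idx), 0.8, 1.2)
    imp <- stats::filter(train, .impact_kernel(sr), method = "convolution",
                         sides = 1)
    imp[is.na(imp)] <- 0
    imp <- as.numeric(imp)
    dyn[, 1L] <- dyn[, 1L] + imp
    dyn[, 3L] <- dyn[, 3L] + 0.8 * imp
    dyn[, 2L] <- dyn[, 2L] + 0.4 * imp
  }
  if (is.finite(beh$smoothing)) {
    bf <- signal::butter(2, beh$smoothing / (sr / 2), type = "low")
    for (j in 1:3) dyn[, j] <- signal::filtfilt(bf, dyn[, j])
  }
  if (!is.na(beh$sway_freq) && beh$sway_amp > 0) {
    ph <- runif(2, 0, 2 * pi)
    dyn[, 2L] <- dyn[, 2L] + beh$sway_amp * sin(2 * pi * beh$sway_freq * t + ph[1])
    dyn[, 1L] <- dyn[, 1L] + 0.5 * beh$sway_amp * sin(2 * pi * beh$sway_freq * t + ph[2])
  }
  dyn + matrix(rnorm(3L * n, 0, beh$noise), n, 3L)
}

.gravity_vector <- function(pitch_deg) {
  th <- pitch_deg * pi / 180
  c(cos(th), 0, sin(th))
}

# Hip and wrist sample matrices for one bout; fully seeded.
.bout_signals <- function(behavior, n, params, seed) {
  local_seed(seed, {
    hip_dyn <- .bout_dynamic(behavior, n, params)
    w <- params$wrist
    arm <- matrix(rnorm(3L * n, 0, w$arm_amp), n, 3L)
    if (n > 12L) {
      bf <- signal::butter(2, min(w$arm_cutoff / (params$sample_rate / 2), 0.99),
                           type = "low")
      for (j in 1:3) arm[, j] <- signal::filtfilt(bf, arm[, j])
    }
    wrist_dyn <- w$gain * hip_dyn + arm
    list(hip = hip_dyn, wrist = wrist_dyn)
  })
}

.finish_trace <- function(dyn, pitch, params, site, start_time = 0) {
  g <- .gravity_vector(pitch)
  samples <- sweep(dyn, 2L, g, "+")
  cr <- params$clip_range
  samples[samples > cr] <- cr
  samples[samples < -cr] <- -cr
  accel_trace(samples, params$sample_rate, site, start_time)
}

#' Simulate a single behavior bout
#'
#' Generates one wear site's triaxial trace for `duration_s` seconds of a
#' named behavior. The static gravity component is rotated by the behavior's
#' trunk pitch (90 degrees for crawling puts gravity on axis 3, leaving axis 1
#' dominated by dynamic motion); quiescent behaviors (stand, sit, stroller)
#' have no oscillatory component, only sensor noise.
#'
#' @param behavior Behavior name; see [default_sim_params()].
#' @param duration_s Bout duration in seconds (> 0).
#' @param site `"hip"` or `"wrist"`.
#' @param params Simulation parameters, see [default_sim_params()].
#' @param seed Integer seed; identical arguments give bit-identical traces.
#' @return An [accel_trace()].
#' @examples
#' tr <- simulate_bout("walk", 10, "hip", seed = 1)
#' trace_duration(tr)
#' @export
simulate_bout <- function(behavior, duration_s, site = c("hip", "wrist"),
                          params = default_sim_params(), seed = 1) {
  site <- match.arg(site)
  if (!behavior %in% names(params$behaviors)) {
    stop(sprintf("unknown behavior \"%s\"; known behaviors: %s", behavior,
                 paste(names(params$behaviors), collapse = ", ")))
  }
  assert_scalar_number(duration_s, "duration_s", min = 1e-9)
  n <- round(duration_s * params$sample_rate)
  sig <- .bout_signals(behavior, n, params, seed)
  pitch <- if (site == "hip") params$behaviors[[behavior]]$pitch else
    params$wrist$pitch
  .finish_trace(sig[[site]], pitch, params, site)
}

#' Construct a bout schedule
#'
#' @param participant Participant identifier.
#' @param behavior Character vector of behavior names.
#' @param duration_s Bout durations in seconds (rounded to whole seconds;
#'   must round to >= 1 s).
#' @return A `data.frame` of class `bout_schedule`.
#' @export
bout_schedule <- function(participant, behavior, duration_s) {
  behavior <- as.character(behavior)
  if (!length(behavior)) stop("schedule must contain at least one bout")
  bad <- setdiff(unique(behavior), behavior_vocabulary())
  if (length(bad)) stop("unknown behavior(s): ", paste(bad, collapse = ", "))
  duration_s <- round(duration_s)
  if (any(duration_s < 1)) stop("bout durations must round to >= 1 s")
  structure(
    data.frame(participant = as.character(participant), behavior = behavior,
               duration_s = as.numeric(duration_s), stringsAsFactors = FALSE),
    class = c("bout_schedule", "data.frame")
  )
}

#' Default per-participant bout schedule
#'
#' Draws a seeded session of bouts whose per-behavior frequencies and
#' durations emulate a free-play session in an indoor playroom: walking
#' dominates, quiescent behaviors (stand/sit/stroller) are common, running,
#' crawling, climbing, riding and being carried occur a few times each, and
#' an occasional participant bounces. Bout order is shuffled.
#'
#' @param participant Participant identifier.
#' @param seed Integer seed.
#' @return A [bout_schedule()].
#' @export
default_schedule <- function(participant, seed = 1) {
  spec <- list(
    # behavior, n bouts, mean extra seconds beyond the 5-s minimum
    walk        = c(n = 15, extra = 5),
    run         = c(n = 1,  extra = 3),
    crawl       = c(n = 2,  extra = 3),
    climb       = c(n = 2,  extra = 4),
    carried     = c(n = 2,  extra = 8),
    ride_on_toy = c(n = 2,  extra = 5),
    stand       = c(n = 5,  extra = 2),
    sit         = c(n = 3,  extra = 9),
    stroller    = c(n = 2,  extra = 7)
  )
  local_seed(seed, {
    beh <- character(0)
    dur <- numeric(0)
    for (b in names(spec)) {
      nb <- spec[[b]][["n"]]
      beh <- c(beh, rep(b, nb))
      dur <- c(dur, 5 + rpois(nb, spec[[b]][["extra"]]))
    }
    if (runif(1) < 4 / 21) {  # a minority of toddlers bounce
      beh <- c(beh, "bounce")
      dur <- c(dur, 5 + rpois(1, 3))
    }
    ord <- sample.int(length(beh))
    bout_schedule(participant, beh[ord], dur[ord])
  })
}

#' Simulate a full annotated session
#'
#' Concatenates the scheduled bouts with short seeded `"transition"` segments
#' between them, producing time-aligned hip and wrist traces plus the
#' ground-truth label track whose intervals exactly tile the session.
#'
#' @param schedule A [bout_schedule()].
#' @param params Simulation parameters.
#' @param seed Integer seed.
#' @return A list with elements `hip` and `wrist` ([accel_trace()]s) and
#'   `labels` (a [label_track()]).
#' @examples
#' s <- simulate_session(bout_schedule("p1", "walk", 10), seed = 1)
#' s$labels
#' @export
simulate_session <- function(schedule, params = default_sim_params(), seed = 1) {
  if (!nrow(schedule)) stop("schedule must contain at least one bout")
  sr <- params$sample_rate
  segs <- list()
  k <- 0L
  for (i in seq_len(nrow(schedule))) {
    if (i > 1L && params$transition_s > 0) {
      k <- k + 1L
      segs[[k]] <- list(behavior = "transition",
                        duration = round(params$transition_s))
    }
    k <- k + 1L
    segs[[k]] <- list(behavior = schedule$behavior[i],
                      duration = schedule$duration_s[i])
  }
  hip <- wrist <- vector("list", length(segs))
  starts <- ends <- numeric(length(segs))
  t0 <- 0
  for (i in seq_along(segs)) {
    n <- round(segs[[i]]$duration * sr)
    sig <- .bout_signals(segs[[i]]$behavior, n, params, sub_seed(seed, i))
    beh <- params$behaviors[[segs[[i]]$behavior]]
    hip[[i]] <- sweep(sig$hip, 2L, .gravity_vector(beh$pitch), "+")
    wrist[[i]] <- sweep(sig$wrist, 2L, .gravity_vector(params$wrist$pitch), "+")
    starts[i] <- t0
    ends[i] <- t0 + segs[[i]]$duration
    t0 <- ends[i]
  }
  clip <- function(m) {
    cr <- params$clip_range
    m[m > cr] <- cr
    m[m < -cr] <- -cr
    m
  }
  list(
    hip = accel_trace(clip(do.call(rbind, hip)), sr, "hip"),
    wrist = accel_trace(clip(do.call(rbind, wrist)), sr, "wrist"),
    labels = label_track(schedule$participant[1L],
                         vapply(segs, `[[`, "", "behavior"),
                         starts, ends)
  )
}

# Behaviors coders most often confuse each label with.
.confusion_partner <- c(
  run = "walk", walk = "stand", crawl = "sit", climb = "walk",
  ride_on_toy = "sit", stand = "transition", sit = "stroller",
  stroller = "sit", carried = "sit", bounce = "run",
  transition = "stand", other = "transition"
)

#' Perturb a label track with an emulated coder-error model
#'
#' Jitters shared label boundaries by a rounded Gaussian shift and swaps a
#' seeded fraction of labels to a confusable behavior (e.g. standing vs
#' transition), emulating inter-coder disagreement. Interval validity
#' (ordering, positive duration, whole seconds) is preserved.
#'
#' @param track A [label_track()].
#' @param shift_sd_s SD of the boundary jitter in seconds (>= 0).
#' @param confusion_rate Probability a label's behavior is swapped, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A perturbed [label_track()].
#' @export
perturb_labels <- function(track, shift_sd_s = 0, confusion_rate = 0, seed = 1) {
  assert_scalar_number(shift_sd_s, "shift_sd_s", min = 0)
  if (confusion_rate < 0 || confusion_rate > 1) {
    stop("`confusion_rate` must lie in [0, 1]")
  }
  out <- as.data.frame(track)
  local_seed(seed, {
    if (shift_sd_s > 0 && nrow(out) > 1L) {
      for (j in 2:nrow(out)) {
        if (out$start[j] == out$end[j - 1L]) {
          delta <- round(rnorm(1, 0, shift_sd_s))
          lo <- out$start[j - 1L] + 1 - out$end[j - 1L]
          hi <- out$end[j] - 1 - out$start[j]
          delta <- max(lo, min(hi, delta))
          out$end[j - 1L] <- out$end[j - 1L] + delta
          out$start[j] <- out$start[j] + delta
        }
      }
    }
    swap <- runif(nrow(out)) < confusion_rate
    out$behavior[swap] <- unname(.confusion_partner[out$behavior[swap]])
  })
  label_track(out$participant, out$behavior, out$start, out$end,
              coder = out$coder)
}
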