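test_that("default parameters match the device configuration and are stable", {
  p <- default_sim_params()
  expect_equal(p$sample_rate, 30)
  expect_equal(p$clip_range, 6)
  expect_identical(default_sim_params(), default_sim_params())
  for (b in p$behaviors) {
    expect_gte(b$vamp, 0)
    expect_gte(b$hamp, 0)
    expect_gte(b$freq, 0)
    expect_gte(b$noise, 0)
  }
  expect_setequal(setdiff(names(p$behaviors), c("bounce", "transition")),
                  toddler_behaviors())
})

test_that("bouts are seeded-deterministic, clipped, and gravity-conserving", {
  p <- default_sim_params()
  for (beh in names(p$behaviors)) {
    a <- simulate_bout(beh, 10, "hip", p, seed = 11)
    b <- simulate_bout(beh, 10, "hip", p, seed = 11)
    expect_identical(a, b)
    expect_lte(max(abs(a$samples)), p$clip_range)
    expect_equal(nrow(a$samples), round(10 * p$sample_rate))
  }
  # static postures: the mean acceleration vector has magnitude ~1 g
  for (beh in c("stand", "sit", "stroller")) {
    tr <- simulate_bout(beh, 30, "hip", p, seed = 3)
    expect_equal(sqrt(sum(colMeans(tr$samples)^2)), 1, tolerance = 0.02)
    wr <- simulate_bout(beh, 30, "wrist", p, seed = 3)
    expect_equal(sqrt(sum(colMeans(wr$samples)^2)), 1, tolerance = 0.05)
  }
})

test_that("quiescent behaviors have dynamic RMS at the noise floor", {
  p <- default_sim_params()
  tr <- simulate_bout("sit", 10, "hip", p, seed = 5)
  dyn <- sweep(tr$samples, 2L, colMeans(tr$samples))
  expect_lte(sqrt(mean(dyn^2)), 2 * p$behaviors$sit$noise)
})

test_that("crawling reorients gravity onto the perpendicular axis", {
  p <- default_sim_params()
  tr <- simulate_bout("crawl", 30, "hip", p, seed = 7)
  pitch <- p$behaviors$crawl$pitch * pi / 180
  expect_equal(mean(tr$samples[, 1]), cos(pitch), tolerance = 0.05)
  expect_equal(mean(tr$samples[, 3]), sin(pitch), tolerance = 0.05)
  # axis 1 static component near zero but dynamic component large
  expect_gt(sd(tr$samples[, 1]), 0.2)
})

test_that("sessions tile time exactly with labeled transitions", {
  p <- default_sim_params()
  one <- simulate_session(bout_schedule("p1", "walk", 10), p, seed = 1)
  expect_equal(nrow(one$labels), 1L)
  expect_equal(one$labels$behavior, "walk")
  expect_equal(one$labels$end - one$labels$start, 10)

  sched <- bout_schedule("p2", c("walk", "stand", "run"), c(10, 8, 6))
  s <- simulate_session(sched, p, seed = 2)
  n_trans <- nrow(sched) - 1L
  total <- sum(sched$duration_s) + n_trans * p$transition_s
  expect_equal(trace_duration(s$hip), total)
  expect_equal(trace_duration(s$wrist), total)
  # labels exactly tile [0, total]
  expect_equal(s$labels$start[1], 0)
  expect_equal(s$labels$end[nrow(s$labels)], total)
  expect_equal(s$labels$start[-1], s$labels$end[-nrow(s$labels)])
  expect_equal(sum(s$labels$behavior == "transition"), n_trans)
  expect_identical(s, simulate_session(sched, p, seed = 2))
})

test_that("invalid generator inputs are rejected by name", {
  expect_error(simulate_bout("cartwheel", 5, "hip"), "cartwheel")
  expect_error(simulate_bout("walk", -1, "hip"), "duration")
  expect_error(bout_schedule("p1", character(0), numeric(0)), "at least one")
})

test_that("higher oscillation amplitude yields strictly higher axis-1 counts", {
  p_lo <- default_sim_params()
  p_hi <- default_sim_params()
  p_hi$behaviors$walk$vamp <- 2.5 * p_lo$behaviors$walk$vamp
  c_lo <- compute_counts(simulate_bout("walk", 60, "hip", p_lo, seed = 9), 60)
  c_hi <- compute_counts(simulate_bout("walk", 60, "hip", p_hi, seed = 9), 60)
  expect_gt(c_hi$axis1, c_lo$axis1)
})

test_that("label perturbation follows its error model", {
  track <- label_track("p1", rep("stand", 20), seq(0, 190, 10),
                       seq(10, 200, 10))
  expect_identical(as.data.frame(perturb_labels(track, 0, 0, seed = 1)),
                   as.data.frame(track))
  all_swapped <- perturb_labels(track, 0, 1, seed = 1)
  expect_true(all(all_swapped$behavior != "stand"))
  expect_error(perturb_labels(track, -1, 0), "shift_sd_s")
  expect_error(perturb_labels(track, 0, 1.5), "confusion_rate")

  # boundary jitter preserves interval validity and whole seconds
  jit <- perturb_labels(track, 2, 0, seed = 4)
  expect_true(all(jit$end > jit$start))
  expect_true(all(jit$start == round(jit$start)))

  # E[agreement] with confusion_rate 0.25 is ~75%
  fracs <- vapply(1:40, function(s) {
    percent_agreement(track, perturb_labels(track, 0, 0.25, seed = s))$fraction
  }, 0)
  expect_equal(mean(fracs), 0.75, tolerance = 0.05)
})
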