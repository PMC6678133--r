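test_that("null and static signals register zero counts", {
  zero <- compute_counts(constant_trace(c(0, 0, 0)), 5)
  expect_true(all(zero[c("axis1", "axis2", "axis3")] == 0))
  # device upright and motionless: 1 g DC on axis 1 is removed by the filter
  static <- compute_counts(constant_trace(c(1, 0, 0)), 5)
  expect_true(all(static$axis1 == 0))
})

test_that("counts increase with oscillation amplitude", {
  a <- compute_counts(sine_trace(0.2), 5)
  b <- compute_counts(sine_trace(0.4), 5)
  expect_true(all(b$axis1 > a$axis1))
})

test_that("vector magnitude dominates per-axis counts and vanishes iff all do", {
  cc <- compute_counts(simulate_bout("run", 30, "hip", seed = 2), 5)
  expect_true(all(cc$vm >= pmax(cc$axis1, cc$axis2, cc$axis3)))
  zz <- compute_counts(constant_trace(c(0, 0, 0)), 5)
  expect_true(all(zz$vm == 0))
  expect_true(all(cc$vm[cc$axis1 + cc$axis2 + cc$axis3 > 0] > 0))
})

test_that("1-s counts summed in fives equal 5-s counts", {
  tr <- simulate_bout("walk", 30, "hip", seed = 3)
  c1 <- compute_counts(tr, 1)
  c5 <- compute_counts(tr, 5)
  grp <- rep(seq_len(nrow(c5)), each = 5)
  for (ax in c("axis1", "axis2", "axis3")) {
    expect_equal(unname(rowsum(c1[[ax]][seq_along(grp)], grp)[, 1]), c5[[ax]])
  }
})

test_that("unsupported sample rates are rejected with the supported ones named", {
  tr <- constant_trace(c(0, 0, 0), duration_s = 10, sr = 32)
  expect_error(compute_counts(tr, 5), "multiples of 10")
})

test_that("behavior rates trim the first and last label second", {
  # 1-s counts: value 6 on axis1 everywhere
  cc <- epoch_counts(matrix(c(6, 0, 0), 30, 3, byrow = TRUE), 1)
  # 12-s label trims to 10 s; 10 x 6 = 60 counts -> 30 counts/5 s
  lab <- label_track("p1", "walk", 0, 12)
  r <- behavior_count_rate(cc, lab)
  expect_equal(r$rate[r$measure == "axis1"], 30)
  expect_equal(r$seconds[r$measure == "axis1"], 10)

  # only the interior seconds contribute: label [20, 25) uses epochs 21-23
  cc2 <- epoch_counts(cbind(seq_len(30), 0, 0), 1)  # axis1 count = epoch index
  r2 <- behavior_count_rate(cc2, label_track("p1", "walk", 20, 25))
  expect_equal(r2$rate[r2$measure == "axis1"], sum(22:24) / 3 * 5)

  # quiescent bout -> all-zero rates
  r3 <- behavior_count_rate(epoch_counts(matrix(0, 30, 3), 1),
                            label_track("p1", "sit", 0, 12))
  expect_true(all(r3$rate == 0))
})

test_that("behavior rates scale linearly with counts and reject stray labels", {
  set.seed(42)
  base <- matrix(rpois(90, 20), 30, 3)
  r1 <- behavior_count_rate(epoch_counts(base, 1), label_track("p1", "walk", 2, 20))
  r2 <- behavior_count_rate(epoch_counts(2 * base, 1), label_track("p1", "walk", 2, 20))
  expect_equal(r2$rate, 2 * r1$rate)
  expect_error(
    behavior_count_rate(epoch_counts(base, 1), label_track("p1", "carried", 10, 40)),
    "carried")
})

test_that("cut-point rescaling reproduces published conversions", {
  expect_identical(convert_cutpoint(419, 15, 5), 140L)
  expect_identical(convert_cutpoint(1756, 60, 5), 146L)
  expect_identical(convert_cutpoint(3958, 60, 5), 330L)
  expect_identical(convert_cutpoint(0, 60, 5), 0L)
  expect_error(convert_cutpoint(419, 0, 5), "positive")
})

test_that("intensity classification respects >= bounds and is monotone", {
  cps <- cutpoint_set("toddler_hip_va", 5)
  expect_equal(classify_intensity(144, cps), "mvpa")
  expect_equal(classify_intensity(140, cps), "mvpa")  # boundary joins higher class
  expect_equal(classify_intensity(49, cps), "light")
  expect_equal(classify_intensity(0, cps), "sedentary")
  expect_error(classify_intensity(-1, cps), "non-negative")
  cls <- classify_intensity(0:500, cps)
  lvl <- match(cls, cps$class)
  expect_true(all(diff(lvl) >= 0))
})
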