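test_that("windows tile trimmed labels and never straddle boundaries", {
  sr <- 30
  tr <- constant_trace(c(1, 0, 0), duration_s = 40, sr = sr)
  # 14-s label trims to 12 s -> 2 complete 5-s windows, from the trimmed start
  w <- segment_windows(tr, label_track("p1", "carried", 0, 14))
  expect_length(w, 2L)
  expect_equal(vapply(w, `[[`, 0, "start"), c(1, 6))
  expect_true(all(vapply(w, function(x) nrow(x$samples), 0L) == 5L * sr))
  # 5-s label trims to 3 s -> no window
  expect_length(segment_windows(tr, label_track("p1", "walk", 20, 25)), 0L)
  # adjacent labels never share a window
  two <- label_track("p1", c("walk", "crawl"), c(0, 14), c(14, 28))
  ww <- segment_windows(tr, two)
  for (x in ww) {
    lab <- two[two$behavior == x$behavior, ]
    expect_gte(x$start, lab$start + 1)
    expect_lte(x$start + 5, lab$end - 1)
  }
  # non-classifier behaviors are not windowed
  expect_length(segment_windows(tr, label_track("p1", "stand", 0, 14)), 0L)
  expect_error(segment_windows(tr, two, window_s = 0.21), "whole number")
})

test_that("the feature schema is 30 time + 48 frequency = 78 names", {
  expect_length(feature_names("time"), 30L)
  expect_length(feature_names("freq"), 48L)
  expect_length(feature_names(), 78L)
  expect_identical(feature_names(),
                   c(feature_names("time"), feature_names("freq")))
  expect_false(any(duplicated(feature_names())))
  expect_true(all(spectral_shape_features() %in% feature_names("freq")))
  win <- random_window(1)
  expect_length(time_domain_features(win), 30L)
  expect_length(freq_domain_features(win), 48L)
})

test_that("degenerate windows take their documented values", {
  zero <- matrix(0, 150, 3)
  td <- time_domain_features(zero)
  expect_true(all(td[c("mean_x", "sd_x", "median_x", "min_x", "max_x",
                       "mean_y", "mean_z")] == 0))
  expect_true(all(td[c("skew_x", "kurt_x", "corr_xy")] == 0))
  fd <- freq_domain_features(zero)
  expect_true(all(fd == 0))

  # identical axes correlate perfectly
  set.seed(2)
  v <- rnorm(150)
  same <- cbind(v, v, rnorm(150))
  expect_equal(unname(time_domain_features(same)[["corr_xy"]]), 1)
})

test_that("a pure sinusoid lands in its exact FFT bin", {
  t <- (0:149) / 30
  win <- cbind(1, 0.7 * sin(2 * pi * 1.0 * t), 0)  # 1.0 Hz on axis 2 = "x"
  fd <- freq_domain_features(win)
  bins <- fd[sprintf("fft_bin%02d_x", 1:10)]
  expect_equal(names(which.max(bins)), "fft_bin05_x")  # 0.2 Hz bins: #5 = 1 Hz
  expect_equal(unname(bins[["fft_bin05_x"]]), 0.7, tolerance = 1e-9)
  expect_equal(unname(fd[["fft_max_x"]]), 0.7, tolerance = 1e-9)
  expect_equal(unname(fd[["fft_wmean_x"]]), 1.0, tolerance = 1e-6)
})

test_that("features are amplitude-equivariant", {
  win <- random_window(3)
  f1 <- c(time_domain_features(win), freq_domain_features(win))
  f3 <- c(time_domain_features(3 * win), freq_domain_features(3 * win))
  scale_by_c <- c(outer(c("mean", "sd", "median", "min", "max"),
                        c("x", "y", "z"), paste, sep = "_"),
                  paste0(c("mean", "median", "min", "max"), "_vm"),
                  grep("^fft_(mean|sd|median|min|max|bin)", names(f1),
                       value = TRUE))
  invariant <- c(outer(c("skew", "kurt"), c("x", "y", "z"), paste, sep = "_"),
                 "corr_xy", "corr_yz", "corr_xz")
  expect_equal(f3[scale_by_c], 3 * f1[scale_by_c], tolerance = 1e-12)
  expect_equal(f3[invariant], f1[invariant], tolerance = 1e-9)
})

test_that("every statistic matches a direct-definition oracle", {
  skew_oracle <- function(v) mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5
  kurt_oracle <- function(v) mean((v - mean(v))^4) / mean((v - mean(v))^2)^2 - 3
  for (seed in 1:5) {
    win <- random_window(seed)
    f <- c(time_domain_features(win), freq_domain_features(win))
    for (j in 1:3) {
      ax <- c("y", "x", "z")[j]  # axis1=vertical=y, axis2=x, axis3=z
      v <- win[, j]
      expect_equal(unname(f[[paste0("mean_", ax)]]), mean(v), tolerance = 1e-9)
      expect_equal(unname(f[[paste0("sd_", ax)]]), sd(v), tolerance = 1e-9)
      expect_equal(unname(f[[paste0("median_", ax)]]), median(v))
      expect_equal(unname(f[[paste0("min_", ax)]]), min(v))
      expect_equal(unname(f[[paste0("max_", ax)]]), max(v))
      expect_equal(unname(f[[paste0("skew_", ax)]]), skew_oracle(v),
                   tolerance = 1e-9)
      expect_equal(unname(f[[paste0("kurt_", ax)]]), kurt_oracle(v),
                   tolerance = 1e-9)
      if (requireNamespace("e1071", quietly = TRUE)) {
        expect_equal(unname(f[[paste0("skew_", ax)]]),
                     e1071::skewness(v, type = 1), tolerance = 1e-9)
        expect_equal(unname(f[[paste0("kurt_", ax)]]),
                     e1071::kurtosis(v, type = 1), tolerance = 1e-9)
      }
      spec <- direct_spectrum(v)
      expect_equal(unname(f[[paste0("fft_mean_", ax)]]), mean(spec),
                   tolerance = 1e-9)
      expect_equal(unname(f[[paste0("fft_sd_", ax)]]), sd(spec),
                   tolerance = 1e-9)
      expect_equal(unname(f[[paste0("fft_median_", ax)]]), median(spec),
                   tolerance = 1e-9)
      expect_equal(unname(f[[paste0("fft_wmean_", ax)]]),
                   sum(spec * (1:75) * 0.2) / sum(spec), tolerance = 1e-9)
      expect_equal(unname(f[sprintf("fft_bin%02d_%s", 1:10, ax)]),
                   spec[1:10], tolerance = 1e-9)
    }
    vm <- sqrt(rowSums(win^2))
    expect_equal(unname(f[["mean_vm"]]), mean(vm), tolerance = 1e-9)
    expect_equal(unname(f[["kurt_vm"]]), kurt_oracle(vm), tolerance = 1e-9)
    expect_equal(unname(f[["corr_xy"]]), cor(win[, 2], win[, 1]),
                 tolerance = 1e-9)
    expect_equal(unname(f[["corr_yz"]]), cor(win[, 1], win[, 3]),
                 tolerance = 1e-9)
    expect_equal(unname(f[["corr_xz"]]), cor(win[, 2], win[, 3]),
                 tolerance = 1e-9)
  }
})

test_that("batch extraction is pure and keeps the stable 78-column layout", {
  tr <- simulate_bout("walk", 30, "hip", seed = 4)
  w <- segment_windows(tr, label_track("p1", "walk", 0, 30))
  tab <- extract_features(w)
  expect_equal(ncol(tab), 4L + 78L)
  expect_identical(names(tab)[-(1:4)], feature_names())
  expect_gt(nrow(tab), 0L)
  dup <- extract_features(c(w[1], w[1]))
  expect_equal(dup[1, ], dup[2, ], ignore_attr = TRUE)
  empty <- extract_features(list())
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty)[-(1:4)], feature_names())
})
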