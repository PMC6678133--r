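# Shared fixtures, built in code.

# Trace with a given constant acceleration on each axis.
constant_trace <- function(values = c(0, 0, 0), duration_s = 20, sr = 30,
                           site = "hip") {
  n <- duration_s * sr
  accel_trace(matrix(rep(values, each = n), n, 3L), sr, site)
}

# Trace with a sinusoid on axis 1 riding on 1 g gravity.
sine_trace <- function(amp, freq_hz = 1, duration_s = 20, sr = 30) {
  t <- (0:(duration_s * sr - 1)) / sr
  accel_trace(cbind(1 + amp * sin(2 * pi * freq_hz * t), 0, 0), sr, "hip")
}

# Random feature window, seeded.
random_window <- function(seed, n = 150) {
  set.seed(seed)
  matrix(rnorm(3 * n, mean = c(1, 0, 0), sd = 0.5), n, 3L, byrow = TRUE)
}

# Exact Mann-Whitney enumeration oracle: distribution of U over all
# assignments of the combined sample to groups of the observed sizes.
mw_enumeration <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2L, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  u_obs <- u_stat(a, b)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Brute-force magnitude spectrum by direct DFT sum (independent of fft()).
direct_spectrum <- function(x) {
  n <- length(x)
  x <- x - sum(x) / n
  nb <- n %/% 2
  vapply(seq_len(nb), function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    2 * sqrt(re^2 + im^2) / n
  }, 0)
}
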