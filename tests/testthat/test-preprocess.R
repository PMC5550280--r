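fs_t <- 500

test_that("step artifacts at the light transitions are removed", {
  set.seed(30)
  t <- (0:(180 * fs_t - 1)) / fs_t
  rhythm <- 2e-5 * sin(2 * pi * 0.45 * t) + rnorm(length(t), 0, 5e-7)
  light <- light_epoch(60, 120)
  step <- 50e-6 * (t >= 60 & t < 120)
  out <- correct_step_artifact(rhythm + step, fs_t, light)
  # residual step against the injected-step oracle: the corrected trace
  # minus the known rhythm must have continuous 1-s means (< 1 uV jump)
  resid <- out - rhythm
  jump <- function(y, tt) abs(mean(y[t >= tt & t < tt + 1]) -
                                mean(y[t >= tt - 1 & t < tt]))
  expect_lt(jump(resid, 60), 1e-6)
  expect_lt(jump(resid, 120), 1e-6)

  # opposite-sign steps at the two transitions are both removed
  step2 <- 50e-6 * (t >= 60 & t < 120) - 80e-6 * (t >= 120)
  out2 <- correct_step_artifact(rhythm + step2, fs_t, light)
  resid2 <- out2 - rhythm
  expect_lt(jump(resid2, 60), 1e-6)
  expect_lt(jump(resid2, 120), 1e-6)

  # near-idempotent on clean input (no step to find)
  clean <- correct_step_artifact(rhythm, fs_t, light)
  expect_lt(jump(clean - rhythm, 60), 1e-6)
  expect_lt(max(abs(clean - rhythm)), 3e-6)

  expect_error(correct_step_artifact(rhythm[1:1000], fs_t, light),
               "outside the record")
})

test_that("averaged pulse artifacts are subtracted", {
  set.seed(31)
  n <- 30 * fs_t
  x <- rnorm(n, 0, 1e-6)
  pulse_times <- seq(5, 15, by = 0.01)  # 100 Hz for 10 s
  art <- 20e-6 * c(1, -0.6)
  xa <- x
  for (pt in pulse_times) {
    i <- round(pt * fs_t) + 1
    xa[i:(i + 1)] <- xa[i:(i + 1)] + art
  }
  out <- subtract_pulse_artifacts(xa, fs_t, pulse_times)
  res_power <- function(y) {
    idx <- unlist(lapply(round(pulse_times * fs_t) + 1, function(i) i:(i + 1)))
    sum((y[idx] - x[idx])^2)
  }
  expect_lt(res_power(out), 0.1 * res_power(xa))

  # empty pulse list is the identity; < 10 pulses is a warned no-op
  expect_identical(subtract_pulse_artifacts(xa, fs_t, numeric(0)), xa)
  expect_warning(out2 <- subtract_pulse_artifacts(xa, fs_t, pulse_times[1:5]),
                 "fewer than 10")
  expect_identical(out2, xa)

  # amplitude jitter: only the jitter component survives
  set.seed(32)
  xj <- x
  jit <- rnorm(length(pulse_times), 1, 0.2)
  for (k in seq_along(pulse_times)) {
    i <- round(pulse_times[k] * fs_t) + 1
    xj[i:(i + 1)] <- xj[i:(i + 1)] + art * jit[k]
  }
  outj <- subtract_pulse_artifacts(xj, fs_t, pulse_times)
  expect_lt(res_power(outj), 0.1 * res_power(xj))
})

test_that("integration cascade matches the rectified-sine oracle", {
  t <- (0:(60 * fs_t - 1)) / fs_t
  x <- sin(2 * pi * 50 * t)
  ig <- integrate_neurogram(x, fs_t)
  mid <- ig$samples[(10 * fs_t):(50 * fs_t)]
  # oracle: the mean of the rectified sampled sine (the analytic value is
  # 2/pi; sampling at 10 points/cycle shifts it by ~3%)
  expect_equal(mean(mid), mean(abs(x)), tolerance = 0.01)
  expect_equal(mean(mid), 2 / pi, tolerance = 0.05)
  expect_true(all(ig$samples >= 0))
  # DC is removed by the 10-Hz high-pass; zero input stays zero
  dc <- integrate_neurogram(rep(1, 20 * fs_t), fs_t)
  expect_lt(max(dc$samples[(5 * fs_t):(15 * fs_t)]), 0.01)
  expect_identical(max(abs(integrate_neurogram(rep(0, 5000), fs_t)$samples)), 0)
  expect_error(integrate_neurogram(x, fs = 300), "too low")
})

test_that("slow-potential chain passes the band and rejects out-of-band input", {
  t <- (0:(180 * fs_t - 1)) / fs_t
  inband <- extract_slow_potential(sin(2 * pi * 0.5 * t), fs_t)
  amp_in <- max(abs(inband$samples[(60 * fs_t):(120 * fs_t)]))
  expect_equal(amp_in, 1, tolerance = 0.05)
  outband <- extract_slow_potential(sin(2 * pi * 50 * t), fs_t)
  expect_lt(max(abs(outband$samples[(60 * fs_t):(120 * fs_t)])), 0.05)
  expect_identical(max(abs(extract_slow_potential(rep(0, 5000), fs_t)$samples)),
                   0)
  # zero-mean over long windows (DC rejected)
  dc <- extract_slow_potential(rep(1, 180 * fs_t) + sin(2 * pi * 0.5 * t), fs_t)
  expect_lt(abs(mean(dc$samples[(30 * fs_t):(150 * fs_t)])), 0.02)
})

test_that("both chains are zero-phase and positively homogeneous", {
  set.seed(33)
  t <- (0:(40 * fs_t - 1)) / fs_t
  burst <- exp(-((t - 20)^2) / (2 * 0.5^2)) * sin(2 * pi * 30 * t)
  ig <- integrate_neurogram(burst, fs_t)
  expect_lt(abs(which.max(ig$samples) - which.max(abs(burst))) / fs_t, 0.05)
  sl <- extract_slow_potential(exp(-((t - 20)^2) / 2), fs_t)
  expect_lt(abs(which.max(sl$samples) - 20 * fs_t) / fs_t, 0.1)
  # chain(a x) = a chain(x), a > 0
  x <- rnorm(10 * fs_t, 0, 1e-5)
  expect_equal(integrate_neurogram(3.7 * x, fs_t)$samples,
               3.7 * integrate_neurogram(x, fs_t)$samples, tolerance = 1e-10)
  expect_equal(extract_slow_potential(3.7 * x, fs_t)$samples,
               3.7 * extract_slow_potential(x, fs_t)$samples,
               tolerance = 1e-10)
})

test_that("alignment trim yields a 170-s record with the light at [55, 115)", {
  sc <- small_scenario(seed = 34, n_experiments = 1, trials_per_experiment = 1)
  g <- generate_trial(sc, 1, 1)
  tr <- align_trim(g$trial)
  expect_identical(ncol(tr$samples), 170L * 500L)
  expect_identical(tr$light$onset_s, 55)
  expect_identical(tr$light$offset_s, 115)
  expect_error(align_trim(tr), "at least 180 s")
  # 5-kHz arithmetic: 170 x 5000 samples out
  sc5 <- synthetic_scenario(n_experiments = 1, trials_per_experiment = 1,
                            fs = 5000, seed = 1)
  tr5 <- align_trim(generate_trial(sc5, 1, 1)$trial)
  expect_identical(ncol(tr5$samples), 850000L)
})
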