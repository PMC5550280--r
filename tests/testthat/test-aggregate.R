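t3200 <- (0:3199) * 170 / 3200

mk_phase <- function(deg) {
  structure(list(phase_deg = deg, freq_Hz = rep(0.5, 3200),
                 power = rep(1, 3200), pair = c("a", "b"),
                 pair_class = "bilateral_flexor", time_axis_s = t3200),
            class = "phase_series")
}
mk_rhythm <- function(f) {
  structure(list(freq_Hz = f, power = rep(1, 3200), time_axis_s = t3200,
                 valid = TRUE, trial_id = "t", experiment_id = "e"),
            class = "rhythm_series")
}

test_that("phase normalization follows the stated absolute-change rule", {
  # constant 180 deg -> 0 everywhere
  ns <- normalize_phase(mk_phase(rep(180, 3200)))
  expect_identical(max(abs(ns$values)), 0)
  # control 180, light 150 -> 30 during the light
  ph <- rep(180, 3200); ph[t3200 >= 55 & t3200 < 115] <- 150
  ns2 <- normalize_phase(mk_phase(ph))
  expect_equal(unique(ns2$values[t3200 >= 56 & t3200 < 114]), 30)
  expect_true(all(ns2$values >= 0 & ns2$values <= 180))
  expect_error(normalize_phase(mk_phase(ph), control_window = c(10, 13)),
               "shorter than 5 s")
})

test_that("wrapped phase differences are computed on the circle", {
  # values straddling the +/-180 wrap: brute-force circular oracle
  set.seed(60)
  base_true <- 178
  dev <- stats::rnorm(3200, 0, 6)
  ph <- wrap_deg(base_true + dev)
  expect_true(any(ph < -170) && any(ph > 170))  # straddles the wrap
  ns <- normalize_phase(mk_phase(ph))
  oracle <- abs(vapply(ph - base_true, function(d) {
    atan2(sin(d * pi / 180), cos(d * pi / 180)) * 180 / pi
  }, numeric(1)))
  # baseline is estimated from the control window, so allow its small bias
  expect_lt(max(abs(ns$values - oracle)), 1)
  expect_true(all(ns$values <= 180))
})

test_that("frequency normalization sets the control mean to zero", {
  ns <- normalize_frequency(mk_rhythm(rep(0.5, 3200)))
  expect_identical(max(abs(ns$values)), 0)
  f <- rep(0.5, 3200); f[t3200 >= 55 & t3200 < 115] <- 0.46
  ns2 <- normalize_frequency(mk_rhythm(f))
  expect_equal(unique(ns2$values[t3200 >= 55 & t3200 < 115]), -8)
  expect_lt(abs(mean(ns2$values[t3200 >= 10 & t3200 < 55])), 1e-9)
  expect_error(normalize_frequency(mk_rhythm(rep(0, 3200))), "zero")
})

test_that("firing normalization resamples at 19 Hz onto the wavelet base", {
  env <- rep(2e-5, 170 * 500)
  tr <- filtered_trace(env, 500, "integrated")
  ns <- normalize_firing(tr)
  expect_identical(max(abs(ns$values)), 0)
  expect_identical(length(ns$values), 3200L)
  # envelope halved during the light -> -50% plateau
  t <- (seq_along(env) - 1) / 500
  env2 <- env * ifelse(t >= 55 & t < 115, 0.5, 1)
  ns2 <- normalize_firing(filtered_trace(env2, 500, "integrated"))
  # one 19-Hz sample straddles the transition, nudging the control mean
  expect_equal(stats::median(ns2$values[t3200 >= 60 & t3200 < 110]), -50,
               tolerance = 1e-3)
  expect_identical(eval(formals(normalize_firing)$resample_Hz), 19)
  expect_error(normalize_firing(filtered_trace(env, 500, "slow")),
               "integrated")
  expect_error(normalize_firing(filtered_trace(rep(0, 170 * 500), 500,
                                               "integrated")), "zero")
})

test_that("experiment averaging applies the minimum-valid-trials rule", {
  mk_ns <- function(v) normalized_series("freq_pct", rep(v, 3200), t3200,
                                         c(10, 55), "e1")
  sl <- lapply(c(1, 2, 3, 10), mk_ns)
  avg <- average_experiment(sl, valid = c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(avg$n_valid_trials, 3L)
  expect_equal(unique(avg$values), 2)
  expect_message(
    out <- average_experiment(sl, valid = c(TRUE, TRUE, FALSE, FALSE),
                              experiment_id = "e1"),
    "excluded")
  expect_null(out)
  # idempotence: identical trials average to any one of them
  same <- average_experiment(lapply(c(5, 5, 5), mk_ns))
  expect_equal(same$values, rep(5, 3200))
  mixed <- list(mk_ns(1),
                normalized_series("firing_pct", rep(1, 3200), t3200,
                                  c(10, 55)))
  expect_error(average_experiment(mixed), "mixed")
})

test_that("window summaries implement the four standard 10-s windows", {
  zero <- normalized_series("freq_pct", rep(0, 3200), t3200, c(10, 55))
  expect_identical(unname(window_summary(zero)), c(0, 0, 0, 0))
  v <- rep(0, 3200); v[t3200 >= 55 & t3200 < 115] <- -8
  step <- normalized_series("freq_pct", v, t3200, c(10, 55))
  ws <- window_summary(step)
  expect_equal(unname(ws), c(0, -8, -8, 0))
  expect_identical(names(ws),
                   c("control", "start_light", "end_light", "after_light"))
  # max-change variant picks the extremum inside each window
  v2 <- rep(0, 3200); v2[t3200 >= 56 & t3200 < 57] <- 12
  mx <- window_summary(normalized_series("freq_pct", v2, t3200, c(10, 55)),
                       stat = "max")
  expect_equal(unname(mx[["start_light"]]), 12)
  short <- normalized_series("freq_pct", rep(0, 100), t3200[1:100], c(10, 55))
  expect_error(window_summary(short), "outside")
})

test_that("phase normalization is invariant to a common phase offset", {
  set.seed(61)
  dev <- stats::rnorm(3200, 0, 10)
  for (off in c(-140, 0, 90)) {
    a <- normalize_phase(mk_phase(wrap_deg(120 + dev)))
    b <- normalize_phase(mk_phase(wrap_deg(120 + off + dev)))
    expect_equal(a$values, b$values, tolerance = 1e-9)
  }
})

test_that("series-level cohorts recover the generative frequency drop", {
  # reduced form of the recovery property: 40 experiments, series level
  sc <- synthetic_scenario(n_experiments = 40, trials_per_experiment = 4,
                           light_recovery_tau_s = Inf, seed = 70)
  cohort <- synth_rhythm_series(sc)
  drops <- vapply(seq_along(cohort), function(e) {
    avg <- average_experiment(lapply(cohort[[e]], normalize_frequency))
    window_summary(avg)[["start_light"]]
  }, numeric(1))
  truth <- vapply(seq_along(cohort), function(e) {
    -100 * rootwave:::exp_effects(sc, e)$drop
  }, numeric(1))
  expect_equal(mean(drops), mean(truth), tolerance = abs(mean(truth)) * 0.1)
})
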