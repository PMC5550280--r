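# Spectral fixtures: 170-s traces on a 500-Hz base unless stated.
make_trace <- function(f, fs = 500, dur = 170, phase = 0) {
  sin(2 * pi * f * (0:(dur * fs - 1)) / fs + phase)
}

test_that("spectrogram has 3200 time columns and strictly increasing grid", {
  sp <- cwt_spectrogram(make_trace(0.5), fs = 500)
  expect_identical(dim(sp$coefficients), c(64L, 3200L))
  expect_identical(length(sp$time_axis_s), 3200L)
  expect_true(all(diff(sp$freq_grid_Hz) > 0))
  expect_error(cwt_spectrogram(make_trace(0.5, dur = 100), fs = 500),
               "170")
  expect_error(cwt_spectrogram(make_trace(0.5), fs = 500,
                               freq_grid = c(0.5, 0.4)),
               "strictly increasing")
  expect_identical(max(Mod(cwt_spectrogram(rep(0, 3200),
                                           fs = 3200 / 170)$coefficients)), 0)
})

test_that("stationary-sinusoid ridge matches the FFT-peak oracle within a grid step", {
  for (f in c(0.3, 0.5, 0.8)) {
    x <- make_trace(f)
    oracle <- fft_peak_Hz(x, 500)
    sp <- cwt_spectrogram(x, fs = 500)
    rf <- ridge_frequency(sp)
    mid <- rf$freq_Hz[rf$time_axis_s > 20 & rf$time_axis_s < 150]
    grid_step <- exp(diff(log(range(sp$freq_grid_Hz))) / 63)
    expect_lt(max(abs(log(mid / oracle))), log(grid_step))
    # constant outside the cone of influence: one grid step of wobble
    expect_lt(diff(range(mid)) / stats::median(mid), grid_step - 1)
  }
})

test_that("a descending chirp yields a decreasing ridge", {
  fs <- 500; t <- (0:(170 * fs - 1)) / fs
  finst <- 0.5 - 0.1 * t / 170          # 0.5 -> 0.4 Hz
  x <- sin(2 * pi * cumsum(finst) / fs)
  rf <- ridge_frequency(cwt_spectrogram(x, fs = fs))
  sel <- rf$time_axis_s > 15 & rf$time_axis_s < 155
  expect_lt(cor(rf$time_axis_s[sel], rf$freq_Hz[sel]), -0.98)
  expect_equal(mean(rf$freq_Hz[rf$time_axis_s > 15 & rf$time_axis_s < 25]),
               0.49, tolerance = 0.02)
  expect_equal(mean(rf$freq_Hz[rf$time_axis_s > 145 & rf$time_axis_s < 155]),
               0.41, tolerance = 0.02)
})

test_that("sub-threshold power zeroes the ridge (discard-rule input)", {
  x <- make_trace(0.5)
  x[40000:50000] <- 0   # 20-s silent gap at 80-100 s
  rf <- ridge_frequency(cwt_spectrogram(x, fs = 500))
  gap <- rf$time_axis_s > 88 & rf$time_axis_s < 92
  expect_true(all(rf$freq_Hz[gap] == 0))
  expect_true(all(rf$freq_Hz[rf$time_axis_s > 20 & rf$time_axis_s < 60] > 0))
  expect_true(all(ridge_frequency(cwt_spectrogram(rep(0, 3200),
                                                  fs = 3200 / 170))$freq_Hz
                  == 0))
})

test_that("cross-wavelet phase matches constructed lags and the Hilbert oracle", {
  fs <- 500
  cases <- list(c(lag_s = 0, expect_deg = 0),
                c(lag_s = 0.5, expect_deg = 90),
                c(lag_s = 1, expect_deg = 180))
  for (cs in cases) {
    xa <- make_trace(0.5, fs)
    xb <- make_trace(0.5, fs, phase = -2 * pi * 0.5 * cs[["lag_s"]])
    spa <- cwt_spectrogram(xa, fs = fs); spb <- cwt_spectrogram(xb, fs = fs)
    pp <- pair_phase(spa, spb, pair = c("a", "b"))
    mid <- pp$time_axis_s > 20 & pp$time_axis_s < 150
    meas <- stats::median(pp$phase_deg[mid])
    expect_lt(abs(wrap_deg(meas - cs[["expect_deg"]])), 2)
    hil <- stats::median(hilbert_phase_deg(xa, xb)[(20 * fs):(150 * fs)])
    expect_lt(abs(wrap_deg(meas - hil)), 5)
  }
})

test_that("pair phase is antisymmetric, zero on self, and shift-equivariant", {
  sc <- clean_scenario(seed = 51)
  g <- generate_trial(sc, 1, 1)
  tr <- align_trim(g$trial)
  sa <- cwt_spectrogram(extract_slow_potential(tr$samples[1, ], tr$fs))
  sb <- cwt_spectrogram(extract_slow_potential(tr$samples[2, ], tr$fs))
  ab <- pair_phase(sa, sb); ba <- pair_phase(sb, sa)
  mid <- ab$time_axis_s > 15 & ab$time_axis_s < 155
  expect_lt(max(abs(wrap_deg(ab$phase_deg[mid] + ba$phase_deg[mid]))), 1e-6)
  self <- pair_phase(sa, sa)
  expect_identical(max(abs(self$phase_deg)), 0)
  # identical time shift of both channels leaves the phase unchanged
  sh <- round(0.8 * tr$fs)
  sa2 <- cwt_spectrogram(extract_slow_potential(
    tr$samples[1, c((sh + 1):ncol(tr$samples), 1:sh)], tr$fs))
  sb2 <- cwt_spectrogram(extract_slow_potential(
    tr$samples[2, c((sh + 1):ncol(tr$samples), 1:sh)], tr$fs))
  ab2 <- pair_phase(sa2, sb2)
  mid2 <- ab$time_axis_s > 20 & ab$time_axis_s < 145
  expect_lt(stats::median(abs(wrap_deg(ab2$phase_deg[mid2] -
                                         ab$phase_deg[mid2]))), 5)
  expect_error(pair_phase(sa, cwt_spectrogram(make_trace(0.5),
                                              fs = 500,
                                              freq_grid = default_freq_grid(32))),
               "do not match")
})

test_that("edge clipping marks 10 s per side, idempotently", {
  rf <- ridge_frequency(cwt_spectrogram(make_trace(0.5), fs = 500))
  cl <- clip_edges(rf)
  span <- range(cl$time_axis_s[cl$analyzed])
  expect_gte(span[1], 10)
  expect_lt(span[2], 160)
  # analyzed sample count on the 3200-point axis: t in [10, 160)
  expect_identical(sum(cl$analyzed), 2823L)
  cl2 <- clip_edges(cl)
  expect_identical(cl2$analyzed, cl$analyzed)
})

test_that("the discard rule fires on pre-light/light dropouts only", {
  x <- make_trace(0.5)
  rf_ok <- ridge_frequency(cwt_spectrogram(x, fs = 500))
  expect_true(check_validity(rf_ok))
  # a long silent gap during the light discards at the default threshold
  xg <- x; xg[round(75 * 500):round(90 * 500)] <- 0
  rf_g <- ridge_frequency(cwt_spectrogram(xg, fs = 500))
  expect_false(check_validity(rf_g))
  # a 5-s gap needs a stricter (configurable) power threshold: the
  # wavelet's ~2-s envelope smears power into short gaps
  xg5 <- x; xg5[round(80 * 500):round(85 * 500)] <- 0
  rf_g5 <- ridge_frequency(cwt_spectrogram(xg5, fs = 500),
                           threshold_frac = 0.3)
  expect_false(check_validity(rf_g5))
  # dropout after the light offset does not discard
  xp <- x; xp[round(140 * 500):round(150 * 500)] <- 0
  rf_p <- ridge_frequency(cwt_spectrogram(xp, fs = 500))
  expect_true(check_validity(rf_p))
})
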