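test_that("detrend removes linear drift and leaves clean signals alone", {
  withr::local_seed(1)
  fs <- 100
  t <- (0:999) / fs
  # constant trace + linear drift of slope k
  k <- 0.3
  tr <- raw_trace(5 + k * t + rnorm(1000, 0, 1e-4))
  out <- detrend(tr, "linear", window_s = 2)
  res_slope <- stats::coef(lm(out$fluorescence ~ t))[2]
  expect_lt(abs(res_slope), 0.01 * k)

  # drift-free synthetic beat train passes through nearly unchanged
  sim <- simulate_trace(ca_params(), sim_config(seed = 3, bleach_rate = 0,
                                                noise_sd = 0.01),
                        "spontaneous", length_s = 10)
  out2 <- detrend(sim$trace, "linear", window_s = 2)
  expect_lt(max(abs(out2$fluorescence - sim$trace$fluorescence)), 0.01 * 1)

  # pure exponential decay, exponential model -> residual range < 1% of
  # input range
  y <- 3 * exp(-0.25 * t) + 1
  out3 <- detrend(raw_trace(y, channel = "calcium"), "exponential",
                  window_s = 1)
  expect_lt(diff(range(out3$fluorescence)), 0.01 * diff(range(y)))

  expect_error(detrend(raw_trace(y[1:100]), "linear", window_s = 2),
               "shorter than the trace")
})

test_that("normalize maps affinely onto [0,1] and rejects flat traces", {
  tr <- raw_trace(c(2, 4, 6))
  expect_equal(normalize(tr)$fluorescence, c(0, 0.5, 1))
  tr01 <- raw_trace(c(0, 0.25, 1, 0.5))
  expect_equal(normalize(tr01)$fluorescence, tr01$fluorescence)
  expect_error(normalize(raw_trace(rep(3, 10))), "constant")
})

test_that("segment_beats finds the generated beats and only those", {
  # identical voltage beats at 1 Hz: count and RR recovered
  sim <- simulate_trace(v_params(), sim_config(seed = 5, noise_sd = 0.01),
                        "spontaneous", length_s = 7)
  s <- segment_beats(prep_v(sim))
  expect_equal(nrow(s), nrow(sim$truth$beats))
  expect_equal(mean(rr_intervals(s)), 1, tolerance = 0.01)
  expect_true(all(abs(rr_intervals(s) - 1) < 0.01))

  # flat noise-only trace: no beats at prominence 0.3
  withr::local_seed(8)
  noise <- raw_trace(rnorm(3000, 0, 0.02), channel = "calcium")
  expect_equal(nrow(segment_beats(noise, min_prominence = 0.3)), 0)

  # an injected 10% DAD is not counted as a beat
  sim2 <- simulate_trace(ca_params(), sim_config(seed = 6), "spontaneous",
                         events = data.frame(kind = "DAD", beat_index = 3,
                                             amplitude_fraction = 0.10),
                         length_s = 8)
  s2 <- segment_beats(prep_ca(sim2), min_prominence = 0.3)
  expect_equal(nrow(s2), nrow(sim2$truth$beats))
})

test_that("beat ordering, APD ordering and refractory hold across seeds", {
  for (seed in 1:8) {
    sim <- simulate_trace(ca_params(apd80 = 200 + 40 * seed),
                          sim_config(seed = seed), "spontaneous",
                          length_s = 10)
    s <- segment_beats(prep_ca(sim))
    expect_true(all(diff(s$activation_time_s) > 0.2))
    expect_true(all(s$peak_time_s >= s$activation_time_s))
    expect_true(all(s$amplitude > 0))
    ok <- s$apd_resolved & is.finite(s$apd90_ms)
    expect_true(all(s$apd30_ms[ok] <= s$apd50_ms[ok] + 1e-9))
    expect_true(all(s$apd50_ms[ok] <= s$apd80_ms[ok] + 1e-9))
    expect_true(all(s$apd80_ms[ok] <= s$apd90_ms[ok] + 1e-9))
  }
})

test_that("apd matches closed-form geometry", {
  # step to 1 then linear decay to 0 over 400 ms
  tr <- linear_decay_trace(400)
  act <- tr$time_s[which(tr$fluorescence == 1)[1]]
  s <- manual_beat(tr, act)
  expect_equal(apd(tr, s, 0.3), 120, tolerance = 1)
  expect_equal(apd(tr, s, 0.8), 320, tolerance = 1)
  # APD_r monotone in r on a monotone repolarization
  rr <- seq(0.1, 0.9, by = 0.1)
  vals <- vapply(rr, function(r) apd(tr, s, r), numeric(1))
  expect_true(all(diff(vals) >= 0))

  # square pulse of width w: APD30 = APD80 = w within one sample
  w_ms <- 250
  fs <- 100
  pulse <- c(rep(0, 100), rep(1, w_ms / 1000 * fs), rep(0, 100))
  trp <- raw_trace(pulse)
  sp <- manual_beat(trp, trp$time_s[101])
  expect_equal(apd(trp, sp, 0.3), w_ms, tolerance = 10)
  expect_equal(apd(trp, sp, 0.8), w_ms, tolerance = 10)
  expect_lt(abs(apd(trp, sp, 0.3) - apd(trp, sp, 0.8)), 10)

  expect_error(apd(tr, s, 0), "in \\(0, 1\\)")
  expect_error(apd(tr, s, 1), "in \\(0, 1\\)")
})

test_that("generator beats recover their APD80 target", {
  sim <- simulate_trace(ca_params(apd80 = 350), sim_config(seed = 10),
                        "spontaneous", length_s = 10)
  s <- segment_beats(prep_ca(sim))
  expect_equal(median(s$apd80_ms, na.rm = TRUE), 350, tolerance = 10)
})

test_that("max upstroke velocity matches analytic slopes", {
  fs <- 100
  # linear ramp 0 -> 1 over 50 ms: slope 20/s
  ramp <- c(rep(0, 200), seq(0, 1, length.out = 6)[-1],
            seq(1, 0, length.out = 40), rep(0, 100))
  tr <- raw_trace(ramp)
  pk <- which.max(ramp)
  s <- manual_beat(tr, tr$time_s[pk])
  s$peak_time_s <- tr$time_s[pk]
  expect_equal(max_upstroke_velocity(tr, s), 20, tolerance = 0.5)

  # half-sine upstroke of period 200 ms: analytic max slope pi/0.2 * 1/2
  t_up <- seq(0, 0.1, by = 1 / fs)
  up <- (1 - cos(pi * t_up / 0.1)) / 2
  y <- c(rep(0, 200), up, seq(1, 0, length.out = 50), rep(0, 100))
  tr2 <- raw_trace(y)
  pk2 <- 200 + length(up)
  s2 <- manual_beat(tr2, tr2$time_s[pk2])
  s2$peak_time_s <- tr2$time_s[pk2]
  # analytic max slope of the half-cosine rise (dense-grid oracle agrees):
  # d/dt (1 - cos(pi t / 0.1)) / 2 peaks at pi / 0.2 ~ 15.7 /s
  t_dense <- seq(0, 0.1, by = 1e-5)
  oracle <- max(diff((1 - cos(pi * t_dense / 0.1)) / 2)) / 1e-5
  expect_equal(oracle, pi / 0.2, tolerance = 1e-6)
  expect_equal(max_upstroke_velocity(tr2, s2), oracle,
               tolerance = 0.05 * oracle)

  # calcium kinetics are slower than voltage at matched APDs
  simv <- simulate_trace(v_params(), sim_config(seed = 2, noise_sd = 0),
                         "spontaneous", length_s = 5)
  simc <- simulate_trace(ca_params(), sim_config(seed = 2, noise_sd = 0),
                         "spontaneous", length_s = 5)
  sv <- segment_beats(normalize(simv$trace))
  sc <- segment_beats(normalize(simc$trace))
  expect_gt(median(sv$max_upstroke), median(sc$max_upstroke))
})

test_that("fridericia correction has its closed form and scaling law", {
  expect_identical(fridericia_correct(300, 1.0), 300)
  expect_identical(fridericia_correct(300, 8.0), 150)
  expect_equal(fridericia_correct(300, 0.512), 375)
  # scaling: f(a, c^3 r) = f(a, r) / c
  withr::local_seed(3)
  for (i in 1:20) {
    a <- runif(1, 100, 500); r <- runif(1, 0.3, 2); cc <- runif(1, 0.5, 2)
    expect_equal(fridericia_correct(a, cc^3 * r),
                 fridericia_correct(a, r) / cc, tolerance = 1e-12)
  }
  expect_error(fridericia_correct(300, 0), "positive")
  expect_error(fridericia_correct(300, -1), "positive")
})

test_that("triangulation is the normalized APD spread, bounded in [0,1)", {
  expect_identical(triangulation(320, 320), 0)
  expect_equal(triangulation(120, 320), 0.625)
  withr::local_seed(4)
  for (i in 1:50) {
    a80 <- runif(1, 100, 600); a30 <- runif(1, 1, a80)
    v <- triangulation(a30, a80)
    expect_identical(v, (a80 - a30) / a80)  # brute-force formula
    expect_true(v >= 0 && v < 1)
  }
  expect_error(triangulation(400, 300), "not exceed")
  expect_error(triangulation(0, 300), "positive")
})

test_that("capture_check accepts 1:1 capture and rejects mismatch", {
  cfg_p <- sim_config(seed = 1, pacing_frequency_hz = 1)
  sim <- simulate_trace(ca_params(), cfg_p, "paced", length_s = 10)
  s <- segment_beats(prep_ca(sim))
  expect_true(capture_check(s, 1, tol = 0.05))

  # beats at 1.5 Hz under nominal 1 Hz pacing: rate mismatch
  cfg_f <- sim_config(seed = 2, spontaneous_rate_hz = 1.5)
  sim2 <- simulate_trace(ca_params(apd80 = 300), cfg_f, "spontaneous",
                         length_s = 10)
  s2 <- segment_beats(prep_ca(sim2))
  expect_false(capture_check(s2, 1, tol = 0.05))

  # 2:1 block: beats every 2 s under 1 Hz pacing
  cfg_b <- sim_config(seed = 3, spontaneous_rate_hz = 0.5)
  sim3 <- simulate_trace(ca_params(), cfg_b, "spontaneous", length_s = 12)
  s3 <- segment_beats(prep_ca(sim3))
  expect_false(capture_check(s3, 1, tol = 0.05))

  # fewer than 3 beats is non-capture
  expect_false(capture_check(s3[0, ], 1))
})

test_that("APD recovery property holds over randomized beats", {
  # property over >= 100 generated beats with APD80 targets in [200, 480] ms
  withr::local_seed(2024)
  errs <- vapply(1:100, function(i) {
    apd80 <- runif(1, 200, 480)
    sim <- simulate_trace(ca_params(apd80 = apd80),
                          sim_config(seed = sample.int(1e6, 1),
                                     noise_sd = 0.02),
                          "spontaneous", length_s = 4)
    s <- segment_beats(prep_ca(sim))
    median(s$apd80_ms, na.rm = TRUE) - apd80
  }, numeric(1))
  expect_lte(median(abs(errs)), 10)
  expect_lte(max(abs(errs)), 20)
})
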