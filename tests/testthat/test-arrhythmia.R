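test_that("EAD detector finds injected phase-3 deflections", {
  # one 15% EAD: exactly one event with amplitude close to the injection
  sim <- simulate_trace(ca_params(), sim_config(seed = 15, noise_sd = 0.01),
                        "spontaneous",
                        events = data.frame(kind = "EAD", beat_index = 10,
                                            amplitude_fraction = 0.15),
                        length_s = 30)
  tr <- prep_ca(sim)
  s <- segment_beats(tr)
  e <- detect_eads(tr, s)
  expect_equal(nrow(e), 1)
  expect_equal(e$beat_index, 10)
  expect_equal(e$relative_amplitude, 0.15, tolerance = 0.03 / 0.15)

  # clean monotone beat: no events
  sim0 <- simulate_trace(ca_params(), sim_config(seed = 16, noise_sd = 0),
                         "spontaneous", length_s = 10)
  tr0 <- normalize(sim0$trace)
  expect_equal(nrow(detect_eads(tr0, segment_beats(tr0))), 0)

  # two EADs (10%, 20%) on one long triangulated beat, ordered by time
  sim2 <- simulate_trace(
    beat_template_params("calcium", apd30_ms = 270, apd80_ms = 450),
    sim_config(seed = 42, noise_sd = 0.01), "spontaneous",
    events = data.frame(kind = c("EAD", "EAD"), beat_index = c(10, 10),
                        amplitude_fraction = c(0.10, 0.20),
                        timing = c(0.05, 0.95)),
    length_s = 30)
  tr2 <- prep_ca(sim2)
  e2 <- detect_eads(tr2, segment_beats(tr2))
  expect_equal(nrow(e2), 2)
  expect_true(all(diff(e2$time_s) > 0))
  expect_lt(e2$relative_amplitude[1], e2$relative_amplitude[2])
})

test_that("DAD detector finds diastolic deflections and respects the beat
           partition", {
  sim <- simulate_trace(ca_params(), sim_config(seed = 21, noise_sd = 0.01),
                        "spontaneous",
                        events = data.frame(kind = "DAD", beat_index = 12,
                                            amplitude_fraction = 0.25),
                        length_s = 30)
  tr <- prep_ca(sim)
  s <- segment_beats(tr)
  d <- detect_dads(tr, s)
  expect_equal(nrow(d), 1)
  expect_equal(d$relative_amplitude, 0.25, tolerance = 0.05 / 0.25)
  # the event lies in diastole: after its beat's APD90 crossing
  expect_gt(d$time_s, s$apd90_cross_time_s[d$beat_index])

  # quiescent diastole with noise only: no events
  withr::local_seed(9)
  sim0 <- simulate_trace(ca_params(), sim_config(seed = 22), "spontaneous",
                         length_s = 30)
  tr0 <- prep_ca(sim0)
  expect_equal(nrow(detect_dads(tr0, segment_beats(tr0))), 0)

  # an 80% deflection is a beat (segmentation), not a DAD
  sim8 <- simulate_trace(ca_params(), sim_config(seed = 23), "spontaneous",
                         events = data.frame(kind = "DAD", beat_index = 10,
                                             amplitude_fraction = 0.80),
                         length_s = 30)
  tr8 <- prep_ca(sim8)
  s8 <- segment_beats(tr8)
  expect_equal(nrow(s8), nrow(sim8$truth$beats) + 1)
  expect_equal(nrow(detect_dads(tr8, s8)), 0)
})

test_that("shape irregularity is zero for identical beats and responds to
           alternating amplitudes", {
  sim <- simulate_trace(ca_params(), sim_config(seed = 31, noise_sd = 0.005),
                        "spontaneous", length_s = 12)
  s <- segment_beats(prep_ca(sim))
  expect_lt(shape_irregularity(s), 0.02)

  # alternating amplitudes 1.0 / 0.5: population CV = 1/3
  s2 <- s
  s2$amplitude <- rep(c(1, 0.5), length.out = nrow(s2))
  expect_equal(shape_irregularity(s2), 1 / 3, tolerance = 0.02)

  # torsades-like amplitude modulation drives it past the call threshold
  s3 <- s
  s3$amplitude <- s3$amplitude * (1 + 0.4 * sin(seq_len(nrow(s3))))
  expect_gt(shape_irregularity(s3), 0.2)

  expect_true(is.na(shape_irregularity(s[1:3, ])))
})

test_that("poincare_pairs is the mean-normalized lag-1 embedding", {
  p <- poincare_pairs(c(300, 300, 300, 300))
  expect_equal(p$prev, rep(1, 3))
  expect_equal(p$curr, rep(1, 3))

  p2 <- poincare_pairs(c(300, 360, 300, 360))
  expect_equal(p2$prev, c(300, 360, 300) / 330)
  expect_equal(p2$curr, c(360, 300, 360) / 330)

  # equals a brute-force shifted zip for arbitrary sequences
  withr::local_seed(5)
  for (i in 1:20) {
    x <- runif(sample(3:30, 1), 200, 500)
    p <- poincare_pairs(x)
    z <- x / mean(x)
    expect_identical(p$prev, z[-length(z)])
    expect_identical(p$curr, z[-1])
  }
  expect_error(poincare_pairs(c(300, 310)), "at least 3")
})

test_that("instability index has its closed forms and invariances", {
  # constant sequence: exactly zero, stable
  ii0 <- instability_index(poincare_pairs(rep(321.5, 10)))
  expect_identical(ii0$index, 0)
  expect_false(ii0$unstable)

  # perfect alternans a(1 +/- eps): index = eps * sqrt(2)
  for (eps in c(0.05, 0.1, 0.2)) {
    ii <- instability_index(poincare_pairs(rep(c(1 + eps, 1 - eps), 10) * 300))
    expect_equal(ii$index, eps * sqrt(2), tolerance = 1e-9)
  }
  expect_true(instability_index(
    poincare_pairs(rep(c(330, 270), 10)))$unstable)

  # i.i.d. jitter sigma/mean = 0.01: index ~ 0.01, stable (seeded MC)
  withr::local_seed(77)
  idx <- replicate(20, {
    instability_index(poincare_pairs(rnorm(200, 300, 3)))$index
  })
  expect_equal(mean(idx), 0.01, tolerance = 0.15)
  expect_false(any(idx > 0.05))

  # invariant under uniform APD rescaling
  withr::local_seed(6)
  x <- runif(20, 250, 350)
  i1 <- instability_index(poincare_pairs(x))$index
  i2 <- instability_index(poincare_pairs(x * 7.3))$index
  expect_equal(i1, i2, tolerance = 1e-12)
  expect_gt(i1, 0)
})

test_that("classify_tissue applies the weak / arrhythmic / normal rules with
           precedence", {
  sim <- simulate_trace(ca_params(), sim_config(seed = 41, noise_sd = 0.01),
                        "spontaneous", length_s = 30)
  tr <- prep_ca(sim)
  s <- segment_beats(tr)
  m_amp <- max(s$amplitude)

  # amplitude ratio exactly 0.59 -> weak_or_silent; 0.61 -> normal
  weak <- classify_tissue(tr, s, control_amplitude = m_amp / 0.59)
  expect_identical(weak$category, "weak_or_silent")
  expect_equal(weak$amplitude_vs_control, 0.59)
  norm <- classify_tissue(tr, s, control_amplitude = m_amp / 0.61)
  expect_identical(norm$category, "normal")
  expect_false(is.na(norm$instability_index))

  # zero beats -> weak_or_silent regardless of events
  withr::local_seed(50)
  flat <- raw_trace(rnorm(3000, 0, 0.02), channel = "calcium")
  s0 <- segment_beats(flat)
  call0 <- classify_tissue(flat, s0, control_amplitude = 1)
  expect_identical(call0$category, "weak_or_silent")

  # an EAD at healthy amplitude -> arrhythmic
  sim_e <- simulate_trace(ca_params(), sim_config(seed = 43, noise_sd = 0.01),
                          "spontaneous",
                          events = data.frame(kind = "EAD", beat_index = 8,
                                              amplitude_fraction = 0.2),
                          length_s = 30)
  tr_e <- prep_ca(sim_e)
  s_e <- segment_beats(tr_e)
  call_e <- classify_tissue(tr_e, s_e, max(s_e$amplitude) / 0.9)
  expect_identical(call_e$category, "arrhythmic")
  expect_gte(call_e$n_ead, 1)

  # weak takes precedence even when events are present
  call_we <- classify_tissue(tr_e, s_e, max(s_e$amplitude) / 0.5)
  expect_identical(call_we$category, "weak_or_silent")

  expect_error(classify_tissue(tr, s), "control_amplitude")
})

test_that("cohort_incidence counts categories as percentages summing to 100", {
  calls <- tibble::tibble(
    dose_index = rep(0:1, each = 4),
    category = c("arrhythmic", "normal", "normal", "weak_or_silent",
                 rep("normal", 4)))
  inc <- cohort_incidence(calls)
  d0 <- inc[inc$dose_index == 0, ]
  expect_equal(d0$pct[d0$category == "arrhythmic"], 25)
  expect_equal(d0$pct[d0$category == "weak_or_silent"], 25)
  expect_equal(d0$pct[d0$category == "normal"], 50)
  d1 <- inc[inc$dose_index == 1, ]
  expect_equal(d1$pct[d1$category == "normal"], 100)
  sums <- tapply(inc$pct, inc$dose_index, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  # binomial sampling oracle: p = 0.5, n = 200 within exact binomial CI
  withr::local_seed(99)
  n <- 200
  cat2 <- ifelse(rbinom(n, 1, 0.5) == 1, "arrhythmic", "normal")
  inc2 <- cohort_incidence(tibble::tibble(dose_index = 0, category = cat2))
  ci <- stats::binom.test(sum(cat2 == "arrhythmic"), n, 0.5)$conf.int
  expect_true(0.5 >= ci[1] && 0.5 <= ci[2])
  expect_equal(inc2$pct[inc2$category == "arrhythmic"] / 100,
               mean(cat2 == "arrhythmic"))

  expect_error(cohort_incidence(calls[0, ]), "no calls")
})

test_that("detectors keep their operating characteristics on a seeded batch", {
  # compact version of the calibration experiment: 30 event traces and
  # 30 clean traces (the full 200-trace run lives in the acceptance suite)
  withr::local_seed(1234)
  hits <- matrix(0, 2, 0)
  for (i in 1:30) {
    ev <- data.frame(kind = c("EAD", "DAD"), beat_index = sort(sample(3:25, 2)),
                     amplitude_fraction = runif(2, 0.15, 0.3),
                     timing = runif(2, 0.3, 0.7))
    sim <- simulate_trace(ca_params(), sim_config(seed = sample.int(1e6, 1)),
                          "spontaneous", events = ev, length_s = 30)
    tr <- prep_ca(sim)
    s <- segment_beats(tr)
    e <- detect_eads(tr, s)
    d <- detect_dads(tr, s)
    truth <- sim$truth$events
    ead_hit <- any(abs(e$time_s - truth$time_s[truth$kind == "EAD"]) < 0.15)
    dad_hit <- any(abs(d$time_s - truth$time_s[truth$kind == "DAD"]) < 0.15)
    hits <- cbind(hits, c(ead_hit, dad_hit))
  }
  expect_gte(mean(hits[1, ]), 0.9)
  expect_gte(mean(hits[2, ]), 0.9)
})
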