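test_that("beat templates hit their analytic control points exactly", {
  for (tri in c(0.1, 0.3, 0.5)) {
    apd80 <- 400
    p <- beat_template_params("voltage", apd30_ms = apd80 * (1 - tri),
                              apd80_ms = apd80, amplitude = 0.8)
    # crossing levels at the control points, in time-since-activation
    expect_equal(cardiomps:::beat_value(p$apd30_ms / 1000, p), 0.7 * 0.8)
    expect_equal(cardiomps:::beat_value(p$apd80_ms / 1000, p), 0.2 * 0.8)
    tmpl <- make_beat_template(p, fps = 100)
    expect_identical(attr(tmpl, "apd30_ms"), p$apd30_ms)
    expect_identical(attr(tmpl, "triangulation"), tri)
    expect_equal(max(tmpl$value), 0.8, tolerance = 1e-6)
  }
  # plateau beat: apd30 = 0.9 apd80 -> triangulation 0.1
  pp <- beat_template_params("voltage", apd30_ms = 360, apd80_ms = 400)
  expect_equal(attr(make_beat_template(pp), "triangulation"), 0.1)

  # calcium upstroke is slower than voltage at identical APDs
  tv <- make_beat_template(beat_template_params("voltage"))
  tc <- make_beat_template(beat_template_params("calcium"))
  expect_gt(max(diff(tv$value)), max(diff(tc$value)))

  expect_error(beat_template_params("voltage", apd30_ms = 400,
                                    apd80_ms = 300), "apd30")
  expect_error(beat_template_params("voltage", apd30_ms = 100,
                                    apd80_ms = 300, upstroke_ms = 150),
               "upstroke")
})

test_that("simulate_trace renders the requested train with exact bookkeeping", {
  # 30 s at 1 Hz, no noise: exactly 30 beats; APD80 recovered within ~1 ms
  sim <- simulate_trace(ca_params(), sim_config(noise_sd = 0, bleach_rate = 0),
                        "spontaneous", length_s = 30)
  expect_equal(nrow(sim$truth$beats), 30)
  s <- segment_beats(normalize(sim$trace))
  expect_equal(nrow(s), 30)
  expect_equal(median(s$apd80_ms), 350, tolerance = 6)

  # injected events are all recorded in the ground truth
  ev <- data.frame(kind = c("EAD", "DAD", "DAD"), beat_index = c(4, 9, 15),
                   amplitude_fraction = c(0.2, 0.15, 0.3))
  sim2 <- simulate_trace(ca_params(), sim_config(seed = 2), "spontaneous",
                         events = ev, length_s = 30)
  expect_equal(nrow(sim2$truth$events), 3)
  expect_identical(sort(sim2$truth$events$kind), c("DAD", "DAD", "EAD"))

  # silence: flat noise-only trace, no beats detected
  sim3 <- simulate_trace(ca_params(), sim_config(seed = 3), "spontaneous",
                         length_s = 10, silent = TRUE)
  expect_equal(nrow(sim3$truth$beats), 0)
  expect_equal(nrow(segment_beats(normalize(sim3$trace))), 0)

  # beats overlapping at an impossible rate error out
  expect_error(
    simulate_trace(ca_params(apd80 = 600),
                   sim_config(spontaneous_rate_hz = 1.6), "spontaneous",
                   length_s = 5),
    "overlap")
})

test_that("alternans in the generator reproduces the instability closed form", {
  sim <- simulate_trace(ca_params(), sim_config(seed = 4, noise_sd = 0.01),
                        "spontaneous", length_s = 30, alternans_eps = 0.1)
  s <- segment_beats(prep_ca(sim))
  apd <- s$apd80_ms[s$apd_resolved]
  ii <- instability_index(poincare_pairs(apd))
  expect_equal(ii$index, 0.1 * sqrt(2), tolerance = 0.25 * 0.1414)
  expect_true(ii$unstable)
})

test_that("generator determinism: identical seeds give identical output", {
  cfg <- sim_config(seed = 123)
  a <- simulate_trace(ca_params(), cfg, "spontaneous", length_s = 6)
  b <- simulate_trace(ca_params(), cfg, "spontaneous", length_s = 6)
  expect_identical(a$trace$fluorescence, b$trace$fluorescence)

  design <- dose_escalation_design("HCQ", 1, c(0, 1), n_tissues = 2)
  c1 <- simulate_cohort(design, drug_effect_model(), sim_config(seed = 7))
  c2 <- simulate_cohort(design, drug_effect_model(), sim_config(seed = 7))
  expect_identical(
    lapply(c1$traces$trace, function(tr) tr$fluorescence),
    lapply(c2$traces$trace, function(tr) tr$fluorescence))
  expect_identical(c1$truth$conditions, c2$truth$conditions)
})

test_that("drug effect model components are monotone in dose", {
  m <- drug_effect_model(apd_emax = 1.5, p_ead_max = 0.7, p_dad_max = 0.4,
                         amp_drop_max = 0.5, p_silent_max = 0.9,
                         alternans_max = 0.2)
  doses <- c(0, 0.1, 1, 10, 100, 1000)
  e <- effect_at_dose(m, doses)
  expect_equal(e$apd_multiplier[1], 1)
  expect_true(all(diff(e$apd_multiplier) >= 0))
  expect_true(all(diff(e$p_ead) >= 0))
  expect_true(all(diff(e$p_dad) >= 0))
  expect_true(all(diff(e$p_silent) >= 0))
  expect_true(all(diff(e$amplitude_factor) <= 0))
  expect_true(all(e$p_ead >= 0 & e$p_ead <= 1))
  expect_true(all(e$amplitude_factor > 0 & e$amplitude_factor <= 1))
})

test_that("cohort generator respects the design and its quotas", {
  design <- dose_escalation_design("HCQ", 1, c(0, 1, 100), n_tissues = 5)
  eff <- drug_effect_model(p_ead_max = 0.6, p_ead_ec50_um = 10,
                           p_silent_max = 0)
  cohort <- simulate_cohort(design, eff, sim_config(seed = 21))
  # one trace per tissue x dose x modality
  expect_equal(nrow(cohort$traces), 5 * 3 * 4)
  # generated dose table matches the design exactly
  expect_identical(sort(unique(cohort$traces$dose_um)), design$doses$dose_um)
  # event quota: round(p_ead * n) tissues arrhythmic at each dose
  e <- effect_at_dose(eff, design$doses$effect_dose_um)
  quota <- round(e$p_ead * 5)
  got <- cohort$truth$conditions |>
    dplyr::group_by(.data$dose_index) |>
    dplyr::summarise(n_arr = sum(.data$n_ead_injected > 0), .groups = "drop")
  expect_equal(got$n_arr, quota)
  # ground-truth multiplier at dose 0 is 1 up to the per-tissue deviate
  m0 <- cohort$truth$conditions$apd_multiplier_true[
    cohort$truth$conditions$dose_index == 0]
  expect_equal(mean(m0), 1, tolerance = 0.05)
})

test_that("baseline APD draw matches the truncated-normal tail analytically", {
  withr::local_seed(31)
  draws <- cardiomps:::rtnorm(1000, 350, 60, 200, 600)
  expect_true(all(draws >= 200 & draws <= 600))
  # analytic exclusion probability under the 500 ms screen
  p_tail <- (pnorm(600, 350, 60) - pnorm(500, 350, 60)) /
    (pnorm(600, 350, 60) - pnorm(200, 350, 60))
  ci <- stats::binom.test(sum(draws >= 500), 1000, p_tail)$conf.int
  expect_true(p_tail >= ci[1] && p_tail <= ci[2])
})

test_that("simulated biomarker panels realize their intended retention", {
  for (seed in 1:5) {
    sim <- simulate_biomarker_panel(n_markers = 20, n_samples = 40,
                                    n_neg_controls = 6,
                                    detect_fractions = c(0, 0.3, 0.66, 0.8, 1),
                                    seed = seed)
    res <- lod_filter(sim$panel)
    # forced extremes always agree with intent
    forced <- sim$truth$intended_fraction %in% c(0, 1)
    expect_identical(res$retained[forced], sim$truth$intended_retained[forced])
    # overall agreement is near-perfect by construction
    expect_gte(mean(res$retained == sim$truth$intended_retained), 0.9)
  }
  expect_error(simulate_biomarker_panel(n_neg_controls = 1), "at least 2")
  expect_error(simulate_biomarker_panel(detect_fractions = 1.2), "\\[0, 1\\]")
})
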