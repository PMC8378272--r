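# Synthetic optical AP / calcium transient generator with known ground truth.
# Templates are analytic: a sigmoid upstroke followed by piecewise-linear
# repolarization through fixed control points, so APD30/APD80 of the
# noise-free template equal their targets exactly.

#' Beat template parameters
#'
#' @param channel `"voltage"` (fast dye upstroke) or `"calcium"` (slower
#'   indicator kinetics).
#' @param apd30_ms,apd80_ms Target APDs from the activation point, ms;
#'   `0 < apd30 <= apd80`.
#' @param amplitude Peak amplitude above baseline, normalized units.
#' @param upstroke_ms Upstroke duration; defaults 20 ms (voltage) / 80 ms
#'   (calcium); must be shorter than `apd30_ms`.
#' @return A list of class `beat_template_params`.
#' @export
beat_template_params <- function(channel = c("voltage", "calcium"),
                                 apd30_ms = 245, apd80_ms = 350,
                                 amplitude = 1, upstroke_ms = NULL) {
  channel <- match.arg(channel)
  if (is.null(upstroke_ms)) {
    upstroke_ms <- if (channel == "voltage") 20 else 80
  }
  if (apd30_ms <= 0 || apd30_ms > apd80_ms) {
    stop("need 0 < apd30_ms <= apd80_ms", call. = FALSE)
  }
  if (upstroke_ms >= apd30_ms) {
    stop("upstroke_ms must be shorter than apd30_ms", call. = FALSE)
  }
  if (amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
  structure(list(channel = channel, apd30_ms = apd30_ms, apd80_ms = apd80_ms,
                 amplitude = amplitude, upstroke_ms = upstroke_ms),
            class = "beat_template_params")
}

# analytic beat value at time-since-activation tau (s); vectorized over tau.
# Repolarization control points (from activation): (APD30, 0.7A), (APD80,
# 0.2A), then linear to 0 at APD80 + 0.5 (APD80 - APD30).
beat_value <- function(tau, params, apd_scale = 1, amp_scale = 1) {
  u <- params$upstroke_ms / 1000
  e30 <- params$apd30_ms / 1000 * apd_scale
  e80 <- params$apd80_ms / 1000 * apd_scale
  e_end <- e80 + 0.5 * (e80 - e30)
  A <- params$amplitude * amp_scale
  ts <- u / 10  # logistic time scale: rise occupies [-u/2, u/2]
  lo <- stats::plogis(-5)
  hi <- stats::plogis(5)
  v <- numeric(length(tau))
  in_up <- tau >= -u / 2 & tau <= u / 2
  v[in_up] <- A * (stats::plogis(tau[in_up] / ts) - lo) / (hi - lo)
  seg1 <- tau > u / 2 & tau <= e30
  v[seg1] <- A + (0.7 * A - A) * (tau[seg1] - u / 2) / (e30 - u / 2)
  seg2 <- tau > e30 & tau <= e80
  v[seg2] <- 0.7 * A + (0.2 * A - 0.7 * A) * (tau[seg2] - e30) / (e80 - e30)
  seg3 <- tau > e80 & tau <= e_end
  v[seg3] <- 0.2 * A * (1 - (tau[seg3] - e80) / (e_end - e80))
  v
}

beat_end_tau <- function(params, apd_scale = 1) {
  (params$apd80_ms + 0.5 * (params$apd80_ms - params$apd30_ms)) / 1000 *
    apd_scale
}

#' Sample a noise-free beat template
#'
#' @param params A [beat_template_params()].
#' @param fps Sampling rate, Hz.
#' @return A tibble `time_s`, `value` sampled from upstroke start to the end
#'   of repolarization, with attributes `activation_time_s`, `apd30_ms`,
#'   `apd80_ms`, `triangulation`.
#' @export
make_beat_template <- function(params, fps = 100) {
  t_act <- params$upstroke_ms / 2000
  t_end <- t_act + beat_end_tau(params)
  tt <- seq(0, t_end, by = 1 / fps)
  out <- tibble::tibble(time_s = tt, value = beat_value(tt - t_act, params))
  attr(out, "activation_time_s") <- t_act
  attr(out, "apd30_ms") <- params$apd30_ms
  attr(out, "apd80_ms") <- params$apd80_ms
  attr(out, "triangulation") <-
    (params$apd80_ms - params$apd30_ms) / params$apd80_ms
  out
}

#' Simulation configuration
#'
#' @param seed Integer RNG seed, or `NULL` to use the current RNG stream.
#' @param fps Sampling rate, Hz (default 100).
#' @param noise_sd Additive Gaussian noise SD, normalized units (default
#'   0.02).
#' @param bleach_rate Exponential photobleaching rate, 1/s (default 0.005;
#'   applied multiplicatively to baseline + signal).
#' @param baseline_f Resting fluorescence level, arbitrary units (default 1).
#' @param spontaneous_rate_hz,pacing_frequency_hz Beat rates for the two
#'   rhythms (defaults 1 Hz).
#' @param recording_lengths_s Nominal lengths, seconds.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, fps = 100, noise_sd = 0.02,
                       bleach_rate = 0.005, baseline_f = 1,
                       spontaneous_rate_hz = 1, pacing_frequency_hz = 1,
                       recording_lengths_s = c(6, 30)) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(seed = seed, fps = fps, noise_sd = noise_sd,
                 bleach_rate = bleach_rate, baseline_f = baseline_f,
                 spontaneous_rate_hz = spontaneous_rate_hz,
                 pacing_frequency_hz = pacing_frequency_hz,
                 recording_lengths_s = recording_lengths_s),
            class = "sim_config")
}

# EAD as a smooth local segment replacement during phase 3: approaching dip,
# cosine rise of exactly `h` above the entry value, cosine return to the
# repolarization track. Guarantees the min-to-max rise equals the requested
# fraction of the beat amplitude.
ead_segment <- function(tau, t1, t2, cc, v1, v2, h) {
  v <- numeric(length(tau))
  left <- tau >= t1 & tau <= cc
  v[left] <- v1 + h * (1 - cos(pi * (tau[left] - t1) / (cc - t1))) / 2
  right <- tau > cc & tau <= t2
  v[right] <- v2 + (v1 + h - v2) *
    (1 + cos(pi * (tau[right] - cc) / (t2 - cc))) / 2
  v
}

#' Simulate one fluorescence trace with ground truth
#'
#' Renders a beat train (spontaneous or paced rate from `config`), optionally
#' injects EADs (phase-3 depolarizing deflections of a stated relative
#' amplitude, default width 50 ms) and DADs (Gaussian diastolic bumps,
#' default width 100 ms), applies APD/amplitude alternans, multiplicative
#' exponential photobleaching and additive Gaussian noise.
#'
#' @param params A [beat_template_params()].
#' @param config A [sim_config()]; `config$seed`, when non-`NULL`, seeds the
#'   RNG.
#' @param rhythm `"spontaneous"` or `"paced"`.
#' @param events `NULL` or a data frame with columns `kind` ("EAD"/"DAD"),
#'   `beat_index`, `amplitude_fraction`, and optional `timing` in [0, 1]
#'   (position within the eligible window) and `width_s`.
#' @param length_s Recording length in seconds (default 30).
#' @param alternans_eps Beat-to-beat APD and amplitude alternation fraction
#'   in [0, 0.5) (default 0).
#' @param silent If `TRUE`, generate a beat-free noise-only trace.
#' @return A list: `trace` (an [fl_trace()]) and `truth` (list with `beats`
#'   and `events` tibbles).
#' @export
simulate_trace <- function(params, config = sim_config(),
                           rhythm = c("spontaneous", "paced"), events = NULL,
                           length_s = 30, alternans_eps = 0, silent = FALSE) {
  rhythm <- match.arg(rhythm)
  if (!is.null(config$seed)) set.seed(config$seed)
  fps <- config$fps
  n <- round(length_s * fps)
  t <- (seq_len(n) - 1) / fps
  if (alternans_eps < 0 || alternans_eps >= 0.5) {
    stop("alternans_eps must be in [0, 0.5)", call. = FALSE)
  }
  if (silent) {
    y <- config$baseline_f * exp(-config$bleach_rate * t) +
      stats::rnorm(n, 0, config$noise_sd)
    return(list(
      trace = fl_trace(y, fps, params$channel),
      truth = list(beats = tibble::tibble(beat_index = integer(),
                                          activation_time_s = numeric(),
                                          apd30_ms = numeric(),
                                          apd80_ms = numeric(),
                                          amplitude = numeric()),
                   events = empty_events())
    ))
  }
  rate <- if (rhythm == "paced") config$pacing_frequency_hz else
    config$spontaneous_rate_hz
  u <- params$upstroke_ms / 1000
  max_scale <- 1 + alternans_eps
  if (1 / rate < u / 2 + beat_end_tau(params, max_scale) + 0.02) {
    stop("beat rate too high for the requested APD: beats overlap",
         call. = FALSE)
  }
  acts <- seq(0.35, length_s - 0.01, by = 1 / rate)
  acts <- acts[acts + u / 2 <= t[n]]
  nb <- length(acts)
  sig <- numeric(n)
  gt_beats <- vector("list", nb)
  gt_events <- list()
  events <- if (is.null(events)) empty_sim_events() else
    tibble::as_tibble(events)
  if (!"timing" %in% names(events)) events$timing <- 0.5
  if (!"width_s" %in% names(events)) events$width_s <- NA_real_

  for (k in seq_len(nb)) {
    fac <- 1 + alternans_eps * if (k %% 2 == 1) 1 else -1
    tau <- t - acts[k]
    span <- tau >= -u / 2 & tau <= beat_end_tau(params, fac)
    v <- numeric(n)
    v[span] <- beat_value(tau[span], params, apd_scale = fac, amp_scale = fac)
    ev_k <- events[events$beat_index == k, , drop = FALSE]
    for (j in seq_len(nrow(ev_k))) {
      frac <- ev_k$amplitude_fraction[j]
      timing <- min(max(ev_k$timing[j], 0), 1)
      if (ev_k$kind[j] == "EAD") {
        w <- if (is.na(ev_k$width_s[j])) 0.05 else ev_k$width_s[j]
        e30 <- params$apd30_ms / 1000 * fac
        e80 <- params$apd80_ms / 1000 * fac
        avail <- (e80 - 0.005) - e30
        if (avail < w) w <- max(avail * 0.8, 0.02)
        t1 <- e30 + timing * (avail - w)
        t2 <- t1 + w
        cc <- (t1 + t2) / 2
        h <- frac * params$amplitude * fac
        v1 <- beat_value(t1, params, fac, fac)
        v2 <- beat_value(t2, params, fac, fac)
        inwin <- tau >= t1 & tau <= t2
        v[inwin] <- ead_segment(tau[inwin], t1, t2, cc, v1, v2, h)
        gt_events[[length(gt_events) + 1L]] <- tibble::tibble(
          kind = "EAD", time_s = acts[k] + cc, relative_amplitude = frac,
          beat_index = k)
      } else {
        w <- if (is.na(ev_k$width_s[j])) 0.10 else ev_k$width_s[j]
        sdv <- w / 2.355
        d_start <- beat_end_tau(params, fac) + 2.5 * sdv
        d_end <- (if (k < nb) acts[k + 1] - acts[k] else t[n] - acts[k]) -
          u / 2 - 2.5 * sdv
        if (d_end <= d_start) next
        cc <- d_start + timing * (d_end - d_start)
        h <- frac * params$amplitude * fac
        v <- v + h * exp(-(tau - cc)^2 / (2 * sdv^2))
        gt_events[[length(gt_events) + 1L]] <- tibble::tibble(
          kind = "DAD", time_s = acts[k] + cc, relative_amplitude = frac,
          beat_index = k)
      }
    }
    sig <- sig + v
    gt_beats[[k]] <- tibble::tibble(
      beat_index = k, activation_time_s = acts[k],
      apd30_ms = params$apd30_ms * fac, apd80_ms = params$apd80_ms * fac,
      amplitude = params$amplitude * fac)
  }
  y <- (config$baseline_f + sig) * exp(-config$bleach_rate * t) +
    stats::rnorm(n, 0, config$noise_sd)
  list(
    trace = fl_trace(y, fps, params$channel),
    truth = list(
      beats = dplyr::bind_rows(gt_beats),
      events = if (length(gt_events) == 0) empty_events() else
        dplyr::bind_rows(gt_events)
    )
  )
}

empty_sim_events <- function() {
  tibble::tibble(kind = character(), beat_index = integer(),
                 amplitude_fraction = numeric(), timing = numeric(),
                 width_s = numeric())
}

#' Phenomenological drug effect model
#'
#' Dose-response model used by the cohort generator: a Hill multiplier on
#' APD80, an additive Hill shift on triangulation, logistic (in log dose)
#' probabilities of EADs, DADs and beating cessation, a Hill amplitude
#' suppression and a Hill alternans fraction. All components are monotone in
#' dose; at dose 0 every effect is null.
#'
#' @param apd_emax Maximal APD80 multiplier (default 1.4).
#' @param apd_ec50_um,apd_hill Hill parameters of the APD effect.
#' @param tri_shift_max,tri_ec50_um,tri_hill Maximal additive triangulation
#'   shift and its Hill parameters.
#' @param p_ead_max,p_ead_ec50_um,p_ead_hill Plateau, midpoint and slope of
#'   the EAD probability.
#' @param p_dad_max,p_dad_ec50_um,p_dad_hill Same for DADs.
#' @param amp_drop_max,amp_ec50_um,amp_hill Maximal fractional amplitude loss
#'   and its Hill parameters.
#' @param p_silent_max,p_silent_ec50_um,p_silent_hill Beating-cessation
#'   probability.
#' @param alternans_max,alternans_ec50_um,alternans_hill Alternans fraction.
#' @return A list of class `drug_effect_model`.
#' @export
drug_effect_model <- function(apd_emax = 1.4, apd_ec50_um = 1, apd_hill = 1,
                              tri_shift_max = 0.15, tri_ec50_um = 10,
                              tri_hill = 2,
                              p_ead_max = 0.8, p_ead_ec50_um = 30,
                              p_ead_hill = 2,
                              p_dad_max = 0, p_dad_ec50_um = 10,
                              p_dad_hill = 2,
                              amp_drop_max = 0.3, amp_ec50_um = 100,
                              amp_hill = 2,
                              p_silent_max = 0.8, p_silent_ec50_um = 500,
                              p_silent_hill = 2,
                              alternans_max = 0, alternans_ec50_um = 10,
                              alternans_hill = 2) {
  structure(as.list(environment()), class = "drug_effect_model")
}

hill01 <- function(dose, ec50, h = 2) {
  ifelse(dose <= 0, 0, dose^h / (ec50^h + dose^h))
}

#' Reference phenomenological effect models
#'
#' Illustrative dose-response models for the two reference compounds, used
#' by the validation studies. The HCQ-like model prolongs APD80 with a Hill
#' effect (EC50 at the clinical Cmax of 1 uM, maximal multiplier 1.4),
#' raises the EAD probability monotonically across the ladder (shallow Hill
#' slope, so incidence climbs dose by dose), suppresses amplitude at very
#' high dose and silences most tissues at the top (1 mM) rung. The AZM-like
#' model leaves APD80 essentially unchanged while raising DAD incidence and
#' beat-to-beat instability -- arrhythmia without QT-proxy prolongation.
#'
#' @param which `"HCQ"` or `"AZM"`.
#' @return A [drug_effect_model()].
#' @export
reference_effect_model <- function(which = c("HCQ", "AZM")) {
  which <- match.arg(which)
  switch(which,
    "HCQ" = drug_effect_model(
      apd_emax = 1.4, apd_ec50_um = 1, apd_hill = 1,
      tri_shift_max = 0.15, tri_ec50_um = 10,
      p_ead_max = 1, p_ead_ec50_um = 2, p_ead_hill = 0.8,
      p_dad_max = 0,
      amp_drop_max = 0.3, amp_ec50_um = 300,
      p_silent_max = 0.8, p_silent_ec50_um = 400, p_silent_hill = 3),
    "AZM" = drug_effect_model(
      apd_emax = 1.0,
      tri_shift_max = 0.12, tri_ec50_um = 4,
      p_ead_max = 0, p_dad_max = 0.9, p_dad_ec50_um = 3, p_dad_hill = 0.9,
      amp_drop_max = 0.3, amp_ec50_um = 40,
      p_silent_max = 0.9, p_silent_ec50_um = 50, p_silent_hill = 3,
      alternans_max = 0.12, alternans_ec50_um = 4)
  )
}

#' @rdname drug_effect_model
#' @param model A `drug_effect_model`.
#' @param dose_um Dose(s) in micromolar.
#' @return `effect_at_dose()`: a tibble of realized effect components per
#'   dose.
#' @export
effect_at_dose <- function(model, dose_um) {
  tibble::tibble(
    dose_um = dose_um,
    apd_multiplier = 1 + (model$apd_emax - 1) *
      hill01(dose_um, model$apd_ec50_um, model$apd_hill),
    tri_shift = model$tri_shift_max *
      hill01(dose_um, model$tri_ec50_um, model$tri_hill),
    p_ead = model$p_ead_max *
      hill01(dose_um, model$p_ead_ec50_um, model$p_ead_hill),
    p_dad = model$p_dad_max *
      hill01(dose_um, model$p_dad_ec50_um, model$p_dad_hill),
    amplitude_factor = 1 - model$amp_drop_max *
      hill01(dose_um, model$amp_ec50_um, model$amp_hill),
    p_silent = model$p_silent_max *
      hill01(dose_um, model$p_silent_ec50_um, model$p_silent_hill),
    alternans_eps = model$alternans_max *
      hill01(dose_um, model$alternans_ec50_um, model$alternans_hill)
  )
}

# truncated-normal draws via inverse-CDF (deterministic under set.seed)
rtnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Simulate a dose-escalation cohort with ground truth
#'
#' Emulates the acute dose-escalation protocol: `n_tissues` tissues per drug
#' housed in 4-plex chips, each recorded at every rung of the dose ladder in
#' four modalities (paced and spontaneous 6-s voltage, paced 6-s calcium,
#' spontaneous 30-s calcium -- events are injected into the latter, the
#' classification substrate). Tissue baselines are drawn per tissue: APD80
#' from Normal(350, 60) truncated to [200, 600] ms (so some tissues violate
#' the 500 ms inclusion screen), triangulation from U(0.27, 0.33), amplitude
#' from U(0.9, 1.1), spontaneous rate from U(0.85, 1.05) Hz. Per dose, the
#' effect model sets the APD multiplier (with a per-tissue-dose lognormal
#' deviate, SD `apd_sigma`), triangulation shift, amplitude factor and
#' alternans; arrhythmia and silencing incidences are realized by quota --
#' exactly `round(p * n)` tissues receive the condition, identities
#' randomized -- so the designed incidence curve is reproduced exactly in
#' every cohort.
#'
#' @param design A [dose_escalation_design()].
#' @param effects A [drug_effect_model()].
#' @param config A [sim_config()]; `config$seed` (default 1) drives
#'   everything; per-trace substreams are derived from it.
#' @param apd_sigma SD of the per-tissue-dose log-APD deviate (default 0.03).
#' @param events_per_arrhythmic Number of afterdepolarizations injected into
#'   the 30-s classification trace of each quota-selected tissue (default 3).
#' @return A list: `traces` (a [trace_set()]), `truth` (list of `tissues` and
#'   `conditions` tibbles), `design`, `config`.
#' @export
simulate_cohort <- function(design, effects = drug_effect_model(),
                            config = sim_config(seed = 1), apd_sigma = 0.03,
                            events_per_arrhythmic = 3) {
  stopifnot(inherits(design, "dose_escalation_design"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  nt <- design$n_tissues
  doses <- design$doses
  tissues <- tibble::tibble(
    tissue_id = sprintf("T%02d", seq_len(nt)),
    chip_id = sprintf("chip%02d", (seq_len(nt) - 1) %/%
                        design$chambers_per_chip + 1),
    chamber_index = (seq_len(nt) - 1) %% design$chambers_per_chip + 1L,
    baseline_apd80_ms = rtnorm(nt, 350, 60, 200, 600),
    baseline_triangulation = stats::runif(nt, 0.27, 0.33),
    baseline_amplitude = stats::runif(nt, 0.9, 1.1),
    spontaneous_rate_hz = stats::runif(nt, 0.85, 1.05)
  )
  tissues$included_truth <- tissues$baseline_apd80_ms < 500

  eff <- effect_at_dose(effects, doses$effect_dose_um)
  cond_rows <- list()
  trace_rows <- list()
  for (j in seq_len(nrow(doses))) {
    e <- eff[j, ]
    n_ead_tissues <- round(e$p_ead * nt)
    n_dad_tissues <- round(e$p_dad * nt)
    n_silent <- round(e$p_silent * nt)
    ord <- sample(nt)  # quota identities randomized, counts exact
    silent_ids <- ord[seq_len(n_silent)]
    rest <- setdiff(ord, silent_ids)
    ead_ids <- rest[seq_len(min(n_ead_tissues, length(rest)))]
    rest2 <- setdiff(rest, ead_ids)
    dad_ids <- rest2[seq_len(min(n_dad_tissues, length(rest2)))]
    for (i in seq_len(nt)) {
      mult <- e$apd_multiplier * exp(stats::rnorm(1, 0, apd_sigma))
      apd80 <- tissues$baseline_apd80_ms[i] * mult
      tri <- min(tissues$baseline_triangulation[i] + e$tri_shift, 0.8)
      apd30 <- apd80 * (1 - tri)
      amp <- tissues$baseline_amplitude[i] * e$amplitude_factor
      silent <- i %in% silent_ids
      n_ead <- if (i %in% ead_ids) events_per_arrhythmic else 0L
      n_dad <- if (i %in% dad_ids) events_per_arrhythmic else 0L
      eps <- e$alternans_eps
      category <- if (silent || e$amplitude_factor < 0.6) {
        "weak_or_silent"
      } else if (n_ead + n_dad > 0) {
        "arrhythmic"
      } else {
        "normal"
      }
      cond_rows[[length(cond_rows) + 1L]] <- tibble::tibble(
        tissue_id = tissues$tissue_id[i], dose_index = doses$dose_index[j],
        dose_um = doses$dose_um[j], apd_multiplier_true = mult,
        apd80_target_ms = apd80, triangulation_target = tri,
        amplitude_factor = e$amplitude_factor, alternans_eps = eps,
        n_ead_injected = n_ead, n_dad_injected = n_dad, silent = silent,
        category_truth = category
      )
      specs <- list(
        list(channel = "voltage", rhythm = "paced", len = 6),
        list(channel = "voltage", rhythm = "spontaneous", len = 6),
        list(channel = "calcium", rhythm = "paced", len = 6),
        list(channel = "calcium", rhythm = "spontaneous", len = 30)
      )
      for (sp in specs) {
        sub_seed <- (seed + 97L * i + 1009L * j +
                       13L * (sp$channel == "calcium") +
                       29L * (sp$rhythm == "paced") +
                       7L * sp$len) %% 2147483629L
        cfg <- config
        cfg$seed <- sub_seed
        cfg$spontaneous_rate_hz <- tissues$spontaneous_rate_hz[i]
        cfg$pacing_frequency_hz <- design$pacing_frequency_hz
        par <- beat_template_params(
          channel = sp$channel, apd30_ms = apd30, apd80_ms = apd80,
          amplitude = amp,
          upstroke_ms = min(if (sp$channel == "voltage") 20 else 80,
                            0.8 * apd30))
        ev <- NULL
        if (sp$channel == "calcium" && sp$rhythm == "spontaneous" &&
            sp$len == 30 && (n_ead + n_dad) > 0 && !silent) {
          nb_approx <- floor((30 - 0.7) * cfg$spontaneous_rate_hz)
          bi <- unique(round(seq(3, max(4, nb_approx - 2),
                                 length.out = n_ead + n_dad)))
          ev <- tibble::tibble(
            kind = c(rep("EAD", n_ead), rep("DAD", n_dad))[seq_along(bi)],
            beat_index = bi,
            amplitude_fraction = stats::runif(length(bi), 0.15, 0.30),
            timing = stats::runif(length(bi), 0.3, 0.7)
          )
        }
        sim <- simulate_trace(
          par, cfg, rhythm = sp$rhythm, events = ev, length_s = sp$len,
          alternans_eps = if (sp$rhythm == "spontaneous") eps else 0,
          silent = silent)
        meta <- recording_meta(
          tissue_id = tissues$tissue_id[i], chip_id = tissues$chip_id[i],
          chamber_index = tissues$chamber_index[i], drug = design$drug,
          dose_um = doses$dose_um[j], dose_index = doses$dose_index[j],
          rhythm = sp$rhythm,
          pacing_frequency_hz = if (sp$rhythm == "paced")
            design$pacing_frequency_hz else NA_real_,
          recording_length_s = sp$len)
        trace_rows[[length(trace_rows) + 1L]] <- dplyr::mutate(
          meta, channel = sp$channel, trace = list(sim$trace),
          truth = list(sim$truth))
      }
    }
  }
  list(
    traces = trace_set(dplyr::bind_rows(trace_rows)),
    truth = list(tissues = tissues, conditions = dplyr::bind_rows(cond_rows)),
    design = design, config = config
  )
}

#' Simulate a biomarker panel with known intended retention
#'
#' Negative controls are drawn from marker-specific normals; study samples
#' are placed above or below the marker's population detection limit
#' (`mu + 3 sigma`) with a safety margin, the number detected fixed at
#' `round(fraction * n_samples)` so the realized detection fraction matches
#' the request up to LOD sampling noise.
#'
#' @param n_markers,n_samples,n_neg_controls Panel dimensions.
#' @param detect_fractions Numeric vector (recycled to `n_markers`) of
#'   intended detection fractions in [0, 1].
#' @param seed RNG seed.
#' @return A list: `panel` (a [biomarker_panel()]) and `truth` (tibble with
#'   per-marker intended fraction and intended retention under the >65%
#'   rule).
#' @export
simulate_biomarker_panel <- function(n_markers = 92, n_samples = 40,
                                     n_neg_controls = 8,
                                     detect_fractions = 0.8, seed = 1) {
  if (n_neg_controls < 2) {
    stop("need at least 2 negative controls", call. = FALSE)
  }
  if (any(detect_fractions < 0 | detect_fractions > 1)) {
    stop("detect_fractions must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  frac <- rep_len(detect_fractions, n_markers)
  markers <- sprintf("M%03d", seq_len(n_markers))
  mu <- stats::runif(n_markers, 2, 6)
  sigma <- stats::runif(n_markers, 0.1, 0.5)
  neg <- matrix(stats::rnorm(n_markers * n_neg_controls, mu, sigma),
                nrow = n_markers,
                dimnames = list(markers,
                                sprintf("NC%02d", seq_len(n_neg_controls))))
  vals <- matrix(NA_real_, n_markers, n_samples,
                 dimnames = list(markers, sprintf("S%03d", seq_len(n_samples))))
  for (m in seq_len(n_markers)) {
    lod_pop <- mu[m] + 3 * sigma[m]
    n_det <- round(frac[m] * n_samples)
    det <- sample(n_samples, n_det)
    und <- setdiff(seq_len(n_samples), det)
    vals[m, det] <- lod_pop +
      (1.5 + abs(stats::rnorm(n_det))) * sigma[m]
    vals[m, und] <- lod_pop -
      (1.5 + abs(stats::rnorm(length(und)))) * sigma[m]
  }
  list(
    panel = biomarker_panel(vals, neg),
    truth = tibble::tibble(marker = markers, intended_fraction = frac,
                           intended_retained =
                             round(frac * n_samples) / n_samples > 0.65)
  )
}
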