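# Dose-escalation orchestration: per-recording analysis, metric routing,
# inclusion filtering, baseline normalization, statistics, incidence.

#' Analysis configuration for a dose-escalation study
#'
#' Every tunable threshold of the pipeline in one place. Defaults follow the
#' package conventions: prominence 0.3 of range, 200 ms refractory, 5%
#' capture tolerance, linear detrend for voltage dyes and exponential for
#' GCaMP, and the [call_thresholds()] classification rules. APD metrics are
#' routed from paced recordings when capture passes (RR taken as the pacing
#' period), otherwise from spontaneous recordings; triangulation, beat rate
#' and instability always come from spontaneous recordings.
#'
#' @param min_prominence,refractory_ms See [segment_beats()].
#' @param capture_tol See [capture_check()].
#' @param detrend_window_s See [detrend()].
#' @param thresholds A [call_thresholds()] list.
#' @param apd_from `"paced_captured"` (default) or `"spontaneous"`.
#' @return A list of class `study_config`.
#' @export
study_config <- function(min_prominence = 0.3, refractory_ms = 200,
                         capture_tol = 0.05, detrend_window_s = 2,
                         thresholds = call_thresholds(),
                         apd_from = c("paced_captured", "spontaneous")) {
  structure(list(min_prominence = min_prominence,
                 refractory_ms = refractory_ms, capture_tol = capture_tol,
                 detrend_window_s = detrend_window_s, thresholds = thresholds,
                 apd_from = match.arg(apd_from)),
            class = "study_config")
}

# detrend + normalize with the channel-appropriate drift model
prep_trace <- function(trace, window_s = 2) {
  method <- if (trace_channel(trace) == "calcium") "exponential" else "linear"
  dt <- detrend(trace, method = method, window_s = min(window_s,
                                                       trace_duration(trace) * 0.45))
  rng <- range(dt$fluorescence)
  if (diff(rng) <= .Machine$double.eps) return(dt)  # flat: leave as is
  normalize(dt)
}

#' Analyze every recording of a trace set
#'
#' Detrends, normalizes and segments each recording and summarizes it: median
#' APDs over resolved beats, per-beat triangulation median, beat rate,
#' capture status for paced recordings, median maximum upstroke velocity, and
#' the maximum beat amplitude measured on the detrended (un-normalized)
#' trace scale for the weak-signal rule.
#'
#' @param traces A [trace_set()].
#' @param config A [study_config()].
#' @return A tibble with one row per recording plus `series` and `prepped`
#'   list-columns.
#' @export
analyze_recordings <- function(traces, config = study_config()) {
  traces <- trace_set(traces)
  rows <- purrr::map(seq_len(nrow(traces)), function(i) {
    tr <- traces$trace[[i]]
    method <- if (traces$channel[i] == "calcium") "exponential" else "linear"
    dt <- detrend(tr, method = method,
                  window_s = min(config$detrend_window_s,
                                 trace_duration(tr) * 0.45))
    rng <- diff(range(dt$fluorescence))
    prepped <- if (rng > .Machine$double.eps) normalize(dt) else dt
    series <- segment_beats(prepped, config$min_prominence,
                            config$refractory_ms)
    resolved <- series[series$apd_resolved, , drop = FALSE]
    med <- function(v) if (length(v) == 0) NA_real_ else
      stats::median(v, na.rm = TRUE)
    tri <- if (nrow(resolved) > 0) {
      ok <- is.finite(resolved$apd30_ms) & is.finite(resolved$apd80_ms) &
        resolved$apd30_ms > 0
      if (any(ok)) med(triangulation(resolved$apd30_ms[ok],
                                     resolved$apd80_ms[ok])) else NA_real_
    } else NA_real_
    captured <- if (traces$rhythm[i] == "paced") {
      capture_check(series, traces$pacing_frequency_hz[i], config$capture_tol)
    } else NA
    # beat amplitude on the detrended raw scale (weak-signal rule compares
    # absolute signal strength, not the [0,1]-rescaled one)
    amp_raw <- if (nrow(series) > 0 && rng > .Machine$double.eps) {
      max(series$amplitude) * rng
    } else 0
    tibble::tibble(
      traces[i, c(meta_fields, "channel")],
      n_beats = nrow(series),
      beat_rate_hz = beat_rate(series),
      apd30_ms = med(resolved$apd30_ms), apd50_ms = med(resolved$apd50_ms),
      apd80_ms = med(resolved$apd80_ms), apd90_ms = med(resolved$apd90_ms),
      triangulation = tri,
      max_upstroke = med(series$max_upstroke),
      max_beat_amplitude = amp_raw,
      rr_median_s = if (nrow(series) >= 2)
        stats::median(rr_intervals(series)) else NA_real_,
      captured = captured,
      series = list(series), prepped = list(prepped)
    )
  })
  dplyr::bind_rows(rows)
}

pick_row <- function(df, ...) {
  out <- dplyr::filter(df, ...)
  if (nrow(out) == 0) NULL else out[1, ]
}

#' Per-tissue per-dose metric and classification table
#'
#' Routes recordings to metrics the way the acquisition protocol intends:
#' APD80 (raw and Fridericia-corrected) and upstroke velocities from the
#' paced 6-s recordings when pacing capture passes (RR = pacing period),
#' falling back to spontaneous recordings otherwise; triangulation and beat
#' rate from spontaneous recordings; classification (and instability) from
#' the 30-s spontaneous calcium recording against the same tissue's dose-0
#' control amplitude.
#'
#' @param traces A [trace_set()].
#' @param config A [study_config()].
#' @return A list with `metrics` (tissue x dose tibble), `calls` (tissue x
#'   dose classification tibble), `events` (all detected events) and
#'   `recordings` (the [analyze_recordings()] table without list-columns).
#' @export
analyze_traces <- function(traces, config = study_config()) {
  rec <- analyze_recordings(traces, config)
  combos <- dplyr::distinct(rec, .data$tissue_id, .data$dose_index,
                            .data$dose_um, .data$drug)
  controls <- rec |>
    dplyr::filter(.data$dose_index == 0, .data$channel == "calcium",
                  .data$rhythm == "spontaneous") |>
    dplyr::group_by(.data$tissue_id) |>
    dplyr::slice_max(.data$recording_length_s, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("tissue_id", control_amplitude = "max_beat_amplitude")

  met_rows <- list()
  call_rows <- list()
  ev_rows <- list()
  for (i in seq_len(nrow(combos))) {
    tid <- combos$tissue_id[i]; dj <- combos$dose_index[i]
    sub <- rec[rec$tissue_id == tid & rec$dose_index == dj, ]
    vp <- pick_row(sub, .data$channel == "voltage", .data$rhythm == "paced")
    vs <- pick_row(sub, .data$channel == "voltage",
                   .data$rhythm == "spontaneous")
    cp <- pick_row(sub, .data$channel == "calcium", .data$rhythm == "paced")
    cs <- sub |>
      dplyr::filter(.data$channel == "calcium",
                    .data$rhythm == "spontaneous") |>
      dplyr::slice_max(.data$recording_length_s, n = 1, with_ties = FALSE)
    if (nrow(cs) == 0) cs <- NULL
    use_paced <- config$apd_from == "paced_captured" && !is.null(vp) &&
      isTRUE(vp$captured)
    apd_src <- if (use_paced) vp else vs
    rr <- if (use_paced) 1 / vp$pacing_frequency_hz else
      if (!is.null(vs)) vs$rr_median_s else NA_real_
    apd80 <- if (!is.null(apd_src)) apd_src$apd80_ms else NA_real_
    apd80c <- if (!is.na(apd80) && !is.na(rr) && rr > 0)
      fridericia_correct(apd80, rr) else NA_real_

    # classification against the dose-0 control amplitude; the control is on
    # the raw detrended scale, the segmented amplitudes on the [0,1] scale,
    # so rescale the control into the recording's normalized units
    ctrl <- controls$control_amplitude[controls$tissue_id == tid]
    call <- if (!is.null(cs) && length(ctrl) == 1 && ctrl > 0) {
      series <- cs$series[[1]]
      ctrl_scaled <- if (cs$n_beats > 0 && cs$max_beat_amplitude > 0) {
        ctrl * max(series$amplitude) / cs$max_beat_amplitude
      } else {
        ctrl
      }
      classify_tissue(cs$prepped[[1]], series, ctrl_scaled,
                      config$thresholds) |>
        dplyr::mutate(tissue_id = tid, dose_index = dj,
                      dose_um = combos$dose_um[i], .before = 1)
    } else {
      NULL
    }
    if (!is.null(call)) {
      ev <- call$events[[1]]
      if (nrow(ev) > 0) {
        ev_rows[[length(ev_rows) + 1L]] <- dplyr::mutate(
          ev, tissue_id = tid, dose_index = dj, .before = 1)
      }
      call_rows[[length(call_rows) + 1L]] <- dplyr::select(call, -"events")
    }
    met_rows[[length(met_rows) + 1L]] <- tibble::tibble(
      tissue_id = tid, dose_index = dj, dose_um = combos$dose_um[i],
      drug = combos$drug[i],
      apd80_ms = apd80, rr_s = rr, apd80c_ms = apd80c,
      apd_source = if (use_paced) "paced" else "spontaneous",
      triangulation = if (!is.null(vs)) vs$triangulation else NA_real_,
      beat_rate_hz = if (!is.null(cs)) cs$beat_rate_hz else NA_real_,
      v_max_upstroke = if (!is.null(vp)) vp$max_upstroke else
        if (!is.null(vs)) vs$max_upstroke else NA_real_,
      ca_max_upstroke = if (!is.null(cp)) cp$max_upstroke else NA_real_,
      instability_index = if (!is.null(call)) call$instability_index else
        NA_real_,
      instability_flag = if (!is.null(call)) call$instability_flag else NA,
      category = if (!is.null(call)) call$category else NA_character_
    )
  }
  list(
    metrics = dplyr::arrange(dplyr::bind_rows(met_rows), .data$tissue_id,
                             .data$dose_index),
    calls = dplyr::bind_rows(call_rows),
    events = if (length(ev_rows) == 0) empty_events() else
      dplyr::bind_rows(ev_rows),
    recordings = dplyr::select(rec, -"series", -"prepped")
  )
}

#' Baseline APD inclusion screen
#'
#' Tissues whose baseline (dose 0) APD80 is 500 ms or more are excluded from
#' the study -- mirroring the clinical torsades risk threshold of QT > 500 ms
#' -- as are tissues with no measurable baseline APD. The inequality is
#' strict: exactly 500.0 ms is excluded.
#'
#' @param baseline_metrics A data frame with `tissue_id` and the dose-0
#'   `apd80_ms` per tissue (e.g. the dose-0 rows of
#'   [analyze_traces()]`$metrics`).
#' @param limit_ms Threshold in ms (default 500).
#' @return A tibble: `tissue_id`, `baseline_apd80_ms`, `included`, `reason`.
#' @export
inclusion_filter <- function(baseline_metrics, limit_ms = 500) {
  bm <- tibble::as_tibble(baseline_metrics)
  if (!all(c("tissue_id", "apd80_ms") %in% names(bm))) {
    stop("need columns tissue_id and apd80_ms", call. = FALSE)
  }
  bm |>
    dplyr::transmute(
      tissue_id = .data$tissue_id,
      baseline_apd80_ms = .data$apd80_ms,
      included = !is.na(.data$apd80_ms) & .data$apd80_ms < limit_ms,
      reason = dplyr::case_when(
        is.na(.data$apd80_ms) ~ "no measurable baseline APD80",
        .data$apd80_ms >= limit_ms ~
          sprintf("baseline APD80 %.0f ms >= %g ms", .data$apd80_ms,
                  limit_ms),
        TRUE ~ "included"
      )
    )
}

#' Normalize metrics to each tissue's dose-0 baseline
#'
#' Divides each tissue's per-dose values by its own dose-0 value, so dose 0
#' maps to exactly 1 for every tissue.
#'
#' @param metrics A tissue x dose data frame with `tissue_id`, `dose_index`
#'   and the metric columns.
#' @param cols Character vector of metric columns to normalize (default
#'   `"apd80_ms"` and `"apd80c_ms"`); normalized columns get a `_norm`
#'   suffix (with any `_ms` dropped).
#' @return The input tibble with normalized columns appended.
#' @export
normalize_to_baseline <- function(metrics,
                                  cols = c("apd80_ms", "apd80c_ms")) {
  metrics <- tibble::as_tibble(metrics)
  if (!all(c("tissue_id", "dose_index") %in% names(metrics))) {
    stop("need tissue_id and dose_index columns", call. = FALSE)
  }
  base <- dplyr::filter(metrics, .data$dose_index == 0)
  no_base <- setdiff(unique(metrics$tissue_id), unique(base$tissue_id))
  if (length(no_base) > 0) {
    stop("missing dose-0 baseline for tissue(s): ",
         paste(no_base, collapse = ", "), call. = FALSE)
  }
  for (col in cols) {
    if (!col %in% names(metrics)) next
    b <- stats::setNames(base[[col]], base$tissue_id)
    if (any(!is.na(b) & b == 0)) {
      stop("zero baseline value in column ", col, call. = FALSE)
    }
    newcol <- paste0(sub("_ms$", "", col), "_norm")
    metrics[[newcol]] <- metrics[[col]] / unname(b[metrics$tissue_id])
  }
  metrics
}

#' Run a full dose-escalation analysis
#'
#' Composes the pipeline: coverage check (a dose-0 recording must exist for
#' every tissue), per-recording beat analysis, per-tissue classification,
#' the baseline APD80 < 500 ms inclusion screen, baseline normalization,
#' Dunnett many-to-one statistics on the normalized APD80 (doses whose
#' group has fewer than 2 measurable values -- toxic or silent rungs -- are
#' excluded from the model and listed with a reason rather than imputed),
#' per-dose incidence, pairwise chi-squared tests on arrhythmic incidence,
#' and, when a panel is supplied, the biomarker LOD filter.
#'
#' @param design A [dose_escalation_design()].
#' @param traces A [trace_set()] covering the design.
#' @param panel Optional [biomarker_panel()].
#' @param config A [study_config()].
#' @return An object of class `study_report`: a list of tibbles (`metrics`,
#'   `calls`, `events`, `inclusion`, `incidence`, `dunnett`, `chisq`,
#'   `excluded_doses`, `biomarkers`) plus the design and config echo.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
run_study <- function(design, traces, panel = NULL,
                      config = study_config()) {
  stopifnot(inherits(design, "dose_escalation_design"))
  traces <- trace_set(traces)
  have0 <- unique(traces$tissue_id[traces$dose_index == 0])
  all_t <- unique(traces$tissue_id)
  missing0 <- setdiff(all_t, have0)
  if (length(missing0) > 0) {
    stop("missing dose-0 recording for tissue(s): ",
         paste(missing0, collapse = ", "), call. = FALSE)
  }
  an <- analyze_traces(traces, config)
  inc <- inclusion_filter(dplyr::filter(an$metrics, .data$dose_index == 0))
  included <- inc$tissue_id[inc$included]
  metrics <- an$metrics |>
    dplyr::filter(.data$tissue_id %in% included) |>
    normalize_to_baseline()
  calls <- dplyr::filter(an$calls, .data$tissue_id %in% included)

  grp <- metrics |>
    dplyr::group_by(.data$dose_index) |>
    dplyr::summarise(n_finite = sum(is.finite(.data$apd80_norm)),
                     .groups = "drop")
  usable <- grp$dose_index[grp$n_finite >= 2]
  excluded_doses <- grp |>
    dplyr::filter(.data$n_finite < 2) |>
    dplyr::mutate(reason = "fewer than 2 measurable APD80 values (weak or silent signal)")
  dunnett <- if (length(usable) >= 2 && 0 %in% usable) {
    anova_dunnett(
      dplyr::filter(metrics, .data$dose_index %in% usable,
                    is.finite(.data$apd80_norm)),
      value = "apd80_norm", group = "dose_index", reference = 0)
  } else {
    NULL
  }
  incidence <- if (nrow(calls) > 0) cohort_incidence(calls) else NULL
  chisq <- if (nrow(calls) > 0 &&
                 dplyr::n_distinct(calls$dose_index) >= 2) {
    chi_square_pairwise(calls)
  } else {
    NULL
  }
  biomarkers <- if (!is.null(panel)) lod_filter(panel) else NULL
  out <- list(metrics = metrics, calls = calls, events = an$events,
              recordings = an$recordings, inclusion = inc,
              incidence = incidence, dunnett = dunnett, chisq = chisq,
              excluded_doses = excluded_doses, biomarkers = biomarkers,
              design = design, config = config)
  class(out) <- "study_report"
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %s, %d/%d tissues included\n",
              x$design$drug, sum(x$inclusion$included), nrow(x$inclusion)))
  if (!is.null(x$dunnett)) {
    cat(sprintf("ANOVA F(%d, %d) = %.2f, p = %.3g\n", x$dunnett$df[1],
                x$dunnett$df[2], x$dunnett$f_statistic, x$dunnett$p_anova))
  }
  if (!is.null(x$incidence)) {
    arr <- dplyr::filter(x$incidence, .data$category == "arrhythmic")
    cat("arrhythmic incidence (%):",
        paste(sprintf("%.0f", arr$pct), collapse = " "), "\n")
  }
  invisible(x)
}
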