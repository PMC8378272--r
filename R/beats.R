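# Per-beat electrophysiology: detrending, normalization, beat segmentation,
# APD fractions, upstroke velocity, Fridericia correction, triangulation,
# pacing-capture check.

# Savitzky-Golay smoothing used consistently by segmentation, APD crossing
# location and event detection; preserves bump heights at 100 Hz while
# suppressing shot/read noise.
sg_smooth <- function(x, n = 11L, p = 3L) {
  n <- min(n, if (length(x) %% 2 == 0) length(x) - 1 else length(x))
  if (n %% 2 == 0) n <- n - 1
  if (n < p + 2) return(x)
  as.numeric(signal::sgolayfilt(x, p = p, n = n))
}

# peak prominence relative to the higher of the two flanking key saddles
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    i <- p
    lmin <- x[p]
    while (i > 1 && x[i - 1] <= x[p]) {
      i <- i - 1
      if (x[i] < lmin) lmin <- x[i]
    }
    i <- p
    rmin <- x[p]
    n <- length(x)
    while (i < n && x[i + 1] <= x[p]) {
      i <- i + 1
      if (x[i] < rmin) rmin <- x[i]
    }
    x[p] - max(lmin, rmin)
  }, numeric(1))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Remove slow photobleaching drift from a trace
#'
#' Fits a monotone drift model to the rolling lower envelope (the 5th
#' percentile of consecutive `window_s`-second windows, each point anchored at
#' the time of the sample realizing it) and subtracts the fitted drift,
#' preserving the signal value at the start of the recording. `"linear"` suits
#' voltage-dye recordings; `"exponential"` suits GCaMP bleaching.
#'
#' @param trace An [fl_trace()].
#' @param method `"linear"` or `"exponential"`.
#' @param window_s Envelope window length in seconds (default 2).
#' @return A detrended [fl_trace()] of the same length and rate.
#' @export
detrend <- function(trace, method = c("linear", "exponential"), window_s = 2) {
  assert_trace(trace)
  method <- match.arg(method)
  dur <- trace_duration(trace)
  if (window_s >= dur) {
    stop("window_s (", window_s, " s) must be shorter than the trace (",
         dur, " s)", call. = FALSE)
  }
  x <- trace$fluorescence
  t <- trace$time_s
  fs <- trace_rate(trace)
  # at least 4 envelope points: a drift fit through fewer anchors is
  # dominated by where within each window the quantile happens to sit
  w <- max(2L, round(min(window_s, dur / 4) * fs))
  starts <- seq(1L, length(x) - w + 1L, by = w)
  env_t <- env_v <- numeric(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + w - 1L)
    q <- stats::quantile(x[idx], 0.05, names = FALSE, type = 7)
    at <- idx[which.min(abs(x[idx] - q))]
    env_t[k] <- t[at]
    env_v[k] <- q
  }
  if (length(env_v) < 2) {
    stop("window_s too long: fewer than 2 envelope points", call. = FALSE)
  }
  drift <- switch(method,
    linear = {
      fit <- stats::lm(env_v ~ env_t)
      stats::predict(fit, newdata = data.frame(env_t = t))
    },
    exponential = {
      tt <- env_t - env_t[1]
      c0 <- min(env_v)
      a0 <- env_v[1] - c0
      if (abs(a0) < 1e-12) a0 <- diff(range(x)) * 0.01 + 1e-9
      b0 <- 1 / max(dur / 3, 1e-6)
      dat <- data.frame(tt = tt, v = env_v)
      # a 3-parameter exponential needs at least 4 envelope points; short
      # recordings fall back to the linear drift model
      fit <- if (length(env_v) < 4) NULL else tryCatch(suppressWarnings({
        if (requireNamespace("minpack.lm", quietly = TRUE)) {
          minpack.lm::nlsLM(v ~ a * exp(-b * tt) + c, data = dat,
                            start = list(a = a0, b = b0, c = c0),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
        } else {
          stats::nls(v ~ a * exp(-b * tt) + c, data = dat,
                     start = list(a = a0, b = b0, c = c0))
        }
      }), error = function(e) NULL)
      pred <- if (is.null(fit)) NULL else {
        cf <- stats::coef(fit)
        if (cf[["b"]] <= 0) NULL else  # bleaching is a decay, not growth
          cf[["a"]] * exp(-cf[["b"]] * (t - env_t[1])) + cf[["c"]]
      }
      # degenerate fit (divergent, or drift larger than the data itself):
      # fall back to the linear drift model
      if (is.null(pred) || !all(is.finite(pred)) ||
          diff(range(pred)) > diff(range(x))) {
        fitl <- stats::lm(env_v ~ env_t)
        pred <- stats::predict(fitl, newdata = data.frame(env_t = t))
      }
      pred
    })
  retrace(trace, x - (drift - drift[1]))
}

#' Affinely rescale a trace to [0, 1]
#'
#' @param trace An [fl_trace()].
#' @return An [fl_trace()] with `min -> 0`, `max -> 1`.
#' @export
normalize <- function(trace) {
  assert_trace(trace)
  rng <- range(trace$fluorescence)
  if (diff(rng) <= 0) {
    stop("cannot normalize a constant trace (no dynamic range)", call. = FALSE)
  }
  retrace(trace, (trace$fluorescence - rng[1]) / diff(rng))
}

empty_beats <- function() {
  tibble::tibble(
    beat_index = integer(), activation_time_s = numeric(),
    peak_time_s = numeric(), baseline_value = numeric(), amplitude = numeric(),
    apd30_ms = numeric(), apd50_ms = numeric(), apd80_ms = numeric(),
    apd90_ms = numeric(), apd90_cross_time_s = numeric(),
    max_upstroke = numeric(), apd_resolved = logical()
  )
}

# first downward crossing of `thr` after peak_idx, before limit_idx, with
# sub-frame linear interpolation between the bracketing samples. When the
# raw signal `x` is supplied (negligible noise floor) the search runs on it
# directly, locating sharp repolarization edges exactly; otherwise the
# noise-robust smoothed signal is used. Returns time or NA.
cross_down <- function(xs, t, peak_idx, limit_idx, thr, x = NULL) {
  if (limit_idx <= peak_idx + 1L) return(NA_real_)
  sig <- if (is.null(x)) xs else x
  seg <- sig[(peak_idx + 1L):limit_idx]
  k <- which(seg <= thr)
  if (length(k) == 0) return(NA_real_)
  k <- k[1] + peak_idx
  if (k == peak_idx + 1L && sig[peak_idx] <= thr) return(t[peak_idx])
  x1 <- sig[k - 1L]; x2 <- sig[k]
  if (x1 <= thr) return(t[k - 1L])
  frac <- (x1 - thr) / (x1 - x2)
  t[k - 1L] + frac * (t[k] - t[k - 1L])
}

#' Segment a trace into beats and compute per-beat metrics
#'
#' Detects depolarization peaks whose prominence is at least `min_prominence`
#' of the trace's dynamic range, rejects activations closer than
#' `refractory_ms` to the previous one, and computes for each beat the
#' activation time (maximum upstroke point), peak time, per-beat diastolic
#' baseline (median of the 100 ms window ending 20 ms before activation; the
#' first beat uses the global 5th percentile), amplitude, APD30/50/80/90 by
#' interpolated threshold crossing, and maximum upstroke velocity. Beats whose
#' APD80 never resolves before the next activation are flagged
#' (`apd_resolved = FALSE`) and excluded from APD statistics downstream.
#'
#' @param trace A detrended [fl_trace()].
#' @param min_prominence Minimum peak prominence as a fraction of the trace
#'   range (default 0.3).
#' @param refractory_ms Minimum time between successive activations (default
#'   200 ms).
#' @return A tibble of class `beat_series`, one row per beat, with attributes
#'   `rr_intervals_s` and `beat_rate_hz`. Zero beats is a valid result.
#' @export
segment_beats <- function(trace, min_prominence = 0.3, refractory_ms = 200) {
  assert_trace(trace)
  x <- trace$fluorescence
  t <- trace$time_s
  fs <- trace_rate(trace)
  rng <- diff(range(x))
  out <- empty_beats()
  if (rng <= 0) return(as_beat_series(out))
  xs <- sg_smooth(x)
  cand <- local_maxima(xs)
  if (length(cand) == 0) return(as_beat_series(out))
  prom <- peak_prominences(xs, cand)
  # noise-adaptive absolute floor: in a beat-free trace the dynamic range is
  # pure noise, and fractional prominence alone would hallucinate beats
  sigma_hat <- stats::mad(diff(x)) / sqrt(2)
  # sub-frame crossing refinement against the raw samples is only unbiased
  # when the noise floor is negligible; under measurable noise the smoothed
  # crossing has the better bias properties
  xr <- if (sigma_hat < 0.005 * rng) x else NULL
  keep <- cand[prom >= pmax(min_prominence * rng, 8 * sigma_hat)]
  if (length(keep) == 0) return(as_beat_series(out))

  dx <- diff(xs)   # smoothed: locates the activation point
  dxr <- diff(x)   # raw: the reported max dF/dt
  n <- length(xs)
  global_base <- stats::quantile(xs, 0.05, names = FALSE)

  rows <- list()
  prev_peak <- NA_integer_
  prev_act_t <- -Inf
  bi <- 0L
  for (p in keep) {
    wstart <- if (is.na(prev_peak)) {
      max(1L, p - round(0.5 * fs))
    } else {
      v <- prev_peak + which.min(xs[prev_peak:p]) - 1L
      max(v, prev_peak + 1L)
    }
    if (wstart >= p) wstart <- max(1L, p - 2L)
    dseg <- dx[wstart:(p - 1L)]
    a <- wstart + which.max(dseg) - 1L
    # steepest rise lies between samples a and a+1; refine to sub-sample
    # precision with a parabolic fit through the neighbouring differences
    off <- 0
    if (a > 1L && a < length(dx)) {
      den <- dx[a - 1L] - 2 * dx[a] + dx[a + 1L]
      if (is.finite(den) && den < 0) {
        off <- max(-0.5, min(0.5, 0.5 * (dx[a - 1L] - dx[a + 1L]) / den))
      }
    }
    act_t <- t[a] + (0.5 + off) / fs
    if (act_t - prev_act_t < refractory_ms / 1000) next
    bi <- bi + 1L
    # per-beat diastolic baseline
    b0 <- if (bi == 1L) {
      global_base
    } else {
      i1 <- max(1L, a - round(0.12 * fs))
      i2 <- max(i1, a - round(0.02 * fs))
      stats::median(xs[i1:i2])
    }
    amp <- xs[p] - b0
    if (amp <= 0) { bi <- bi - 1L; next }
    mus <- max(dxr[wstart:(p - 1L)]) * fs
    rows[[bi]] <- list(peak = p, act_idx = a, act_t = act_t, peak_t = t[p],
                       base = b0, amp = amp, mus = mus)
    prev_peak <- p
    prev_act_t <- act_t
  }
  if (length(rows) == 0) return(as_beat_series(out))

  nb <- length(rows)
  res <- vector("list", nb)
  for (i in seq_len(nb)) {
    b <- rows[[i]]
    limit <- if (i < nb) rows[[i + 1]]$act_idx else n
    apd_ms <- vapply(c(0.3, 0.5, 0.8, 0.9), function(r) {
      thr <- b$base + (1 - r) * b$amp
      tc <- cross_down(xs, t, b$peak, limit, thr, xr)
      if (is.na(tc)) NA_real_ else (tc - b$act_t) * 1000
    }, numeric(1))
    thr90 <- b$base + 0.1 * b$amp
    t90 <- cross_down(xs, t, b$peak, limit, thr90, xr)
    res[[i]] <- tibble::tibble(
      beat_index = i, activation_time_s = b$act_t, peak_time_s = b$peak_t,
      baseline_value = b$base, amplitude = b$amp,
      apd30_ms = apd_ms[1], apd50_ms = apd_ms[2], apd80_ms = apd_ms[3],
      apd90_ms = apd_ms[4],
      apd90_cross_time_s = if (is.na(t90)) t[limit] else t90,
      max_upstroke = b$mus, apd_resolved = !is.na(apd_ms[3])
    )
  }
  as_beat_series(dplyr::bind_rows(res))
}

as_beat_series <- function(beats) {
  rr <- if (nrow(beats) >= 2) diff(beats$activation_time_s) else numeric(0)
  rate <- if (nrow(beats) >= 2) {
    (nrow(beats) - 1) / (beats$activation_time_s[nrow(beats)] -
                           beats$activation_time_s[1])
  } else {
    NA_real_
  }
  attr(beats, "rr_intervals_s") <- rr
  attr(beats, "beat_rate_hz") <- rate
  class(beats) <- unique(c("beat_series", class(beats)))
  beats
}

#' @rdname segment_beats
#' @param series A `beat_series`.
#' @export
rr_intervals <- function(series) attr(series, "rr_intervals_s")

#' @rdname segment_beats
#' @export
beat_rate <- function(series) attr(series, "beat_rate_hz")

#' Action potential duration at a repolarization fraction
#'
#' APD at fraction `r` is the time from the beat's activation (maximum
#' upstroke point) to the first post-peak instant the signal falls to
#' `baseline + (1 - r) * amplitude`, located by linear interpolation between
#' the bracketing samples. Returns `NA` ("unresolved") when the signal never
#' reaches the threshold before the next activation.
#'
#' @param trace The detrended [fl_trace()] the beats were segmented from.
#' @param series The [segment_beats()] result for `trace`.
#' @param fraction Repolarization fraction in (0, 1), e.g. 0.8 for APD80.
#' @return Numeric vector of APDs in milliseconds, one per beat.
#' @export
apd <- function(trace, series, fraction) {
  assert_trace(trace)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  if (nrow(series) == 0) return(numeric(0))
  x <- trace$fluorescence
  xs <- sg_smooth(x)
  t <- trace$time_s
  n <- length(xs)
  xr <- if (stats::mad(diff(x)) / sqrt(2) < 0.005 * diff(range(x))) x else
    NULL
  peak_idx <- vapply(series$peak_time_s, function(pt) which.min(abs(t - pt)),
                     integer(1))
  act_idx <- vapply(series$activation_time_s, function(at) {
    max(1L, which.min(abs(t - at)))
  }, integer(1))
  vapply(seq_len(nrow(series)), function(i) {
    limit <- if (i < nrow(series)) act_idx[i + 1] else n
    thr <- series$baseline_value[i] + (1 - fraction) * series$amplitude[i]
    tc <- cross_down(xs, t, peak_idx[i], limit, thr, xr)
    if (is.na(tc)) NA_real_ else (tc - series$activation_time_s[i]) * 1000
  }, numeric(1))
}

#' Maximum upstroke velocity of a beat
#'
#' The maximum of the first difference times the sampling rate over the window
#' from the end of the preceding diastole (the inter-beat minimum, or 0.5 s
#' before the peak for the first beat) to the beat's peak: the optical max
#' dF/dt.
#'
#' @inheritParams apd
#' @return Numeric vector, normalized units per second, one value per beat.
#' @export
max_upstroke_velocity <- function(trace, series) {
  assert_trace(trace)
  if (nrow(series) == 0) return(numeric(0))
  x <- trace$fluorescence
  xs <- sg_smooth(x)
  t <- trace$time_s
  fs <- trace_rate(trace)
  peak_idx <- vapply(series$peak_time_s, function(pt) which.min(abs(t - pt)),
                     integer(1))
  vapply(seq_len(nrow(series)), function(i) {
    p <- peak_idx[i]
    wstart <- if (i == 1) {
      max(1L, p - round(0.5 * fs))
    } else {
      pp <- peak_idx[i - 1]
      pp + which.min(xs[pp:p]) - 1L
    }
    if (p - wstart < 1L) stop("upstroke window shorter than 2 samples",
                              call. = FALSE)
    max(diff(x[wstart:p])) * fs
  }, numeric(1))
}

#' Fridericia rate correction
#'
#' Divides a duration by the cube root of the RR interval (in seconds), the
#' standard heart-rate correction used for QT intervals and applied here to
#' the optical APD80 QT proxy.
#'
#' @param apd_ms Duration(s) in milliseconds.
#' @param rr_s RR interval(s) in seconds, `> 0`. For paced, captured tissues
#'   use the pacing period `1 / pacing_frequency`.
#' @return Corrected duration(s) in milliseconds.
#' @export
#' @examples
#' fridericia_correct(300, 1.0)  # 300
#' fridericia_correct(300, 8.0)  # 150
fridericia_correct <- function(apd_ms, rr_s) {
  if (any(!is.finite(rr_s)) || any(rr_s <= 0)) {
    stop("rr_s must be positive and finite", call. = FALSE)
  }
  apd_ms / rr_s^(1 / 3)
}

#' Repolarization triangulation
#'
#' `(APD80 - APD30) / APD80`, a dimensionless fraction in `[0, 1)`. Higher
#' values indicate loss of the plateau phase, a proarrhythmic repolarization
#' shape.
#'
#' @param apd30_ms,apd80_ms APDs in milliseconds with `0 < apd30 <= apd80`.
#' @return Triangulation fraction(s).
#' @export
#' @examples
#' triangulation(120, 320)  # 0.625
triangulation <- function(apd30_ms, apd80_ms) {
  if (any(apd30_ms <= 0, na.rm = TRUE)) {
    stop("apd30_ms must be positive", call. = FALSE)
  }
  if (any(apd30_ms > apd80_ms, na.rm = TRUE)) {
    stop("apd30_ms must not exceed apd80_ms", call. = FALSE)
  }
  (apd80_ms - apd30_ms) / apd80_ms
}

#' Check 1:1 pacing capture
#'
#' A paced recording captures when the observed beat rate matches the
#' stimulation frequency within `tol` (relative) and the RR intervals are
#' regular (coefficient of variation at most `tol`). Fewer than 3 beats is
#' reported as non-capture.
#'
#' @param series A [segment_beats()] result.
#' @param pacing_frequency Stimulation frequency in Hz.
#' @param tol Relative tolerance (default 0.05).
#' @return `TRUE` if captured, else `FALSE`.
#' @export
capture_check <- function(series, pacing_frequency, tol = 0.05) {
  if (nrow(series) < 3) return(FALSE)
  rr <- rr_intervals(series)
  rate <- beat_rate(series)
  cv <- stats::sd(rr) / mean(rr)
  abs(rate - pacing_frequency) <= tol * pacing_frequency && cv <= tol
}
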