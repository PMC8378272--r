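# Shared fixture builders. Everything is generated in code at test time.

# canonical calcium transient parameters used across tests
ca_params <- function(apd80 = 350, tri = 0.3, amplitude = 1) {
  beat_template_params("calcium", apd30_ms = apd80 * (1 - tri),
                       apd80_ms = apd80, amplitude = amplitude)
}

v_params <- function(apd80 = 350, tri = 0.3, amplitude = 1) {
  beat_template_params("voltage", apd30_ms = apd80 * (1 - tri),
                       apd80_ms = apd80, amplitude = amplitude)
}

# detrend + normalize the way the pipeline does for a calcium recording
prep_ca <- function(sim) normalize(detrend(sim$trace, "exponential"))
prep_v <- function(sim, window_s = 2) {
  normalize(detrend(sim$trace, "linear", window_s = window_s))
}

# a trace built directly from samples (100 Hz unless stated)
raw_trace <- function(x, fs = 100, channel = "voltage") {
  fl_trace(x, sampling_rate = fs, channel = channel)
}

# idealized beat: flat baseline, step to 1 at t_up, linear decay over
# decay_ms back to baseline; pre/post padding keeps segmentation happy
linear_decay_trace <- function(decay_ms = 400, fs = 100, pad_s = 1) {
  npad <- pad_s * fs
  decay <- seq(1, 0, length.out = decay_ms / 1000 * fs + 1)
  raw_trace(c(rep(0, npad), decay, rep(0, npad)), fs = fs)
}

# a manually specified single-beat series for closed-form APD checks:
# activation and peak at the start of the decay, baseline 0, amplitude 1
manual_beat <- function(trace, act_time_s) {
  s <- tibble::tibble(
    beat_index = 1L, activation_time_s = act_time_s,
    peak_time_s = act_time_s, baseline_value = 0, amplitude = 1,
    apd30_ms = NA_real_, apd50_ms = NA_real_, apd80_ms = NA_real_,
    apd90_ms = NA_real_, apd90_cross_time_s = max(trace$time_s),
    max_upstroke = 1, apd_resolved = NA
  )
  attr(s, "rr_intervals_s") <- numeric(0)
  attr(s, "beat_rate_hz") <- NA_real_
  class(s) <- c("beat_series", class(s))
  s
}

expect_tbl_equal <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
}
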