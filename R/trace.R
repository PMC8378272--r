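#' Construct a fluorescence trace
#'
#' A fluorescence trace is a uniformly sampled scalar intensity signal from one
#' optical channel of an MPS recording: either a voltage-sensitive dye or a
#' genetically encoded calcium indicator. Time is implicit: sample `i` (1-based)
#' is acquired at `t0 + (i - 1) / sampling_rate` seconds.
#'
#' @param fluorescence Numeric vector of intensities (arbitrary units), length
#'   at least 2, all finite.
#' @param sampling_rate Sampling rate in Hz (frames per second); default 100,
#'   the nominal acquisition rate of the imaging system.
#' @param channel `"voltage"` or `"calcium"`.
#' @param t0 Acquisition start time in seconds (default 0).
#'
#' @return A tibble of class `fl_trace` with columns `time_s` and
#'   `fluorescence`, carrying `sampling_rate`, `channel` and `t0` as attributes.
#' @export
#' @examples
#' tr <- fl_trace(sin(seq(0, 2 * pi, length.out = 200)), channel = "voltage")
#' trace_duration(tr)
fl_trace <- function(fluorescence, sampling_rate = 100,
                     channel = c("voltage", "calcium"), t0 = 0) {
  channel <- match.arg(channel)
  fluorescence <- as.numeric(fluorescence)
  if (length(fluorescence) < 2) {
    stop("a fluorescence trace needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(fluorescence))) {
    stop("all fluorescence samples must be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.numeric(t0) || length(t0) != 1 || !is.finite(t0)) {
    stop("t0 must be a single finite number (seconds)", call. = FALSE)
  }
  n <- length(fluorescence)
  out <- tibble::tibble(
    time_s = t0 + (seq_len(n) - 1) / sampling_rate,
    fluorescence = fluorescence
  )
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "channel") <- channel
  attr(out, "t0") <- t0
  class(out) <- c("fl_trace", class(out))
  out
}

#' @rdname fl_trace
#' @param trace An `fl_trace`.
#' @export
trace_rate <- function(trace) attr(trace, "sampling_rate")

#' @rdname fl_trace
#' @export
trace_channel <- function(trace) attr(trace, "channel")

#' @rdname fl_trace
#' @export
trace_t0 <- function(trace) attr(trace, "t0")

#' @rdname fl_trace
#' @export
trace_duration <- function(trace) (nrow(trace) - 1) / trace_rate(trace)

# rebuild an fl_trace with new samples but the same clock/metadata
retrace <- function(trace, fluorescence) {
  fl_trace(fluorescence,
           sampling_rate = trace_rate(trace),
           channel = trace_channel(trace),
           t0 = trace_t0(trace))
}

assert_trace <- function(trace) {
  if (!inherits(trace, "fl_trace")) {
    stop("expected an `fl_trace` object (see fl_trace())", call. = FALSE)
  }
  invisible(trace)
}

#' Recording metadata for one MPS trace
#'
#' Describes the provenance of a single recording: which tissue in which
#' chamber of which 4-plex chip, the drug and dose applied, whether the tissue
#' was beating spontaneously or field-paced, and the nominal recording length.
#' `dose_index` 0 denotes the pre-drug baseline recording.
#'
#' @param tissue_id,chip_id Identifier strings.
#' @param chamber_index Chamber within the 4-plex chip, integer 1--4.
#' @param drug Drug name (`"none"` for baseline-only recordings).
#' @param dose_um Dose in micromolar, `>= 0`.
#' @param dose_index Position on the dose ladder, integer `>= 0`; 0 = baseline.
#' @param rhythm `"spontaneous"` or `"paced"`.
#' @param pacing_frequency_hz Field-stimulation frequency in Hz; required when
#'   `rhythm = "paced"` (the protocol uses 1.0, escalated to 1.5 when a chip
#'   fails 1 Hz capture), must be `NA` otherwise.
#' @param recording_length_s Nominal recording length, seconds (6 or 30).
#'
#' @return A one-row tibble of class `recording_meta`.
#' @export
recording_meta <- function(tissue_id, chip_id = tissue_id, chamber_index = 1L,
                           drug = "none", dose_um = 0, dose_index = 0L,
                           rhythm = c("spontaneous", "paced"),
                           pacing_frequency_hz = NA_real_,
                           recording_length_s = 30) {
  rhythm <- match.arg(rhythm)
  chamber_index <- as.integer(chamber_index)
  dose_index <- as.integer(dose_index)
  if (!chamber_index %in% 1:4) {
    stop("chamber_index must be in 1..4 (4-plex chip)", call. = FALSE)
  }
  if (!is.numeric(dose_um) || dose_um < 0 || !is.finite(dose_um)) {
    stop("dose_um must be a finite non-negative dose in µM", call. = FALSE)
  }
  if (dose_index < 0L) stop("dose_index must be >= 0", call. = FALSE)
  if (rhythm == "paced") {
    if (!is.numeric(pacing_frequency_hz) || is.na(pacing_frequency_hz) ||
        pacing_frequency_hz <= 0) {
      stop("paced recordings require pacing_frequency_hz > 0", call. = FALSE)
    }
  } else if (!is.na(pacing_frequency_hz)) {
    stop("pacing_frequency_hz must be NA for spontaneous recordings",
         call. = FALSE)
  }
  if (!is.numeric(recording_length_s) || recording_length_s <= 0) {
    stop("recording_length_s must be positive", call. = FALSE)
  }
  out <- tibble::tibble(
    tissue_id = as.character(tissue_id),
    chip_id = as.character(chip_id),
    chamber_index = chamber_index,
    drug = as.character(drug),
    dose_um = as.numeric(dose_um),
    dose_index = dose_index,
    rhythm = rhythm,
    pacing_frequency_hz = as.numeric(pacing_frequency_hz),
    recording_length_s = as.numeric(recording_length_s)
  )
  class(out) <- c("recording_meta", class(out))
  out
}

meta_fields <- c("tissue_id", "chip_id", "chamber_index", "drug", "dose_um",
                 "dose_index", "rhythm", "pacing_frequency_hz",
                 "recording_length_s")

#' Bundle recordings into a trace set
#'
#' A trace set is the tabular container for a study's recordings: one row per
#' recording with all metadata columns plus a `channel` column and a `trace`
#' list-column of [fl_trace()] objects. Rows must be unique on
#' (tissue_id, dose_index, channel, rhythm, recording_length_s).
#'
#' @param entries A data frame with the [recording_meta()] columns, a `channel`
#'   column, and a `trace` list-column.
#' @return The validated tibble with class `trace_set`.
#' @export
trace_set <- function(entries) {
  entries <- tibble::as_tibble(entries)
  need <- c(meta_fields, "channel", "trace")
  missing <- setdiff(need, names(entries))
  if (length(missing) > 0) {
    stop("trace_set is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- entries[c("tissue_id", "dose_index", "channel", "rhythm",
                   "recording_length_s")]
  if (anyDuplicated(key) > 0) {
    stop("trace_set keys (tissue_id, dose_index, channel, rhythm, ",
         "recording_length_s) must be unique", call. = FALSE)
  }
  ok <- vapply(entries$trace, inherits, logical(1), what = "fl_trace")
  if (!all(ok)) stop("every entry of `trace` must be an fl_trace", call. = FALSE)
  class(entries) <- unique(c("trace_set", class(entries)))
  entries
}

# full-precision decimal formatting: round-trips doubles exactly
fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write the trace CSV dialect
#'
#' The on-disk format is UTF-8 CSV with a commented header: one `#key=value`
#' line per [recording_meta()] field plus `sampling_rate` and `channel`,
#' followed by a `time_s,fluorescence` header row and data rows at full decimal
#' precision. The explicit time column is validated against the implicit
#' uniform clock `t0 + i/sampling_rate` with tolerance 1e-6 s; gaps, reversals
#' or non-finite samples are format errors. The write/read pair is lossless.
#'
#' @param path File path.
#' @return `read_trace_csv()`: a list with elements `meta` (one-row tibble) and
#'   `trace` (an [fl_trace()]). `write_trace_csv()`: `path`, invisibly.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed header line: ", hdr[bad][1], call. = FALSE)
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  names(vals) <- keys
  need <- c(meta_fields, "sampling_rate", "channel")
  missing <- setdiff(need, keys)
  if (length(missing) > 0) {
    stop("trace CSV header missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(body) < 1 || body[1] != "time_s,fluorescence") {
    stop("expected column header 'time_s,fluorescence'", call. = FALSE)
  }
  dat <- utils::read.csv(text = body, header = TRUE,
                         colClasses = c("numeric", "numeric"))
  if (nrow(dat) < 2) stop("trace must contain at least 2 samples", call. = FALSE)
  if (anyNA(dat) || !all(is.finite(dat$fluorescence))) {
    stop("non-finite value in trace data", call. = FALSE)
  }
  rate <- as.numeric(vals[["sampling_rate"]])
  pf <- vals[["pacing_frequency_hz"]]
  meta <- recording_meta(
    tissue_id = vals[["tissue_id"]], chip_id = vals[["chip_id"]],
    chamber_index = as.integer(vals[["chamber_index"]]),
    drug = vals[["drug"]], dose_um = as.numeric(vals[["dose_um"]]),
    dose_index = as.integer(vals[["dose_index"]]), rhythm = vals[["rhythm"]],
    pacing_frequency_hz = if (identical(pf, "NA")) NA_real_ else as.numeric(pf),
    recording_length_s = as.numeric(vals[["recording_length_s"]])
  )
  t0 <- dat$time_s[1]
  expected <- t0 + (seq_len(nrow(dat)) - 1) / rate
  if (max(abs(dat$time_s - expected)) > 1e-6) {
    stop("time column deviates from uniform sampling at ", rate,
         " Hz (tolerance 1e-6 s)", call. = FALSE)
  }
  trace <- fl_trace(dat$fluorescence, sampling_rate = rate,
                    channel = vals[["channel"]], t0 = t0)
  list(meta = meta, trace = trace)
}

#' @rdname read_trace_csv
#' @param meta A [recording_meta()] row.
#' @param trace An [fl_trace()].
#' @export
write_trace_csv <- function(meta, trace, path) {
  # revalidate: rows sliced out of a trace_set or edited after construction
  args <- as.list(tibble::as_tibble(meta)[1, meta_fields])
  meta <- do.call(recording_meta, args)
  assert_trace(trace)
  hdr <- c(
    vapply(meta_fields, function(f) {
      v <- meta[[f]][1]
      v <- if (is.numeric(v) && !is.na(v)) fmt_num(v) else as.character(v)
      paste0("#", f, "=", v)
    }, character(1)),
    paste0("#sampling_rate=", fmt_num(trace_rate(trace))),
    paste0("#channel=", trace_channel(trace))
  )
  rows <- paste(fmt_num(trace$time_s), fmt_num(trace$fluorescence), sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, "time_s,fluorescence", rows), con)
  invisible(path)
}

#' Reduce a multi-frame TIFF stack to a mean-ROI fluorescence trace
#'
#' Sample `i` of the returned trace is the mean pixel intensity of the ROI in
#' frame `i`. ROI coordinates are 0-based, half-open: `[x0, x1) x [y0, y1)`
#' in pixel units, `x` along image columns and `y` along rows.
#'
#' @param path Path to a single-channel multi-frame grayscale TIFF.
#' @param roi Numeric vector `c(x0, x1, y0, y1)`.
#' @param sampling_rate Acquisition rate in Hz.
#' @param channel Channel label for the resulting trace.
#' @return An [fl_trace()].
#' @export
tiff_to_trace <- function(path, roi, sampling_rate = 100,
                          channel = c("voltage", "calcium")) {
  channel <- match.arg(channel)
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("tiff_to_trace requires the 'tiff' package", call. = FALSE)
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(dim(frames[[1]])) > 2) {
    stop("multi-channel TIFF stacks are not supported", call. = FALSE)
  }
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  roi <- as.numeric(roi)
  if (length(roi) != 4) stop("roi must be c(x0, x1, y0, y1)", call. = FALSE)
  x0 <- roi[1]; x1 <- roi[2]; y0 <- roi[3]; y1 <- roi[4]
  if (x0 < 0 || y0 < 0 || x1 > nc || y1 > nr || x0 >= x1 || y0 >= y1) {
    stop("roi [", x0, ",", x1, ")x[", y0, ",", y1,
         ") outside frame bounds ", nc, "x", nr, call. = FALSE)
  }
  cols <- (x0 + 1):x1
  rows <- (y0 + 1):y1
  samples <- vapply(frames, function(fr) mean(fr[rows, cols]), numeric(1))
  fl_trace(samples, sampling_rate = sampling_rate, channel = channel)
}

#' Read a directory of trace CSVs into a trace set
#'
#' @param dir Directory containing `*.csv` files in the [read_trace_csv()]
#'   dialect.
#' @return A [trace_set()] tibble.
#' @export
read_trace_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no trace CSVs found in ", dir, call. = FALSE)
  rows <- purrr::map(files, function(f) {
    x <- read_trace_csv(f)
    dplyr::mutate(x$meta, channel = trace_channel(x$trace),
                  trace = list(x$trace))
  })
  trace_set(dplyr::bind_rows(rows))
}

#' Write a trace set to a directory of trace CSVs
#'
#' File names encode the key: `tissue_dose<index>_<channel>_<rhythm>_<len>s.csv`.
#'
#' @param set A [trace_set()].
#' @param dir Output directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
write_trace_dir <- function(set, dir) {
  set <- trace_set(set)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(set))
  for (i in seq_len(nrow(set))) {
    nm <- sprintf("%s_dose%02d_%s_%s_%gs.csv", set$tissue_id[i],
                  set$dose_index[i], set$channel[i], set$rhythm[i],
                  set$recording_length_s[i])
    paths[i] <- file.path(dir, nm)
    write_trace_csv(set[i, ], set$trace[[i]], paths[i])
  }
  invisible(paths)
}
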