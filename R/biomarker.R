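# Effluent biomarker panel container and the limit-of-detection filter.

#' Construct a biomarker panel
#'
#' Holds a marker x sample matrix of relative abundances (assay units)
#' together with a marker x control matrix of negative-control measurements
#' used to set each marker's limit of detection, and optional per-sample
#' metadata (drug/dose).
#'
#' @param values Numeric matrix, markers in rows (rownames required), study
#'   samples in columns.
#' @param negative_controls Numeric matrix with the same marker rownames and
#'   at least 2 control columns (a standard deviation must be defined).
#' @param sample_meta Optional data frame with one row per study sample
#'   (column `sample_id` matching `colnames(values)` plus e.g. `drug`,
#'   `dose_um`).
#' @return A list of class `biomarker_panel`.
#' @export
biomarker_panel <- function(values, negative_controls, sample_meta = NULL) {
  values <- as.matrix(values)
  negative_controls <- as.matrix(negative_controls)
  if (is.null(rownames(values)) || is.null(rownames(negative_controls))) {
    stop("both matrices need marker rownames", call. = FALSE)
  }
  if (!setequal(rownames(values), rownames(negative_controls))) {
    stop("markers must be present in both the study and the negative-control ",
         "matrix", call. = FALSE)
  }
  negative_controls <- negative_controls[rownames(values), , drop = FALSE]
  n_ctrl <- rowSums(!is.na(negative_controls))
  if (any(n_ctrl < 2)) {
    stop("marker(s) with fewer than 2 negative controls: ",
         paste(rownames(values)[n_ctrl < 2], collapse = ", "), call. = FALSE)
  }
  if (!is.null(sample_meta)) {
    sample_meta <- tibble::as_tibble(sample_meta)
    if (!"sample_id" %in% names(sample_meta)) {
      stop("sample_meta needs a `sample_id` column", call. = FALSE)
    }
  }
  structure(list(values = values, negative_controls = negative_controls,
                 sample_meta = sample_meta),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker_panel: %d markers x %d samples (%d negative controls)\n",
              nrow(x$values), ncol(x$values), ncol(x$negative_controls)))
  invisible(x)
}

#' Limit-of-detection filter for a biomarker panel
#'
#' For each marker the limit of detection (LOD) is the mean of its negative
#' controls plus 3 sample standard deviations. A study sample is "detected"
#' when strictly above the LOD; a marker is retained when its detection
#' fraction over non-missing study samples is strictly greater than
#' `min_fraction` (default 0.65, i.e. the ">65% of samples above LOD" rule).
#'
#' @param panel A [biomarker_panel()].
#' @param min_fraction Retention threshold on the detection fraction
#'   (strict inequality; default 0.65).
#' @return A tibble with one row per marker: `marker`, `lod`, `n_samples`,
#'   `n_detected`, `detection_fraction`, `retained`.
#' @export
lod_filter <- function(panel, min_fraction = 0.65) {
  if (!inherits(panel, "biomarker_panel")) {
    stop("expected a biomarker_panel", call. = FALSE)
  }
  nc <- panel$negative_controls
  lod <- apply(nc, 1, mean, na.rm = TRUE) +
    3 * apply(nc, 1, stats::sd, na.rm = TRUE)
  v <- panel$values
  n_samples <- rowSums(!is.na(v))
  n_detected <- rowSums(sweep(v, 1, lod, `>`), na.rm = TRUE)
  frac <- n_detected / n_samples
  tibble::tibble(
    marker = rownames(v), lod = unname(lod), n_samples = unname(n_samples),
    n_detected = unname(n_detected), detection_fraction = unname(frac),
    retained = unname(frac > min_fraction)
  )
}

#' Read and write biomarker panel CSVs
#'
#' The values CSV has markers as rows (first column `marker`) and samples as
#' columns; the sample-metadata CSV has one row per sample with at least
#' `sample_id` and a logical `is_negative_control` column separating the
#' negative-control samples from study samples.
#'
#' @param values_csv,meta_csv File paths.
#' @return A [biomarker_panel()].
#' @export
read_biomarker_panel <- function(values_csv, meta_csv) {
  vals <- utils::read.csv(values_csv, check.names = FALSE)
  if (names(vals)[1] != "marker") {
    stop("first column of the values CSV must be `marker`", call. = FALSE)
  }
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$marker
  meta <- tibble::as_tibble(utils::read.csv(meta_csv))
  if (!all(c("sample_id", "is_negative_control") %in% names(meta))) {
    stop("meta CSV needs `sample_id` and `is_negative_control`", call. = FALSE)
  }
  neg_ids <- meta$sample_id[as.logical(meta$is_negative_control)]
  study_ids <- setdiff(colnames(m), neg_ids)
  biomarker_panel(
    values = m[, study_ids, drop = FALSE],
    negative_controls = m[, intersect(colnames(m), neg_ids), drop = FALSE],
    sample_meta = meta[!as.logical(meta$is_negative_control), ]
  )
}

#' @rdname read_biomarker_panel
#' @param panel A [biomarker_panel()].
#' @export
write_biomarker_panel <- function(panel, values_csv, meta_csv) {
  if (!inherits(panel, "biomarker_panel")) {
    stop("expected a biomarker_panel", call. = FALSE)
  }
  m <- cbind(panel$values, panel$negative_controls)
  df <- data.frame(marker = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, values_csv, row.names = FALSE)
  meta <- tibble::tibble(
    sample_id = colnames(m),
    is_negative_control = colnames(m) %in% colnames(panel$negative_controls)
  )
  if (!is.null(panel$sample_meta)) {
    meta <- dplyr::left_join(meta, panel$sample_meta, by = "sample_id")
  }
  utils::write.csv(meta, meta_csv, row.names = FALSE)
  invisible(c(values_csv, meta_csv))
}
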