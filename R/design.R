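# Dose-escalation study designs: dose ladders anchored at clinical Cmax,
# cohort structure, recording protocol, and YAML round trip.

#' Define a dose-escalation design
#'
#' Doses are specified as multiples of the drug's clinical Cmax and resolved
#' to micromolar at construction, the single canonical unit used downstream.
#' A constant companion drug (polytherapy: an escalating ladder on top of a
#' fixed co-treatment) is supported; the combined ladder, in summed Cmax
#' multiples, must start at 0 and be strictly increasing.
#'
#' @param drug Escalated drug name.
#' @param cmax_um Clinical Cmax of the escalated drug, in micromolar.
#' @param dose_ladder_xcmax Dose ladder in multiples of Cmax, starting at 0.
#' @param companion_drug,companion_cmax_um,companion_ladder_xcmax Optional
#'   co-treatment: name, Cmax (micromolar) and its per-step ladder in Cmax
#'   multiples (same length as `dose_ladder_xcmax`).
#' @param n_tissues Tissues per drug (default 7).
#' @param chambers_per_chip Chambers per chip (4-plex; default 4).
#' @param pacing_frequency_hz Field pacing frequency, 1.0 or 1.5 Hz.
#' @param incubation_min_per_dose Per-dose incubation, minutes (default 30).
#' @param recording_lengths_s Spontaneous recording lengths (default 6 and
#'   30 s).
#' @return A list of class `dose_escalation_design` whose `doses` element is
#'   a tibble with `dose_index`, per-drug micromolar columns, `dose_um` (the
#'   escalated drug) and `effect_dose_um`.
#' @export
dose_escalation_design <- function(drug, cmax_um, dose_ladder_xcmax,
                                   companion_drug = NULL,
                                   companion_cmax_um = NULL,
                                   companion_ladder_xcmax = NULL,
                                   n_tissues = 7, chambers_per_chip = 4,
                                   pacing_frequency_hz = 1,
                                   incubation_min_per_dose = 30,
                                   recording_lengths_s = c(6, 30)) {
  if (n_tissues < 1) stop("n_tissues must be >= 1", call. = FALSE)
  lad <- as.numeric(dose_ladder_xcmax)
  if (lad[1] != 0) stop("dose ladder must start at 0", call. = FALSE)
  comp <- if (is.null(companion_ladder_xcmax)) rep(0, length(lad)) else
    as.numeric(companion_ladder_xcmax)
  if (length(comp) != length(lad)) {
    stop("companion ladder must match the primary ladder length",
         call. = FALSE)
  }
  total <- lad + comp
  if (any(diff(total) <= 0)) {
    stop("combined dose ladder (in summed Cmax multiples) must be strictly ",
         "increasing", call. = FALSE)
  }
  doses <- tibble::tibble(
    dose_index = seq_along(lad) - 1L,
    dose_xcmax = lad,
    dose_um = lad * cmax_um
  )
  if (!is.null(companion_drug)) {
    doses[[paste0(tolower(companion_drug), "_um")]] <-
      comp * companion_cmax_um
  }
  doses$effect_dose_um <- doses$dose_um +
    if (is.null(companion_drug)) 0 else comp * companion_cmax_um
  structure(list(
    drug = drug, cmax_um = cmax_um, companion_drug = companion_drug,
    companion_cmax_um = companion_cmax_um, doses = doses,
    n_tissues = as.integer(n_tissues),
    chambers_per_chip = as.integer(chambers_per_chip),
    pacing_frequency_hz = pacing_frequency_hz,
    incubation_min_per_dose = incubation_min_per_dose,
    recording_lengths_s = recording_lengths_s
  ), class = "dose_escalation_design")
}

#' Reference acute dose-escalation designs
#'
#' The three acute study layouts: hydroxychloroquine (HCQ, Cmax 1 uM; ladder
#' 0, 0.1, 1, 10, 100, 1000 x Cmax), azithromycin (AZM, Cmax 0.67 uM; ladder
#' 0, 0.1, 1, 10, 100 x Cmax) and the polytherapy in which AZM (0, 0, 0.1,
#' 0.3, 1, 3, 10 x Cmax) escalates on top of HCQ held at Cmax from step 1
#' (HCQ ladder 0, 1, 1, 1, 1, 1, 1). Seven tissues per drug.
#'
#' @param which `"HCQ"`, `"AZM"` or `"HCQ+AZM"`.
#' @param ... Overrides passed to [dose_escalation_design()].
#' @return A [dose_escalation_design()].
#' @export
reference_design <- function(which = c("HCQ", "AZM", "HCQ+AZM"), ...) {
  which <- match.arg(which)
  switch(which,
    "HCQ" = dose_escalation_design(
      drug = "HCQ", cmax_um = 1,
      dose_ladder_xcmax = c(0, 0.1, 1, 10, 100, 1000), ...),
    "AZM" = dose_escalation_design(
      drug = "AZM", cmax_um = 0.67,
      dose_ladder_xcmax = c(0, 0.1, 1, 10, 100), ...),
    "HCQ+AZM" = dose_escalation_design(
      drug = "AZM", cmax_um = 0.67,
      dose_ladder_xcmax = c(0, 0, 0.1, 0.3, 1, 3, 10),
      companion_drug = "HCQ", companion_cmax_um = 1,
      companion_ladder_xcmax = c(0, 1, 1, 1, 1, 1, 1), ...)
  )
}

#' Read and write a design as YAML
#'
#' @param design A [dose_escalation_design()].
#' @param path File path.
#' @return `read_design_yaml()`: a [dose_escalation_design()];
#'   `write_design_yaml()`: `path`, invisibly.
#' @export
write_design_yaml <- function(design, path) {
  stopifnot(inherits(design, "dose_escalation_design"))
  x <- list(
    drug = design$drug, cmax_um = design$cmax_um,
    dose_ladder_xcmax = design$doses$dose_xcmax,
    n_tissues = design$n_tissues,
    chambers_per_chip = design$chambers_per_chip,
    pacing_frequency_hz = design$pacing_frequency_hz,
    incubation_min_per_dose = design$incubation_min_per_dose,
    recording_lengths_s = design$recording_lengths_s
  )
  if (!is.null(design$companion_drug)) {
    x$companion_drug <- design$companion_drug
    x$companion_cmax_um <- design$companion_cmax_um
    x$companion_ladder_xcmax <-
      design$doses[[paste0(tolower(design$companion_drug), "_um")]] /
      design$companion_cmax_um
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(dose_escalation_design, x)
}

#' @export
print.dose_escalation_design <- function(x, ...) {
  cat(sprintf("dose_escalation_design: %s (Cmax %g uM)%s, %d tissues\n",
              x$drug, x$cmax_um,
              if (is.null(x$companion_drug)) "" else
                paste0(" + ", x$companion_drug), x$n_tissues))
  print(x$doses, ...)
  invisible(x)
}
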