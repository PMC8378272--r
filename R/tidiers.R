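# broom-style tidiers for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Dunnett fit
#'
#' @param x A [anova_dunnett()] result.
#' @param ... Unused.
#' @return One row per many-to-one comparison: `group`, `reference`,
#'   `estimate`, `std_error`, `statistic`, `df`, `adj_p_value`, `stars`.
#' @export
tidy.dunnett_fit <- function(x, ...) x$comparisons

#' @rdname tidy.dunnett_fit
#' @return `glance()`: a one-row tibble with the overall ANOVA F statistic,
#'   degrees of freedom and p-value.
#' @export
glance.dunnett_fit <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df_between = x$df[1],
                 df_within = x$df[2], p_anova = x$p_anova,
                 n_groups = length(x$group_sizes),
                 n_obs = sum(x$group_sizes))
}

#' Tidy a study report
#'
#' @param x A [run_study()] report.
#' @param what Which table: `"metrics"` (default), `"calls"`, `"incidence"`,
#'   `"dunnett"`, `"chisq"`, `"inclusion"`, `"events"`, or `"biomarkers"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.study_report <- function(x, what = c("metrics", "calls", "incidence",
                                          "dunnett", "chisq", "inclusion",
                                          "events", "biomarkers"), ...) {
  what <- match.arg(what)
  out <- switch(what, dunnett = if (!is.null(x$dunnett))
    tidy(x$dunnett) else NULL, x[[what]])
  if (is.null(out)) {
    stop("report has no `", what, "` table", call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' @rdname tidy.study_report
#' @return `glance()`: one row summarizing the study: tissue counts, the
#'   ANOVA p-value, the top-dose arrhythmic incidence and the number of
#'   retained biomarkers (if a panel was analyzed).
#' @export
glance.study_report <- function(x, ...) {
  top_arr <- if (!is.null(x$incidence)) {
    arr <- dplyr::filter(x$incidence, .data$category == "arrhythmic")
    arr$pct[which.max(arr$dose_index)]
  } else NA_real_
  tibble::tibble(
    drug = x$design$drug,
    n_tissues = nrow(x$inclusion),
    n_included = sum(x$inclusion$included),
    n_doses = nrow(x$design$doses),
    p_anova = if (!is.null(x$dunnett)) x$dunnett$p_anova else NA_real_,
    top_dose_arrhythmic_pct = top_arr,
    n_biomarkers_retained = if (!is.null(x$biomarkers))
      sum(x$biomarkers$retained) else NA_integer_
  )
}
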