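# Cohort statistics: one-way ANOVA with Dunnett many-to-one comparisons
# against the dose-0 baseline, and pairwise chi-squared tests of arrhythmia
# incidence.

# Gauss-Legendre nodes/weights on [a, b], cached by order
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, a, b) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    i <- 1:(n - 1)
    bv <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- bv
    J[cbind(i + 1, i)] <- bv
    e <- eigen(J, symmetric = TRUE)
    .gl_cache[[key]] <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  }
  g <- .gl_cache[[key]]
  list(x = (a + b) / 2 + (b - a) / 2 * g$x, w = g$w * (b - a) / 2)
}

# Two-sided Dunnett many-to-one adjusted p-values by deterministic numerical
# integration of the multivariate t. The many-to-one t statistics share only
# the reference group, giving the factor structure corr[j,k] = lam_j * lam_k
# with lam_j = sqrt(n_j / (n_j + n0)); conditioning on the reference normal
# deviate z0 and the pooled scale s = sqrt(chi2_df / df), the joint CDF is a
# product of univariate normal probabilities, integrated on a 48 x 48
# Gauss-Legendre grid (absolute accuracy ~1e-5).
dunnett_p_adj <- function(tstats, lams, df, nq = 48) {
  gz <- gauss_legendre(nq, -8, 8)
  qhi <- df + 12 * sqrt(2 * df)
  gq <- gauss_legendre(nq, 1e-8, qhi)
  s <- sqrt(gq$x / df)
  wq <- stats::dchisq(gq$x, df) * gq$w
  wz <- stats::dnorm(gz$x) * gz$w
  sq <- sqrt(1 - lams^2)
  vapply(abs(tstats), function(tt) {
    prod_grid <- matrix(1, nq, nq)  # rows: z0 nodes, cols: s nodes
    for (j in seq_along(lams)) {
      up <- outer(-lams[j] * gz$x, tt * s, `+`) / sq[j]
      lo <- outer(-lams[j] * gz$x, -tt * s, `+`) / sq[j]
      prod_grid <- prod_grid * (stats::pnorm(up) - stats::pnorm(lo))
    }
    p <- 1 - as.numeric(wz %*% prod_grid %*% wq)
    max(0, min(1, p))
  }, numeric(1))
}

signif_stars <- function(p) {
  dplyr::case_when(
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Tests each dose group against the dose-0 reference. The overall F test is
#' the classical one-way ANOVA; the per-dose adjusted p-values are two-sided
#' Dunnett tests computed from the multivariate-t distribution of the
#' many-to-one t statistics (correlated through the shared reference group),
#' integrated deterministically by Gauss-Legendre quadrature over the
#' reference deviate and the pooled scale (absolute accuracy about 1e-5),
#' with the pooled within-group variance. With a single comparison the
#' adjusted p-value reduces to the two-sample pooled t-test.
#'
#' @param data A data frame with one observation per row.
#' @param value,group Column names (strings) of the response and the dose
#'   grouping variable. Groups are ordered by their sorted unique values.
#' @param reference The reference group value (default: the smallest, i.e.
#'   dose 0).
#' @return An object of class `dunnett_fit`: a list with `comparisons` (a
#'   tibble of per-dose estimates, t statistics and adjusted p-values with
#'   significance stars), `f_statistic`, `df`, `p_anova`, `reference` and
#'   `group_sizes`. Supports [generics::tidy()] and [generics::glance()].
#' @export
anova_dunnett <- function(data, value = "value", group = "dose",
                          reference = NULL) {
  data <- tibble::as_tibble(data)
  if (!all(c(value, group) %in% names(data))) {
    stop("data must contain columns `", value, "` and `", group, "`",
         call. = FALSE)
  }
  y <- data[[value]]
  g <- data[[group]]
  keep <- is.finite(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  levels_g <- sort(unique(g))
  if (length(levels_g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(reference)) reference <- levels_g[1]
  if (!reference %in% levels_g) {
    stop("reference group not present in data", call. = FALSE)
  }
  ns <- vapply(levels_g, function(l) sum(g == l), numeric(1))
  if (any(ns < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(levels_g[ns < 2], collapse = ", "), call. = FALSE)
  }
  means <- vapply(levels_g, function(l) mean(y[g == l]), numeric(1))
  ss_within <- sum(vapply(levels_g, function(l) {
    v <- y[g == l]; sum((v - mean(v))^2)
  }, numeric(1)))
  N <- length(y); k <- length(levels_g)
  df <- N - k
  s2 <- ss_within / df
  ss_between <- sum(ns * (means - mean(y))^2)
  f_stat <- (ss_between / (k - 1)) / s2
  p_anova <- stats::pf(f_stat, k - 1, df, lower.tail = FALSE)

  others <- setdiff(levels_g, reference)
  i0 <- match(reference, levels_g)
  n0 <- ns[i0]
  idx <- match(others, levels_g)
  est <- means[idx] - means[i0]
  se <- sqrt(s2 * (1 / ns[idx] + 1 / n0))
  tstat <- est / se
  m <- length(others)
  lam <- sqrt(ns[idx] / (ns[idx] + n0))
  p_adj <- if (m == 1) {
    2 * stats::pt(-abs(tstat), df)
  } else {
    dunnett_p_adj(tstat, lam, df)
  }

  out <- list(
    comparisons = tibble::tibble(
      group = others, reference = reference, estimate = est,
      std_error = se, statistic = tstat, df = df, adj_p_value = p_adj,
      stars = signif_stars(p_adj)
    ),
    f_statistic = f_stat, df = c(k - 1, df), p_anova = p_anova,
    reference = reference,
    group_sizes = stats::setNames(ns, as.character(levels_g))
  )
  class(out) <- "dunnett_fit"
  out
}

#' @export
print.dunnett_fit <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_anova))
  cat("Dunnett comparisons vs", format(x$reference), "\n")
  print(x$comparisons, ...)
  invisible(x)
}

#' Pairwise chi-squared tests of arrhythmia incidence
#'
#' Builds the 2x2 table (arrhythmic vs not) for every pair of doses and
#' applies the chi-squared test of homogeneity. By default no continuity
#' correction is applied (`correct = FALSE`); Yates correction is available
#' via the flag. Pairs in which neither group has any arrhythmic (or any
#' non-arrhythmic) tissue have identical proportions and are reported with
#' statistic 0 and p-value 1.
#'
#' @param calls Either a per-tissue calls data frame with `dose_index` (or
#'   `dose_um`) and `category` columns, or a per-dose count table with
#'   columns `dose_index`, `n_arrhythmic`, `n_total`.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A tibble with one row per dose pair: `dose_a`, `dose_b`,
#'   `statistic`, `p_value`, `stars`.
#' @export
chi_square_pairwise <- function(calls, correct = FALSE) {
  calls <- tibble::as_tibble(calls)
  key <- if ("dose_index" %in% names(calls)) "dose_index" else "dose_um"
  if ("category" %in% names(calls)) {
    counts <- calls |>
      dplyr::group_by(dose = .data[[key]]) |>
      dplyr::summarise(n_arrhythmic = sum(.data$category == "arrhythmic"),
                       n_total = dplyr::n(), .groups = "drop")
  } else if (all(c("n_arrhythmic", "n_total") %in% names(calls))) {
    counts <- dplyr::rename(calls, dose = dplyr::all_of(key))
  } else {
    stop("calls must contain `category` or `n_arrhythmic`/`n_total`",
         call. = FALSE)
  }
  if (any(counts$n_total == 0)) {
    stop("dose group with zero tissues", call. = FALSE)
  }
  doses <- sort(counts$dose)
  pairs <- utils::combn(doses, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    a <- counts[counts$dose == pr[1], ]
    b <- counts[counts$dose == pr[2], ]
    tab <- rbind(c(a$n_arrhythmic, a$n_total - a$n_arrhythmic),
                 c(b$n_arrhythmic, b$n_total - b$n_arrhythmic))
    if (any(colSums(tab) == 0)) {
      stat <- 0; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      stat <- unname(ct$statistic); p <- ct$p.value
    }
    tibble::tibble(dose_a = pr[1], dose_b = pr[2], statistic = stat,
                   p_value = p)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(stars = signif_stars(.data$p_value))
}
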