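#' Pearson correlation with t-based significance
#'
#' Product-moment correlation of two numeric vectors with the least-squares
#' regression line and a two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' With fewer than 3 pairs `r` is still reported but the p-value is `NA`.
#'
#' @param x,y Numeric vectors of equal length (at least 2), each
#'   non-constant.
#' @param x_name,y_name Labels carried into the result.
#' @return An object of class `repeat_cor` with fields `x_name`, `y_name`,
#'   `n`, `r`, `t_stat`, `p_value`, `slope`, `intercept` and the paired
#'   `data`. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' pearson_cor(c(1, 2, 3), c(3, 2, 1))
#' @export
pearson_cor <- function(x, y, x_name = "x", y_name = "y") {
  if (!is.numeric(x) || !is.numeric(y)) abort("`x` and `y` must be numeric")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  if (n < 2) abort("need at least 2 complete pairs")
  if (sd(x) == 0) abort(sprintf("`%s` is constant; r is undefined", x_name))
  if (sd(y) == 0) abort(sprintf("`%s` is constant; r is undefined", y_name))

  r <- cor(x, y)
  if (n >= 3 && abs(r) < 1) {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  } else if (n >= 3) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- NA_real_
    p <- NA_real_
  }
  slope <- r * sd(y) / sd(x)
  structure(
    list(x_name = x_name, y_name = y_name, n = n, r = r, t_stat = t_stat,
         p_value = p, slope = slope, intercept = mean(y) - slope * mean(x),
         data = tibble::tibble(x = x, y = y)),
    class = "repeat_cor"
  )
}

#' @export
print.repeat_cor <- function(x, ...) {
  cat(sprintf("<repeat_cor> %s ~ %s: r = %.4f, n = %d, p = %.4g\n",
              x$y_name, x$x_name, x$r, x$n, x$p_value))
  invisible(x)
}

#' @export
tidy.repeat_cor <- function(x, ...) {
  tibble::tibble(x_name = x$x_name, y_name = x$y_name, n = x$n,
                 estimate = x$r, statistic = x$t_stat, p.value = x$p_value,
                 slope = x$slope, intercept = x$intercept)
}

#' @export
glance.repeat_cor <- function(x, ...) {
  tibble::tibble(n = x$n, r = x$r, p.value = x$p_value)
}

#' @export
autoplot.repeat_cor <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "#D7261E") +
    ggplot2::labs(
      x = object$x_name, y = object$y_name,
      subtitle = sprintf("r = %.3f, n = %d, p = %.3g",
                         object$r, object$n, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Read a cohort phenotype table
#'
#' Tab-separated table with columns `individual_id` and `aao_years` (age at
#' myoclonus onset, years).
#'
#' @param path Input TSV path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(ph, c("individual_id", "aao_years"), "read_phenotypes")
  ph$individual_id <- as.character(ph$individual_id)
  ph
}

#' Genotype-phenotype correlations across a cohort
#'
#' Computes the four standard panels on carrier individuals: age at onset
#' against the median TTTCA count, the median TTTTA count and the median
#' expansion size (bp), plus the TTTCA-count against TTTTA-count panel.
#' Non-carriers and individuals without an age at onset are dropped with a
#' warning. P-values are two-sided and reported without multiple-testing
#' correction across the four panels.
#'
#' @param genotypes Genotype table from [summarize_genotypes()].
#' @param phenotypes Tibble with `individual_id` and `aao_years`.
#' @return A tibble with one row per panel (`x_name`, `y_name`, `n`, `r`,
#'   `t_stat`, `p_value`, `slope`, `intercept`), carrying the fitted
#'   `repeat_cor` objects in the `panels` attribute and the merged
#'   per-individual data in the `data` attribute.
#' @export
correlate_cohort <- function(genotypes, phenotypes) {
  check_columns(genotypes, c("individual_id", "carrier", "median_tttca",
                             "median_tttta", "median_size_bp"),
                "correlate_cohort")
  check_columns(phenotypes, c("individual_id", "aao_years"),
                "correlate_cohort")

  merged <- dplyr::left_join(genotypes, phenotypes, by = "individual_id")
  dropped <- merged$individual_id[!merged$carrier | is.na(merged$aao_years)]
  if (length(dropped) > 0) {
    warn(sprintf("dropping %d individual(s) without carrier status or AAO: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  usable <- merged[merged$carrier & !is.na(merged$aao_years), ]
  if (nrow(usable) < 3) {
    abort(sprintf(
      "need at least 3 carrier individuals with AAO (have %d); excluded: %s",
      nrow(usable),
      if (length(dropped)) paste(dropped, collapse = ", ") else "none"))
  }

  panels <- list(
    pearson_cor(usable$aao_years, usable$median_tttca,
                "aao_years", "median_tttca"),
    pearson_cor(usable$aao_years, usable$median_tttta,
                "aao_years", "median_tttta"),
    pearson_cor(usable$aao_years, usable$median_size_bp,
                "aao_years", "median_size_bp"),
    pearson_cor(usable$median_tttta, usable$median_tttca,
                "median_tttta", "median_tttca")
  )
  out <- dplyr::bind_rows(lapply(panels, tidy)) |>
    dplyr::rename(r = "estimate", t_stat = "statistic",
                  p_value = "p.value")
  attr(out, "panels") <- panels
  attr(out, "data") <- usable
  out
}

#' Plot the four cohort correlation panels
#'
#' Scatter plots with fitted least-squares lines for each panel produced by
#' [correlate_cohort()].
#'
#' @param cors Result of [correlate_cohort()].
#' @return A ggplot object (faceted).
#' @export
plot_cohort_correlations <- function(cors) {
  panels <- attr(cors, "panels")
  if (is.null(panels)) {
    abort("`cors` must be the direct result of correlate_cohort()")
  }
  df <- dplyr::bind_rows(lapply(panels, function(p) {
    dplyr::mutate(p$data,
                  panel = sprintf("%s ~ %s (r = %.2f)",
                                  p$y_name, p$x_name, p$r))
  }))
  lines <- dplyr::bind_rows(lapply(panels, function(p) {
    tibble::tibble(panel = sprintf("%s ~ %s (r = %.2f)",
                                   p$y_name, p$x_name, p$r),
                   slope = p$slope, intercept = p$intercept)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept),
                         colour = "#D7261E") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Write the correlation report
#'
#' @param cors Result of [correlate_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_report <- function(cors, path) {
  check_columns(cors, c("x_name", "y_name", "n", "r", "p_value"),
                "write_correlation_report")
  readr::write_tsv(as.data.frame(cors), path)
  invisible(path)
}
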