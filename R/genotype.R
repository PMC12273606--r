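#' Tukey box-plot statistics
#'
#' Quartiles use linear interpolation (R quantile type 7); the median uses
#' the lower-median convention so that every reported value is an attainable
#' integer unit count. Whiskers extend to the most extreme data points
#' within 1.5 IQR of the quartiles; points beyond are outliers.
#'
#' @param values Numeric vector with at least one value.
#' @return One-row tibble: `q1`, `median`, `q3`, `whisker_low`,
#'   `whisker_high`, `n_outliers`.
#' @examples
#' boxplot_stats(1:9)
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("`values` must contain at least one value")
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  tibble::tibble(
    q1 = q[1],
    median = median_lower(values),
    q3 = q[2],
    whisker_low = min(values[values >= lo]),
    whisker_high = max(values[values <= hi]),
    n_outliers = sum(values < lo | values > hi)
  )
}

#' Somatic mosaicism metrics
#'
#' Per-read repeat-count dispersion within one individual's expanded-allele
#' reads. `frac_reads_high_tttca` operationalizes the "reads with a higher
#' number of TTTCA repeats" phenomenon as the fraction of reads whose TTTCA
#' count exceeds the (lower) median by more than `mosaic_delta` units.
#'
#' @param tttca_counts,tttta_counts Integer vectors of per-read unit counts
#'   from expanded-class reads.
#' @param mosaic_delta Units above the median that count as a high-TTTCA
#'   read (default 3).
#' @return One-row tibble: `tttca_iqr`, `tttta_iqr`, `tttca_range`,
#'   `tttta_range`, `frac_reads_high_tttca`. All `NA` when fewer than two
#'   reads are available.
#' @export
mosaicism_metrics <- function(tttca_counts, tttta_counts, mosaic_delta = 3) {
  check_number(mosaic_delta, "mosaic_delta", lower = 0, integer = TRUE)
  if (length(tttca_counts) < 2 || length(tttta_counts) < 2) {
    return(tibble::tibble(tttca_iqr = NA_real_, tttta_iqr = NA_real_,
                          tttca_range = NA_real_, tttta_range = NA_real_,
                          frac_reads_high_tttca = NA_real_))
  }
  iqr7 <- function(x) {
    q <- unname(quantile(x, c(0.25, 0.75), type = 7))
    q[2] - q[1]
  }
  med <- median_lower(tttca_counts)
  tibble::tibble(
    tttca_iqr = iqr7(tttca_counts),
    tttta_iqr = iqr7(tttta_counts),
    tttca_range = diff(range(tttca_counts)),
    tttta_range = diff(range(tttta_counts)),
    frac_reads_high_tttca = mean(tttca_counts > med + mosaic_delta)
  )
}

#' Summarize repeat genotypes per individual
#'
#' Aggregates classified reads into one genotype row per individual. Count
#' summaries (medians, quartiles, whiskers, mosaicism metrics) are computed
#' over expanded-class reads only, since they describe the expansion-bearing
#' allele; the short allele is summarized separately for completeness. The
#' expansion size in bp is `5 * (median_tttta + median_tttca)`. An
#' individual is called a carrier when at least `min_support` reads land in
#' the expanded class. Individuals without expanded reads get `carrier =
#' FALSE` and `NA` (not zero) medians.
#'
#' @param assignments Classified decomposition table from
#'   [classify_reads()], with an `individual_id` column.
#' @param min_support Minimum expanded-read support for a carrier call
#'   (default 10).
#' @param mosaic_delta Passed to [mosaicism_metrics()].
#' @return A tibble with one row per individual: read counts per allele
#'   class, `median_tttta`, `median_tttca`, `median_size_bp`, quartiles,
#'   whiskers and outlier counts per motif, mosaicism metrics,
#'   `short_median_tttta`, and `carrier`.
#' @export
summarize_genotypes <- function(assignments, min_support = 10,
                                mosaic_delta = 3) {
  check_columns(assignments,
                c("read_id", "individual_id", "allele_class",
                  "n_TTTTA", "n_TTTCA"),
                "summarize_genotypes")
  check_number(min_support, "min_support", lower = 1, integer = TRUE)

  if (nrow(assignments) == 0) {
    abort("`assignments` has no rows; pass at least one classified read")
  }
  assignments |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_modify(function(df, key) {
      summarize_one(df, min_support, mosaic_delta)
    }) |>
    dplyr::ungroup()
}

summarize_one <- function(df, min_support, mosaic_delta) {
  exp_reads <- df[df$allele_class == "expanded", ]
  short_reads <- df[df$allele_class == "short", ]
  n_exp <- nrow(exp_reads)

  base <- tibble::tibble(
    n_reads_total = nrow(df),
    n_reads_expanded = n_exp,
    n_reads_short = nrow(short_reads),
    n_reads_ambiguous = sum(df$allele_class == "ambiguous"),
    carrier = n_exp >= min_support
  )

  if (n_exp == 0) {
    stats <- tibble::tibble(
      median_tttta = NA_real_, median_tttca = NA_real_,
      median_size_bp = NA_real_,
      tttta_q1 = NA_real_, tttta_q3 = NA_real_,
      tttta_whisker_low = NA_real_, tttta_whisker_high = NA_real_,
      tttta_n_outliers = NA_integer_,
      tttca_q1 = NA_real_, tttca_q3 = NA_real_,
      tttca_whisker_low = NA_real_, tttca_whisker_high = NA_real_,
      tttca_n_outliers = NA_integer_
    )
    mos <- mosaicism_metrics(integer(0), integer(0), mosaic_delta)
  } else {
    bs_a <- boxplot_stats(exp_reads$n_TTTTA)
    bs_c <- boxplot_stats(exp_reads$n_TTTCA)
    stats <- tibble::tibble(
      median_tttta = bs_a$median, median_tttca = bs_c$median,
      median_size_bp = 5 * (bs_a$median + bs_c$median),
      tttta_q1 = bs_a$q1, tttta_q3 = bs_a$q3,
      tttta_whisker_low = bs_a$whisker_low,
      tttta_whisker_high = bs_a$whisker_high,
      tttta_n_outliers = bs_a$n_outliers,
      tttca_q1 = bs_c$q1, tttca_q3 = bs_c$q3,
      tttca_whisker_low = bs_c$whisker_low,
      tttca_whisker_high = bs_c$whisker_high,
      tttca_n_outliers = bs_c$n_outliers
    )
    mos <- mosaicism_metrics(exp_reads$n_TTTCA, exp_reads$n_TTTTA,
                             mosaic_delta)
  }

  short_median <- if (nrow(short_reads) > 0) {
    median_lower(short_reads$n_TTTTA)
  } else {
    NA_real_
  }

  dplyr::bind_cols(base, stats, mos,
                   tibble::tibble(short_median_tttta = short_median))
}

#' Summarize a single individual
#'
#' Convenience wrapper around [summarize_genotypes()] for reads from one
#' individual (the `individual_id` column may be absent).
#'
#' @inheritParams summarize_genotypes
#' @param individual_id Label used when the column is absent.
#' @return A one-row genotype tibble.
#' @export
summarize_individual <- function(assignments, min_support = 10,
                                 mosaic_delta = 3,
                                 individual_id = "individual") {
  if (!"individual_id" %in% names(assignments) ||
      all(is.na(assignments$individual_id))) {
    assignments$individual_id <- individual_id
  }
  summarize_genotypes(assignments, min_support, mosaic_delta)
}

#' Write the per-individual genotype report
#'
#' @param genotypes Output of [summarize_genotypes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_report <- function(genotypes, path) {
  check_columns(genotypes, c("individual_id", "carrier"),
                "write_genotype_report")
  readr::write_tsv(genotypes, path)
  invisible(path)
}

#' Box plots of per-read repeat counts
#'
#' Distribution of per-read TTTTA and TTTCA unit counts over expanded-class
#' reads, one box per individual and motif.
#'
#' @param assignments Classified decomposition table with `individual_id`.
#' @return A ggplot object.
#' @export
plot_repeat_distributions <- function(assignments) {
  check_columns(assignments, c("individual_id", "allele_class",
                               "n_TTTTA", "n_TTTCA"),
                "plot_repeat_distributions")
  df <- assignments |>
    dplyr::filter(.data$allele_class == "expanded") |>
    dplyr::select("individual_id", TTTTA = "n_TTTTA", TTTCA = "n_TTTCA") |>
    tidyr::pivot_longer(c("TTTTA", "TTTCA"), names_to = "motif",
                        values_to = "units")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$individual_id,
                                   y = .data$units)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~motif, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "repeat units per read") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
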