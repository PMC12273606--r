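#' Assign reads to the expanded or short allele
#'
#' Applies the consecutive-TTTCA separation rule: a read belongs to the
#' expanded (pathogenic-type) allele when its longest run of consecutive
#' `TTTCA` units reaches `ttca_min_run` (default 2), and to the short
#' (TTTTA-only) allele otherwise. Reads spanning fewer than
#' `min_total_units` motif units are too short to be informative and are
#' classed `ambiguous` regardless of their TTTCA content. Interrupted TTTCA
#' runs do not concatenate: the rule uses the maximum single run.
#'
#' @param decs Decomposition table from [decompose_reads()].
#' @param ttca_min_run Minimum consecutive TTTCA units for the expanded
#'   class (at least 1).
#' @param min_total_units Minimum number of motif units a read must span.
#' @param motif The discriminating motif (default `"TTTCA"`).
#' @return The input tibble with added columns `max_tttca_run`,
#'   `total_units` and `allele_class`
#'   (`"expanded"`/`"short"`/`"ambiguous"`).
#' @export
classify_reads <- function(decs, ttca_min_run = 2, min_total_units = 20,
                           motif = "TTTCA") {
  check_columns(decs, c("read_id", "runs", "n_units_total"), "classify_reads")
  check_number(ttca_min_run, "ttca_min_run", lower = 1, integer = TRUE)
  check_number(min_total_units, "min_total_units", lower = 0, integer = TRUE)

  decs$max_tttca_run <- if (nrow(decs)) {
    unname(max_consecutive(decs, motif))
  } else {
    integer()
  }
  decs$total_units <- unname(decs$n_units_total)
  decs$allele_class <- dplyr::case_when(
    decs$total_units < min_total_units ~ "ambiguous",
    decs$max_tttca_run >= ttca_min_run ~ "expanded",
    TRUE ~ "short"
  )
  decs
}

#' Partition one individual's reads by allele class
#'
#' Deterministic element-wise partition consistent with [classify_reads()].
#'
#' @param decs Decomposition table; classified with [classify_reads()]
#'   first when the `allele_class` column is absent (passing `...` on).
#' @param ... Parameters forwarded to [classify_reads()].
#' @return A named list with tibbles `expanded`, `short` and `ambiguous`
#'   (always all three, possibly with zero rows).
#' @export
separate_alleles <- function(decs, ...) {
  if (!"allele_class" %in% names(decs)) decs <- classify_reads(decs, ...)
  out <- lapply(c(expanded = "expanded", short = "short",
                  ambiguous = "ambiguous"),
                function(cl) decs[decs$allele_class == cl, , drop = FALSE])
  out
}

#' Write the per-read allele assignment report
#'
#' @param assignments Output of [classify_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  check_columns(assignments, c("read_id", "allele_class", "max_tttca_run",
                               "total_units"), "write_assignments")
  readr::write_tsv(
    dplyr::select(assignments, "read_id", "allele_class", "max_tttca_run",
                  "total_units"),
    path
  )
  invisible(path)
}
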