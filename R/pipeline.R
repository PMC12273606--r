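#' Default pipeline parameters
#'
#' One place for every stage threshold, so a minimal run needs no tuning.
#'
#' @param ... Overrides of individual parameters by name.
#' @return A named list: `max_flank_edit_frac` (`NULL` = take from the
#'   locus config), `per_unit_max_edits`, `other_cost`, `include_partial`,
#'   `smooth_interruptions`, `ttca_min_run`, `min_total_units`,
#'   `min_support`, `mosaic_delta`.
#' @export
default_params <- function(...) {
  params <- list(
    max_flank_edit_frac = NULL,
    per_unit_max_edits = 2,
    other_cost = 2,
    include_partial = FALSE,
    smooth_interruptions = TRUE,
    ttca_min_run = 2,
    min_total_units = 20,
    min_support = 10,
    mosaic_delta = 3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown) > 0) {
    abort(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  params[names(dots)] <- dots
  params
}

#' Run the per-individual genotyping pipeline
#'
#' Executes orient -> trim -> decompose -> classify -> summarize on one
#' individual's reads. Deterministic: identical inputs and parameters give
#' identical outputs. When no read survives trimming the genotype row is
#' still produced, with `carrier = FALSE` and a warning.
#'
#' @param reads Read tibble (`read_id`, `bases`, optionally
#'   `individual_id`).
#' @param cfg A [locus_config()].
#' @param params Parameter list from [default_params()].
#' @param individual_id Label used if the reads carry none.
#' @param outdir Optional directory; when given, per-stage TSV reports are
#'   written (`trim.tsv`, `decomposition.tsv`, `assignments.tsv`,
#'   `genotype.tsv`).
#' @return A list with `trims`, `decompositions`, `assignments` and the
#'   one-row `genotype` tibble.
#' @export
run_individual <- function(reads, cfg, params = default_params(),
                           individual_id = "individual", outdir = NULL) {
  stopifnot(inherits(cfg, "locus_config"))
  check_columns(reads, c("read_id", "bases"), "run_individual")
  if (!"individual_id" %in% names(reads) || all(is.na(reads$individual_id))) {
    reads$individual_id <- individual_id
  }
  iid <- reads$individual_id[1]

  trims <- trim_flanks(reads, cfg,
                       max_flank_edit_frac = params$max_flank_edit_frac)
  decs <- decompose_reads(trims, cfg,
                          per_unit_max_edits = params$per_unit_max_edits,
                          other_cost = params$other_cost,
                          include_partial = params$include_partial,
                          smooth_interruptions = params$smooth_interruptions)
  assignments <- classify_reads(decs,
                                ttca_min_run = params$ttca_min_run,
                                min_total_units = params$min_total_units)

  if (nrow(assignments) == 0) {
    warn(sprintf("individual '%s': no read survived trimming; carrier = FALSE",
                 iid))
    genotype <- empty_genotype_row(iid)
  } else {
    genotype <- summarize_genotypes(assignments,
                                    min_support = params$min_support,
                                    mosaic_delta = params$mosaic_delta)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_trim_report(trims, file.path(outdir, "trim.tsv"))
    write_decomposition_report(decs, file.path(outdir, "decomposition.tsv"))
    write_assignments(assignments, file.path(outdir, "assignments.tsv"))
    write_genotype_report(genotype, file.path(outdir, "genotype.tsv"))
  }

  list(trims = trims, decompositions = decs, assignments = assignments,
       genotype = genotype)
}

empty_genotype_row <- function(individual_id) {
  dplyr::bind_cols(
    tibble::tibble(individual_id = individual_id, n_reads_total = 0L,
                   n_reads_expanded = 0L, n_reads_short = 0L,
                   n_reads_ambiguous = 0L, carrier = FALSE),
    tibble::tibble(median_tttta = NA_real_, median_tttca = NA_real_,
                   median_size_bp = NA_real_,
                   tttta_q1 = NA_real_, tttta_q3 = NA_real_,
                   tttta_whisker_low = NA_real_,
                   tttta_whisker_high = NA_real_,
                   tttta_n_outliers = NA_integer_,
                   tttca_q1 = NA_real_, tttca_q3 = NA_real_,
                   tttca_whisker_low = NA_real_,
                   tttca_whisker_high = NA_real_,
                   tttca_n_outliers = NA_integer_,
                   tttca_iqr = NA_real_, tttta_iqr = NA_real_,
                   tttca_range = NA_real_, tttta_range = NA_real_,
                   frac_reads_high_tttca = NA_real_,
                   short_median_tttta = NA_real_)
  )
}

#' Run the cohort pipeline end-to-end
#'
#' Runs [run_individual()] for every individual in the read table, binds
#' the genotype rows, and — when at least three carriers have an age at
#' onset — computes the four genotype-phenotype correlation panels.
#' Results are independent of the order in which individuals are
#' processed. A manifest with the resolved parameters is written alongside
#' the reports when `outdir` is given.
#'
#' @param reads Read tibble for the whole cohort (must carry
#'   `individual_id`).
#' @param phenotypes Tibble with `individual_id` and `aao_years` (or `NULL`
#'   to skip correlations).
#' @param cfg A [locus_config()].
#' @param params Parameter list from [default_params()].
#' @param outdir Optional output directory; writes `genotypes.tsv`,
#'   `correlations.tsv` (when computed), `manifest.yaml` and per-individual
#'   stage reports under `individuals/<id>/`.
#' @return A list with `genotypes`, `correlations` (or `NULL`) and
#'   `individuals` (per-individual stage results).
#' @export
run_cohort <- function(reads, phenotypes = NULL, cfg = example_locus(),
                       params = default_params(), outdir = NULL) {
  check_columns(reads, c("read_id", "bases", "individual_id"), "run_cohort")
  ids <- unique(reads$individual_id)
  individuals <- lapply(ids, function(id) {
    run_individual(reads[reads$individual_id == id, ], cfg, params,
                   individual_id = id,
                   outdir = if (is.null(outdir)) NULL else
                     file.path(outdir, "individuals", id))
  })
  names(individuals) <- ids
  genotypes <- dplyr::bind_rows(lapply(individuals, `[[`, "genotype"))

  correlations <- NULL
  if (!is.null(phenotypes)) {
    correlations <- tryCatch(
      suppressWarnings(correlate_cohort(genotypes, phenotypes)),
      error = function(e) {
        warn(sprintf("correlations skipped: %s", conditionMessage(e)))
        NULL
      }
    )
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_genotype_report(genotypes, file.path(outdir, "genotypes.tsv"))
    if (!is.null(correlations)) {
      write_correlation_report(correlations,
                               file.path(outdir, "correlations.tsv"))
    }
    manifest <- list(
      package = "pentarep",
      version = as.character(utils::packageVersion("pentarep")),
      locus = cfg$locus_name,
      motifs = cfg$motifs,
      params = params[!vapply(params, is.null, logical(1))],
      n_individuals = length(ids),
      n_reads = nrow(reads)
    )
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }

  list(genotypes = genotypes, correlations = correlations,
       individuals = individuals)
}
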