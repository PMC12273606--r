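#' Repeat-primed PCR primer model
#'
#' A generic model of an RP-PCR repeat primer: `units_in_primer` copies of
#' the repeat unit (default `TTTCA`) that anneal wherever that many
#' consecutive units match the template with at most `max_mismatches`
#' substitutions, plus an optional locus-specific anchor contributing fixed
#' fragment length.
#'
#' @param unit Repeat unit pentamer.
#' @param units_in_primer Number of unit copies in the primer (the repeat
#'   part must be at least 10 bp, i.e. at least 2 units).
#' @param max_mismatches Mismatches tolerated across the repeat part
#'   (substitution-only annealing model).
#' @param anchor_len Length in bp of the anchored (non-repeat) primer part.
#' @return An object of class `primer_model`.
#' @export
primer_model <- function(unit = "TTTCA", units_in_primer = 4,
                         max_mismatches = 0, anchor_len = 0) {
  unit <- normalize_bases(check_string(unit, "unit"))
  check_dna(unit, "unit", allow_n = FALSE)
  if (nchar(unit) != 5) abort("`unit` must be a pentamer")
  check_number(units_in_primer, "units_in_primer", lower = 2, integer = TRUE)
  check_number(max_mismatches, "max_mismatches", lower = 0, integer = TRUE)
  if (max_mismatches >= units_in_primer * 5) {
    abort("`max_mismatches` must be smaller than the repeat part of the primer")
  }
  check_number(anchor_len, "anchor_len", lower = 0, integer = TRUE)
  structure(
    list(unit = unit, units_in_primer = as.integer(units_in_primer),
         max_mismatches = as.integer(max_mismatches),
         anchor_len = as.integer(anchor_len)),
    class = "primer_model"
  )
}

#' @export
print.primer_model <- function(x, ...) {
  cat(sprintf("<primer_model> (%s)x%d + %d bp anchor, <= %d mismatch(es)\n",
              x$unit, x$units_in_primer, x$anchor_len, x$max_mismatches))
  invisible(x)
}

#' Enumerate repeat-primer annealing sites
#'
#' All 0-based start offsets on the template where `units_in_primer`
#' consecutive copies of the unit match with at most `max_mismatches` total
#' substitutions.
#'
#' @param template DNA template string.
#' @param primer A [primer_model()].
#' @return Integer vector of 0-based offsets (possibly empty).
#' @examples
#' enumerate_priming_sites(strrep("TTTCA", 10), primer_model())
#' @export
enumerate_priming_sites <- function(template, primer) {
  stopifnot(inherits(primer, "primer_model"))
  template <- normalize_bases(check_string(template, "template"))
  if (!nzchar(template)) abort("`template` must be non-empty")
  probe <- strrep(primer$unit, primer$units_in_primer)
  mm <- hamming_scan_cpp(template, probe)
  if (length(mm) == 0) return(integer(0))
  which(mm <= primer$max_mismatches) - 1L
}

#' Simulate a repeat-primed PCR fragment ladder
#'
#' One fragment per annealing site, of length equal to the site offset from
#' the template's fixed (5') end plus the primer length plus
#' `fixed_tail_bp` (the locus primer side and any anchored tail). On clean
#' repeat templates the peaks are spaced exactly one unit (5 bp) apart.
#' The qualitative profile mirrors diagnostic usage: `absent` (no sites),
#' `truncated` (a sawtooth that stops after at most `truncation_threshold`
#' peaks, as with a short TTTCA insertion), or `continuous` (the classical
#' pattern of a long TTTCA expansion).
#'
#' @param template DNA template string.
#' @param primer A [primer_model()].
#' @param fixed_tail_bp Fixed length contribution of the opposite primer
#'   (default 60).
#' @param truncation_threshold Maximum number of peaks still called
#'   `truncated` (default 15).
#' @param decay Optional per-peak amplification-efficiency decay factor in
#'   (0, 1]; peak intensity is `decay^(k-1)` for the k-th peak. `NULL`
#'   (default) disables decay and reports site counts.
#' @return An object of class `ladder_profile`: a tibble of peaks
#'   (`length_bp`, `intensity`) with attributes `n_sites` and `pattern`.
#' @examples
#' simulate_ladder(strrep("TTTCA", 200), primer_model())
#' @export
simulate_ladder <- function(template, primer, fixed_tail_bp = 60,
                            truncation_threshold = 15, decay = NULL) {
  stopifnot(inherits(primer, "primer_model"))
  check_number(fixed_tail_bp, "fixed_tail_bp", lower = 0, integer = TRUE)
  check_number(truncation_threshold, "truncation_threshold", lower = 1,
               integer = TRUE)
  if (!is.null(decay)) check_number(decay, "decay", lower = 1e-6, upper = 1)

  sites <- enumerate_priming_sites(template, primer)
  n_sites <- length(sites)
  primer_len <- 5L * primer$units_in_primer + primer$anchor_len
  if (n_sites == 0) {
    peaks <- tibble::tibble(length_bp = integer(), intensity = numeric())
  } else {
    len <- sort(unique(sites)) + primer_len + fixed_tail_bp
    counts <- as.integer(table(sites + primer_len + fixed_tail_bp))
    intensity <- as.numeric(counts)
    if (!is.null(decay)) intensity <- intensity * decay^(seq_along(len) - 1)
    peaks <- tibble::tibble(length_bp = len, intensity = intensity)
  }
  pattern <- if (n_sites == 0) {
    "absent"
  } else if (n_sites <= truncation_threshold) {
    "truncated"
  } else {
    "continuous"
  }
  structure(peaks, n_sites = n_sites, pattern = pattern,
            class = c("ladder_profile", class(peaks)))
}

#' @export
print.ladder_profile <- function(x, ...) {
  cat(sprintf("<ladder_profile> %d site(s), pattern: %s\n",
              attr(x, "n_sites"), attr(x, "pattern")))
  NextMethod()
}

#' @export
glance.ladder_profile <- function(x, ...) {
  tibble::tibble(n_sites = attr(x, "n_sites"), pattern = attr(x, "pattern"),
                 n_peaks = nrow(x))
}

#' Write a ladder profile as TSV
#'
#' @param ladder A [simulate_ladder()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ladder_tsv <- function(ladder, path) {
  check_columns(ladder, c("length_bp", "intensity"), "write_ladder_tsv")
  readr::write_tsv(tibble::as_tibble(ladder), path)
  invisible(path)
}

#' Plot an RP-PCR ladder profile
#'
#' @param ladder A [simulate_ladder()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ladder <- function(ladder, ...) {
  stopifnot(inherits(ladder, "ladder_profile"))
  df <- tibble::as_tibble(ladder)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_bp,
                                   ymax = .data$intensity, ymin = 0)) +
    ggplot2::geom_linerange() +
    ggplot2::labs(x = "fragment length (bp)", y = "intensity",
                  subtitle = sprintf("pattern: %s", attr(ladder, "pattern"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ladder_profile <- function(object, ...) plot_ladder(object, ...)
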