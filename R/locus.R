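#' Locus configuration for a pentanucleotide repeat tract
#'
#' A locus configuration names the repeat locus, fixes its genomic interval
#' (0-based, half-open), and carries the two flanking sequences that anchor
#' the repeat tract in each amplicon read, the ordered motif alphabet used
#' for decomposition, and the flank-matching stringency.
#'
#' The motif order is a priority order: when two motifs explain a window of
#' read sequence at equal edit cost, the earlier motif wins. The default
#' order puts `TTTCA` first so that `TTTCA`/`TTTTA` junctions resolve toward
#' the clinically decisive motif.
#'
#' @param locus_name Locus label, e.g. the gene harbouring the repeat.
#' @param flank5,flank3 Uppercase DNA immediately 5' / 3' of the repeat
#'   tract; each must be at least 15 bp so that semiglobal matching is
#'   specific.
#' @param chrom,start,end,strand Genomic interval of the tract (0-based,
#'   half-open).
#' @param assembly Genome assembly label.
#' @param motifs Ordered character vector of pentamer motifs (priority
#'   order, no duplicates).
#' @param max_flank_edit_frac Maximum edit distance for a flank match,
#'   expressed as a fraction of the flank length; in `[0, 0.3]`.
#' @return An object of class `locus_config`.
#' @seealso [trim_flanks()], [decompose_reads()], [example_locus()]
#' @examples
#' cfg <- locus_config(
#'   locus_name = "toy",
#'   flank5 = "ACGTACGTACGTACGTACGT",
#'   flank3 = "TGCATGCATGCATGCATGCA"
#' )
#' cfg
#' @export
locus_config <- function(locus_name = "locus",
                         flank5,
                         flank3,
                         chrom = "chrUn",
                         start = 0L,
                         end = 0L,
                         strand = "+",
                         assembly = "unknown",
                         motifs = c("TTTCA", "TTTTA", "TTTTG", "TTATG"),
                         max_flank_edit_frac = 0.25) {
  check_string(locus_name, "locus_name")
  check_string(assembly, "assembly")
  check_string(chrom, "chrom")
  check_string(strand, "strand")
  if (!strand %in% c("+", "-", ".")) abort("`strand` must be '+', '-' or '.'")
  check_number(start, "start", lower = 0, integer = TRUE)
  check_number(end, "end", lower = start, integer = TRUE)
  check_number(max_flank_edit_frac, "max_flank_edit_frac", 0, 0.3)

  flank5 <- normalize_bases(check_string(flank5, "flank5"))
  flank3 <- normalize_bases(check_string(flank3, "flank3"))
  check_dna(flank5, "flank5", allow_n = FALSE)
  check_dna(flank3, "flank3", allow_n = FALSE)
  if (nchar(flank5) < 15 || nchar(flank3) < 15) {
    abort("flank5 and flank3 must each be at least 15 bp")
  }

  motifs <- normalize_bases(motifs)
  if (length(motifs) < 1 || anyDuplicated(motifs) > 0) {
    abort("`motifs` must be a non-empty vector without duplicates")
  }
  if (any(nchar(motifs) != 5)) abort("every motif must be a pentamer")
  check_dna(motifs, "motif", allow_n = FALSE)

  structure(
    list(
      locus_name = locus_name, assembly = assembly,
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = strand,
      flank5 = flank5, flank3 = flank3,
      motifs = motifs,
      max_flank_edit_frac = max_flank_edit_frac
    ),
    class = "locus_config"
  )
}

#' @export
print.locus_config <- function(x, ...) {
  cat(sprintf("<locus_config> %s (%s %s:%d-%d%s)\n",
              x$locus_name, x$assembly, x$chrom, x$start, x$end, x$strand))
  cat(sprintf("  flank5: %s (%d bp)\n", x$flank5, nchar(x$flank5)))
  cat(sprintf("  flank3: %s (%d bp)\n", x$flank3, nchar(x$flank3)))
  cat(sprintf("  motifs: %s\n", paste(x$motifs, collapse = " > ")))
  cat(sprintf("  max_flank_edit_frac: %g\n", x$max_flank_edit_frac))
  invisible(x)
}

#' Synthetic example locus
#'
#' A ready-made configuration for a FAME-type pentanucleotide repeat locus
#' with invented (synthetic) 30 bp flanking sequences. It is intended for
#' examples, tests and simulation; the flanks are not the sequence of any
#' real locus.
#'
#' @return A [locus_config()].
#' @examples
#' example_locus()
#' @export
example_locus <- function() {
  locus_config(
    locus_name = "FAME_repeat_synthetic",
    assembly = "synthetic",
    chrom = "chrS", start = 10000L, end = 10030L, strand = "+",
    flank5 = "GATCGGAAGAGCACACGTCTGAACTCCAGT",
    flank3 = "ATCTCGTATGCCGTCTTCTGCTTGAAAGCA"
  )
}

#' Read or write a locus configuration file
#'
#' Locus configurations are stored as plain YAML mirroring the
#' [locus_config()] fields.
#'
#' @param path File path.
#' @return `read_locus_config()` returns a [locus_config()];
#'   `write_locus_config()` returns `path` invisibly.
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' does not exist", path))
  y <- yaml::read_yaml(path)
  needed <- c("locus_name", "flank5", "flank3")
  missing <- setdiff(needed, names(y))
  if (length(missing) > 0) {
    abort(sprintf("config is missing field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  do.call(locus_config, y)
}

#' @rdname read_locus_config
#' @param cfg A [locus_config()].
#' @export
write_locus_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "locus_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Export the locus interval as 6-column BED
#'
#' Returns the configured genomic interval as one BED record (0-based,
#' half-open) and optionally writes it to a headerless tab-separated file.
#'
#' @param cfg A [locus_config()].
#' @param path Optional output path; when given, the record is written as a
#'   BED line.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
locus_to_bed <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "locus_config"))
  bed <- tibble::tibble(
    chrom = cfg$chrom, start = cfg$start, end = cfg$end,
    name = cfg$locus_name, score = 0L,
    strand = if (cfg$strand == ".") "." else cfg$strand
  )
  if (!is.null(path)) {
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  bed
}
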