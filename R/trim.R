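#' Orient amplicon reads to the forward strand
#'
#' LR-PCR amplicon reads arrive in both orientations. A read is flipped to
#' its reverse complement when the 5' flank matches the reverse complement
#' better than the read itself (smaller best semiglobal edit distance);
#' ties keep the read as-is.
#'
#' @param reads Read tibble with at least `read_id` and `bases`.
#' @param cfg A [locus_config()].
#' @return The input tibble with `bases` on the forward strand and an added
#'   `orientation` column (`"forward"` or `"reverse"`).
#' @export
orient_reads <- function(reads, cfg) {
  stopifnot(inherits(cfg, "locus_config"))
  check_columns(reads, c("read_id", "bases"), "orient_reads")
  if (nrow(reads) == 0) {
    return(dplyr::mutate(reads, orientation = character()))
  }
  rc <- revcomp(reads$bases)
  d_fwd <- vapply(reads$bases, function(b) semiglobal_dist_cpp(cfg$flank5, b),
                  integer(1), USE.NAMES = FALSE)
  d_rev <- vapply(rc, function(b) semiglobal_dist_cpp(cfg$flank5, b),
                  integer(1), USE.NAMES = FALSE)
  flip <- d_rev < d_fwd # ties stay forward
  reads$orientation <- ifelse(flip, "reverse", "forward")
  reads$bases <- ifelse(flip, rc, reads$bases)
  if ("quals" %in% names(reads)) {
    reads$quals <- ifelse(flip & !is.na(reads$quals),
                          vapply(reads$quals, function(q) {
                            paste(rev(strsplit(q, "", fixed = TRUE)[[1]]),
                                  collapse = "")
                          }, character(1), USE.NAMES = FALSE),
                          reads$quals)
  }
  reads
}

#' Excise the repeat tract by aligning the flanking sequences
#'
#' Locates the best semiglobal occurrence of each flank in every read
#' (substitutions and indels, unit costs; `N` mismatches every base) and
#' reports the repeat tract strictly between them. A flank counts as found
#' when its edit distance is at most `max_flank_edit_frac * nchar(flank)`.
#' Tie-breaking is deterministic: the leftmost best occurrence for the 5'
#' flank and the rightmost best occurrence for the 3' flank.
#'
#' Reads are auto-oriented with [orient_reads()] if no `orientation` column
#' is present. Possible `status` values:
#' \describe{
#'   \item{both_flanks}{both flanks found in order; `tract` lies between them}
#'   \item{five_only}{only the 5' flank found; `tract` runs to the read end}
#'   \item{three_only}{only the 3' flank found; `tract` starts at the read start}
#'   \item{none}{no usable flank, or the two flank occurrences overlap}
#' }
#'
#' @param reads Read tibble (`read_id`, `bases`, optionally `orientation`,
#'   `individual_id`).
#' @param cfg A [locus_config()].
#' @param max_flank_edit_frac Override of the configured stringency.
#' @return A tibble with one row per read: `read_id`, `individual_id`,
#'   `orientation`, `status`, `tract`, `tract_length`, `flank5_edits`,
#'   `flank3_edits`. Edit counts are `NA` for flanks that were not accepted.
#' @examples
#' cfg <- example_locus()
#' reads <- tibble::tibble(
#'   read_id = "r1",
#'   bases = paste0(cfg$flank5, strrep("TTTTA", 8), cfg$flank3)
#' )
#' trim_flanks(reads, cfg)
#' @export
trim_flanks <- function(reads, cfg, max_flank_edit_frac = NULL) {
  stopifnot(inherits(cfg, "locus_config"))
  check_columns(reads, c("read_id", "bases"), "trim_flanks")
  frac <- max_flank_edit_frac %||% cfg$max_flank_edit_frac
  check_number(frac, "max_flank_edit_frac", 0, 0.3)
  if (!"orientation" %in% names(reads)) reads <- orient_reads(reads, cfg)
  iid <- if ("individual_id" %in% names(reads)) reads$individual_id else
    rep(NA_character_, nrow(reads))

  max5 <- frac * nchar(cfg$flank5)
  max3 <- frac * nchar(cfg$flank3)

  one <- function(bases) {
    h5 <- flank_hit_cpp(cfg$flank5, bases, leftmost = TRUE)
    h3 <- flank_hit_cpp(cfg$flank3, bases, leftmost = FALSE)
    ok5 <- h5$dist <= max5
    ok3 <- h3$dist <= max3
    n <- nchar(bases)
    if (ok5 && ok3) {
      if (h5$end > h3$start) {
        # overlapping flank occurrences: no clean tract
        return(list(status = "none", tract = "",
                    e5 = h5$dist, e3 = h3$dist))
      }
      list(status = "both_flanks",
           tract = substr(bases, h5$end + 1, h3$start),
           e5 = h5$dist, e3 = h3$dist)
    } else if (ok5) {
      list(status = "five_only", tract = substr(bases, h5$end + 1, n),
           e5 = h5$dist, e3 = NA_integer_)
    } else if (ok3) {
      list(status = "three_only", tract = substr(bases, 1, h3$start),
           e5 = NA_integer_, e3 = h3$dist)
    } else {
      list(status = "none", tract = "", e5 = NA_integer_, e3 = NA_integer_)
    }
  }

  res <- purrr::map(reads$bases, one)
  tract <- purrr::map_chr(res, "tract")
  tibble::tibble(
    read_id = reads$read_id,
    individual_id = iid,
    orientation = reads$orientation,
    status = purrr::map_chr(res, "status"),
    tract = tract,
    tract_length = nchar(tract),
    flank5_edits = purrr::map_int(res, function(r) as.integer(r$e5)),
    flank3_edits = purrr::map_int(res, function(r) as.integer(r$e3))
  )
}

#' Write the per-read trimming report
#'
#' Standard columns plus the extracted `tract` itself, so the downstream
#' decomposition stage can be re-run from this file alone.
#'
#' @param trims Output of [trim_flanks()].
#' @param path Output TSV path.
#' @param include_tract Include the `tract` column (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trim_report <- function(trims, path, include_tract = TRUE) {
  check_columns(trims, c("read_id", "orientation", "status", "tract_length",
                         "flank5_edits", "flank3_edits"), "write_trim_report")
  cols <- c("read_id", "individual_id", "orientation", "status",
            "tract_length", "flank5_edits", "flank3_edits",
            if (include_tract) "tract")
  readr::write_tsv(
    dplyr::select(trims, dplyr::any_of(cols)),
    path
  )
  invisible(path)
}

#' Minimal semiglobal edit distance
#'
#' Edit distance of `pattern` aligned end-to-end against the best-matching
#' substring of `subject` (substitutions and indels, unit costs). This is
#' the score that drives read orientation and flank matching.
#'
#' @param pattern,subject DNA strings.
#' @return A single integer.
#' @examples
#' semiglobal_dist("TTTCA", "GGGTTTCAGGG")
#' @export
semiglobal_dist <- function(pattern, subject) {
  check_string(pattern, "pattern")
  check_string(subject, "subject")
  semiglobal_dist_cpp(pattern, subject)
}
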