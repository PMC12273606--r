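#' Read amplicon reads from FASTA or FASTQ
#'
#' Loads sequencing reads (plain or gzip-compressed) into the tibble layout
#' used throughout the package: one row per read, with `read_id`, `bases`
#' (uppercase, RNA `U` mapped to `T`), `quals` (Phred+33 string, `NA` for
#' FASTA) and `individual_id`.
#'
#' @param path Input file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` to infer from the file
#'   extension.
#' @param individual_id Optional individual label attached to every read.
#' @return A tibble with columns `read_id`, `bases`, `quals`,
#'   `individual_id`. An empty file yields a zero-row tibble.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ttttatttca"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           individual_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist", path))
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    format <- switch(ext,
      fa = , fasta = , fna = "fasta",
      fq = , fastq = "fastq",
      abort(sprintf("cannot infer format from extension '.%s'; pass `format`",
                    ext))
    )
  }

  if (format == "fastq") validate_fastq_structure(path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format,
                               with.qualities = (format == "fastq")),
    error = function(e) {
      abort(sprintf("failed to parse '%s' as %s: %s", path, format,
                    conditionMessage(e)))
    }
  )
  n <- length(set)
  if (n == 0) {
    return(tibble::tibble(read_id = character(), bases = character(),
                          quals = character(), individual_id = character()))
  }

  ids <- unname(sub("\\s.*$", "", names(set)))
  bases <- unname(normalize_bases(as.character(set)))
  bad <- which(!grepl("^[ACGTN]+$", bases))
  if (length(bad) > 0) {
    abort(sprintf(
      "record %d ('%s') contains characters outside {A,C,G,T,N,U}",
      bad[1], ids[bad[1]]))
  }

  quals <- rep(NA_character_, n)
  if (format == "fastq") {
    quals <- unname(as.character(S4Vectors::mcols(set)$qualities))
  }

  tibble::tibble(read_id = ids, bases = bases, quals = quals,
                 individual_id = individual_id)
}

#' Write reads to FASTQ or FASTA
#'
#' @param reads A read tibble (see [read_sequences()]). Missing qualities are
#'   written as constant Phred 40 (`"I"`).
#' @param path Output path; a `.gz` suffix gzip-compresses the file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_columns(reads, c("read_id", "bases"), "write_fastq")
  quals <- if ("quals" %in% names(reads)) reads$quals else NA_character_
  quals <- ifelse(is.na(quals), strrep("I", nchar(reads$bases)), quals)
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$bases,
                           "+", quals))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(reads, path) {
  check_columns(reads, c("read_id", "bases"), "write_fasta")
  lines <- as.vector(rbind(paste0(">", reads$read_id), reads$bases))
  readr::write_lines(lines, path)
  invisible(path)
}

# Structural FASTQ validation (4-line records, matching lengths) ahead of
# Biostrings parsing, which silently pads short quality strings.
validate_fastq_structure <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  n <- length(lines)
  if (n == 0) return(invisible(path))
  if (n %% 4 != 0) {
    abort(sprintf("record %d: truncated FASTQ record at end of '%s'",
                  n %/% 4 + 1, path))
  }
  headers <- lines[seq(1, n, 4)]
  seqs <- lines[seq(2, n, 4)]
  seps <- lines[seq(3, n, 4)]
  quals <- lines[seq(4, n, 4)]
  bad <- which(!startsWith(headers, "@"))
  if (length(bad) > 0) {
    abort(sprintf("record %d: header does not start with '@'", bad[1]))
  }
  bad <- which(!startsWith(seps, "+"))
  if (length(bad) > 0) {
    abort(sprintf("record %d: separator line does not start with '+'",
                  bad[1]))
  }
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad) > 0) {
    abort(sprintf(
      "record %d ('%s'): quality string length (%d) differs from sequence length (%d)",
      bad[1], sub("^@", "", sub("\\s.*$", "", headers[bad[1]])),
      nchar(quals[bad[1]]), nchar(seqs[bad[1]])))
  }
  invisible(path)
}
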