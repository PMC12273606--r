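# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp("TTTCA")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nz <- !is.na(x) & nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out[!nzchar(x) & !is.na(x)] <- ""
  out[is.na(x)] <- NA_character_
  out
}

# Normalize a raw sequence string: uppercase, RNA U -> T.
normalize_bases <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- which(!grepl(pat, x))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s %d contains characters outside the %s alphabet",
      what, bad[1], if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}"
    ))
  }
  invisible(x)
}

# Lower median: for even n, the lower of the two central order statistics,
# so that reported medians are attainable integer unit counts.
median_lower <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x)[ceiling(n / 2)]
}

# scalar input checks -------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (integer && x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s]", name, format(lower),
                  format(upper)))
  }
  invisible(x)
}

check_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single string", name))
  }
  invisible(x)
}

# Column presence check for tibble-first verbs.
check_columns <- function(df, cols, fn) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s()` needs column(s) %s in its input data frame",
                  fn, paste0("`", missing, "`", collapse = ", ")))
  }
  invisible(df)
}
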