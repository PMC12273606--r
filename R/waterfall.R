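#' Encode decompositions as a waterfall matrix
#'
#' Samples reads without replacement (at most `sample_size`, uniformly,
#' seeded) and encodes each as its unit-by-unit label sequence: one label
#' per motif unit and one per `OTHER` base, in tract order. Rows are ordered
#' by total unit count, longest read first, so the stacked rows form the
#' classic waterfall display of per-read repeat composition.
#'
#' @param decs Decomposition table from [decompose_reads()] (needs the
#'   `runs` list-column).
#' @param sample_size Maximum number of reads to include (default 300).
#' @param seed Integer seed controlling the sampling.
#' @return An object of class `waterfall`: list with `rows` (list of
#'   character label vectors), `read_ids`, `sample_size` and `seed`.
#' @export
waterfall_encode <- function(decs, sample_size = 300, seed = 1L) {
  check_columns(decs, c("read_id", "runs"), "waterfall_encode")
  if (nrow(decs) == 0) abort("`decs` must contain at least one read")
  check_number(sample_size, "sample_size", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)

  n_take <- min(sample_size, nrow(decs))
  idx <- withr_seed_sample(seq_len(nrow(decs)), n_take, seed)
  sub <- decs[idx, ]

  rows <- purrr::map(sub$runs, function(r) {
    if (nrow(r) == 0) return(character())
    rep(r$motif, r$unit_count)
  })
  len <- lengths(rows)
  ord <- order(-len, sub$read_id)
  structure(
    list(rows = rows[ord], read_ids = sub$read_id[ord],
         sample_size = as.integer(sample_size), seed = as.integer(seed)),
    class = "waterfall"
  )
}

# Seeded sampling without replacement that restores the caller's RNG state.
withr_seed_sample <- function(x, size, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  sample(x, size)
}

#' @export
print.waterfall <- function(x, ...) {
  cat(sprintf("<waterfall> %d read(s), longest %d units, seed %d\n",
              length(x$rows), if (length(x$rows)) max(lengths(x$rows)) else 0L,
              x$seed))
  invisible(x)
}

#' @export
tidy.waterfall <- function(x, ...) {
  purrr::imap(x$rows, function(labels, i) {
    if (length(labels) == 0) return(NULL)
    tibble::tibble(read_id = x$read_ids[i], row = i,
                   unit = seq_along(labels), label = labels)
  }) |>
    purrr::compact() |>
    dplyr::bind_rows()
}

#' Write a waterfall matrix as TSV
#'
#' One row per read, one label per tab-separated column (rows are ragged;
#' shorter reads simply have fewer columns).
#'
#' @param x A [waterfall_encode()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waterfall_tsv <- function(x, path) {
  stopifnot(inherits(x, "waterfall"))
  lines <- vapply(x$rows, paste, character(1), collapse = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

# Display colors from the conventional repeat-composition palette.
waterfall_palette <- function(motifs) {
  base <- c(TTTTA = "#F2C93B", TTTCA = "#D7261E", TTTTG = "#27C4C4",
            TTATG = "#2B50C8", OTHER = "#000000")
  extra <- setdiff(motifs, names(base))
  if (length(extra) > 0) {
    base <- c(base, setNames(grDevices::hcl.colors(length(extra), "Dark 3"),
                             extra))
  }
  base
}

#' Plot a waterfall matrix
#'
#' Renders stacked per-read rows, one colored cell per repeat unit
#' (TTTTA yellow, TTTCA red, TTTTG cyan, TTATG blue, OTHER black).
#'
#' @param x A [waterfall_encode()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(x, ...) {
  stopifnot(inherits(x, "waterfall"))
  df <- tidy(x)
  pal <- waterfall_palette(unique(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = pal, name = "motif") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "repeat unit", y = "read") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.waterfall <- function(object, ...) plot_waterfall(object, ...)
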