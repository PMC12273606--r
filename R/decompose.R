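#' Decompose a repeat tract into motif runs
#'
#' Computes the minimum-total-cost tiling of a tract where each tile is
#' either a window of 3-7 bp (within `per_unit_max_edits` of the unit
#' length) matched to one configured pentamer motif with edit distance at
#' most `per_unit_max_edits` (cost = the edit distance), or a single base
#' labeled `OTHER` (cost = `other_cost`). The variable window length
#' absorbs up to `per_unit_max_edits` indels per repeat unit. The tiling is
#' found by dynamic programming with a lexicographic objective: minimal
#' total edit cost first; among minimum-cost tilings, fewest label switches
#' between adjacent tiles (noise-induced ties inside a homogeneous run must
#' not spawn spurious short runs); then most tiles (a same-cost two-unit
#' explanation of a deletion-damaged region wins over a single long
#' window). Remaining ties prefer motif tiles over `OTHER` and earlier
#' motifs in the configured priority order. Maximal adjacent tiles with the
#' same label are merged into runs.
#'
#' @param tract DNA string over `{A,C,G,T,N}` (typically from
#'   [trim_flanks()]).
#' @param cfg A [locus_config()] supplying the motif alphabet.
#' @param per_unit_max_edits Maximum edit distance for one motif tile
#'   (0, 1 or 2). The default 2 makes noiseless tracts decompose exactly
#'   while absorbing up to two scattered sequencing errors per repeat unit,
#'   as needed for indel-rich long reads.
#' @param other_cost Cost of labeling one base `OTHER`; must be at least 1.
#' @param read_id Optional read label carried into the result.
#' @return An object of class `decomposition`: a list with `read_id`,
#'   `runs` (tibble `motif`, `unit_count`, `start`, `end`, `cost`; 0-based
#'   half-open offsets into the tract), `counts` (named integer vector of
#'   total units per configured motif), `other_bases`, `total_cost` and
#'   `tract_length`. For motif runs `unit_count` counts repeat units; for
#'   `OTHER` runs it counts bases.
#' @examples
#' dec <- decompose_tract("TTTTATTTTATTTCATTTCA", example_locus())
#' dec$runs
#' dec$counts
#' @export
decompose_tract <- function(tract, cfg, per_unit_max_edits = 2,
                            other_cost = 2, read_id = NA_character_) {
  stopifnot(inherits(cfg, "locus_config"))
  check_string(tract, "tract")
  if (!per_unit_max_edits %in% 0:2) {
    abort("`per_unit_max_edits` must be 0, 1 or 2")
  }
  check_number(other_cost, "other_cost", lower = 1, integer = TRUE)
  tract <- normalize_bases(tract)
  if (nzchar(tract)) check_dna(tract, "tract")

  if (!nzchar(tract)) {
    runs <- tibble::tibble(motif = character(), unit_count = integer(),
                           start = integer(), end = integer(),
                           cost = integer())
    return(new_decomposition(read_id, runs, cfg$motifs, 0L))
  }

  raw <- decompose_tract_cpp(tract, cfg$motifs, as.integer(per_unit_max_edits),
                             as.integer(other_cost))
  labels <- c("OTHER", cfg$motifs)[raw$motif_idx + 1L]
  runs <- tibble::tibble(
    motif = labels,
    unit_count = raw$unit_count,
    start = raw$start,
    end = raw$end,
    cost = raw$cost
  )
  new_decomposition(read_id, runs, cfg$motifs, nchar(tract),
                    total_cost = raw$total_cost)
}

new_decomposition <- function(read_id, runs, motifs, tract_length,
                              total_cost = NULL) {
  counts <- setNames(integer(length(motifs)), motifs)
  mruns <- runs[runs$motif != "OTHER", ]
  if (nrow(mruns) > 0) {
    agg <- tapply(mruns$unit_count, mruns$motif, sum)
    counts[names(agg)] <- as.integer(agg)
  }
  other_bases <- sum(runs$unit_count[runs$motif == "OTHER"])
  structure(
    list(read_id = read_id, runs = runs, counts = counts,
         other_bases = as.integer(other_bases),
         total_cost = as.integer(total_cost %||% sum(runs$cost)),
         tract_length = as.integer(tract_length)),
    class = "decomposition"
  )
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %s: %d bp, %d run(s), total cost %d\n",
              x$read_id %||% "<unnamed>", x$tract_length, nrow(x$runs),
              x$total_cost))
  cat("  ", run_string(x$runs), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.decomposition <- function(x, ...) {
  dplyr::mutate(x$runs, read_id = x$read_id, .before = 1)
}

#' @export
glance.decomposition <- function(x, ...) {
  out <- tibble::tibble(read_id = x$read_id,
                        n_units_total = sum(x$counts),
                        other_bases = x$other_bases,
                        total_cost = x$total_cost,
                        tract_length = x$tract_length)
  for (m in names(x$counts)) out[[paste0("n_", m)]] <- x$counts[[m]]
  out
}

run_string <- function(runs) {
  if (nrow(runs) == 0) return("")
  paste(sprintf("%s:%d", runs$motif, runs$unit_count), collapse = ",")
}

#' Decompose a table of trimmed reads
#'
#' Tibble-first, vectorized version of [decompose_tract()]. Rows whose
#' trimming `status` is not `both_flanks` are dropped by default: reads that
#' do not span the full tract give unreliable counts (set
#' `include_partial = TRUE` to keep them).
#'
#' @param trims Tibble with `read_id` and `tract` columns (typically from
#'   [trim_flanks()]); `status` and `individual_id` are honoured when
#'   present.
#' @param cfg A [locus_config()].
#' @inheritParams decompose_tract
#' @param include_partial Keep reads with partial flank support?
#' @param smooth_interruptions Relabel isolated single-unit runs flanked on
#'   both sides by runs of one common motif (see
#'   [smooth_single_interruptions()]). Default `TRUE`: such units arise at
#'   about 1% per unit from single substitutions (one `T -> C` turns a
#'   TTTTA unit into a perfect TTTCA) and would otherwise bias motif
#'   counts upward in long runs. Blocks of up to 3 units are relabeled;
#'   a genuine interior insertion of that size would be smoothed away (a
#'   documented limitation).
#' @return A tibble with one row per decomposed read: `read_id`,
#'   `individual_id`, one `n_<MOTIF>` column per configured motif,
#'   `n_units_total` (total motif units), `other_bases`, `total_cost`,
#'   `run_string`, and a `runs` list-column of per-run tibbles.
#' @export
decompose_reads <- function(trims, cfg, per_unit_max_edits = 2,
                            other_cost = 2, include_partial = FALSE,
                            smooth_interruptions = TRUE) {
  stopifnot(inherits(cfg, "locus_config"))
  check_columns(trims, c("read_id", "tract"), "decompose_reads")
  if ("status" %in% names(trims) && !include_partial) {
    trims <- dplyr::filter(trims, .data$status == "both_flanks")
  }
  iid <- if ("individual_id" %in% names(trims)) trims$individual_id else
    rep(NA_character_, nrow(trims))

  trims$tract <- unname(trims$tract)
  decs <- purrr::map2(trims$tract, trims$read_id, function(tr, id) {
    decompose_tract(tr, cfg, per_unit_max_edits, other_cost, read_id = id)
  })

  runs <- purrr::map(decs, "runs")
  if (smooth_interruptions) {
    runs <- purrr::map2(runs, trims$tract, function(r, tr) {
      smooth_single_interruptions(r, tract = tr)
    })
  }

  out <- tibble::tibble(
    read_id = trims$read_id,
    individual_id = iid
  )
  counts <- purrr::map(runs, function(r) {
    m <- r[r$motif != "OTHER", ]
    tapply(m$unit_count, factor(m$motif, levels = cfg$motifs), sum,
           default = 0L)
  })
  for (m in cfg$motifs) {
    out[[paste0("n_", m)]] <-
      vapply(counts, function(ct) as.integer(ct[[m]]), integer(1))
  }
  out$n_units_total <- vapply(counts, function(ct) as.integer(sum(ct)),
                              integer(1))
  out$other_bases <- vapply(runs, function(r) {
    as.integer(sum(r$unit_count[r$motif == "OTHER"]))
  }, integer(1))
  out$total_cost <- vapply(decs, function(d) d$total_cost, integer(1))
  out$run_string <- vapply(runs, run_string, character(1))
  out$runs <- runs
  out
}

#' Smooth short run interruptions
#'
#' Relabels interior blocks of foreign motif runs when the runs on both
#' sides share one motif and the block is better explained as sequencing
#' error than as a real interruption, then re-merges. Two rules are
#' available:
#'
#' * With the tract sequence (`tract`), a candidate block is relabeled when
#'   re-explaining its bases as flanking-motif units would cost at most
#'   `max_relabel_cost` extra edits. One substitution turns a TTTTA unit
#'   into a perfect TTTCA, so such artifacts re-explain at +1 edit, whereas
#'   a true TTTCA stretch of five units costs about +5 and survives.
#' * Without the sequence, a simple size rule: blocks of at most
#'   `max_interrupt` total units are relabeled.
#'
#' Blocks containing `OTHER` runs and blocks at the tract edges are never
#' touched; `total_cost` of the originating tiling is not recomputed.
#'
#' @param runs A per-read runs tibble (`motif`, `unit_count`, `start`,
#'   `end`, `cost`).
#' @param max_interrupt Maximum total units of a relabeled block (default 3
#'   without sequence context, 6 with it).
#' @param tract The tract DNA string the runs were derived from (enables
#'   the cost-aware rule).
#' @param max_relabel_cost Maximum extra edits tolerated when re-explaining
#'   a block with the flanking motif (default 2).
#' @return The smoothed runs tibble.
#' @export
smooth_single_interruptions <- function(runs, max_interrupt = NULL,
                                        tract = NULL,
                                        max_relabel_cost = 2) {
  if (nrow(runs) < 3) return(runs)
  cost_aware <- !is.null(tract)
  max_interrupt <- max_interrupt %||% (if (cost_aware) 6 else 3)
  motif <- runs$motif
  units <- runs$unit_count
  start <- runs$start
  end <- runs$end
  cost <- runs$cost
  changed <- FALSE
  repeat {
    n <- length(motif)
    if (n < 3) break
    # candidate blocks: consecutive foreign motif runs between two runs of
    # one common motif; relabel the best candidate, then rescan
    best <- NULL
    for (i in 2:(n - 1)) {
      if (motif[i] == "OTHER") next
      flank <- motif[i - 1]
      if (flank == "OTHER" || flank == motif[i]) next
      total <- 0L
      j <- i
      while (j < n && motif[j] != "OTHER" && motif[j] != flank &&
             (total + units[j]) <= max_interrupt) {
        total <- total + units[j]
        if (motif[j + 1] == flank) {
          if (cost_aware) {
            seg <- substr(tract, start[i] + 1, end[j])
            as_flank <- drop(utils::adist(seg, strrep(flank, total)))
            delta <- as_flank - sum(cost[i:j])
          } else {
            delta <- 0L
          }
          if (delta <= max_relabel_cost &&
              (is.null(best) || delta < best$delta ||
                 (delta == best$delta && total < best$total))) {
            best <- list(i = i, j = j, delta = delta, total = total)
          }
          break
        }
        j <- j + 1
      }
    }
    if (is.null(best)) break
    motif[best$i:best$j] <- motif[best$i - 1]
    changed <- TRUE
    grp <- cumsum(c(TRUE, motif[-1] != motif[-length(motif)]))
    first <- !duplicated(grp)
    last <- rev(!duplicated(rev(grp)))
    units <- as.integer(rowsum(units, grp)[, 1])
    cost <- as.integer(rowsum(cost, grp)[, 1])
    motif <- motif[first]
    start <- start[first]
    end <- end[last]
  }
  if (!changed) return(runs)
  tibble::tibble(motif = motif, unit_count = units, start = start,
                 end = end, cost = cost)
}

merge_runs <- function(runs) {
  n <- nrow(runs)
  if (n < 2) return(runs)
  grp <- cumsum(c(TRUE, runs$motif[-1] != runs$motif[-n]))
  first <- !duplicated(grp)
  tibble::tibble(
    motif = runs$motif[first],
    unit_count = as.integer(rowsum(runs$unit_count, grp)[, 1]),
    start = runs$start[first],
    end = runs$end[rev(!duplicated(rev(grp)))],
    cost = as.integer(rowsum(runs$cost, grp)[, 1])
  )
}

#' Longest run of a motif
#'
#' The maximum `unit_count` over runs of the given motif; 0 when the motif
#' is absent. This is the quantity behind the consecutive-TTTCA allele
#' separation rule.
#'
#' @param x A `decomposition`, a runs tibble (`motif`, `unit_count`), or a
#'   decomposition table from [decompose_reads()] (returns one value per
#'   row).
#' @param motif Motif label.
#' @return Integer (vector for decomposition tables).
#' @examples
#' dec <- decompose_tract("TTTCATTTTATTTCATTTCA", example_locus())
#' max_consecutive(dec, "TTTCA")
#' @export
max_consecutive <- function(x, motif) {
  check_string(motif, "motif")
  if (inherits(x, "decomposition")) return(max_run(x$runs, motif))
  if (is.data.frame(x) && "runs" %in% names(x)) {
    return(vapply(x$runs, max_run, integer(1), motif = motif,
                  USE.NAMES = FALSE))
  }
  if (is.data.frame(x) && all(c("motif", "unit_count") %in% names(x))) {
    return(max_run(x, motif))
  }
  abort("`x` must be a decomposition, a runs tibble, or a decomposition table")
}

max_run <- function(runs, motif) {
  u <- runs$unit_count[runs$motif == motif]
  if (length(u) == 0) 0L else as.integer(max(u))
}

#' Write the per-read decomposition report
#'
#' @param decs Decomposition table from [decompose_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_decomposition_report <- function(decs, path) {
  check_columns(decs, c("read_id", "n_units_total", "other_bases",
                        "total_cost", "run_string"),
                "write_decomposition_report")
  readr::write_tsv(dplyr::select(decs, -dplyr::any_of("runs")), path)
  invisible(path)
}
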