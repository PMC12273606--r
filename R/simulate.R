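#' Repeat structure specifications
#'
#' A structure spec is the ground truth of a simulated allele: an ordered
#' list of (pentamer motif, unit count) blocks, written in the conventional
#' notation `"(TTTTA)388(TTTCA)5(TTTTA)3"`.
#'
#' @param motifs Character vector of pentamer motifs.
#' @param unit_counts Integer vector of block unit counts (each >= 1);
#'   adjacent blocks must differ in motif.
#' @return A `structure_spec`: a tibble with columns `motif` and
#'   `unit_count`.
#' @examples
#' spec <- structure_spec(c("TTTTA", "TTTCA", "TTTTA"), c(388, 5, 3))
#' format_structure(spec)
#' @export
structure_spec <- function(motifs, unit_counts) {
  motifs <- normalize_bases(motifs)
  if (length(motifs) != length(unit_counts) || length(motifs) == 0) {
    abort("`motifs` and `unit_counts` must be non-empty and of equal length")
  }
  if (any(nchar(motifs) != 5)) abort("every motif must be a pentamer")
  check_dna(motifs, "motif", allow_n = FALSE)
  if (any(unit_counts < 1) || any(unit_counts != as.integer(unit_counts))) {
    abort("every unit count must be a whole number >= 1")
  }
  if (length(motifs) > 1 &&
      any(motifs[-1] == motifs[-length(motifs)])) {
    abort("adjacent blocks must differ in motif")
  }
  structure(
    tibble::tibble(motif = motifs, unit_count = as.integer(unit_counts)),
    class = c("structure_spec", class(tibble::tibble()))
  )
}

#' Parse a structure string
#'
#' Grammar: one or more `(MOTIF)count` blocks, e.g.
#' `"(TTTTA)388(TTTCA)5(TTTTA)3"`. Whitespace is not allowed; counts must
#' be positive.
#'
#' @param text Structure string.
#' @return A [structure_spec()].
#' @examples
#' parse_structure("(TTTTA)10(TTTCA)5")
#' @export
parse_structure <- function(text) {
  check_string(text, "text")
  block_re <- "\\(([ACGTUacgtu]{5})\\)([0-9]+)"
  ml <- gregexpr(block_re, text, perl = TRUE)
  m <- ml[[1]]
  matched <- if (m[1] == -1) 0L else
    sum(attr(m, "match.length"))
  consecutive_ok <- m[1] == 1 &&
    all(m[-1] == head(m, -1) + head(attr(m, "match.length"), -1))
  if (m[1] == -1 || !consecutive_ok || matched != nchar(text)) {
    pos <- if (m[1] == -1 || m[1] != 1) 1L else {
      ends <- m + attr(m, "match.length")
      gaps <- which(m[-1] != head(ends, -1))
      if (length(gaps) > 0) ends[gaps[1]] else ends[length(ends)]
    }
    abort(sprintf("malformed structure string at position %d: '%s'",
                  pos, text))
  }
  blocks <- regmatches(text, ml)[[1]]
  motifs <- sub(block_re, "\\1", blocks, perl = TRUE)
  counts <- as.integer(sub(block_re, "\\2", blocks, perl = TRUE))
  zero <- which(counts == 0)
  if (length(zero) > 0) {
    abort(sprintf("malformed structure string at position %d: zero unit count",
                  m[zero[1]]))
  }
  structure_spec(motifs, counts)
}

as_structure_spec <- function(spec) {
  if (inherits(spec, "structure_spec")) return(spec)
  if (is.character(spec) && length(spec) == 1) return(parse_structure(spec))
  abort("`spec` must be a structure_spec or a structure string")
}

#' Render a structure spec
#'
#' `render_structure()` concatenates the blocks into the DNA sequence of
#' the repeat tract; `format_structure()` writes the spec back in
#' `(MOTIF)count` notation, so `parse_structure(format_structure(s))`
#' round-trips.
#'
#' @param spec A [structure_spec()] or structure string.
#' @return A DNA string / a structure string.
#' @export
render_structure <- function(spec) {
  spec <- as_structure_spec(spec)
  paste(strrep(spec$motif, spec$unit_count), collapse = "")
}

#' @rdname render_structure
#' @export
format_structure <- function(spec) {
  spec <- as_structure_spec(spec)
  paste(sprintf("(%s)%d", spec$motif, spec$unit_count), collapse = "")
}

#' Build a full allele sequence
#'
#' Flank5 + rendered repeat tract + flank3. With `cfg = NULL` the bare
#' tract is returned.
#'
#' @param spec A [structure_spec()] or structure string.
#' @param cfg A [locus_config()] supplying the flanks, or `NULL`.
#' @return A DNA string.
#' @export
build_allele <- function(spec, cfg = NULL) {
  tract <- render_structure(spec)
  if (is.null(cfg)) return(tract)
  stopifnot(inherits(cfg, "locus_config"))
  paste0(cfg$flank5, tract, cfg$flank3)
}

#' Per-base sequencing error model
#'
#' Independent per-base substitution, insertion and deletion probabilities
#' emulating indel-rich long-read noise. The defaults (3% substitutions,
#' 2% insertions, 3% deletions) are a stand-in for older-pore nanopore
#' chemistry.
#'
#' @param sub_rate,ins_rate,del_rate Probabilities in `[0, 0.2]`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.03) {
  check_number(sub_rate, "sub_rate", 0, 0.2)
  check_number(ins_rate, "ins_rate", 0, 0.2)
  check_number(del_rate, "del_rate", 0, 0.2)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate),
            class = "error_model")
}

#' @rdname error_model
#' @export
no_errors <- function() error_model(0, 0, 0)

#' Somatic mosaicism model
#'
#' Per-read jitter of block unit counts emulating somatic repeat
#' instability. Block counts receive a symmetric truncated-geometric delta:
#' `P(delta = d)` proportional to `(1 - p_mosaic)^|d|` for
#' `|d| <= max_delta`, with the default truncations reflecting the observed
#' biology: appreciable TTTTA instability (up to +-10 units) but a stable
#' TTTCA stretch (`max_delta_tttca = 0`). In addition, with probability
#' `p_gain` a read gains a uniform 1-40 extra TTTCA units, reproducing the
#' occasional higher-TTTCA reads seen in blood at low frequency. Deltas
#' never drive a block count below zero.
#'
#' @param p_mosaic Geometric parameter of the jitter (default 0.5).
#' @param max_delta_tttta,max_delta_tttca Truncation of the jitter for each
#'   motif (defaults 10 and 0 units).
#' @param p_gain Probability of a larger TTTCA gain (default 0.03).
#' @param gain_range Integer range of gained TTTCA units (default 1-40).
#' @return An object of class `mosaicism_model`.
#' @export
mosaicism_model <- function(p_mosaic = 0.5, max_delta_tttta = 10,
                            max_delta_tttca = 0, p_gain = 0.03,
                            gain_range = c(1, 40)) {
  check_number(p_mosaic, "p_mosaic", lower = 1e-9, upper = 1)
  check_number(max_delta_tttta, "max_delta_tttta", lower = 0, integer = TRUE)
  check_number(max_delta_tttca, "max_delta_tttca", lower = 0, integer = TRUE)
  check_number(p_gain, "p_gain", 0, 1)
  if (length(gain_range) != 2 || gain_range[1] > gain_range[2] ||
      gain_range[1] < 1) {
    abort("`gain_range` must be an increasing integer pair with minimum >= 1")
  }
  structure(list(p_mosaic = p_mosaic,
                 max_delta_tttta = as.integer(max_delta_tttta),
                 max_delta_tttca = as.integer(max_delta_tttca),
                 p_gain = p_gain, gain_range = as.integer(gain_range)),
            class = "mosaicism_model")
}

#' @rdname mosaicism_model
#' @export
no_mosaicism <- function() {
  mosaicism_model(max_delta_tttta = 0, max_delta_tttca = 0, p_gain = 0)
}

# Probability mass function of the symmetric truncated-geometric jitter.
jitter_pmf <- function(p, max_delta) {
  d <- seq.int(-max_delta, max_delta)
  w <- (1 - p)^abs(d)
  tibble::tibble(delta = d, prob = w / sum(w))
}

sample_jitter <- function(n, p, max_delta) {
  if (max_delta == 0) return(integer(n))
  pmf <- jitter_pmf(p, max_delta)
  sample(pmf$delta, n, replace = TRUE, prob = pmf$prob)
}

# Apply given mosaicism deltas to one spec; the delta for each motif goes
# to its largest block. Counts are clamped at zero; empty blocks vanish at
# render.
apply_deltas <- function(motifs, counts, d_a, d_c) {
  bump <- function(counts, motif, d) {
    if (d == 0) return(counts)
    i <- which(motifs == motif)
    if (length(i) == 0) return(counts)
    i <- i[which.max(counts[i])]
    counts[i] <- max(0L, counts[i] + as.integer(d))
    counts
  }
  counts <- bump(counts, "TTTTA", d_a)
  counts <- bump(counts, "TTTCA", d_c)
  keep <- counts > 0
  list(motif = motifs[keep], unit_count = counts[keep])
}

# Draw per-read mosaicism deltas for n reads (TTTTA delta, TTTCA delta
# including the occasional large gain).
draw_deltas <- function(n, mos) {
  d_a <- sample_jitter(n, mos$p_mosaic, mos$max_delta_tttta)
  d_c <- sample_jitter(n, mos$p_mosaic, mos$max_delta_tttca)
  if (mos$p_gain > 0) {
    gained <- runif(n) < mos$p_gain
    if (any(gained)) {
      d_c[gained] <- d_c[gained] +
        sample(seq.int(mos$gain_range[1], mos$gain_range[2]), sum(gained),
               replace = TRUE)
    }
  }
  list(tttta = d_a, tttca = d_c)
}

#' Simulate nanopore-like reads from one allele
#'
#' For each read: the block counts receive per-read somatic jitter, the
#' allele (flanks + tract) is rendered, per-base errors are applied, and
#' the read is emitted in a random orientation. Fully reproducible for a
#' given seed.
#'
#' @param spec A [structure_spec()] or structure string (allele truth).
#' @param cfg A [locus_config()] supplying the flanks.
#' @param n Number of reads.
#' @param err An [error_model()].
#' @param mos A [mosaicism_model()].
#' @param seed Optional integer seed (`set.seed()` is called when given;
#'   pass `NULL` to draw from the current RNG stream).
#' @param individual_id Individual label for the reads.
#' @param read_prefix Prefix of generated read ids.
#' @return A read tibble (`read_id`, `bases`, `quals`, `individual_id`)
#'   with a `truth` attribute: one row per read with the jittered true unit
#'   counts (`true_TTTTA`, `true_TTTCA`) and the emitted orientation.
#' @examples
#' reads <- simulate_reads("(TTTTA)10(TTTCA)3", example_locus(), n = 2,
#'                         err = no_errors(), mos = no_mosaicism(), seed = 1)
#' reads
#' @export
simulate_reads <- function(spec, cfg, n, err = error_model(),
                           mos = mosaicism_model(), seed = NULL,
                           individual_id = "sim1",
                           read_prefix = individual_id) {
  spec <- as_structure_spec(spec)
  stopifnot(inherits(cfg, "locus_config"), inherits(err, "error_model"),
            inherits(mos, "mosaicism_model"))
  check_number(n, "n", lower = 1, integer = TRUE)
  if (!is.null(seed)) set.seed(seed)

  bases <- character(n)
  tttta <- integer(n)
  tttca <- integer(n)
  orientation <- character(n)
  deltas <- draw_deltas(n, mos)
  spec_motifs <- spec$motif
  spec_counts <- spec$unit_count
  for (i in seq_len(n)) {
    jit <- apply_deltas(spec_motifs, spec_counts,
                        deltas$tttta[i], deltas$tttca[i])
    tttta[i] <- sum(jit$unit_count[jit$motif == "TTTTA"])
    tttca[i] <- sum(jit$unit_count[jit$motif == "TTTCA"])
    tract <- paste(strrep(jit$motif, jit$unit_count), collapse = "")
    seq_i <- paste0(cfg$flank5, tract, cfg$flank3)
    seq_i <- apply_errors_cpp(seq_i, err$sub_rate, err$ins_rate,
                              err$del_rate)
    orientation[i] <- if (runif(1) < 0.5) "reverse" else "forward"
    bases[i] <- seq_i
  }
  flip <- orientation == "reverse"
  if (any(flip)) bases[flip] <- revcomp(bases[flip])

  ids <- sprintf("%s_read%04d", read_prefix, seq_len(n))
  out <- tibble::tibble(read_id = ids, bases = bases,
                        quals = strrep("I", nchar(bases)),
                        individual_id = individual_id)
  attr(out, "truth") <- tibble::tibble(
    read_id = ids, true_TTTTA = tttta, true_TTTCA = tttca,
    orientation = orientation
  )
  out
}

#' Cohort simulation specification
#'
#' Study-shaped defaults: 8 expansion carriers and 15 non-carrier
#' relatives; carrier expanded alleles drawn as
#' `(TTTTA)t (TTTCA)c (TTTTA)terminal` with `t` uniform in
#' `tttta_range` (default 385-453), `c` uniform in `tttca_range` (default
#' 5-11) and a terminal TTTTA block of 3 or 1 units; every individual also
#' carries short TTTTA-only alleles of 10-25 units. Age at onset follows
#' `aao_intercept + aao_slope_tttca * c` plus Gaussian noise, floored at 1
#' year; non-carriers are unaffected (no AAO).
#'
#' @param n_carriers,n_noncarriers Cohort composition.
#' @param tttta_range,tttca_range Inclusive integer ranges of the expanded
#'   allele's unit counts.
#' @param terminal_tttta Candidate terminal TTTTA block sizes (one is drawn
#'   per carrier).
#' @param short_range Inclusive integer range of short-allele TTTTA counts.
#' @param aao_intercept,aao_slope_tttca,aao_noise_sd Age-at-onset model
#'   (years); the default slope is negative, encoding the inverse
#'   dependence of onset age on TTTCA count.
#' @param reads_per_individual Reads simulated per individual (split about
#'   evenly between the two alleles).
#' @param err An [error_model()].
#' @param mos A [mosaicism_model()].
#' @param seed Master seed; all randomness flows from it.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_carriers = 8, n_noncarriers = 15,
                            tttta_range = c(385, 453),
                            tttca_range = c(5, 11),
                            terminal_tttta = c(3, 1),
                            short_range = c(10, 25),
                            aao_intercept = 70,
                            aao_slope_tttca = -3.5,
                            aao_noise_sd = 2,
                            reads_per_individual = 100,
                            err = error_model(),
                            mos = mosaicism_model(),
                            seed = 1L) {
  check_number(n_carriers, "n_carriers", lower = 0, integer = TRUE)
  check_number(n_noncarriers, "n_noncarriers", lower = 0, integer = TRUE)
  for (nm in c("tttta_range", "tttca_range", "short_range")) {
    r <- get(nm)
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1) {
      abort(sprintf("`%s` must be an increasing integer pair with minimum >= 1",
                    nm))
    }
  }
  if (length(terminal_tttta) < 1 || any(terminal_tttta < 0)) {
    abort("`terminal_tttta` must contain non-negative counts")
  }
  check_number(aao_noise_sd, "aao_noise_sd", lower = 0)
  check_number(reads_per_individual, "reads_per_individual", lower = 1,
               integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  stopifnot(inherits(err, "error_model"), inherits(mos, "mosaicism_model"))
  structure(
    list(n_carriers = as.integer(n_carriers),
         n_noncarriers = as.integer(n_noncarriers),
         tttta_range = as.integer(tttta_range),
         tttca_range = as.integer(tttca_range),
         terminal_tttta = as.integer(terminal_tttta),
         short_range = as.integer(short_range),
         aao_intercept = aao_intercept,
         aao_slope_tttca = aao_slope_tttca,
         aao_noise_sd = aao_noise_sd,
         reads_per_individual = as.integer(reads_per_individual),
         err = err, mos = mos, seed = as.integer(seed)),
    class = "cohort_sim_spec"
  )
}

sample_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq.int(r[1], r[2]), 1L)
}

#' Simulate a full cohort
#'
#' Draws per-individual allele truths according to a [cohort_sim_spec()],
#' simulates reads for both alleles of every individual, and builds the
#' phenotype table. All randomness derives from the spec's master seed, so
#' two runs with equal specs are identical.
#'
#' @param spec A [cohort_sim_spec()].
#' @param cfg A [locus_config()] (default [example_locus()]).
#' @return An object of class `cohort_sim`: list with `reads` (one tibble
#'   for the whole cohort), `truth` (one row per individual: allele truths
#'   and AAO) and `phenotypes` (`individual_id`, `aao_years`).
#' @export
simulate_cohort <- function(spec = cohort_sim_spec(), cfg = example_locus()) {
  stopifnot(inherits(spec, "cohort_sim_spec"), inherits(cfg, "locus_config"))
  set.seed(spec$seed)

  all_reads <- list()
  truth_rows <- list()

  simulate_two_alleles <- function(id, spec1, spec2) {
    n <- spec$reads_per_individual
    n1 <- rbinom(1, n, 0.5)
    parts <- list()
    if (n1 > 0) {
      parts[[1]] <- simulate_reads(spec1, cfg, n1, spec$err, spec$mos,
                                   seed = NULL, individual_id = id,
                                   read_prefix = paste0(id, "_a1"))
    }
    if (n - n1 > 0) {
      parts[[length(parts) + 1]] <-
        simulate_reads(spec2, cfg, n - n1, spec$err, spec$mos,
                       seed = NULL, individual_id = id,
                       read_prefix = paste0(id, "_a2"))
    }
    dplyr::bind_rows(lapply(parts, function(p) {
      tibble::as_tibble(p)
    }))
  }

  for (i in seq_len(spec$n_carriers)) {
    id <- sprintf("carrier%02d", i)
    t_units <- sample_range(spec$tttta_range)
    c_units <- sample_range(spec$tttca_range)
    term <- if (length(spec$terminal_tttta) == 1) spec$terminal_tttta else
      sample(spec$terminal_tttta, 1L)
    exp_motifs <- c("TTTTA", "TTTCA")
    exp_counts <- c(t_units, c_units)
    if (term > 0) {
      exp_motifs <- c(exp_motifs, "TTTTA")
      exp_counts <- c(exp_counts, term)
    }
    expanded <- structure_spec(exp_motifs, exp_counts)
    short <- structure_spec("TTTTA", sample_range(spec$short_range))
    aao <- max(1, spec$aao_intercept + spec$aao_slope_tttca * c_units +
                 rnorm(1, 0, spec$aao_noise_sd))
    all_reads[[id]] <- simulate_two_alleles(id, expanded, short)
    truth_rows[[id]] <- tibble::tibble(
      individual_id = id, carrier = TRUE,
      expanded_structure = format_structure(expanded),
      true_tttta = t_units + term, true_tttca = c_units,
      terminal_tttta = term,
      short_units = short$unit_count[1],
      aao_years = aao
    )
  }

  for (i in seq_len(spec$n_noncarriers)) {
    id <- sprintf("noncarrier%02d", i)
    a1 <- structure_spec("TTTTA", sample_range(spec$short_range))
    a2 <- structure_spec("TTTTA", sample_range(spec$short_range))
    all_reads[[id]] <- simulate_two_alleles(id, a1, a2)
    truth_rows[[id]] <- tibble::tibble(
      individual_id = id, carrier = FALSE,
      expanded_structure = NA_character_,
      true_tttta = NA_integer_, true_tttca = NA_integer_,
      terminal_tttta = NA_integer_,
      short_units = a1$unit_count[1],
      aao_years = NA_real_
    )
  }

  truth <- dplyr::bind_rows(truth_rows)
  structure(
    list(reads = dplyr::bind_rows(all_reads),
         truth = truth,
         phenotypes = dplyr::select(truth, "individual_id", "aao_years")),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d individual(s), %d read(s), %d carrier(s)\n",
              nrow(x$truth), nrow(x$reads), sum(x$truth$carrier)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' One FASTQ per individual plus `truth.tsv` and `phenotypes.tsv` (the
#' phenotype file matches the [read_phenotypes()] schema).
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in unique(sim$reads$individual_id)) {
    write_fastq(sim$reads[sim$reads$individual_id == id, ],
                file.path(dir, paste0(id, ".fastq")))
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  invisible(dir)
}
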