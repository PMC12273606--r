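# Independent oracles and fixture builders used across the test files.
# All oracles deliberately use a different code path than the package
# (plain R recursion / utils::adist) so they can vouch for it.

# minimal valid locus configuration with short flanks for tiny-read tests
tiny_cfg <- function() {
  locus_config(
    locus_name = "tiny",
    flank5 = "GATCGGAAGAGCACA",
    flank3 = "ATCTCGTATGCCGTC"
  )
}

# brute-force semiglobal edit distance: minimum adist over all substrings
oracle_semiglobal <- function(pattern, subject) {
  n <- nchar(subject)
  best <- nchar(pattern) # empty substring: delete whole pattern
  for (s in seq_len(n)) {
    for (e in s:n) {
      d <- drop(utils::adist(pattern, substr(subject, s, e)))
      if (d < best) best <- d
    }
  }
  best
}

# brute-force minimal tiling cost over all tilings of the decomposition
# cost model: motif windows of length 3-7 (within max_edits of the unit
# length) at edit-distance cost, or single OTHER bases at other_cost
oracle_tiling_cost <- function(tract, motifs, max_edits = 2,
                               other_cost = 2) {
  n <- nchar(tract)
  best <- c(0, rep(Inf, n))
  for (p in seq_len(n)) {
    b <- best[p] + other_cost
    for (L in 3:7) {
      if (p - L < 0 || abs(L - 5) > max_edits) next
      w <- substr(tract, p - L + 1, p)
      for (m in motifs) {
        ed <- drop(utils::adist(w, m))
        if (ed <= max_edits) b <- min(b, best[p - L + 1] + ed)
      }
    }
    best[p + 1] <- b
  }
  best[n + 1]
}

# plain-R reverse complement, independent of Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# two-pass product-moment correlation, written from the formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random structure spec over the default motif alphabet
random_spec <- function(n_blocks, max_units = 50,
                        motifs = c("TTTCA", "TTTTA", "TTTTG", "TTATG")) {
  ms <- character(n_blocks)
  ms[1] <- sample(motifs, 1)
  if (n_blocks > 1) {
    for (i in 2:n_blocks) ms[i] <- sample(setdiff(motifs, ms[i - 1]), 1)
  }
  structure_spec(ms, sample.int(max_units, n_blocks, replace = TRUE))
}

# random DNA string
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# closed-form pmf of the simulator's TTTCA delta (truncated-geometric
# jitter convolved with the occasional uniform gain)
tttca_delta_pmf <- function(mos) {
  d <- seq.int(-mos$max_delta_tttca, mos$max_delta_tttca)
  w <- (1 - mos$p_mosaic)^abs(d)
  pj <- w / sum(w)
  gains <- seq.int(mos$gain_range[1], mos$gain_range[2])
  pmf <- numeric(0)
  support <- seq.int(min(d), max(d) + max(gains))
  pmf <- setNames(numeric(length(support)), support)
  for (i in seq_along(d)) {
    pmf[as.character(d[i])] <- pmf[as.character(d[i])] +
      pj[i] * (1 - mos$p_gain)
    for (g in gains) {
      key <- as.character(d[i] + g)
      pmf[key] <- pmf[key] + pj[i] * mos$p_gain / length(gains)
    }
  }
  tibble::tibble(delta = as.integer(names(pmf)), prob = unname(pmf))
}
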