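cfg <- example_locus()

test_that("clean tracts decompose into exact runs at zero cost", {
  dec <- decompose_tract("TTTTATTTTATTTCATTTCA", cfg)
  expect_equal(dec$runs$motif, c("TTTTA", "TTTCA"))
  expect_equal(dec$runs$unit_count, c(2L, 2L))
  expect_equal(dec$total_cost, 0L)

  # the miniature 3'-architecture: long TTTTA, short TTTCA, terminal TTTTA
  dec2 <- decompose_tract(render_structure("(TTTTA)10(TTTCA)5(TTTTA)3"), cfg)
  expect_equal(unname(dec2$counts[c("TTTTA", "TTTCA")]), c(13L, 5L))
  expect_equal(nrow(dec2$runs), 3L)
  expect_equal(dec2$total_cost, 0L)

  dec3 <- decompose_tract("TTTTGTTTTG", cfg)
  expect_equal(dec3$runs$motif, "TTTTG")
  expect_equal(dec3$runs$unit_count, 2L)
  expect_equal(dec3$total_cost, 0L)
})

test_that("a single substituted unit is absorbed into its run", {
  dec <- decompose_tract("TTTTATTGTATTTTA", cfg)
  expect_equal(dec$runs$motif, "TTTTA")
  expect_equal(dec$runs$unit_count, 3L)
  expect_equal(dec$total_cost, 1L)
})

test_that("empty tract yields an empty decomposition, not an error", {
  dec <- decompose_tract("", cfg)
  expect_equal(nrow(dec$runs), 0L)
  expect_equal(sum(dec$counts), 0L)
  expect_equal(dec$total_cost, 0L)
})

test_that("runs cover the tract contiguously with consistent counts", {
  set.seed(31)
  for (i in 1:25) {
    tract <- random_dna(sample(10:80, 1))
    dec <- decompose_tract(tract, cfg)
    expect_equal(dec$runs$start[1], 0L)
    expect_equal(dec$runs$end[nrow(dec$runs)], nchar(tract))
    if (nrow(dec$runs) > 1) {
      expect_equal(dec$runs$start[-1], dec$runs$end[-nrow(dec$runs)])
    }
    expect_equal(sum(dec$runs$cost), dec$total_cost)
    expect_true(all(dec$runs$motif[-1] != dec$runs$motif[-nrow(dec$runs)]))
    # motif run widths stay within the allowed per-unit window lengths
    mot <- dec$runs[dec$runs$motif != "OTHER", ]
    if (nrow(mot) > 0) {
      width <- mot$end - mot$start
      expect_true(all(width >= 3 * mot$unit_count &
                        width <= 7 * mot$unit_count))
    }
  }
})

test_that("noiseless rendered structures are recovered exactly", {
  set.seed(7)
  for (i in 1:100) {
    spec <- random_spec(sample(2:6, 1), max_units = 50)
    dec <- decompose_tract(render_structure(spec), cfg)
    expect_equal(dec$total_cost, 0L)
    expect_equal(dec$runs$motif, spec$motif)
    expect_equal(dec$runs$unit_count, spec$unit_count)
  }
})

test_that("DP minimal cost matches brute-force enumeration on short strings", {
  set.seed(13)
  for (i in 1:120) {
    tract <- random_dna(sample(1:25, 1))
    dec <- decompose_tract(tract, cfg)
    expect_equal(dec$total_cost,
                 oracle_tiling_cost(tract, cfg$motifs, 2, 2))
  }
})

test_that("one substitution perturbs cost and counts only locally", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  for (i in 1:40) {
    spec <- random_spec(sample(1:3, 1), max_units = 15)
    tract <- render_structure(spec)
    pos <- sample(nchar(tract), 1)
    old <- substr(tract, pos, pos)
    mut <- tract
    substr(mut, pos, pos) <- sample(setdiff(bases, old), 1)
    dec <- decompose_tract(mut, cfg)
    expect_lte(dec$total_cost, max(2, 2)) # max(other_cost, per-unit bound)
    delta <- dec$counts -
      decompose_tract(tract, cfg)$counts
    expect_true(all(abs(delta) <= 1))
  }
})

test_that("decomposition mirrors under reverse complement", {
  rc_cfg <- locus_config(
    locus_name = "rc", flank5 = revcomp(cfg$flank3),
    flank3 = revcomp(cfg$flank5), motifs = revcomp(cfg$motifs)
  )
  set.seed(23)
  for (i in 1:20) {
    spec <- random_spec(sample(2:4, 1), max_units = 20)
    tract <- render_structure(spec)
    fwd <- decompose_tract(tract, cfg)
    rev <- decompose_tract(revcomp(tract), rc_cfg)
    expect_equal(rev$total_cost, fwd$total_cost)
    expect_equal(rev$runs$motif, revcomp(rev(fwd$runs$motif)))
    expect_equal(rev$runs$unit_count, rev(fwd$runs$unit_count))
  }
})

test_that("max_consecutive returns the longest single run", {
  runs <- tibble::tibble(motif = c("TTTTA", "TTTCA", "TTTTA"),
                         unit_count = c(10L, 5L, 3L),
                         start = c(0L, 50L, 75L), end = c(50L, 75L, 90L),
                         cost = 0L)
  expect_equal(max_consecutive(runs, "TTTCA"), 5L)
  expect_equal(max_consecutive(runs, "TTATG"), 0L)

  interrupted <- tibble::tibble(
    motif = c("TTTCA", "TTTTA", "TTTCA"),
    unit_count = c(1L, 4L, 3L),
    start = c(0L, 5L, 25L), end = c(5L, 25L, 40L), cost = 0L
  )
  expect_equal(max_consecutive(interrupted, "TTTCA"), 3L)
})

test_that("interruption smoothing relabels error-scale blocks only", {
  mk <- function(motif, units) {
    end <- cumsum(units * 5L)
    tibble::tibble(motif = motif, unit_count = units,
                   start = c(0L, head(end, -1)), end = end, cost = 0L)
  }
  # isolated foreign unit inside a long run is relabeled
  sm <- smooth_single_interruptions(mk(c("TTTTA", "TTTCA", "TTTTA"),
                                       c(10L, 1L, 9L)))
  expect_equal(sm$motif, "TTTTA")
  expect_equal(sm$unit_count, 20L)

  # a broken TTTCA stretch is repaired
  sm2 <- smooth_single_interruptions(mk(c("TTTTA", "TTTCA", "TTTTA",
                                          "TTTCA"),
                                        c(50L, 2L, 1L, 3L)))
  expect_equal(sm2$motif, c("TTTTA", "TTTCA"))
  expect_equal(sm2$unit_count, c(50L, 6L))

  # blocks above the limit and edge runs are untouched
  keep <- mk(c("TTTTA", "TTTCA", "TTTTA"), c(10L, 5L, 3L))
  expect_equal(smooth_single_interruptions(keep), keep)
  edge <- mk(c("TTTCA", "TTTTA"), c(1L, 10L))
  expect_equal(smooth_single_interruptions(edge), edge)
  terminal <- mk(c("TTTTA", "TTTCA", "TTTTA"), c(400L, 8L, 1L))
  expect_equal(smooth_single_interruptions(terminal), terminal)
})

test_that("decompose_reads summarises per read and honours trim status", {
  spec <- "(TTTTA)30(TTTCA)6"
  trims <- tibble::tibble(
    read_id = c("a", "b"),
    individual_id = "p1",
    status = c("both_flanks", "none"),
    tract = c(render_structure(spec), "")
  )
  decs <- decompose_reads(trims, cfg)
  expect_equal(nrow(decs), 1L) # partial/failed reads dropped by default
  expect_equal(decs$n_TTTTA, 30L)
  expect_equal(decs$n_TTTCA, 6L)
  expect_equal(decs$n_units_total, 36L)
  expect_equal(decs$run_string, "TTTTA:30,TTTCA:6")

  both <- decompose_reads(trims, cfg, include_partial = TRUE)
  expect_equal(nrow(both), 2L)
  expect_equal(both$n_units_total[2], 0L)
})

test_that("waterfall encoding samples, orders and reproduces deterministically", {
  trims <- tibble::tibble(
    read_id = sprintf("r%03d", 1:40),
    status = "both_flanks",
    tract = vapply(1:40, function(i) {
      render_structure(structure_spec(c("TTTTA", "TTTCA"), c(i %% 7 + 2, 2)))
    }, character(1))
  )
  decs <- decompose_reads(trims, cfg)

  w_all <- waterfall_encode(decs, sample_size = 300, seed = 4)
  expect_equal(length(w_all$rows), 40L) # sample larger than population
  expect_true(all(diff(lengths(w_all$rows)) <= 0)) # longest first

  w_sub <- waterfall_encode(decs, sample_size = 10, seed = 4)
  expect_equal(length(w_sub$rows), 10L)
  expect_identical(w_sub, waterfall_encode(decs, sample_size = 10, seed = 4))
  expect_false(identical(w_sub$read_ids,
                         waterfall_encode(decs, 10, seed = 5)$read_ids))

  # labels expand the runs unit by unit
  first_id <- w_all$read_ids[1]
  src <- decs$runs[[match(first_id, decs$read_id)]]
  expect_equal(w_all$rows[[1]], rep(src$motif, src$unit_count))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_waterfall_tsv(w_sub, path)
  expect_equal(length(readLines(path)), 10L)
})
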