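test_that("locus_config validates its invariants", {
  expect_s3_class(tiny_cfg(), "locus_config")
  expect_error(locus_config(flank5 = "ACGT", flank3 = tiny_cfg()$flank3),
               "15 bp")
  expect_error(locus_config(flank5 = tiny_cfg()$flank5,
                            flank3 = tiny_cfg()$flank3,
                            motifs = c("TTTCA", "TTTCA")),
               "duplicates")
  expect_error(locus_config(flank5 = tiny_cfg()$flank5,
                            flank3 = tiny_cfg()$flank3,
                            motifs = c("TTTC")),
               "pentamer")
  expect_error(locus_config(flank5 = tiny_cfg()$flank5,
                            flank3 = tiny_cfg()$flank3,
                            max_flank_edit_frac = 0.5),
               "max_flank_edit_frac")
})

test_that("locus config round-trips through YAML and exports BED", {
  cfg <- example_locus()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_locus_config(cfg, path)
  cfg2 <- read_locus_config(path)
  expect_equal(cfg2, cfg)

  bed <- locus_to_bed(cfg, path = withr::local_tempfile(fileext = ".bed"))
  expect_named(bed, c("chrom", "start", "end", "name", "score", "strand"))
  expect_equal(bed$start, cfg$start) # 0-based half-open, no +-1 shifts
  expect_equal(bed$end, cfg$end)
})

test_that("read_sequences normalizes case and alphabet", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ttttatttca"), fa)
  reads <- read_sequences(fa)
  expect_equal(reads$read_id, "r1")
  expect_equal(reads$bases, "TTTTATTTCA")

  # RNA U maps to T
  writeLines(c(">r1", "uuuca"), fa)
  expect_equal(read_sequences(fa)$bases, "TTTCA")
})

test_that("read_sequences handles FASTQ, empty files and malformed input", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@a", "ACGTA", "+", "IIIII", "@b", "GGCC", "+", "JJJJ"), fq)
  reads <- read_sequences(fq)
  expect_equal(nrow(reads), 2L)
  expect_equal(nchar(reads$quals), nchar(reads$bases))

  # quality line shorter than the sequence is a parse error naming the record
  writeLines(c("@a", "ACGTA", "+", "IIIII", "@b", "GGCC", "+", "JJ"), fq)
  expect_error(read_sequences(fq), "record 2")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(read_sequences(empty)), 0L)

  expect_error(read_sequences(withr::local_tempfile(fileext = ".txt")),
               "does not exist|format")
})

test_that("FASTQ writing round-trips through gzip", {
  reads <- tibble::tibble(read_id = c("x", "y"),
                          bases = c("ACGTACGT", "TTTTATTTCA"),
                          quals = c("IIIIIIII", "JJJJJJJJJJ"),
                          individual_id = "p1")
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(reads, gz)
  back <- read_sequences(gz, individual_id = "p1")
  expect_equal(back, reads)
})

test_that("revcomp matches an independent implementation and involutes", {
  set.seed(11)
  seqs <- replicate(20, random_dna(sample(1:40, 1)))
  expect_equal(revcomp(seqs), oracle_revcomp(seqs))
  expect_equal(revcomp(revcomp(seqs)), seqs)
  expect_equal(revcomp("NNACG"), "CGTNN")
})

test_that("orientation is recovered for both strands and is involutive", {
  cfg <- tiny_cfg()
  fwd <- paste0(cfg$flank5, strrep("TTTTA", 10), cfg$flank3)
  reads <- tibble::tibble(read_id = c("f", "r"),
                          bases = c(fwd, revcomp(fwd)))
  oriented <- orient_reads(reads, cfg)
  expect_equal(oriented$orientation, c("forward", "reverse"))
  expect_equal(oriented$bases, c(fwd, fwd))

  # unresolvable reads pass through unchanged
  nn <- tibble::tibble(read_id = "n", bases = strrep("N", 60))
  expect_equal(orient_reads(nn, cfg)$orientation, "forward")
})

test_that("flank trimming recovers exact and noisy tracts", {
  cfg <- tiny_cfg()
  tract <- strrep("TTTTA", 8)
  reads <- tibble::tibble(read_id = "r", bases = paste0(cfg$flank5, tract,
                                                        cfg$flank3))
  tr <- trim_flanks(reads, cfg)
  expect_equal(tr$status, "both_flanks")
  expect_equal(tr$tract, tract)
  expect_equal(tr$flank5_edits, 0L)
  expect_equal(tr$flank3_edits, 0L)

  # one substitution inside flank5 still yields the same tract, 1 edit
  fl5 <- cfg$flank5
  substr(fl5, 7, 7) <- ifelse(substr(fl5, 7, 7) == "A", "C", "A")
  tr2 <- trim_flanks(tibble::tibble(read_id = "r",
                                    bases = paste0(fl5, tract, cfg$flank3)),
                     cfg)
  expect_equal(tr2$status, "both_flanks")
  expect_equal(tr2$tract, tract)
  expect_equal(tr2$flank5_edits, 1L)

  # fragment containing only the 5' flank
  tr3 <- trim_flanks(tibble::tibble(read_id = "r",
                                    bases = paste0(cfg$flank5, tract)),
                     cfg)
  expect_equal(tr3$status, "five_only")
  expect_equal(tr3$tract, tract)
  expect_true(is.na(tr3$flank3_edits))

  # no flank at all
  tr4 <- trim_flanks(tibble::tibble(read_id = "r", bases = strrep("N", 80)),
                     cfg)
  expect_equal(tr4$status, "none")
  expect_equal(tr4$tract, "")
  expect_equal(tr4$tract_length, 0L)
})

test_that("semiglobal flank distances agree with the brute-force oracle", {
  set.seed(5)
  for (i in 1:40) {
    pattern <- random_dna(sample(4:12, 1))
    subject <- random_dna(sample(10:60, 1))
    expect_equal(semiglobal_dist(pattern, subject),
                 oracle_semiglobal(pattern, subject))
  }
})

test_that("trimming round-trips rendered structures exactly", {
  cfg <- tiny_cfg()
  set.seed(21)
  for (i in 1:20) {
    spec <- random_spec(sample(2:4, 1), max_units = 20)
    tract <- render_structure(spec)
    tr <- trim_flanks(tibble::tibble(read_id = "r",
                                     bases = build_allele(spec, cfg)),
                      cfg)
    expect_equal(tr$status, "both_flanks")
    expect_equal(tr$tract, tract)
    expect_equal(tr$flank5_edits + tr$flank3_edits, 0L)
  }
})

test_that("trim report writes the documented columns", {
  cfg <- tiny_cfg()
  reads <- tibble::tibble(read_id = "r",
                          bases = paste0(cfg$flank5, strrep("TTTCA", 4),
                                         cfg$flank3))
  tr <- trim_flanks(reads, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trim_report(tr, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_true(all(c("read_id", "orientation", "status", "tract_length",
                    "flank5_edits", "flank3_edits", "tract") %in%
                    names(back)))
})
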