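cfg <- example_locus()

test_that("structure strings parse, format and render consistently", {
  spec <- parse_structure("(TTTTA)388(TTTCA)5(TTTTA)3")
  expect_equal(nrow(spec), 3L)
  expect_equal(sum(spec$unit_count), 396L)
  expect_equal(format_structure(spec), "(TTTTA)388(TTTCA)5(TTTTA)3")

  single <- parse_structure("(TTTCA)1")
  expect_equal(render_structure(single), "TTTCA")

  set.seed(19)
  for (i in 1:30) {
    s <- random_spec(sample(1:5, 1), max_units = 40)
    txt <- format_structure(s)
    expect_equal(format_structure(parse_structure(txt)), txt)
    expect_equal(nchar(render_structure(s)), 5 * sum(s$unit_count))
  }
})

test_that("malformed structure strings fail with a position", {
  expect_error(parse_structure("(TTTTA)0"), "zero unit count")
  expect_error(parse_structure("(TTTT)3"), "position")
  expect_error(parse_structure("(TTTTA)3x(TTTCA)2"), "position 9")
  expect_error(parse_structure("TTTTA"), "position 1")
  expect_error(structure_spec(c("TTTTA", "TTTTA"), c(2, 3)), "adjacent")
})

test_that("build_allele concatenates flanks and tract", {
  short_cfg <- locus_config(locus_name = "s",
                            flank5 = strrep("ACGTA", 4),
                            flank3 = strrep("TGCAT", 4))
  spec <- structure_spec("TTTTA", 10)
  expect_equal(nchar(build_allele(spec, short_cfg)), 20 + 50 + 20)
  expect_equal(build_allele(spec, NULL), strrep("TTTTA", 10))

  # family-6-like architecture: a single terminal TTTTA unit
  fam6 <- build_allele("(TTTTA)20(TTTCA)8(TTTTA)1", NULL)
  expect_equal(substr(fam6, nchar(fam6) - 4, nchar(fam6)), "TTTTA")
})

test_that("noise-free simulation reproduces the allele on either strand", {
  allele <- build_allele("(TTTTA)10(TTTCA)3", cfg)
  reads <- simulate_reads("(TTTTA)10(TTTCA)3", cfg, n = 20,
                          err = no_errors(), mos = no_mosaicism(), seed = 8)
  expect_true(all(reads$bases %in% c(allele, revcomp(allele))))
  truth <- attr(reads, "truth")
  expect_true(all(truth$true_TTTTA == 10 & truth$true_TTTCA == 3))
  expect_equal(reads$bases %in% revcomp(allele),
               truth$orientation == "reverse")
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_reads("(TTTTA)30(TTTCA)5", cfg, n = 15, seed = 42)
  b <- simulate_reads("(TTTTA)30(TTTCA)5", cfg, n = 15, seed = 42)
  expect_identical(a, b)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  c <- simulate_reads("(TTTTA)30(TTTCA)5", cfg, n = 15, seed = 43)
  expect_false(identical(a$bases, c$bases))
})

test_that("substitution rate is reproduced within binomial bounds", {
  set.seed(101)
  template <- random_dna(1000)
  n_rep <- 50
  mism <- 0L
  for (i in seq_len(n_rep)) {
    noisy <- pentarep:::apply_errors_cpp(template, 0.03, 0, 0)
    expect_equal(nchar(noisy), 1000L) # substitutions preserve length
    mism <- mism + sum(strsplit(noisy, "")[[1]] !=
                         strsplit(template, "")[[1]])
  }
  n_bases <- 1000 * n_rep
  # 99.99% binomial interval around 0.03
  half <- 3.9 * sqrt(0.03 * 0.97 / n_bases)
  expect_lt(abs(mism / n_bases - 0.03), half)
})

test_that("insertion and deletion rates shift read length as expected", {
  set.seed(102)
  template <- random_dna(2000)
  lens_ins <- nchar(replicate(30, pentarep:::apply_errors_cpp(template, 0,
                                                              0.02, 0)))
  lens_del <- nchar(replicate(30, pentarep:::apply_errors_cpp(template, 0,
                                                              0, 0.03)))
  expect_lt(abs(mean(lens_ins) - 2000 * 1.02), 10)
  expect_lt(abs(mean(lens_del) - 2000 * 0.97), 10)
})

test_that("the TTTCA gain probability is realised within binomial bounds", {
  mos <- mosaicism_model()
  set.seed(103)
  n <- 6000
  deltas <- pentarep:::draw_deltas(n, mos)
  # a delta beyond the jitter truncation implies a gain event
  observed <- mean(deltas$tttca > mos$max_delta_tttca)
  pmf <- tttca_delta_pmf(mos)
  expected <- sum(pmf$prob[pmf$delta > mos$max_delta_tttca])
  half <- 3.9 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), half)
  # TTTTA jitter stays within its truncation
  expect_true(all(abs(deltas$tttta) <= mos$max_delta_tttta))
})

test_that("jitter never drives block counts below zero", {
  reads <- simulate_reads("(TTTTA)3(TTTCA)1", cfg, n = 200,
                          err = no_errors(),
                          mos = mosaicism_model(max_delta_tttta = 10,
                                                max_delta_tttca = 2,
                                                p_gain = 0),
                          seed = 11)
  truth <- attr(reads, "truth")
  expect_true(all(truth$true_TTTTA >= 0))
  expect_true(all(truth$true_TTTCA >= 0))
})

test_that("cohort simulation mirrors the study design", {
  spec <- cohort_sim_spec(reads_per_individual = 4, err = no_errors(),
                          mos = no_mosaicism(), seed = 5)
  sim <- simulate_cohort(spec, cfg)
  expect_equal(nrow(sim$truth), 23L)
  expect_equal(sum(sim$truth$carrier), 8L)
  expect_equal(sum(!is.na(sim$truth$true_tttca)), 8L)
  with_c <- sim$truth[sim$truth$carrier, ]
  expect_true(all(with_c$true_tttca >= 5 & with_c$true_tttca <= 11))
  expect_true(all(with_c$true_tttta - with_c$terminal_tttta >= 385 &
                    with_c$true_tttta - with_c$terminal_tttta <= 453))
  expect_true(all(with_c$terminal_tttta %in% c(1L, 3L)))
  expect_true(all(is.na(sim$truth$aao_years[!sim$truth$carrier])))
  expect_equal(nrow(sim$reads), 23L * 4L)

  # deterministic under the master seed
  sim2 <- simulate_cohort(spec, cfg)
  expect_identical(sim, sim2)
})

test_that("a noise-free AAO model gives a perfect inverse correlation", {
  spec <- cohort_sim_spec(reads_per_individual = 2, aao_noise_sd = 0,
                          err = no_errors(), mos = no_mosaicism(), seed = 9)
  sim <- simulate_cohort(spec, cfg)
  carriers <- sim$truth[sim$truth$carrier, ]
  expect_equal(cor(carriers$aao_years, carriers$true_tttca), -1)
})

test_that("write_cohort produces FASTQ per individual plus tables", {
  dir <- withr::local_tempdir()
  spec <- cohort_sim_spec(n_carriers = 2, n_noncarriers = 1,
                          reads_per_individual = 3, err = no_errors(),
                          mos = no_mosaicism(), seed = 2)
  sim <- simulate_cohort(spec, cfg)
  write_cohort(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("carrier01.fastq",
                                               "carrier02.fastq",
                                               "noncarrier01.fastq",
                                               "truth.tsv",
                                               "phenotypes.tsv")))))
  back <- read_sequences(file.path(dir, "carrier01.fastq"),
                         individual_id = "carrier01")
  expect_equal(back$bases,
               sim$reads$bases[sim$reads$individual_id == "carrier01"])
  phen <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_named(phen, c("individual_id", "aao_years"))
})
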