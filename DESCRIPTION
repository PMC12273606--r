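Package: pentarep
Title: Pentanucleotide Repeat Expansion Genotyping from Long Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes tandem pentanucleotide repeat expansions, such as the
    intronic TTTTA/TTTCA expansions underlying familial adult myoclonus
    epilepsy, from long-range PCR amplicon long reads. Provides flank-anchored
    extraction of the repeat tract by semiglobal alignment, error-tolerant
    decomposition of each read into motif runs by dynamic programming, allele
    separation based on consecutive TTTCA content, per-individual repeat-count
    and somatic-mosaicism summaries, genotype-phenotype (age-at-onset)
    correlation, an in-silico repeat-primed PCR ladder simulator, and a
    synthetic nanopore-like read and cohort generator so that every stage can
    be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    yaml,
    generics,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
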