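---
title: "Genotyping pentanucleotide repeat expansions from long amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping pentanucleotide repeat expansions from long amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentarep)
```

## The problem

Familial adult myoclonus epilepsy (FAME) and related cortical myoclonus
syndromes are caused by intronic pentanucleotide repeat expansions: a long
tract of TTTTA units that acquires a stretch of TTTCA units. TTTTA-only
expansions are benign; the TTTCA insertion makes the allele pathogenic, and
even a short stretch (five or so units) next to a few hundred TTTTA units
suffices. Diagnostic workflows therefore amplify the locus by long-range
PCR (LR-PCR), screen for the TTTCA content by repeat-primed PCR (RP-PCR),
and sequence the amplicons with nanopore long reads to count the repeat
units on every single molecule.

pentarep implements the computational half of this workflow on basecalled
reads: it extracts the repeat tract between known flanking sequences,
decomposes it into motif runs under realistic per-base error, separates the
expanded from the wild-type allele, summarizes per-individual repeat counts
and somatic variability, and correlates counts with the age at myoclonus
onset (AAO). A synthetic-data generator produces truth-known reads and
cohorts so that every stage is testable without patient data, and an
in-silico RP-PCR model reproduces the qualitative ladder shapes used in
screening.

## Tract extraction

Each read is first oriented: the 5' flank is aligned semiglobally (free
ends on the read, full-length on the flank, unit edit costs) against the
read and its reverse complement, and the better orientation wins, ties
staying forward. Both flanks are then located; the tract is the sequence
strictly between the leftmost best occurrence of the 5' flank and the
rightmost best occurrence of the 3' flank (0-based, half-open coordinates
throughout). A flank is accepted when its edit distance is at most
`max_flank_edit_frac` times its length.

The default stringency is 0.25. At the default read accuracy (about 8%
errors per base) a 30 bp flank accumulates Poisson-like edits with mean
2.4; a 0.15 threshold would reject roughly one flank in ten and with it a
substantial fraction of perfectly usable full-span reads, while random
non-locus sequence still stays far above 0.25 of the flank length.
Reads with only one recoverable flank are reported with their status
(`five_only`, `three_only`, `none`) and excluded from genotyping by
default, since a read that does not span the tract cannot yield a total
unit count.

## Motif decomposition

The decomposition is the package's core. A tract is tiled with two kinds of
tiles:

* a window of 3-7 bp matched to one configured pentamer motif with edit
  distance at most `per_unit_max_edits` (cost = that distance), or
* a single base labeled `OTHER` at cost `other_cost`.

Dynamic programming finds a tiling with a lexicographic objective:

1. minimal total edit cost;
2. among minimum-cost tilings, the fewest label switches between adjacent
   tiles;
3. among those, the most tiles;
4. remaining ties prefer motif tiles over `OTHER`, earlier motifs in the
   configured priority order (TTTCA first, so junction ambiguities resolve
   toward the clinically decisive motif), and a parent tile that already
   carries the same label (an ambiguous window at a run junction joins the
   5'-side run rather than extending the 3'-side one).

The secondary and tertiary criteria matter because indel-rich reads create
many cost ties. A single inserted base turns `TTTTA` into `TTTTCA`, which
is one edit from both TTTTA and TTTCA: resolved by global motif priority
alone, such ties convert a material fraction of a long TTTTA run into
scattered false TTTCA units. Minimizing switches keeps homogeneous runs
homogeneous without ever sacrificing edit cost, and maximizing tiles stops
a same-cost single long window from silently swallowing a deletion-damaged
pair of units. On noiseless sequence the minimum cost is zero, every tile
is an exact 5 bp motif window, and the decomposition reproduces the
generating structure exactly — the tie-breaks only select among optimal
explanations of noisy sequence.

`per_unit_max_edits` defaults to 2 with window lengths 3-7 (a unit that
lost or gained up to two bases is still recognisable); with at most one
edit, doubly-damaged units — about 6% of units at 8% per-base error — fall
out of motif matching and the per-read TTTTA count loses tens of units.
`other_cost` defaults to 2, making one `OTHER` base as expensive as a
maximally damaged motif window, so `OTHER` only absorbs sequence that no
motif explains.

### Run smoothing

After tiling, `decompose_reads()` applies a context rule that the local
cost model cannot express: an interior block of foreign-motif runs flanked
on both sides by runs of one common motif is relabeled to that motif when
re-explaining its bases as flanking-motif units costs at most
`max_relabel_cost = 2` extra edits. A single substitution converts a TTTTA
unit into a *perfect* TTTCA — locally indistinguishable from a true
interruption, but re-explainable at +1 edit — whereas a genuine TTTCA
stretch of five units would cost about +5 and always survives. The same
rule repairs a true stretch split by one error
(`TTTCA:2,TTTTA:1,TTTCA:2` back to `TTTCA:5`). The known cost: a genuine
interior insertion of one or two foreign units cannot be distinguished
from noise at this error rate and is smoothed away. `decompose_tract()`
itself never smooths, so the pure minimum-cost tiling remains available
and exactly recovers arbitrary noiseless structures, including single-unit
interior blocks.

## Allele separation and genotypes

A read is assigned to the expanded allele when its longest run of
consecutive TTTCA units reaches `ttca_min_run = 2`; a single isolated
TTTCA unit is not treated as evidence. Interrupted runs do not
concatenate. Reads spanning fewer than `min_total_units = 20` motif units
are `ambiguous` — LR-PCR amplicons imply near-full span, so shorter reads
are fragments whose counts would mislead.

Per individual, medians and quartiles of per-read TTTTA and TTTCA counts
are computed over expanded-class reads (the short allele is summarized
separately). Medians use the lower-median convention so every reported
value is an attainable integer unit count; quartiles use linear
interpolation and box plots the Tukey 1.5 IQR whisker convention. The
expansion size is `5 * (median_tttta + median_tttca)` bp, which for
study-scale alleles lands on the 2-3 kb LR-PCR product scale. An
individual is called a carrier when at least `min_support = 10` reads land
in the expanded class; somatic variability is reported as IQRs, ranges and
`frac_reads_high_tttca`, the fraction of expanded reads whose TTTCA count
exceeds the median by more than `mosaic_delta = 3` units.

## Genotype-phenotype correlation

`correlate_cohort()` computes the four standard panels on carriers with a
recorded AAO: AAO against the median TTTCA count, the median TTTTA count
and the median expansion size, plus TTTCA against TTTTA. `pearson_cor()`
reports the product-moment `r`, the least-squares line, and a two-sided
p-value from `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
freedom; sidedness is stated because the source analyses do not specify
it, and no multiple-testing correction is applied across the four panels,
matching how such panels are conventionally presented. With fewer than
three usable individuals the function refuses and names the exclusions.

## The RP-PCR simulator

The repeat primer is modeled as `units_in_primer` copies of the repeat
unit (default four TTTCA copies) plus an optional anchored part
contributing fixed length; it anneals wherever that many consecutive units
match with at most `max_mismatches` substitutions (no thermodynamics). On
a clean `(unit)^m` template this yields exactly `max(0, m - j + 1)` sites
spaced one unit (5 bp) apart. Each site emits one fragment; a profile with
no sites is `absent`, with at most `truncation_threshold = 15` peaks
`truncated` (the sawtooth that stops after a few peaks, as produced by a
short TTTCA stretch), and `continuous` above that (the classical pattern
of a long TTTCA expansion). An optional per-peak efficiency decay is off
by default because the qualitative pattern, not intensity physics, is the
diagnostic signal.

## The synthetic-data generator

`simulate_cohort()` emulates the study design: 8 expansion carriers and
15 non-carrier relatives. Each carrier draws one expanded allele
`(TTTTA)t (TTTCA)c (TTTTA)terminal` with `t` uniform on 385-453, `c`
uniform on 5-11 and a terminal block of 3 or 1 units, plus one short
TTTTA-only allele of 10-25 units (short-allele sizes at such loci are not
published; 10-25 is a realistic normal-allele scale). Non-carriers carry
two short alleles. Reads (default 100 per individual, split about evenly
between the two alleles) receive per-read somatic jitter, per-base errors
(3% substitutions, 2% insertions, 3% deletions — an older-pore nanopore
stand-in), and a random strand. AAO follows
`70 - 3.5 * c + Normal(0, 2)` years, floored at one year; the intercept
and slope place onsets in the observed 27-55 year range across the TTTCA
range, encoding the inverse dependence of onset age on TTTCA count.
Because `t` and `c` are drawn independently, only the TTTCA-AAO
relationship carries signal in simulated cohorts; the AAO-TTTTA and
TTTCA-TTTTA panels are null under this generator, unlike in real families
where the two counts co-vary.

Somatic mosaicism defaults: the TTTTA block jitters by a symmetric
truncated-geometric delta (parameter 0.5, truncated at +-10 units), the
TTTCA stretch is stable apart from a `p_gain = 0.03` chance of gaining a
uniform 1-40 extra units — reproducing limited higher-TTTCA reads on a
background of appreciable TTTTA variability. All randomness flows from
the master seed; equal specifications give byte-identical output.

What the generator does not emulate: homopolymer-dependent error rates
(errors are i.i.d. per base), PCR chimeras and length-biased
amplification, signal-level artifacts, and within-read error bursts.
Passing tests on this generator therefore demonstrate correctness of the
decomposition and inference logic under calibrated indel-rich noise, not
performance on any particular real flow cell.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: the DP
tiling cost against brute-force enumeration over all tilings (1,000 random
strings up to 40 bp), the semiglobal aligner against an exhaustive
substring scan, noiseless decomposition against 500 random generating
structures (2-6 blocks, 1-50 units), Pearson statistics against a
from-scratch two-pass formula and a 2,000-replicate independence null, and
the full pipeline against simulated truth: allele mixtures at default
noise over 20 seeds, median recovery for TTTTA in {390, 420, 450} crossed
with TTTCA in {5, 8, 11} at 100 reads over 20 replicates (+-2 unit
tolerance), and 20 study-shaped cohorts checked for exact carrier
separation, in-range TTTCA medians and a significant negative TTTCA-AAO
correlation. These sizes keep the whole suite within a few minutes on one
core while exercising every code path at study-realistic scale.

## Limitations

* Counts are estimated per read and summarized by medians; no consensus
  polishing or signal-space counting is attempted, so per-read counts
  carry the residual indel bias of single-molecule sequencing (about one
  unit per several hundred at default noise).
* Interior foreign blocks of 1-2 units are attributed to sequencing error
  by design; loci whose biology features such micro-insertions need the
  smoothing disabled and higher-accuracy reads.
* Allele separation is rule-based (consecutive-TTTCA content), not a
  probabilistic mixture model; alleles distinguished only by length are
  not phased.
* The phenotype model is a single linear AAO-TTTCA link; no penetrance,
  censoring or anticipation modeling.
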