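---
title: "Methods: transposable-element load and hybrid-dysgenesis inference"
author: "dysgene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposable-element load and hybrid-dysgenesis inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysgene)
```

# The problem

P-elements are DNA transposons of *Drosophila* with four exons (numbered
0-3) and 31-bp terminal inverted repeats (TIRs). When a female whose
germline lacks the element (an M-cytotype mother) is crossed to a male
carrying it (a P father), unrepressed transposase activity damages the
daughters' germline: ovaries atrophy, ovariole counts drop, and
reproductive senescence accelerates - the syndrome of hybrid dysgenesis
(HD). The severity of the syndrome depends on the paternal element load,
the maternal cytotype, temperature, and their interactions; a second DNA
transposon, *hobo*, can contribute independently.

`dysgene` implements the full inference chain from sequencing alignments
to phenotype models:

1. estimate element copy number per isofemale line from read depth;
2. call insertion sites from split short reads and spanning long reads;
3. profile internally deleted copies along the element consensus;
4. fit the multinomial / Poisson / permutation / bootstrap models linking
   copy number, cytotype and temperature to ovary phenotypes.

A synthetic-data module generates every input the chain consumes, so the
whole pipeline is testable end to end without external data or an
aligner.

# Copy number from depth ratios

For a line sequenced at roughly uniform coverage, the number of element
copies per genome is estimated as

$$\widehat{CN} = \frac{\text{mean depth over the element consensus}}
                      {\text{mean depth over the host genome}},$$

with zero-depth positions included in both denominators. A diploid line
carrying a single heterozygous copy contributes 0.5 consensus-depth
units, so lines with $\widehat{CN} < 0.5$ are classified M
(element-negative); the boundary itself classifies as P because the rule
is a strict "fewer than". Copy numbers are reported to two decimals.

Assumptions worth keeping in mind:

* depth must be computed from primary alignments above a mapping-quality
  floor (default 20); secondary and supplementary records are excluded by
  default because double-counting split reads inflates the numerator;
* internally deleted copies contribute only their retained fraction of
  the consensus, so the depth ratio estimates *full-length-equivalent*
  copies, not insertion count - a line with eight complete and four
  half-length copies reads as about ten;
* the genome denominator assumes the reference is largely free of
  element-homologous sequence. Both the threshold and the filters are
  arguments, not constants.

# Insertion sites from split reads

A read crossing an insertion junction aligns partly to the host genome
and partly to the element; the clipped portion of the genomic alignment
marks the breakpoint. `call_insertions_short()` requires

* a genomic record with a soft/hard clip of at least `min_clip = 20` bp,
* whose read also aligns within `terminal_window = 200` bp of an element
  terminus (junction sequence is TIR-proximal by construction),
* with at least `min_support = 3` such reads after single-linkage
  grouping of raw breakpoints within `group_window = 15` bp.

Split-read evidence is consumed at a mapping-quality floor of 1 - far
below the depth filter - because clipped reads legitimately map poorly.
A site is *exact* when the modal breakpoint carries more than half of its
support (the reported position is the mode) and *approximate* otherwise
(the support-weighted median). This operationalisation is deterministic
and monotone in read support; none of these thresholds has a canonical
published value, so all are exposed as arguments.

Element insertion leaves an 8-bp target-site duplication (TSD), so every
insertion has two true breakpoints 8 bp apart (one per junction). The
simulator records an insertion's position as the *midpoint of the TSD*;
both junction breakpoints then sit 4 bp from the recorded position, and a
caller reporting either junction or their median is within 5 bp of
truth. Long-read calling (`call_insertions_long()`) accepts a site only
when a single read anchors at least `anchor_min = 200` bp of genomic
sequence on *both* sides of its element-aligned segments, and reports the
midpoint between the flanking genomic blocks - the same convention.

Per-line site lists are first-class; clustering across lines
(`cluster_sites_across_lines()`, 50-bp single-linkage window, at most one
site per line per cluster) is a separate, explicit step. The summary
statistic

$$\frac{\#\text{sites}}{\#\text{lines} \times \text{haplotypes/line}
  \times \overline{CN}}$$

("haplotype-sites per copy") is near 1 when insertion sites are private
to single haplotypes within the sequenced pools; it is reported to three
decimals, truncated, matching the precision at which such pooled
frequencies are printed.

# Internally deleted copies

Element populations degenerate quickly: copies retaining only the
terminal exons (0 and 3) accumulate because internal deletions spare the
TIRs that transposase recognises. Two complementary views:

* **Coverage profile.** Per-base short-read depth along the consensus.
  With truncated copies three times as numerous as complete ones, the
  expected depth over exons 0/3 is $(3 + 1)$ units against 1 unit over
  exons 1/2 - a 4-fold terminal/internal ratio, computed by
  `exon_summary()`.
* **Spanning long reads.** For a read that fully spans a copy with both
  genomic anchors, `classify_copy_structure()` marks an exon *retained*
  when at least 80% of its bases are covered by the read's
  element-aligned segments; a copy is complete iff all exons are
  retained. The 80% threshold is this package's choice (no published
  value exists); it tolerates alignment-edge noise while rejecting
  half-deleted exons.

# The synthetic-data generator

`make_te_library()` builds a random consensus whose last `tir_length`
bases reverse-complement the first, plus deletion variants concatenating
a chosen exon subset between both TIRs. `make_line_genome()` places
copies uniformly at random (exact-spacing construction, minimum 1-kb
separation) with an 8-bp TSD; `zygosity < 1` adds the insertion-free
haplotype to the pool with the complementary weight, emulating a
segregating isofemale line.

Read simulators draw `round(coverage * L / (2 * read_length))` fragment
pairs (or `round(coverage * L / length_mean)` long reads) uniformly from
the haplotype pool and emit **truth alignments** directly: a read
crossing a junction is split into one aligned block per underlying
segment, with clip fields set exactly as a mapper would set them. Split
blocks are all emitted as primary records so that depth computed under
the default filters is unbiased (a real mapper would mark one part
supplementary). Defaults mirror the study conditions: 100-150-bp pairs
at 30x for short reads; long reads much longer than the element, so most
element-overlapping reads span it with both anchors.

What the generator deliberately does **not** emulate: realistic error
profiles (substitutions are uniform; no indels, no quality model),
mapping ambiguity from genomic repeats or element-homologous reference
sequence, reference-assembly errors, and piRNA-mediated repression
dynamics. Passing recovery tests therefore demonstrates the correctness
of the *inference logic* under idealised alignments, not robustness to
mapper artefacts on real libraries - an optional hook for running a real
aligner on the emitted FASTQ exists precisely because those artefacts are
out of model.

Phenotypes (`simulate_phenotypes()`) are drawn from the same model
families later fitted: ovary count (0/1/2) from a 3-category multinomial
logit with reference "2 ovaries", per-ovary ovariole counts from a
log-linear Poisson model, over the terms intercept, maternal cytotype,
paternal element copy numbers, temperature, age and their interactions.
The shipped preset (`hd_preset_coefficients()`) was chosen once, a
priori, to reproduce the qualitative pattern - dysgenesis only in
M x P crosses, only at high temperature, monotone in paternal copy
number, with an extra senescence slope on the order of $6 \times 10^{-3}$
per day for a 10-copy father at 29 °C - because no fitted generative
coefficients exist to copy; magnitudes are simulation defaults, not
estimates. Each simulation seeds its own stream from one master seed, so
partial re-runs are reproducible.

# Phenotype models

* **Ovary counts** are fitted with `nnet::multinom` behind
  `fit_multinomial()`, reference category "2 ovaries" so that negative
  logit shifts read as dysgenesis. Complete separation - routine here,
  since entire cross types can be uniformly healthy - is detected from
  exploding coefficients (or a single observed category, anchored with
  weight-$10^{-3}$ pseudo-records) and handled by a small ridge penalty;
  the fit is flagged, never silently dropped.
* **Ovariole counts** use the mean per functional ovary, rounded to
  integer, as a Poisson response (`fit_poisson()`). Published analyses
  state both "nearest integer" and "upper nearest integer" in different
  places; the rounding mode is an argument (`"nearest"` default, `"up"`
  available) applied identically everywhere. Females with both ovaries
  atrophied are missing data for ovariole models but full data for
  ovary-count models.
* **Inference** is by likelihood ratio throughout: `lrt()` for nested
  pairs, `type3_terms()` for per-term tests (LR statistics; terms whose
  interactions remain in the model are marked non-deletable rather than
  tested against a marginality-violating reduction), and
  `stepwise_simplify()` for highest-order-first deletion at a chosen
  alpha.
* **Permutation tests.** `fisher_pitman()` uses the standardised
  difference of group sums under label permutation - exact enumeration
  up to 10 observations, Monte-Carlo with the add-one estimate above.
  The Bonferroni threshold for the six pairwise cross comparisons
  (0.05/6 = 0.008) ships as the constant `HD_ALPHA`.
* **Explained deviance.** `dsquared()` is
  $(D_{null} - D_{res})/D_{null}$, the GLM analogue of $R^2$.
  `bootstrap_r2_compare()` resamples each dataset with replacement,
  collects the $D^2$ distributions, and compares them with a two-sided
  permutation Wilcoxon rank test.

## A caveat on comparing bootstrap distributions

Treating `n_boot` bootstrap replicates as independent observations makes
the rank test extremely powerful against *any* difference, including
pure dataset-level sampling error: each distribution concentrates around
its own dataset's point estimate, so even two halves of one homogeneous
dataset typically differ "significantly". The procedure is implemented
as described because it is the procedure being reproduced, but its P
values should be read as a description of the bootstrap distributions,
not as a calibrated test of model equality; the honest nulls are
identical inputs (median difference negligible against the bootstrap
spread). This anticonservatism is visible in published uses, where
percent-scale $D^2$ differences yield |Z| > 25.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; SAM positions
  convert on ingest (`target_start = POS - 1`), and clip fields always
  refer to the original read, whatever the strand or dialect.
* Breakpoint ties: the modal breakpoint resolves ties to the smallest
  position; medians round half away from the left end via `round()`.
* `estimate_copy_number()` refuses a zero genome depth rather than
  returning 0; `classify_infection()` rejects negative input; zero-depth
  internal exons flag the fold ratio as non-finite instead of dividing.
* LRTs clamp the statistic at 0 (numerically negative improvements are
  treated as ties) and define P = 1 for identical models.
* All Monte-Carlo machinery takes explicit seeds; simulation helpers
  accept one seed per call and are byte-reproducible under it.

# Problem sizes used by the tests

The test suite and the acceptance script run the chain at the study's
stated conditions scaled to desk size: 100-kb single-contig genomes,
0-20 homozygous copies, 30x paired 150-bp reads (10-20 replicate
simulations per condition), long reads of mean 12-15 kb, diallel
phenotype tables of 300-400 females per cross, 500-1000 replicate null
fits for calibration checks, and $10^5$ permutations where Monte-Carlo
and exact permutation P values are compared. These sizes give the
estimators sampling noise well inside the tolerances being checked
(e.g. depth ratios vary by ~2% at 30x over 100 kb).

# Known limitations

* Truncation profiling classifies retained exon *sets*; it does not
  reconstruct deletion breakpoints at base resolution.
* The depth-ratio estimator reports full-length-equivalent copies; a
  genome rich in short fragments under-counts insertions (by design -
  the same bias exists in the real estimator).
* Insertion frequency within a pooled line is summarised only by the
  closed-form haplotype-sites-per-copy statistic; no per-site pool
  genotyping is attempted.
* The multinomial/Poisson machinery covers fixed-effects models only; no
  mixed-effects extensions.
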