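---
title: "lincscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincscreen)
```

# Scope

`lincscreen` implements the computational backbone of a multi-strain
lincRNA knockout screen: selecting candidate loci that are confidently
noncoding, predicting their function from coexpression, testing whether a
deleted locus behaved as a local (cis) enhancer, and the genetic and
morphometric statistics used to characterise knockout strains. Upstream
read alignment, transcript assembly and differential-expression estimation
are out of scope: their outputs (FPKM matrices and Cuffdiff2-style
differential tables) are consumed as inputs. Likewise, PhyloCSF scores,
mass-spectrometry tag counts, synteny and chromatin flags arrive
precomputed; the package applies the decision rules, it does not rederive
the evidence.

All genomic coordinates are 0-based half-open (BED convention) throughout;
conversion to the 1-based closed convention of `GenomicRanges` happens at
a single internal boundary, never downstream.

# Candidate selection

The filter cascade (`run_selection_pipeline()`) applies, in order:

1. **Annotation overlap** — a candidate is excluded if its locus overlaps
   one or more bases of any non-lncRNA annotation, strand-agnostically.
   Half-open abutment is not overlap. No slack is applied because the
   selection rule is stated as plain overlap.
2. **Codon substitution frequency** — kept iff `csf_score < -200`,
   strictly; a score of exactly −200 is excluded (literal reading of
   "scores below −200"). Candidates with no score cannot demonstrate
   noncodingness and are routed out with reason `no_score`.
3. **Mass-spectrometry tags** — kept iff at most 2 mapped peptide tags.
4. **Ribosome release score screen** — the published selection compared
   candidate RRS values against the distribution for known coding genes
   without stating a numeric cutoff. To make the screen executable we flag
   a candidate as coding-like when its maximum RRS exceeds a percentile
   (default 5th) of a user-supplied coding-gene RRS distribution; the
   percentile is a config knob, and with no reference distribution the
   screen passes everyone. A candidate whose RRS is undefined carries no
   ribosome evidence and passes.
5. **Boolean genomic criteria** — human syntenic ortholog and the
   H3K4me3/H3K36me3 active-transcription signature, consumed as boolean
   columns. The enhancer-like chromatin flag is carried through but never
   filtered on: it marked a subset of interest in the original design, not
   a requirement, and no numeric rule converting chromatin states into
   that flag is published, so it is consumed as a boolean input.

Filters short-circuit for reporting (a candidate's trace stops at its
first failure) but membership is unaffected: the kept set equals the
intersection of the individual filters' keeps, which the test suite checks
as an invariant.

The timecourse filter (`temporal_induction_filter()`) reproduces the
two-stage human-ortholog selection: genes differentially expressed
(`q < 0.01`) between any two adjacent differentiation timepoints, and the
subset also significantly changed *and* up relative to day 0. "Induced"
requires a strictly positive direction at the same q threshold as the
adjacent-pair test — a single coherent false-discovery rate rather than a
second, unstated one.

# ORFs and the ribosome release score

`enumerate_orfs()` defines a putative coding region as the span from an
ATG to the next in-frame stop codon. Three boundary conventions are fixed
here and used consistently:

* the stop codon is counted inside the CDS span, so its length is a
  multiple of 3 and at least 6 nt (one codon plus stop); no longer-ORF
  threshold is applied because none is stated for the original screen;
* the putative 3′-UTR runs from the end of the stop codon to the next ATG
  *in any frame*, or to the transcript end; it can be empty;
* codons containing `N` never match a start or stop (conservative calling).

`compute_rrs()` is the ratio of ratios
`(F_cds / F_utr) / (R_cds / R_utr)` over per-position count sums of the
footprint (`F`) and total-RNA (`R`) tracks. Whether the original counts
were per-read-overlap or per-5′-end is not stated; counting here is
per-position coverage sums, which is flagged as this package's choice. An
empty 3′-UTR or a zero denominator makes the score *undefined* (`NA`), not
zero or infinite: division artifacts would otherwise dominate the
maximum. `max_rrs()` maximises over defined ORF scores; ties go to the
5′-most ORF for determinism. Uniform tracks give RRS = 1 for every ORF,
and a common positive scale factor on both tracks cancels — both are
tested properties.

# Rank-based enrichment and guilt by association

`gsea()` ranks genes by their signed differential test statistic
(descending; ties broken lexicographically by gene id so results are
reproducible), maps each gene set into the ranking, and tests members
against non-members with a Mann-Whitney U test. The test is two-sided —
enrichment and depletion are both of interest — with direction reported
via the sign of the set z-score. P-values are Benjamini-Hochberg corrected
across the tested sets (`stats::p.adjust` behind the `bh_correct()`
surface); sets mapping fewer than `min_set_size` (default 5) genes are
skipped with a reason and excluded from the correction.

**Exact vs approximate.** When `|set| * |background| <= 10000` the exact
null distribution of U is used. For untied scores it is computed by an
in-package dynamic program over the Gaussian-binomial recurrence (cached
per set/background size, cross-checked against `pwilcox` and exhaustive
permutation in the tests). Scores with ties have no closed-form exact
distribution, so small tied problems (`choose(n, m) <= 20000`) are
enumerated exhaustively; anything larger falls back to the normal
approximation with average ranks, tie-corrected variance and continuity
correction. If every score is identical the test is degenerate and `p = 1`
by convention. The exact and normal branches agree within 0.02 by n = 200,
which the suite checks.

**Set z-score.** The published heatmaps are shaded by a z-score of the
statistic for set members "relative to all genes" without a formula. We
use the standardized set mean,

`z = (mean_set − mean_all) / (sd_all / sqrt(|set|))`,

with `sd_all` the population standard deviation of all values — a
standard choice, invariant under affine transforms of the statistic, and
isolated in `set_zscore()` so it can be swapped. A zero background
standard deviation yields an `NA` sentinel.

`gba()` computes the Pearson correlation of a focal lincRNA's FPKM profile
with every protein-coding gene across the compendium samples (zero
variance rows are excluded with a record; a zero-variance focal profile is
an error), ranks coding genes by correlation, and feeds the same
Mann-Whitney machinery. Set significance is called on the *raw* p-value at
`1e-6`, matching the published threshold; BH q-values are reported
alongside for stricter use. Mapping mouse ids to human gene-set
namespaces is consumed as an optional external two-column table, not
computed.

# The cis-enhancer bootstrap

`bootstrap_cis_test()` counts OK-status genes with `q <= 0.05` whose TSS
lies within ±1 Mb of the focal TSS (closed window after clipping to the
chromosome; the focal gene itself is excluded) and compares that count
with the counts in 1000 random genome-wide windows of the same total
width. Three conventions:

* **TSS-point membership**, not interval overlap — unambiguous at window
  edges; the TSS is the interval start on `+` and the end on `-`.
* **Closed window edges** after clipping; the effect is negligible but
  determinism at boundaries matters for testing.
* **Null windows are fully random**, weighted by eligible start positions
  per chromosome, not matched for gene density. The reported p is
  therefore a background-local-enrichment probability, never a
  density-adjusted one.

The empirical p is the defined ratio `#(null >= observed) / n`, which can
be exactly zero; the conservative add-one variant `(k+1)/(n+1)` is always
reported alongside, and doubles as the resampling false-discovery-rate
estimate (the original methods mention such an estimate without defining
it; this is the one quantity the same resampling supports).

**Calibration methodology.** The bootstrap p is discrete (counts are small
integers), so a plain Kolmogorov-Smirnov test against Uniform(0,1) would
reject for discreteness rather than miscalibration. The calibration suite
therefore tests the *randomized* (fuzzy) p-value
`(#(null > obs) + U * (#(null = obs) + 1)) / (n + 1)`, `U ~ Uniform(0,1)`,
which is exactly uniform when the focal window is drawn by the same scheme
as the null windows — the standard construction for assessing discrete
tests. The package itself always reports the plain ratio.

# Mendelian and morphometric statistics

`expected_mendelian()` gives unrounded expected class counts: 1:2:1 for an
autosomal heterozygote intercross and uniform quarters for an X-linked
carrier-female × wild-type-male cross (the design consistent with a viable
carrier line; other designs are supplied as explicit proportion vectors).
`chi_square_goodness()` is the standard `sum((O−E)^2/E)` statistic with
`df = classes − 1`.

Two penetrance estimators are deliberately distinct:

* `penetrance_of_lethality(observed, expected)` is the reporting-style
  ratio `max(0, 1 − observed/expected)` for a supplied expectation (for a
  published census, the genotyped total times the Mendelian proportion).
  It is clamped at zero because sampling noise can push the observed count
  above the expectation.
* `estimate_penetrance(counts)` recovers the generating penetrance from a
  simulated cross by scaling the *unaffected* classes (e.g.
  `(wt + het)/3` expected homozygotes for an autosomal intercross). The
  census-total convention is biased downward under lethality — the deaths
  shrink the genotyped total — which the test suite demonstrates.

Even the best estimator is noisy at realistic litter totals: with
n = 500 offspring the standard deviation of the recovered penetrance is
about 0.05–0.08 across the penetrance range, so a ±0.05 recovery band
cannot be hit in 95% of simulations at that size; the consistency property
is instead verified at n = 4000, where the estimator concentrates.

Morphometric comparisons use the unpaired pooled-variance Student t test
(`ttest_equal_var()`, two-sided; degenerate zero-variance inputs follow
`t = 0, p = 1` / infinite-t conventions), group summaries as mean ± SEM
with the sample (n−1) standard deviation, and signed percent change
`100 (m_test − m_ref)/m_ref`, reported to two decimals. Note percent
changes recomputed from *rounded* published group means can differ from
published percentages in the second decimal (e.g. 13.01% vs a printed
12.97%); the printed means are the authoritative inputs here and the
recomputed value is what the code reports.

# The synthetic-data module

Every generator is a pure function of its arguments and a seed; the global
seed expands into per-generator substreams by hashing the generator name,
so adding a generator never perturbs another's draws, and the caller's RNG
state is restored. Defaults are fixed once at field-realistic values:

* `gen_genome()` — 5 chromosomes around 100 Mb, 4000 genes of 5–50 kb,
  20% lincRNA: roughly mammalian gene density (~8 genes/Mb), so a ±1 Mb
  window holds 10–20 genes as in a real cis test.
* `gen_ribosome_profile()` — Poisson counts at mean depth 50 inside the
  first ORF and a 10-fold drop outside it for coding transcripts
  (translated ORFs show an order-of-magnitude footprint drop after the
  stop); uniform tracks for noncoding transcripts and for total RNA.
* `gen_expression_compendium()` — a shared latent sample profile with
  loading `sqrt(r)` gives planted rows pairwise correlation `r`; baseline
  FPKM 100 ± 20 keeps the zero-truncation (FPKM is non-negative) rare, so
  truncation is applied rather than redrawn and leaves means and
  correlations essentially unchanged.
* `gen_diff_table()` — significance is planted exactly (`n_local_de`
  in-window, `n_global_de` elsewhere), with `p <= q` per row so the table
  respects BH monotonicity.
* `gen_cross_counts()` — multinomial Mendelian draws, then independent
  removal of null homozygotes with the planted penetrance.

What the generators do **not** emulate — and therefore what passing tests
do not show about real data: library-size and length normalization
artifacts in FPKM, correlated gene modules beyond the single planted one,
gene-density and GC structure along real chromosomes, overdispersed or
positionally biased ribosome footprints, linkage between genotype classes,
and batch effects across compendium samples. The suite demonstrates that
the algorithms recover what was planted under their stated assumptions,
not that those assumptions hold for any particular dataset.

# Problem sizes and numerical choices

The default test run uses desk-scale sizes chosen to exercise every code
path while keeping the suite quick: 1000 random transcripts (length ≤ 300)
for the ORF oracle; exhaustive permutation for all label splits up to
n = 10; 500 replicates for each calibration (enrichment, bootstrap,
chi-square) with 150–1000 resampling iterations inside; 100–200 seeds for
power and recovery properties. Tolerances: exact-oracle comparisons at
1e-12; stochastic properties at the binomial bounds stated inline.

Other numerical conventions collected in one place: BH q-values are
returned in input order; empty gene sets and inverted/empty BED intervals
are errors naming the offender; `NOTEST` differential rows are retained on
read but excluded from every significance count; undefined RRS values
propagate as `NA` sentinels, never as zeros.

# Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from package
functions alone, the worked viability and morphometry figures (from the
published group means and genotype counts, which are inputs) and the
seeded synthetic recoveries (planted GBA module, planted cis enrichment,
RRS properties), writing one JSON object per quantity. The README shows a
worked example with the numbers it prints.
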