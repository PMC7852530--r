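---
title: "Methods: trio de novo variant analysis in denovotrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio de novo variant analysis in denovotrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
rules each stage implements, the assumptions behind them, the parameters
that matter and why their defaults are what they are, what the synthetic
data generator does and does not emulate, and the design choices that were
genuinely open.

## The analysis in one paragraph

Whole-genome sequencing of parent-offspring trios allows direct detection
of de novo variants (DNVs): alleles present in the child and absent from
both parents. In a cohort of trios whose children share a complex disease,
the genomic distribution of DNVs can be compared with DNVs from healthy
population trios; an excess of patient DNVs in a functional compartment —
promoters, open chromatin, dense transcription-factor-binding clusters —
implicates that compartment in disease risk even though each individual
variant is unique. Around this core comparison sit supporting analyses:
strict per-call filtering (DNV calling is precision-limited), read-backed
assignment of each DNV to the parental gamete of origin, regression of DNV
counts on paternal age, and a specificity-oriented consensus procedure for
de novo structural variants.

## DNV candidate detection and filtering

A site is a Mendelian violation when the child carries an alternate allele
seen in neither parental genotype. Only the canonical pattern — child
`0/1`, both parents `0/0` — becomes a candidate by default.
Child-homozygous-alternate patterns (`1/1` with `0/0` parents) would
require the same mutation on both gametes and are overwhelmingly
genotyping artefacts at ~30x coverage; they are flagged for audit but
excluded unless `emit_flagged = TRUE`. Sites with a missing parental
genotype cannot be classified and are counted separately. This default is
our choice (the germline callers this mirrors behave the same way), kept
behind a flag because the right behaviour depends on the caller upstream.

Three independent filters follow; their order never matters because each
sets its own flag:

* **Genotype posterior quality** (`min_posterior`, phred, default 20): the
  minimum over the three trio members must reach Q20, i.e. 99% posterior
  confidence per genotype. The trio minimum is used because a single wrong
  genotype in any member fabricates or destroys a DNV.
* **Allele balance** (`ab_low`/`ab_high`, default 0.30/0.70, inclusive):
  the fraction of the child's reads carrying the alternate allele. True
  germline heterozygotes cluster at 0.5; low AB indicates postzygotic
  mosaicism or error. The source analysis states the window as "between
  30 and 70%" without inclusivity; we chose inclusive bounds so a 10-read
  site with 3 alternate reads passes. Zero-depth sites fail with the
  distinct reason `zero_depth`.
* **External classifier score** (`score_threshold`, default 0.5): hooks in
  a machine-learned de novo score (DNMFilter-style gradient boosting over
  read-level features). The model is external by design — its training
  data and features are not part of this analysis — so the package accepts
  a per-variant score table and applies the threshold; calls without a
  score pass, making the hook optional.

Validation arithmetic is deliberately plain: with `t` assays that returned
a result and `c` confirmations, the false discovery rate is
`100 (t − c) / t` percent, rounded half-up for reporting (all reported
integers in the package round half away from zero, avoiding R's banker's
rounding).

## Annotation

Gene-position classes use the precedence
exon > UTR5 > UTR3 > upstream > downstream > intron > intergenic, one
label per variant, in the style of the annotator this mirrors; the
precedence is not stated in the source analysis and is our fixed choice.
"Upstream" is a strand-aware window of `upstream_window` bp (default
1000, the annotator convention) 5′ of a transcription start site.
Chromatin states (Promoter/Enhancer/Other) come from a ChromHMM-style
segmentation of a B-lymphocyte line — B cells because the motivating
disease is characterized by B-cell dysfunction; positions in segmentation
gaps are `Other`. The TFBS feature counts binding-site intervals
overlapping the variant position, thresholded at ≥ 10 (inclusive, as the
source's feature is labelled "TFBS >= 10").

The GC filter excludes variants in 100 bp windows with at least 75% GC
(inclusive at exactly 75) or in "difficult promoter" lists, and is applied
to case and control sets symmetrically before any counting, because
GC-rich regions have library-preparation-dependent coverage and the
control resource was sequenced with different library chemistry. Windows
are non-overlapping tiles anchored at coordinate origin — the source does
not specify tiling versus sliding; tiling makes the window of a variant
reproducible and the filter idempotent.

Nonsynonymous status is taken from a precomputed per-variant column
rather than re-derived from codons: no CDS-bearing gene model exists in
the synthetic world, and the published nonsynonymous counts enter the
enrichment arithmetic as counts. The column slot keeps the feature in the
table without pretending to a translation step the package does not have.

## Enrichment statistics

For feature counts `a` of `n1` (cases) and `b` of `n2` (controls) the
primary statistic is the **ratio of proportions** `R = (a/n1)/(b/n2)`.
The published table this reproduces labels its column "odds ratio", but
its printed values reproduce from its printed counts only under the
ratio-of-proportions formula (87/4157 over 1442/97942 gives 1.42 where the
cross-product odds ratio gives 1.43); both statistics are therefore
emitted, with `R` primary. One published row ("TFBS ≥ 10", printed 1.61)
matches the cross-product value instead, suggesting the formula was not
applied uniformly at the source; the package does not special-case it.

Significance is Pearson's chi-squared on the 2×2 table with 1 df, with
Yates' continuity correction available as a flag (the source used plain
Pearson for the main table and Yates for a small visually-curated subset).
The package reports its own p values: the published promoter p (0.0019) is
not exactly recovered from the published counts by either variant (0.0013
plain, 0.0016 Yates), plausibly because the GC filter slightly altered the
totals behind the printed table; forcing agreement would be fabrication.
Bonferroni correction multiplies by `m` (default 13, the number of
features tested) and caps at 1.

Two derived quantities summarize effect size in patient terms. The
expected excess `E = a − a/R` is the number of feature DNVs above the
control-rate expectation. Under uniform allocation of `k` excess variants
among `T` patients, each patient carries at least one with probability
`1 − (1 − 1/T)^k`; both the unrounded probability and the rounded patient
count are reported because the published frequency (0.26) corresponds to
the unrounded probability, not to the rounded patient ratio.

Degenerate inputs are explicit: `b = 0` yields an `NA` ratio sentinel with
a continuity-corrected alternative `((a+½)/n1)/((b+½)/n2)` always
available; a zero expected cell is an error for the chi-squared test; an
empty case cohort (before or after GC filtering) is an error rather than
an empty table.

## Parent of origin and paternal age

A DNV is phased by linking it, on a physical read, to an **informative**
inherited SNV: a child-heterozygous site whose parental genotypes admit
exactly one assignment of the child's two alleles to parents (father
`1/1` / mother `0/0`; or father `0/1` / mother `0/0`, where the mother
cannot have donated the alternate allele; and the mirrored patterns).
Each read carrying the de novo allele and covering an informative site
votes for the parent that donated the observed informative allele; reads
whose informative sites disagree internally are discarded. Assignment
requires at least two concordant reads — the stated rule — and, our
addition, zero opposing reads: the source specifies only the two-read
minimum, and the strict conflict rule matches its evident preference for
specificity over yield. The search window defaults to 500 bp,
approximately the read-pair span at a 350 bp insert; spanning mate pairs
are allowed by the evidence format, which records all positions a read
pair observed.

The paternal-age effect is unweighted ordinary least squares of per-child
DNV counts on the father's age at conception (slope in DNVs/year, Pearson
r, t-test p), with a second fit on both parents' ages giving the
conditional paternal slope. The source names only "linear regression";
OLS without weights is the minimal reading. Degenerate designs (constant
age, fewer than three children) are errors.

## De novo structural variants

Germline SV callers do not emit de novo calls, so the pipeline derives
them with four ordered, individually auditable stages (the ordering
matters only for attribution — each removed candidate records the first
stage that failed it):

1. **Consensus**: child calls longer than 10 bp present in both callers'
   output, same type, at reciprocal overlap ≥ 0.5 (both fractions,
   inclusive). Pairing is greedy on the best minimum-fraction overlap with
   ties broken by smaller start coordinate; each call is used once. The
   consensus interval keeps the caller-A coordinates, on the view that the
   breakpoint-precise caller provides the better coordinate set and one
   canonical interval simplifies everything downstream.
2. **Parental subtraction**: any same-type parental record matching at the
   same threshold removes the candidate — including low-confidence
   *candidate* records from the callers, which is the stated design: a
   variant weakly visible in a parent is inherited, not de novo.
3. **Annotation exclusion**: a candidate whose interval is covered more
   than `phi` (default 0.5) by any single exclusion track (ENCODE-style
   blacklist, low mappability, segmental duplications, repeats) is
   removed. `phi = 0` makes any overlap fatal.
4. **Coverage similarity**: profiles of binned read depth over the
   interval plus `flank` bp (default 1000) on a common grid are compared
   between child and each parent by Pearson correlation; similarity
   ≥ `rho` (default 0.9) to either parent removes the candidate. A true
   de novo deletion halves the child's interior depth while the parents
   stay flat, breaking the correlation; a shared mapping artefact dips in
   all three and is removed. "Similar pattern" is not defined in the
   source's main text — the correlation rule is our interpretation, kept
   isolated in one function so it can be replaced. Strictly constant
   profiles leave the correlation undefined; such candidates are kept
   with a warning rather than silently dropped, and the manual
   genome-browser confirmation step of the source is replaced by the
   audit trail.

SV coordinates follow the HGVS convention for lengths: a deletion of
bases `start..end` (1-based, both deleted) has length `end − start + 1`,
which equals `END − POS` of a VCF record whose POS is the padding base.
The reader therefore stores `start = POS + 1`, `end = END`, and takes
`abs(SVLEN)` when present.

## Coordinate conventions

All in-memory intervals are `GRanges` (1-based, closed) — the
field-standard container in R — rather than the 0-based half-open
convention a Python implementation would pick. BED input and output pass
through `rtracklayer`, which performs the 0-based/1-based conversion, and
VCF positions are 1-based natively, so converting twice is the identity
in both directions. Multiallelic VCF sites are decomposed into one
biallelic record per alternate allele by default (a `skip` option exists),
because every de novo rule is defined per alternate allele; the source
does not state how such sites were handled.

## The synthetic world

The generator emulates the statistical structure the analysis needs, with
defaults fixed once to the stated or field-realistic values:

* 71 trios; per-child DNV counts Poisson with mean
  `lambda0 + 1.56 × father_age` (Poisson is the standard count model; the
  source implies only linearity). Father ages are uniform on 20–45 years,
  and `lambda0 = 8.3` so the cohort mean is ~59 DNVs per child at the
  mean age; mothers are on average 2.5 years younger with a zero maternal
  slope by default.
* DNV positions drawn by rejection sampling with per-feature multipliers
  (default 1 everywhere: the null), which makes planted enrichments
  exactly controllable. The genome is two 500 kb chromosomes with 24
  genes whose geometry (3 kb introns) gives a realistic ~37% intronic,
  ~55% intergenic class distribution. TFBS-rich promoters carry stacked
  clusters of 10–15 sites so the ≥ 10 threshold has mass on both sides.
* Depths are Poisson around 30x with binomial allele balance — so a
  realistic ~1.6% of true planted DNVs legitimately fail the 30–70%
  window — and 3% of genotype qualities fall below Q20. The ledger
  records each planted DNV's expected fate under the default thresholds,
  so audits distinguish "filtered, correctly" from "lost".
* Phasing: 60% of DNVs get an informative SNV within the 500 bp window;
  supporting-read counts are drawn from a distribution with 15% mass at a
  single read, so the two-read rule visibly leaves DNVs unassigned;
  origins are Bernoulli with paternal fraction 0.8 (~4:1).
* Control sets (default 97,942 variants, the size of the population
  resource the analysis emulates) use multiplier-1 placement.
* SV data plant five categories per trio — true de novo (both callers,
  jittered breakpoints still above 50% reciprocal overlap), inherited
  (half subtractable only via parental *candidate* records), coverage
  artefacts (identical dip in all three samples), exclusion-region decoys
  and single-caller calls — each with a known intended failure stage.

What the generator does **not** emulate: sequencing errors and base
qualities (evidence is emitted at the observation level, not as reads to
align), mosaicism, population haplotype structure, recombination,
multi-nucleotide events, and caller-specific artefact spectra. A green
test therefore establishes that the pipeline's logic is faithful to its
rules and recovers planted structure; it says nothing about robustness to
upstream alignment or calling pathologies, which the real pipeline
delegates to the external callers and the validation assays.

Determinism is a contract: every generator output is a pure function of
its configuration (including the seed), which the tests verify by
regeneration.

## Test and acceptance design

The test suite prefers independent oracles over re-derived expectations:
candidate detection is checked against an exhaustive 27-pattern genotype
enumeration classified from first principles; the chi-squared statistic
against the brute-force Pearson formula on a thousand random tables; the
phasing rule against enumeration of all vote patterns up to four reads;
greedy SV pairing against validity and optimality audits on small random
fixtures. Parameter-recovery runs (paternal-age slope, paternal-origin
fraction, a planted twofold promoter enrichment) use 100 replicate
cohorts at reduced size — 20 trios against one fixed 10,000-variant
control set — purely for runtime; the generating values are the package
defaults, and each must fall inside the 95% Monte-Carlo interval of its
estimates. The slope estimate is attenuated by the ~5% of planted DNVs
the quality filters legitimately remove; the interval absorbs this. The
acceptance script recomputes only quantities that are exactly derivable
from published summary counts, through the same exported functions the
pipeline uses.

## Known limitations

* The enrichment test treats DNVs as independent observations; within-
  child correlation (shared ascertainment, shared coverage profile) is
  ignored, as in the source analysis.
* The ratio-of-proportions/odds-ratio discrepancy at the source cannot be
  resolved from the published material; both are reported.
* nsSNV status requires an external column; the package does not
  translate codons.
* The coverage-similarity rule is one reasonable formalization of
  "similar coverage pattern"; alternatives (rank correlation, interior
  dosage tests) plug into the same stage.
* The command-line surface is R functions plus `scripts/acceptance.R`;
  there is no shell subcommand wrapper, since the intended users drive
  the analysis from R.
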