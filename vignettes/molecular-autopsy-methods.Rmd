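---
title: "Methods: cohort-level molecular autopsy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level molecular autopsy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mautopsy)
```

## The problem

A molecular autopsy (MA) asks whether a heritable variant can explain a
sudden unexpected death in a young person. At the level of a single case
this is a variant-interpretation exercise; at the level of a cohort it
becomes a set of statistical questions: how much does exome sequencing add
over a cardiac gene panel, do pathogenic variants co-occur in the same genes
across cases, can a "genetic fingerprint" group cases with similar
genotypes, and does the mitochondrial genome carry an independent signal?
`mautopsy` implements those cohort analyses over per-sample annotated
variant tables, a case-metadata table, a gene panel, and a pedigree.

## The filter cascade

Each sample's raw calls are reduced in four stages: (1) raw; (2) QC pass;
(3) removal of internally common variants, internal-cohort MAF ≥ 5%;
(4) retention of population-rare variants, reference-panel MAF < 1%.

Two conventions deserve emphasis because they are easy to get silently
wrong:

- **Boundary asymmetry.** The internal filter *removes at* the threshold
  (≥ 0.05 is out) while the population filter *keeps strictly below* its
  threshold (< 0.01 stays). The defaults mirror how the thresholds are
  conventionally stated, and both are arguments of `apply_cascade()`.
- **Missing frequency passes.** A variant absent from the internal database
  or the reference panel is unobserved, hence rare, hence the analysis
  target; dropping it would discard exactly the novel variants the method
  exists to find. `strict_missing = TRUE` flips this for sensitivity
  analyses.

The cascade is idempotent and its stage counts are monotone non-increasing;
both properties are enforced by tests on random inputs.

Interpretation sits on top of the ordinal pathogenicity categories
(1 reported recognised cause, 2 unreported expected-causal type,
3 unknown significance, 4–5 synonymous/non-coding). When input already
carries categories they are never overridden; otherwise
`assign_category()` applies a deliberately simple, fully configurable rule
set (lookup of reported alleles → 1; protein-truncating → 2; missense → 3;
lower tiers by effect). It is a stand-in for a full annotation engine, not
a reimplementation of one, and is documented as such. Causal tiers then
follow: *likely* = category 1–2 in a sudden-death gene, *plausible* =
category 3 in a sudden-death gene, *speculative* = category 1–3 outside
that list but implicated in another disorder. A report is positive iff a
likely-tier variant exists. Whether the "sudden-death genes" for tiering
equal the restriction panel is a user decision; the functions accept
separate lists, and binding them is the default behaviour in the
command-line wrapper.

`summarize_counts()` states its quartile convention (linear interpolation
between order statistics, R type 7) because published count summaries
rarely name one; an independent sort-and-interpolate oracle checks it.

## Panel versus exome, co-occurrence

Panel restriction is by case-normalised gene symbol: the panel is a symbol
list, so coordinate overlap would add a second source of truth without a
reference to arbitrate it. Records without a gene symbol are excluded from
per-gene outputs and surfaced in an `n_unassigned` count rather than
silently dropped. An optional exclusion regex (off by default) supports
masking recurrently artefactual locus families such as the protocadherin
gamma cluster.

Gene-level abundance thresholds (`min_likely`) are applied per cohort, not
per sample, matching pooled histograms. Sharing (`max_shared`) counts
gene-set overlap between samples regardless of the specific allele — the
question is whether the same *genes* recur. The sharing histogram is
cumulative by default ("shares at least k genes with some other sample");
an exact-k mode is provided because both readings of such histograms occur
in practice.

## The genetic fingerprint

Per sample, categories 1–3 collapse to a gene set; category 3 is included
because categories 1–2 alone leave pairwise overlaps of at most a few
genes, too sparse to classify on. Similarity is intersection-over-union
(Jaccard), with two documented conventions: the similarity of two empty
sets is 0 (an empty union carries no evidence of similarity), and the
diagonal is 1 for non-empty sets.

Z-score standardisation uses the distribution of **all** n(n−1)/2 distinct
pairs globally, not per row, because the analysis reports one scalar Z per
pair and counts pairs above a global threshold. The standard deviation uses
the sample convention (divisor n_pairs − 1) by default; the population
convention is available, and on any realistic pair count the difference is
far below the reporting threshold. An all-equal similarity matrix has no
scale and is rejected as degenerate rather than standardised to NaN.

Clustering defaults — complete linkage on Euclidean distances between rows
of the (symmetric) matrix — are the defaults of a standard R heatmap, which
is the natural reference behaviour for this analysis; linkage and a direct
`1 − J` distance are configurable. The masked (NA) diagonal is replaced by
0 before row distances are taken. Merge heights are validated against a
naive O(n³) agglomeration oracle in the tests.

## Mitochondrial heteroplasmy

The heteroplasmic fraction is the alternate-depth share,
HF = d_alt / (d_ref + d_alt); no formula beyond this is standard, so it is
stated here and in the function documentation. Variants qualify when
`hf_low < HF < hf_high` and population MAF < 0.05. The lower bound 0.2 is
the published rule (strict, so HF = 0.2 exactly is out); the upper bound
0.95 is this package's documented default for separating heteroplasmy from
effective homoplasmy and is configurable because only the lower bound is
conventional. The D-loop is the rCRS control region, 16024–16569 and
1–576 (1-based inclusive); the locus map is extensible. High burden means
≥ 10 qualifying variants.

Parental sharing uses exact (position, ref, alt) identity with no HF
tolerance: transmission is a statement about which alleles are present,
not about their fractions. Mother and father are counted independently, so
maternal transmission and paternal background are distinguishable in
trios.

## Cohort statistics

Age groups overlap by design: infants (strictly under 12 months — a
one-year-old is not an infant), minors (≤ 18 years, the trio-sequenced
stratum), full cohort. Ages arrive either as "3 months" or as numeric
years and are normalised to months. The one sibling-pair case collapses to
a single analysis proband chosen by the cohort rule (the
forensic-autopsy-negative sibling); because the source table does not map
the two printed ages to the two siblings, the case's analysis age is the
younger sibling's, which is the only choice that reproduces the published
minors count.

The diagnostic-yield table is a plain 2×2 of MA × FA status with margins.
Weekday convention is ISO (Monday first) and affects labels only. The
clock-window fraction uses an inclusive start and exclusive end
(08:00–20:00 by default). Weekday clustering is tested with the exact
binomial upper tail, P = Σ_{i=k}^{n} C(n,i)(d/7)^i(1−d/7)^{n−i}; the
choice of an exact test (rather than chi-square or permutation) is
deliberate for n as small as 8, and the tests verify it against exhaustive
enumeration of all 7^n weekday assignments for every n ≤ 8.

## What the synthetic generator emulates

`generator_config()` defaults encode the cohort structure the analyses
assume: a bimodal age distribution (infant weight 8/50, infant ages 1–11
months; adult ages rising exponentially towards 44 years with scale 150
months — the exact form is configuration, not a claim), a 1:2
female:male ratio, logistic-in-age forensic-autopsy positivity
(intercept −2.5, slope 0.009/month: near zero for infants, around
two-thirds for older adults), per-gene variant counts proportional to a
locus-footprint column whose panel share is ~2% (the observed panel share
of cascade survivors), per-stage cascade survival set to the ratios of the
published per-stage medians (0.815 × 0.0582 × 0.0757 ≈ 0.36%,
"~0.4%"), and mitochondrial burdens with D-loop enrichment, full
maternal transmission by default, and a high-burden infant subgroup of
probability 0.5.

One coupling is worth spelling out. The cohort exhibits both a 28%
positive-report rate and a 54% rate of samples carrying ≥ 1 likely
pathogenic panel variant; if every such variant triggered a positive
report the two would be equal. The generator therefore draws the
per-sample panel likely-count from the published multinomial
(46/36/12/6% for 0–3) and, conditional on the count being nonzero, marks
one planted variant as a *recognised* cause (category 1 in a designated
causal sublist of the panel) with probability 0.28/0.54. Judging reports
against the causal sublist recovers 28% positives while the panel
likely-count histogram stays multinomial — one cohort satisfies both
published rates, mirroring the fact that real report positivity involves
adjudication beyond "category 1–2 in a panel gene".

What the generator does **not** emulate: linkage between variants, real
allele-frequency spectra (frequencies are drawn from uniform mixtures
calibrated only to the stage survival probabilities), sequencing depth
structure or caller error profiles, haplogroups, and any correlation
between nuclear genotype and demographics. Passing parameter-recovery
tests therefore demonstrates that the pipeline measures what the
generator plants — not that real cohorts will show these rates.

Determinism: every generator function seeds the RNG from `config$seed`
(with fixed offsets per stage), so a configuration reproduces its cohort
exactly across runs.

## Problem sizes and numerical choices in the test suite

Simulation sizes in the tests and the acceptance script are the package's
own choices, set where the standard errors of the recovered parameters are
small relative to their targets: 2,000 cases for rate recoveries
(3 binomial SEs ≈ 3 percentage points), 40 samples × 30,000 raw calls for
cascade retention (the cascade acts per variant, so retention statistics
are scale-free and do not require the ~98,667 calls per sample of a real
exome), 200 trios for maternal sharing, and 2,000 infants for the
high-burden fraction. Oracle comparisons run at the sizes where brute
force is exact and fast: ≤ 10 samples for set-arithmetic checks of the
Jaccard/Z matrices, ≤ 6 samples for the naive agglomeration oracle, and
all n ≤ 8 for exhaustive weekday enumeration.

## Known limitations

- Category assignment is a rule-based stand-in; it does not attempt ACMG
  scoring, and lookups are local files, not live database queries.
- Gene matching is symbol-based; there is no coordinate liftover or
  BED-overlap mode.
- The fingerprint analysis standardises a single global pair population;
  per-stratum fingerprints (e.g. infants only) require subsetting before
  the call.
- The temporal analyses treat death timestamps as exact; uncertainty in
  the recorded time of death is not modelled.
- Published exome-scale magnitudes that depend on the unreleased study
  sequence data (per-sample variant medians, specific Z-score values,
  per-gene counts) are out of reach by construction and are not targets of
  the test suite.
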