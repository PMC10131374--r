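---
title: "Estimating somatic variant clonality and its clinical correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating somatic variant clonality and its clinical correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonarch)
```

## The problem

Liquid biopsies report, for each called variant, an allele fraction (AF):
the fraction of cell-free DNA fragments carrying the alternate allele.  AF
conflates two quantities — how much of the plasma DNA came from the tumor
(the ctDNA fraction, or "shed"), and what fraction of tumor cells carry the
variant (its cancer-cell fraction).  Separating the two is what makes it
possible to ask whether two mutations in the same gene, e.g. the two
*PIK3CA* hotspot mutations frequently co-occurring in ER+/HER2− breast
cancer, are carried by the same dominant clone (and thus plausibly act in
concert on the same pathway) or by distinct subclones.

`clonarch` implements that separation and everything downstream of it:
sample-level tumor-fraction estimation, per-variant clonal fractions,
clonality categories by target-gene mutation multiplicity, co-alteration
contrasts between categories, and response/survival comparisons.

## Tumor-fraction estimation

**Liquid mode.**  When an aneuploidy-based tumor-fraction estimate is
available it is used directly (it is treated as an input; computing it from
coverage is out of scope).  Otherwise the maximum somatic allele fraction
(MSAF) stands in for the ctDNA fraction:

$$\mathrm{MSAF} = \max_i \{\mathrm{AF}_i : \text{somatic, non-CH}\}$$

Germline variants (AF ≈ 0.5 regardless of shed) and clonal-hematopoiesis
(CH) variants (blood-derived, present at AFs unrelated to tumor shed) would
otherwise dominate the maximum, so both are excluded — CH via the
per-variant flag plus a configurable gene list (`DNMT3A`, `TET2`, `ASXL1`
by default; panel blocklists differ, so the list is an argument).  Two
further choices:

* Calls with *ambiguous* somatic/germline status are excluded by default
  (conservative: a mis-included germline call inflates MSAF and deflates
  every clonal fraction); `include_ambiguous = TRUE` reverses this.
* A variant with observed AF = 0 carries no evidence of shed and cannot
  define MSAF.  A sample with no eligible positive-AF variant has no
  estimable tumor fraction, and any target-gene mutations it carries are
  `unestimable`.

**Tissue mode.**  With copy-number model outputs per variant (mutated
copies $mc$, wild-type copies $wc$), each somatic variant implies a sample
tumor fraction

$$\mathrm{TF} = \frac{2\,\mathrm{AF}}{mc - \mathrm{AF}\,(wc + mc - 2)},$$

which reduces to $2\,\mathrm{AF}$ for a heterozygous variant in a diploid
region.  The sample estimate is the maximum over somatic variants; variants
on amplified alleles can push the raw value above 1, so estimates are
capped at 1 with the raw value retained in an attribute and a warning
emitted.

## Clonal fractions and categories

The clonal fraction of a variant is $\mathrm{AF} / \mathrm{TF}$, capped at
1 (same amplified-allele caveat; capping never changes a label because both
thresholds are below 1).  Labels use **inclusive** thresholds: clonal at
≥ 0.25 in ctDNA mode — the clonal fraction at which a heterozygous
single-copy alteration is present in a majority of diploid tumor cells —
and ≥ 0.50 in tissue mode.  Both are exposed as configuration for
sensitivity analyses.

A sample's category is decided by its pathogenic target-gene SNVs
(oncogenicity `known`/`likely`; indels, copy-number alterations and
rearrangements in the target gene are reported but do not count toward
multiplicity):

| target SNVs | clonal among them | category |
|---|---|---|
| 0 | — | `no_pik3ca` |
| 1 | 1 | `clonal_single` |
| 1 | 0 | `subclonal_single` |
| ≥ 2 | ≥ 2 | `clonal_multiple` |
| ≥ 2 | ≤ 1 | `subclonal_multiple` |

Degenerate cases are explicit rather than silent: if any required label is
`unestimable` (tumor fraction or AF unavailable) the sample is categorised
`unestimable` and surfaced in the cohort-flow table, not dropped.  This
includes the genuinely ambiguous case of one clonal plus one unestimable
target mutation — the sample could be either kind of multiple, so no
category is asserted.

## Co-alteration analysis

A pathway is altered when at least one of its genes carries an alteration
of known or likely oncogenic significance, of any class.  The target gene
is removed from its own pathway list by default — in a cohort defined by
pathogenic *PIK3CA* mutations every sample would otherwise be PI3K-altered.
The shipped RTK/PI3K/MAPK/p53 lists are an approximation restricted to a
~70-gene liquid-panel-like universe and are user-overridable; analyses that
must match a specific published panel should supply their own
`pathway_config()`.

Group contrasts use the two-sided Fisher exact test under the
point-probability convention (sum of all tables with the observed margins
whose probability does not exceed the observed table's, within relative
tolerance 1e−7).  P-values are unadjusted by default — these are
exploratory contrasts — with an optional Benjamini–Hochberg column.  Genes
altered in neither group are omitted, matching tile-plot semantics.
Pairwise pathway co-occurrence reports odds ratios with the
Haldane–Anscombe 0.5 correction when a cell is empty, flagged in the
output.

## Outcome analysis

Response rates carry Clopper–Pearson exact intervals, computed from the
beta-quantile closed form; this is the interval family whose 0-of-5 upper
bound is $1 - 0.025^{1/5} = 0.522$, and display rounding is two significant
figures on the percent scale.  Comparisons between groups use an exact
conditional test: unstratified it is exactly the Fisher test; stratified,
the null distribution of the total group-A responders is the convolution of
per-stratum central hypergeometric distributions, with the same two-sided
point-probability rule.  Strata in which one group is absent are
uninformative and dropped with a warning.  Enumeration is exact — the
support of the convolution is tiny for trial-scale strata — so no Monte
Carlo fallback is needed at realistic sizes.

Survival comparisons use the Kaplan–Meier estimator (median = smallest time
at which the curve reaches 0.5 or below; absent if never reached), the
log-rank test, and a single-covariate Cox model with Efron tie handling (a
deliberate fixed default; exposed via the underlying fit object) for the
hazard ratio and its Wald interval.

## The synthetic-cohort generator

No patient-level data are distributable, so the generator produces
truth-labelled cohorts with the statistical structure the analysis assumes,
and the test-suite claims are claims about that structure:

* **Shed**: lognormal, `meanlog = log(0.08)`, `sdlog = 1`, truncated to
  (0, 1] — a median shed of 8% with a long right tail, typical of
  second-line metastatic breast cancer plasma.
* **Mutations**: each sample draws a true category (multiplicity 66/337,
  clonal share 0.712 among multiples and 247/271 among singles — the
  reported cohort composition); clonal mutations draw CCF in [0.6, 1],
  subclonal in [0.04, 0.20].  The gap around the 0.25 threshold is
  deliberate: truth labels are exact, and residual misclassification
  reflects read-sampling noise, not boundary ambiguity.
* **Observation model**: AF = CCF × shed / 2 (heterozygous diploid), with
  binomial noise at 5000× depth.  Every sample carries a truncal somatic
  passenger (CCF 1) so that MSAF tracks shed/2 the way a real panel's
  passenger repertoire does, plus Poisson extra passengers, CH contaminants
  (25% of samples) and germline variants (50%, AF 0.5).
* **Co-alterations**: per-category pathway rates (RTK 19.1% clonal vs
  47.4% subclonal multiples, PI3K 6.1%/13.1%, MAPK 24.0%/16.5%, p53 45%
  both — the last not reported as a contrast, set to a plausible mid
  value, as are the single-mutation rates).
* **Outcomes**: Bernoulli response and Weibull PFS (shape 1.2) with
  category- and arm-specific parameters matching the reported subgroup
  rates and medians (e.g. 7.6 vs 5.1 months in the experimental arm),
  independent exponential censoring at 0.03/month, 2:1 randomisation.

One `set.seed()` call governs a single RNG stream; the per-sample draw
order (shed, category, CCFs, passengers, CH, germline, pathways, clinical)
is part of the stable interface, so a fixed seed is bit-reproducible.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: variant detection (all rows are emitted,
possibly with AF 0; caller sensitivity and hotspot artifacts are absent),
copy-number effects on AF in liquid mode (the amplified-allele
overestimation the cap guards against is never generated), correlated
co-alteration structure beyond category-specific marginal rates,
non-proportional hazards, and informative censoring.  In tissue mode the
generator emits heterozygous-diploid copy numbers primarily so that
tumor-fraction recovery is testable; a truncal variant sits exactly at the
0.5 clonal-fraction boundary there, so tissue category recovery is
intentionally not a test target.

## Problem sizes and tolerances used by the test suite

Category recovery uses 1,000 samples at 5000× depth with shed ≥ 0.2
(accuracy ≥ 95% required; observed ≈ 100%).  Calibration of the generator's
clonal share uses the default 339-sample cohort against a 95% binomial
interval around 0.712.  PFS calibration uses a 2,400-sample all-multiples
cohort (KM medians within 15% of the configured values; Cox HR within 0.3
on the log scale of the design value).  Clopper–Pearson coverage uses
10,000 replicates per (n, p) pair.  These sizes make the checks sharp
enough to catch sign and scale errors while keeping the default test run
fast.

## Known limitations

* Clonal fractions ignore zygosity and local copy number by construction;
  in liquid mode a variant on an amplified allele can be called clonal at
  a true CCF below threshold.
* MSAF is itself an estimate; its binomial noise propagates into every
  clonal fraction in the sample.  The MSAF-defining variant has clonal
  fraction exactly 1 by definition, which slightly inflates the clonal
  share at very low shed.
* The stratified exact conditional test conditions on per-stratum margins;
  with many sparse strata it can be very conservative.
* Default pathway lists are approximations; published contrasts should be
  reproduced from their printed counts (as the acceptance script does), not
  from these lists.
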