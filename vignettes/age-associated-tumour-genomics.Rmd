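---
title: "Methods: age-association analysis of tumour multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-association analysis of tumour multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoage)
```

# Scope and data model

`oncoage` quantifies how the somatic landscape of tumours changes with
patient age, across three analysis tracks that share one statistical
engine. All inputs are plain TSV tables with 1-based inclusive genomic
coordinates; every internal length is `end − start + 1`. A cohort is a
set of samples of one cancer type; pan-cohort analyses treat cancer type
as a covariate.

# Genome-instability metrics

A tumour's copy-number state is a set of non-overlapping allele-specific
segments `(n_major, n_minor)` per chromosome, assumed already
purity-corrected (as allele-specific callers emit them). Three per-sample
metrics are derived, all over **autosomes only** and with the **measured
segment length** as denominator, so unprofiled gaps never dilute a score:

* **Ploidy** — length-weighted mean of `n_major + n_minor`.
* **GI score** — percent of measured length whose allele pair deviates
  from the ground state: 1+1 for non-WGD tumours, 2+2 after whole-genome
  duplication. A WGD tumour sitting entirely at 2+2 therefore scores 0.
* **Percent genomic LOH** — percent of measured length retaining exactly
  one parental allele (`n_minor = 0`, `n_major ≥ 1`). Homozygous
  deletions (0+0) retain no allele and are deliberately *not* LOH.

Sex chromosomes are excluded from every denominator. The convention is
stated for LOH in the source analyses of this kind; we apply it uniformly
to ploidy and GI as well so the three metrics describe the same genomic
universe (configurable in principle by pre-filtering the segments).

**WGD calling.** Public allele-specific copy-number releases ship WGD
flags without printing their decision rule. When a flag is absent we call
WGD from the linear boundary `ploidy > τ0 − τ1 · LOH fraction` with
defaults `τ0 = 2.9`, `τ1 = 2` — the convention used for SNP-array
releases of this type. Both parameters are exposed
(`instability_summary(tau0 =, tau1 =)`) and the choice only matters for
tumours near the boundary; the synthetic generator places non-WGD
tumours near ploidy 2 and WGD tumours near ploidy 4, where the call is
unambiguous (and the test suite verifies the call recovers the planted
flag exactly).

# SCNA scores

GISTIC-style events are classified from their log2 copy-number ratio
into five half-open bands: `≥ 1 → 2`, `[0.25, 1) → 1`,
`[−0.25, 0.25) → 0`, `[−1, −0.25) → −1`, `< −1 → −2`. Broad (per-arm)
values become one **chromosome-level** event when both arms carry the
same log2 ratio, else two **arm-level** events. "Same" is
`|Δlog2| ≤ 1e−9` by default: GISTIC repeats one number across both arms
of a whole-chromosome event, so the tolerance only has to absorb decimal
round-tripping. Chromosomes represented by a single arm row (the five
acrocentric chromosomes, whose p arms the arrays do not cover) are
scored as arm-level, since the two-arm equality test cannot be evaluated.

Per sample and level, the raw score is `Σ|class|`; raw scores are then
rank-normalised within each cancer-type cohort (`rank/N`, average ranks
on ties, so a unique most-altered tumour scores exactly 1 and the cohort
mean is fixed at `(N+1)/(2N)` under distinct scores). Samples with no
events participate with raw score 0, anchoring the low ranks — leaving
them out would inflate every other tumour's normalised score. The
overall score is the sum of the three normalised levels;
`chrom_arm = arm + chromosome`.

Focal regions overlapping a centromere or a telomere window are removed
before association testing. Overlap tests convert the 1-based inclusive
input to half-open intervals, so a region *ending exactly at* a window
boundary is kept. Telomere windows default to the terminal 10 kb of each
chromosome: recurrence tools do not define this width, 10 kb is small
enough never to touch a genuine mid-arm lesion, and the value is a
declared parameter (`telomere_width`).

# Mutation metrics

Only the nine protein-altering MAF classes count as non-silent
(frame-shift and in-frame indels, missense, nonsense, nonstop, splice
site, translation start site). Burden is the non-silent count per
exome; because "log-transformed" does not pin down a base or offset, we
use `log10(burden + 1)` so zero-burden samples stay representable, and
declare it in the output. Hypermutation is *strictly* more than 1000
non-silent variants; the gene-level analyses retain samples with
*strictly fewer* than 1000. Both inequalities are honoured as stated,
so a burden of exactly 1000 is neither hypermutated nor analysed at the
gene level — the gap affects only those samples and is logged.

Substitution classes collapse purine-reference SNVs onto the six
pyrimidine-reference classes (G>A ≡ C>T, etc.); fractions sum to 1 for
any sample with at least one usable SNV. Multi-base or multi-allele
records are skipped with a warning; `ref == alt` is a hard error.

Age groups split at 50 years, young inclusive. Hypermutation enrichment
between age groups uses the two-sided Fisher exact test (sum of
hypergeometric probabilities no larger than the observed table's).

# The association engine

Every age association follows a two-stage cascade:

1. **Screen** — the simple model (outcome ~ age) per cohort; p values
   BH-adjusted *across cohorts* within one analysis.
2. **Adjust** — cohorts with adjusted p < 0.05 are refit with
   covariates: candidates with < 10% missingness and more than one
   observed level, plus tumour purity when available. Complete cases
   only; the per-fit `n_used` is reported. Stage-2 p values are
   BH-adjusted across the promoted cohorts.

Categorical covariates use the most frequent level as reference; levels
carried by fewer than 5 samples are pooled into `"other"` before dummy
expansion, which keeps small cohorts from producing empty design
columns. Rank-deficient designs are an error naming the aliased columns.

Binary outcomes are fit by maximum-likelihood logistic regression and
reported as **odds ratios per year** with Wald 95% CIs. When the design
is (quasi-)separated the ML estimate is infinite; separation is
diagnosed from the divergence of the ML coefficient path (standardized
coefficients growing past a bound of 15 while the likelihood plateaus —
validated in the tests against an exhaustive one-predictor separability
check), and such fits are routed to **Firth-penalized logistic
regression**. The Firth fit maximizes `l(β) + ½ log|I(β)|` by Newton
iterations on the hat-adjusted score
`U*(β) = Xᵀ(y − π + h(½ − π))`, with step-halving, convergence at
score norm < 1e−8 within 50 iterations, and Wald CIs from the
penalized-fit information matrix. Wald intervals (rather than
profile-penalized-likelihood intervals, the default of the classic
implementation) are used for both logistic variants so effect summaries
are uniform across methods; profile CIs are a clean extension point. On
a saturated 2×2 design the Firth estimate has the closed form
`log[(a+½)(d+½)/((b+½)(c+½))]`, which the tests verify to 1e−6, and the
estimate stays finite under complete separation.

Group comparisons of correlation coefficients use the tie-corrected
Kruskal–Wallis H with its chi-square p value, pairwise two-sided Dunn
tests on pooled ranks with Bonferroni multiplication, and additionally
the Wilcoxon rank-sum p for two groups. The chi-square reference is an
asymptotic choice; for pooled samples of at most 10 observations
`rank_group_tests` also reports an exact permutation p for H by full
enumeration of group assignments, because at such sizes the asymptotic
and exact answers can differ several-fold.

# Expression/methylation coupling

Expression enters as RSEM ≥ 0, filtered to genes positive in strictly
more than half the samples, and transformed `log2(x + 1)` — the `+1`
offset is adopted uniformly (it is required for zero RSEM values and
matches the transform used for the SCNA–expression correlations).
Methylation β values are regressed untransformed: the age effects of
interest are planted and interpreted on the β scale, and an M-value
transform would only reweight the boundary. Probes map to genes
one-to-one by the most-negative Pearson correlation with the gene's
log2 expression over shared samples (≥ 3 complete pairs required;
exact ties break to the lexicographically smallest probe ID so the
mapping is independent of input order).

Per-feature age regressions share a single design matrix, so one QR
decomposition serves the whole matrix; features with zero variance are
skipped and leave the BH family. The BH family is all retained features
of one matrix in one cohort. Flags (age-DEG / age-DMG) require
BH-adjusted p < 0.05. Overlap genes are classified into the four
(methylation direction × expression direction) quadrants; the
"opposite-direction" percentage counts meth↑expr↓ plus meth↓expr↑.
Correlation groups partition the union universe into DMG∩DEG, DMG-only,
DEG-only and others; per-gene methylation–expression correlations use
complete cases per gene. The gene universe for concordance and grouping
is the intersection of post-filter expression genes and mapped
methylation genes. Ranked lists sort by age coefficient, descending,
ties lexicographic.

# The synthetic cohort generator

The generator produces cohorts with the statistical structure the
analysis assumes, with every planted parameter recoverable by the
pipeline itself. Defaults describe an *endometrial-like* condition;
`"null"` (no planted effects) and `"glioma-like"` (driver odds falling
with age) presets ship as YAML.

* Ages are uniform integers on 30–85 (the adult TCGA-like range);
  purity is Beta(5, 2); covariates are fixed multinomials, with alcohol
  deliberately missing in > 10% of samples so covariate selection always
  has something to drop.
* Segments: WGD ~ Bernoulli(plogis(−2 + 0.03·age)); a non-ground genome
  fraction `f = 0.05 + 0.003·age + N(0, 0.03)` (clamped) is laid out per
  chromosome as an LOH block (`n_minor = 0`), an off-ground block, then
  ground state — so the realised fractions are recovered *exactly* by
  the metrics, which the tests assert.
* Mutations: burden ~ Poisson(exp(3.3 + 0.01·age)) for non-hypermutators
  (≈ 37–63 variants across the age range); hypermutators (rates 0.34
  young / 0.11 old, mirroring the published endometrial contingency
  magnitudes) get burden > 1000 plus an MSI-H or POLE/POLD1 explanation;
  the C>T share rises as `0.15 + 0.003·age`, with records emitted in
  purine-reference form half the time to exercise strand collapsing.
* Expression/methylation: age genes carry
  `β = clamp01(μ_g + 0.003·age + ε)` and
  `log2 expr = ν_g + coupling·β + δ` with `coupling = −4`; separate
  blocks carry the age signal in methylation only or expression only —
  a generator design choice ensuring all four correlation groups are
  populated so the group tests are well defined. Each gene gets 1–3
  probes, exactly one carrying the signal.
* GISTIC events: one designated arm's gain odds rise with age
  (OR/year 1.03); other arms and focal lesions are age-independent
  background, placed clear of centromere/telomere windows.

Slopes are kept small enough that the clamping of β and of genome
fractions almost never binds inside the age range, so linear-model
recovery of the planted slopes is approximately unbiased — this is why
the defaults are mild. What the generator does **not** emulate:
realistic breakpoint processes, mutational-signature structure,
subclonality, cell-type composition, or correlated covariates.
Consequently, passing recovery tests demonstrates the *statistical
machinery* is correct and calibrated, not that real tumour data meet
the generative assumptions.

# Numerical choices and degenerate inputs

* Chromosome/arm equality tolerance 1e−9; Firth score tolerance 1e−8,
  max 50 Newton steps with up to 25 step-halvings.
* Correlations require ≥ 3 complete pairs; zero-variance vectors yield
  an undefined flag and leave the BH family rather than propagate NaN.
* Fully tied inputs to the group tests return H = 0, p = 1.
* Empty cohorts, one-class outcomes, empty gene universes, β outside
  [0, 1] and overlapping segments are classed validation errors
  (`oncoage_validation_error`), distinguishable from convergence
  failures (`oncoage_convergence_error`).
* All simulation randomness derives from a single integer seed per
  parameter set; fixed seeds give bit-identical cohorts.

# Problem sizes used by the test suite

The property suites run at sizes chosen to keep the full test run in a
few minutes while leaving each check well powered: 1000 null experiments
of 10 cohorts × 200 samples for the screening-cascade calibration;
100 seeded replicates at n = 500 (genomic tracks) and n = 150–300
(omics tracks) for parameter recovery; 200 random micro-cohorts (≤ 6
samples, ≤ 4 events) against the brute-force SCNA oracle; 1000 random
vectors against the step-up BH definition; 50 random separated 2×2
tables against the Firth closed form.

# Known limitations

* Wald CIs undercover slightly in very small cohorts; profile-likelihood
  intervals for the Firth fit are not implemented.
* The WGD boundary is a convention; tumours near the boundary inherit
  its uncertainty and the parameters should be reported alongside any
  WGD-derived result.
* Purity enters as a linear covariate; this cannot fully remove
  infiltrating-cell expression signal.
* The screening stage uses age-only models; confounding that acts only
  through stage-1 selection is not corrected.
* Pathway-alteration and driver-list inputs are consumed as plain
  binary matrices/gene lists; their curation is out of scope.
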