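# oncoage

Age is the dominant risk factor for cancer, yet tumours arising at
different patient ages can carry measurably different somatic landscapes.
`oncoage` packages the statistical machinery needed to quantify those
differences across a multi-omic tumour cohort:

* **Genome instability** from allele-specific copy-number segments: the
  GI score (percent of the measured autosomal genome outside the ground
  state, 1+1 for non-WGD tumours and 2+2 after whole-genome duplication),
  percent genomic LOH (segments with minor copy number 0 and at least one
  retained allele), length-weighted ploidy, and a configurable
  WGD call from the linear boundary `ploidy > 2.9 − 2·LOH fraction`.
* **SCNA scores** from GISTIC-style broad/focal tables: log2 ratios are
  classified into `{−2, −1, 0, 1, 2}` at cutpoints ±0.25 and ±1, summed as
  `Σ|class|` per level (focal / arm / chromosome, where a chromosome event
  requires equal log2 on both arms), then rank-normalised (`rank/N`)
  within each cancer-type cohort; the overall score is the sum of the
  three normalised levels.
* **Mutation metrics** from minimal MAF tables: non-silent filtering
  (nine protein-altering classes), burden and `log10(burden+1)`,
  hypermutation (> 1000 non-silent variants), the six pyrimidine-reference
  substitution-class fractions, binary driver-gene matrices with a strict
  > 5% frequency floor, and young (≤ 50) vs old hypermutation enrichment
  by two-sided Fisher exact test.
* **A screen-then-adjust association engine**: per-cohort simple
  regressions of each outcome on age, Benjamini–Hochberg correction
  across cohorts, covariate-adjusted refits (covariates kept only when
  < 10% missing, plus tumour purity) for the cohorts passing the screen,
  odds ratios per year with Wald 95% CIs for binary outcomes, and a
  hand-written Firth-penalized logistic regression
  (`l(β) + ½ log|I(β)|`) used automatically when separation is detected.
* **Coupled expression/methylation analysis**: per-gene age regressions
  on `log2(RSEM+1)` expression and methylation β, age-DEG/age-DMG calls
  at BH-adjusted p < 0.05, one-to-one probe→gene mapping by most-negative
  correlation with expression, overlap quadrant classification,
  methylation–expression correlation groups compared by Kruskal–Wallis
  and Dunn tests, and ranked-list export for enrichment tools.
* **A synthetic cohort generator** that plants recoverable age effects in
  every layer (instability/LOH/WGD slopes, clock-like burden growth with
  an age-dependent C>T share, a young-enriched hypermutator
  subpopulation, negatively coupled methylation→expression age genes), so
  the whole pipeline can be validated end to end without access to
  controlled patient data.

## Worked example

```r
library(oncoage)

params <- load_scenario("endometrial-like", n_samples = 200, seed = 42)
cohort <- simulate_cohort(params)

summ <- instability_summary(cohort$profiles)
head(summ, 3)
#>   sample ploidy gi_score percent_loh loh_fraction   wgd
#> 1  S0001   4.03     32.4        9.88       0.0988  TRUE
#> 2  S0002   2.15     26.2        5.79       0.0579 FALSE
#> 3  S0003   2.06     11.0        2.73       0.0273 FALSE

d <- merge(cohort$clinical, summ, by.x = "sample_id", by.y = "sample")
screen_then_adjust(d, "gi_score", "continuous")
#>      cohort    stage method n_used coefficient ci_low ci_high        p    adj_p
#> 1 UCEC-like   screen    ols    200       0.292  0.265   0.320 5.68e-52 5.68e-52
#> 2 UCEC-like adjusted    ols    172       0.297  0.268   0.325 2.08e-46 2.08e-46
```

The screen stage regresses the GI score on age alone; since the
BH-adjusted p is below 0.05 the cohort is refit with the retained
clinical covariates plus purity (stage `adjusted`, complete cases only).
The coefficient ≈ 0.29 is the fitted GI-score increase per year of age —
close to the planted slope of 0.3 percent of genome per year.

The other tracks follow the same pattern:

```r
mut <- mutation_summary(cohort$mutations$mutations,
                        samples = cohort$clinical$sample_id)
en <- hypermutation_enrichment(mut$hypermutated,
                               age_group_split(cohort$clinical$age))
#> young 44%, old 10%, Fisher p = 9.1e-08     (planted rates 0.34 / 0.11)

expr   <- filter_expressed(cohort$omics$expression)
mapped <- map_probes(cohort$omics$methylation, cohort$omics$probe_map, expr)
er <- age_feature_regression(log2_expr(expr), cohort$clinical)
mr <- age_feature_regression(mapped$meth,     cohort$clinical)
coefficient_concordance(er, mr)
#> r = -0.64 (p = 2.1e-24)   # age effects on expression oppose methylation
```

A full staged run with TSV outputs and provenance headers:

```r
run_pipeline(pipeline_config("results/run1", seed = 1,
                             scenario = "endometrial-like"))
```

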