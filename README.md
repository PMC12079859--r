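# partmr: pathway- and tissue-partitioned Mendelian randomization

Mendelian randomization (MR) treats genetic variants as instrumental
variables to estimate the causal effect of an exposure (blood pressure,
BMI, ...) on a disease outcome. For complex exposures the instruments are
biologically heterogeneous: different variants act through different
organ systems and pathways, so a single pooled estimate can hide opposing
mechanism-specific effects. `partmr` implements *partitioned* MR: it
splits an exposure's instruments into biologically labelled subsets and
asks whether the subsets carry different causal effects — and whether an
observed difference is larger than what random assortment of instruments
would produce.

Two partitioning routes are provided:

* **Pathway partitioning** — each instrument gets an LD interval
  (bounded by the most distant variant with r² ≥ 0.8 within 1 Mbp);
  Mendelian-disease genes (coding region ± 1000 bp flanks) overlapping
  the interval contribute their phenotype-ontology terms; terms are
  tested for enrichment against a length-preserving random-relocation
  null; instruments join a category (e.g. "renal", "vessel") when their
  interval overlaps a gene carrying an enriched term of that category.
* **Tissue partitioning** — each instrument is colocalized against
  per-tissue cis-eQTLs over ±100 kbp windows using the approximate
  Bayes factor framework (Wakefield ABFs, five hypotheses H0–H4);
  an instrument joins a tissue group when max PP_H4 > 0.9.

Partition-specific effects are then estimated by:

* **One-sample MR** on individual-level data: weighted genetic risk
  scores, rank-based inverse-normal transforms, covariate-adjusted
  two-stage IV regression (linear/logistic), and two-score multivariable
  models giving each partition's direct effect;
* **Two-sample MR** on summary statistics: Wald ratio, IVW (fixed and
  multiplicative random effects), MR-Egger, weighted median, weighted
  mode, PP_H4-weighted multivariable MR, with Cochran's Q, I²,
  Q_het = Q/(Q_df − 1), mean F, total R², and Steiger directionality;
* **Resampling nulls**: random SNP-subset draws (pathway) or pooled
  PP_H4 permutation (tissue), 1000 replicates, two-tailed empirical p
  with floor 1/R (10⁻³ at R = 1000) and an empirical 95% interval of the
  difference.

A seeded synthetic-data generator (`simulate_study()`) produces a
complete study — block-LD genotypes, pathway-structured phenotypes,
GWAS-style summary statistics from independent cohorts, planted eQTL
colocalizations, category-labelled gene annotations — with full ground
truth, so the entire pipeline is testable offline.

## Worked example

```r
library(partmr)

st <- simulate_study(sim_params(seed = 7))     # theta1 = 0.15, theta2 = 0
iset  <- clump(st$exposure_stats, st$ld)       # p < 5e-8, r2 < 0.001, 10 Mbp
pairs <- harmonize(iset, st$outcome_stats)

tr <- st$truth[match(pairs$variant_id, st$truth$variant_id), ]
ivw(pairs[tr$pathway == "P1", ])
#> ivw: beta = 0.1101 (SE 0.0235, p = 2.66e-06, nsnp = 7)
ivw(pairs[tr$pathway == "P2", ])
#> ivw: beta = 0.0139 (SE 0.0219, p = 0.524, nsnp = 8)
```

The partition-1 instruments carry the planted causal signal (true
direct effect 0.15 per SD of exposure); partition 2 is null. The IVW
point estimate sits a little below 0.15 because instruments selected
and estimated in the same exposure GWAS suffer winner's-curse
attenuation (discussed in the vignette). The same contrast in a
one-sample two-score multivariable model:

```r
covs <- c("age", "sex", "chip", paste0("pc", 1:10))
g1 <- build_grs(st$cohort, data.frame(variant_id = pairs$variant_id[tr$pathway == "P1"],
                                      weight = pairs$beta_exp[tr$pathway == "P1"]))
g2 <- build_grs(st$cohort, data.frame(variant_id = pairs$variant_id[tr$pathway == "P2"],
                                      weight = pairs$beta_exp[tr$pathway == "P2"]))
mv <- mvmr_two_scores(st$cohort, g1, g2, "exposure", "outcome_cont", covs)
mv$a
#> multivariable IV estimate (continuous outcome): 0.1879 (SE 0.0237, p = 2.29e-15, n = 10000, F = 2186.8)
mv$b
#> multivariable IV estimate (continuous outcome): 0.0178 (SE 0.0221, p = 0.422, n = 10000, F = 2590.4)
```

Is the observed between-partition difference more than random subsets
produce?

```r
an <- function(a, b) c(ivw(pairs[pairs$variant_id %in% a, ])$beta,
                       ivw(pairs[pairs$variant_id %in% b, ])$beta)
p1 <- pairs$variant_id[tr$pathway == "P1"]; p2 <- pairs$variant_id[tr$pathway == "P2"]
empirical_diff_test(an, function() draw_pathway_null(pairs$variant_id, length(p1), length(p2)),
                    list(p1, p2), R = 200, seed = 11)
#> resampling null []: observed |diff| = 0.0962, empirical p = 0.005 (R = 200)
#>   95% interval of null |diff|: [0.0013, 0.0661]; failed replicates: 0
```

The observed difference of 0.096 is exceeded by 1/200 random-assortment
replicates: evidence that the partition structure is real.

A command-line front end mirrors this flow
(`inst/cli/partmr simulate | clump | harmonize | twosample | resample`).

## Layout

```
R/                  data model & I/O, LD reference, instrument selection,
                    pathway & tissue partitioning, one-/two-sample MR,
                    resampling nulls, synthetic-data generator, CLI
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R   acceptance report (above)
vignettes/partitioned-mr.Rmd   methods vignette
```
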