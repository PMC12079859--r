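---
title: "Partitioned Mendelian randomization: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned Mendelian randomization: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem and the model

Mendelian randomization estimates the causal effect of an exposure $X$ on
an outcome $Y$ from genetic instruments $G_j$: variants associated with
$X$, assumed independent of confounders and affecting $Y$ only through
$X$. When $X$ is a physiological composite (blood pressure, BMI), its
instruments act through heterogeneous mechanisms, and the pooled estimate
averages over them. `partmr` formalizes the partitioned view: write the
genetic part of the exposure as a sum of pathway components,

$$X = C_1 + C_2 + C_0 + \varepsilon_X, \qquad
  C_k = \sum_{j \in P_k} \beta_j G_j,$$

and let the outcome respond to each component with its own direct effect,

$$Y = \theta_1 C_1 + \theta_2 C_2 + \theta_0 C_0 + \varepsilon_Y.$$

Instruments in $P_1$ identify $\theta_1$, instruments in $P_2$ identify
$\theta_2$: the per-instrument Wald ratio is
$\mathbb{E}[b_{Y_j}]/\mathbb{E}[b_{X_j}] = \theta_k$ for $j \in P_k$.
Partitioned MR is the estimation of $(\theta_1, \theta_2)$ given a
biological rule that sorts instruments into $P_1$ and $P_2$, plus a
resampling argument that an observed $|\hat\theta_1 - \hat\theta_2|$
exceeds what arbitrary instrument assortment produces.

Two assignment rules are implemented.

**Pathway (Mendelian-disease) partitioning.** Each instrument's LD
interval is delimited by the most distant variant with $r^2 \ge 0.8$
within 1 Mbp either side. Genes (coding region with 1000 bp 5' and 3'
flanks) overlapping the interval contribute their disease-ontology
terms. Term enrichment across the interval set is assessed against a
relocation null (below), and an instrument joins category $C$ when its
interval overlaps a gene carrying a term of $C$ *and* at least one of
$C$'s terms is enriched ($p \le$ `enrich_p_max`, default 0.05). A
variant may join several categories; "specific" marks membership in
exactly one.

**Tissue (colocalization) partitioning.** For each instrument, every
gene with cis-eQTL statistics overlapping a ±100 kbp window is
colocalized against the exposure signal by enumeration of the five
hypotheses H0 (neither trait associated), H1/H2 (one trait only), H3
(two distinct causal variants), H4 (one shared causal variant), using
per-variant Wakefield log approximate Bayes factors

$$\log \mathrm{ABF} = \tfrac12\log\!\frac{se^2}{se^2+W} +
  \frac{z^2}{2}\,\frac{W}{se^2+W}, \qquad z = \beta/se,$$

with prior effect-sd $\sqrt W = 0.15$ per trait and priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (standard quantitative-trait
defaults; the aggregation across a group's sub-tissues and genes is the
maximum PP_H4). Membership requires max PP_H4 strictly above 0.9.

# Estimators

*One-sample:* the genetic risk score $S = \sum_j w_j G_j$ (weights =
exposure GWAS betas) instruments the exposure in a two-stage design —
stage 1 regresses the SD-standardized exposure on $S$ plus covariates;
stage 2 regresses the outcome (linear, or logistic for binary) on the
stage-1 fitted exposure plus the same covariates. The two-score
multivariable model runs stage 1 separately per partition score and
fits both fitted exposures jointly in stage 2; each coefficient is that
partition's direct effect per SD of exposure. Stage-2 standard errors
are model-based; a seeded nonparametric bootstrap (default 500
resamples) is available and recommended for logistic outcomes, where
plug-in two-stage SEs are anti-conservative.

*Two-sample:* IVW is the weighted origin regression of $b_Y$ on $b_X$
with weights $1/se_Y^2$; the default multiplicative random-effects
model scales the fixed SE by $\max(1, \sqrt{Q/Q_{df}})$. MR-Egger adds
an intercept (average directional pleiotropy) after orienting exposure
betas positive, with a $t_{k-2}$ reference. The weighted median
interpolates the cumulative standardized inverse-variance weights of
the ordered Wald ratios to the 0.5 crossing; the weighted mode takes
the peak of an inverse-variance-weighted Gaussian kernel density with
bandwidth `bandwidth_factor` × $0.9\,\min(sd, mad)\,k^{-1/5}$; both get
seeded parametric-bootstrap SEs. Heterogeneity follows the printed
conventions: $Q = \sum w_j(r_j - \hat\beta_{IVW})^2$ with
$w_j = (se_{Y_j}/b_{X_j})^{-2}$, $I^2 = \max(0, (Q - Q_{df})/Q)$, and
the average heterogeneity $Q_{het} = Q/(Q_{df}-1)$. Steiger
directionality uses the sample-size-only approximation
$r^2_j = z_j^2/(z_j^2 + n - 2)$ summed over instruments, compared via
Fisher's z. The PP_H4-weighted multivariable model regresses $b_Y$ on
$(b_X \cdot \mathrm{PP}_{H4,A},\; b_X \cdot \mathrm{PP}_{H4,B})$
jointly without intercept; instruments below the 0.9 gate in both
tissues are excluded by default (mirroring partition membership; a
keep-all mode exists). Its "conditional F" output is a heuristic
weighted-residual strength index (the residual weighted sum of squares
of each scaled-exposure column after projecting out the other, divided
by k), not the Sanderson–Windmeijer statistic, which requires
per-exposure SE matrices that scaled betas do not carry.

# The resampling null

For pathway partitions the null draws two subsets of the observed sizes
$n_1, n_2$ uniformly without replacement (independently, so the subsets
may overlap, as the observed categories may). For tissue partitions all
$2m$ PP_H4 values are pooled, permuted across variants *and* tissues,
and the per-tissue memberships re-extracted, so null subset sizes vary.
The identical analysis is re-run on each replicate; the two-tailed
empirical p is the exceedance frequency of the observed
$|\hat\theta_1-\hat\theta_2|$, floored at $1/R$ (so $10^{-3}$ at the
default $R = 1000$) — implemented as $\max(c/R, 1/R)$ rather than
$(c+1)/(R+1)$ to reproduce the stated floor exactly. Replicates on
which the analysis fails (empty subset, collinearity) are redrawn, up
to $5R$ attempts, and a failure fraction above 20% aborts with an
"unstable null" error. The 95% interval of the difference is the 2.5%
and 97.5% quantile of the replicate distribution.

# The synthetic world

`simulate_study()` generates, from one seed: a genome of `n_blocks`
(default 30) independent LD blocks of `snps_per_block` (10) variants
5 kb apart; genotypes as two latent AR-1 Gaussian haplotypes
(correlation `ld_rho` = 0.8 between neighbours) thresholded at the MAF
quantile (MAF ~ U(0.1, 0.5)); one causal variant per block, assigned to
P1/P2/P0 in proportions 0.4/0.4/0.2. Exposure effects are drawn normal
and rescaled so the instruments jointly explain `h2_exposure` = 0.6 of
an exposure calibrated to unit variance — this makes the per-SD and raw
scales coincide, so recovery of $(\theta_1, \theta_2) = (0.15, 0)$ can
be assessed on one scale, and it emulates the real-world situation in
which published instruments are all genome-wide significant (with
unsized effects, half the planted instruments would fail $5\times
10^{-8}$ and partitions could collapse). `effects = "fixed"` gives all
instruments equal $|\beta|$: the "clean" world used for exact-recovery
checks. Summary statistics come from exact per-SNP OLS on independently
generated cohorts (exposure GWAS, outcome GWAS, and the one-sample
cohort are three disjoint samples, avoiding sample-overlap bias), with
p-values from the normal approximation. eQTL panels plant each P1
instrument as the causal eQTL of a gene in `tissue_a` (P2 in
`tissue_b`) with effect `eqtl_effect` = 0.6 per genotype SD in an
independent sample of `n_eqtl` = 300 — z ≈ 8 regardless of MAF;
decoy genes (causal variant at the far end of the block, r² ≈ 0.02
with the instrument) appear in the other tissue at rate 0.3, and P0
instruments get pure-noise regions at rate 0.5. Gene annotations place
a category-term gene inside each matching instrument's interval with
probability `specificity` (1) and elsewhere at `background_rate` (0),
plus 20 term-less background genes.

What a green test does *not* establish: the generator has no realistic
human LD map (blocks are independent AR-1), no population structure
(the principal-component covariates are pure noise), no pleiotropy, no
overlapping pathway membership, no allele-frequency–dependent effect
architecture, and its binary outcome is generated from the same linear
predictor as the continuous one. Results on it validate the machinery,
not the biology.

# Numerical and design choices

* **Enrichment null.** The matched-permutation scheme of interval
  enrichment tools is replaced by length-preserving uniform relocation
  (chromosome drawn proportional to length, start uniform): fully
  specifiable, and it preserves the inferential question (more overlap
  than chance?). Empirical p is $(1 + \#\{null \ge obs\})/(R+1)$.
* **Clumping** is greedy p-ordered (as in plink), ties broken by
  chromosome, position, then id; the output is audited against its own
  pairwise-r² invariant after construction.
* **Palindromic variants** are resolved by allele frequency only when
  both EAFs are outside 0.5 ± 0.08, else dropped; missing EAF on a
  palindrome is a precondition error, never imputed.
* **Proxies** use the proxy's outcome-side statistics with the original
  instrument's exposure-side statistics; the best candidate is the
  maximum r² (> 0.8), ties by distance then id.
* **Coloc arithmetic** is entirely in log space (log-sum-exp; H3 via a
  log-difference guarded against cancellation); posteriors are asserted
  to sum to 1 within 1e-9. PP_H4 ties at the threshold are
  non-membership (strict >). PP_H4 is invariant to jointly rescaling one
  region's betas, SEs and prior sd by the same constant (tested).
* **Winner's curse.** Instruments selected and estimated in the same
  exposure GWAS give attenuated summary-level ratios. The package's
  recovery experiments therefore run on the planted instrument list;
  the selection path is validated separately (audits, calibration).
  A selection-robust design (three-way splitting) is out of scope.
* **IVW with one instrument** returns the Wald ratio with a warning
  rather than erroring, matching the k = 1 limiting behaviour.
* **Null-calibration experiments** draw the "observed" subsets from the
  same random-assortment generator as the replicates, making the
  empirical p conditionally uniform by exchangeability; a disjoint
  planted partition is not exchangeable with overlapping random draws.
* **Degenerate scores** (all-zero weights) are excluded from the
  multivariable stage-2 fit and reported NA, instead of being left to
  `lm` pivoting, which could silently drop a covariate instead.
* **Noise-region PP_H4.** For a pure-noise eQTL region at a true
  instrument, the H4:H1 posterior odds are bounded below by
  $(p_{12}/p_1)\cdot BF_{eQTL}$, so PP_H4 lands in 0.1–0.3 whenever the
  noise region shows $|z| \gtrsim 1.5$ at the instrument; the package
  asserts such regions never cross the 0.9 gate (and decoy regions are
  H3-dominated below 0.1) rather than an unattainable "< 0.1 always".

# Known limitations

Single-causal-variant colocalization only (no SuSiE-style multi-signal
extension); no LD-aware correlated-instrument MR; no MR-PRESSO-type
outlier removal; the logistic one-sample model uses the fitted-exposure
second stage (a direct-GRS variant would differ under strong
non-collapsibility); ontology term hierarchies are not traversed — the
term-to-category map is user configuration.
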