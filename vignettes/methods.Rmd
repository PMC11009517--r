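---
title: "Methods: DII scoring, FTO risk scores and gene-diet interaction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DII scoring, FTO risk scores and gene-diet interaction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diigrs)
```

`diigrs` implements the computational chain of a longitudinal gene-diet
interaction analysis: a Dietary Inflammatory Index (DII) scored from
nutrient intakes, an odds-ratio-weighted genetic risk score (GRS) over three
common FTO variants, derived adiposity measures and their dichotomized
changes, an auditable exclusion cascade, and stratified
quartile-by-genotype logistic models. This vignette records the models, the
defaults, and the design decisions taken where the construction was
genuinely open.

## The DII score

For each dietary parameter $i$ with intake $x_i$, global reference mean
$\mu_i$, reference SD $\sigma_i$ and inflammatory effect score $w_i$:

$$ z_i = \frac{x_i - \mu_i}{\sigma_i}, \qquad
   c_i = 2\,\Phi(z_i) - 1, \qquad
   \mathrm{DII} = \sum_i w_i\, c_i . $$

The centered-percentile step $c_i \in (-1, 1)$ de-skews the right-tailed
intake distributions; $\Phi$ is the standard normal CDF, which is the
conventional reading of "converted to proportions" in the DII literature.
Each parameter contributes at most $|w_i|$, so
$|\mathrm{DII}| \le \sum_i |w_i|$, and a cohort eating exactly the global
reference scores 0 — both properties are enforced by tests.

Decisions worth stating:

* **Energy adjustment.** Intakes are energy-adjusted before scoring. The
  default is the *density* method (amount per 1000 kcal), because density
  scaling is what per-1000-kcal fibre reporting in cohort descriptive tables
  evidences; the *residual* method (cohort-wide regression of intake on
  energy, residual plus prediction at the reference energy) is available via
  `energy_adjust_intakes(method = "residual")`. Energy itself is never
  energy-adjusted — adjusting energy by energy is degenerate — and carries
  `energy_adjust = FALSE` in the registry.
* **Reference registry.** The global means, SDs and effect scores of the
  published DII construction are literature-derived and not redistributed
  here: the shipped 37-parameter registry
  (`default_dii_registry()`, file `dii_registry_synthetic.tsv`) contains
  *synthetic* values, plausible in sign and rough magnitude only. Real
  analyses should load their own table with `read_dii_registry()`.
* **Reduced parameter set.** The full DII construction uses 45 parameters;
  food-frequency questionnaires typically cover fewer (here 37). Scoring
  simply sums over available parameters with no renormalization of the
  reference distribution; `n_parameters_used` is reported per participant,
  and participants under the configurable coverage minimum (default: all
  37) are flagged rather than partially scored.
* **Quartiles.** Empirical 25/50/75th percentile cuts (`quantile()` type 7);
  values tying a cut point go to the lower quartile, making assignment
  deterministic. Q1 (most anti-inflammatory) is the reference exposure
  level.

## Derived adiposity measures

BMI = weight/height$^2$ (kg/m$^2$). Both waist ratios are computed — waist/hip
and waist/height — because the field's "WHR" label is used for either;
the change analysis uses waist-to-hip by default with `ratio = "whtr"`
selectable. The Visceral Adiposity Index uses the standard sex-specific
form with TG/HDL in mmol/L (a `lipid_units = "mg/dL"` flag divides by
88.57 and 38.67):

$$ \mathrm{VAI}_{m} = \frac{WC}{39.68 + 1.88\,BMI}\cdot\frac{TG}{1.03}
   \cdot\frac{1.31}{HDL}, \qquad
   \mathrm{VAI}_{f} = \frac{WC}{36.58 + 1.89\,BMI}\cdot\frac{TG}{0.81}
   \cdot\frac{1.52}{HDL}. $$

Changes are follow-up minus baseline; the binary outcomes code a strictly
positive change as 1 and change $\le 0$ as 0.

## Genotypes and the GRS

Genotypes are risk-allele counts 0/1/2 (the minor allele is the declared
BMI-elevating risk allele by default; `default_snp_specs()` is editable).
Hardy-Weinberg equilibrium is tested by the 1-df Pearson chi-square against
expected counts from observed allele frequencies. The stratified models use
the dominant coding: major-allele homozygotes (the "wild-type" stratum,
code 0) versus carriers (code 1).

The GRS is the *raw-OR*-weighted allele count
$\mathrm{GRS} = \sum_j OR_j \, g_j$, with each $OR_j$ estimated in the
analysis cohort itself by a per-SNP logistic regression of the BMI-increase
outcome on the additive genotype. Raw-OR weighting (rather than the more
conventional log-OR weighting) is deliberate: it reproduces the published
GRS equation this pipeline re-implements. Consequences: the score is
positive, bounded by $2\sum_j OR_j$, and monotone in every risk-allele
count. If a declared risk allele is estimated protective the weight is kept
and a warning raised — no silent allele flipping. The high/low strata split
at the cohort median, ties going high; with $t$ values tied at the median
the split can be imbalanced by at most $2t-1$. Participants missing any
call are excluded from GRS analyses (strict policy).

## Exclusion cascade

`apply_exclusions()` applies ordered rules — minors (age $\le 18$),
medication/missing-data, DNA purity outside the open interval
$1.7 < A_{260}/A_{280} < 2$, energy intake outside $[800, 4200]$ kcal/day
(bounds retained), pregnancy, lactation — attributing each participant to
the *first* rule that excludes them, as participant-flow diagrams do. A
missing field required by a rule excludes at that rule. Final membership is
order-invariant; only the attribution depends on order. The audit satisfies
$n_{in} = n_{out} + \sum \text{excluded}$ by construction.

## Stratified models

All models are unconditional maximum-likelihood logistic regressions (IRLS,
coefficient tolerance $10^{-10}$, max 100 iterations), adjusted for age,
sex, energy intake, education ($>14$ vs $\le 14$ years), physical activity
(low/moderate/high at cohort tertiles of MET/min/wk — the cut points are
not standardized anywhere, so tertiles are the documented choice) and
smoking (never/ex/current). Wald 95% CIs on the log-odds scale.

* **8-group model.** Exposure enters as a single factor over DII quartile
  $\times$ stratum; the omitted reference is (Q1, stratum 0). Published
  tables show each stratum against its own Q1, so stratum-1 cells are
  linear contrasts of two dummies with delta-method SEs; each stratum's Q1
  cell is fixed at OR 1.
* **P-trend.** Quartile as a single ordinal covariate 1–4 (simpler and more
  standard than quartile medians), Wald test, per stratum.
* **P-interaction.** "General linear model" is underspecified for a binary
  outcome; the implementation is the logistic model with ordinal quartile,
  stratum, covariates and the quartile$\times$stratum product term, Wald
  test of the product term. A 3-df categorical-quartile LRT variant is
  available (`quartile_form = "categorical"`). The ordinal test is well
  calibrated under the null (checked at 1000 replicates of $n = 2000$) but
  has modest power against non-monotone ("one elevated cell") patterns.
* **Baseline trends.** OLS of each baseline measure on continuous DII per
  stratum, with a pooled DII$\times$stratum product-term t-test for
  interaction.

Separation, non-convergence and rank deficiency raise errors naming the
offending term; they are never returned as estimates.

## The synthetic cohort

Because individual-level cohort data of this design are not publicly
deposited, `simulate_cohort()` generates cohorts with the statistical
structure the analysis assumes, and is itself first-class, tested code.

* **Genotypes**: independent SNPs in exact HWE, count
  $\sim \mathrm{Binomial}(2, q)$ at risk-allele frequencies 0.42/0.40/0.41
  (synthetic, chosen $>0.2$ as in common-variant obesity panels).
* **Intakes**: energy is truncated log-normal (median 2300 kcal, log-SD
  0.25, truncated inside the 800–4200 plausibility window so the default
  cohort passes the cascade intact); each parameter is a log-normal
  multiple of its registry mean on the per-1000-kcal scale, scaled by
  energy. A latent "inflammatory diet" factor loads on every parameter with
  the sign of its effect score (loading 0.25, noise 0.30), producing the
  classic gradient — SFA rising, fibre falling across DII quartiles — and a
  mild negative energy gradient (loading $-0.10$).
* **Covariates**: age truncated normal (40 $\pm$ 13.5, $\ge 19$), 45% male,
  smoking 62/12/26% never/ex/current, education 11 $\pm$ 4.5 years,
  physical activity log-normal around 650 MET/min/wk.
* **Baseline anthropometry**: sex-specific normals with a mild inverse DII
  gradient on BMI ($-0.45$ per DII SD), WC ($-1.2$ cm) and WHR
  ($-0.007$), mirroring the inverse cross-sectional association such
  cohorts report.
* **Outcomes**: each increase flag is Bernoulli with
  $\mathrm{logit}(p) = \alpha_o + \beta' x + \gamma s + \theta_o[q, s]$,
  where $\theta_o$ is a 4$\times$2 matrix of within-stratum quartile
  log-ORs (row Q1 $\equiv$ 0) — exactly the quantity the 8-group model
  estimates, so injected cell ORs are recoverable by construction. The
  generative covariate effects use the same codings the analysis adjusts
  for, so the fitted model is correctly specified. DII quartiles are
  computed with the package's own scoring chain, making the generative and
  recovered quartiles identical.
* **Follow-up**: each measure moves by a half-normal magnitude (scales:
  BMI 1.6 kg/m$^2$, WC 5 cm, WHR 0.035, VAI 0.12) in the direction its
  flag dictates; hip circumference and triglycerides are back-solved so
  that recomputing deltas through the anthropometry module reproduces the
  simulated flags exactly — an integrity property the tests assert.
* **GRS stratification** is two-stage, as in the re-implemented design: the
  BMI outcome is drawn first (covariate and per-allele SNP effects only,
  defaults 0.10/0.12/0.11 per allele), OR weights are estimated from it
  exactly as the analysis does, and the resulting median split is the
  stratum carrying the other outcomes' effects. Under GRS stratification
  the BMI outcome therefore cannot itself carry stratified cell effects
  (the configuration rejects that).
* **Determinism**: one `set.seed()` call and a fixed draw order make every
  table a pure function of the configuration; a single stream proved
  simpler and equally reproducible than per-component sub-streams, at the
  cost that sub-tables cannot be regenerated in isolation.

What the generator does *not* emulate: food-composition structure beyond a
one-factor correlation, linkage disequilibrium between the SNPs (simulated
independent), measurement error, dropout, or secular trends. Passing
recovery tests therefore demonstrates that the pipeline estimates what it
claims on data satisfying its own assumptions — not that those assumptions
hold in any real cohort.

## Validation experiments and problem sizes

`or_recovery_experiment()` injects a known within-stratum OR structure,
runs the *full* pipeline (cascade, scoring, genotype/GRS coding, adjusted
8-group model) on 20 cohorts of $n = 4480$, and summarizes a target cell's
estimates by their geometric mean; `scripts/acceptance.R` runs the two
headline experiments. Null calibration of the trend and interaction tests
uses 1000 replicates of $n = 2000$; the HWE test's size, 1000 replicates of
$n = 10^4$. These sizes give Monte-Carlo standard errors comfortably inside
the tolerances asserted.

## Known limitations

* The synthetic registry's reference values are placeholders; absolute DII
  magnitudes from it are not comparable to published DII scores.
* Which waist ratio a given published "WHR" table used can be ambiguous;
  both are supported, but results differ and the default (waist-to-hip) is
  a judgement call.
* The ordinal interaction test trades power against non-monotone
  alternatives for parsimony; use the categorical form when the alternative
  is cell-concentrated.
* No multiple-testing correction is applied across the outcome-by-
  stratifier grid, matching field practice for these designs; with 16
  tables, isolated small interaction p-values are expected under the null.
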