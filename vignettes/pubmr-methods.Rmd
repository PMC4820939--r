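---
title: "Methods: genetically proxied pubertal development and prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically proxied pubertal development and prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubmr)
```

## The question and the design

Whether the timing of male puberty influences prostate cancer risk is hard to
study observationally: there is no discrete pubertal event in boys analogous
to menarche, recall over five decades is unreliable, and early-life exposures
correlate with many later-life risk factors. `pubmr` implements the
Mendelian-randomization (MR) design for this question: thirteen SNPs
associated with Tanner genital stage in adolescent boys act as instruments
for pubertal timing, and their associations with prostate cancer endpoints —
case status, Gleason grade (high ≥ 7 vs low ≤ 6), TNM stage (locally
advanced T3–T4 vs localized T1–T2), and long-term mortality — identify the
causal effect of developmental timing, under the instrumental-variable
assumptions, free of conventional confounding and reverse causation.

Two analysis routes are implemented, matching how such a study is actually
run:

1. **Individual level**: a weighted genetic risk score (GRS) over the 13
   variants, entered in tertiles into logistic models adjusted for age,
   recruitment centre and principal components; Cox models with cluster-robust
   (study-level sandwich) standard errors for mortality in a multi-study
   consortium setting; and fixed-/random-effects meta-analysis across studies.
2. **Summarized data**: per-SNP effect pairs (effect on Tanner stage; effect
   on the cancer endpoint) combined by the allele-score estimator for
   correlated variants, with MR-Egger regression as the pleiotropy
   sensitivity analysis and Cochran-Q heterogeneity across per-variant Wald
   ratios.

Because the underlying individual-level cohort data are confidential, the
package ships a fully seeded synthetic-data generator that emulates both
routes' inputs under configurable causal effects, confounding and pleiotropy,
so every stage is testable and the whole pipeline reproducible end to end.

## Sign conventions

Everything is oriented to **pubertal delay**, measured as Tanner-stage
*decrease* at a fixed age. The catalog's effect alleles are the
Tanner-decreasing alleles, so a higher GRS means genetically later puberty.
In `mr_sumstats`, `beta_exposure` is the per-allele effect on the
Tanner-stage decrease (positive once oriented via
`orient_to_exposure_decreasing()`, which flips both effect signs and allele
labels together — an involution that leaves every Wald ratio unchanged).
Causal estimates are therefore log odds ratios **per unit decrease in Tanner
stage**: protective effects of later development appear as OR < 1.

## The genetic risk score

For individual $i$ with harmonized effect-allele dosages $d_{ij} \in [0,2]$
and per-allele weights $w_j > 0$ (Tanner units),

$$S_i = \frac{J}{\sum_j w_j} \sum_{j=1}^{J} w_j d_{ij},$$

so a unit increase in the score corresponds approximately to one risk allele,
and an individual homozygous for every effect allele scores exactly $2J = 26$
whatever the weights. The rescaling constant $J/\sum_j w_j$ is not uniquely
pinned down by the verbal definition "a unit ≈ one risk allele"; this
standard normalization was adopted and the constant is exposed as an
attribute for transparency. Missing dosages are imputed as $2 p_j$ from the
**catalog** reference frequency rather than the cohort, so scores are
reproducible across arbitrary data subsets; this is configurable.

Tertiles use the empirical 1/3 and 2/3 quantiles, ties going to the lower
tertile, with T1 (earliest maturation) as reference. Whether the original
analysis formed tertiles on the full sample or controls only is not
documented; the default here is the full analysis sample, with
`basis = "controls"` available.

**Placeholder weights.** The published per-allele male Tanner-stage effect
sizes live in discovery-GWAS supplementary material and are not
redistributed. The bundled catalog therefore carries clearly labelled
synthetic placeholder weights (0.030–0.080 Tanner units per allele, LIN28B
variants strongest), chosen so the 13-SNP score explains ≈ 1.8 % of the
latent Tanner variance — the weak-instrument regime typical of such scores.
Users with access to the real effect sizes can supply their own catalog TSV.

## Allele harmonization and quality checks

Dosage files are harmonized to the catalog's effect alleles: matching pairs
are kept, swapped pairs flipped ($d \mapsto 2-d$), and strand-complementary
pairs resolved only for non-palindromic SNPs. Palindromic variants (the
catalog contains C/G SNPs such as rs2274465) are matched by allele identity
alone — frequency-based strand inference is deliberately **not** attempted,
because silent strand flips are a classic source of sign errors in MR; an
explicit override flag exists. Hardy–Weinberg equilibrium is checked with the
exact conditional test (probability-mass-ordered two-sided p), which is
well-defined at any sample size and is verified in the test suite against an
exhaustive enumeration oracle over every genotype table up to n = 200. The
variant rs6427782, whose control-sample HWE p was 0.005 in the original
cohort, is retained in the default catalog as it was in the analysis it
mirrors (its exclusion was reported to make no appreciable difference).

## Summarized-data causal estimation

With oriented per-SNP pairs $(\hat b_{Xj}, \hat b_{Yj})$ and LD correlation
matrix $\rho$, the allele-score estimator for correlated variants is the
generalized weighted least-squares solution

$$\hat\beta = \frac{b_X^\top \Omega^{-1} b_Y}{b_X^\top \Omega^{-1} b_X},
\qquad \Omega_{jk} = se_{Yj}\, se_{Yk}\, \rho_{jk},$$

with $se(\hat\beta) = (b_X^\top \Omega^{-1} b_X)^{-1/2}$ and generalized
Cochran heterogeneity $Q = r^\top \Omega^{-1} r$, $r = b_Y - \hat\beta b_X$,
$I^2 = \max(0, (Q - df)/Q) \cdot 100$.

**Exposure-side uncertainty (a deliberate extension).** The textbook
weighting above ignores the sampling error of $b_X$. For these instruments
that is not negligible: at an exposure GWAS of $n \approx 5\times10^4$, with
per-allele weights ≈ 0.03–0.08 Tanner units and a strong causal effect
($|\beta| \approx 1.5$), the ignored variance component
$\beta^2 se_X^2 / se_Y^2$ reaches ≈ 0.3–0.7 and the nominal 95 % intervals
cover at only ≈ 87–92 %. `ivw_correlated()` therefore defaults to
$\Omega + \hat\beta^2\, (se_X se_X^\top \circ \rho)$, iterated to
convergence — which reduces smoothly to the textbook form as $se_X \to 0$ or
$\beta \to 0$ — and offers `exposure_uncertainty = FALSE` for the exact
classical formula (that is also the form the oracle-equivalence tests pin to
the hand-coded inverse-variance-weighted mean). Simulation in the test suite
confirms 95 % ± 2 % coverage under the default.

**LD matrix.** The analysis accepts any user-supplied correlation matrix and
regularizes it by flooring eigenvalues at $10^{-6}$ of the largest (the
condition number is reported on failure). With no matrix supplied, identity
is assumed with a loud warning, since three of the catalog SNPs sit in the
same TMEM38B region. Which LD source produced the published point estimate is
not documented, so exact numeric reproduction of the headline OR carries
method-choice uncertainty even with the original summary data.

**MR-Egger.** Weighted least squares of $b_Y$ on $b_X$ *with* intercept,
weights $1/se_Y^2$, exposure effects oriented positive. The slope is the
pleiotropy-adjusted causal estimate; the intercept estimates directional
pleiotropy and its p-value is the formal test. Standard errors carry a
multiplicative overdispersion factor floored at 1. With that floor, a
t-reference makes the intercept test noticeably conservative at 13
instruments (type-I ≈ 2 %), so p-values and intervals use the normal
reference (type-I ≈ 4 % in the package's null calibration, within the
nominal band); the residual conservatism at exactly-null overdispersion is a
known property of the floor.

**Wald ratios** use the first-order delta SE $|se_Y / b_X|$ by default
(exposure error ignored at this level, as is conventional for per-variant
displays); a second-order option exists and is validated against a parametric
bootstrap. The funnel table (ratio vs precision) and the effect-versus-effect
table (per-SNP proportional risk reduction $1 - e^{b_Y}$ against the absolute
Tanner-lowering effect, with a through-origin trend line) are emitted as
plot-ready data; rendering is left to the user. Both the origin-constrained
$R^2$ and the unconstrained squared Pearson correlation between the raw
effect vectors are returned, since either convention may be meant by a
reported effect–effect correlation.

## Individual-level models

`fit_logistic()` wraps the standard IRLS fit (deviance tolerance $10^{-10}$,
100 iterations) and adds the diagnostics a pipeline needs to fail loudly:
rank-deficient designs name their collinear columns, and perfect separation
(zero deviance, or a diverging coefficient with saturated probabilities) is
an explicit error. Tertile analyses fit both codings used in practice —
indicator coding against T1 with a joint likelihood-ratio p, and the numeric
1–3 trend ("per tertile increase"). `fit_cox()` uses the Efron tie
correction, administrative censoring at exactly the stated horizon (15 years
by default), treats other-cause deaths as censoring for the prostate-specific
endpoint, and computes the cluster-sandwich variance grouped by study; with a
single cluster level the sandwich is degenerate, so the fit falls back to
model-based standard errors with a warning. The proportional-hazards check is
the score test on scaled Schoenfeld residuals against the Kaplan–Meier time
transform (the transform used originally is not documented; KM is the default
here). Group comparisons are Welch t-tests and Pearson chi-square without
continuity correction, with a natural-log option for skewed biomarkers. The
confounder screen regresses each covariate on the score among controls and
reports unadjusted p-values (as such screens are usually read) plus a
Bonferroni column.

Meta-analysis is inverse-variance fixed-effect as the headline (the
replication consortium showed low between-study heterogeneity), always
accompanied by DerSimonian–Laird random effects; tau² truncation makes the
two identical when $Q \le df$. The Knapp–Hartung adjustment is off by
default (flag available). The test suite cross-checks both against the
independent `metafor` implementation.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions used throughout the tests:

* **Genotypes** at the catalog control frequencies, Binomial(2, $p_j$);
  optional LD blocks are generated from two latent-Gaussian haplotypes with
  the latent correlation solved numerically (via the bivariate-normal
  orthant probability) so the realized *dosage* correlation matches the
  requested $\rho$; infeasible targets for the given frequencies error.
* **Latent Tanner stage**
  $T_i = 3.5 - \sum_j w_j d_{ij} + 0.3\,U_i + \varepsilon_i$, with $U_i$ a
  shared standard-normal confounder and $\varepsilon_i \sim N(0, 0.75^2)$;
  staging cuts the latent at 1.5/2.5/3.5/4.5 so a mid-adolescent population
  spans stages 2–5. The score explains ≈ 1.8 % of the latent variance —
  an explicit assumption, since the variance explained by the real 13 SNPs
  in boys is not documented.
* **Outcomes** follow
  $\text{logit}\,P(Y_i) = a + \beta^* D_i + \sum_j \alpha_j d_{ij} + 0.3\,U_i$,
  where $D_i$ is the centred pubertal delay, $\alpha_j$ are injectable
  pleiotropic direct effects (none/balanced/directional/explicit), and
  intercepts are solved numerically for the target fractions (38.8 % cases;
  30 % high grade and 11.6 % advanced stage among cases). Grade and stage are
  defined only among cases. Mortality among cases is Weibull
  proportional-hazards (shape 1.2, scale 12 years) with log-hazard
  $\ln(0.62)\, D_i$, independent exponential other-cause mortality (rate
  0.02/year) and administrative censoring at 15 years.

**Marginal-scale causal parameters.** Logistic effects are non-collapsible:
with a latent exposure of SD ≈ 0.8, a conditional coefficient $\beta^*$
produces per-SNP marginal associations attenuated by roughly
$1/\sqrt{1 + \beta^{*2}\sigma^2/2.89}$, and summary-data MR estimates the
*population-averaged* effect, not $\beta^*$. `causal_log_or` is therefore
interpreted on the marginal scale by default: the generator numerically
calibrates $\beta^*$ (by Gaussian integration of the collapsed
logit-probability curve) so the per-allele outcome associations equal
$\beta \times w_j$ — making "the generative causal OR" exactly the estimand
the estimators target, which is what gives parameter-recovery simulations a
well-defined truth. `effect_scale = "conditional"` passes the raw coefficient
through instead. Two consequences are worth knowing:

* There is a hard feasibility bound: the attainable marginal log-OR per unit
  of a Gaussian exposure saturates at
  $\phi(z_\pi)/(\pi(1-\pi)\,\sigma_{delay})$ as $\beta^* \to \infty$. At the
  default dispersion that bound is ≈ 2.0, comfortably above the strongest
  effect studied here ($|\ln 0.23| = 1.47$); a latent Tanner SD above ≈ 1.13
  would make an OR of 0.23 per unit *impossible to generate* in this model
  family. The calibration errors informatively on infeasible requests. This
  bound drove the choice of the default noise SD.
* The calibration solves the collapsed curve at the population mean and
  ignores the (tiny, ≈ 0.1 %) per-SNP share of the latent variance; large-n
  diagnostics show per-SNP marginal effects within ≈ 0.5 % of target.

**Two-sample structure.** `simulate_summary_study()` draws two independent
cohorts — an adolescent-GWAS-style exposure arm (per-SNP linear regressions
of the pubertal delay on dosage) and a case-control outcome arm (per-SNP
logistic regressions, run among cases for the grade and stage contrasts) —
mirroring the actual design in which the exposure GWAS and the cancer study
are distinct samples. The LD matrix is estimated from the outcome arm's
genotypes. Per-SNP fits use a dedicated Newton solver validated against
`glm`, keeping replicate studies fast enough for 500-replicate operating
characteristics on one CPU.

**What the generator does not emulate**: genome-wide LD beyond the
configured blocks, PSA-screening detection dynamics, population
stratification beyond independent PC covariates, age structure in the
hazards, and between-study heterogeneity in phenotype definitions. Passing
tests therefore demonstrate the estimators' statistical properties under the
assumed causal structure, not the fidelity of any particular published
number derived from confidential data.

## Problem sizes used in the checks

The bundled checks run, per invocation: 25 replicate synthetic stand-ins at
the published study's scale (exposure arm 4,000; outcome cohort 2,927 with
the grade contrast among its ≈ 1,136 cases); a 500-replicate recovery study
and a 1,000-replicate null study at $5\times10^4$ and $10^4$ per arm
respectively; a 21-study meta-analysis and a 15-study mortality cohort of
30,000. These sizes give Monte-Carlo standard errors of ≈ 0.5 % on coverage
and type-I rates while keeping a full run in the minutes range on a single
core.

## Known limitations

* The placeholder weights make all individual-level effect *magnitudes*
  (e.g. per-tertile ORs) depend on an assumed score strength; only the
  summarized-data estimators have a calibrated generative truth.
* The exact-reproduction targets that require the original supplementary
  per-SNP tables (notably the reported effect–effect $R^2 \approx 31\%$)
  cannot be matched by any synthetic stand-in: that statistic reflects the
  particular scatter of the real effect estimates, and the stand-ins at the
  same sample sizes put it near 3–5 %.
* Egger's intercept test inherits mild conservatism from the overdispersion
  floor; the weighted-median and modal estimators, MR-PRESSO, multivariable
  MR and Steiger filtering are out of scope by design.
* Survival generation uses cause-specific hazards with independent competing
  mortality; Fine–Gray-style subdistribution modelling is not attempted.
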