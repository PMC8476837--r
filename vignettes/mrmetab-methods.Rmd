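---
title: "Methods: batch two-sample Mendelian randomization for metabolite panels"
author: "mrmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch two-sample Mendelian randomization for metabolite panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmetab)
```

## The problem and the model

Circulating metabolites are plausible intermediates between genetic variation
and cardiometabolic disease, but observational metabolite-disease
associations are confounded by diet, medication and reverse causation.
Two-sample Mendelian randomization (MR) sidesteps this by using genetic
variants as instrumental variables: variant-exposure associations
$(\hat\gamma_j, \sigma_{Xj})$ come from a metabolite GWAS in one sample, and
variant-outcome associations $(\hat\Gamma_j, \sigma_{Yj})$ from a disease
GWAS in a second, non-overlapping sample. If variant $j$ is a valid
instrument (associated with the exposure; independent of confounders;
affecting the outcome only through the exposure), its Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ estimates the causal effect
$\beta$ of a 1-SD increase in the metabolite on the log odds of disease.

`mrmetab` packages the whole screen for panels of hundreds of exposures:
instrument selection, allele harmonization, five causal estimators,
sensitivity diagnostics, and a multi-model decision rule, plus a synthetic
two-sample GWAS generator so the entire pipeline is testable with known
ground truth.

## Instrument selection

Four filters are applied in a fixed order, each recorded in a per-exposure
`filter_trace()`:

1. **Significance screen** (`select_by_pvalue()`): retain SNPs with exposure
   $p < 10^{-5}$ (strict inequality), the conventional relaxed threshold for
   metabolite instruments, where genome-wide significance would leave too
   few instruments for most metabolites.
2. **LD clumping** (`ld_clump()`): greedy index-SNP selection — repeatedly
   take the remaining candidate with the smallest $p$, and remove every
   candidate on the same chromosome within 10,000 kb (inclusive distance
   between 1-based positions) whose $r^2$ with it exceeds 0.001. Ties on
   $p$ are broken by (chromosome, position, identifier) so the result never
   depends on input order. Candidates absent from the LD reference are kept
   and logged rather than silently dropped, which would bias screens toward
   sparse panels; the behaviour is visible in the log.
3. **Cross-exposure restriction** (`restrict_cross_exposure()`): a SNP whose
   exposure $p$-value is sub-threshold in two or more exposures likely
   regulates a shared pathway, threatening the exclusion restriction; it is
   removed from every instrument set.
4. **Exclusion list** (`apply_exclusion_list()`): SNPs known to associate
   with the outcome disease or its risk factors, supplied as a plain-text
   list (one identifier per line).

Exposures then keep between 3 and 100 instruments (inclusive); fewer give
unstable estimates and the Egger/mode estimators need at least 3, while very
many instruments at a relaxed threshold usually indicate a poorly specified
exposure.

## Harmonization

`harmonize()` aligns outcome effects onto the exposure's effect allele over
the shared SNPs, trying the recorded alleles as-is, swapped, and on the
complementary strand; a swap negates $\hat\Gamma_j$ and complements the
outcome allele frequency, with `flipped = TRUE`. Palindromic SNPs (A/T and
G/C) are strand-ambiguous from labels alone; by default they are aligned by
allele frequency — effect-allele frequencies on the same side of 0.5 keep
the orientation, opposite sides flip it — and dropped as ambiguous when
`min(eaf, 1 - eaf) > 0.42` in either study or when a frequency is missing.
The 0.42 cut-off is the standard compromise between losing instruments and
risking silent strand errors; set `palindromic_policy = "drop"` to discard
all palindromic SNPs instead. Indels and multi-allelic records are rejected
at read time: the screen targets biallelic SNPs, for which strand logic is
well defined.

## The five estimators

All operate on the harmonized arrays; weights are first-order
inverse-variance weights $w_j = \hat\gamma_j^2 / \sigma_{Yj}^2$
(equivalently, ratio SE $\sigma_{Yj}/|\hat\gamma_j|$).

- **IVW** (`mr_ivw()`, the primary estimator):
  $\hat\beta = \sum_j w_j \hat\theta_j / \sum_j w_j$, a zero-intercept
  weighted regression of $\hat\Gamma$ on $\hat\gamma$. The default variance
  model is multiplicative random effects: the fixed-effect SE
  $(\sum_j w_j)^{-1/2}$ is inflated by $\max(1, \hat\phi)$ with
  $\hat\phi^2 = Q/(J-1)$, so between-instrument dispersion widens the
  interval but underdispersion is never credited.
- **MR-Egger** (`mr_egger()`): the same regression with a free intercept,
  after orienting every SNP so $\hat\gamma_j \ge 0$. The slope estimates
  $\beta$ under the InSIDE assumption (instrument strength independent of
  direct effects); the intercept estimates the average directional
  pleiotropy. SEs carry the same $\max(1,\hat\phi)$ inflation with
  $\hat\phi^2 = Q'/(J-2)$, and $p$-values use $t_{J-2}$.
- **Weighted median** (`mr_weighted_median()`): the 50% point of the
  weighted empirical distribution of ratios, interpolated across cumulative
  weight midpoints; consistent when valid instruments carry at least half
  the weight.
- **Simple and weighted mode** (`mr_simple_mode()`, `mr_weighted_mode()`):
  the argmax of a Gaussian kernel density over the ratios (unweighted or
  inverse-variance weighted), consistent under the zero-modal-pleiotropy
  assumption — the largest cluster of agreeing instruments is the valid
  one.

Bootstrap SEs (weighted median and modes) resample
$\theta_j^* \sim N(\hat\theta_j, se_j)$ for `n_boot = 1000` replicates by
default and are seeded; identical seeds give identical output, and the
batch driver derives one sub-seed per exposure and method from its master
seed, so results do not depend on panel ordering.

### Numerical choices

- **Mode bandwidth**: $h = \phi \cdot 1.06 \, s \, J^{-1/5}$ with $s$ the
  smaller of the SD and the consistency-scaled MAD of the ratios
  ($\phi = 1$ by default). The robust scale keeps a single wild ratio from
  flooding the bandwidth. When the MAD is exactly zero (a majority of
  identical ratios) the density degenerates and the estimator returns the
  most heavily weighted tied value, breaking ties toward the smallest
  ratio.
- **Mode argmax**: a 512-point grid over
  $[\min\theta - 3h, \max\theta + 3h]$ picks the basin, then
  `stats::optimize()` refines it locally; a multi-modal plateau is resolved
  toward the smallest ratio with a warning.
- **$p$-values**: two-sided normal for IVW, weighted median and the modes;
  $t_{J-2}$ for both Egger coefficients.
- **Empirical $p$-values** (MR-PRESSO global, outlier and distortion tests)
  use the $(1+k)/(1+n)$ correction so a simulated $p$ of exactly zero is
  impossible.

## Sensitivity layers

- **Cochran's Q** (`cochran_q()`) for both the IVW and Egger fits, with
  $\chi^2_{J-1}$ / $\chi^2_{J-2}$ reference distributions; $p > 0.05$ is
  read as no evidence of heterogeneity. $Q_{IVW}$ equals
  $(J-1)\hat\phi^2$ from the IVW dispersion estimate by construction.
- **Egger intercept test** (`egger_intercept_test()`): no evidence of
  directional pleiotropy when $|\hat\beta_0| < 0.1$ (strict) *and*
  $p > 0.05$.
- **MR-PRESSO** (`mr_presso()`): the observed residual sum of squares
  around leave-one-out IVW slopes is compared against `n_sim = 1000`
  parametric simulations of the no-pleiotropy model (global test); each
  SNP's squared residual against its own simulated distribution with
  Bonferroni adjustment over $J$ (outlier test, $\alpha = 0.05$); and the
  IVW change after removing flagged outliers against 1000 random same-size
  removals (distortion test).
- **Leave-one-out** (`leave_one_out()`): the IVW estimate with each SNP
  removed in turn; the result is stable when every reduced-set interval
  $\hat\beta \pm 1.96\,se$ excludes zero. SNPs whose removal opens the
  interval are reported as sensitive.

## Decision rule and significance tiers

With $M$ exposures screened, the Bonferroni tier is
$p_{IVW} < 0.05/M$ (for a 486-metabolite panel, $1.03\times10^{-4}$); the
nominal tier is $p_{IVW} < 0.05$. An exposure is a **candidate causal
feature** when the IVW estimate is nominally significant, at least three of
the five models (necessarily including IVW) have $p < 0.05$, and all five
point estimates share a sign. Sign consistency operationalizes "similar
causal estimates"; a magnitude-based similarity cut would need an arbitrary
scale and is left out. $M$ defaults to the number of exposures supplied,
not the number surviving filters, so the correction reflects the full
screen.

## The synthetic-data generator

`simulate_two_sample()` generates both samples directly on the
summary-statistic scale. True instrument effects are drawn from
`gamma_dist`; direct effects $\alpha_j$ follow the configured pleiotropy
regime (`none`, `balanced`, `directional`, or `inside_violating`, where
$\alpha_j$ is coupled to $\gamma_j$ with coefficient 0.5); true outcome
effects are $\Gamma_j = \sum_k \beta_k\gamma_{jk} + \alpha_j$. Observed
effects add independent noise with
$\sigma_{Xj} = 1/\sqrt{2 n_1 f_j(1-f_j)}$ for a standardized quantitative
exposure at allele frequency $f_j$, and the analogous $\sigma_{Yj}$ at the
outcome's *effective* sample size on the log-odds scale. LD blocks are
exchangeable within-block correlations reproduced exactly in the emitted
panel. All randomness flows from one seed through per-exposure sub-streams,
so adding exposures never perturbs existing ones.

Defaults emulate the targeted study design at desk scale: $n_1 = 7{,}824$
(a metabolomics GWAS), $n_2 = 180{,}000$ effective (a heart-failure
meta-analysis of 47,309 cases and 930,014 controls;
$4/(1/n_{\rm case}+1/n_{\rm control}) \approx 1.8\times10^5$), minor-allele
frequencies uniform on $(0.05, 0.45)$, causal effect $\beta = 0.2$
log-odds per SD, and instrument effects $N(0.5, 0.2^2)$ per SD — the
strong selected metabolite QTLs such screens retain, explaining roughly
6–10% of metabolite variance each.

What the generator deliberately does **not** emulate: individual-level
case-control sampling (outcome effects are drawn directly on the log-odds
scale), LD-correlated sampling noise between SNPs within a block (noise is
independent across SNPs even where dosages are correlated), real metabolite
genetic architectures or effect-size spectra, and population stratification
or sample overlap. Passing tests therefore demonstrate correctness of the
estimators and pipeline logic under the stated model, not robustness to
those real-data complications.

`make_fixture_study()` writes a complete on-disk study (default 20
exposures × 500 SNPs) with one planted feature per pipeline stage — a
causal exposure ($\beta = 0.2$), a two-instrument exposure for the count
filter, a SNP instrumenting two exposures for the restriction, an $r^2=0.9$
pair for the clump, an exclusion-listed instrument, a retained palindromic
instrument, an outcome-shifted MR-PRESSO outlier, and swapped-allele
outcome rows for the harmonizer.

## Calibration and recovery checks: design

The test suite measures type-I error of Cochran's Q and the null
distribution of the MR-PRESSO global $p$ under the *sharp null*
($\beta = 0$, no pleiotropy). This is deliberate: conditional on the
observed $\hat\gamma$, Q at $\beta = 0$ is exactly $\chi^2_{J-1}$, whereas
for $\beta \ne 0$ the first-order ratio SE omits a $\beta^2\sigma_{Xj}^2$
term and every heterogeneity statistic is anti-conservative by construction
— a property of the estimators, not of any implementation. Parameter
recovery is checked at $J = 50$ instruments, $n_1 = 8000$, $n_2 = 50000$,
500 replicates; calibration at $J = 10$ over 2000 replicates (MR-PRESSO
with `n_sim = 200` per replicate to keep the suite inside a desk-scale run
time). These sizes are stated here as the package's chosen study
conditions.

## Known limitations

- **Regression dilution (NOME violation)**: sampling noise in
  $\hat\gamma$ attenuates IVW toward the null by a factor
  $\approx \sum\gamma_j^2 / (\sum\gamma_j^2 + J\sigma_X^2)$. At the default
  instrument strength this is a relative bias of order $10^{-3}$ and is
  visible in high-replicate simulations; weak-instrument corrections are
  out of scope.
- **Egger orientation**: orienting instruments by the observed sign of
  $\hat\gamma_j$ means the intercept estimates the average *oriented*
  direct effect $E[\mathrm{sign}(\gamma_j)\,\alpha_j]$. When some true
  instrument effects sit near zero, sign flips carry their $\alpha_j$ with
  inverted sign and the intercept slightly under-recovers a directional
  mean — measurable in the recovery simulations at the default
  `gamma_dist`.
- **MR-PRESSO global test is conservative at small $J$**: the observed RSS
  is a leave-one-out (PRESS-type) statistic while simulated datasets embed
  the spread of the estimated leave-one-out slopes and are refitted; the
  resulting null rejection deficit is $O(1/J)$ and disappears by
  $J \approx 50$ in the suite's measurements.
- The five estimators protect against different invalidity patterns but
  none against instruments acting through a shared upstream confounder of
  many metabolites; the cross-exposure restriction is a heuristic guard.
- Binary-outcome effects are treated as log odds throughout; no
  non-collapsibility correction is attempted.
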