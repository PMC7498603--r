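---
title: "Bidirectional two-sample Mendelian randomization: models, design choices and limitations"
author: "bimr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimr)
```

## The problem

Observational associations between an exposure (say adiposity, measured as
BMI) and a disease (say atopic dermatitis) are confounded and may run in
either direction. Mendelian randomization (MR) uses genetic variants as
instrumental variables: alleles are allocated at random at conception, so a
variant that raises the exposure mimics a small randomized intervention on
it. In *two-sample* MR the SNP–exposure associations $\hat\gamma_j \pm
\sigma_{Xj}$ and the SNP–outcome associations $\hat\Gamma_j \pm \sigma_{Yj}$
come from two non-overlapping GWAS, combined at summary-statistic level.
Running the analysis in both directions (exposure→outcome and
outcome→exposure, with instruments selected for each trait in turn)
addresses the direction of causality.

`bimr` implements the full workflow: instrument selection and pruning,
harmonization with LD-proxy substitution, five causal estimators,
instrument-strength diagnostics, analytic power, and a synthetic
summary-statistic generator with known ground truth that stands in for the
real GWAS downloads in all tests and examples.

## Estimators

Each instrument supplies a Wald ratio $\hat\beta_j = \hat\Gamma_j /
\hat\gamma_j$ with delta-method standard error; the first-order form
$\sigma_{Yj}/|\hat\gamma_j|$ is the default (the dominant two-sample
convention), the second-order form
$\sqrt{\sigma_{Yj}^2/\hat\gamma_j^2 + \hat\Gamma_j^2\sigma_{Xj}^2/\hat\gamma_j^4}$
is available by configuration. The multi-SNP estimators are:

* **IVW**: the inverse-variance weighted mean of the ratios, equal to
  weighted least squares of $\hat\Gamma_j$ on $\hat\gamma_j$ through the
  origin. Heterogeneity is summarized by Cochran's $Q$; under the
  *multiplicative random-effects* model the fixed-effects SE is inflated by
  $\max\{1, \sqrt{Q/(k-1)}\}$ — inflation only, never deflation. This is
  the convention of the standard two-sample MR software; an additive
  random-effects model is not offered.
* **Modified IVW**: the same estimator on the instrument set after removing
  SNPs annotated to likely confounders (education, smoking, alcohol,
  physical activity, psychiatric traits, ...) in a PhenoScanner-style
  annotation table, matched case-insensitively by substring (trait labels
  are free text; exact matching is available).
* **Maximum likelihood**: observed $(\hat\gamma_j, \hat\Gamma_j)$ are
  modelled as independent normals with means $(\gamma_j, \beta\gamma_j)$
  and known SDs; the $\gamma_j$ are profiled out in closed form and the
  1-D profile deviance $\sum_j (\hat\Gamma_j - \beta\hat\gamma_j)^2 /
  (\sigma_{Yj}^2 + \beta^2\sigma_{Xj}^2)$ is minimized numerically. The SE
  comes from the inverse observed information of the *full* joint
  likelihood at the optimum (the description of the method we follow
  specifies the inverse Hessian; whether the original used profile or full
  joint likelihood is not stated — we implement the full joint). The
  measurement-error term in the denominator is what makes this estimator
  less attenuated than IVW when exposure-side noise matters.
* **Weighted median**: order the ratios, normalize the weights
  $w_j \propto 1/\mathrm{se}_j^2$, and interpolate the ratio at which the
  standardized cumulative weight $s_j = \sum_{i\le j} w_i - w_j/2$ crosses
  one half, so that 50% of the weight lies at or below the estimate.
  Consistent when at least half the weight comes from valid instruments.
  The SE is a parametric bootstrap (each ratio resampled from
  $N(\hat\beta_j, \mathrm{se}_j)$, default 1000 draws, mandatory seed).
* **MR-Egger**: weighted regression of $\hat\Gamma_j$ on $\hat\gamma_j$
  (weights $1/\sigma_{Yj}^2$) with a free intercept, after orienting every
  instrument to a non-negative exposure effect — without that orientation
  the intercept, which estimates average directional pleiotropy, is not
  interpretable. The slope is the causal estimate under InSIDE (pleiotropic
  effects independent of instrument strength); the intercept test flags
  directional pleiotropy. P-values use $t_{k-2}$; both SEs carry the same
  $\max(1, \text{residual scale})$ inflation as IVW.

P-values for IVW, ML and the median use the normal reference; all 95% CIs
are $\hat\beta \pm 1.96\,\mathrm{se}$, so the report matches the usual
two-decimal OR tables. Estimates for a binary outcome are reported on both
the log-odds and the OR ($e^{\hat\beta}$) scale.

## Harmonization

Both association tables must refer to the same effect allele per SNP.
Comparing allele pairs yields one of: match, swap (betas negated, EAF
complemented), strand flip (labels complemented, effect unchanged), swap
plus flip, or *palindromic ambiguity* — an A/T or C/G variant is its own
strand complement, so alleles alone cannot resolve orientation. The default
policy `align_by_eaf` orients palindromic variants by agreement of the
allele-frequency sides (both below or both above 0.5) and drops the variant
when either frequency falls within ±0.08 of 0.5 (configurable) or is
absent. The band is our choice: the study we model checked palindromes by
hand and found no inversions, but a reproducible pipeline needs an
automatic rule, and ±0.08 is the customary default of the two-sample MR
tooling. Harmonization never alters effect magnitudes or standard errors —
only signs, labels and frequency sides — and re-harmonizing its own output
is the identity; both properties are enforced bit-exactly in the tests.

Instruments absent from the outcome table are replaced by the
outcome-present LD proxy with the highest $r^2 \ge 0.6$ (ties broken by
rsid for determinism; the threshold mirrors standard practice). The proxy's
effect allele is mapped through the LD table's allele-phase columns when
present, otherwise by frequency-side agreement, which requires the proxy to
be non-palindromic with EAF away from 0.5. The proxy's beta and SE stand in
unchanged — no $r^2$ attenuation correction — matching standard two-sample
practice. Variants with no usable proxy are dropped and logged; the
disposition log accounts for every input instrument exactly once.

## Instrument selection

`filter_genome_wide()` applies a strict p-value threshold (1e-8 or 5e-8 in
the analyses shipped here). `prune_instruments()` implements greedy
keep-best-p pruning: records are visited in ascending p-value (ties broken
by chromosome, then position), and a record is dropped if it violates an
$r^2$ threshold within a window, or a minimum distance, against an
already-kept record on the same chromosome. LD pairs absent from the
supplied table are treated as independent and the assumption is logged —
supplied LD tables are sparse by nature. The pruning ladder used for
sensitivity reruns ($r^2 > 0.5/0.2/0.1$ within 500 kb; $r^2 > 0.01/0.001$
within 1000 kb; 4 Mb distance pruning) is expressed as configuration.

## Diagnostics

Measurement error in $\hat\gamma_j$ (violation of the NO-Measurement-Error
assumption) attenuates the estimators. Per-SNP instrument strength is
$F_j = (\hat\gamma_j/\sigma_{Xj})^2$ — the squared z-statistic, the
standard large-sample single-SNP F. The description we follow reads
literally as "effect size over variance", which is not scale-invariant; we
use the standard form and expose the choice. $\bar F$ is a simple mean by
default (the weighting of the original's "weighted F" is not defined; an
inverse-variance weighted mean is selectable) and the expected relative
attenuation of IVW is $(\bar F - 1)/\bar F$. For MR-Egger the relevant
statistic is $I^2_{GX} = \max\{0, (Q_{GX} - (k-1))/Q_{GX}\}$, the fraction
of the dispersion of the (orientation-aligned) exposure estimates that is
true signal; values near 1 mean the Egger slope is barely diluted, small
values mean Egger should not be trusted.

## Power

Power of the 1-df Wald test uses the noncentral chi-square: reject when the
statistic exceeds the central $\chi^2_{1,1-\alpha}$ quantile, power is the
noncentral upper tail. For a continuous outcome
$\mathrm{NCP} = n R^2 \beta^2 \sigma_x^2/\sigma_y^2$. For a binary outcome
the odds ratio is first converted to an approximate risk-difference slope
$b = K\left(\frac{\mathrm{OR}}{1 + K(\mathrm{OR}-1)} - 1\right)$ with case
fraction $K$, and $\mathrm{NCP} = b^2 n R^2 / (K(1-K) - b^2)$ — the
construction of the standard web power calculator for MR. The OR is
consumed per unit of the exposure as measured, with $R^2$ on the same
scale. `minimum_detectable_effect()` inverts the monotone power function by
bisection to $10^{-6}$ in achieved power.

`simulate_power()` is an independent check: it simulates the score–outcome
regression (logistic for binary, OLS for continuous) at the design's sample
size and counts rejections. The continuous formula validates everywhere we
tested. The binary conversion is a small-effect approximation: the oracle
shows it overstates the slope by roughly a factor
$1 + (0.5 - K)(\mathrm{OR} - 1)$, so at low case fractions with OR
$\gtrsim 1.2$ the analytic power is a few percentage points optimistic.
At the designs analysed here ($K \approx 0.18$, OR $\approx 1.09$) the
distortion is negligible; treat low-$K$/large-OR outputs as upper bounds.

## The synthetic generator

`simulate_two_sample_gwas()` emulates a pair of GWAS at summary level. MAFs
are uniform on a configurable range (default 0.05–0.40, keeping palindromic
variants orientable by frequency); per-SNP exposure effects are drawn
half-normal — oriented to the exposure-increasing allele, the convention
under which directional pleiotropy is defined — and rescaled so the
explained variance hits `target_r2` exactly. Direct (pleiotropic) outcome
effects $\alpha_j$ are added per regime (none / balanced / directional,
optionally on a fraction of SNPs, with an InSIDE-violating correlation
parameter); the truth identity $\Gamma_j = \beta\gamma_j + \alpha_j$ holds
exactly in every dataset. Observed effects add normal noise at the standard
GWAS standard-error approximations,
$\sigma \approx \sqrt{\sigma_{trait}^2 / (2p(1-p)n)}$ for a continuous
trait and $\sigma \approx 1/\sqrt{2p(1-p)\,n\,K(1-K)}$ (log-odds) for a
binary one. Outcome records are randomly re-presented (allele swap, strand
flip, or both) so harmonization is always exercised, and a configurable
fraction of instruments is removed from the outcome table with proxies of
configurable $r^2$ (some deliberately below threshold or absent).
Everything derives from one seed; replicate seeds in
`evaluate_operating_characteristics()` are counter-derived so replicates
are independent yet reproducible.

Two presets mirror the study designs this package reanalyses:
`bmi_to_ad_like` (941 instruments, $R^2 = 0.06$, exposure GWAS
$n = 681{,}275$, binary outcome with 21,000 cases / 95,000 controls, true
OR 1.08, one instrument proxied at $r^2 = 1$) and `ad_to_bmi_like` (24
instruments of a binary exposure, $R^2 = 0.026$, continuous outcome of
variance 16 at $n = 681{,}275$, true effect 0, with 14 outcome-missing
instruments of which 10 are proxiable and 4 are not, leaving 20 usable).
Two calibration points deserve comment:

* **Exposure scale.** The forward preset treats the exposure on its
  standardized (unit-variance) scale. The published precision of the
  941-instrument IVW (CI width ≈ ±0.06 on the log-OR) is consistent with
  $\sum 2p(1-p)\gamma^2 = R^2$ on a unit-variance exposure, and the same
  convention is built into the binary power formula (no $\sigma_x^2$
  term); on the raw-variance scale the implied SEs would be four times
  tighter than anything reported. We therefore calibrate to the printed
  precision.
* **Pleiotropy presets.** The `directional_pleiotropy` benchmark draws
  instrument effects uniform, bounded away from zero, from a large exposure
  GWAS ($I^2_{GX} \approx 0.99$). This is the regime in which the Egger
  slope is a meaningful estimand: with many near-null instruments, noise
  flips the orientation of weak SNPs and breaks InSIDE *by construction*
  (an orientation bias of the data, not the estimator), while with a
  modest exposure GWAS the Egger slope is visibly NOME-diluted (by
  $\approx 1 - I^2_{GX}$). Both regimes are real and are why $I^2_{GX}$ is
  reported; the reverse-direction analysis of the motivating study
  ($I^2_{GX} = 4\%$) is exactly such a case.

What the generator does **not** emulate: LD between instruments (only
designated proxy pairs carry $r^2$), selection effects (instrument lists
are taken as given, so there is no winner's curse, and re-filtering a
generated table at genome-wide significance thins it — real conditional
analyses pre-select their hits), sample overlap between the two GWAS,
population stratification, and EAF estimation noise. Passing tests
therefore demonstrate correctness of the estimators and plumbing under the
stated measurement model, not robustness to those artefacts of real data.

## Numerical choices

The ML profile deviance is minimized with Brent's method on a bracket of
±max(1, 50 SE) around the IVW start, expanding up to 12 times if the
optimum touches the boundary (then an error with the bracket reported);
the information matrix is assembled analytically, so no numerical Hessian
is involved. Egger is solved by explicit weighted normal equations rather
than `lm`, so an exactly affine dataset (zero residual) yields the
known-weights SE instead of 0/0. The weighted-median and bootstrap seeds
are mandatory and restore the caller's RNG state. Ratio weights are
recomputed from the chosen delta-method order. Degenerate inputs follow
the rules: a single instrument reduces IVW/ML to the Wald ratio (random
effects falls back to fixed with a warning), the median needs $k \ge 3$,
Egger $k \ge 3$ (it reports failure inside the suite rather than aborting
it), $Q_{GX} = 0$ yields $I^2_{GX} = 0$.

## Problem sizes in the shipped tests

The acceptance-style checks run 2000 null replicates for type-I error
(realized rate 0.0445 at the shipped seed; the multiplicative
random-effects truncation makes the test mildly conservative, which is why
the null preset uses 300 strong instruments — at small $k$ the residual
scale is noisy and the conservatism grows), 200 replicates of the
941-instrument recovery design, 200 replicates of the pleiotropy
benchmarks, 1000 harmonization round-trip datasets, and a 6-design power
grid at 5000 oracle replicates each. The whole suite runs in roughly five
minutes on one CPU; the `analysis/` scripts use smaller replicate counts
and finish in about two.

## Known limitations

Beyond the generator's scope above: the weighted median carries a
finite-sample quantile-shift bias of order one ratio-SE under grossly
*one-sided* contamination (its breakdown robustness is an asymptotic,
noise-to-zero statement); MR-Egger requires both strong instruments and
effect-size spread, and its orientation step is itself a small-sample bias
source near $\hat\gamma_j = 0$; the binary power formula is optimistic at
low case fractions with large ORs; and no multi-allelic variants, indels,
VCF input, liftover, MR-PRESSO, mode-based or multivariable estimators are
provided.
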