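---
title: "Methods: two-sample Mendelian randomization in mrkit"
author: "mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The causal model and its assumptions

`mrkit` estimates the causal effect of genetically proxied exposures on
(typically binary) outcomes from two-sample GWAS summary statistics. A
variant $j$ is a valid instrument when it satisfies the three
instrumental-variable conditions: it is associated with the exposure
(*relevance*), shares no unmeasured confounder with the outcome
(*independence*), and affects the outcome only through the exposure
(*exclusion restriction*). Under a linear structural model on the
summary scale, the variant-outcome association decomposes as

$$\Gamma_j = \sum_{k=1}^{K} \theta_k\, \gamma_{jk} + \alpha_j,$$

where $\gamma_{jk}$ is the variant's effect on exposure $k$, $\theta_k$
the causal effect of interest (log odds ratio per exposure unit for
binary outcomes), and $\alpha_j$ a direct (horizontally pleiotropic)
effect that is zero for valid instruments. The estimators differ in what
they assume about the $\alpha_j$:

* **IVW** assumes all $\alpha_j = 0$; it is the efficient weighted
  least-squares fit of $\hat\Gamma_j$ on $\hat\gamma_j$ through the
  origin, with weights $1/\sigma^2_{yj}$.
* **MR-Egger** allows a common directional component: it adds a free
  intercept and relies on the InSIDE assumption (instrument strength
  independent of direct effects). Instruments are re-oriented so every
  $\hat\gamma_j \ge 0$ before fitting, the standard convention that makes
  the intercept interpretable as the average directional pleiotropy per
  exposure-raising allele.
* The **weighted median** is consistent when valid instruments carry at
  least half the total weight $\gamma_j^2/\sigma_{yj}^2$.
* **MVMR** generalizes IVW to a $J \times K$ design, estimating each
  exposure's *direct* effect adjusted for the others — the adjustment
  that distinguishes a genuinely causal exposure from one that merely
  shares instruments with it.
* **MR-BMA** treats the choice of exposure subset as a Bayesian model
  selection problem (next section).

Two-sided p-values use the normal distribution throughout, the summary
data convention.

## Heterogeneity, outliers, and error models

Cochran's $Q = \sum_j w_j(\hat\Gamma_j - \hat\theta\hat\gamma_j)^2$ on
$J-1$ (IVW) or $J-2$ (Egger) degrees of freedom measures residual
heterogeneity. The default error model is multiplicative random effects:
standard errors are inflated by $\max(1, \sqrt{Q/\mathrm{df}})$, which
reduces to the fixed-effect SE in homogeneous data and never deflates
it. The fixed-effect model is available by flag. This conservative
default was chosen because over-dispersion is the rule in practice and
the truncation at 1 protects small-$J$ analyses.

The outlier search mirrors the MR-PRESSO idea: for each instrument the
leave-one-out IVW estimate $\hat\theta_{-j}$ defines a residual
$r_j = \hat\Gamma_j - \hat\theta_{-j}\hat\gamma_j$; the observed weighted
RSS is compared with `n_sim` parametric simulations of
$\hat\Gamma_j^* \sim N(\hat\theta_{-j}\hat\gamma_j, \sigma^2_{yj})$,
giving a global p-value with the add-one correction
$(1 + \#\{RSS^* \ge RSS\})/(n_\mathrm{sim}+1)$ and per-variant exceedance
p-values, Bonferroni-adjusted over $J$. Note the granularity constraint:
a variant can only be flagged at level $\alpha$ if
$J/(n_\mathrm{sim}+1) < \alpha$, so the default `n_sim = 1000` supports
$J \le 50$ at $\alpha = 0.05$. The distortion test of the original
procedure is not implemented — flagged variants are simply removed and
the estimate recomputed, which is how the machinery is used here. The
same simulation-count reasoning applies to the weighted-median bootstrap
(`n_boot = 1000`); both are seeded and reproducible.

## Bayesian model averaging

Effects are standardized by the outcome standard error
($\tilde y_j = \hat\Gamma_j/\sigma_{yj}$,
$\tilde x_{jk} = \hat\gamma_{jk}/\sigma_{yj}$). For an exposure subset
$S$ of size $p_S$, the Zellner g-prior marginal likelihood of the
origin-constrained regression is

$$\mathrm{ML}(S) \propto (1+g)^{-p_S/2}\,\bigl[\tilde y^\top\tilde y -
\tfrac{g}{1+g}\,\tilde y^\top X_S(X_S^\top X_S)^{-1}X_S^\top\tilde
y\bigr]^{-J/2},$$

combined with an independent-inclusion prior
$q^{|S|}(1-q)^{K-|S|}$ and normalized into model posterior probabilities
(PP). Marginal inclusion probabilities (MIP) sum the PP of models
containing an exposure; model-averaged causal effects (MACE) sum
PP-weighted conditional posterior means
$\tfrac{g}{1+g}(X_S^\top X_S)^{-1}X_S^\top \tilde y$. Defaults are
$q = 0.1$ and $g = J$ (unit information), both surfaced in the API and
echoed in results. Enumeration is exhaustive (all $2^K$ subsets), which
is exact and fast at the intended scale ($K = 6$ gives 64 models);
stochastic search is deliberately out of scope.

Two design points deserve emphasis. First, the **empty model is
enumerated** alongside the non-empty subsets. Without it the average MIP
is bounded below by $1/K$ regardless of the data, and no-signal data
cannot push inclusion probabilities below the prior; with it, the
posterior behaves like a genuine BMA posterior, and the implementation's
calibration is verified by a prior-predictive test (drawing causal
status and effects from the model's own prior, mean MIP equals the prior
inclusion probability within Monte-Carlo error). Second, under a *point*
null ($\theta = 0$ fixed), mean MIP is expected to fall **below** the
prior: each model's Bayes factor has expectation one, but MIP is
strictly concave in the Bayes factor, so consistent model selection
drives the average down (about 0.03 against a prior of 0.1 at
$J = 100$, $g = J$). This is a property of Bayesian model selection, not
an implementation artifact, and the test suite records it as such.

Influence diagnostics refit every model whose PP reaches a threshold
(default 0.02) and compute, per instrument, Cook's distance
$d_j = \frac{e_j^2}{p_S s^2}\frac{h_j}{(1-h_j)^2}$ and the squared
standardized residual $q_j = e_j^2$; instruments exceed thresholds at the
median of $F(p_S, J-p_S)$ or the $\chi^2_1$ quantile at $0.05/J$. Fits
whose residual sum of squares is numerically zero (relative to
$10^{-12}\sum \tilde y^2$) are treated as exact, with no influential
points. Flagged instruments can be removed and the averaging re-run
side-by-side for a stability report.

## Instrument selection and harmonization

Selection is significance screening (default $p < 5\times10^{-8}$)
followed by greedy LD clumping: candidates ranked by p-value (ties
broken by chromosome, position, id for determinism) are accepted when
their $r^2$ with every accepted variant is below the threshold (default
0.001) within a 10,000 kb window; different chromosomes are independent
by construction, and variants missing from the LD matrix are assumed
independent with a logged warning (a strict mode drops them instead —
the permissive default suits simulated matrices that cover all loci).

Harmonization orients outcome records onto the exposure's effect allele:
identical pairs are kept, swapped pairs flip the outcome beta,
complementary-strand pairs (A↔T, C↔G) are corrected first. Palindromic
variants carry no strand information in their alleles; they are resolved
by allele-frequency agreement when both frequencies are away from 0.5
(`min(eaf, 1-eaf) <= 0.42` on both sides, the common practice threshold)
and dropped otherwise, always dropped when a frequency is missing.
Variants absent from the outcome are dropped and logged rather than
proxied — proxy lookup requires an external LD reference panel, outside
this package's scope. Every shared variant receives exactly one action
code, making the exclusion audit complete; flip-invariance of all
downstream estimates under allele re-orientation is enforced by property
tests at $10^{-12}$.

## The synthetic-data generator

The generator emulates the package's target study directly on the
summary scale, with no individual-level genotypes. True instrument
effects are drawn with configurable spread and cross-exposure
correlation (either instruments shared by all exposures, or per-exposure
instrument blocks with proportional leakage); observed effects add
normal noise at the analytic standard errors
$\sigma_x \approx 1/\sqrt{n\,2f(1-f)}$ (continuous traits, SD units) and
$\sigma_y \approx 1/\sqrt{n\,c(1-c)\,2f(1-f)}$ (binary traits, log-odds,
case fraction $c$), with allele frequencies uniform on $[0.05, 0.95]$ to
keep those formulas non-degenerate. LD is block-diagonal with constant
within-block $r^2$. Directional pleiotropy is applied **relative to the
exposure-raising allele**: $\alpha_j$ multiplies the sign of the
variant's first-exposure effect. This matches how directional
pleiotropy is defined in the MR literature (and in Egger's intercept,
which is estimated after orienting instruments the same way); applying a
fixed-sign $\alpha$ to sign-symmetric instrument effects would cancel
itself and simulate balanced, not directional, pleiotropy. An InSIDE
violation option correlates $|\alpha_j|$ with instrument strength.

The bundled `study_scale_truth()` scenario uses the magnitudes of the
motivating study: six exposures with instrument counts 121, 4, 7, 22, 4
and 10, exposure GWAS sizes of 472,174 (telomere length) and ~34,450
(methylation clocks), and a binary outcome of 1,493 cases in 301,445
participants. Every simulated variant's true $\gamma$, $\alpha$,
$\Gamma$ and validity flag is recorded in a manifest that estimators
never read. What the generator does **not** model: realistic human LD
maps, winner's curse from discovery-stage selection, sample overlap
between exposure and outcome GWAS, non-collapsibility of the odds ratio,
and indels or multi-allelic variants. Tests passing on this generator
demonstrate the estimators' statistical properties under the stated
model, not robustness to those additional features of real data.

## Validation scenarios and problem sizes

The acceptance checks run the full simulate–select–harmonize–estimate
pipeline at the study scale described above: 2,000 replicates for IVW
type-I error ($J = 100$), 500 for effect recovery and coverage
(60 instruments, true OR 2), 500 for the Egger intercept test size, 300
each for directional-pleiotropy recovery, weighted-median robustness
(40% invalid instruments) and multivariable de-confounding
($\theta = (0.4, 0)$ with effect correlation 0.6), 200 for
model-averaging ranking with $K = 6$, and 40 seeded runs for the outlier
machinery. These sizes give Monte-Carlo standard errors a factor of
several below the tolerance of each check while the whole suite runs in
well under a minute.

## Numerical choices

* Weighted least squares is solved by Cholesky on the normal equations;
  rank deficiency raises a collinearity error naming the offending
  columns (an all-zero exposure column is therefore an error, not a
  silent reduction).
* The LASSO of per-instrument intercepts alternates a soft-threshold
  update $\alpha_j \leftarrow S(r_j,\ \lambda/2w_j)$ with a WLS update
  of the exposure effects, to absolute tolerance $10^{-8}$ or 10,000
  iterations; the penalty grid is 50 log-spaced values from the smallest
  all-zero $\lambda$ down by a factor 1000, and the chosen valid set is
  the largest whose post-selection Q stays below the $\chi^2_{0.95}$
  quantile.
* The weighted-median CDF uses midpoint stacking
  $p_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$ with linear
  interpolation at $1/2$, clamping to the extreme ratios outside the
  covered range.
* Simulated p-values are floored at the smallest normalized double so
  biobank-scale z-scores never underflow to an invalid zero.
* Report tables round ORs and CIs to 4 decimals (half-even), and
  `meta_fixed()` pools on the beta scale with exact inverse-variance
  algebra, so $k$ identical cohorts shrink the SE by exactly
  $\sqrt{k}$.

## Known limitations

Single-variable CIs are Wald-type and therefore log-symmetric around the
OR — the geometric mean of the CI bounds reproduces the OR to rounding,
an identity the package uses to audit reported results. Published
multivariable CIs are not always log-symmetric (robust or differently
rounded constructions exist); `mrkit` reports Wald CIs for MVMR as well
and makes no attempt to reproduce other constructions. Overlapping
exposure/outcome samples, correlated-instrument IVW with an LD-aware
covariance, Steiger directionality filtering, mode-based estimators and
proxy-variant substitution are out of scope.
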