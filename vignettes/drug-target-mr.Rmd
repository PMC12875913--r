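---
title: "Drug-target Mendelian randomization: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem and the model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from two independent GWAS: per-variant associations
with the exposure ($\hat\gamma_j$, with standard error
$\sigma_{\gamma j}$) and with the outcome ($\hat\Gamma_j$,
$\sigma_{\Gamma j}$). Under the instrumental-variable assumptions, each
variant satisfies

$$\Gamma_j = \theta\,\gamma_j + \alpha_j,$$

where $\theta$ is the causal effect and $\alpha_j$ is a direct
(pleiotropic) effect, zero for a valid instrument. Every estimator in this
package is a way of combining the per-variant Wald ratios
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ while being robust to, or
diagnosing, nonzero $\alpha_j$.

The package implements two instrument designs over the same machinery:

* **cis (drug-target) design** — instruments restricted to a flanked gene
  region encoding a drug target. For a glycemic exposure such as HbA1c and
  the glucokinase gene *GCK*, HbA1c-lowering alleles in the region mimic
  lifelong pharmacological activation of glucokinase.
* **genome-wide comparator** — instruments selected across the genome with
  the target region excluded, mimicking exposure lowering by any mechanism.
  An outcome association present under the cis design but absent under the
  comparator suggests the target effect is not solely exposure lowering;
  `compare_designs()` reports exactly that flag and nothing stronger.

## Units and allele orientation

The exposure table is first oriented so the effect allele is the
trait-lowering allele (`orient_to_lowering()`): records with positive beta
have alleles swapped, beta negated, and frequency complemented. During
harmonization the working exposure effect is then re-expressed as
$\gamma_j^{\mathrm{work}} = -\hat\gamma_j > 0$, i.e. the exposure unit
becomes "1 unit (here, 1%) *lower* exposure", while the outcome effect
keeps its sign. Consequently a variant set whose lowering alleles protect
against a binary outcome yields negative $\Gamma_j$, a negative pooled
log-odds estimate, and an odds ratio below 1 — the convention in which
drug-target MR results are usually read. The alternative of negating both
sides would leave Wald ratios expressed per unit *higher* exposure and flip
every reported sign.

## Harmonization rules

For each rsid shared by exposure and outcome, outcome alleles are aligned
to the exposure coding: identical pairs are copied, swapped pairs negate
the outcome beta and complement its frequency, and reverse-strand pairs are
complemented first. Palindromic variants (A/T, C/G) cannot be strand
resolved from the alleles; they are aligned by allele frequency when both
frequencies are available, outside the ambiguity band
$[\ell, 1-\ell]$ (default $\ell = 0.42$, a common operational choice), and
on concordant sides of 0.5 — otherwise dropped with reason
`palindromic-ambiguous`. Variants missing from the outcome are dropped, not
proxied. Indels and non-ACGT records never enter: they are removed at read
time. Each drop is recorded in a per-outcome ledger so that
`pairs + dropped` always reconciles with the instrument count.

## Instrument selection

Selection is a three-stage cascade with the conventional defaults baked
into `analysis_config()` and overridable everywhere:

| parameter | default | meaning |
|---|---|---|
| region flank | 100 kb | bases added both sides of the gene region |
| `p_threshold` | 5e-8 | genome-wide significance, inclusive boundary |
| `clump_window_bases` | 1e7 (10 Mb) | clumping window around the index variant |
| `r2_threshold` | 0.3 cis / 0.001 genome-wide | maximum retained LD |

Clumping is the greedy PLINK-style algorithm: repeatedly retain the
smallest-p unprocessed variant and discard unprocessed variants within the
window whose $r^2$ with it exceeds the threshold. Ties on p-value break by
smaller position, then lexicographic rsid, making the output independent of
input row order. Variants absent from the LD source are dropped with a
warning rather than assumed independent — the conservative reading.
$r^2$ is computed from reference dosages as the squared Pearson
correlation (`compute_ld_from_genotypes()`).

Instrument strength is summarized by the per-variant approximation
$F_j = (\hat\gamma_j/\sigma_{\gamma j})^2$ — the squared GWAS z-score —
and its arithmetic mean. This form needs no variance-explained or
sample-size inputs and matches the magnitude conventionally reported for
strong drug-target instruments; an explained-variance form
$F = (n-2)R^2/(1-R^2)$ is exposed as an option for users who prefer it.

## Estimators

* **Wald ratio** — $\hat\theta_j$ with the first-order delta SE
  $\sigma_{\Gamma j}/|\hat\gamma_j|$. The second-order term
  $\hat\Gamma_j^2\sigma_{\gamma j}^2/\hat\gamma_j^4$ is available behind a
  flag but off by default; with instrument F in the tens to hundreds the
  first-order form is standard. A consequence worth knowing: when the true
  $|\theta|$ is large, the ignored exposure-side variance makes ratios
  over-dispersed relative to their nominal SEs, so Cochran's Q can reject
  even without pleiotropy. The multiplicative random-effects model absorbs
  exactly this kind of extra dispersion into the SE.
* **IVW** — inverse-variance-weighted mean of the ratios. `"fixed"` gives
  $\mathrm{se} = (\sum w_j)^{-1/2}$; `"random"` (default) multiplies it by
  $\max(1, \sqrt{Q/(J-1)})$, the multiplicative random-effects model with
  the dispersion floored at 1, so the random-effects SE never undercuts the
  fixed-effect SE. P-values use a normal reference. The fixed-effect
  estimate is algebraically the no-intercept WLS slope of $\hat\Gamma$ on
  $\hat\gamma$ with weights $1/\sigma_{\Gamma j}^2$; the test suite asserts
  this identity numerically.
* **MR-Egger** — WLS of $\hat\Gamma_j$ on $\hat\gamma_j$ *with* intercept,
  weights $1/\sigma^2_{\Gamma j}$. Under InSIDE (instrument strength
  independent of direct effects) the slope remains consistent for $\theta$
  under directional pleiotropy, and the intercept estimates the average
  direct effect; its t-test with $J-2$ df is the pleiotropy diagnostic.
  SEs are scaled by $\max(1, \sqrt{\mathrm{RSS}_w/(J-2)})$; the unscaled
  covariance is computed from the normal equations directly so an exact fit
  (zero residual) yields finite SEs. Egger requires $J \ge 3$ and
  non-constant $\gamma$.
* **Odds-ratio scale** — for binary outcomes (log-odds $\Gamma$),
  `to_or_scale()` exponentiates the estimate and its 95% CI. CIs use 1.96
  throughout.

## Sensitivity diagnostics

**Cochran's Q** with $J-1$ df tests heterogeneity of the ratios and is the
same Q that drives the random-effects dispersion (the suite asserts
$\mathrm{se}_{RE}/\mathrm{se}_{FE} = \max(1,\sqrt{Q/(J-1)})$).

**MR-PRESSO** follows the simulation logic of the residual-sum-of-squares
outlier test. Observed residuals use leave-one-out fixed-effect IVW slopes
$\theta_{(-j)}$: $ss_j = (\hat\Gamma_j - \theta_{(-j)}\hat\gamma_j)^2$.
Null replicates redraw both sides from
$\Gamma^*_j \sim N(\theta_{(-j)}\hat\gamma_j, \sigma^2_{\Gamma j})$ and
$\gamma^*_j \sim N(\hat\gamma_j, \sigma^2_{\gamma j})$ and are scored by
the same leave-one-out procedure; global and per-instrument p-values are
empirical with the $+1$ correction, so $p \ge 1/(n_{\mathrm{sim}}+1)$,
and outlier flags are Bonferroni-adjusted across instruments. Defaults:
$n_{\mathrm{sim}} = 1000$, minimum 4 instruments (the leave-one-out slope
needs 3 remaining), $\alpha = 0.05$. The distortion test is reported only
when outliers exist: the observed coefficient
$(\theta_{\mathrm{all}} - \theta_{\mathrm{corrected}})/|\theta_{\mathrm{corrected}}|$
is compared against a null built by removing random instrument subsets of
the same size — one of several null constructions in circulation; this one
was chosen for its symmetry with the outlier set and is documented here
because the choice is not forced by the method's description.

Determinism: all replicate draws come from one explicit seed, consumed in
sorted-rsid order, so results are bit-identical across runs and invariant
to instrument permutation.

No across-outcome multiple-testing adjustment is applied anywhere:
$\alpha = 0.05$ is used per outcome, and users testing many outcomes
should adjust externally if they want family-wise control.

## The synthetic-data generator

`simulate_two_sample()` draws the structural model directly on the
summary-statistic scale: MAFs uniform on [0.05, 0.5], true effects
$\gamma_j \sim N(0, 0.045^2)$ (% HbA1c per allele), GWAS standard errors
from the standardized-trait approximation
$\sigma = (2\,\mathrm{maf}(1-\mathrm{maf})\,n)^{-1/2}$ with
$n_{\mathrm{exp}} = 146{,}806$ and $n_{\mathrm{out}} = 211{,}717$ by
default, observed effects normal around truth, and p-values from the
normal reference. These defaults put single-variant F statistics around
50–150 — the strong-instrument regime in which well-powered drug-target
analyses operate. Pleiotropy is controlled by
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$, with an optional
$\gamma$-correlated component for InSIDE violation, and outliers are
implanted by shifting chosen outcome effects by a stated multiple of their
SE. `gamma_dist = "positive"` draws half-normal exposure effects,
emulating data already expressed in the analysis orientation; directional
pleiotropy only has a direction relative to such a shared orientation,
which is why the Egger-versus-IVW separation experiments use it.

`simulate_ld_blocks()` uses a Gaussian factor model — variants in a block
share a latent factor with loading $r_2^{1/4}$ on the latent scale, then a
linear map into [0, 2] dosage space — so realized within-block $r^2$
concentrates at the target and cross-block $r^2$ near zero.

What the generator does **not** emulate: real human LD maps, sample
overlap between the two GWAS, winner's curse from in-sample instrument
selection, case/control asymmetry beyond an effective-sample-size
approximation, and individual-level binary sampling (binary outcomes are
simulated directly on the log-odds scale). Passing calibration tests on
this generator therefore demonstrates the estimators' correctness under
the model they assume, not robustness to those real-data features.

## Numerical and degenerate-input choices

* Input p-values of exactly 0 (underflow in source files) are floored to
  the smallest positive double, with a warning; duplicate rsids keep the
  smallest p.
* `beta = 0` exposure records cannot be oriented and trigger a warning;
  the Wald ratio errors on $\gamma = 0$ and pooled estimators silently use
  only nonzero-$\gamma$ pairs.
* Zero-variance reference genotypes are an error naming the variant.
* An exact Egger fit returns zero residual with finite, positive SEs.
* All tolerance-sensitive identities (IVW/WLS equivalence, Q dispersion
  identity, clumping against a brute-force oracle) are asserted in tests
  at 1e-10 or tighter.

## Problem sizes used by the checks

The test suite and acceptance script run entirely on generated data at
sizes chosen to make Monte-Carlo error small relative to the bands being
checked: null calibration with $J = 17$ over 2000 replicates, recovery at
$\theta = 0.3$, $J = 50$ over 1000 replicates, pleiotropy separation at
$J = 100$ over 500 replicates, outlier recovery at $J = 20$ with
$8\sigma$ implants over 200 replicates with $n_{\mathrm{sim}} = 1000$, and
200 random clumping instances of up to 10 variants against an exhaustive
oracle. The six scripts under `analysis/` run a two-design, four-outcome
synthetic study (40 cis candidates in 20 LD blocks; 60 genome-wide
variants) end to end.

## Known limitations

* First-order Wald SEs understate ratio variance when $|\theta|$ is large
  (see above); the random-effects dispersion compensates in the pooled SE
  but per-variant CIs remain slightly narrow in that regime.
* The Egger intercept test has low power at small $J$; a non-significant
  intercept is not evidence of no pleiotropy.
* Empirical PRESSO p-values are bounded below by $1/(n_{\mathrm{sim}}+1)$;
  raise `n_sim` if very small global p-values need resolving.
* No proxy-variant substitution: instruments missing from an outcome GWAS
  reduce $J$ rather than being rescued from an LD reference.
* No liftover: all tables must share a genome build; the build label is
  carried as metadata and trusted.
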