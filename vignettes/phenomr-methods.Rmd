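---
title: "Phenome-wide two-sample MR screening: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenome-wide two-sample MR screening: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomr)
```

## The model

Two-sample Mendelian randomisation treats genetic variants as instruments
for an exposure. For instrument $j$, let $\gamma_j$ be its effect on the
exposure (SD units) and $\Gamma_j$ its effect on the outcome (log-odds for
a binary outcome such as primary open angle glaucoma). Under the three
instrumental-variable assumptions — the variant is robustly associated
with the exposure, shares no confounder with the outcome, and affects the
outcome only through the exposure — each instrument identifies the causal
effect $\theta$ through $\Gamma_j = \theta\,\gamma_j$, and the Wald ratio
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ estimates it.

Horizontal pleiotropy adds a direct effect:
$\Gamma_j = \theta\,\gamma_j + \alpha_j$. The estimator battery spans the
main violation patterns: the multiplicative random-effects IVW is the
primary estimator and tolerates *balanced* heterogeneity by inflating its
standard error with $\hat\sigma = \sqrt{Q/(J-1)}$ (never below the
fixed-effects SE); MR-Egger adds an intercept that absorbs *directional*
pleiotropy when instrument strength is independent of the direct effects
(InSIDE); the weighted median requires only that a majority of the weight
be on valid instruments; the weighted mode only a plurality. Cochran's
$Q$, the Egger intercept test, $I^2_{GX}$, the mean instrumental $F$
statistic, radial-MR outlier contributions, Steiger directionality
filtering and leave-one-out refits provide the quality control.

A phenome-wide screen multiplies every per-trait fragility by thousands of
traits, so the pipeline is deliberately strict: a trait is reported as
causal only when the FDR-corrected MRE-IVW, all three robust estimators at
nominal level, and every leave-one-out refit agree. Traits passing only
the FDR and leave-one-out arms are labelled `ivw_fdr_only` — candidates,
not calls.

## Pipeline order and the choices behind it

`run_trait()` executes: ladder selection → proxy substitution → clumping →
harmonisation → Steiger filter → radial outlier removal → estimators.
Decisions that were genuinely open:

- **Ladder eligibility is the post-clumping count, strictly greater than
  5.** "More than 5" is read literally as at least 6 independent
  instruments; counting before clumping would let a single LD block
  masquerade as many instruments.
- **Proxies are substituted before the final clump.** A proxy inherits its
  own exposure and outcome rows (it must be present in both datasets), so
  no haplotype phasing across the pair is needed; clumping afterwards
  guarantees the substituted set is still independent. The alternative
  order (clump first) risks admitting a proxy in LD with another retained
  instrument.
- **Per-variant $R^2$ uses the t-statistic identity**
  $r^2_j = t_j^2/(t_j^2 + n - 2)$ rather than $2p(1-p)\beta^2$: it needs
  no trait-variance assumption and is exact for a standardised continuous
  exposure. The $F$ statistic is the product form
  $((N-1-k)/k)\cdot(R^2/(1-R^2))$; the division form sometimes quoted
  yields nonsensical values and is incompatible with the "mean $F > 10$"
  convention.
- **Steiger filtering is strict**: removed only when the outcome p-value
  is strictly smaller than the exposure p-value; ties are kept.
- **Radial outliers are removed greedily, one at a time**, refitting the
  radial IVW after each removal. A single gross outlier drags a one-pass
  radial fit far enough to implicate a large share of clean variants;
  greedy removal keeps the false-flag rate at the nominal per-variant
  level while still catching planted outliers. The default flagging level
  is 0.05 per variant with a Bonferroni option (`radial_bonferroni`),
  which the screen's acceptance experiments use.
- **BH denominator is the number of traits entering the screen**, not the
  number with successful fits: a failed trait consumes no p-value but
  still counts, matching correction for the full screen size.
- **Leave-one-out is interpreted strictly**: every omission must stay
  nominally significant for the `loo_all_nominal` flag.
- **Duplicate traits** resolve by largest sample size, then (same
  population, tied $n$) largest mean $F$, then largest case count for
  binary traits, then identifier — fully deterministic.
- **Single-instrument traits** fall back to a labelled Wald ratio and are
  ineligible for the significance call, which requires Egger, median and
  mode.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| ladder | 5e-8 × 10 → 5e-4 | instrument p-value thresholds |
| `min_count` | 5 (exceed strictly) | independent instruments required |
| `clump_r2`, `clump_window_kb` | 0.001, 10,000 | clumping independence |
| `proxy_min_r2` | 0.9 | minimum LD for proxy substitution |
| `palindrome_maf_max` | 0.42 | palindromic ambiguity ceiling |
| `nominal_alpha`, `fdr_alpha` | 0.05, 0.05 | significance arms |
| `radial_alpha` | 0.05 (Bonferroni option) | outlier flagging |
| `n_boot` | 1000 | median/mode bootstrap replicates |
| `bandwidth_factor` | 1 | weighted-mode bandwidth multiplier |
| `rho` (MVMR) | 0.1 and 0.9 | assumed exposure-sample correlation |
| burden `maf_max`, `revel_min` | 0.001, 0.25 (strict) | qualifying variants |

The weighted-mode bandwidth is
$h = \text{factor} \times 1.4826\,\mathrm{med}_{i<j}|\beta_i-\beta_j| / \sqrt2$,
a scale estimate consistent for the normal SD built from the median
absolute pairwise deviation of the ratios; it degrades gracefully to
`mad()` and then to a small positive floor when ratios coincide.

## The synthetic generator

`simulate_trait_pair()` works directly on the summary-statistic scale:
MAF $\sim U(0.05, 0.5)$; per-variant standard errors
$(2\,\mathrm{maf}(1-\mathrm{maf})\,n)^{-1/2}$; true exposure effects
scaled so the instrument set explains `r2_exposure` (default 5%) of
exposure variance; outcome effects $\theta\gamma_j$ plus pleiotropy on the
configured fraction of invalid instruments; sampling noise on both sides;
LD laid out in explicit blocks (within-block $r^2 \sim U(0.2, 1)$ listed
pair by pair, between-block exactly 0, blocks 20 Mb apart) so clumping
ground truth is enumerable; a configurable fraction of palindromic allele
pairs; and random outcome recoding (allele swap with sign flip and
frequency complement, strand complement, or both) to exercise
harmonisation. Defaults describe one exposure screened against a large
binary-outcome meta-analysis: $n_{\text{exposure}} = 10^5$,
$n_{\text{outcome}} = 216{,}257$ (16,677 cases + 199,580 controls),
20% palindromic variants, 30% recoded outcome rows, pleiotropy scale
$\sigma_\alpha = 0.05$ on the log-odds scale — the magnitude of a typical
genuine SNV effect on a binary trait.

Two modelling choices deserve emphasis. First, instrument effect
magnitudes are drawn bounded away from zero
($|\gamma| \propto 0.5 + |N(0,1)|$): the generator emulates instruments —
variants robustly associated with the exposure — and near-null effects
that no selection threshold would admit produce sign-misorientation
artefacts in MR-Egger that real instrument panels do not exhibit. Second,
pleiotropic effects act on the *exposure-increasing allele*
($\Gamma = \theta\gamma + \mathrm{sign}(\gamma)\,\alpha$): this is the
frame the Egger intercept is defined in; a frame-free $\alpha$ would have
its "directional" mean scrambled to zero by Egger's orientation step.

What the generator does **not** emulate: realistic LD from a reference
panel (blocks are synthetic and exactly disjoint), winner's curse from
discovery selection, sample overlap between exposure and outcome beyond
cohort labels, indels or multi-allelic variants, and case/control
imbalance effects on outcome standard errors (the binary outcome is
modelled on the summary log-odds scale with the continuous-trait SE law,
as a two-sample MR consumes it). Passing tests therefore certify the
statistics and the plumbing, not robustness to those real-data phenomena.

`simulate_phenome()` derives per-trait seeds as
`(base_seed * 1000003 + 7919 * index) mod 2147483629`, so any trait is
regenerable in isolation and screen output is order-independent.

## Numerical choices

P-values are floored at the smallest positive double so extreme signals
never underflow to an invariant-violating zero. IVW p-values are normal;
Egger p-values use $t_{J-2}$. The Egger design is solved in closed form;
a rank-deficient design (all oriented $\gamma$ equal) returns a degenerate
fit with missing estimates, a missing $I^2_{GX}$ and the NOME warning
raised. The median/mode bootstrap redraws each ratio from
$N(\hat\beta_j, se_j)$ with fixed weights; mode replicates are evaluated
by the same linear-binning + FFT Gaussian-smoothing algorithm
`stats::density()` uses, batched across replicates on a shared 512-point
grid. Radial fits iterate the modified second-order weights to $10^{-8}$
(cap 100 iterations, warning on non-convergence). Clumping breaks p-value
ties by identifier; proxy ties break by r², then base-pair distance, then
identifier. All simulation and bootstrap RNG runs on local streams that
restore the caller's `.Random.seed`.

## Known limitations

- **Finite instrument strength dilutes IVW.** With noisy exposure effects
  the IVW slope estimates
  $\theta\,\bar F/(\bar F + 1)$ where
  $\bar F \approx r^2 n_{\text{exposure}}/J$ — about a 1% shrinkage at the
  default $\bar F = 100$, and the reason the "mean $F > 10$" convention
  (up to ~10% shrinkage) matters. The same mechanism leaves 95% CI
  coverage a little below nominal at strong $\theta$, since the IVW SE
  conditions on the observed exposure effects (the NOME assumption). The
  acceptance script reports the realised mean estimate at
  $\theta = \ln 2$.
- **Bootstrap intervals see sampling noise only.** Under heavy balanced
  contamination (e.g. 40% invalid instruments), which instruments are
  invalid in a given panel is itself a random draw; the weighted median's
  parametric bootstrap conditions on the observed panel and cannot see
  that component, so its across-panel coverage sits below nominal even
  though the estimate remains centred on $\theta$.
- **The discrete burden test is conservative** (exact hypergeometric
  p-values), and its odds ratio uses the Haldane correction only when a
  zero cell would make the cross-product undefined, with a flag.
- **The conditional-F and adjusted-Q forms** follow the heterogeneity-based
  multivariable-MR methodology with the phenotypic-correlation term
  $\rho\,se_{jk}se_{jk'}$ supplied by assumption (0.1 and 0.9 as the
  conventional sensitivity pair); $\rho$ should be 0 for non-overlapping
  cohorts.

## Problem sizes used in the test suite

The simulation experiments shipped with the package use: 1,000 null
traits at $J = 30$ for type-I calibration; 500 replicates at $J = 50$,
$n = 10^5$ for recovery and robust-estimator behaviour; 20 replicates of a
200-trait synthetic phenome (10 causal at $\theta = \ln 2$) with 300
bootstrap replicates per trait for the end-to-end screen; 1,000 recoded
SNVs for the harmonisation round trip; and 200 planted-outlier replicates
for radial MR. These sizes keep Monte-Carlo error well inside the margins
being tested while the whole suite runs in minutes on one CPU.
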