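---
title: "Methods: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cryomethyl quantifies how long-term cryopreservation of extracted DNA
biases CpG methylation measurements. This vignette records the statistical
models the package implements, the design of its synthetic-data generator,
and the numerical conventions chosen where more than one reasonable option
existed.

## The scientific problem

Spontaneous hydrolytic deamination slowly converts 5-methylcytosine so
that, after bisulfite or enzymatic conversion, an originally methylated
CpG reads as unmethylated. Over storage times of a few years this produces
a small but directional *hypomethylation* bias in archived DNA: invisible
when methylation is averaged genome-wide, but detectable as an excess of
CpGs whose methylation declines with storage duration. The pipeline tests
both levels:

1. **Global**: per-sample mean methylation (M scale) regressed robustly on
   storage duration as DNA, with and without covariates (age, storage as
   buffy coat, six blood cell-type proportions), compared by AIC/BIC.
2. **Per-CpG**: gene-wise linear models of methylation on storage
   duration, empirical-Bayes moderated t-statistics, Storey q-values,
   directional counts (hypo vs hyper), and a permutation null.
3. **Replication and genomic distribution**: discovery hits (q < 0.05)
   re-tested in a validation cohort (p < 0.05, same direction), and the
   replicated list tested for enrichment by relation-to-island category
   with exact conditional inference.

## Measurement scales

Beta values (proportion methylated, in [0,1]) are transformed to
M values, `M = log2(b / (1 - b))`, for linear modelling; M values are
closer to homoscedastic and unbounded. Betas are clipped into
`[epsilon, 1 - epsilon]` first, with `epsilon = 1e-6` by default: the
clip keeps M finite for fully (un)methylated CpGs while distorting a beta
of 0.999 999 by nothing measurable. Every analysis also runs directly on
the beta scale (`scale = "beta"`), which preserves the directional
conclusions; only effect-size units change.

## Robust global model

`huber_irls()` fits a Huber M-estimator by iteratively reweighted least
squares: tuning constant `k_tune = 1.345` (95% Gaussian efficiency),
scale re-estimated each iteration as 1.4826 times the median absolute
residual, convergence when the largest coefficient change falls below
`1e-8`, at most 200 iterations. Numerical conventions:

* **Zero-residual fits**: the scale is floored at `1e-10` so exact fits
  do not divide by zero.
* **Near-collinearity**: the six estimated cell proportions sum to
  roughly (not exactly) 1, so the full design with an intercept is nearly
  but not exactly collinear. The design is fit as-is; only if it is
  numerically singular (condition number above 1e10 — e.g. when *true*
  simplex proportions are supplied) is the last dependent column dropped,
  with a warning.
* **Inference**: Wald intervals and normal-approximation p-values from
  the standard asymptotic covariance of the Huber estimator.
* **AIC/BIC for a robust fit** have no canonical definition. The package
  evaluates the Gaussian log-likelihood at the robust coefficients and
  robust scale and applies the usual penalties, counting the scale as a
  parameter: `AIC = -2l + 2(k+1)`, `BIC = -2l + (k+1) log n`. This is a
  documented convention — monotone in the residual sum of squares and
  adequate for comparing nested designs on the same data, which is its
  only use here.

## Per-CpG models and moderation

Each CpG is fit by least squares on its own non-missing samples
(complete-case per CpG), so residual degrees of freedom `d_g = n_g - k`
vary across CpGs; CpGs with `d_g < 1` are flagged and excluded from
testing. Variance moderation follows the classical empirical-Bayes
scaled-F model: the prior degrees of freedom `d0` and prior variance
`s0^2` are estimated by matching the mean and variance of `log s_g^2`
via the digamma/trigamma moment equations (trigamma inverted by Newton
iteration), each CpG contributing its own `d_g`. The posterior variance
`(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` yields the moderated t on
`d0 + d_g` degrees of freedom. Degenerate cases: if the observed
log-variances are *less* dispersed than chance, `d0 = Inf` and all
posterior variances equal the mean sample variance. An unmoderated mode
(`moderation = FALSE`) reproduces the ordinary regression t-test and is
used for oracle comparisons.

Storey q-values are computed with `pi0(lambda) = #[p > lambda] /
(m (1 - lambda))` over `lambda = 0.05, ..., 0.95`, smoothed by a cubic
smoothing spline with 3 degrees of freedom, evaluated at `lambda = 0.95`,
and clipped into (0, 1]; with fewer than twice as many p-values as grid
points the estimate is unstable and `pi0 = 1` (the Benjamini–Hochberg
special case) is used. Monotonization assigns tied p-values the shared
(larger-rank) q-value. Forcing `pi0 = 1` makes the q-values identical to
`p.adjust(p, "BH")`, which the tests exploit as an oracle.

The permutation null reassigns storage duration as DNA across samples
(one permutation by default, matching the design it emulates; `n_perm`
generalizes it) while every other covariate stays attached to its sample,
then reruns the whole per-CpG pipeline.

## Exact contingency inference

`fisher_exact()` implements the conditional exact test: two-sided p-value
by the point-probability criterion (summing hypergeometric probabilities
no larger than the observed one, with a `1e-7` relative tolerance for
floating-point ties), odds ratio by conditional maximum likelihood (the
root of `E[a | margins, OR] = a_obs`, solved on the log scale to
`1e-10`), and the 95% interval by inverting the two one-sided exact
tests. Probabilities use log-gamma arithmetic and the support is bounded
by the smallest margin, so tables with hundreds of thousands of
observations remain exact and fast. At the support edges the odds ratio
is reported as 0 or infinity rather than an error.

## The synthetic-data generator

Because the motivating cohort data are not public, the generator is a
first-class module that emulates the study conditions: a discovery-like
cohort (n = 126, storage 2.79–4.17 years as DNA, 1–77 days as buffy
coat, ages 38–72) and a validation-like cohort (n = 136, storage
1.25–3.17 years, no buffy-coat stage). Its components:

* **Decay law.** Deamination is a spontaneous first-order reaction, so
  the methylated fraction decays as `exp(-r t)`; the unmethylated
  fraction is unaffected (a deaminated unmethylated cytosine still reads
  unmethylated). Expected beta is `exp(-r t_i) * sum_k w_ik B_gk` for
  cell-type weights `w` and baseline profiles `B`.
* **Deamination rate.** No measured value exists for frozen extracted
  DNA at these timescales; the default `r = 7e-4`/year was calibrated
  once so that roughly 0.5% of CpGs reach q < 0.05 at n = 126 under the
  default noise level — the regime of a just-detectable storage effect
  that the pipeline exists to flag.
* **Noise.** Homoscedastic Gaussian noise on the M scale
  (`noise_sd_m = 0.25` by default, a typical array-replicate dispersion),
  applied after the decay and back-transformed, keeping betas in (0,1).
* **Baseline methylation by island relation.** Island CpGs are drawn
  mostly unmethylated (Beta(0.5, 8)); shore CpGs are switch-like bimodal,
  half fully methylated (Beta(40, 1.2)) and half unmethylated
  (Beta(0.8, 10)), reflecting sharp methylation boundaries at island
  edges; shelf and open-sea CpGs are highly but *partially* methylated
  (Beta(12, 2.5) and Beta(20, 4)): imperfect maintenance in bulk tissue
  keeps measured beta near 0.8–0.9 rather than at 1. This last point is
  load-bearing. Detection power for a uniform decay rate rises steeply
  with baseline beta (on the M scale the yearly effect scales as
  `1/(1 - b)`), so whichever category holds the most nearly-fully
  methylated CpGs dominates the significant list. With the fully
  methylated shore mode and saturating-but-partial open sea, the
  simulated pipeline mechanistically reproduces the empirical genomic
  gradient — shores enriched among replicated hypomethylated CpGs,
  islands depleted — from baseline methylation alone, with no
  category-specific decay rates. An earlier candidate design with
  unimodal intermediate shores (Beta(2, 2)) and a heavy-tailed open sea
  (Beta(8, 1.5)) provably cannot produce shore enrichment under a uniform
  rate, and the package does not use it.
* **Cell mixtures.** Six leukocyte proportions drawn from a Dirichlet
  concentrated on granulocytes (expected Gran ≈ 0.59, total
  concentration 50, typical of adult blood). Cell types differ at a
  configurable 2% of CpGs by a beta-scale separation of 0.4, mimicking
  the discriminating marker CpGs that reference-based deconvolution
  relies on; the generator emits the matching reference matrix.
  Deconvolution solves non-negative least squares per sample (no
  sum-to-one constraint, so all six terms plus an intercept remain
  meaningful in the full design).
* **Reproducibility.** One seed per `generate_dataset()` call;
  reference, sample-level, and noise draws use deterministically derived
  sub-seeds, so outputs are byte-identical across runs.

What the generator does **not** emulate: array chemistry (two probe
designs, dye bias), batch and plate effects, SNP-affected probes,
cross-reactivity, age- or disease-associated methylation drift, and
correlated (regional) noise. Tests passing on synthetic data therefore
demonstrate that the statistical machinery is correct and calibrated
under the stated model, not that real archived cohorts are free of those
artifacts; on real data the normalization and probe-QC steps upstream of
this package carry that burden.

## Problem sizes

The test suite and acceptance script keep simulations at sizes that make
the checked properties stable without waste: null calibration at 5,000
CpGs x 126 samples over multiple seeds; directional-bias checks at
10,000 CpGs; the two-cohort replication/enrichment run at 40,000 CpGs
per cohort (enough for tens of replicated CpGs and stable per-category
odds ratios); deconvolution recovery at 5,000 CpGs x 100 samples.
Exhaustive Fisher enumeration covers every 2x2 table with row margins up
to 30.

## Known limitations

* The exponential decay law is an assumption (first-order kinetics); the
  data it emulates cannot distinguish it from other slowly varying
  monotone laws over a 1–4 year window.
* AIC/BIC for robust fits are a convention (above); absolute values are
  not comparable across packages, only differences within a run.
* The permutation null uses a single permutation by default, which
  checks for gross miscalibration but has no resolution below the
  per-run discovery count; use `n_perm` for calibration studies.
* Detection-p filtering uses the strict "greater than threshold in any
  sample" rule; with many samples this is aggressive, and ties at the
  threshold are deliberately kept.
* Reference-based deconvolution is only as good as the supplied
  reference; the package bundles no human reference profiles.
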