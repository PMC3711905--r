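---
title: "Multi-class probabilistic classification of regional brain morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-class probabilistic classification of regional brain morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroprobit)
```

## The problem this package addresses

Progressive supranuclear palsy (PSP), multiple system atrophy (MSA, with
parkinsonian MSA-P and cerebellar MSA-C variants) and idiopathic Parkinson's
disease (IPD) can be clinically indistinguishable, yet differ in prognosis
and treatment response. Structural MRI shows disease-specific patterns of
subcortical atrophy — PSP affecting midbrain/brainstem and basal ganglia,
MSA the pontocerebellar system and putamen, IPD the midbrain only and
subtly — which makes region-masked morphometric maps natural inputs for a
classifier that assigns a *single patient* to one of several diagnostic
classes, with a probability attached to each.

`neuroprobit` implements that pipeline end to end: a multi-class
probabilistic kernel classifier over voxelwise two-channel (grey/white)
morphometric features, masked to a subcortical motor network (bilateral
cerebellum, brainstem, caudate, putamen, pallidum, accumbens), a single
region, or the whole brain; leave-one-out cross-validation (LOO-CV) with
all preprocessing embedded in the loop; balanced multi-class metrics;
Monte Carlo permutation significance; and voxel weight maps that localize
the discriminative anatomy per class. Because patient MRI data of this kind
are not freely available, the package ships a synthetic cohort generator so
that every stage is testable, end to end, against data with known structure.

## The classifier

Subjects are represented by rows of a feature matrix: both tissue channels
vectorized over the mask and concatenated, then compared through a linear
kernel $K_{ij} = \langle x_i, x_j \rangle$ (divided by the mean training
self-similarity so that sampler step sizes do not depend on mask size).

The model is a multinomial probit with one independent latent function per
class. For $m$ classes, latent vectors $f_c \sim \mathcal N(0,\; s\,(K +
\epsilon I))$ are drawn per class over the $n$ training subjects, and the
observed label of subject $i$ is

$$y_i \;=\; \arg\max_c \left( f_c(x_i) + \varepsilon_{ic} \right),
\qquad \varepsilon_{ic} \sim \mathcal N(0, 1).$$

Inference is auxiliary-variable Gibbs sampling in the style of Albert–Chib:
conditional on the latents, the auxiliary scores $g_{ic} = f_c(x_i) +
\varepsilon_{ic}$ are one-sided truncated normals constrained so the
observed class attains the maximum; conditional on the auxiliaries, each
$f_c$ has a closed-form Gaussian conditional with posterior-mean operator
$C(C+I)^{-1}$ and covariance $C - C(C+I)^{-1}C$, where $C = s(K+\epsilon
I)$. Both operators are precomputed once per fit; the sweep itself is
implemented in C++ and driven by R's RNG so `set.seed()` fixes the entire
draw sequence.

For a test subject with cross-kernel row $k_*$ the latent conditional mean
per draw is $k_*(K+\epsilon I)^{-1} f_c$ with a shared conditional variance
$v$; combining analytically with the probit noise, the probability that
class $c$ attains the argmax is a one-dimensional integral evaluated by
Gauss–Hermite quadrature and averaged over post-burn-in draws. Rows of the
resulting probability matrix are normalised to sum to one.

Design choices made where the design was genuinely open:

* **$m$ independent latent functions** (symmetric parameterization) rather
  than $m-1$ contrasts. The weight maps depend on this: each class owns a
  latent function, hence its own map.
* **Fixed hyperparameters**: the prior scale $s$ (default 1 on the
  trace-normalized kernel) and jitter ($10^{-6}\times$ mean kernel
  diagonal) are not sampled. This keeps the LOO-times-permutation loops
  tractable and is a deliberate divergence from a fully Bayesian treatment.
* **Defaults** `n_burnin = 500`, `n_samples = 2000` for reported runs;
  tests use smaller chains where only coarse functionals (argmax labels,
  calibration) are needed.
* **Tie-breaking** in hard assignment goes to the lowest class index, with
  a warning; exact ties essentially only occur for degenerate inputs such
  as an all-zero cross-kernel.

The binary ($m = 2$) case collapses to probit classification on the latent
difference, for which the predictive probability can be computed by direct
numerical quadrature over the latent-difference posterior at small $n$.
The test suite uses that quadrature as an independent oracle and requires
agreement within 0.02 at 2000 draws; observed agreement is typically
an order of magnitude tighter.

## Cross-validation and leakage control

Generalization is estimated by leave-one-out cross-validation. The contract
that matters is that *no statistic crosses the train/test boundary*: the
fold preprocessor (per-feature centering on the training mean; optional
variance scaling, off by default) is re-estimated within every fold, the
kernel normalisation constant comes from the training rows only, and the
held-out subject enters solely through its cross-kernel row. The original
analytic pipeline embedded template construction and registration inside
the loop; those image-level steps are outside this package's scope, and
fold-local centering is the preserved stand-in for the independence
contract. A smoke test verifies the contract behaviourally: a feature
column that encodes the label drives LOO accuracy to ceiling, while the
same column shuffled restores chance.

Because the fold kernels depend on features only — never on labels — the
permutation test precomputes them once and replays label permutations over
them. This is exactly equivalent to rerunning the embedded-preprocessing
loop per permutation and makes the calibration simulations affordable.

## Metrics and significance

With rows as true classes and columns as predictions, sensitivity of class
$i$ is $C_{ii}/\sum_j C_{ij}$ and predictive value is $C_{ii}/\sum_j
C_{ji}$ (defined as 0, with a warning, for a class never predicted, so a
degenerate classifier is penalised rather than excused). Balanced accuracy
and overall predictive value are the *unweighted* class means, making them
invariant to duplicating all members of a class — a property the tests
assert exactly. Aggregate chance is $1/m$ (33%, 25%, 20% for the three-,
four- and five-class contrasts); per-class chance bars use training-set
class proportions. Both definitions are exposed separately rather than
merged.

Significance uses Monte Carlo label permutation with the add-one estimator
$p = (1 + \#\{\text{permuted} \ge \text{observed}\})/(1 + N)$, $N = 999$ by
default. The add-one form cannot return $p = 0$ and is conservative under
ties, which is relevant because balanced accuracy is discrete at small $n$:
the type-I calibration simulation therefore tracks a continuous functional
of the same pipeline (mean predicted probability of the true class), for
which the empirical rejection rate at $\alpha = 0.05$ is nominal.

A Beta Monte Carlo interval for the balanced accuracy is provided
(`balanced_accuracy_interval()`): per-class Beta($C_{ii}+1$,
$n_i-C_{ii}+1$) posteriors, averaged draws, central quantiles. It is a
descriptive companion, deliberately not validated against any published
interval construction, and is reported as such.

## Weight maps

For a linear kernel the fitted dual form maps back to voxel space: with
posterior-mean latents $\bar f_c$, dual coefficients $\alpha_c =
(K+\epsilon I)^{-1}\bar f_c$ give the primal weights $w_c = X^\top
\alpha_c$ (divided by the kernel normalisation). Averaging the latents
first and solving once is cheaper than solving per draw and equal in
expectation; it is the implemented route. Maps are exported unthresholded,
in raw and per-class unit-norm variants, one NIfTI per class per channel.
Note the maps inherit Monte Carlo noise from the draws: permuting the
training order perturbs them at the sampling-noise level, not identically
to zero.

## What the synthetic generator emulates — and what it does not

The generator produces two-channel 3-D volumes on a small grid (default
$32^3$; tests use $16^3$) with six disjoint spheres standing in for the
bilateral network regions inside a spherical background compartment. Each
subject of class $c$ receives baseline $-$ `effect_matrix[c, r]` $\times$
noise SD inside region $r$ on both channels, plus per-channel white
Gaussian noise smoothed with a FWHM-2-voxel kernel (rescaled so the
planted effects stay in units of the *post-smoothing* voxel SD), all
multiplied by a subject-level factor $1 + \mathcal N(0, 0.05)$ emulating
global intensity/volume nuisance. Atrophy is encoded as a negative shift
on both channels — the sign convention is internal.

The default cohort matches the study structure this pipeline is designed
for: 19 controls, 17 PSP, 14 IPD, 12 MSA-P, 7 MSA-C. The default effect
matrix mirrors the qualitative disease pattern: PSP loads on all six
regions (brainstem strongest), IPD on the brainstem only at half
magnitude, MSA-P on cerebellum/brainstem/putamen, MSA-C strongest
pontocerebellar involvement, controls null. No per-region effect sizes
were published for the real cohort, so the magnitudes (1–3.5 SD) are a
modelling choice fixed once: large enough that the disease contrasts are
mostly separable at desk scale, with IPD deliberately the hardest class,
matching its clinical profile.

What the generator does **not** emulate: realistic brain geometry,
registration and template construction, partial-volume and bias-field
artifacts, inter-regional covariance of atrophy, site/scanner effects.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated — they do not certify any accuracy level on real
patient data.

## Numerical choices and degenerate inputs

* Truncated-normal draws use inverse-CDF sampling in the relevant tail,
  accurate far from the mean; a guard returns the bound when the remaining
  mass underflows.
* The posterior covariance is symmetrized and given a $10^{-10}$ relative
  ridge before Cholesky.
* Kernels are checked for positive semi-definiteness (eigenvalues above
  $-10^{-8}\times$ trace) at fit time; the check can be disabled inside
  resampling loops after validating once.
* Gauss–Hermite nodes (20 by default) are cached per process.
* A class with a single member is refused before any LOO computation; a
  test point with zero cross-kernel reverts to the uniform prior $1/m$
  exactly.
* Convolution at volume edges is zero-padded, so edge voxels have slightly
  lower noise variance; planted regions sit in the interior.

## Problem sizes used in the shipped simulations

The test suite and the acceptance script run, by choice, at desk scale:
$16^3$ grids, cohorts of 12–24 subjects for calibration and recovery
suites (200 calibration repetitions at 99 permutations each), 40–3000
posterior draws depending on whether a hard label or a tight probability
is needed, and the full 69-subject default design only for structural
checks. The same code paths scale to the default $32^3$ grid and
2000-draw chains unchanged.

## Known limitations

* Kernel hyperparameters are fixed, not learned; badly scaled inputs are
  the user's responsibility (trace normalisation mitigates but does not
  remove this).
* LOO-CV estimates have high variance at these cohort sizes; the
  permutation machinery quantifies significance, not stability.
* The Beta interval for balanced accuracy ignores between-class
  correlation of errors.
* Weight maps are descriptive: unthresholded, no multiple-comparison
  control, and only defined for the linear kernel.
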