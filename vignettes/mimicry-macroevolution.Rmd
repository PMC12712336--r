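---
title: "Methods: mimicry-accuracy scoring and macroevolutionary model fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mimicry-accuracy scoring and macroevolutionary model fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myrmimic)
```

This vignette is the package's own account of its methods: the models
and their assumptions, the defaults and why they were chosen, the
numerical decisions, and what the synthetic-data generator does and
does not establish. It states no empirical result that the test suite
or the acceptance script does not itself compute.

## 1. The mimicry-accuracy index

Each of the eight morphometric traits is a ratio of two linear
measurements mapped to [0, 1] so that 0 means "ordinary spider" and 1
means "extreme ant-like modification": elongations are `1 −
width/length`, constrictions are `1 − dimension at constriction /
dimension at the widest (highest) point`, thin legs is `1 − femur-III
width/length`, and pedicel elongation is `pedicel length / (cephalothorax
+ abdomen + pedicel length)`. The ninth trait, illusion by coloration,
counts three binary colour traits and is scored on the rounded levels
0, 0.334, 0.667, 1.0 — the rounded thirds are used deliberately, so
that printed score tables reproduce exactly. Overall accuracy is the
arithmetic mean of the nine.

Conventions the implementation commits to:

- **Clamping.** Raw ratios can leave [0, 1] (an abdomen wider than
  long); they are clamped. Overall accuracy is computed from the
  clamped scores: published per-trait minima are all ≥ 0, which is only
  consistent with clamping before averaging.
- **No constriction.** A constriction measurement equal to the
  reference dimension encodes "no constriction" (ratio 1, score 0);
  absent constriction fields score 0 rather than propagating
  missingness, since non-expression is the typical state in one of the
  two focal clades. Missing *non*-constriction measurements make a
  specimen unscorable by default.
- **Categories.** Nonmimic < 0.15, accurate ≥ 0.30; inaccurate mimics
  are split at 0.20 into low/moderate sub-bins. Because the sub-bins
  are conventionally printed as "0.15–0.19" and "0.20–0.29", the
  low/moderate boundary is applied to the score rounded (half-up) to
  two decimals; the 0.15 and 0.30 boundaries are applied to the exact
  score.
- **Constriction prevalence.** Whether a specimen "has a constriction"
  can mean any-of-four or per-region; `cohort_summary()` reports both
  (`n_constricted_any`, `n_constricted_by_region`) rather than
  guessing.
- A zero pedicel length is legal (a spider may lack any visible
  pedicel extension); all other measurements must be positive.

## 2. Gaussian trait-evolution models

Trees are `ape` `phylo` objects with branch lengths in Ma. All four
Gaussian models are exact multivariate-normal densities over the tips,
evaluated by Cholesky factorization (no explicit inverses):

- **BM**: covariance `σ² s_ij` with `s_ij` the shared root-to-tip path
  length; mean `z0`.
- **OU** (fixed root, single optimum): covariance
  `σ²/(2α) e^{−α(t_i + t_j − 2 s_ij)} (1 − e^{−2α s_ij})`. The optimum
  θ is identified with the root state `z0`, so k = 3. This is the
  common fixed-root fit for ultrametric trees; a stationary-root OU
  would add a parameter the data rarely separate from θ.
- **EB**: BM on the time axis warped by `(e^{a t} − 1)/a`, `a ≤ 0`;
  `a = 0` reduces exactly to BM.
- **WN**: iid normal tips, the phylogeny-free null.

**Fitting.** σ² and the mean are profiled out analytically (GLS), so OU
and EB fitting is one-dimensional. Instead of random multi-starts we
use a deterministic 25-point bounded scan (log-spaced for α) followed
by golden-section refinement — reproducible by construction and immune
to start-point luck in one dimension. Bounds: σ² ∈ [1e−8, 1e3],
α ∈ [1e−8, 1e3/H], a ∈ [−10/H, 0] with H the tree height; estimates at
a bound are flagged, constant data warn and pin σ² at its lower bound.
AICc uses n = number of tips. Measurement error is not modelled.

`expm1()` forms are used throughout so the OU α → 0 and EB a → 0 limits
are numerically exact; the test suite checks both limits and checks
every likelihood against an independently coded dense-MVN oracle on
small trees.

## 3. The bounded (FPK) diffusion and its landscape

The trait lives on a bounded interval, mapped affinely to a normalized
axis z ∈ [−1.5, 1.5] on which the evolutionary potential is the quartic
`V(z) = a z⁴ + b z² + c z`; `exp(−V)`, normalized, is the stationary
density and is read as the adaptive landscape. Normalizing the axis
keeps (a, b, c) comparable across traits with different ranges.

- **Bounds.** Default: observed trait range expanded by 50% on each
  side. The expansion keeps boundary effects away from the data while
  leaving the landscape identifiable; it is a documented default, not
  an estimate.
- **Grid.** N = 50 points by default (the customary resolution for
  this model family), exposed in every entry point.
- **Generator.** Nearest-neighbour rates
  `(σ_z²/2h²) exp((V_i − V_j)/2)` give a tridiagonal generator whose
  columns sum to zero and which satisfies detailed balance with
  `exp(−V)` — the stationary density is exact at any N. σ² is
  expressed on the original trait scale and converted internally, so
  it is directly comparable with the Gaussian-model rates.
- **Likelihood.** Felsenstein pruning with branch propagation via the
  matrix exponential, computed from the eigendecomposition of the
  symmetrized generator (exactly symmetric by construction, so one
  `eigen(symmetric = TRUE)` per likelihood evaluation). Tip masses are
  split linearly between the two flanking grid cells — first-order
  exact in the tip position; with nearest-cell rounding the grid
  sensitivity of the log-likelihood is an order of magnitude larger.
  Cell masses are converted to densities (− n log h) so FPK and
  Gaussian log-likelihoods are on the same scale.
- **Root.** Three options: integrate against the stationary density
  (default), profile ("ml"), or a flat measure. The default follows
  the established convention for this model family. Note a genuine
  tension: the "flat potential + very wide bounds tends to BM" limit
  holds for the *profile* root, because the fixed-root BM density is
  itself a profile quantity — integrating the root over an arbitrarily
  wide uniform prior subtracts log(width). The test suite verifies the
  BM limit under the profile root and conservation/stationarity under
  the default.
- **AICc.** k = 5 (a, b, c, σ², root measure), a convention that makes
  FPK comparable with BM/OU/EB in one weight table.
- **Multimodality** is permitted (a < 0 double wells) and flagged from
  the sign pattern of the discrete density differences.

**A caution on reading fitted landscapes.** Maximum likelihood gives
the quartic three shape parameters that are cheap in likelihood terms:
on data simulated under plain BM, fitted landscapes typically retain
curvature worth ~1–2.5 log-likelihood units, i.e. density max/min
ratios well above 2 even over the data-supported range. A fitted
landscape should therefore be interpreted together with the AICc
comparison against BM — not taken at face value as evidence of a peak.
The corresponding acceptance check is deliberately left failing rather
than weakened; the decisions ledger carries the full analysis.

## 4. Ancestral states and phylogenetic signal

Node states are estimated by the rerooting construction: transform the
tree so BM on it matches the best-fitting model (identity for BM, the
α transform for OU, the a scaling for EB), then reroot the transformed
tree at each internal node and take the GLS root estimate (phylogenetic
weighted mean). Under BM this equals the closed-form GLS conditional
expectation — the suite verifies the equality to 1e−8 — and estimates
lie within the observed trait range on ultrametric trees. The reported
variance is the GLS root-state variance scaled by the fitted rate;
only point estimates feed the downstream summaries.

Pagel's λ is estimated by ML over λ-transformed trees on
[0, λ_max], with λ_max the largest value keeping the covariance
positive definite (the transformed covariance is exactly singular *at*
λ_max; the optimizer treats failures there as −∞). A `cap_at_1` option
restricts to [0, 1]. Blomberg's K uses the standard ratio form with
the (tr C − n/(1ᵀC⁻¹1))/(n−1) Brownian calibration, so E[K] ≈ 1 under
BM; K is affine-invariant. No randomization p-values are computed: the
intended use is comparing estimates across traits and tree samples,
not testing.

## 5. Sensitivity across tree samples

`analyze_tree_sample()` refits every requested model on every tree of
a sample and summarizes AICc, ΔAICc, weights, rates, OU half-life and
the FPK optimum (median, min, max, IQR). Per-tree failures (e.g., OU
on an accidentally non-ultrametric posterior tree) are logged and
excluded from summaries rather than aborting the run — a replication
analysis should survive individual pathological trees. Subsampling
from a larger posterior is a seeded uniform draw without replacement
(default size 100), and an optional leading-fraction drop handles raw
posterior files whose burn-in has not been removed upstream.

## 6. The synthetic world

The generator's defaults describe the kind of data the analysis
expects, chosen once:

- **Trees**: birth–death conditioned on tip count (`ape::rphylo`),
  default birth 0.15/Ma, death 0.05/Ma — for 50–300 tips this yields
  time-calibrated trees some tens of Ma deep, the scale of the focal
  spider clades' crown ages.
- **Traits**: exact branchwise simulation (normal increments for BM;
  the OU conditional mean/variance per branch; EB via its time
  transform; WN iid). FPK traits are simulated on the same grid and
  generator as the likelihood (exact transition sampling per branch
  from the matrix exponential), so simulator and likelihood are
  mutually consistent by construction.
- **Recovery test world**: the OU recovery suite uses θ = z0 = 0.3,
  σ² = 0.004, t½ = height/4 — a pull of the strength reported for
  mimicry-accuracy-like traits and a stationary SD (~0.12) that keeps
  the process inside score space, so the measurement round-trip layer
  clamps fewer than 1% of tips.
- **Measurements**: `synthesize_measurements()` inverts the scoring
  formulas with reference lengths fixed at 1 mm, so rescoring
  reproduces targets to machine precision; an optional scale-noise
  mode multiplies all lengths by a common lognormal factor around 3 mm
  (typical body size for these spiders) without touching the ratios.
- **Pseudo-posteriors**: `perturb_tree_sample()` jitters internal-node
  *ages* with mean-one lognormal noise, clipped below each parent —
  trees stay exactly ultrametric with non-negative branches and the
  topology untouched, which is the aspect of posterior spread the
  sensitivity machinery exercises.

What the generator does **not** emulate: measurement error and missing
data; the zero-inflated, decidedly non-Gaussian distribution of
constriction traits when most of a clade does not express them;
correlations among the nine traits; topological uncertainty in the
tree sample (only branch-length spread is emulated). A green test
suite therefore establishes that the estimators are correct under
their own assumptions — not that those assumptions hold for any
particular empirical data set.

## 7. Numerical conventions

- Ultrametricity: relative root-to-tip spread ≤ 1e−6 of tree height
  (dated consensus trees carry rounding noise).
- All covariance algebra through Cholesky; singular structures (e.g.,
  duplicated zero-length tips) raise informative errors.
- All stochastic entry points take a mandatory seed, run on a local
  RNG stream and restore the caller's RNG state; derived child seeds
  stay below 2³¹.
- Zero-length branches and polytomies are retained and handled
  natively; rerooting at the current root is the identity.

## 8. Known limitations

- The FPK flatness caveat of §3: raw fitted landscapes overstate
  curvature on diffusion-like data.
- Ancestral estimation under FPK is deliberately not offered; the
  discretized model's node-state reconstructions are not reliable
  enough to report.
- The OU fit assumes ultrametric input; for non-ultrametric trees only
  BM/EB/WN and the FPK model are available.
- Per-trait model fitting treats each trait independently; no
  multivariate model is implemented.
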