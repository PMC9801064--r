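---
title: "Methods: synergy and sensitivity scoring of dose-response matrices"
author: "synergyscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy and sensitivity scoring of dose-response matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyscore)
```

## Data model and response scale

A *combination block* is one self-contained experiment: $n$ drugs, each
with a strictly increasing ladder of nonzero test doses, measured on the
full factorial grid formed by every ladder plus dose 0. The all-zeros cell
is the untreated control; the monotherapy conditions of drug $i$ are the
cells where every other dose is 0; the *combination* cells — the ones that
receive synergy scores — are those where every drug is at a nonzero dose.

All model mathematics runs on the inhibition **fraction** $y \in [0,1]$
(viability inputs are converted as $y = 1 - v$); percentages appear only
at input/output boundaries. Measured responses outside $[0,1]$ are kept
and flagged, never silently clamped: assays over- and under-shoot, and
difference-based scores (HSA, LOEWE) are well defined for them. The one
place values are clamped to $[0,1]$ is inside Bliss/ZIP *product* terms,
where a negative survival factor would corrupt the probabilistic
expectation.

Dose tuples are matched by exact decimal-string equality after
harmonizing SI-prefix units (pM/nM/µM/mM) per drug. Dose grids come from
pipetting protocols, so two doses that differ in the file are two doses;
tolerance-based matching would merge them silently. Replicates feed the
statistics module only; everywhere else the observed response of a
condition is the replicate mean.

## Dose-response curves

Monotherapies and all conditional slices use the four-parameter
log-logistic (4PL) model

$$f(x) = E_{min} + (E_{max}-E_{min})\,
  \frac{(x/m)^\lambda}{1+(x/m)^\lambda},$$

increasing in dose ($\lambda > 0$), with $f(0) = E_{min}$ taken
analytically — dose 0 never enters a logarithm. Fitting is
box-constrained Levenberg–Marquardt least squares (`minpack.lm`), with
$m$ optimized on the log scale. Defaults and rationale:

* $E_{min}, E_{max} \in [0,1]$: inhibition fractions; relaxable through
  `eBounds` for assays that legitimately exceed the range.
* $\lambda \in [10^{-3}, 10]$: slopes outside this range are
  indistinguishable from step functions or flat lines at screening dose
  resolutions.
* Initialization: $E_{min}/E_{max}$ at the response extremes, $m$ at the
  dose nearest the half response, and three slope starts (0.5, 1, 3),
  keeping the best residual sum of squares. Multi-start stabilizes
  shallow curves at negligible cost.
* Convergence: `ftol` $10^{-10}$, at most 500 iterations.

Constant responses yield a flagged degenerate flat curve. A free fit that
wants $E_{max} < E_{min}$ (responses decreasing in dose) is collapsed to
a flagged flat curve at the mean: a decreasing "monotherapy curve" has no
inverse and would poison Loewe. The inverse
$f^{-1}(y) = m\,(t/(1-t))^{1/\lambda}$, $t = (y-E_{min})/(E_{max}-E_{min})$,
returns one-sided limits (0 and $+\infty$) outside the asymptotes. Note a
numerical fact, not a bug: the round-trip $f^{-1}(f(x))$ is exact to
$10^{-8}$ relative only while the response is away from the asymptotes;
once $f(x)$ saturates, $1-t$ loses precision and no double-precision
implementation can recover $x$. Tests therefore exercise the round trip
over each curve's dynamic range.

## Synergy scores

At each combination cell, with observed mean $y_c$:

* $S_{HSA} = (y_c - \max_i y_i)\cdot 100$, monotherapy responses taken as
  observed condition means.
* $S_{BLISS} = (y_c - [1 - \prod_i(1-y_i)])\cdot 100$. The product form is
  implemented directly; it equals the inclusion–exclusion expansion.
* $S_{LOEWE} = (y_c - y_L)\cdot 100$ where $y_L$ solves
  $\sum_i x_i / f_i^{-1}(y_L) = 1$ by bisection on
  $(\max_i E_{min,i} + 10^{-9},\ \min_i E_{max,i})$, tolerance $10^{-10}$,
  at most 200 iterations. The left-hand side is strictly decreasing in
  $y$, so the root is unique when bracketed. When the doses lie beyond all
  upper asymptotes the equation has no root and the expectation saturates
  at $\min_i E_{max,i}$ (bounded and continuous in dose); when a
  heterogeneous floor forces the other edge, at $\max_i E_{min,i}$. A
  degenerate constituent curve makes LOEWE undefined for the block —
  scores are emitted as missing with a warning rather than invented.
* $S_{ZIP} = (\hat y_c - y_{ZIP})\cdot 100$ with
  $\hat y_c = \frac1n \sum_i f'_i(x_i)$ and
  $y_{ZIP} = 1 - \prod_i (1 - f_i(x_i))$. Each conditional curve $f'_i$ is
  a 1-D 4PL fit along drug $i$'s ladder at fixed partner doses, with its
  floor pinned: $E_{min}(f'_i) = f'_{-i}(x_{-i})$, the fitted response of
  the remaining drugs with drug $i$ absent. For two drugs that pin is the
  partner's fitted monotherapy value. For three or more it is defined
  recursively as the $(n-1)$-drug ZIP fitted response of the sub-block
  with drug $i$ at dose 0 — one defensible generalization by induction;
  the base case reproduces the established two-drug behaviour exactly,
  which is the property we consider binding. $E_{max}$, $m$ and
  $\lambda$ of a conditional fit stay free within the usual bounds, so a
  strongly antagonistic slice may fit $E_{max} < E_{min}$ (a decreasing
  conditional curve); such curves are used forward-only and never
  inverted. A conditional fit with fewer than two finite points, or one
  that fails, falls back to the observed condition means for that drug's
  term and is counted.

Scores are percentage points (roughly $[-100, 100]$), the scale on which
published block averages are quoted. Block averages are unweighted means
over all combination cells; cells missing from ragged grids are excluded.

The **barometer** reads one cell: observed response and the four
expectations on one % inhibition scale, with consensus "synergistic" only
when the observed response exceeds *every* expectation (strictly), and
"antagonistic" only when it is below every one. Ties are "mixed" — a
response sitting exactly on one model's expectation is evidence for that
model's null, not beyond it.

## Sensitivity (CSS)

For each drug $i$, the partner drugs are fixed at their fitted IC50s; the
combination response along drug $i$ is obtained by interpolating between
the two bracketing tested partner doses, linearly in $\log_{10}$ dose —
the minimal assumption that produces an off-grid slice. A 4PL curve is
fitted to that slice (the zero-dose anchor included) and

$$CSS_i = 100\,\frac{\int f\, d\log_{10} x}
  {\log_{10} x_{max} - \log_{10} x_{min}}$$

integrates the *fitted* curve (adaptive quadrature, relative tolerance
$10^{-8}$) over the drug's nonzero tested range; raw-point trapezoids
would inherit the noise the fit removes. $CSS$ is the mean over the drug
axes. A partner IC50 outside its tested ladder is evaluated at the
nearest tested dose; more than one $\log_{10}$ unit outside is flagged
`extrapolated`. The integration bounds (the tested nonzero range) are a
stated choice of this package. For more than two drugs all partners are
fixed at their IC50s simultaneously; this is marked experimental, as the
two-drug case is the established one. The SS plot pairs CSS with the
block-average score of a chosen model (default ZIP) and ranks blocks by
`css + synergy` descending, surfacing the top-right corner.

## Statistics

With replicates, each bootstrap matrix draws one response per condition
from $N(\mu, \sigma)$, the replicate mean and SD of that condition
(conditions with one replicate get $\sigma = 0$ — imputing a pooled SD
would invent structure). Sampled responses are not clamped, preserving
the stated normal model. HSA/BLISS scores are recomputed directly per
resample; LOEWE/ZIP with full curve refitting over the whole matrix.
Failed refits are dropped and counted; at or above 10% of $B$ the model
aborts. Per condition, the bootstrap SE is the $(B-1)$-denominator SD of
the $B$ scores and the 95% CI is exactly $\bar s \pm 1.96\,SE$. At block
level, $z = |\bar s'| / SE'$ over the bootstrap block averages and
$P = \exp(-0.717 z - 0.416 z^2)$, the closed-form approximation to the
two-sided normal tail ($P(1.96) \approx 0.0496$). Defaults: $B = 1000$,
one RNG stream per run, the seed recorded in all output metadata.

Without replicates the per-condition scores of the single matrix are
pooled and compared to zero with their standard error of the mean — a
one-sample location-test analogue.

Because a bootstrap matrix draws a single response per condition (not a
mean of $k$ replicates), $SE'$ overestimates the sampling error of the
observed block average by roughly $\sqrt{k}$; the resulting test is
deliberately conservative, which the null calibration in the test suite
and acceptance script confirms (type-I error well below nominal
$\alpha$). When two or more blocks are analyzed together, a
Benjamini–Hochberg adjusted column is appended to the statistics table as
plumbing for screen-level use.

## Landscape layout

Each grid cell's doses are replaced by per-drug ranks: 0 for dose 0
(reserved — so monotherapy edges are distinguishable on the map), $k$ for
the $k$-th smallest nonzero tested dose. Classical (Torgerson) MDS of the
Euclidean distances between rank vectors gives 2-D coordinates:
deterministic, seed-free, and exact for two-drug grids, whose rank
vectors are already planar — backward consistency with classic heatmaps.
Stress is Kruskal's stress-1. Orientation is canonicalized by rotating
drug 1's rank gradient onto the $+x$ axis and reflecting so drug 2's
ranks increase upward, making layouts reproducible across condition
orderings. One caveat: highly symmetric grids (e.g. a $\{0,1,2\}^3$
lattice) have tied Gram eigenvalues, so the embedding plane within the
tied eigenspace is basis-dependent; the retained eigenvalue mass — the
quantity classical MDS optimizes — is invariant, and that is what the
tests pin down. The smoothed landscape raster in `plotLandscape()` is
Gaussian kernel smoothing (bandwidth 0.8 rank units), cosmetic only and
never fed back into scores.

## Synthetic data generator

`generatorSpec()`/`generateBlock()` produce full-factorial blocks with
known ground truth: per-drug 4PL curves, a baseline surface per
interaction model (`none_hsa`, `none_bliss`, the `none_loewe_sham`
single-curve sham experiment, `potency_shift` with halved conditional
IC50s — the potency-gain pattern ZIP is built to detect — and
`dose_window_boost`, an additive response boost over a rank window), plus
additive Gaussian noise per replicate. Defaults emulate common screen
shapes: 5-dose ladders spanning two decades either side of the IC50;
`nDrugs = 3` with 10/10/12-point ladders reproduces the
triple-combination matrix shape (1200 combination cells), and
`replicates = 4` the replicated two-drug design. Noise is additive on the
inhibition fraction, matching the bootstrap's normal model, and
truncation-free. The boost is additive on the response scale so
Bliss/HSA ground truth stays exact.

What the generator deliberately does **not** emulate: plate artifacts
(edge effects, drift), heteroscedastic or non-Gaussian noise, shared
monotherapy rows across blocks, and non-monotone dose responses. Passing
tests on generated data therefore demonstrate correctness of the scoring
mathematics and calibration under the stated model, not robustness to
assay pathology.

## Problem sizes and numerical choices in the test suite

The suite and `scripts/acceptance.R` run on 5 × 5 two-drug grids
(3 × 3 × 3 and 2 × 2 × 2 for three drugs), 200-block null batteries with
$B = 200$ bootstrap draws, and a single 10 × 10 × 12 triple block for the
grid-count law — sizes chosen so every law is exercised on the same code
paths real screens use while the whole suite stays interactive.
Tolerances follow the mathematics: HSA/Bliss null laws are exact (pure
arithmetic on the generator's own surface), the Loewe sham holds to
$10^{-6}$ through fit + root-solve, ZIP's null to 0.5 points (it refits
curves, so optimizer termination enters), and the two-drug oracle
comparison to $10^{-8}$ for direct formulas and $10^{-4}$ where fitted
curves intervene.

## Known limitations

* LOEWE requires invertible monotherapy curves; flat or decreasing fits
  make it undefined for the block (reported as missing, never guessed).
* The ZIP recursion for $n \ge 3$ is one reading of the conditional-floor
  construction; alternatives (e.g. averaging pairwise floors) would
  differ at third order while agreeing for $n = 2$.
* CSS beyond two drugs is experimental and flagged as such.
* The bootstrap is conservative by construction (single-draw matrices);
  users comparing against nominal $\alpha$ should know rejection rates
  run below it under the null.
* Scores at out-of-range observed responses are reported as computed;
  only product terms clamp.
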