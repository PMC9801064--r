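# synergyscore

Synergy and sensitivity scoring for drug combinations of any order.

High-throughput drug combination screens measure cell responses over
full-factorial dose matrices — two-drug checkerboards with replicates, or
higher-order designs such as 10 × 10 × 12 triple-combination blocks. To
decide whether a combination does more than its parts, the observed
response must be compared with what *non-interacting* drugs would have
produced. `synergyscore` implements the four major non-interaction
reference models for *n*-drug combinations, the combination sensitivity
score that measures overall efficacy, bootstrap statistics for both, and a
dimension-reduction layout that makes higher-order synergy landscapes
drawable. It is aimed at translational researchers and screening
facilities who need to rank combinations by both interaction and efficacy.

## The models

Responses are percent inhibition, used as fractions *y* ∈ [0, 1] in all
model mathematics. With *y_c* the observed combination response and *y_i*
the monotherapy response of drug *i* at its dose *x_i*:

* **HSA** (highest single agent): expected response
  *y*\_HSA = max(*y*\_1, …, *y*\_n).
* **BLISS** (Bliss independence): *y*\_BLISS = 1 − ∏(1 − *y_i*),
  probabilistic independence of effects.
* **LOEWE** (Loewe additivity): the response *y* solving the isobole
  (dose-equivalence) equation ∑ *x_i* / *f_i*⁻¹(*y*) = 1, where *f_i* is
  the drug's fitted dose–response curve. A drug "combined" with itself
  scores zero (sham compliance).
* **ZIP** (zero interaction potency): compares fitted conditional
  combination curves *f′_i* — whose floor is pinned at the fitted response
  of the remaining drugs — against the Bliss surface of the fitted
  monotherapies: *S*\_ZIP = (1/n) ∑ *f′_i*(*x_i*) − [1 − ∏(1 − *f_i*(*x_i*))].

Every synergy score is *S* = (*y* − *y*\_model) × 100 percentage points,
positive for synergy. Dose–response relationships use the four-parameter
log-logistic model
*f*(*x*) = *E*\_min + (*E*\_max − *E*\_min)(*x*/*m*)^λ / (1 + (*x*/*m*)^λ)
with IC50 *m* and slope λ.

Around the scores the package provides:

* **Bootstrap statistics** — responses are resampled per condition from
  N(μ, σ) of the replicates; per-dose 95% CIs are s̄ ± 1.96·SE and the
  block-level empirical *P* is exp(−0.717 z − 0.416 z²) with
  z = |s̄′|/SE′. Without replicates, the per-condition scores are pooled.
* **CSS** (combination sensitivity score) — normalized area under the
  log10-dose combination response curve with each partner fixed at its
  IC50; same 0–100 scale as percent inhibition. The synergy–sensitivity
  (SS) plot pairs CSS with a block-average synergy score.
* **Synergy barometer** — one dose condition's observed response placed
  against all four expectations on one % inhibition scale.
* **Landscape layout** — classical MDS of per-drug dose-rank vectors into
  the plane, exact for two-drug grids and well-defined for any order.

## Worked example

Simulate a replicated two-drug screen with a synergy window (a +12 point
response boost over the top-right 2 × 2 dose window of a Bliss baseline),
then score it:

```r
library(synergyscore)

spec <- generatorSpec(
  nDrugs = 2,
  curves = list(list(eMin = 0, eMax = 0.75, ic50 = 1, slope = 1.2),
                list(eMin = 0, eMax = 0.55, ic50 = 5, slope = 0.8)),
  interaction = "dose_window_boost", delta = 0.12,
  noiseSd = 0.03, replicates = 4, blockId = "demo")
blk <- generateBlock(spec, seed = 42)$block
blk
#> CombinationBlock 'demo': 2 drug(s) [drug1, drug2]
#>   grid: 36 conditions (5 x 5 nonzero ladder doses), scale: inhibition
#>   replicates per condition: 4-4

surf <- scoreSurface(blk)
round(blockSummary(surf), 2)
#>   hsa bliss loewe   zip
#>  7.61  2.63 11.68  2.42
```

The block averages are in percentage points: the mean observed response
sits 2.6 points above Bliss independence and 11.7 above Loewe additivity
(the window boost diluted over the whole 5 × 5 grid). Is the Bliss excess
more than noise?

```r
bootstrapSurface(blk, models = "bliss", B = 1000, seed = 42)$bliss
#> BootstrapSummary [bliss]: B=1000, block score 2.298 (SE 1.483), z=1.550, P=0.1211
```

Borderline — at this noise level a 2.3-point average Bliss excess is not
significant (*P* ≈ 0.12). Efficacy and the single most synergistic dose
tell a crisper story:

```r
round(cssScore(blk)$css, 2)
#> [1] 55.92                      # overall efficacy, % inhibition scale

barometer(surf, c(10, 10))
#> BarometerReading at (drug1=10, drug2=10)
#>   observed: 90.56% inhibition, consensus: synergistic
#>   expected: LOEWE=58.68  HSA=69.16  ZIP=78.76  BLISS=78.99
```

Inside the boost window the observed 90.6% inhibition exceeds all four
model expectations — consensus synergy at that dose. Finally the layout
for painting landscapes (exact for two drugs, MDS of dose ranks for
three or more):

```r
mdsLayout(blk, "score_bliss", surf)
#> LandscapeLayout 'demo': 36 points, paint=score_bliss, stress=4.34e-16
```

`runReport()` (or the `inst/scripts/synergyscore.R` command-line wrapper
with subcommands `score`, `stats`, `ss`, `layout`, `simulate`, `report`)
runs this whole pipeline over every block of a long-format CSV/TSV table
and writes surface/stats/SS/layout CSVs plus a barometer JSON per block.

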