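---
title: "Hit calling in reciprocal extracellular interaction screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hit calling in reciprocal extracellular interaction screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecia)
```

## The measurement and its biases

An extracellular interaction assay (ECIA) screen measures binding
between the extracellular domains (ECDs) of cell-surface receptors in
an all-by-all design. Each protein is prepared twice: as a *bait*
(Fc fusion, adsorbed to a protein-A-coated well) and as a *prey*
(alkaline-phosphatase fusion, pentamerized for avidity, detected
colorimetrically at 650 nm). Every ordered (bait, prey) combination
occupies one well, so a family of $n$ receptors yields an $n \times n$
absorbance matrix in which rows are bait preparations, columns are
prey preparations, and each unordered pair is measured twice — once in
each orientation. A self-pair occupies a single well that effectively
tests both orientations at once.

Raw A650 values are dominated by nuisance structure: an assay-wide
background, plus additive offsets specific to each bait preparation
and each prey preparation (expression level, protein stability, plate
batch, intrinsic stickiness). True interactions are sparse, so the
signal of interest is a small set of positive outliers sitting on this
two-way background.

## Two-way median polish

The background model is additive,

$$y_{ij} = \mu + a_i + b_j + r_{ij},$$

and is fitted by Tukey's median polish rather than by row/column
means or a two-way ANOVA: medians have a 50% breakdown point, so a
sparse set of genuinely interacting wells cannot inflate the estimated
background of their own row or column. `median_polish()` alternately
sweeps row medians into the row effects and column medians into the
column effects (rows first, then columns — the fixed point of median
polish is not unique, so the sweep order is fixed for determinism),
re-centring the effect vectors through the overall term after each
half-sweep. Medians over an even count are the mean of the two central
order statistics. Missing cells (unmeasured pairs) are excluded from
every median and never imputed.

Two numerical properties are contracts, not aspirations, and are
tested as such:

* the additive identity
  $\mu + a_i + b_j + r_{ij} = y_{ij}$ holds to floating point after
  *every* sweep, not just at convergence;
* at convergence every row and column median of the residual matrix is
  below the tolerance.

Iteration stops when the largest absolute median removed during a full
sweep drops to `tol` (default `1e-8` absorbance units — far below any
meaningful assay signal). The sweep deltas shrink geometrically but
slowly: measured on simulated screens, a $50 \times 50$ matrix crosses
`1e-8` after roughly 110 sweeps and a $200 \times 200$ matrix after
roughly 330, so the default `max_iter` is 500. Stopping earlier (the
residual changes at sweep 20 are already ~`1e-5`) would not visibly
change downstream scores, but a pipeline that routinely reports
non-convergence invites doubt about the wrong thing. Because the
tolerance is expressed in absorbance units, rescaling the data
rescales the natural tolerance with it; the equivariance tests scale
`tol` accordingly.

The polish is fitted once, globally. Plate-level offsets are not
modelled separately because the long input format carries no plate
assignment; whatever plate structure exists is absorbed by the overall
and preparation terms to the extent that it is additive.

## MAD-unit scoring and the 2.5 cutoff

Residuals are scored against the pooled, screen-wide residual
distribution:

$$s_{ij} = \frac{r_{ij} - \mathrm{median}(r)}{\mathrm{MAD}(r)},
\qquad \mathrm{MAD}(r) = \mathrm{median}\,|r - \mathrm{median}(r)|.$$

Median and MAD are again chosen for robustness: the residual
distribution is a unimodal bulk of non-interacting pairs with a right
tail of true interactions, and the spread estimate must not be
stretched by that tail. The MAD is used *raw*, without the 1.4826
normal-consistency constant — the screen's score unit and its fixed
cutoff of 2.5 are defined in raw MAD units. Users comparing to
robust-z conventions should note that 2.5 raw MAD units is only about
1.69 normal SDs, so the per-well null exceedance rate is ~4.6%, not
0.6%; the stringency of the screen comes from requiring *both*
orientations to perform, not from the marginal cutoff.

`call_hits()` classifies every unordered pair:

* the geometric-mean score $\sqrt{s_{ab}\,s_{ba}}$ is defined only
  when both orientation scores are strictly positive. This guard is
  essential: without it, two *below-median* measurements
  ($s_{ab}, s_{ba} < 0$) would multiply into a positive "score".
  True interactions live in the right tail only;
* **bidirectional**: geometric mean defined and $> 2.5$ (strict);
* **unidirectional**: not bidirectional, and
  $\max(s_{ab}, s_{ba}) > 2.5$ (strict);
* **none** otherwise. Self-pairs use their single score as both
  orientations and as the geometric mean; pairs with an unmeasured
  orientation can be at most unidirectional.

The two hit classes are disjoint by construction (bidirectional takes
precedence). One consequence of the geometric-mean rule is worth
stating plainly: a very strong single-orientation signal *can* be
called bidirectional when the opposing orientation's noise score
exceeds $2.5^2/s_{ab}$ — e.g. ~0.5 MAD units against a 12-MAD-unit
planted signal, which pure noise does roughly a third of the time.
The tests therefore pin the exact guarantee (a non-positive opposing
score always blocks a bidirectional call; leakage occurs only through
that inequality) rather than a blanket "one-sided signals are never
bidirectional", which no threshold rule of this form can deliver.

## Retest confirmation

A retest screen re-measures the predicted interactions (plus controls)
with freshly expressed proteins. Its composition is small and biased
towards positives, so the primary screen's polish-and-MAD machinery —
which assumes a large, mostly-null population — cannot be reused.
Instead both screens' raw paired absorbances are put on a common scale
by interquartile-range normalization,

$$x \mapsto \frac{x - \mathrm{median}(x)}{\mathrm{IQR}(x)},$$

applied to each screen separately (quartiles by linear interpolation,
R's default type-7 rule; conventions differ across software, so the
choice is fixed and documented). An option to normalize the two
screens jointly exists for sensitivity analysis; per-screen is the
default and the variant makes no fidelity claim. IQR normalization
absorbs any positive affine transform of a screen's values, which is
exactly the between-screen comparability being sought; it does not
(and cannot) equate screens that differ non-linearly.

The confirmation threshold is derived from the primary screen: the
*minimum* IQR-normalized geometric-mean absorbance over the primary
bidirectional set — the weakest pair still included, i.e. the
inclusion threshold, read off the data with no free parameter. A
retest pair is confirmed when its normalized geometric mean strictly
exceeds that threshold. Strict inequality has a visible corner case:
if the retest were literally identical to the primary screen, the
boundary pair itself (and any predicted hit whose geometric mean is
undefined because one orientation fell below the screen median) would
not reconfirm; the tests assert exactly this behaviour rather than a
nominal 100%.

Reproducibility is summarized by the Spearman rank correlation between
the two screens' normalized geometric means, and hit-versus-control
separation by a Mann-Whitney rank-sum comparison against pooled
prey-only negative-control wells. Both are rank-based for the same
reason the scoring is: no distributional assumption on A650 values.

## The synthetic screen generator

`simulate_screen()` generates data from the additive model the polish
is built to invert:

$$y_{ij} = \max\!\big(0,\; \beta + u_i + v_j + \varepsilon_{ij}
          + \Delta\,\mathbb{1}[\text{pair planted in orientation } ij]\big),$$

with bait-preparation biases $u_i$ and prey-preparation biases $v_j$
drawn independently (a protein's bait and prey preparations are
different physical reagents), i.i.d. well noise, and a configurable
set of planted interacting pairs, optionally one-orientation-only.
Clipping at zero reflects that absorbance is non-negative; it is a
deliberate, small deviation from pure additivity. Prey-only
negative-control wells (no bait-row bias) and a strongly interacting
positive-control pair can be appended, mirroring the plate controls
of the real assay.

Defaults are the package's desk-scale study conditions, chosen once:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 50 | screen dimension (2,500 wells) |
| `overall_background` | 0.2 A650 | assay-wide background |
| `row_effect_sd`, `col_effect_sd` | 0.05 A650 | preparation-bias spread |
| `noise_sd` | 0.02 A650 | per-well measurement noise |
| `n_true_pairs` | 30 | planted interacting pairs |
| `effect_size` | `8 * noise_sd` = 0.16 A650 | added signal per planted orientation |

The absorbance scale mirrors a typical plate-reader experiment: a
background a few tenths of an OD unit, preparation offsets a few times
the read noise, and clear interactions rising a few tenths above
background. A `lognormal-additive` noise family (centred, rescaled,
right-skewed) probes robustness to the skew real colorimetric noise
tends to show. At the default effect size the full pipeline recovers
essentially all planted symmetric pairs with a bidirectional
false-positive rate near the null tail mass (~1% of unordered pairs);
the benchmark in `analysis/04_recovery_benchmark.R` maps sensitivity
over effect sizes from 2 to 12 noise SDs.

What the simulator does *not* emulate — and what green tests therefore
do not establish about real screens: 96-well spatial (edge) effects,
ligand-dependent or avidity-dependent signal, correlated noise within
plates, multiplicative (rather than additive) preparation biases, and
dropout of failed wells. The generative model is intentionally the
analysis model plus clipping; it validates the inference machinery,
not the biology.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated
data: a single full-design $200 \times 200$ screen (40,000 wells,
matching the family-wide design with its 20,100 unordered pairs),
$50 \times 50$ screens for recovery and validation, and small seeded
matrices for the oracle comparisons. All randomness flows through
explicit integer seeds in the simulator config, so every reported
number is exactly reproducible. The analysis drivers under `analysis/`
write their tables beneath `results/`.

## Known limitations

* The polish assumes additive preparation biases; strongly
  multiplicative biases would leak into residuals (a log transform
  before polishing would be the first thing to try, but is not applied
  by default because the assay's zero-anchored scale makes logs
  ill-behaved at background).
* With ~4.6% per-well null exceedance at 2.5 raw MAD units, the
  unidirectional set is expected to carry a substantial noise
  component; the bidirectional set, and retest confirmation, are the
  high-confidence products.
* The confirmation threshold is an extreme statistic (a minimum), so
  it is sensitive to the single weakest member of the primary
  bidirectional set; this matches its definition as an inclusion
  threshold but means it should not be reused across screens with
  different hit-set compositions.
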