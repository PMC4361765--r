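---
title: "Methods: composite ocean-health scoring and catch-only stock assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite ocean-health scoring and catch-only stock assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohindex)
```

## The model

`ohindex` scores the health of coastal reporting regions against ten
societal goals (food provision, tourism & recreation, clean waters,
biodiversity, and so on) and combines them into a single 0--100 Index.
Each goal contributes four ingredients per region:

* **current status** $x \in [0,1]$: the goal's present value relative to a
  reference point representing its sustainable maximum;
* **trend** $T \in [-1,1]$: the recent direction of change;
* **pressure** $p \in [0,1]$ and **resilience** $r \in [0,1]$: cumulative
  stressors and the governance/ecological factors mitigating them.

Likely future status modifies the present by these forces,

$$\hat x_F = (1+\delta)^{-1}\left[1 + \beta T + (1-\beta)(r-p)\right] x,$$

with discount rate $\delta = 0$ (ocean-health values are largely
time-independent; prior sensitivity work found scores robust to higher
rates) and trend weight $\beta = 0.67$, giving the observed trend twice
the influence of the pressure--resilience balance. A goal's score is
$100\,(x + \hat x_F)/2$ and the Index is the weighted mean of goal scores,
with equal weights by default. Goals not relevant to a region score NA and
are excluded with the remaining weights renormalized (configurable off via
`na_exclude`).

Two numerical choices are ours. First, the future-status expression can
leave $[0,1]$ for extreme $T$ or $r-p$; because status is a proportion of
a reference point we clamp the result back to $[0,1]$ after evaluation.
The raw response is available (`clamp = FALSE`) for sensitivity analysis,
where the clamped function would be flat at the boundary and a finite
difference would measure the clamp rather than the model. Second, scores
are computed and stored at full precision; deltas between assessments are
taken before any display rounding, and display rounding is
half-away-from-zero (`round_half_up()`).

## Fisheries sub-goal

### Catch-only stock assessment

Most commercially landed stocks lack the data for formal assessment, so
stock status is inferred from the catch series alone by stock-reduction
analysis (`assess_stock()`). A Schaefer surplus-production model

$$B_{t+1} = B_t + r B_t (1 - B_t/K) - C_t, \qquad B_{MSY} = K/2$$

is projected under every candidate parameter pair: $r$ log-uniform on
resilience-category bounds (very-low 0.015--0.1, low 0.05--0.5, medium
0.2--1.0, high 0.6--1.5; medium when life history is unknown), $K$
log-uniform on $[\max C,\ 100 \max C]$, and initial depletion uniform on
$[0.5, 0.9]$ when the series starts below half its peak (a fishery caught
while developing), else $[0.3, 0.6]$. A pair is *viable* when its
trajectory never collapses (below $0.01K$), never exceeds $K$, and ends at
a final depletion inside a prior window. Sampling is $n = 10{,}000$ draws
with one retry at $10\times$ before a stock is flagged unassessable.

The final-depletion window switches on management context. Stocks with a
catch-weighted governance resilience score of at least 0.6 get an
uninformative window $(0.01, 1]$: in well-managed fisheries declining
catch often reflects declining effort, and a constrained prior would
misread it as depletion. Below 0.6 the constrained windows apply: final
catch under half of peak ⇒ depleted, $(0.01, 0.4)$; otherwise
$(0.3, 0.7)$. The uniform window's positive lower bound is our choice: it
keeps $B/B_{MSY}$ defined.

Retained trajectories are summarised per year. The default averages
per-pair *depletion* $B_t/K$ arithmetically and doubles it, keeping every
pair on a common scale; averaging raw biomass (divided by the mean $K/2$)
is available as `mean_mode = "biomass"` but lets large-$K$ pairs dominate.
Proxy $B/B_{MSY}$ values for coarsely reported taxa are floored at
$10^{-4}$ so the geometric mean's logarithm stays finite.

Each stock's random stream is derived from the run seed and the stock
identifier, so per-stock results are independent of assessment order and
bit-reproducible.

### From B/BMSY to a regional status

Species-level (taxonomic level 6) stocks are scored from their assessed
$B/B_{MSY}$ by a piecewise rule centred on the management target
$B/B_{MSY} = 1$ with a 5% measurement buffer: below the buffer the score
is $B/B_{MSY}$ itself; inside it, 1; above it the score declines at slope
$\alpha = 0.5$ (under-harvesting penalized at half the over-harvesting
rate) down to a floor $\beta = 0.25$ protecting exceptionally productive
years. The discontinuity at $0.95$ (0.94 scores 0.94; 0.95 scores 1) is
kept exactly as the rule prints; we do not smooth it.

Taxa reported above species level take a penalized proxy: the median
species-level $B/B_{MSY}$ of the same fishing area and year, shrunk by
0.90, 0.80, 0.50, 0.25 or 0.01 as resolution coarsens from level 5 to 1 —
coarse reporting signals weak monitoring. The median pools the matching
year only; when an area-year has no species-level stocks we fall back to
the nearest prior year within the area, else the taxon is excluded with a
warning. Medians interpolate linearly at even counts.

A region's fisheries status is the geometric mean of its stocks' scores,
weighted by each stock's share of the region's mean catch (averaged from
the first non-null record, counting zeros; later nulls are treated as
zero catch, i.e. non-reporting). The geometric mean lets a collapsed
small stock drag the score more than its tonnage alone would, valuing
catch diversity.

## Mariculture and tourism

Mariculture status is sustainability-weighted yield per coastal capita,
$Y_M = \sum_k Y_k S_{M,k} / P_C$, rescaled to a reference equal to the
95th percentile across regions of each region's maximum $Y_M$ over the
years assessed, and capped at 1 (a proportion of a sustainable maximum
cannot meaningfully exceed it — the cap is our choice). The per-region
maximum reading is the only one that keeps the percentile nondegenerate.

Tourism & recreation status multiplies the direct tourism employment
share, corrected for unemployment, $E_d = E_t / (L_t - L_t U_t)$, by a
sustainability index $S_t$, then rescales to the 90th percentile of the
composite score across the regions of the current assessment (the top raw
scores are extreme outliers, so the maximum is not a usable reference);
regions above the reference score 100. Missing employment data yield NA
status — gap-filling, where done at all, belongs at the score level,
because filling the employment layer can produce more tourism jobs than
labor force. Percentiles use linear interpolation between order statistics
(R type 7) everywhere, configurable via `quantile_type`.

## Synthetic worlds and what they do (and do not) show

`synthetic_world()` generates every input the engine consumes with known
ground truth. Stocks follow true Schaefer dynamics from an unfished start
under one of four effort archetypes, chosen to exercise the prior switch
on both sides:

* `one_way_trip`: harvest rate ramps linearly to $1.2r$ — catch peaks and
  then declines as the stock is driven to 3--17% of $K$;
* `boom_bust`: rapid ramp past $r$, then decline — collapse with partial
  recovery;
* `managed_recovery`: ramp to $0.8r$, then managed down to $0.25r$ —
  catch falls while biomass rebuilds, the case a constrained prior
  misreads;
* `lightly_fished`: constant harvest at $0.02r$ (under 2% of $K$ per
  year) — the stock sits near $K$, so $B/B_{MSY} \to 2$.

Reported catch is the true catch times mean-unbiased lognormal noise
(CV 0.1 by default), split across 1--3 regions of the stock's area, with
staggered reporting onset producing realistic leading nulls. Regions are
split into well-managed (fisheries resilience 0.6--0.9) and
poorly-managed (0.2--0.55) halves; managed archetypes are landed only in
well-managed regions, so each stock's catch-weighted resilience falls on
the intended side of the 0.6 threshold. Each stock's r-category is
assigned from its true $r$ (low under 0.4, medium to 0.7, high above) as
a stand-in for the life-history knowledge a practitioner would bring;
every category interval contains the truth.

Non-modelled goal layers draw statuses from Beta(2,2), trends from a
truncated normal on $[-1,1]$ (SD 0.1), pressures from Beta(2,5) and
resilience from Beta(5,2); mariculture yields are lognormal (right-skewed,
as real per-capita yields are) and tourism employment shares are small
and right-skewed (Beta(1.5, 30)). A constant-status mode sets every
status to a single value $c$ with zero trends and $p = r$, making
Index $= 100c$ an exact fixed point used to validate the aggregation
path end to end.

The generator emulates the *statistical shape* of real inputs, not their
spatial autocorrelation, reporting revisions, or multi-gear structure.
Passing tests on synthetic worlds therefore validate the engine's
arithmetic, determinism and contracts — not the real-world accuracy of
any particular data assembly.

## Parameter-recovery behavior and known limitations

The test suite scores the assessment model against simulated truth on 50
stocks spanning $r \in [0.1, 0.8]$ across the four archetypes with CV 0.1
observation noise at 10,000 draws per stock (a few seconds of compute;
these sizes are our standing study conditions). Two summaries are
tracked: the median absolute error of final-year $B/B_{MSY}$, and
final-decade trend agreement, where the trend is the least-squares slope
over the last ten catch years, the truth is classified
rising/stable/falling with a meaningful-change threshold of 0.01 per year
(0.1 $B/B_{MSY}$ per decade), and the estimate agrees by sign for
directional truth or by small magnitude for stable truth. The threshold
exists because a stock at equilibrium has a true slope near $10^{-4}$
whose literal sign is noise.

Recovery of the final *level* is adequate (median absolute error around
0.29 under the standing conditions). Trend *direction* is weaker
(about 72--77% agreement), and the failures are structural rather than
sampling accidents:

* **Deep terminal collapses starve the accept--reject step.** For
  one-way-trip stocks ending at 3--10% of $K$, the conventional initial-
  depletion prior (at most 0.9) sits below the unfished truth, and the
  collapse floor $0.01K$ leaves a razor-thin viable slice — sometimes
  single-digit viable pairs out of 110,000 draws. The surviving pairs,
  truncated from below by the depletion window, produce flat-to-rising
  estimated tails while the truth still declines.
* **The catch-ratio rule misbins slow collapses.** A slow stock can end
  depleted while its final catch is still above half of peak, drawing the
  $(0.3, 0.7)$ window and an upward-biased estimate.

These are properties of the assessment rules themselves (priors, bounds
and retry schedule are part of the method's definition), so we report
them as limitations rather than re-tuning the simulator around them.
Users should treat estimated trends for severely collapsed stocks with
caution and rely on the final-level estimate plus the diagnostic count of
viable pairs (`n_viable` in the fit object and the audit log).

## Degenerate inputs and tie-breaks

All-zero catch series, all-NA goal vectors, tourism scores that are all
zero, and mariculture with no positive yield are errors, not silent
zeros. Catch series shorter than 10 non-null years (configurable
`min_years`) are rejected. Ties at percentile references resolve by the
interpolation rule; the buffer boundaries of the stock-status rule are
closed on both sides ($0.95 \le b \le 1.05$ scores 1). Trends outside
$[-1,1]$ are clamped with a warning rather than rejected, since trend
layers are upstream estimates.

## Reproducibility contract

Every stochastic step descends from a single integer seed: the sampler
seed per stock is derived from (run seed, stock id), the synthetic world
from (seed, table name). Identical implementation version, configuration
and seed give byte-identical output files; the configuration hash is
recorded in the audit log of every run.
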