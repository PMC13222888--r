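---
title: "Ranking land degradation drivers with partial orders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking land degradation drivers with partial orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldrank)
```

## The problem and the model

Land degradation (LD) at the county scale is driven jointly by natural
conditions, human activities, economic intensity and urbanisation. The
usual attribution tools — regressions, composite indices, variance-based
detectors — require either a functional form linking drivers to
degradation or a weighting scheme that collapses incommensurable
indicators into a single score. `ldrank` takes the partial-order route:
for a set of counties X described by an indicator set F (one driver
group), county x dominates county y exactly when every oriented indicator
agrees,

$$x \ge y \iff f_i(x) \ge f_i(y)\ \ \forall f_i \in F,$$

and the pair is incomparable otherwise. This is the componentwise
(product) order; it is reflexive, transitive and — after collapsing
identical indicator vectors into equivalence classes — antisymmetric, so
it is a genuine partial order. No weights, no linearity, no distributional
assumptions enter; the cost is that some pairs simply cannot be ranked,
and the method treats that honestly as information (incomparability)
rather than noise.

The Hasse diagram is the transitive reduction of this order. Three derived
quantities carry the interpretation:

* **Levels**, counted top-down: maximal (undominated) elements occupy the
  top level L, and each element sits at `L − depth`, where depth is the
  longest upward cover-path to a maximal element. A county's level in a
  group's diagram is read as the relative strength of that driver group's
  influence. The top-down convention is chosen because it is the only one
  consistent with reading "higher level = stronger influence, undominated
  at the top" off the published worked example that
  `six_county_example()` reproduces.
* **Maximal chains** — source-to-sink paths in the cover DAG — along which
  influence increases monotonically.
* **Isolated elements**, incomparable with every other county. They are
  assigned the top level (they are, after all, undominated) but are
  flagged separately and excluded from chain enumeration, because their
  position carries no comparative information; a county with extreme
  values in opposite directions is a case for individual attention, not a
  rank.

Average ranks use the LPOM0 closed form
$R_{av}(x) = (S+1)(N+1)/(N+1-U)$, with S the number of elements strictly
below x, U the number incomparable with x and N the element count. LPOM0
is the standard local approximation to the exact mean rank over all linear
extensions; the package's tests verify it is exact on chains and
antichains and order-consistent with exhaustive linear-extension
enumeration on small posets. Exact enumeration is deliberately not offered
beyond the test oracle (N ≤ 8): its cost grows factorially and LPOM0 is
the accepted field practice.

### Dominance attribution

Each driver group g yields its own diagram; a unit's position is rescaled
to [0, 1] by one of two methods:

* `level_height` (default): `(level − 1)/(L − 1)`;
* `lpom_norm`: `(Rav − 1)/(N − 1)`.

A one-level (or one-element) diagram carries no ordering information and
scores 0.5 for every unit, so a structureless group can neither win nor
lose by construction. The dominant set of a unit is
`{g : score_g ≥ max score − tie_tol}`; with the default `tie_tol = 0` this
is the argmax set and co-dominance arises only from exact ties, which is
how a unit can legitimately be reported as driven by several groups at
once. The attribution rule is a documented reconstruction of "higher
level = stronger influence" reasoning — the level-based reading is the
method's own, and both the scoring method and the tolerance are exposed as
configuration precisely because other defensible operationalizations
exist.

## Preprocessing assumptions

**Normalization** is per-indicator min-max over the unit set, mapping the
observed extremes to 0 and 1. It is invariant under positive affine
rescaling of the raw indicator (tested), which is what makes the poset
scale-free: converting units of measurement cannot change any comparison.
A constant column is mapped to 0.5 everywhere — any constant leaves every
pairwise comparison unchanged, and 0.5 keeps the column visibly neutral in
plots and scores.

**Orientation** flips inverse indicators by `v ↦ 1 − v` after
normalization. The default inverse set is annual total precipitation plus
the four distance-to-built-up indicators: more rain mitigates degradation,
and proximity (small distance) to urban land, settlements, roads and other
built-up land means stronger urbanisation pressure. Orienting twice is an
error by design: the flip is an involution, and a silent second
application would invert the analysis. Orientation is directional
standardization only — it does not assume any linear dose-response
relation between a driver and degradation.

**Comparison ties.** Equality of floating-point indicator values is exact
by default (`tol = 0`): after min-max normalization, ties come from
genuinely identical inputs and are meaningful. An optional tolerance is
available for noisy data; it is implemented by snapping values to a
`tol`-grid *before* comparison, rather than by tolerant pairwise
comparison, because the latter breaks transitivity ("equal" would stop
being an equivalence) while snapping provably yields a valid partial
order.

**Zonal means and IDW.** County values of continuous surfaces are
arithmetic zonal means ignoring missing cells. Station series are gridded
with inverse distance weighting, `w_k = d_k^{-p}`, all stations
contributing and `p = 2` by default — the plain textbook estimator;
without evidence for a particular neighbourhood or power, the simplest
standard choice is preferred and both are arguments. The interpolant is
exact at station locations and bounded by the sample range (tested).

**Collinearity screen.** Pearson correlations between the indicators of
two groups, flagged at |r| ≥ 0.7 — the conventional threshold above which
collinearity starts to distort joint interpretation. Zero-variance columns
yield undefined r and are flagged rather than silently dropped.

## Land-cover accounting choices

Cells missing (nodata) in either epoch are excluded from every area and
every denominator; transition-matrix row sums therefore reproduce
first-epoch class areas over jointly valid cells exactly, and the tests
assert this conservation to machine identity. The annual change rate is

$$\text{rate} = 100 \cdot \frac{\text{changed area}}{\text{valid area}} \cdot \frac{1}{T}\ \ [\%\,\text{yr}^{-1}],$$

the simplest rate consistent with reporting a period's change as an
equal annual fraction of the study area. Degraded and restored areas are
reported as gross per-direction totals; no netting of re-conversions is
attempted, and both totals are always reported side by side so a "net"
reading remains the caller's explicit step. Distances to a class are
planar cell-centre to cell-centre Euclidean distances (an exact distance
transform; synthetic grids are planar, so no geodesic correction applies).
Grid I/O uses the plain-text Esri ASCII format with explicit nodata.

## What the synthetic generator emulates — and what it does not

`scenario_config()` defaults define the study conditions: 20 units on a
50 × 50 grid of 1 km² cells; twelve indicators in the 2/2/4/4
natural/human/economic/urbanisation structure with precipitation and the
four distances inverse-oriented; planted effect size δ = 0.5 and noise
σ = 0.05 on the latent influence scale; a grassland-dominated class
mixture (45 % grassland, 25 % forest, 15 % cropland) with a decadal
transition regime of grassland/forest reclamation to cropland (5 %/1 %),
modest recovery of cropland and bare areas to grassland (3 %/2 %) and
minor impervious expansion (0.5 %) over a 10-year period — transition
intensities chosen to land the degradation rate in the few-tenths-of-a-
percent-per-year range typical of semi-arid agro-pastoral regions.

For unit u with planted group g\*, indicators in g\* are drawn as
`δ + N(0, σ)` on the latent scale and all others as `N(0, σ)`; a fixed
affine map per indicator (decreasing for inverse ones) then produces
plausible raw measurement scales. Because normalization undoes affine
maps, the planted structure survives the pipeline exactly, which is what
makes ground-truth recovery a sharp test: at σ = 0 recovery must be
exact; at σ = 0.05 (a tenth of the effect size) the measured recovery
rate across 200 replicate scenarios is the package's headline stochastic
check. δ = 0.5 with σ = 0.05 encodes "clearly dominant group, mild
measurement noise"; the recovery-vs-noise curve is itself tested to be
non-increasing.

The generator deliberately does **not** produce spatially autocorrelated
fields, realistic climate surfaces, within-county heterogeneity, or
correlated indicators across groups. Passing tests therefore demonstrate
that the machinery is correct and that the attribution rule recovers a
planted signal under independent noise — they do not demonstrate that
real-world driver attributions are causally valid, nor how the method
behaves under strong cross-group collinearity (that is what the Pearson
screen is for).

A unit's planted group counts as *recovered* when it belongs to the
unit's dominant set under the default rule; at σ = 0 the stricter
condition (dominant set exactly equals the plant) is asserted.

## Numerical and degenerate-input conventions

* Equivalence classes are formed before ordering; members inherit their
  representative's level, rank and scores.
* Cycle detection in level assignment guards against invalid input
  relations (impossible for posets built in-package, checked anyway).
* A single-unit table ranks without error: one element, no relations,
  neutral scores of 0.5 in every group, all four groups co-dominant.
* Seed handling: one master seed feeds fixed per-generator substreams, so
  regenerating one artifact never perturbs another; the caller's RNG
  state is restored afterwards.
* All stochastic test assertions use explicit bounds (99 % binomial
  bands, 5-sigma binomial tolerances) rather than snapshot values.

## Problem sizes

The test suite exercises posets up to 8 elements against brute-force
oracles (500 random posets for reduction/levels/chains; exhaustive
linear-extension enumeration up to 8! permutations), 200 replicate
recovery scenarios of 20 units each, and grids up to 60 × 60 — sizes at
which every oracle is exact and the full suite runs in well under a
minute. Real county sets (≈ 50 units) are far below the package's
practical limits: poset construction is O(n²k) in units and indicators.

## Known limitations

* Rankings are sensitive to indicator selection and to extreme values —
  an outlier county can become isolated (as the worked example's ZLT
  does); this is surfaced, not suppressed.
* LPOM0 is an approximation away from chains/antichains; its error grows
  with interleaved incomparability, and the package intentionally does
  not claim exact mean ranks for large N.
* The dominance rule is one defensible operationalization of level-based
  reading; conclusions should be checked under `lpom_norm` and a nonzero
  `tie_tol`.
* No statistical significance attaches to a level or a dominance count;
  the method is descriptive.
* Grid I/O is plain-text Esri ASCII only, and grids are treated as
  planar — reprojection and geodesic corrections are out of scope.
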