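---
title: "Models and methods: multifarious tile self-assembly and nucleation-based classification"
author: "mfsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mfsa)
```

This vignette is the package's own account of the science it implements:
the free-energy model, the two nucleation estimators, the merge designer's
proofreading criteria, the pattern-recognition training loop, the
winner-take-all anneal model, and the fluorescence analytics — together
with the numerical choices, default parameters and fixture designs, and
what each of them does and does not establish.

## The free-energy model

A tile system is a set of square tiles, each with four glue labels (N, E,
S, W); a glue binds only its starred complement, and the null glue (the
empty string) binds nothing. A target shape is a layout assigning tiles to
lattice locations of a bounded canvas, with complementary glues across
every internal edge and null glues on every boundary edge.

The free energy of a partial assembly $A$ with $B$ bonds, in units of RT,
is

$$G(A) \;=\; \sum_{i \in A} G^i_{\mathrm{mc}} \;-\; B\,G_{\mathrm{se}} \;-\; \alpha,
\qquad G^i_{\mathrm{mc}} = \alpha - \ln (c_i/u_0),$$

where $c_i$ is the free concentration of tile $i$, $u_0$ a reference
concentration and $G_{\mathrm{se}} > 0$ the stabilising energy per matched
bond. All logarithms are natural (RT-unit convention). Defaults are
$u_0 = 1\,$M and $\alpha = 0$: $\alpha$ cancels in every free-energy
difference at fixed assembly size (and in the monomer $G$), and only
relative rates matter downstream, so absolute $G$ values are
convention-dependent and nothing in the package depends on them.

Attachment of the correct tile for a location by $b$ bonds changes the free
energy by $\Delta G = G_{\mathrm{mc}} - b\,G_{\mathrm{se}}$. The regime of
interest throughout is $G_{\mathrm{se}} < G_{\mathrm{mc}} < 2G_{\mathrm{se}}$:
one bond is unfavourable, two or more are favourable. Fixture studies use
the fixed values $G_{\mathrm{se}} = 11$ RT against a 50 nM base
concentration ($G_{\mathrm{mc}} \approx 16.8$), comfortably inside that
window, or the worked pair $G_{\mathrm{mc}} = 5$, $G_{\mathrm{se}} = 3$
whose barriers have closed forms.

Temperature dependence is available through per-domain standard enthalpy
and entropy: $G_{\mathrm{se}}(T) = (-\Delta H^\circ + T\Delta S^\circ)/(RT)$
with $\Delta H^\circ$ in kcal/mol. The defaults
($\Delta H^\circ = -80$ kcal/mol, $\Delta S^\circ$ solved so that one
domain contributes $-9$ kcal/mol at 53 °C, the usual SST design target)
give $G_{\mathrm{se}}(53\,^\circ\mathrm{C}) \approx 13.9$ RT. A fixed-$G_{\mathrm{se}}$
mode bypasses temperature entirely; it is the default for everything except
the anneal simulations.

## The Stochastic Greedy Model (SGM)

Nucleation rates are estimated by sampling greedy assembly pathways. A path
starts from the monomer at a chosen location and repeatedly adds one tile
adjacent to the current assembly:

* while any attachment has $\Delta G < 0$, the single most favourable one
  is made deterministically, ties broken by a fixed row-major location
  order;
* otherwise one unfavourable attachment is chosen at random with Boltzmann
  weights $e^{-\Delta G}$ (a linear weighting of the relative
  free-energy differences is available behind a switch, but the Boltzmann
  form is the thermodynamically natural reading);
* the path stops at full tiling, or once the running $G$ has fallen a
  margin (default 10 RT) below the running maximum — after commitment to
  downhill growth the barrier can no longer change — or at a configurable
  size cap.

Two phrasings of greedy growth ("all favourable attachments are added" and
"the most favourable attachment is made deterministically") are reconciled
by exhausting favourable attachments one at a time, most favourable first:
since favourable additions strictly lower $G$, the recorded barrier is
unaffected by their order.

The barrier of a path is the highest $G$ visited; the state at which it is
attained is the critical seed. Sampling `nPaths` paths from every start
site, the rate estimate applies the Arrhenius approximation with an
equilibrium occupation of each *distinct* barrier state $A_s$ (identical
seeds reached by different growth orders are deduplicated so they are not
double-counted):

$$\eta \;=\; \sum_{\text{distinct } A_s} e^{-G(A_s)}
\sum_{\text{attachments from } A_s} c_{\text{tile}}/u_0 ,$$

with forward kinetics second order in the attaching tile's concentration
and no per-tile rate constants. All sums are computed in log space; the
classifier compares `logRate` values, so underflow of $e^{-G}$ is
harmless. Paths are confined to one target layout at a time (the correct
tile for each location); chimeric growth is not sampled.

The estimator is validated against an independent exhaustive oracle: on
layouts of up to nine tiles the minimum achievable barrier (the minimax
over all single-tile-addition orders, computed by a Dijkstra-style search
over the lattice of connected subassemblies) is attained by SGM sampling
with 200 paths per start site, and sampling never reports a barrier below
the oracle minimum, for uniform and randomly perturbed concentration
patterns alike.

Each estimate also reports a participation map — per location, the
contribution-weighted fraction of the total rate carried by barrier states
containing that location — and the median barrier-state size $K$, the
length scale over which colocalization promotes nucleation. Raising
$G_{\mathrm{se}}$ (lower temperature) shrinks $K$: stronger bonds make
smaller seeds critical.

## The Window Nucleation Model (WNM)

The WNM is a fast proxy used inside training loops: for every $k \times k$
window of locations fully inside a shape, the weight is the equilibrium
Boltzmann weight of the fully assembled window,

$$w = \exp\Big( \sum_{i \in \text{window}} \ln (c_i/u_0) + B_w G_{\mathrm{se}} \Big),
\qquad B_w = 2k(k-1),$$

and the shape's score is the sum over windows. Windows never extend over
unoccupied canvas. The score is monotone increasing in every concentration
and exact closed forms exist for uniform patterns (for a $3\times3$ shape
at $k=2$: four windows of weight $(c/u_0)^4 e^{4 G_{\mathrm{se}}}$). The
window size plays the role of an assumed seed scale; $k = 2$ is the default
for classification on the fixtures, $k = 3$ for the anneal studies where
larger seeds are needed to discriminate colocalization from chance
clustering on a small canvas.

## The merge designer

The initial design gives every location of every shape its own tile, a
fresh binding domain for each internal edge, and null glues on the shape
boundary. Merging proposes two tiles from different shapes with null glues
on exactly the same sides (the stricter reading of side compatibility),
unifies their four glues side by side — complements are propagated through
a signed union–find over the domain labels, and a proposal that would force
a domain to equal its own complement is rejected — relabels every
occurrence system-wide, and canonicalises tiles whose four-glue signatures
have become identical. Merging within a single shape is not attempted, and
a merge that would make a tile occur twice in one layout is rejected.

A merge is accepted only if the modified system still satisfies both
proofreading criteria, checked against the full pooled tile set (errors may
come from any shape's tiles):

* **Self-healing**: for every location, against the glue constraints
  presented by *all* of its neighbours, every wrong tile matches at most
  one. Match counts are monotone under taking neighbour subsets, so the
  all-neighbours profile is the worst case and the check covers every
  correct subassembly.
* **Second-order sensitivity**: for every wrong tile that attaches by
  exactly one bond, no further tile can attach by two or more bonds at a
  neighbouring empty position using the error's presented glue plus correct
  neighbours — so a first error tends to fall off rather than be locked in.
  Only single-bond initial errors and immediate neighbours are considered;
  deeper error chains are out of scope.

Both checks are vectorised but are verified, on every fixture size used in
the tests, against naive exhaustive error-attachment enumerations written
independently in the test suite. The algorithm runs a chequerboard phase
first (proposals restricted to one $(row+col)$ parity, where merges are
most likely to be compatible), then a global phase; "exhausted" means every
currently eligible pair has been tried and rejected since the last accepted
merge, and each accepted merge resets that memory since acceptability is
context-dependent. Across restarts the minimum-tile-count system is kept.
Fully unique designs satisfy both criteria trivially, which is asserted as
a regression test.

## Images, the pixel map θ, and training

Images are standardised to a fixed size (30×30 for the full-scale problem)
by deterministic area-average resampling, then discretised to ten grayscale
levels $p = k/9$, $k = 0..9$, by intensity rank (ties broken by row-major
scan order) so that every image has exactly the same per-level pixel
counts. Rank-based discretisation makes the result invariant under
monotone transforms of the resampled image and idempotent on standardised
images; area averaging commutes with affine but not with nonlinear
transforms of the raw input, which bounds what the invariance covers.

The level histogram is not an external given, so the package freezes one as
part of its contract: level counts follow a geometric profile in the level
index — the unique ratio whose continuous profile has mean tile
concentration exactly 60 nM under the exponential map below — rounded by
largest remainder and minimally adjusted so the realised mean still rounds
to 60 nM. For 900 pixels the frozen counts are
254, 185, 135, 99, 72, 53, 38, 28, 21, 15; the same construction applies at
any pixel count, which is what the toy problems use.

A pixel map θ assigns pixels injectively to tiles; the ten levels map to
concentrations $c = 16.67\,e^{3p\ln 3}$ nM — geometric from 16.67 to 450 nM
(nearest nM) in steps of $3^{1/3}$. Tiles not set by any pixel are filled
at the base concentration, and reserved tiles (fluorophore/quencher label
locations, which must not vary in concentration) are drawn from that
unassigned pool first and are never assigned to pixels; a 917-tile system
under a 900-pixel image leaves 17 such tiles.

Training minimises, by strict hill climbing (moves: swap the tiles of two
pixels, or swap an assigned tile with an unassigned non-reserved one;
accept only strict improvements, so the loss trajectory is provably
non-increasing), a loss summed over training images:

$$\mathcal{L} = \sum_{\text{images}} -\Big( \log r_{\text{on}} -
\log \sum_{\text{off}} r_{\text{off}} \Big) \; + \;
\lambda_{\text{site}} (\text{participation outside preferred regions}) \; + \;
\lambda_{\text{rep}} (\text{reserved-tile violations}).$$

The exact heuristic used for the published map is not available in closed
form, so this softmax-margin form is the package's own documented stand-in
with every weight configurable (the site term defaults to off, with a
neutral weight map). It is validated behaviourally rather than by matching
loss values: restarted climbs attain the global optimum of a 6-pixel toy
problem enumerable by brute force (all 720 assignments), trained maps
classify all fixture training images at two images per class, and mean
training accuracy declines monotonically as the images per class grow from
one to six — the associative-memory capacity effect — averaged over ten
seeds at a fixed budget (400 steps × 3 restarts of the WNM phase; the
cached window evaluator makes a loss evaluation a single indexed sum per
shape). The WNM drives most steps; an optional SGM refinement phase
re-optimises from the WNM optimum under the more detailed model.

## Winner-take-all anneals

Temperature protocols are continuous piecewise-linear schedules; presets
reproduce the experimental programs (a 71→53 °C melt over 40 min, a
1 °C/h descent to the initial growth temperature, then 47 °C held for 51 h,
48→46 °C over 100 h, or 48→45 °C over 150 h, each ending with a cool to
39 °C at 1 °C per 26 min).

The competitive model is the package's own mean-field definition,
constrained to reproduce the qualitative behaviours expected of shared
resource pools rather than fitted to any time course:

* each shape nucleates at rate $\eta_s = k_{\mathrm{nuc}}\,\sigma(\log S_s)$,
  where $S_s$ is the shape's WNM score at the current temperature and free
  concentrations and $\sigma$ the logistic function — a saturating switch
  that turns on as the score crosses unity; nucleation shuts off entirely
  once any required tile falls below a floor fraction (default 1 %) of its
  initial concentration;
* every incomplete assembly grows at
  $g_s = k_{\mathrm{gro}} \langle \max(0,\, 1 - e^{\Delta G}) \rangle_{\text{sites}}$
  with $\Delta G = G_{\mathrm{mc}} - 2G_{\mathrm{se}}(T)$ — the net
  two-bond growth-front bias, zero exactly at the balance point
  $2G_{\mathrm{se}} = G_{\mathrm{mc}}$ and saturating at one;
* growth and nucleation consume tiles pro rata over the shape's layout
  (seeds cost `seedSize` tiles, default 3), by explicit Euler steps with
  per-shape throttling: each shape is limited by its own scarcest tile, so
  a shape that exhausts its pool cannot stall an independent competitor,
  while shared tiles throttle every shape that uses them. Free
  concentrations are clamped at zero and tile conservation
  (free + incorporated = initial) is tracked and asserted to numerical
  tolerance at every step; halving the step size changes final selectivity
  by well under one percent at the default `dt = 0.1` h.

Selectivity is on-target nucleation over total nucleation, reported as
undefined (NA) when nothing has nucleated. The rate scales
($k_{\mathrm{nuc}} = 5$ nM/h at saturation, $k_{\mathrm{gro}} = 20$
tiles/h per assembly in the studies) are chosen once so that depletion
completes within tens of hours at 50 nM pools — the regime where anneal
rate and growth rate are comparable, which is precisely where the
winner-take-all contrast lives.

The anneal study uses a dedicated paired fixture (`wtaStudySystems`): two
12×12 shapes assembling from the *same* 144 tiles in different
arrangements, versus a control pair with disjoint tile sets. The enhanced
(flag) tiles are contiguous in shape S1 and placed on a stride-3 sublattice
in S2 — a deterministic emulation of "scattered", needed because on a small
canvas random placement leaves dense patches by chance, whereas in a
hundreds-of-tiles system a 13-tile flag is sparse everywhere else by
counting alone. With $k = 3$ windows the on-target nucleation temperature
then sits a few degrees above the off-target one, the condition the
winner-take-all contrast presupposes. Under a 61→53 °C ramp, slowing the
anneal from 5 h to 50 h raises selectivity for the shared pair and lowers
it for the disjoint pair: with shared tiles, early on-target growth
depletes the common pool before the off-target window opens; with disjoint
pools, the on-target yield saturates at its own pool while off-target
nucleation keeps accumulating. These tile sets are abstract (null glues):
only arrangements and concentrations enter the window kinetics, which is
all the mean-field model consumes.

## Fluorescence analytics

Traces are normalised to their own maximum, making the entire pipeline
invariant to per-trace multiplicative constants. The quench time is the
first time the signal has dropped 10 % below its reference level, linearly
interpolated between samples; the reference is the running maximum by
default (robust to upward drift before the drop, and identical to the
global maximum whenever the maximum precedes the drop), with a global-max
switch. The estimator adds three robustness layers, each a no-op on clean
monotone traces: an edge-preserving running-median prefilter (default 7
samples), a sustained-crossing requirement (2 consecutive samples below
threshold, against single-sample dips), and a plateau refinement — when the
samples just before the provisional crossing still sit within half a
threshold of the running maximum, the plateau *median* replaces the noisy
maximum as the level estimate, removing the early bias that the maximum of
a noisy flat stretch otherwise introduces. The refinement deliberately
stands down for slow declines and rising drifts, where no plateau exists.

Growth time is the span from 10 % quenching to the end of the growth
segment, zero if quenching never occurs. Summaries average growth times
over each shape's labels, and report the on-target fraction (selectivity)
and per-shape fractions (ternary coordinates), defined as NA rather than
NaN when total growth is zero. The synthetic generator plants sigmoidal
quenches positioned so the true 10 % crossing equals the scheduled time,
with configurable depth, width, drift and multiplicative log-normal noise;
recovery is exact to within interpolation on noiseless traces and, at 2 %
noise and 30-minute sampling, within one sampling interval for at least
95 % of traces in the fixed-seed simulation study. Sampling intervals of
12 and 30 minutes are both supported.

## Problem sizes and what the fixtures do not show

All tests run on miniature analogues: chunky 12×12 letters (stroke width
4, with sizeable interiors, echoing mostly-filled large canvases), 6×6
letters for the merge fixtures (≤ 44 tiles, where exhaustive
error-enumeration oracles are feasible), solid blocks for window-count
checks, 4×4 toy images against the 60-odd-tile fixture for training, and
barrier oracles up to nine tiles. The two-sublattice fixture
(`variant = "checker"`) reproduces the architectural idea — shared tiles on
one chequerboard parity, shape-specific interaction tiles mediating their
binding, unique boundary tiles — but is *not* run through the proofreading
merge pipeline, and at this scale its shared pool is small, so flag windows
of size 3 (rather than the published 5×5) are used on the letter fixtures;
the 13/12-tile chequerboard counts of a full 5×5 window are checked on
solid-block fixtures where such a window fits. Passing at this scale
establishes the algorithms' correctness and the direction of every
qualitative effect, not quantitative agreement with any wet-lab system:
real data add sequence-dependent energetics, partial and mismatched
binding, assembly intermediates and imaging artefacts that are explicitly
out of scope. The published 24×24 three-shape layouts are treated as
optional input data — when placed under `inst/extdata/published/` the
design-total checks (tile, domain and sharing counts) run against them;
they are not bundled.

## Known limitations

* The SGM is irreversible within a path (no detachment); fully reversible
  kinetic simulations would refine barrier estimates but are out of scope.
* The WNM's fixed window size is an assumed seed scale; it switches on at
  temperatures that depend on $k$ through the bonds-per-tile ratio, so
  cross-$k$ comparisons of absolute onset temperatures are not meaningful —
  only pattern-to-pattern orderings at fixed $k$ are used.
* The mean-field anneal model has no spatial structure, no stochasticity
  in nucleation timing, and rate scales in arbitrary units; only ratios,
  orderings and trends are interpreted.
* The default per-domain ΔH°/ΔS° pins one design point (−9 kcal/mol at
  53 °C); with $\alpha = 0$ the model's absolute nucleation window need not
  coincide with any particular experimental window, and the anneal studies
  therefore place their temperature ramps around the model's own window.
* The training loss is a documented stand-in for an unpublished heuristic;
  its weights are configuration, not constants.
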