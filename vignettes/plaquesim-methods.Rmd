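---
title: "Models and methods behind plaquesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plaquesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquesim)
```

plaquesim studies how a cytolytic (oncolytic) virus spreads through a
spatially arranged, growing population of target cells, and when that
spread ends in eradication of the cells, extinction of the virus, or
coexistence. This vignette describes the models, the conventions and
numerical choices behind the implementation, and what the synthetic
experiments shipped with the package do and do not show.

## The agent-based lattice model

Cells live on an `N x N` grid; each spot is empty, holds an uninfected
(susceptible) cell, or holds an infected cell. Time advances in discrete
steps. In each step the grid is sampled `N^2` times sequentially, uniformly
with replacement, and the rule is applied to the evolving grid
(asynchronous update):

* a sampled **uninfected** cell attempts division with probability `R`: a
  destination is drawn uniformly from its eight Moore neighbors and the
  offspring is placed there only if the destination is inside the grid and
  empty (no retry). If no division was attempted, the cell dies with
  probability `D`.
* a sampled **infected** cell attempts transmission with probability `B`:
  a uniformly drawn Moore neighbor is infected only if it holds a
  susceptible cell; the source survives transmission (transmission is not
  coupled to lysis). If no transmission was attempted, the cell dies with
  probability `A`. Infected cells never divide.

Weights above one (used in wide parameter scans) are divided by
`max(1, R, D, B, A)`, which leaves all rate ratios — the quantities the
phase diagrams depend on — unchanged.

**Why action-before-death.** The two per-sampling draws could be combined
in several ways; the choice matters only when the weights are of order
one. With disjoint death/action windows, an infected cell performs on
average `B/A` transmission attempts over its lifetime, each succeeding
with probability at most one. In the near-critical corner `A` slightly
above `B` (around `B = 0.6`, where the classic plaque morphologies live),
`B/A < 1` makes the virus a subcritical branching process that dies within
a few tens of steps — no ring, no growth law, nothing. Attempting the
action first and applying death only to cells that took no action gives an
effective per-sampling death probability `(1 - B) * A` and an expected
`B / ((1 - B) A)` attempts per lifetime, which sustains front propagation
in that corner while reducing to the nominal rates `R, D, B, A` in the
small-weight regime on which all the analytic theory below is built. All
qualitative regimes (hollow ring, filled ring, disperse, concentric rings,
the long-run extinction/coexistence map) are reproduced under this
convention; the locations of regime boundaries in the near-critical corner
shift relative to a convention with a different effective death rate, so
classifications at specific legend-value parameter combinations from that
corner are convention-dependent. This is a known limitation.

Boundaries are hard walls: the destination is drawn among the eight
conceptual neighbor positions and the event silently fails off-grid, so
edge cells act more slowly, consistent with a physical wall. Centered
initial squares are shifted one spot toward the origin when parities
differ. All randomness comes from R's seeded generator; a run is a pure
function of `(params, init, seed)` and the tests assert bit-identical
reruns.

Two standard initial conditions mirror the two kinds of experiment: a
30-cell infected square inside a fully susceptible 300 x 300 grid (early
plaque growth), and a 5-cell infected square inside a 13-cell susceptible
square inside an otherwise empty grid (long-run dynamics, where both
populations can expand).

## Pattern and growth-law classification

Plaque morphologies are read off radial occupancy profiles: annuli of
width 3 spots around the infected centroid of the first snapshot. The
rules, with the package defaults
(`theta_detect = 0.05`, `theta_hollow = 0.2`, `theta_filled = 0.5`,
`theta_sparse = 0.2`, `theta_mix = 0.15`), are applied in order:
two infected annuli separated by a near-infection-free gap (each carrying
at least 5% of the infected cells) are concentric rings; a core emptied
below occupancy 0.2 under an infected rim is a hollow ring; a rim whose
infected fraction at least doubles the core's, over a predominantly
susceptible core, is a filled ring; interspersed infected and susceptible
cells with no rim contrast are the disperse pattern. The rim-contrast
requirement operationalizes "a ring encloses the core": without it, any
expanding mixture whose interior has relaxed to a low infected density
would masquerade as a filled ring.

Growth laws: quadratic growth of the infected count (linear `sqrt(I)`
against `t`) is the signature of a compact infected mass growing at its
surface; linear growth is the signature of an expanding ring of constant
thickness. The classifier fits both single laws and a
quadratic-then-linear changepoint model, compares residuals on the count
scale, and prefers the changepoint model only when it improves the summed
squared residuals by more than 10%. Because the founder block partially
dies off before expansion takes over, the series is trimmed to start at
its minimum — the growth law describes the expansion phase. Tests pin the
changepoint against a brute-force scan and check invariance under count
and time rescaling.

## The local-neighborhood ODE theory

Mass-action dynamics of one interaction neighborhood (a cell plus its
eight neighbors, carrying capacity `K = 9`):

$$\dot S = R S (1 - (S + I)/K) - D S - B S I / K, \qquad
  \dot I = B S I / K - A I.$$

With `D = 0` the coexistence equilibrium is `S1 = A K / B`,
`I1 = R K (B - A) / (B (R + B))`; it exists and the virus invades iff
`A < B` (`R0 = B/A > 1`). The form of the density-dependent division term
was fixed by requiring that these closed forms hold exactly; the tests
verify the right-hand side vanishes there to machine precision over
random parameter draws. `D` enters as a separate linear death term; every
reproduced experiment keeps `D = 0`.

The outcome predictor reads the spatial fate off the local equilibria:
`S1 < 1` (less than one uninfected cell per neighborhood) predicts target
cell extinction or low-level controlled persistence; `S1 > 1` and
`I1 > 1` predict uncontrolled coexistence; `A >= B`, or invasion with
`I1 < 1`, predicts loss of the virus. The concordance experiment
(`local_theory_concordance()`) samples the `(log10(R/B), log10(A/B))`
plane at `B = 0.5`, excluding bands of half-width 0.35 and 0.25 dex around
the loci `S1 = 1` and `I1 = 1`, and compares the prediction with the
majority outcome of 30 x 30 lattice runs. The sampling window
`[-2, 1] x [-2.5, 0.5]` covers all three outcome regions while keeping
the slowest dynamics resolvable within the 4000-step budget; at desk
scale (40 points, 10 seeds) the run takes well under a minute.

Integration uses `deSolve::lsoda` at relative tolerance `1e-8` with
states clipped at zero; stability at the coexistence point is read from
the Jacobian (real negative eigenvalues: monotone node; complex:
damped-oscillation spiral) and cross-checked against trajectory extrema.

## The stochastic metapopulation and its wave theory

The one-dimensional metapopulation holds `n` patches of capacity `k` with
per-patch rates: susceptible birth `r S (1 - (S + I)/k)` (clipped at zero
when a patch is over capacity), infection `beta S I / k`, deaths `a I`
and `d S`, and migration of either population to each adjacent patch at
rate `m/2` per cell (total outflow `m`; the chain has walls, so end
patches emigrate at half the interior rate — the symmetric per-neighbor
convention for migration to the two nearest patches). Simulation is an
exact
Gillespie direct method; per-patch total rates are maintained
incrementally and recomputed from scratch every 10^3 events, with the
worst discrepancy reported and asserted to be at round-off level. The
standard initial condition seeds the middle patch with `0.3 k` infected
and `0.7 k` uninfected cells and the five patches on each side with
uninfected cells at capacity.

The continuum limit of hopping at `m/2` per side is diffusion with
`D = m h^2 / 2` (`h` the patch spacing); a pure-migration simulation
verifies the constant through the measured front displacement. Front
speeds follow the pulled-front (linear-spreading) construction: the
susceptible wave invades empty space at `v_S = 2 sqrt(D_S (r - d))`, the
infected wave invades a medium holding `S_front` targets per patch at
`v_I = 2 sqrt(D_I (beta S_front / k - a))` (zero when the argument is
not positive; in particular the infection cannot advance into its own
equilibrium wake `S_front = a k / beta`). Equating the two speeds gives
the co-moving front density `H = k (a + (r - d) D_S / D_I) / beta`,
reducing to `k (a + r) / beta` in the symmetric case. `H < 1` separates
virus-mediated joint extinction (the infected wave destroys the
target-cell wave mid-domain) from boundary-mediated extinction (the waves
travel together until the wall). These closed forms are reconstructions
from the standard linear-spreading theory; the tests validate them
empirically — measured front speeds approach the predictions from below
as `k` grows (within 20% at `k = 400`), as expected for fluctuating
pulled fronts — and pin `H` against a bisection root of `v_S = v_I`.

Empirical front tracking uses the outermost patch at half capacity with
linear interpolation, and a least-squares slope of position against time;
profile windows are chosen to end before the front reaches the wall.

Outcome labels mirror the lattice: joint extinction before/after the
target-cell wave touches an end patch (boundary contact deliberately
tracks the susceptible population — infected cells also random-walk into
the walls while dying out, which carries no information about the cell
wave); virus extinction with or without a prior four-fold rise of the
infected total; survival with broad (at least 40% of patches) versus
sparse occupancy separating true coexistence from persistence through
splitting fronts.

## Phase scans and overlay lines

Scans tally outcome labels over a grid in the ratio plane with the
transmission rate fixed at a reference value, with per-point,
per-replicate seeds derived deterministically from one master seed
(bit-for-bit reproducible). Overlay lines come from the closed forms:
`S1 = 1` is horizontal at `log10(A/B) = -log10 K` (about -0.954 at
`K = 9`), `I1 = 1` satisfies `A/B = 1 - (R/B + 1)/(K R/B)`, and the
metapopulation green line is `k (a + r) / beta = 1`. The invasion
threshold has no closed form; it is bisected along `A/B` for the smallest
ratio at which the four-fold invasion frequency drops below 5%. Desk-scale
defaults (12 x 12 points, 10 replicates, 30 x 30 grid) keep a scan in
minutes; the full-scale preset raises resolution and replicates.

## Fitting the simulator to counts

Observed plaques are converted from fluorescence areas to cell counts by
dividing the mean plaque area by the mean single-cell area; replicate
measurements propagate to a standard deviation via relative errors in
quadrature. The fit minimizes the unweighted sum of squared differences
between observed counts and the predicted mean infected series (an
average over simulator replicates, linearly interpolated from steps to
days through a steps-per-day factor that can be fitted or pinned).

Common random numbers — per-replicate seeds fixed across objective
evaluations — make the objective a deterministic function of the
parameters, so a derivative-free search is usable: multi-start
Nelder-Mead on log-parameters, followed by degeneracy probes that restart
from the best point with each parameter displaced threefold (at most two
rounds). The fit is flagged non-identifiable when any endpoint lies
within 5% of the best residual sum plus the objective's Monte-Carlo noise
floor (`2 * sum(sd_i^2) / replicates`, below which residual sums are
statistically indistinguishable) at parameters differing by more than
10%. Infected-count series over a short growth window genuinely do not
pin down all three rates — notably the division rate, which acts mostly
behind the front — and the self-consistency experiment at
`(R, B, A) = (0.2, 0.5, 0.1)` reproduces exactly this degeneracy: the
transmission rate recovers well while distinct `(R, A)` combinations fit
equally well, raising the flag. The desk default is 100 simulator
replicates per evaluation on a 60 x 60 grid; a full-scale switch raises
the averaging to 1000.

## Synthetic data

All fixtures are synthetic and generated in code: parametric geometric
snapshots (annuli and mixtures) with known labels, simulator-generated
count series with optional Gaussian measurement noise emulating
replicate area-measurement error, and translated logistic front profiles
with known speed. They emulate the *geometry* and *sampling noise* of
fluorescence-derived plaque data, not its biology: no segmentation
artifacts, no anti-viral host responses, no heterogeneity between foci.
Passing tests therefore demonstrate internal consistency of the models
and classifiers and reproduction of the theory's predictions at desk
scale — not agreement with any particular experimental culture.

## Problem sizes and limitations

The shipped experiments use desk-scale sizes chosen to make every claim
checkable in minutes: 20 seeds for pattern majorities on the 300 x 300
grid, 40 concordance points with 10 seeds on 30 x 30, 10-seed regime
galleries, 3-seed front-speed averages at `k <= 400`, and 100-replicate
fit objectives. Known limitations: the event-scheme convention above;
pattern thresholds are heuristics exposed in `pattern_thresholds()`;
the outcome of near-line parameter points is genuinely ambiguous at small
grid sizes; and stochastic front speeds sit systematically below the
deterministic predictions, so the 20% agreement band is one-sided in
practice.
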