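---
title: "Methods: free-energy reconstruction and ring-puckering analysis in ringpmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy reconstruction and ring-puckering analysis in ringpmf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringpmf)
```

`ringpmf` analyses reaction trajectories of glycoside hydrolase
bond-cleavage events along two axes: the free-energy profile over the
glycosidic-bond reaction coordinate, and the conformational itinerary of
the substrate sugar ring. Because converged QM/MM sampling of a solvated
enzyme is far beyond desk scale, the package pairs the analysis machinery
with a synthetic generator whose statistical structure matches what the
analysis assumes; the generator's landmark values are free-energy
features reported for an inverting cellulase mechanism, so recovering
them end-to-end validates the whole chain. This vignette documents the
models, the parameter choices, and what the validation does and does not
demonstrate.

## 1. Umbrella sampling and WHAM

The free-energy profile G(ξ) along a reaction coordinate ξ (here the
C1–O4 glycosidic distance, called RC2 throughout; larger values mean a
more dissociated bond) is estimated from `M` harmonically restrained
windows with bias

$$w_j(\xi) = \tfrac12 k_j (\xi - c_j)^2 .$$

Both the generator and `wham()` use the ½-inclusive convention; the force
constant is quoted as `k` in kcal/mol/Å². Because both conventions
circulate, `wham(half_k = FALSE)` switches to $k(\xi-c)^2$ — the test
suite checks that `k` under one convention equals `k/2` under the other.

`wham()` iterates the standard self-consistency equations (see
`?wham` for the exact formulas) on a fixed grid of `bin_width` 0.02 Å,
until the largest change in any window offset $F_j$ is below
`tol = 1e-7` in units of $k_BT$ ($k_B$ = 0.0019872041 kcal/mol/K,
T = 300 K by default, the usual production MD temperature). On the
default dataset this converges in a few thousand iterations, well under
`max_iter = 1e5`. The density is normalised to unit integral before the
log transform and the profile anchored to zero at its minimum over
populated bins.

Two deliberate strictness choices:

* **Connectivity.** If an interior bin between the first and last
  populated bins is empty, `wham()` raises a connectivity error naming the
  gap rather than bridging it by interpolation. A gap means the windows do
  not overlap there, and silently bridging it would hide undersampling
  exactly where the profile is least reliable.
* **No multidimensional WHAM.** Only the 1-D profile along RC2 is
  reconstructed. In the motivating mechanism several auxiliary coordinates
  (proton transfers, nucleophile approach) advance together with RC2; free-energy
  profiles for this reaction are conventionally reported one-dimensionally
  in RC2, and the generator likewise parameterises everything by RC2.

`direct_histogram_pmf()` — plain Boltzmann inversion of a histogram — is
kept as a first-class function because it is the natural independent
oracle: on unbiased samples WHAM must reduce to it (the suite requires
agreement below 0.05 kcal/mol per bin, and observes ~1e-10).

### Landmarks

`landmarks()` locates the reactant minimum, the interior maximum and the
product minimum, each refined by a parabola through the extremal bin and
its two neighbours. The refinement is exact for locally quadratic
profiles; where the second derivative jumps across a stationary point
(as at the surrogate's nodes, where a harmonic wall meets a spline
segment) it carries an O(bin width) bias of a few mÅ — negligible against
the 0.05 Å tolerances used for position recovery, which is why the exact
grid test asserts positions to 5 mÅ rather than machine precision.
A profile that rises monotonically after a single well has no interior
maximum and is reported as an error, not as a boundary landmark.

### Profile spread

`profile_sd()` computes the RMS pointwise difference between two profiles
over a stated RC2 range, after re-anchoring each at its own minimum
(optionally restricted to an anchor window). Both the comparison range and
the anchoring are explicit parameters because a "standard deviation
between two profiles" is meaningless without them; the package's own
reproducibility check uses the transition-state-to-product range
[2.17, 3.2] Å, where profiles from independent runs are observed to agree
within a few tenths of a kcal/mol — comfortably inside the ~1 kcal/mol
run-to-run spread typical of umbrella-sampling campaigns of this size.

## 2. The landmark surrogate and its sampler

`surrogate_potential()` interpolates the landmark table
(1.5 Å, 0) – (2.17 Å, 19) – (3.2 Å, 5) kcal/mol with cubic Hermite
segments of zero slope at every node, so the listed positions are exact
stationary points, plus harmonic walls (100 kcal/mol/Å²) beyond the outer
nodes. Energy and first derivative are continuous everywhere; the
gradient is analytic (checked against central differences to 1e-6).
Of the reported pair of reaction free energies (5 and 4 kcal/mol, from
two independent profiles of the same campaign), the product node uses 5 kcal/mol, the value paired
with the 19 kcal/mol barrier of the primary profile.

`langevin_sample()` integrates overdamped (position) Langevin dynamics on
the biased surface with an Euler–Maruyama step. The stationary
distribution of the exact dynamics is the Boltzmann density of the biased
potential — precisely the assumption WHAM inverts — so the dynamical
parameters only need to mix well, not to model real kinetics. One
integration step is calibrated to 0.001 ps, so the default
`n_equil = n_prod = 10000` mirrors a 10 ps equilibration + 10 ps
production window protocol; `dt = 0.1`, `D = 0.001` satisfy the stability
bound `dt·D·(k + max U'')/kBT < 0.5` for the stiffest default restraint
(k = 500 kcal/mol/Å², the bond-breaking/forming value; 100 is the
value conventionally used for the softer proton-transfer coordinates).

**Discretisation bias.** For an Ornstein–Uhlenbeck process the
Euler–Maruyama stationary variance exceeds $k_BT/k$ by the factor
$1/(1 - a/2)$ with $a = Dk\,dt/k_BT$: about 4.4% at the default
`dt = 0.1` with k = 500. This slightly softens the recovered profile (the
observed barrier underestimate of ~0.1–0.2 kcal/mol is well inside the
1 kcal/mol recovery tolerance), and it is why the stationary-variance
property test integrates at `dt = 0.05`, where the predicted inflation is
~2%: the property under test is the Boltzmann limit, not the O(dt) error
of one integrator setting. The default `dt` is kept at 0.1 because halving
it doubles runtime for no benefit to the landmark recovery the defaults
are sized for.

`generate_umbrella_dataset()` spaces 42 window centres evenly over
[1.3, 3.5] Å. The window count follows the QM/MM campaign the generator
emulates; the range and spacing are not constrained by it and are a stated
assumption wide enough to bracket both minima. Per-window sub-seeds are drawn once
from the master seed via `sample.int()` rather than by adding the window
index to the master seed: with additive sub-seeds, two datasets generated
under adjacent master seeds would share almost all of their noise streams
window-for-window, which would artificially correlate two "independent"
profiles and invalidate the two-seed spread check. Drawing the sub-seed
vector once keeps the dataset a pure function of (parameters, seed) and
keeps windows independently regenerable in any order.

## 3. Cremer–Pople analysis

Ring atoms are taken in the order O5, C1, C2, C3, C4, C5. The mean plane
is the Cremer–Pople construction (not a least-squares plane), with its
normal oriented so that a ring traversed in atom order counterclockwise
gets the +z normal; under this convention θ = 0 is the ⁴C₁ chair and
θ = 180 the ¹C₄ — the common carbohydrate convention. The same mean plane
is reused by `ring_plane_angle()`, so axial/equatorial calls about, e.g.,
the leaving-group bond are consistent with the puckering analysis.

Absolute φ depends on the atom-numbering origin and the sign convention
of the sine sum; other codes may differ by a fixed offset or reflection.
Conformer *names* are therefore the comparison surface across software,
and the canonical table is defined in the package's own convention: the
38 vertices (2 chairs, 6 boats and 6 skew-boats on the equator every 30°,
12 envelopes at θ = 54.74°/125.26° interleaved with 12 half-chairs at
θ = 50.77°/129.23°) were derived by projecting ideal displacement
patterns — e.g. the two-up boat pattern (−½,−½,1,−½,−½,1) for ²,⁵B, the
one-atom flap (5,−1,…,−1) for an envelope — onto the q₂/q₃ modes. The
test suite regenerates table entries from such ideal geometries and
checks that, e.g., ¹S₃ lands at (θ = 90°, φ = 210°) with zero geodesic
distance.

Classification is nearest-vertex by great-circle distance, ties broken by
table order; no region polygons are drawn on the sphere, since Stoddart-diagram
region boundaries in the literature are qualitative. Rings with
Q < 0.1 Å are labelled `"planar"` — θ and φ are numerically unstable as
the amplitude vanishes, and 0.1 Å is far below the 0.4–0.6 Å amplitudes
of real pyranose rings, so the threshold never fires on meaningful data.

## 4. The synthetic conformational path

`pucker_path()` anchors the itinerary at
(rc2 = 1.5 Å, ¹S₃, Q = 0.57 Å) → (2.17 Å, ²,⁵B, Q = 0.45 Å) →
(2.8 Å, ⁴C₁, Q = 0.57 Å), joined by great-circle arcs. The transition
state's lower amplitude reflects the flattening of the ring toward the
oxocarbenium-like geometry (partial C1–O5 double bond); it is a modelling
choice, not a literature value. Progress along each arc is warped by a
symmetric logistic (sharpness 12), so the conformation dwells near the
anchors and switches over a narrow rc2 interval — matching the observed
behaviour that the Stoddart projections change sharply near the
transition state rather than drifting linearly. Because the warp is
symmetric, the rc2 midpoint of two anchors still maps to the geodesic
midpoint, equidistant from both.

Noise is applied isotropically on the sphere: the path point is rotated
by an angle drawn from N(0, 8°) about a random perpendicular axis, and Q
is jittered by N(0, 0.03 Å). Perturbing θ and φ independently instead
would inflate the φ noise near the poles, biasing chair-region labels.
With these defaults the majority conformer in the reactant
(1.5–1.8 Å), transition-state (2.0–2.3 Å) and product (2.4–3.2 Å)
regions is ¹S₃, ²,⁵B and ⁴C₁ respectively, with majorities around
80–90%; the minority labels are the adjacent vertices on the sphere
(B₀,₃-side boats in the reactant region, ²E envelopes near the product
descent), as expected for a path that passes close to them.

## 5. What the synthetic validation shows — and what it cannot

The end-to-end check (generate → WHAM → landmarks) recovers the barrier
to ±1 kcal/mol, positions to ±0.05 Å and the reaction free energy to
±0.5 kcal/mol under the default problem size (42 windows × 10⁴ production
steps, ~1 minute on one CPU; the two-seed reproducibility check doubles
this). That validates the estimator chain: biasing, histogramming,
self-consistent unbiasing, anchoring and landmark refinement, on data
with realistic window overlap and autocorrelation.

It does not validate anything about real QM/MM data generation: the
surrogate is one-dimensional, its noise is a single overdamped timescale
(no slow orthogonal degrees of freedom, no hysteresis between forward and
reverse window initialisations), the ring generator produces ideal-radius
rings with isotropic angular noise (no coupling between puckering and
substituent sterics), and nothing in the package evaluates quantum or
molecular-mechanical energies. Landmark recovery from the surrogate says
the analysis would faithfully summarise a converged campaign; it says
nothing about whether a given campaign is converged.

## 6. Degenerate inputs and numerical edges

* Planar rings (Q ≈ 0): valid `cremer_pople()` result with θ, φ = `NA`;
  collinear rings are a geometry error.
* φ is reported in [0, 360); values within 1e-9 of 360 wrap to 0.
* `landmarks()` refuses windows with no populated bins, a product minimum
  at or before the reactant minimum, and profiles without an interior
  maximum.
* `langevin_sample()` rejects parameter sets violating the explicit
  stability bound instead of silently diverging; `D = 0` is allowed and
  gives the deterministic drift-free fixed point used in tests.
* All generators are pure functions of (parameters, seed); they save and
  restore the caller's RNG state.

## 7. Pipeline artifacts

`run_pipeline()` stages write TSV artifacts with `#`-prefixed headers
(units fixed to Å and kcal/mol, 0-based frame indices) and JSON for
landmarks and configuration; every artifact carries the package version,
a hash of the scientific configuration (artifact paths excluded, so
relocating a run does not change its identity) and the master seed.
Configurations are validated against the known-key schema before any
stage runs, and unknown keys are rejected loudly.
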