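---
title: "The toothwave model: kinetics, regimes, and detection conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The toothwave model: kinetics, regimes, and detection conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(toothwave)
```

## The biological picture

Mouse molars are patterned sequentially along the anteroposterior axis of a
posteriorly growing strip of dental epithelium. Activation (read out by
*Edar* expression) first spreads broadly through newly grown tissue and only
later restricts to a focal signaling center. Two early centers (MS, R2) are
transient: each is overrun ("erased") by the next broad activation wave,
after which the pattern re-forms — R2 recovers next to the newly formed
early-M1 center, and in the lower jaw the two subsequently fuse into one
large center. `toothwave` implements a one-dimensional
reaction–diffusion model of this sequence and the analytics needed to detect
and classify its pattern events.

## Model

Two fields live on the growing interval `[0, L(t)]` (anterior at `x = 0`):
an activator `a` and its faster-diffusing inhibitor `i`,

$$\partial_t a = D_a\, a_{xx} + Q(a)\, a (1-a)\,\bigl(a - \theta_0 - \gamma i\bigr) + F_{mes}(x,t),$$
$$\partial_t i = D_i\, i_{xx} + \phi(\rho)\, \frac{b\, a^2}{(K_i^2 + a^2)\,(1 + q_{auto}\, i)} - d_i\, i.$$

The activator kinetics are a cubic autocatalysis between an inactivated
state `a = 0` and an activated state `a = 1`; the inhibitor raises the
activation threshold `theta0 + gamma*i` (repression), while the activator
drives inhibitor production through a saturating (Hill) term. The
self-regulation strength `Q(a)` switches smoothly from `Q_l` below the
unstable intermediate state to `Q_h` above it; `Q_h > Q_l` makes the
activated state the more stable one and turns the interface between the
states into an invading wave.

`q_auto` — the inhibitor's negative feedback on its own production — is the
single parameter distinguished by tissue maturity: immature tissue uses
`q_bistable`, mature tissue `q_turing < q_bistable`. With strong
auto-inhibition the inhibitor stays low and the kinetics are bistable (two
stable uniform states, traveling fronts). When maturation lowers `q_auto`,
inhibitor production rises steeply with activation and the same kinetics
support patterning: a homogeneous intermediate state becomes unstable to a
band of finite wavenumbers (a Turing instability, see
`dispersionRelation()`), broad activated plateaus collapse, and localized
activator peaks of a self-selected width are the stable structures. The
`mutant_scale` factor lowers both `q_auto` values together; values below 1
mean *less* auto-inhibition, hence *more* inhibitor — the
loss-of-function situation in which the wave is suppressed and the first
center forms late and posteriorly.

Three slower layers close the model:

* **Maturation** `m` grows exponentially at a slow baseline rate and is
  boosted where the activator exceeded a threshold a delay `tau` earlier
  (ring-buffer history with linear interpolation; pre-history equals the
  initial condition). Where `m` reaches its threshold the cell's regime
  flag flips irreversibly from bistable to Turing.
* **Mesenchymal priming**: a posterior reservoir `s` charges while the
  posterior window is inactive and is released as an activator source where
  local activation is below a low threshold; above a high threshold a mild
  direct sink applies. Episode termination is dominated by the
  maturation-triggered regime switch (the mature inhibitor crashes the
  activated plateau), which together with the recharge time and the
  inhibitory lock of the last-formed peak produces the periodic posterior
  activation.
* **Cell density** `rho` (optional) obeys a Keller–Segel equation
  `rho_t = D_rho rho_xx - (chi rho a_x)_x`: cells drift up activator
  gradients. Crowding feeds back by down-regulating inhibitor production
  through `phi(rho)`, a multiplier equal to 1 at the reference density,
  suppressing at the full `feedback_strength` above it and only weakly
  releasing below it (a cell-mediated suppression saturates once the cells
  are gone). This asymmetry matters: a symmetric response boosts inhibitor
  production exactly in the depleted gap between two peaks and blocks their
  fusion.

## Canonical parameterization

The published description of the model fixes the scenario inputs (domain
lengths 2.6 and 3, chemotaxis levels 0, 0.1, 0.5) and the qualitative
behaviors; the reaction constants themselves are this package's own
calibration, chosen once, by construction, to satisfy the model's stated
structural properties:

* `theta0 = 0.1`, `gamma = 1.2`, `q_bistable = 3/4`: with the immature
  inhibitor equilibrium `i1 = 2/3` at `a = 1`, the two uniform states have
  *exactly* equal leading Jacobian eigenvalues (`-Q theta0 = -0.19`); this
  is the symmetric configuration in which fronts between the states are
  stationary.
* `K_i = 1.0547` (Hill half-saturation of inhibitor production, with
  `b = d_i (1 + K_i^2)` so the normalized drive reaches 1 at full
  activation): tuned by a one-dimensional root-find so that the *measured*
  PDE front speed of the symmetric configuration vanishes (the residual is
  below 0.3% of the reference Nagumo speed). The Hill saturation bends the
  slaved threshold curve into balance without touching the eigenvalue
  symmetry.
* `q_turing = 0.1`: in the mature regime an interior homogeneous state
  exists, is stable to uniform perturbations and unstable to a band of
  wavenumbers with fastest mode `k_max ≈ 5.4` (wavelength ≈ 1.17, matching
  the two-peak geometry of the length-2.6 domain); the uniform activated
  state is unstable (`theta(i_eq) ≈ 1.3 > 1`), so broad mature plateaus
  collapse into localized peaks.
* `d_i = b/(1+K_i^2) = 4`: the inhibitor relaxes several times faster than
  the activator; slower inhibitors produce oscillatory overshoot that
  destroys the localized peaks.
* `D_a = 0.0034`, `D_i = 0.4`: front interface width ≈ 0.05 (about six
  grid nodes at the default `dx = 2.6/300`) and inhibitor range ≈ 0.3,
  giving stable peaks of width ≈ 0.5 and spacing ≈ 1.1–1.2.

Growth, maturation and mesenchyme rates (`growth_speed = 0.02`,
`baseline_rate = 0.002`, boost 0.25 with delay 8, priming gain/relaxation
0.05) were chosen so that one activation episode matures into one peak
before the next episode ignites, giving sequential peak addition with
spacing near the Turing wavelength.

Two presets deviate from the canonical values, in line with the model's own
sensitivity analysis. The palimpsest scenario (`fig3_palimpsest`) raises
`q_bistable` to 8 and slows maturation (boost 0.1, delay 15): stronger
immature auto-inhibition weakens both the self-limiting inhibitor plume the
wave pushes ahead of itself and the halo of the established anterior
center, which is precisely the regime in which the wave can reach and erase
it. It also starts from an established, matured anterior center
(`init$mode = "anterior_peak"`), the configuration the palimpsest is about.
The mutant preset differs from it in `regimes.mutant_scale = 0.5` only
(machine-checked by `configDiff()`).

## Numerics

Second-order central differences with ghost-node no-flux boundaries; IMEX
time stepping (implicit diffusion by a Thomas tridiagonal solve — which
conserves mass exactly for the no-flux Laplacian — explicit reaction and
upwind conservative chemotactic advection), with a fully explicit scheme as
a cross-check; an R-level reference step (`stepState()`) is tested to agree
with the compiled explicit path to 1e-12. Growth appends whole cells at
fixed `dx` when a fractional accumulator fills (apical growth, not domain
dilation); new cells start at the low state, immature, bistable. Negative
field values beyond -1e-12 abort the run; smaller excursions are clipped to
zero and counted. Symmetry breaking for Turing onset uses a seeded uniform
perturbation of relative amplitude 1e-3, making every run reproducible from
its configuration.

Default problem sizes: 300 nodes for the length-2.6 fixed-domain runs
(531 for the 3.4-length growing runs), `dt = 0.005` (5e-4 with chemotaxis,
limited by advection), horizons of 100–600 time units per scenario. These
resolutions put the self-convergence error of final peak positions below
half a node and leave the event-type multisets of the growing-domain
scenarios unchanged under halving `dt` and `dx` (both checked in the test
suite).

## Detection conventions

The analytics operationalize terms the biology leaves qualitative; the
conventions are the package's own:

* A **peak** is a connected region with activator above `theta_peak = 0.5`
  (the midpoint of the two uniform states) at least `4 dx` wide.
* Peaks are tracked frame-to-frame by support overlap; a new track becomes
  a **birth** after persisting 20 frames. Objects present from the first
  frame are initial conditions, not births.
* An object wider than `broad_width = 1.3` (comfortably above one pattern
  wavelength) is a **broad activation front**, not a peak. When it overruns
  a peak the merge is logged as a **front passage** (with the front's
  fitted speed, positive anteriorly) together with the **erasure** of the
  overrun center — the restricted pattern it formed has ceased to exist.
* A merge of two peak-like objects is a **fusion** if the merged object
  persists 20 frames; if it dies earlier its confirmed constituents are
  logged as erased. A merge is therefore never double-logged.
* A birth whose support comes within `site_tolerance = 0.5` (about half a
  pattern wavelength) of an erased support is a **recovery**: two centers
  closer than half a wavelength occupy the same slot of the pattern. In the
  palimpsest scenario the re-formed anterior center sits about 0.2–0.4
  posterior of the erased one; treating it as the recovered center matches
  the phenomenology the scenario models.

## What the synthetic data do and do not show

All inputs are generated: scenario presets build their initial conditions
in code, and `makeProfileFixture()` / `makeChronogramFixture()` provide
profiles and space–time records with ground truth known by construction
(bump centers, imposed front speeds) for testing the analytics without the
solver. Passing tests therefore demonstrate the internal consistency of the
model and its analytics under the stated conditions — peak counts, event
grammars, oracle agreements — not agreement with measured expression
patterns: the model is one-dimensional, treats the mesenchyme as a scalar
posterior reservoir rather than a tissue, imposes the regime switch through
an explicit maturation threshold, and its time and length units are
nondimensional.

## Known limitations

* The palimpsest requires its own immature auto-inhibition level; with the
  canonical `q_bistable = 3/4` the anterior center's inhibitor halo always
  stalls the wave. The model shares this sensitivity ("suitable
  synchronization" of growth, priming, wave speed and maturation) with the
  biology it abstracts.
* Recovery of the erased center is positional only to within about half a
  wavelength (see above); exact same-site recovery does not occur because
  the re-patterning treats the erased zone's boundary as its edge.
* Fusion requires a strong, saturating density feedback
  (`feedback_strength = 6`); weaker feedback fattens the two peaks into a
  stable pair with a gap that never closes.
* The posterior oscillation is spatial: one activation episode per stretch
  of newly grown, unlocked tissue. A zero-dimensional reduction of the
  activator/mesenchyme pair does not oscillate — the fast, slaved
  inhibitor (needed for stable localized peaks) leaves a single node
  parked at an interior balance point after its first ignition.
* Event tracking assumes the anterior-aligned grid of the growth model;
  chronograms from other sources must share that convention.
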