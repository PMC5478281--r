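---
title: "Methods: axon shaft zippering, from single vertices to network coarsening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axon shaft zippering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonzipper)
```

## The physical picture

Axons growing on a planar substrate adhere to each other along their
shafts. Where two axons (or fascicles) share an adhered segment, the three
segments meet at a mobile *zipper vertex*; its advance fasciculates the
pair, its recession defasciculates them. Two forces compete. The effective
tension `T` of each axon — axial tension combined with axon–substrate
adhesion, measured in nN (equivalently nJ per metre of axon) — penalizes
total length and pulls the vertex back. The axon–axon adhesion `S`, an
energy per unit zippered length (also nN), rewards zippered length and
pulls the vertex forward. Their ratio sets the equilibrium zipper angle
`beta` between the free segments:

\[ S = 2T\left(1 - \cos\tfrac{\beta}{2}\right). \]

Everything in this package is a consequence of this balance, its
asymmetric generalization, and the dissipative dynamics around it.

### Assumptions

* Segments are straight between anchor points (tension keeps them taut);
  mechanical stress is uniform along each axon.
* Bending rigidity at the vertex is neglected (for single axons and thin
  fascicles its energy density is an order of magnitude below the tensile
  one); the dissipative cost of bending rearrangements is absorbed into
  the empirical vertex friction instead.
* Tensions are constant in time during a single zippering transient
  (no active tension regulation), and constant along the axon (no Hookean
  length dependence within a configuration).
* The fixed points A, B, C do not move during a vertex relaxation; moving
  anchors (loop collapse) are handled at the network level.

## Statics

`config_energy()` implements
\(E = T_1(|VA|+|VC|) + T_2(|VB|+|VC|) - S\,|VC|\);
`vertex_force()` is its exact negative gradient
\(\vec F_v = T_1\hat a + T_2\hat b + (T_1+T_2-S)\hat c\)
(unit vectors from V toward A, B, C). Equilibria solve
\(-(T_1+T_2-S)+T_1\cos\alpha_1+T_2\cos\alpha_2=0\) with
\(T_1\sin\alpha_1 = T_2\sin\alpha_2\). `equilibrium_angles_asymmetric()`
reduces the pair to one equation by eliminating `alpha2` through the
transverse balance and solves it by bracketed root finding on
\(\alpha_1\in(0^\circ,90^\circ)\) — deterministic, no starting-point
dependence, residuals at machine precision.
`find_equilibrium_vertex()` minimizes the energy with the analytic
gradient and polishes the root of \(\vec F_v=0\) by Newton iteration.

Two boundary regimes are returned as first-class states rather than
errors, so network-level callers can react:

* `S >= 2T` (symmetric case): no open equilibrium; `is_full_zippering()`
  is true and, dynamically, the vertex runs to the straight A–V–B
  configuration (`beta` → 180°).
* adhesion too weak for the local geometry: the minimum sits at `V = C`
  with zero zippered length (state `"zero_zipper"`); dynamically the
  adhered segment shrinks to nothing and the axons separate
  (`"detached"`).

The orientation convention matters: the zipper *advances* by moving the
vertex away from C, so a vanishing `|VC|` means detachment, not full
zippering.

## Dynamics

The vertex is overdamped: \(\vec F_v = \overleftrightarrow H(x,y)\,\vec u\).
`assemble_friction_tensor()` builds \(H\) from three mechanisms, each a
positive semidefinite quadratic form in the vertex velocity:

* **Elongation viscosity** `eta_elong` (nN·s): viscous axial stress
  \(\eta_\Updownarrow \dot L/L\) per axon, giving
  \((\eta_\Updownarrow/L_i)(\hat a+\hat c)(\hat a+\hat c)^T\) terms, with
  `L_i` the axon's full free length including its zippered share.
* **Vertex-localized friction** `eta_Z` (nN·s/μm ≡ 10⁻³ N·s/m): rank-one
  along the zipper axis, geometry independent; models the
  bending/unbinding losses concentrated at the moving vertex.
* **Substrate friction** `eta_par`, `eta_perp` (Pa·s): a Rayleigh
  dissipation density along every segment under a linear velocity profile
  (zero at the fixed point, vertex velocity at V), which integrates to
  \((\ell/3)(\eta_\parallel \hat t\hat t^T + \eta_\perp(I-\hat t\hat t^T))\)
  per segment. The exact interior velocity field of a pivoting taut
  segment may carry additional geometric factors; the linear profile is
  the stated contract and is cross-checked against numerical quadrature
  in the tests.

For mirror-symmetric zippers this reduces exactly to
\[\dot y = \frac{S - 2T(1-\cos\beta/2)}
               {2\eta_\Updownarrow(\cos\beta/2-1)^2/L + \eta_Z},\]
and the general simulation reproduces that 1-D integration to sub-0.1 μm
(tested).

### Numerical choices

`simulate_zipper()` uses an explicit Euler step with three guards: a
displacement cap (0.2 μm per step), energy-guarded adaptive halving (the
configuration energy is a Lyapunov function whenever the mechanics are
constant; a step that raises it is rejected and retried at half the step),
and geometric step growth once any tension/adhesion protocol has ended.
Because the force residual at the stated speed threshold
(`stop_speed = 1e-5` μm/s) scales with the friction magnitude, the
integrator finishes with a *Newton snap*: when the speed criterion is met
and the exact equilibrium (recomputed independently) lies within 0.05 μm,
the trajectory is terminated on it. The remaining displacement is far
below anything measurable, and the terminal force residual is then below
1e-6 nN in all three friction regimes — the property the tests assert.

When no substrate friction is present, \(H\) is singular (vertex friction
only) or can become arbitrarily ill-conditioned (elongation only, when the
two strain directions align); a small 1 Pa·s substrate term is then added
automatically, generalizing the regularization the model itself prescribes
for the vertex-friction case.

`fit_velocity_vs_angle()` mirrors the experimental analysis: the angle
series is smoothed with a Gaussian kernel and the zippering velocity is
the convolution of the zippered-length series with the same kernel's
derivative; ordinary least squares of velocity on \(1-\cos\beta/2\) then
identifies `-2T/eta_Z` (slope) and `S/eta_Z` (intercept) when vertex
friction dominates. With appreciable elongation viscosity the relation is
curved; the fit reports the reduced \(R^2\) rather than correcting for it.

## BFP tension analysis

An aspirated red blood cell is a linear spring of stiffness
\[ k = \frac{R_p\,\Delta P\,\pi\,(1-\hat R_p)}
            {\ln\!\frac{4}{\hat R_p \hat R_c}
             - \left(1-\tfrac{\hat R_p}{4}-\tfrac{3\hat R_p^2}{8}
                + \hat R_c^2\right)} \]
(`probe_stiffness()`; radii scaled by the unstrained aspirated cell
radius). The grouping of the logarithm's argument is typographically
ambiguous in the sources this formula circulates in; the package adopts
\(\ln(4/(\hat R_p\hat R_c))\), the reading under which the documented
probe parameter ranges (Rp 0.6–1.0 μm, Rc 0.75–1.2 μm, R0 2–3 μm,
ΔP 200–250 Pa) produce stiffnesses in the documented working band of a
few hundred pN/μm; the alternative reading lands at 500–700 pN/μm and is
rejected. At the extreme soft corner of those ranges the formula evaluates
just below 100 pN/μm, which we report as-is rather than force into the
band.

`detect_plateaux()` finds the intervals where the pipette was held fixed
as runs of sub-threshold windowed force standard deviation (defaults:
2 s window, 5 pN threshold, 3 s minimum duration — the method literature
states no thresholds, so these are configurable analyst defaults). A raw
windowed-sd run systematically under-covers each plateau by about half a
window on each side, so a second pass expands every run while the force
remains within three noise standard deviations of the plateau level
(requiring several consecutive outliers to stop, for robustness to single
frames). `fit_tension()` regresses the per-plateau mean transverse force
\(F\sin\varphi\) on the mean \(\sin\delta\) with a free intercept — the
slope is \(2T\); the intercept absorbs the unstrained-length calibration
offset; pushing plateaux (`delta < 0`) are excluded by default.

**Uncertainty model.** The reported `T_sd` combines the regression slope
standard deviation with the method's dominant systematic — the ~14%
probe-stiffness calibration uncertainty — in quadrature. This is a
deliberate departure from a residual-only error: with `k` plateaux the
studentized slope error has exactly `k − 2` degrees of freedom, so a
±2(residual sd) interval covers only 81–92% for realistic plateau counts,
and no honest residual-only interval can meet a 95% two-sigma calibration
target. With the calibration term included, recovery of a planted tension
lies within 2·`T_sd` in well over 95% of seeded replicates under the
stated noise model (per-frame angle noise 0.5°, bead-tracking noise tens
of nm). If the generator is also asked to mis-calibrate the stiffness
(`k_error_sd = 0.14`), coverage drops to ≈94% because the error is
multiplicative and the band is centred on the biased estimate — a known
property, not a defect.

`population_tension_pdf()` represents each axon's fit as a Normal and
normalizes the equal-weight mixture on a 1 pN grid.

## Distribution inference

`transform_tension_to_angle()` implements the change of variables through
the equilibrium condition. With \(\Phi = 1-\cos\beta/2\),
\[ q(\beta) = p\!\left(\frac{S}{2\Phi}\right)\frac{S}{4}
             \frac{\sqrt{2-\Phi}}{\Phi^{3/2}}, \]
evaluated on a 0.05° angle grid; tension grids use 1 pN spacing and all
integrals are trapezoidal. Tension mass below `S/2` has no finite
equilibrium angle (full zippering); it is carried explicitly as an `atom`
of the result instead of being renormalized away. Medians are computed by
inverse interpolation of the piecewise-linear CDF.

Two estimators of `S`:

* `match_adhesion()` — exhaustive 1 pN screening of `S`, maximizing the
  Pearson correlation between the transformed tension distribution and
  the observed angle distribution (deterministic; no gradient method).
  Recovers a planted `S` within one grid bin on self-generated data.
* `joint_screening()` — treats tension and angle as independent, forms
  the product joint density, and integrates each (T, β) cell's mass into
  1 pN bins of \(S = 2T(1-\cos\beta/2)\). Because real tensions and
  angles are partially dependent, the spread of this distribution is an
  upper bound on the spread of `S`.

**Fascicle scaling.** For a fascicle of `n` axons with independent
per-axon tensions, the mean tension scales as `n` and its sd as `√n`; the
fascicle–fascicle adhesion scales with the contact surface, hence `√n`
for an approximately circular cross-section. The square-root exponents
are essential: scaling all three parameters linearly leaves the angle
distribution *exactly* invariant (the balance is homogeneous), and this
negative control is a test. With the single-axon baseline (lognormal,
mean 0.68 nN, sd 0.25 nN, S = 0.17 nN) and `n = 1.50`,
`median_angle_shift()` computes 6.43°; the value is reproduced to four
decimals by the closed-form median identity (the transform is monotone,
so the median maps through), which makes the grid computation
self-verifying.

`crossing_probability()` is the CDF of the equilibrium-angle
distribution: a pair meeting at an incidence angle below its equilibrium
angle zippers, above it crosses.

## Network statistics

A segmentation export (CSV or JSON; one polyline per drawn edge, pixel
size applied on load) becomes a planar graph: endpoints within the snap
tolerance (default 1 μm — manual segmentation jitter) merge into nodes;
crossings are drawn as overlapping polylines without shared endpoints and
so never create connectivity. Total length sums the drawn polylines
(shared zippered segments are drawn once). Chordless loops are the
bounded faces of the planar embedding, traced by the rotational
(leftmost-turn) rule and measured by the shoelace formula on the full
polyline geometry; the suite checks the Euler relation
\(V - E + F_{bounded} = 1\) per connected component against brute-force
fixtures. Zipper angles at degree-3 junctions take the sharpest of the
three pairwise tangent angles (tangents estimated over a 5 μm window —
the measurement protocol states no rule, so this window is an explicit
default), with per-junction overrides for configurations where the
sharpest pair is not the zipper. `timeseries_stats()` assembles per-frame
totals and the Pearson correlation between median angle and total length,
with optional normalization to a reference time point.

## The synthetic-data generators

The generators provide seeded, bit-reproducible stand-ins for the three
kinds of inputs the analysis consumes. What they emulate — and what they
do not — bounds what a green test establishes.

* `gen_tension_and_angle_samples()`: lognormal tensions (mean 0.68 nN,
  sd 0.25 nN), equilibrium angles from the planted adhesion (default
  0.17 nN) plus 3° measurement noise; default sizes 7 tensions and 34
  angle measurements, mirroring the experimental sample sizes.
* `gen_bfp_recording()`: a staircase of ≥3 pulling plateaux at 65 frames
  per second, deflections up to ~5° (where beads typically detach),
  per-frame angle noise 0.5°, force noise equal to stiffness × 20 nm
  tracking error (inside the documented 10–50 nm band; 20 nm keeps the
  default 5 pN detection threshold above the 4 pN frame noise at
  k = 200 pN/μm), plus an optional stiffness mis-calibration.
* `gen_network_sequence()`: a field of independent mirror-symmetric
  zipper motifs plus triangular loops and annotated crossings (default
  composition 32/3/4; 28% of motifs flagged entangled and blocked from
  receding; crossing and entangled fractions follow the electron-
  microscopy vertex counts). Time evolution is two-timescale, matching
  the separation observed in culture: discrete zippering events are
  minutes-long transients advancing a vertex at a constant speed drawn
  from the observed 0.3–2 μm/min band (the near-constant-velocity regime
  of the equation of motion under gradual forcing), while between events
  every junction angle sits on the quasi-static equilibrium law for
  fascicle parameters rescaled with the running mean fascicle size
  `n(t) = L(0)/L(t)`. Scenario presets: `"coarsening"` (events advance;
  the default composition and event rate 1/70 min⁻¹ per motif realize
  the observed ≈20% total-length decay over 3 h, and triangular loops
  shrink and collapse, each collapse removing exactly two junctions),
  `"stable"` (no events; angles sit exactly on the planted law, which is
  what the distributional tests consume), and `"decoarsen"` (events
  reverse after an onset time, lengthening the network; entangled motifs
  stay put).

**Limitations.** The motifs are mechanically independent: length loss
(event-driven) and the angle trend (fascicle-scaled equilibrium law) are
imposed jointly rather than emerging from one coupled network relaxation,
anchor points do not move except in loop collapse, and no new contacts
form during a run. A green generator-based test therefore establishes
that the *analysis* correctly recovers planted structure of the stated
statistical form — not that a full mechanical network simulation would
produce that structure.

## Known limitations

* The substrate-friction tensor assumes the linear interior velocity
  profile; pivoting-segment corrections would add geometry factors.
* The joint-screening spread of `S` is an upper bound by construction
  (independence assumption).
* The lognormal stand-in for fascicle tensions is checked against the
  n-fold convolution of the single-axon law only qualitatively (their
  medians and the resulting angle distributions agree closely for small
  n); no formal closeness criterion is imposed.
* Entanglement is modelled as a binary no-recession flag; no quantitative
  model of entanglement formation exists to emulate.
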