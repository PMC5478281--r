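# axonzipper

Biophysics of axon shaft zippering: the mechanics that makes growing axons
fasciculate (bundle) or defasciculate by progressively adhering along their
shafts. The package is written for developmental neurobiologists and
biophysicists who image planar axon networks (e.g. explant cultures on a
2-D substrate) or measure axon tension with a Biomembrane Force Probe
(BFP), and who want to turn those measurements into forces, friction
constants and network-level predictions.

## The model

Two axons adhered along a shared segment meet the free segments at a mobile
*zipper vertex*. With effective axon tension `T` (axial tension plus
axon–substrate adhesion, in nN ≡ nJ/m) and axon–axon adhesion strength `S`
(energy per unit zippered length), the symmetric vertex is in equilibrium at
the full zipper angle β given by

    S = 2 T (1 − cos(β/2))

For unequal tensions `T1 ≠ T2` the balance along and transverse to the
zippered segment reads

    −(T1 + T2 − S) + T1 cos α1 + T2 cos α2 = 0,   T1 sin α1 = T2 sin α2

and the configuration energy over vertex position V (fixed points A, B, C)
is `E = T1(|VA|+|VC|) + T2(|VB|+|VC|) − S|VC|`. Out of equilibrium the
overdamped vertex obeys `F_v = −∇E = H(x, y) u`, with a friction tensor `H`
assembled from elongation viscosity (η⇕), vertex-localized friction (η_Z)
and substrate friction (η∥, η⊥, Rayleigh dissipation with a linear velocity
profile along each segment). For the symmetric zipper this reduces to

    ẏ = [S − 2T(1 − cos(β/2))] / [2η⇕(cos(β/2) − 1)²/L + η_Z]

so that, under vertex-dominated friction, the zippering velocity is linear
in `1 − cos(β/2)` with slope `−2T/η_Z` and intercept `S/η_Z` — the basis of
the dynamic inference of `S/T` and `η_Z` from tracked vertices.

On the population level, a tension distribution `p(T)` maps to an
equilibrium-angle distribution through the change of variables

    q(β) = p(S/(2Φ)) · (S/4) · √(2−Φ)/Φ^{3/2},   Φ = 1 − cos(β/2)

which underlies two estimators of `S` (best-match and independent joint
screening), the fascicle-scaling prediction (mean tension ∝ n, tension sd
∝ √n, adhesion ∝ √n for mean fascicle size n), and the probability that two
axons meeting at incidence angle β_inc cross rather than zipper,
`Π(β_inc) = ∫₀^{β_inc} q(β) dβ`.

## Modules

| Area | Key functions |
| --- | --- |
| Zipper statics | `equilibrium_angle_symmetric`, `adhesion_from_angle`, `equilibrium_angles_asymmetric`, `config_energy`, `vertex_force`, `find_equilibrium_vertex`, `loop_mean_angle`, `adhesion_energy_density` |
| Zipper dynamics | `symmetric_velocity`, `assemble_friction_tensor`, `simulate_zipper`, `fit_velocity_vs_angle`, `infer_st_ratio`, `infer_eta_z`, `dissipation_rate` |
| BFP analysis | `bfp_probe`, `probe_stiffness`, `detect_plateaux`, `fit_tension`, `population_tension_pdf` |
| Distributions | `kde`, `transform_tension_to_angle`, `match_adhesion`, `joint_screening`, `lognormal_from_moments`, `fascicle_scale`, `median_angle_shift`, `crossing_probability` |
| Network graphs | `load_segmentation`, `network_frame`, `total_length`, `count_junctions`, `chordless_loops`, `zipper_angles`, `timeseries_stats`, `vertex_type_fractions` |
| Synthetic data | `generator_spec`, `gen_tension_and_angle_samples`, `gen_bfp_recording`, `gen_network_sequence` |

## Worked example

```r
library(axonzipper)

# equilibrium angle for the measured median tension and adhesion
equilibrium_angle_symmetric(tension = 0.638, adhesion = 0.17)
#> [1] 59.82886        # degrees

# BFP round trip on a synthetic recording (planted T = 906 pN; the
# recording carries a drawn stiffness-calibration error, the method's
# dominant uncertainty)
rec <- gen_bfp_recording(generator_spec(seed = 4), T_true = 906, k = 200)
fit_tension(rec)
#> BFP tension estimate: T = 949 +/- 133 pN (R^2 = 1.000, 5 plateaux)

# dynamic inference from the printed velocity-angle fit
infer_st_ratio(slope = -4.1692, intercept = 0.0825)
#> [1] 0.03957594      # S/T ~ 0.04
infer_eta_z(slope = -4.1692, tension = 2)
#> [1] 0.9594167       # nN s / um, i.e. ~1e-3 N s / m

# fascicle coarsening lowers the median zipper angle
median_angle_shift(fascicle_params(0.68, 0.25, 0.17), n = 1.5)
#> [1] 6.43484         # degrees
```

The first number is the predicted equilibrium angle (about 60°) for a
single-axon zipper at the median measured tension; the BFP fit recovers the
planted tension within its reported uncertainty (dominated by the ~14%
stiffness-calibration term); the slope/intercept arithmetic reproduces the
dynamic adhesion-to-tension ratio of 0.04 and a vertex friction constant of
order 1e-3 N·s/m; and rescaling the tension law to mean fascicle size 1.5
shifts the predicted median angle down by ~6.4°.

A command line interface with subcommands (`simulate-zipper`, `analyze-bfp`,
`estimate-adhesion`, `predict-angles`, `analyze-network`, `gen-synthetic`)
is exposed through `az_cli()` and the `inst/cli/axonzipper` wrapper.

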