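---
title: "A torsional bead-spring model of supercoiling-driven DNA unknotting and decatenation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A torsional bead-spring model of supercoiling-driven DNA unknotting and decatenation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(supercoilr)
```

## The problem

Freshly replicated circular DNA molecules come out of replication catenated
with each other and often knotted, yet they also come out torsionally
relaxed, carrying nicks and short single-stranded gaps in the freshly
synthesized strands. Type I topoisomerases such as topoisomerase III act
preferentially at such nicks and gaps, but a passage at a random
juxtaposition is as likely to entangle as to disentangle. `supercoilr`
implements a coarse-grained molecular-dynamics model in which the missing
ingredient is supplied by DNA gyrase: as gyrase winds negative supercoils
into a nicked or gapped molecule, the growing plectonemic region confines
the entanglement (knot or catenane interlink) and pushes it along the
contour toward the site where torsion is dissipated — exactly where topoIII
waits. The package simulates this process and quantifies it with polymer
topology tools.

## The chain model

One repeat unit represents 8 bp; the reduced length unit is sigma = 2.5 nm,
the energy unit is epsilon = k_BT, masses are m = 1. Each unit contributes a
main-chain bead M. Consecutive M beads are bonded by a shifted FENE
potential with rest length 1 sigma. Bending carries an energy
K_b (1 − cos θ) per vertex. Excluded volume is a purely repulsive WCA
potential with an enlarged diameter σ_ex = 1.5 sigma — larger than the bond
length, which closes the mesh of the chain so that two duplex segments
cannot pass through each other even under strong torsional driving.
Screened electrostatics is a truncated Debye–Hückel repulsion,
U = ε l_B q_i q_j exp(−κ r)/r for r ≤ 8 sigma, with q = −2 per duplex bead
(the non-neutralized charge of an 8 bp fragment at physiological salt),
l_B = 0.28 sigma and κ = 1/(1.2 sigma).

Torsion needs a frame. Each bond carries an axial bead A at its midpoint and
a periaxial bead P at distance 1 sigma from the axis, held perpendicular to
the bond by rigid constraints. The dihedral angle φ between consecutive
(P, A, A, P) frames is locked by V(φ) = K_D (1 − cos(φ − p)) with K_D = 20 ε;
because the frame is periaxial rather than attached to surface beads, φ
remains well defined up to ~90° bends. The phase p is 0 for ordinary duplex
DNA.

Three local perturbations complete the model:

* **Active swivel (gyrase).** One dihedral's phase is ramped continuously at
  ω rotations per time unit (7 × 10⁻⁴ by default; 7 × 10⁻³ for the short
  1000 bp circles, which would otherwise dissipate torsion faster than one
  motor can inject it). With the default sign the measured linking number of
  a closed chain decreases: negative supercoiling.
* **Nick (passive swivel).** One dihedral lock removed; the flanking
  segments swivel freely and torsional stress dissipates there.
* **Gap.** Three consecutive units lose their dihedral locks, carry half the
  charge (−1: single strands have half the linear charge density) and get a
  single-strand bending constant (default 0.6 ε, corresponding to an ssDNA
  persistence length of ~1.5 nm).
* **topoIII mode.** The WCA repulsion between gap beads and all other beads
  is removed, so supercoiling can drive a duplex segment through the gap —
  the model of a topoIII-mediated passage. Whether the electrostatic term
  should also be removed is ambiguous; it is kept by default and exposed as
  `remove_dh`.

## Dynamics

The equations of motion m r̈ = −∇U − γ ṙ + F^R are integrated by velocity
Verlet with per-bead-type drags γ_M = 0.5, γ_P = γ_A = 0.2 m/τ (0.9 m/τ per
repeat unit in total) and random forces with variance 2 γ k_BT/Δτ per
component per step, each bead's noise scaled by its own drag
(fluctuation–dissipation consistent). The default step is Δτ = 0.001.

Constraints are handled as follows. The axial beads are massless virtual
sites pinned exactly to the bond midpoints; forces acting on them (from the
dihedral potential and from their own drag and noise, which act on the
midpoint velocity) are spread onto the flanking M beads. This transmission
matters: it is what lets torsional stress buckle the chain into writhe, and
a projection that only repositioned the auxiliary beads would silently
decouple twist from bending and no plectoneme could ever form. The two
remaining constraints per bond — unit length and perpendicularity of the
P offset — are enforced after every step by an iterative symmetric Lagrange
projection over P and the two M beads; the projection leaves the frame
azimuth (the torsional degree of freedom) untouched, and the corresponding
velocity components are removed. In-run constraint residuals are held below
10⁻⁴ sigma (refined to 10⁻¹² by the explicit `enforce_frame_constraints()`
projection); with the thermostat off the integrator conserves energy to
better than 10⁻⁴ relative over 10⁴ steps.

The FENE wall is continued linearly beyond 98% of the maximal extension.
Equilibrium occupancy beyond that point is ~e⁻¹², so thermodynamics is
unaffected, but the continuation prevents a rare discrete step from jumping
across the numerically thin divergence on long runs.

### Desk-scale integration step

All defaults follow the model's stated parameterization (Δτ = 0.001). The
bundled scenario runs and the measurement wrappers use Δτ = 0.004 (0.002
where noted): the stiffest frequencies present (FENE ≈ 7.7 rad/τ, dihedral
≈ 6.3 rad/τ) are still resolved ~250-fold, the NVE drift and equipartition
checks pass unchanged, and the four-fold speed-up is what makes the
reduced-scale phenomenon suites affordable on one CPU.

## Units: from reduced time to seconds

The time unit is calibrated through rotational diffusion. An 8 bp DNA
fragment in water has D_rot ≈ 6 × 10⁷ rad²/s; intracellular viscosity up to
several thousand times that of water scales it down by Stokes' law — for a
factor 5000, D_target = 1.2 × 10⁴ rad²/s. The simulated counterpart is
measured by `measure_rotational_diffusion()`: the cumulative azimuthal
rotation of an interior torsional frame is tracked (with parallel transport
of the reference direction, so tumbling of the local axis does not alias
into the angle) and D is the slope of its mean-squared displacement over
intermediate lags, divided by two. Because the angular velocity
decorrelates over m/γ ≈ 5 τ, the slope is fitted with a free intercept;
fitting through the origin underestimates D by ~20%.

A single isolated frame is dominated by the tumbling of its own axis; a
repeat unit embedded in torsionally continuous DNA instead spins together
with its locked neighbours. The measurement therefore uses the minimal
fragment in which the tracked frame is interior and torsionally coherent —
four M beads carrying three locked frames. Its collective azimuthal drag is
3 γ_P (offset 1 sigma), so k_BT/(3 × 0.2) ≈ 1.67 rad²/τ is the expected
scale; the measured value is ≈ 1.6 rad²/τ. The calibration chain then gives
τ = D_sim/D_target ≈ 1.3 × 10⁻⁴ s, and the default swivel speed of
7 × 10⁻⁴ rotations/τ corresponds to ≈ 5.2 rotations per second — inside
the experimentally observed 1–5 rotations/s range of gyrase.

```{r}
rot <- measure_rotational_diffusion(seed = 1)
calibration_chain(D_sim = rot$D)
```

## Bending constant and persistence length

The chain's stiffness results from bending, excluded volume and
electrostatics together, so K_b cannot be set analytically; it is tuned by
simulation (`tune_bending_constant()`, bisection over K_b with a
persistence-length measurement per iterate) so that an open chain has
L_p = 50 nm = 20 sigma. The bundled default `bend_constant` is the tuned
value. `persistence_length()` fits exp(−s/L_p) to the mean cosine of the
angle between bond vectors separated by contour distance s. Three numerical
points deserve mention. Bending modes with wavelengths near L_p relax very
slowly, so the estimate pools several independent replicate chains (each
started from an in-ensemble worm-like-chain conformation, never from a
straight rod, which would leave seed-dependent stiffness memory) rather
than one long trajectory. The fit window is s ∈ [1, 12]: the decay is
strictly single-exponential from a couple of bonds on (R² > 0.999), while
larger separations are dominated by the slow global modes and contribute
noise, not information — including them inflates the seed-to-seed scatter
of L_p several-fold. And where C(s) does reach its noise floor, the log
transform would turn symmetric noise into a systematic downward bias, so
such separations are excluded as well.

## Topology toolkit

* **Writhe** — exact discrete Gauss self-integral (per-segment-pair solid
  angles), deterministic; an average-of-signed-crossings projection
  estimator is kept in the test suite as an independent oracle.
* **Twist** — per junction, the rotation of the P offset relative to
  parallel transport across the vertex, summed in turns. For closed intact
  chains Tw + Wr equals the integer linking number (discrete White
  theorem), and with junction phases subtracted (`relative_to_phase`) the
  change of Tw + Wr tracks the rotations injected by the motor: a closed
  circle with one active swivel loses exactly ω t turns of linking,
  partitioned between twist and writhe.
* **Linking number** of two closed curves — Gauss double sum, exact
  integer.
* **Knot identification** — the determinant of the knot |Δ(−1)|
  (1 unknot, 3 trefoil, 45 for 8_18), computed from a generic projection of
  the KMT-reduced polygon via the Fox-coloring matrix in exact modular
  arithmetic, cross-checked over independent projections. KMT vertex
  elision is conservative: any near-coplanar blocking segment counts as an
  obstruction, which costs a few extra vertices but can never change the
  knot type.
* **Knot core localization** — two-pointer shrinking of an arc whose
  far-point ray closure retains the chain's determinant while the
  complement closes to an unknot; several starting cuts are tried since
  localization depends on where the circle is cut. Distances from the core
  midpoint to nicks/gaps are contour distances on the circular map,
  min(d, N − d).

## Starting configurations

Circles are regular polygons; the trefoil is the (2,3) torus-knot curve;
8_18 is built from the closure of the alternating three-strand braid
(σ₁ σ₂⁻¹)⁴ realized as an annular polyline with over/under lifts (a torus
embedding would give the non-alternating torus knot instead). Catenanes are
(2, 2n) torus links realized on a common torus so the components stay
interlinked after joint rescaling to unit bonds. All curves are resampled
to 1 sigma bond length by arclength interpolation; torsional frames are
parallel-transported along the chain, with the closure holonomy spread
evenly over all junctions so every dihedral starts equally (and nearly)
relaxed. Initial velocities are Maxwell–Boltzmann, then projected onto the
constraint manifold. `thermalize()` runs the dynamics with all motors off,
requires the potential-energy running mean of the last two quarters to
agree within 2%, and verifies that the knot determinant is unchanged.

Pre-tied linear knots keep the knotted arc interior by cutting one bond of
a knotted circle and extending straight tails along the end tangents.

## Reduced-scale study conditions

Full-scale runs (3000 bp, 5 × 10⁸ steps) are cluster work. The package's
bundled scenarios reproduce the phenomena at reduced scale:

* the named figure scenarios (`run_scenario()`) use 1000 bp (125-unit)
  circles with the fast swivel rate 7 × 10⁻³ rotations/τ defined for
  short circles, 2 × 10⁶ steps at Δτ = 0.004 (8000 τ);
* the replicate suites for topoIII-mediated unknotting and decatenation in
  the acceptance tests use 384 bp (48-unit) gapped knotted circles (10⁶
  steps per replicate) and 240 bp (30-unit) doubly-interlinked circle pairs
  (1.3 × 10⁶ steps) at the same rate. These are the sizes at which the
  whole cycle — supercoiling build-up, confinement of the entanglement at
  the gap, and passage — completes reliably within a desk-scale run; at
  500–1000 bp the same events occur but the final passage (the last
  interlink of a catenane in particular) becomes too slow for runs ~100×
  shorter than full-scale ones. This extends the logic by which the fast
  motor rate is assigned to short circles: the smaller the system and the
  shorter the run, the faster the motor must cycle.

What the reduced scale does show: arising supercoiling confines knots,
pushes them toward nicks/gaps, and topoIII passages then unknot and
decatenate, never occurring with the passage mode off. What it cannot show:
quantities tied to the full 3 kb contour, such as the ~100 rotations needed
to push a knot to a nick in a 3 kb plasmid (≈ 20 s of gyrase work at ~5
rotations/s); at 1/3 to 1/6 of the contour length both the distances and
the rotation counts are compressed.

## Known limitations

* Hydrodynamic interactions beyond per-bead drag are absent, as are bound
  proteins; the large rotational drag of the crowded cell is represented
  through the viscosity-scaled calibration only.
* Sequence effects, groove geometry and explicit base pairs are out of
  scope; the chain is isotropic.
* The knot-core arc is defined through arc closures and is therefore
  closure-dependent for delocalized knots; the closure method is exposed.
* The exact bonded-potential constants of the reference parameterization
  are not published; the shifted-FENE constants used here (K = 30 ε/σ²,
  R0 = 0.5 σ, r0 = 1 σ) are substitutes that reproduce a stiff 1 σ bond.
* At the default FENE stiffness the divergence is logarithmic, so the wall
  reaches only ~50 ε within 10⁻⁶ of full extension; the linear continuation
  beyond 98% extension (see above) is a numerical safeguard, not a model
  feature.
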