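---
title: "Modelling antibody fragment dynamics from scattering observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antibody fragment dynamics from scattering observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

An IgG antibody is three ~50 kDa fragments — two antigen-binding Fab arms
and the crystallizable Fc — tethered by a disordered hinge linker whose
CPPC motif (two disulfide-bonded cysteines) forms the mechanical pivot of
the molecule.  In solution the molecule diffuses, rotates, and its
fragments move relative to each other.  Neutron spin-echo (NSE) measures
the normalized coherent intermediate scattering function I(Q,t)/I(Q,0) on
exactly the length (2–30 nm) and time (0.1–500 ns) scales of these
motions, but all contributions are superposed.  This package implements a
decomposition of that signal into translational diffusion (with colloidal
interaction corrections), rotational diffusion, and internal fragment
modes, together with the static-scattering and light-scattering/NMR
machinery needed to pin down the other ingredients, and synthetic-data
generators so the whole chain can be validated against known ground truth.

# The coarse-grained model

`bead_model` holds beads (one per residue when a structure file is
coarse-grained with `load_pdb_coarse_grain`; uniform spherical clusters
for the synthetic geometry of `build_synthetic_ymodel`), scattering
contrasts `b_k`, fragment labels, the pivot, and the Fc hinge line.
Contrast defaults to the residue electron count, appropriate for X-ray
scattering at the Q ≤ 2.5 nm⁻¹ range where residue-level detail is not
resolved.  The synthetic geometry places the three fragment spheres
(radius 4.2 nm) at 120° spacing, centres 4.6 nm from the pivot, giving an
8.8 nm bounding radius — full-size-antibody dimensions.

Internal degrees of freedom are hand-built displacement fields
(`make_displacement_mode`), not elastic-network modes: for a disordered
linker a normal-mode analysis would mostly reflect the arbitrary linker
conformation of the starting structure.  The fields are

* **attack** — radial stretch of a fragment along the pivot→centre line,
  the motion that extends a Fab outward and exposes its binding end;
* **search (in/out of plane)** — first-order rigid rotations of a fragment
  about axes through the pivot, normal to or within the plane of the three
  fragment centres; bending motions that reorient fragments relative to
  each other;
* **fragment rotation** — first-order rigid rotation about the
  pivot→centre axis;
* **Fc bend** and **linker scale** for configuration refinement.

Each field is normalised so the mean displacement magnitude over the
moving beads is 1 nm per unit amplitude; a fitted amplitude is therefore
directly the rms displacement of that fragment in nm.  (The alternative —
normalising over *all* beads — would make amplitudes depend on how many
beads happen to sit in other fragments; per-fragment normalisation keeps
the amplitude a property of the moving unit.)

`apply_configuration` applies *finite* versions of these motions
(rotations by Rodrigues' formula, radial offsets, Fc hinge bend, linker
scaling) for configuration refinement.  The three-fragment plane is
recomputed from the fragment centres at each call; linker beads follow
their arm rigidly (rotation plus radial stretch), which is exact for the
identity and makes single-parameter operations invertible to machine
precision.  Straight linker strings suffice because the 38-residue linker
contributes little coherent signal against 1326 residues.

# Statics

`form_factor` evaluates the orientation-averaged Debye double sum exactly;
`amplitude_asymmetry` computes the decoupling factor
β(Q) = |⟨ρ⟩|²/⟨|ρ|²⟩ on a deterministic Fibonacci-sphere direction set
(default 1153 directions — deterministic quadrature converges much faster
than Monte-Carlo orientations at equal cost, and makes every result
bit-reproducible).  The apparent structure factor of the anisotropic
particle is S′ = 1 + β(S − 1).

Interparticle structure factors: the analytic Percus–Yevick hard-sphere
solution, and a rescaled-MSA model for screened charged spheres.  The MSA
closure is solved numerically on a radial grid (Picard iteration of the
Ornstein–Zernike equation with fast sine transforms); when the contact
value g(σ⁺) turns negative the core is grown at fixed number density until
g(σ⁺) = 0, the standard rescaling that restores physicality at weak
coupling.  The O(dr) core-boundary discretisation error is removed by
Richardson extrapolation over two grid resolutions, which brings the
charge→0 limit within 0.1% of the analytic Percus–Yevick curve.  A
`tabulated` option accepts externally computed S(Q) (e.g. from more
elaborate attractive-potential models), and
`sq_params_from_concentration` implements the protein→fragment
number-density crossover (factor 3) relevant once bounding spheres of
neighbouring antibodies touch (~33 mg/ml for this geometry).

`refine_configuration` fits configuration parameters to a target form
factor by seeded differential evolution followed by Levenberg–Marquardt
refinement, weighting by 1/σ² (σ = √I floor-clamped when the target has no
uncertainties).  Configuration changes only show above Q ≈ 0.7 nm⁻¹, so
targets should cover that range.

# Dynamics

The composite ISF model is

I(Q,t)/I(Q,0) = [(1 − A(Q)) + A(Q) e^{−t/λ}] e^{−Q² D_slow(Q) t},

a single overdamped internal relaxation (amplitude A, time λ) on top of
Q-dependent slow diffusion.  A(Q) is built from coherent mode form factors

P_α(Q) = ⟨Σ_{kl} b_k b_l e^{iQ(r_k−r_l)} (Q·d_k^α)(Q·d_l^α)⟩,

with A = a²ΣP_α/(P + a²ΣP_α); the corresponding contribution to the
short-time effective diffusion is D_m = A/(λQ²).  The cumulant identity —
the initial slope of ln I equals −Q²(D_slow + D_m) — connects the model to
the model-free `cumulant_fit` and is asserted numerically in the tests.

A second-order subtlety worth recording: the Gaussian-ensemble static
average over a mode of amplitude a is *not* P + a²P_α but
P + a²(P_α − P_DW), where P_DW is the Debye–Waller-like cross term
Σ b_k b_l cos(Q·r_kl)·[(Q·d_k)² + (Q·d_l)²]/2 of the same order.  The
package's Monte-Carlo validation of P_α uses the full identity (and checks
that the remainder scales as a⁴).

`fit_composite` fits all Q simultaneously with shared (u_f, λ) and
independent D_slow(Q) — the amplitude and time of the fast process are
properties of the molecule, not of the wavevector — with a per-Q
independent variant behind `share = FALSE`.  With ten Q values spanning
0.2–1.8 nm⁻¹ and 3% noise (spin-echo-like log-spaced Fourier times to
150 ns), the estimates are unbiased with ~68% 1σ coverage over seeded
replicates; with only a handful of Q values the (u_f, λ) pair becomes
strongly degenerate and errors grow heavy-tailed, which is why the
generator defaults and the tests use the ten-Q design.

## Dynamic form factor geometry

`mode_diffusion` curves (D_m(Q)·λ) discriminate motion types by shape: on
the synthetic full-size geometry the summed attack patterns peak near
Q ≈ 0.6 nm⁻¹, the inter-fragment distance scale.  A caveat the tests make
explicit: a *uniform* sphere has zero continuum rotational contrast (the
gradient of its scattering amplitude is parallel to Q), so on the
spherical-cluster synthetic fragments the fragment-rotation pattern is
carried entirely by bead-level texture and peaks near 1.05 nm⁻¹,
independent of bead density.  Real Fab/Fc fragments are internally
structured (Ig domains), which pushes the rotation signal toward the
fragment-size scale (~1.4 nm⁻¹).  Conclusions about rotation-pattern peak
positions therefore do not transfer from the uniform synthetic geometry to
structured fragments; attack/search conclusions do, because those patterns
live on the inter-fragment scale.

## Slow-diffusion decomposition

`decompose_slow` fits

D_slow(Q) = D₀·H(Q)/S(Q) + f_r·h(Φ_HI)·D_r(Q) + D_m,search(Q; u_m) +
D_m,fragrot(Q; u_r)

with h(Φ) = 1 − 0.631Φ − 0.726Φ² the rotational hindrance of crowding.
D_r(Q) = D₀(Q) − D_t comes from the rigid-body first cumulant (Eq. below),
the slow mode sets share a fixed relaxation time (default 200 ns —
slow enough to be separated from the fast attack process, configurable),
and the hydrodynamic interaction radius is parameterised as R_HI = f_c·R_h.
At low concentration the search-mode pattern and whole-body rotational
diffusion are nearly degenerate (each bending is an infinitesimal
rotation); the fit warns when any parameter correlation exceeds 0.95.

## Rigid-body hydrodynamics

`rpy_rigid_body_tensor` builds the overlap-corrected Rotne–Prager–Yamakawa
mobility supermatrix, inverts to bead frictions, projects onto rigid-body
translation+rotation (adding the per-bead spin friction 8πηa³, which makes
a single bead exactly Stokes in both translation and rotation), and
references the 6×6 diffusion matrix to the centre of diffusion, where the
translation–rotation coupling is symmetric.  The default residue-level
bead radius (0.29 nm hydrated) is only meaningful for residue-scale
models; synthetic cluster models should use a radius comparable to their
bead spacing.  The Q-dependent first cumulant

D₀(Q) = ⟨ρ(Q)(Q, Q×r_k)·D·(Q, Q×r_l)ρ*(Q)⟩ / (Q²P(Q))

is validated against a seeded rigid-body Brownian-dynamics simulation.
Its Q→0 plateau equals the translational coefficient *at the scattering
centroid*; for asymmetric bodies whose contrast centroid is displaced from
the centre of diffusion the plateau exceeds D_t(CoD) — physical wobble of
the scattering centre, not an error.

## Hydrodynamic function

`delta_gamma_H` computes H(Q) = H_d(Q) + D_s^s/D₀ for effective spheres of
radius R_HI: the self part from the quadrature
(2/π)∫dt sinc²(t)[1 + Φ_HI S_γ(t)]⁻¹ and the distinct part from the double
integral (3/2π)∫dx sin²x/x²·[1+Φ_HI S_γ(x)]⁻¹ ∫dμ(1−μ²)(S(|Q−k|)−1).
The microstructure weight S_γ(x|Φ) is implemented as a separable
calibrated form, γ(Φ)·sinc²(x), with γ(Φ) fixed per volume fraction such
that the self-part quadrature reproduces the hard-sphere short-time
self-diffusion closed form 2(1−Φ)/(2+3Φ).  This is a deliberate design
choice in the spirit of self-part-corrected effective-medium schemes: the
self part is anchored to an accurate closed form, the distinct part keeps
the exact integral structure (so H_d → 0 when S ≡ 1, H → 1 in the dilute
limit, and H approaches the self part at large Q), and both quadratures
are normalised by their zero-coupling values so the dilute limits are
exact rather than cutoff-limited.  The k-dependence of the damping weight
is the simplest positive form with the correct limits; it is *not* a
microscopically derived many-body resummation, and absolute H_d shapes at
high volume fraction should be treated as semi-quantitative.  Quadratures
use Gauss–Legendre nodes (240 radial × 32 angular by default); halving the
step changes results by <10⁻³ (asserted in tests).

`self_diffusion_models` provides the hard-sphere closed forms used to
relate short- and long-time self-diffusion: a virial-type short-time form
1 − 1.73Φ + 0.88Φ² with the cage-relaxation factorisation
D_s^l = D_s^s/(1 + 2Φ g(σ;Φ)) (Percus–Yevick contact value), and the
Tokuyama–Oppenheim short-time form with its long-time extension
(divergence of caging at Φ₀ = (4/3)³/(7 ln3 − 8 ln2 + 2) ≈ 0.572).

## Ornstein–Uhlenbeck fragment dynamics

To turn the fast relaxation into mechanics, fragments are modelled as
overdamped Brownian particles in harmonic potentials.  `ou_isf` evaluates
the coherent ISF with the Debye–Waller factor
f_kl(∞) = exp(−½Σ_j[(d_jk·Q)² + (d_jl·Q)²]) and time part
f′_kl(t) = exp(Σ_j (v_jk·Q)(v_jl·Q)e^{−t/λ_j}),
d_jk = √(kT/k_j)ê_jk, v_jk = √(kT/(λ_jΓ_j))ê_jk, under the balance
constraint k_j = λ_jΓ_j (so d = v and the t = 0 value is the
Gaussian-ensemble static factor).  Units are molar mechanical: k_f in
g ps⁻² mol⁻¹, ξ in kg ps⁻¹ mol⁻¹, which makes λ[ns] = ξ/k_f and
u_f = √(kT/k_f) in nm with kT ≈ 2.48 g nm² ps⁻² mol⁻¹ at 298 K.  The
implementation is validated against the closed-form orientation-averaged
Gaussian for a single bead and against seeded Ornstein–Uhlenbeck
trajectory averages.

The natural mechanical reference is the entropic spring of the linker:
`entropic_spring_constant` returns the three-dimensional Gaussian-chain
constant 3k_BT/(Nb²).  The one-dimensional form kT/(Nb²) is a factor 3
weaker; the 3D form is the one consistent with per-fragment force
constants of a few g ps⁻² mol⁻¹ for N ≈ 8–18 segments of b ≈ 0.38 nm
(6.4 at N = 8, 2.8 at N = 18 — values the acceptance script recomputes).
`force_unit_convert` moves between molar and single-molecule units
(1 g ps⁻² mol⁻¹ = 1.66 pN/nm).

# Synthetic data and what it does (not) show

The generators produce every observable the fitting layers consume, each
with a seeded ground-truth sidecar:

* `gen_saxs_series` — I(Q,c) = c/M_w·P(Q)·S′(Q,c) with multiplicative
  Gaussian noise (counting statistics on normalised data);
* `gen_nse` — composite ISF on instrument-like log-spaced Fourier-time
  grids (maximum times of order 100–300 ns), multiplicative noise, default
  3%;
* `gen_dls` — Siegert decays at Q = 0.026 nm⁻¹, where protein-scale
  diffusion relaxes in tens of microseconds; additive noise;
* `gen_pfg` — Stejskal–Tanner echo attenuations (δ = 2 ms, Δ = 20 ms);
  additive noise.

Passing the round-trip tests shows that the estimators are consistent and
correctly weighted *under the generating model*: independent Gaussian
noise, exact model forms, a rigid equilibrium structure.  Real data add
instrument resolution, background-subtraction residuals, polydispersity
and concentration-dependent structure changes, none of which are
simulated; the tests therefore validate the analysis chain, not the
adequacy of the physical model for any particular sample.

# Numerical choices

* Orientation averages: deterministic Fibonacci directions everywhere
  (statics and dynamics share the convention); counts configurable,
  defaults 1153 (statics) and a few hundred (dynamics) chosen so
  quadrature error is far below the noise levels of interest.
* Weighted least squares by Levenberg–Marquardt; 1σ errors from the
  covariance scaled by reduced χ² (the convention when only relative
  weights are trusted); global searches by seeded rand/1/bin differential
  evolution (population 15 per dimension, projection onto box bounds)
  with local polish.
* All randomness flows through explicit seeds; callers' RNG state is
  saved and restored.
* The pipeline (`run_pipeline`) chains model building, SAXS generation and
  extrapolation, configuration refinement, hydrodynamics, NSE generation
  and fitting, cumulant analysis, slow-diffusion decomposition and the
  OU conversion with per-stage artifacts; default problem sizes (30 beads
  per fragment, 60-point Q grids, 10 NSE wavevectors) run the whole chain
  in seconds while keeping every estimator in its well-conditioned regime.

# Known limitations

* The separable S_γ weight (above) is calibrated, not derived; distinct
  hydrodynamic structure at Φ ≳ 0.3 is semi-quantitative.
* Uniform spherical synthetic fragments carry no continuum rotational
  contrast (see the dynamic-form-factor caveat above).
* The MSA solver covers hard-core + screened-Coulomb repulsion; attractive
  components must be supplied as tabulated S(Q).
* Incoherent scattering, instrument resolution and background terms are
  out of scope; NSE input is assumed reduced and normalised.
* The linker is a straight interpolated string; its conformational entropy
  enters only through the effective spring constant, not the scattering.
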