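---
title: "Methods: soft vesicles filled with chiral active particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soft vesicles filled with chiral active particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The package simulates a two-dimensional soft vesicle — a flexible ring
polymer of `L` monomers — enclosing `N` chiral active Brownian particles.
Everything is overdamped: inertia is dropped and each particle's velocity
is its mobility times the force on it, plus noise.  In the units of the
package (`sigma` = particle diameter = 1, `eps` = k~B~T = 1), the active
particles obey

$$
\dot{\mathbf r}_i = V_0 \mathbf u_i - \tfrac{1}{\gamma}\nabla_i U
  + \sqrt{2 D_0}\,\boldsymbol\xi^T_i(t), \qquad
\dot\theta_i = \omega + \sqrt{2 D_\theta}\,\xi^R_i(t),
$$

with $\mathbf u_i = (\cos\theta_i, \sin\theta_i)$.  Membrane monomers
follow the same translational equation with $V_0 = 0$.  The potential
$U = U_\mathrm{WCA} + U_\mathrm{bond}$ combines purely repulsive
excluded volume — the Lennard-Jones potential truncated at
$2^{1/6}\sigma$ and shifted by $+\varepsilon$ so it vanishes continuously
at the cutoff — between **all** particle pairs, and stiff harmonic bonds
$\tfrac{k_s}{2}(|\mathbf r_{i,i+1}| - r_0)^2$ along the closed ring.

A chiral active particle swims in circles of radius $\sim V_0/\omega$.
Confined by a soft ring, the circular bias tilts its collisions with the
membrane, so the collision angle is systematically below $\pi/2$ and every
impact deposits a small counterclockwise tangential impulse: the vesicle
rotates unidirectionally.  The package exists to quantify that rotation,
the accompanying shape changes, and the centre-of-mass diffusion.

## Parameters

All defaults reproduce the reference regime of the model and are held in
`sim_params()`:

| parameter | default | units | meaning |
|---|---|---|---|
| `D0`     | 0.01 | σ²/time | translational diffusion; sets γ = ε/D₀ = 100 |
| `Dtheta` | 0.03 | rad²/time | rotational diffusion, 3·D₀/σ² |
| `V0`     | 0.5  | σ/time | self-propulsion speed |
| `omega`  | 0    | rad/time | chiral angular velocity (CCW > 0) |
| `ks`     | 4000 | ε/σ² | bond spring constant |
| `r0`     | 1    | σ | bond rest length |
| `dt`     | 0.01 | time | 10⁻⁴ of the diffusive time τ₀ = σ²/D₀ |
| `box`    | 200  | σ | periodic box side |

The vesicle's initial configuration is a circle: a regular `L`-gon of
circumradius $R_0 = \sigma/(2\sin(\pi/L))$, so every bond starts at its
rest length.  The particle count follows from the target area fraction
through $\rho = N\sigma^2/(4R_0^2)$, rounded to the nearest integer
(the reference case L = 150, ρ = 0.7 gives N = 1596).

## Numerical choices

* **Integrator.** Euler–Maruyama.  The equations are first order and the
  noise is additive, so this is the standard choice; a weak-order-1
  consistency test (halving `dt` leaves ensemble MSDs unchanged within
  Monte-Carlo error) guards the default `dt`.
* **Neighbour search.** A cell list over the periodic box with cell side
  ≥ the WCA cutoff, rebuilt every step; it is contractually identical to
  the brute-force all-pairs sum (tested to 10⁻¹² on 50 seeded
  configurations).  Minimum-image convention everywhere, although the
  vesicle is far smaller than the box.
* **RNG.** The compiled loop uses its own xoshiro256++ generator seeded
  from `params$seed`, with a fixed draw order (active translations,
  active rotations, membrane translations), so trajectories are
  bit-reproducible for a given seed regardless of R's RNG state.  The
  R-level reference integrator `step_state()` uses R's global RNG and is
  cross-checked against the compiled loop on noise-free systems.
* **WCA between bonded neighbours** is kept on by default
  (`wca_bonded_neighbors`).  The source model is ambiguous; at
  $r \approx \sigma$ the extra repulsion only shifts the effective bond
  rest length by ~0.006σ, and the flag allows either convention.
* **Active-particle placement** uses a deterministic triangular lattice
  (widest spacing ≥ σ that fits all N inside radius R₀ − σ) rather than
  rejection sampling: placement is then bit-reproducible and capacity
  failures are explicit ("maximum feasible N" errors).  Orientations are
  the only random element of the initial state.
* **Overlap guards.** Exact zero pair distance aborts; pairs closer than
  0.3σ increment a counter surfaced as a "timestep too large?" warning,
  and a membrane whose bonds exceed 3σ at the end of a run triggers a
  "membrane ruptured" warning (sweeps flag such runs as failed).
* **Timestep at high density.** The reference regime was published with
  inertial (mass-bearing) Langevin dynamics at dt = 10⁻⁴ τ₀ = 0.01.  A
  purely overdamped Euler step at that dt overshoots deep WCA contacts
  when the interior is dense: contact stiffness k ≈ 10⁴ ε/σ² gives a
  stability limit dt ≲ γ/k ≈ 0.01, and force chains in a jammed
  interior push pairs past it, so at ρ = 0.6 some seeds blow up and at
  ρ = 0.7 most do.  The package keeps dt = 0.01 as the default (the
  stated regime, safe for ρ ≲ 0.5) and uses dt = 0.005 at ρ = 0.6 and
  dt = 0.002 at ρ = 0.7 in its own acceptance runs; ω′ at ρ = 0.6 is
  unchanged between dt = 0.01 and 0.005 (6.79 vs 6.77 ×10⁻³), so the
  physics is dt-converged where both are stable.

## Observables

* **Rotation.** Each monomer's polar angle about the instantaneous
  membrane centroid is accumulated frame-to-frame with increments wrapped
  into (−π, π]; the mean over monomers is β(t) and the vesicle's angular
  velocity ω′ is the least-squares slope of β over the post-burn-in
  window (default: second half), ensemble-averaged with a standard error.
  Measuring about the centroid keeps translation from aliasing into
  rotation.  Increments ≥ 0.95π raise an undersampling error — beyond π
  the accumulation is ambiguous by construction, so the guard fires just
  below the hard limit.
* **Membrane forces.** The per-frame force each monomer receives from
  active particles is recorded by the integrator itself (not recomputed
  by analysis code), then projected on the local tangent
  (normalised `mem[i+1] − mem[i−1]`, oriented counterclockwise via the
  shoelace sign) and the outward normal (tangent rotated −π/2).
  `P_n` is the monomer-mean *positive outward* normal force divided by
  the mean bond length — force per unit contour length.  The enclosed
  particles can only push outward (repulsive interactions), which is why
  the outward projection is the meaningful pressure; this is a documented
  package convention, as is the "stacked" criterion `N_s` (distance to
  nearest monomer ≤ the interaction range 2^{1/6}σ, configurable).
* **Shape.** Asphericity Δ = (λ₁−λ₂)²/(λ₁+λ₂)² from the 2×2 gyration
  tensor of the membrane monomers only (a flag-worthy choice: the
  interior particles are deliberately excluded, as "vesicle shape" means
  the membrane).  Interior angles come from signed turning angles, so
  reflex vertices are handled and the exterior angles always sum to 2π
  for a simple ring; ΔΦ is the time mean of the per-frame standard
  deviation (1/L normalisation).  Local curvature is the reciprocal
  circumradius of each monomer triplet — collinear triplets give 0, not
  an error — and its distribution is reported as κ/κ₀ with κ₀ = 1/R₀
  (61 bins over [0, 3] by default, widened if data exceed the range).
* **Diffusion.** g₃(t) is the MSD of the centre of mass of all N + L
  particles (equal masses) from unwrapped coordinates, averaged over
  multiple time origins spaced about one rotational correlation time
  1/D~θ~ apart, on log-spaced lags.  The closed-form theory

  $$g_3(t) = 4Dt + A\left[e^{-D_\theta t}\cos(\omega t + \phi_0) - \cos\phi_0\right]$$

  with $A = 2NV_0^2 / ((D_\theta^2+\omega^2)(N+L)^2)$, $D = AD_\theta/4$
  and $\cos\phi_0 = (D_\theta^2-\omega^2)/(D_\theta^2+\omega^2)$ treats
  the swimmers' propulsion forces as uncorrelated and neglects
  translational noise.  The phase branch is fixed to $\sin\phi_0 \ge 0$
  (i.e. $\phi_0 = \mathrm{atan2}(2D_\theta\omega, D_\theta^2-\omega^2)$):
  that is the unique branch for which g₃(0) = 0 and g₃′(0) = 0, verified
  against direct numerical quadrature of the underlying force-correlation
  integral to 10⁻⁸.  `fit_deff()` keeps A and φ₀ fixed and fits the
  single linear parameter D~eff~ in closed form over the default window
  t ∈ [0.1/D~θ~, 10/D~θ~], which spans the damped oscillation and the
  diffusive regime.  For theory comparisons the translational noise can
  be switched off (`translational_noise = FALSE`); with it on, the
  composite gains an extra 4·D₀/(N+L)·t that the theory does not contain.

## What the synthetic data does and does not establish

All test inputs are generated in code: seeded runs of the simulator
itself, regular polygons, ellipses, rigid rotations, and ensembles of
non-interacting free swimmers (`eps = 0`) whose MSD has a closed form.
A green suite establishes that the force field matches its formulas and
an independent gradient check, that the integrator is consistent and
reproducible, that the observables hit closed-form values on geometric
fixtures, and that the scaled-down stochastic behaviour (rotation
optimum near ω ≈ 0.04, shape trends, MSD oscillation at period 2π/ω)
reproduces at reduced statistics with quoted standard errors.  It does
**not** establish behaviour at the full published scale (≥ 2×10⁸ steps,
500-run ensembles), hydrodynamic effects (absent from the model by
construction), or 3D behaviour.

## Known limitations and recorded deviations

* With active particles inside, the ring is under tension: at ρ = 0.3
  the vesicle swells by ~9% and the bonds sit systematically stretched
  by about the same fraction.  The stiff spring bounds the bond-length
  *fluctuations* (±0.1σ about the mean), not the literal window around
  r₀; the passive ring satisfies the literal window.  Halving `dt` does
  not change this — it is physics (membrane tension), not integrator
  error.
* Ensemble sizes are desk-scale (default 8–16 replicates with standard
  errors) instead of the published >500 runs; run lengths default to
  2×10⁶ steps.  Full-scale values are reachable through configuration.
* The collision-angle mechanism is used qualitatively; no per-collision
  decomposition is attempted.
* The membrane has no bending stiffness: curvature statistics describe a
  freely-jointed ring under WCA + bond forces only.
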