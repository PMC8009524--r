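---
title: "Frozen-density embedding for real-time TDDFT: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frozen-density embedding for real-time TDDFT: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
partitioned model and its assumptions, the parameters that matter, what the
shipped fixtures emulate (and do not), and the numerical decisions taken
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The model

### Subsystem partitioning

The supersystem electron density is split as `rho_tot = rho_I + rho_II`,
where subsystem I (the *active* molecule) is treated self-consistently and
subsystem II (the *environment*) is computed once, in isolation, and then
frozen. The active subsystem feels the environment through a local
one-electron embedding potential

```
v_emb(r) = v_nuc_env(r) + v_coul_env(r) + v_nad_xc(r) + v_nad_kin(r)
```

whose four parts are the environment's nuclear attraction, the Coulomb
potential of its frozen density, and the *nonadditive* exchange-correlation
and kinetic potentials `v[rho_I + rho_II] - v[rho_I]`. The nonadditive
kinetic term exists because the orbitals of the two subsystems are never
mutually orthogonalized; an orbital-free kinetic functional must supply the
repulsion that Pauli exclusion would otherwise provide. We use the
Thomas-Fermi functional `T_s = C_TF Integral rho^(5/3)` there — the standard
zeroth-order choice, adequate for weakly overlapping (hydrogen-bonded,
van-der-Waals) partitions and increasingly wrong as the subsystems share
covalent density.

Assumptions inherited from this model, in decreasing order of severity:

* **Frozen environment (uncoupled response).** Only subsystem I responds to
  the external field. The embedding potential still varies in time because
  it depends on `rho_I(t)`, but environment polarization and excitonic
  coupling are absent. Good for localized excitations of a solvated
  chromophore; wrong when the environment absorbs at the same energies.
* **No freeze-and-thaw.** The environment density is never relaxed in the
  field of the active subsystem. For neutral hydrogen-bonded environments
  the first-order polarization effect is small; for ionic environments it is
  not, and such systems are out of scope.
* **Closed-shell, spin-restricted, LDA.** The backend implements Slater
  exchange with VWN5 correlation only. All internal consistency checks
  (real-time vs linear-response, shifts, conservation laws) are
  functional-agnostic, so nothing in the validation logic depends on this
  choice — but absolute excitation energies are LDA-quality.

### Ground state: split-SCF

The initial condition of an embedded propagation is a *polarized* ground
state: `split_scf()` alternates (a) an SCF of the active subsystem with a
frozen embedding-potential matrix and (b) a rebuild of `v_emb` from the
relaxed active density, until successive active SCF energies agree to 1e-8
hartree (at most 50 macro-iterations, error on failure). One rebuild per
macro-iteration — rather than per SCF micro-iteration — was chosen for
stability and cost; both paths share the fixed point, which the test suite
verifies by rebuilding once more at convergence and checking the energy is
stationary.

No double-counting correction is applied to embedded total energies: the
reported SCF energy simply includes `tr(D V_emb)`. Only energy *differences*
(shifts, polarization energies) are meaningful, and the package reports the
polarization energy as the isolated-functional energy of the polarized
density minus the isolated ground-state energy, which is nonnegative by the
variational principle.

### Real-time propagation

The one-electron density matrix in the (polarized) ground-state MO basis
follows the Liouville-von Neumann equation `i dD/dt = [F(t), D]`, integrated
with the second-order midpoint Magnus propagator
`U = exp(-i F(t + dt/2) dt)`, evaluated by exact eigendecomposition — exactly
unitary for Hermitian `F`, so the spectrum, trace and idempotency of `D` are
conserved by construction and any drift measures Fock-build error, not
integrator error.

The midpoint Fock is refined by a predictor/corrector: predict by linear
extrapolation from the two previous midpoint Focks (first step: the Fock at
`t`), propagate, rebuild the midpoint Fock from the interpolated density
`(D(t) + D(t+dt))/2`, and iterate until the propagated density moves less
than `pc_tol` in max-norm between iterates. Converged, the scheme is
time-reversal symmetric; the suite drives a kicked water molecule 100 steps
forward and 100 backward and recovers the initial density to 1e-6.

### Fields and spectra

* **delta kick** `E(t) = kappa delta(t) n`: applied analytically at `t = 0`
  as the unitary boost `exp(-i kappa P_n)` of the density. With
  `kappa = 1e-5` a.u. the response is linear to well below 0.5% (the suite
  checks `kappa` vs `2 kappa`), and one kick exposes all dipole-allowed
  excitations at once.
* **cos^2 laser pulse**
  `E(t) = E0 cos^2(pi (t - tau/2)/tau) sin(omega0 t) n` on `[0, tau]`, with
  `tau = n_cycles * 2 pi / omega0` unless overridden. This closed form was
  fixed as the package's envelope definition.
* **Strength function** `S(omega) = (2 omega / 3 pi) sum_p Im alpha_pp`,
  with `alpha_pp = FT[mu_p^ind]/kappa` from three kicks. The Fourier
  transform uses diagonal Pade approximants (order `floor(N/2)`, denominator
  from a least-squares Toeplitz solve, singular systems falling back to the
  plain discrete sum with a warning), which resolve line positions far below
  the `2 pi / T` limit of a bare FFT — essential at the 2000-3000-step
  problem sizes used throughout.
* **HHG spectrum** `P(omega) = |Integral_0^tau mu(t) exp(-i omega t) dt|^2`
  by plain discrete quadrature with rectangular truncation at the pulse end
  `tau` — deliberately no Pade and no apodization, since harmonic plateaus
  are broadband and the windowing convention is part of the observable's
  definition here.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `dt` | 0.1 | a.u. time | resolves dynamics up to a few hartree with Magnus O(dt^3) error; the conservation suite runs 9000 steps at this value |
| `pc_tol` | 1e-7 | max-norm of D | tight enough that time-reversal holds to 1e-6 over 100 steps; 1-3 corrector iterations per step in practice |
| `pc_max_iter` | 20 | — | exceeding it is a hard error: the instability signal, never silently absorbed |
| `emb_update_stride` | 1 | steps | rebuild `v_nad` from the instantaneous density every step; 0 freezes the potential (static-embedding limit); the suite shows stride 10 moves the lowest peak by far less than 0.02 eV |
| `kappa` | 1e-5 | a.u. field impulse | linear-response regime |
| `gamma` | 1e-4 | a.u. | spectral damping; peak positions are insensitive across [1e-4, 4e-4] |
| omega grid | 0 to 1.0 step 1e-4 | a.u. | covers valence excitations to ~27 eV at 0.003 eV resolution |
| grid preset | `medium` | — | see below |
| `rho_min` | 1e-10 | bohr^-3 | density floor below which LDA/TF potentials are set to zero, so `rho^(-1/3)`-type factors cannot amplify quadrature noise in near-vacuum regions |

## Numerical choices

**Integration grids.** Atom-centered product quadrature: `nrad`
Gauss-Legendre radial nodes under the mapping `r = Rm (1+x)/(1-x)` with
`Rm = max(1, Slater radius)`, times a Gauss-Legendre (cos theta) x uniform
(phi) angular product, with Becke fuzzy-cell partitioning (three smoothing
passes, no atomic size adjustment — with these radial scales the size
adjustment was found to degrade the overlap-quadrature error slightly).
The `medium` preset (40 x 14 x 28 per atom) reproduces analytic overlap
matrices to ~1e-6 per element and electron counts to better than 1e-5
relative; `coarse` (25 x 8 x 16) is used for the strong-field fixture where
spectral morphology, not sub-microhartree quadrature, is at stake. Grid
points without active-basis support are dropped when a system is assembled —
they cannot contribute to any projected matrix element.

**Embedding grids.** Default scope is supramolecular (active + environment
centers); `active_only` is available and the suite checks both scopes give
consistent spectra. Environment electrostatics are evaluated *analytically*
(attraction-type integrals of the environment density's basis
representation) rather than by grid-on-grid quadrature — accurate where it
matters most, near the active region — and computed once per run: they are
frozen, and the suite asserts byte-identical values across rebuilds. The
component summation order (nuclear, Coulomb, XC, kinetic) is fixed for
bitwise reproducibility.

**Linear-response cross-check.** The Casida solver shares the integrals and
grids with the propagation but none of its dynamics: for a pure density
functional `A - B` is diagonal and the singlet eigenproblem
`[diag(w_ia^2) + 2 sqrt(w) K sqrt(w)] Z = w^2 Z` with
`K = 2[(ia|jb) + (ia|f_xc|jb)]` is solved by direct diagonalization. For
embedded references the pointwise embedding kernel
`f_xc[rho_tot] - f_xc[rho_I] + f_TF[rho_tot] - f_TF[rho_I]` is added, which
is exactly the linearization of a propagation whose embedding potential
tracks the instantaneous active density — making rt and LR agree not just
for isolated molecules but for embedded ones, shift for shift. This was an
open design point (one could instead freeze `v_emb` in both routes); the
dynamic-kernel convention matches the default `emb_update_stride = 1`.

**VWN variant.** "LDA correlation" is ambiguous across codes; VWN5 was fixed
as the package's convention. The independent check is not another library
but the identity `v = d(rho e)/drho`, verified by central differencing on
random densities.

**Pade order.** Signals longer than `2 * max_order + 1` points (default
order cap 1200) are decimated before the Toeplitz solve; the spectral window
of interest (< 1.2 a.u.) lies far below Nyquist even after decimation, and
the solve stays O(minutes-free) at every problem size the package runs.

**Degenerate inputs.** Zero kick strength is the identity; zero environment
density collapses every nonadditive quantity to exactly zero (floored, not
rounded); grid points coincident with environment nuclei are regularized
with a warning; non-Hermitian midpoint Focks beyond 1e-10 abort the run —
that symptom means a broken Fock build, and absorbing it would corrupt the
unitarity guarantees silently.

## What the fixtures emulate — and what passing tests do not show

The shipped geometries (`h2o`, `nh3`, the hydrogen-bonded `h2o_nh3_adduct`,
ring-shaped `h2o_cluster_n`) are literature-standard monomers and generated
hydrogen-bond arrangements: physically sensible, *synthetic* stand-ins, not
coordinates from any published cluster snapshot. Together with the minimal
(STO-3G) and 6-31G bases they define the package's study conditions:

* delta kicks of `kappa = 1e-5`, 2000-9000 steps of `dt = 0.1` (4.8-21.8 fs);
* the water-ammonia adduct at a 2.95 Angstrom O...N hydrogen bond;
* a cos^2 pulse with `E0 = 0.054` a.u. (1.0e14 W/cm^2), `omega0 = 0.05696`
  a.u. (Ti:sapphire, 1.55 eV), 10 cycles for the reduced strong-field
  fixture (the cutoff arithmetic uses the standard 20-cycle parameters).
  The pulse is polarized perpendicular to the water plane: on that axis a
  reflection symmetry forbids even harmonics exactly, so odd-harmonic
  dominance is a sharp diagnostic. Along the permanent dipole the molecule's
  nonzero hyperpolarizability makes even orders symmetry-allowed, and in a
  bound-state basis (no recollision continuum, hence no true plateau) that
  quadratic response would bury the weak high harmonics.

Passing tests therefore demonstrate *internal correctness* — propagator
exactness against closed forms, conservation laws at production step counts,
rt/LR agreement to 0.05 eV including the embedding shift, stride robustness,
odd-harmonic dominance under a strong field — under small-basis, LDA, fixed
geometry conditions. They do not certify basis-set-converged excitation
energies, literature-geometry shift magnitudes (published values for
aug-cc-pVTZ-class bases and MD-snapshot geometries differ from these
fixtures'), HHG cutoffs beyond the semiclassical estimate, or any system
where environment response matters.

## Known limitations

* Gaussian s and p shells only (H through Ne in STO-3G; H, N, O in 6-31G):
  enough for the shipped fixtures, not for polarization-augmented bases.
* One Gaussian backend for both subsystems; reference implementations of
  this method family pair a Gaussian active code with a Slater-basis
  environment code, so absolute numbers are not transferable.
* LDA only (active XC and nonadditive XC); Thomas-Fermi only (nonadditive
  kinetic) — no GGA kinetic functionals.
* No ionization channel: localized bases cannot describe the continuum, so
  strong-field observables above the saturation intensity (and HHG plateau
  intensities generally) are qualitative.
* Uncoupled response only; no Ehrenfest nuclear motion; no absorbing
  boundaries.
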