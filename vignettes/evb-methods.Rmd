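---
title: "Methods: two-state EVB free energies and variant screening analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-state EVB free energies and variant screening analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evbscreen)
```

## The model

A reactive event is represented by two diabatic valence-bond states —
the reactant bonding pattern (here: proton bound to the donor) and the
product pattern (proton bound to the acceptor). Each state is an
ordinary force field: Morse or harmonic bonds, harmonic angles, partial
charges and Lennard-Jones parameters, with the pairs bonded *in that
state* excluded from that state's nonbonded sum. State 2 additionally
carries a constant gas-phase shift $\alpha$. The adiabatic ground
surface is the lower eigenvalue of the $2\times2$ Hamiltonian with
constant coupling $H_{12}$:

$$E_g = \tfrac12(\varepsilon_1+\varepsilon_2)
      - \tfrac12\sqrt{(\varepsilon_1-\varepsilon_2)^2 + 4H_{12}^2},$$

and the mixing weights $c_1^2, c_2^2$ follow from the eigenvector
(equivalently, $c_1^2 = \partial E_g/\partial\varepsilon_1$). A constant
$H_{12}$ is the common calibration choice; a distance-dependent coupling
is deliberately out of scope at this system size.

Two conventions are fixed package-wide and worth stating prominently:

* **Energy convention $k\,d^2$** (not $\tfrac12 k\,d^2$) for harmonic
  bonds, angles and all positional restraints, so force constants quoted
  in kcal mol⁻¹ Å⁻² are usable verbatim.
* **Gap sign convention** $x = \varepsilon_1 - \varepsilon_2$ with state
  1 = reactant, so the reactant basin sits at negative $x$. The
  generators construct systems consistent with this.

Units everywhere: kcal/mol, Å, fs, e, amu; the Coulomb constant is
332.0636 kcal Å mol⁻¹ e⁻². No nonbonded cutoff is applied: the systems
this package targets are small droplets where exact sums are affordable
and make the analytic oracles exact.

## Sampling

Dynamics are velocity-Verlet (trajectory-equivalent to leapfrog), with
either a Langevin thermostat (BAOAB splitting; the default, because it
samples the canonical ensemble that the free-energy estimators assume)
or a Berendsen thermostat (offered for protocol fidelity with the
droplet simulations this package emulates; it does *not* generate the
canonical ensemble and is not used in any estimator test). Bond
constraints are not implemented; stability comes from timesteps of at
most 1 fs (0.1 fs during low-temperature minimization), which the stiff
Morse proton bond tolerates comfortably.

The droplet boundary is a layered restraint model: atoms whose
*reference* positions lie in the inner 85 % of the sphere are free,
the outer shell is held by 10 kcal mol⁻¹ Å⁻² positional restraints,
anything outside the sphere by 200 kcal mol⁻¹ Å⁻², and bath particles
feel a half-harmonic radial wall at the surface. This emulates the
surface-constrained droplet boundary of the original protocol without
its surface-polarization machinery. The default equilibration schedule
mirrors that protocol in shape — a 1 K minimization-like stage at
0.1 fs with 200 kcal mol⁻¹ Å⁻² restraints, then heating to 300 K while
the reactive-region restraint decays geometrically from 200 to
0.5 kcal mol⁻¹ Å⁻², then unrestrained dynamics — with desk-scale
durations (total ≈ 1.8 ps by default; every figure is configurable).

## Free-energy estimators

Sampling runs on mapping potentials
$\varepsilon_m = (1-\lambda_m)\varepsilon_1 + \lambda_m\varepsilon_2$
over an even $\lambda$ grid (11 windows by default; 51 reproduces the
full protocol). Free energies between adjacent windows use Zwanzig
exponential averaging in both directions; the reported value is the
forward/backward mean and the difference is reported as hysteresis — a
useful convergence diagnostic, since wide per-step energy distributions
show up immediately as large hysteresis.

The profile on the gap coordinate is the standard umbrella estimator

$$g(x_b) = \Delta G(\lambda_m)
 - k_BT\,\ln\left\langle \mathbf{1}_b\,
   e^{-\beta(E_g-\varepsilon_m)}\right\rangle_m,$$

combined across windows per bin. Windows are weighted by sample count
by default; inverse-variance weighting (delta-method variance of the
log-average) is available by flag — the choice matters little on the
systems tested, and both are provided because neither can claim
canonical status. Defaults: 50 bins over the observed gap range, bins
with fewer than 10 samples masked as `NA` rather than interpolated.
$\Delta G^\ddagger$ is measured from the masked-profile maximum nearest
$x=0$ (ties toward higher $g$), because the transition state of a
two-state model sits at the diabatic crossing; $\Delta G_0$ is the
difference of the flanking minima. A monotone profile raises an
explicit "no barrier" error, and a single replicate reports s.e.m. 0
with a warning rather than pretending at precision.

Calibration against a reference reaction exploits the near-diagonal
structure of the problem: $\alpha$ moves $\Delta G_0$ with slope ≈ 1 and
$H_{12}$ moves $\Delta G^\ddagger$ with slope ≈ −1, so alternating
secant updates (falling back to those unit slopes when the local secant
is degenerate) converge in a handful of iterations. The internal
simulations reuse a fixed seed, which makes the objective deterministic
— without this, a 0.1 kcal/mol convergence tolerance would be
meaningless at desk-scale sampling. Infeasible targets
($\Delta G^\ddagger < \max(0, \Delta G_0)$) are rejected up front.

The reorganization energy is estimated from the endpoint ensembles,
$\lambda_R = \tfrac12(\langle\varepsilon_2-\varepsilon_1\rangle_0 -
\langle\varepsilon_2-\varepsilon_1\rangle_1)$, which for equal-force-
constant harmonic diabats reduces to $k\,d^2$ — one of the package's
analytic cross-checks.

## LRA group decomposition

Per-group electrostatic contributions to the barrier are
$\tfrac12(\langle\Delta U\rangle_{RS} + \langle\Delta U\rangle_{TS})$
where $\Delta U$ is the Coulomb interaction between the group and the
reactive region evaluated with transition-state minus reactant-state
charges, divided by a dielectric factor (default 4, appropriate for a
buried hydrophobic site). Two genuinely open choices were resolved as
follows:

* the **TS ensemble proxy** is the mapping window whose mean gap is
  nearest zero, i.e. the window sampling the diabatic crossing;
* the **TS charge set** is the per-frame mixing-weighted blend
  $c_1^2 q^{(1)} + c_2^2 q^{(2)}$ — consistent with the two-state
  picture — with a fixed-$\lambda$ blend available as an alternative;
* the dielectric scaling is applied **uniformly** to all groups, since
  restricting it to ionized groups would require a protonation model
  this package does not contain.

Contributions below 2 kcal/mol in magnitude are flagged `small`; for
this reaction class most per-residue contributions are expected to be
small because the transition state resembles the reactant in both
geometry and charge distribution.

## Kinetics and screening

Rates come from blank-corrected Beer–Lambert conversion (default
extinction coefficient 15 800 M⁻¹ cm⁻¹ at 380 nm). Michaelis–Menten
parameters are unweighted nonlinear least squares (Levenberg–Marquardt
via minpack.lm) started from a Hanes linearization; standard errors come
from the fit covariance. Because substrate solubility often makes
saturation unreachable in this assay class, fits with
$\max(S) < K_M$ are flagged curvature-poor rather than rejected.
TST conversions use $\Delta G^\ddagger = RT\ln(k_BT/(h\,k_{cat}))$ at
298.15 K with transmission coefficient 1; the inverse is exact to
1e-10, and the rounding convention for table comparisons is half away
from zero at one decimal. Cosolvent extrapolation is a straight
ordinary-least-squares line — the short extrapolations it is meant for
do not support higher-order fits.

Screening analytics operate on variant tables (delimited text with
"value ± error" cells, header aliases, and unit normalization to 1/s,
mM, M⁻¹ s⁻¹). "Substantially enhanced" is operationalized as
efficiency ≥ 1.5× the reference — a threshold, exposed as an argument,
chosen because it cleanly separates the enhanced group in the packaged
tables. Efficiency consistency (`kcat/KM` vs the independently fitted
column) is *reported*, not enforced, because independently fitted
efficiencies legitimately disagree with the ratio when saturation is
poor. Correlations are reported as signed Pearson $r$ together with
$r^2$; negative "R²" values sometimes quoted in this literature are
interpreted as signed correlation coefficients.

## The synthetic generators

`make_toy_reaction_system()` builds a donor–H–acceptor triad (Morse
proton bond in each state, harmonic donor–acceptor scaffold, mirrored
charge sets) in a nonpolar Lennard-Jones droplet with a radial wall.
The product shift is calibrated at generation time against a rigid 1D
proton scan so the scan's minimum-energy difference equals the
requested reaction free energy (to 0.005 kcal/mol); generation fails if
the calibrated triad has no forward barrier. Default parameters
(Morse $D$ = 80 kcal/mol, $a$ = 1.5 Å⁻¹, $r_0$ = 1.0 Å, D–A distance
2.8 Å) put the rigid-scan barrier in the 10–20 kcal/mol band typical of
measured proton-abstraction barriers in engineered eliminases. The bath
is uncharged by default — this keeps the environmental reorganization
small and the runs fast; `charged_bath = TRUE` gives the bath
alternating ±0.2 e charges to exercise the LRA group analysis.

`make_harmonic_diabat_system()` is the two-parabola Marcus picture
realised as a radial coordinate (frozen anchor + one mobile particle).
Because the particle moves in 3D, the radial Jacobian $r^2$ enters all
closed forms: the quadrature oracle integrates
$r^2 e^{-\beta E_g(r)}$, and a system with $\alpha = -2$ and minima at
2 and 4 Å has an equilibrium $\Delta G_0$ of
$\alpha - 2k_BT\ln(r_2/r_1) \approx -2.83$ kcal/mol, not $-2$. Tests
account for this; it is physics, not error.

`simulate_kinetics_dataset()` and `make_variant_table()` generate noisy
rate profiles and screening tables with planted structure (barriers
linear in the donor–acceptor distance over the plausible 2.64–4.25 Å
range, kcat derived by inverse Eyring so kinetics and thermodynamics
are mutually consistent).

What the generators do **not** emulate: protein electrostatics and
preorganization, slow conformational dynamics, charged/polar solvent
response, and any real force-field parameterization. Passing tests
therefore demonstrate that the estimators are correct and internally
consistent on systems with known answers — they say nothing about the
accuracy of any particular protein calculation, which additionally
requires a validated parameter set and orders of magnitude more
sampling.

## Problem sizes

Default analyses are sized for a single CPU: the droplet pipeline runs
11 windows × 5 ps × 5 replicates (the full protocol this emulates used
51 × 100 ps × 30, and every figure is configurable to those values);
the verification analyses in the test-suite and acceptance script use
up to 11 × 200 ps × 5 on the two-atom harmonic model and
11 × 20 ps × 10 on the 11-atom droplet, sizes at which the recovery of
planted reaction free energies is reliable to better than 0.5 kcal/mol.

## Known limitations

* Exponential averaging over 0.1-λ steps is noisy when the gap
  distribution is wide (reorganization energies of hundreds of
  kcal/mol); the hysteresis diagnostic exposes this, and more windows —
  not longer windows — is the effective remedy, exactly as in the full
  51-window protocol.
* The Berendsen option reproduces protocol shape, not canonical
  statistics.
* Nonbonded sums are exact (no cutoff, no periodic images), which is a
  feature at droplet scale and a non-starter for full proteins.
* PDB handling covers the ATOM/HETATM/MODEL/ENDMDL subset used for
  trajectories and small structures; crystallographic metadata is out
  of scope.
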