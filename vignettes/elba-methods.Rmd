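---
title: "Coarse-grained membrane dynamics with elbamd: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained membrane dynamics with elbamd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`elbamd` is a self-contained molecular dynamics package for the
electrostatics-based (ELBA) coarse-grain representation of hydrated
phospholipid membranes.  This vignette is the package's account of the
science it implements: the interaction model and its assumptions, the
parameters that matter and where they come from, the numerical choices,
and what the shipped tests do and do not demonstrate.

## The model

**Water.**  Each water molecule is one Stockmayer particle: a soft
Lennard-Jones sphere (`sigma` = 0.3 nm, `epsilon` = 1.95 kJ/mol) with an
embedded point dipole of 2.3 D.  Electrostatics act through a relative
permittivity of exactly 1; all dielectric screening is emergent from the
explicit dipoles.  The site's inertial mass (40 amu) and moment of
inertia (1 amu nm^2) are dynamical tuning parameters chosen to reproduce
the experimental self-diffusion coefficient; the *represented* molecule
still weighs 18.015 g/mol, and all density and volume bookkeeping in the
package uses that physical mass (the parameter file carries both values
as `mass` and `mass_phys`).  With the inertial mass used instead, the
model's equilibrium state would correspond to an absurd 2.2 g/cm^3, so
the two roles must not be conflated.

**Lipids.**  DOPC, DSPC and DOPE are 15 spherical sites: two headgroup
sites carrying opposite point charges (+0.7 e choline or amine, -0.7 e
phosphate), a glycerol site and two ester sites each carrying a
restrained point dipole, and two tails of five uncharged sites, each
site standing for three consecutive carbons.  Electron and atom counts
are partitioned per site so molecular totals match the molecular
formulas (434 e-/138 atoms for DOPC, 438 for DSPC, 410 for DOPE); the
electron-density profile deposits each site's electrons at its centre.
DSPC differs from DOPC only by the saturated reference angle on the
mid-tail triplets; DOPE replaces choline by a smaller amine site
(tail-sized `sigma`) with its own hydrogen-bond scalings.

**Interactions.**  All nonbonded terms are strictly truncated with
shifted-force corrections so both the potential and force vanish
continuously at the cutoff (0.9 nm for water-water, 1.2 nm otherwise):
Stoddard-Ford Lennard-Jones, shifted-force Coulomb, a charge-dipole term
whose radial scalar factor is shifted the same way, and the classical
dipole-dipole interaction under a C1 cubic switch running from
`0.9 * cutoff` to the cutoff.  Unlike pairs mix by Lorentz-Berthelot
rules; hydrogen-bonding pairs (water or amine against phosphate,
glycerol, ester; amine-water) get an `epsilon` boost `s_ij > 1`.  Bonds
are harmonic with half-prefactor convention and reference lengths
derived from the two Lennard-Jones diameters,
`r0 = (sigma_i + sigma_j)/2`.  Angles default to the cosine-harmonic
form `U = (ka/2)(cos th - cos th0)^2`; a true harmonic-in-angle form is
available through the `angle_style` key in the parameter file (see
"Design choices").  Glycerol and ester dipoles are restrained along
their reference bonds by `U = kd (1 - cos delta)`, with momentum- and
angular-momentum-conserving reaction forces on the bond sites.

## Integration and ensemble control

Point dipoles are linear rotors: the orientation is a unit vector, the
angular velocity is kept exactly perpendicular to it (the axial
component is unphysical), and orientations advance by an exact rotation
about the angular-velocity axis, preserving unit norm to round-off.
Translation and rotation are propagated together in a velocity-Verlet
half-kick/drift/half-kick cycle at a default 15 fs timestep.
Temperature and pressure use Berendsen weak coupling; lipid and water
baths couple separately, translational and rotational degrees of
freedom independently (`tau_T` = 1 ps), and pressure coupling offers
isotropic, semi-isotropic (membrane: z from `P_zz`, the x-y area
jointly, interface kept square) and anisotropic modes (`tau_P` = 5 ps,
compressibility 4.6e-5 atm^-1).  The net system momentum is removed
every step, and for bilayers the net lateral momentum of each
monolayer, which would otherwise contaminate lipid diffusion estimates.

Energy conservation: with all couplings off, the secular drift of the
total energy of a 216-site water box is about 4e-4 of |E| per 10^4
steps at 15 fs and scales approximately quadratically over 5-20 fs.
The shifted-force potentials are C1 but not C2 at the cutoffs, which
sets the floor on this drift.

## Observables

Depth-resolved profiles slice the box into slabs of about 0.1 nm along
the bilayer normal, the slab count fixed and the thickness recomputed
per frame as the box fluctuates; z = 0 follows the instantaneous lipid
mass centre.  Profiles are not symmetrised over the monolayers, so
symmetry is available as a statistical check.

* Electron density: per-slab electron count over slab volume; its
  integral recovers the system total exactly.  The bilayer thickness
  `D_HH` is the headgroup peak-to-peak distance.
* Lateral pressure: `pi(z) = P_T(z) - P_N(z)` from per-slab kinetic plus
  virial contributions accumulated during the run, with each pair's
  virial split half to the slab of each partner (Harasima assignment);
  three-body angle terms are assigned to the apex site's slab.
* Curvature elastics: first and second integral moments of `pi(z)` per
  monolayer (averaged over the two), spontaneous curvature
  `c0 = -M1 / kappa_m` with the monolayer modulus half the bilayer
  value, pivotal distance `delta` as the half-distance between the two
  global profile minima, and the Gaussian modulus from the zero-tension
  pivotal-plane expansion `kappa_G = M2 - 2 delta M1`.  The sign
  convention makes negative `c0` mean bending toward water (the
  PE-like direction).
* Electrostatic potential: double integral of the headgroup charge
  density minus the single integral of the z-projected dipole density
  (water + glycerol + ester), over the vacuum permittivity, referenced
  to bulk water; `delta_psi` is the core-minus-water difference, and a
  per-species decomposition is attached.
* Segmental order parameter `S` per tail-tail bond against the normal,
  averaged over the four bonds per tail then over lipids: 1 for
  normal-aligned, -0.5 in-plane, 0 isotropic.
* `K_A` from the area fluctuations (`kB T <A> / var(A)`), and `k_c` from
  `K_A` and `D_HH` through the polymer-brush relation
  `k_c = K_A (D_HH - h0)^2 / 24` with `h0` = 1 nm by default.
* Lateral lipid diffusion by the origin-averaged lateral displacement
  formula (`/4Nt`), bulk water diffusion from an MSD slope fit, and
  water permeability by hysteresis-counted full crossings through
  Fick's law `P = (N/2)/(t A dc)` with `dc` = 33.4 nm^-3.

## Parameter provenance and reconstruction

All numeric force-field values live in `inst/extdata/elba-ff.txt`,
never in code, and every output embeds the file's checksum.  The core
water parameters, the bonded rigidities (`kb` 1260 kJ/mol/nm^2, `ka`
30 kJ/mol, `kd` 10 kJ/mol), the headgroup sigmas and the site masses
are fixed by the published parameter set.  A number of values in the
shipped file are reconstructions calibrated against published
observables rather than transcriptions, and are documented as such in
the file header's spirit:

* tail/amine `sigma` = 0.47 nm: a three-heavy-atom bead; at this size
  two chains occupy about the experimental gel-phase area (47 A^2) and
  a DSPC bilayer ordered at 303 K stays ordered, while thinner beads
  melt even when compressed.
* head reference angle 90 degrees: puts the P-N headgroup dipole close
  to the membrane plane, the orientation observed experimentally; a
  collinear head points the dipole along the normal and drives the
  dipole potential of fluid PC bilayers negative.
* hydrogen-bond scalings and the glycerol/ester dipole magnitudes
  (2.0/3.0 D) follow the documented orderings (phosphate > ester >
  glycerol for water; amine strongest with phosphate and ester) with
  magnitudes chosen of the order of the water dipole.

## Design choices

* **Angle style.**  Both conventions are implemented; the shipped
  default is the cosine-harmonic form.  Note its stiffness is quartic,
  not harmonic, about a 180-degree reference; a probe with the
  harmonic form at the same `ka` over-orders the fluid phase (S near
  0.7 at 333 K), so the soft form is retained.
* **Rotational representation.**  Unit vector plus in-plane angular
  velocity.  Quaternions are deliberately avoided: a linear rotor has
  no physical axial degree of freedom.
* **Exclusions.**  Only directly bonded (1-2) pairs are excluded from
  nonbonded terms; 1-3 pairs interact, which is part of the effective
  bonded geometry.
* **Barostat scaling** is per-site, not per-molecule: with stiff CG
  bonds and coupling constants of picoseconds the difference is
  negligible and the simpler choice is exactly volume-preserving in
  composition.
* **Neighbour search.**  Cell-binned Verlet lists with a 0.2 nm skin,
  rebuilt when any site moves half the skin or the box changes; the
  box must exceed twice the largest cutoff or construction aborts.
* **Degenerate inputs.**  Site overlaps below 1e-6 nm and non-finite
  energies abort the run, returning the last logged state; angle
  gradients are evaluated through the cosine derivative and stay
  finite at 0/180 degrees; zero area variance yields an explicit
  non-finite `K_A` with a warning.
* **Initial bilayer geometry.**  Straight-chain conformations are
  compressed along z to the volume-consistent leaflet thickness before
  placement; without this the chains contract on relaxation and leave
  a vacuum lamella at the midplane that pressure coupling closes only
  on much longer timescales.  Random dispersions place compacted
  lipids (factor 0.7) under a hard 0.8 sigma overlap criterion.

## Problem sizes in the shipped tests

The validation suite runs at desk scale, chosen to exercise the physics
honestly in minutes: 512-site water boxes for the density (150 ps
production) and diffusion (300 ps) checks; 216-site boxes for the NVE
conservation ladder; 64-lipid DSPC bilayers (about 120 ps of production
after staged equilibration) for the gel/fluid contrast; a 32-lipid DOPC
dispersion run for about 0.9 ns for self-assembly.  At these sizes the
ordinal statements (gel more ordered, thicker and slower than fluid;
positive fluid-PC dipole potential led by the ester dipoles; assembly
into a single lamellar aggregate) are reproducible, while the
slow-converging absolute quantities of production-scale studies
(compressibility moduli, microsecond diffusion and permeability
coefficients, converged pressure-profile moments) are not expected to
match at these run lengths and are deliberately not asserted.

## Known limitations

* Truncated electrostatics: no Ewald or reaction field, by
  construction; the bulk dielectric constant is therefore not a
  well-defined observable of the model.
* Profiles assume a flat bilayer.  Systems beyond ~256 lipids undulate,
  which blurs slab averages and shrinks the projected area; the
  package warns rather than corrects (no undulation-corrected frames).
* The synthetic builders produce idealised starting states (lattice
  water, straight lipids); equilibration erases the lattice but any
  result quoted from very short runs inherits construction memory.
* Several force-field values are calibrated reconstructions (see
  above); absolute observables that depend on them (areas, moduli,
  potential magnitudes) carry systematic uncertainty beyond the
  statistical error of a run.
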