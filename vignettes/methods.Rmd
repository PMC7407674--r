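---
title: "Coarse-grained kinetic Monte Carlo simulation of protein-protein association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained kinetic Monte Carlo simulation of protein-protein association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`cgassoc` estimates bimolecular association rate constants
(k_on, M^-1 s^-1) for a two-protein complex by simulating many short
rigid-body diffusion trajectories of the two partners and counting how
often they find a native-like *encounter complex*.

## Two-site coarse-graining

Each residue is represented by two sites: its Calpha atom and a
side-chain functional center (SC). The SC is placed at the centroid of
the residue's side-chain heavy atoms; glycine's SC coincides with its
Calpha. The per-residue functional-center atom selections used by prior
coarse-grained work are not published as a table, so the centroid rule is
this package's documented, reproducible stand-in. Formal charges
(ASP/GLU -1, LYS/ARG +1, HIS neutral by default, all configurable) and
Kyte-Doolittle hydropathy scores sit on the SC site. All intramolecular
degrees of freedom are frozen: each protein moves as a rigid body, and a
pose is a rotation plus a translation of the centered reference
coordinates.

## The hybrid force field

The intermolecular energy is a weighted mixture

    E_tot = (1 - omega) * E_physics + omega * E_statistics,   0 <= omega <= 1

with all energies in units of kT (the Metropolis temperature is
therefore 1).

**Physics-based part.** Three terms:

* *Screened electrostatics* (Kim-Hummer form): for charged SC pairs,
  `q_i q_j / (4 pi eps0 D_eff r)` with the distance-dependent dielectric
  `D_eff = D_s exp(r / xi)`. `D_s = 80` is the solvent dielectric and
  `xi` the Debye length in Angstrom; `xi = 3.04 / sqrt(I)` converts an
  ionic strength in mol/L, with 10 A as the default when no ionic
  strength is supplied. The term is truncated at 30 A (several Debye
  lengths; the screened interaction is negligible there) and evaluated
  with minimum-image distances.
* *Hydrophobic contacts*: `-w_alpha * sum(HP_i + HP_j)` over SC-SC pairs
  within 7.5 A. Written with no distance dependence the term would be
  configuration-independent, so a contact cutoff is required; 7.5 A
  spans the first side-chain coordination shell. The sign convention
  makes burial of hydrophobic (positive-score) residues favorable; both
  the cutoff and the sign are configuration options. `w_alpha` (kT per
  hydropathy unit) balances hydrophobicity against electrostatics and is
  a free parameter: published work tunes it against a benchmark without
  reporting the value.
* *Excluded volume*: a stepped 12-6 term
  `eps_ij ((sigma0/r)^12 - (sigma0/r)^6)` where `eps_ij` is 5 kT inside
  the kind-dependent contact radius `sigma0` (3.8 A CA-CA, 2.8 A CA-SC,
  2.2 A SC-SC) and 0 outside.

**Statistics-based part.** A Go-like contact term over the *native
interface pairs*: residue pairs of the native complex whose side-chain
heavy atoms come within 5.5 A. Each pair carries its native SC-SC
distance `r0` and a strength `u_sc(i, j)` from a 20 x 20 contact
potential. With `x = r0 / r`, the default (`stat_mode = "go"`) form is

* attractive pair (`u_sc < 0`): `|u| (x^12 - 2 x^6)` - a well of depth
  `|u|` with its minimum exactly at the native distance;
* repulsive pair (`u_sc > 0`): `|u| x^6`;
* `u_sc = 0`: no contribution.

Two alternative modes implement the sign-function form in which an
attractive pair receives `-(x^12 + x^6)` (optionally scaled by `|u|`).
That form has no repulsive wall: its attraction grows without bound as
`r -> 0`, and because `r0` is always well above the SC-SC excluded-volume
radius, the excluded-volume term cannot compete with it (the prefactor
ratio is `(r0/sigma0)^12`, about 10^3). In simulations this sends most
trajectories into a collapsed, non-native trap: interface distances fall
below 2 A, energies reach -10^4 kT and beyond, and the association
probability stops responding to either the well depth or the trajectory
length. The `"go"` well is therefore the default; `"scaled"` and
`"literal"` remain available (and unit-tested) for comparison.

**The quasi-chemical contact potential.** `u_sc` is derived from a
library of binding interfaces by

    u_sc(i, j) = -kT ln[ N_obs(i, j) / (chi_i chi_j N_obs) ]

where `N_obs(i, j)` counts residue-type pairs in contact (5.5 A
side-chain atom criterion), `N_obs` is the total and `chi_i` the mole
fraction of type `i` among interface residues. Counting is symmetrized,
which makes `chi` the marginal of the pair counts and the table exactly
symmetric. Cells never observed receive a pseudo-count of 1 rather than
an infinite repulsion. Note an identifiability caveat: adding a constant
to every entry rescales the implied pair distribution uniformly, so the
table is recoverable from data only up to that gauge; any table that
*is* the quasi-chemical transform of some distribution satisfies
`sum chi_i chi_j exp(-u) = 1` at its own mole fractions.
`random_usc_table()` constructs ground-truth tables in that recoverable
form, which is what makes exact parameter-recovery tests possible. The
shipped default table (`default_usc_table()`) is generated by this
synthetic pipeline and is labelled synthetic; it is a working default,
not a reproduction of any literature-derived potential, whose source
library is not distributed.

## The kinetic Monte Carlo engine

Each trajectory:

1. **Random initialization.** Both centers of mass uniform in a cubic
   box (default edge 100 A), orientations uniform over SO(3) via random
   quaternions. Independent Euler-angle sampling would bias
   orientations, which is why the quaternion route is used even though
   Euler angles are the more common description. Placements with any
   site pair inside its excluded-volume radius are resampled (up to 1000
   attempts).
2. **Diffusion move.** Both proteins translate by isotropic Gaussian
   displacements (per-axis sd `sqrt(2 D_t dt)`) and rotate about a
   uniformly random axis through their center of mass by a Gaussian
   angle (sd `sqrt(2 D_r dt)`); `dt` defaults to 1 ns. Centers re-wrap
   into the periodic box; all inter-protein distances use the minimum
   image.
3. **Metropolis acceptance.** The move pair is accepted jointly with
   probability `min(1, exp(-(E_new - E_old)))`. Whether the two
   proteins' moves should be accepted jointly or independently is not
   settled; joint acceptance is the simpler correct chain and is what
   the engine does.
4. **Encounter check.** After every accepted move the association
   criteria are evaluated. A native contact is *restored* when its
   current SC-SC distance is within 2 A of `r0`. The default criterion
   is at least 3 restored contacts; restored percentage, RMSD to native,
   interface distance and total energy can be added, all combined
   conjunctively. On association the trajectory terminates (a
   configuration flag disables termination for landscape studies, where
   the final configurations of all trajectories are needed).

A trajectory runs at most `n_steps` (default 1000) steps. An ensemble
(default 10^4 trajectories, trajectory `t` seeded with `base_seed + t`)
yields the association probability `P` as the associated fraction;
trajectories are independent given their seeds, so results do not depend
on execution order.

**Diffusion constants.** Stokes-Einstein estimates in water at 298 K:
`D_t = kT / (6 pi eta R_h)`, `D_r = kT / (8 pi eta R_h^3)`, with the
hydrodynamic radius approximated as `0.9 Rg + 4` A. Boundary-element
hydrodynamics would be more accurate per protein, but the rate
conversion below rescales the ensemble anyway, so any monotone size
proxy serves; both constants are overridable per protein.

**Energy evaluation.** The engine evaluates energies through a
precomputed pair-index context (contact radii, charge products,
hydropathy sums and statistical coefficients are laid out once per
system). The public energy functions are the readable reference path;
the test suite asserts the two agree to numerical identity, and both are
checked against naive double-loop oracles. The engine is vectorized base
R throughout: at the system sizes this package targets the work per step
is a handful of small matrix operations, where compiled code would add a
second implementation of every term without changing what the tests can
exercise.

## From probabilities to rates

    kon_i = kon_min * 10^[ (P_i - P_min) / (P_max - P_min) * N ]

`P_min`/`P_max` are the extreme probabilities over the analyzed set,
`kon_min = 1.03e5` M^-1 s^-1 anchors the slowest benchmark complex, and
`N = 4` spans the 1e5..1e9 range of measurable rates. `log10(kon)` is
affine and strictly increasing in `P`. Probabilities outside
`[P_min, P_max]` (possible when a frozen model is applied to new
complexes) are reported as censored bounds rather than extrapolated.
Benchmark agreement is summarized by the Pearson correlation between
`log10` simulated and experimental rates and by the count of predictions
off by more than one order of magnitude. The `omega` scan re-runs the
full ensembles at every weight - Metropolis acceptance depends on
`omega`, so re-mixing recorded energy components would bias the chain -
and recomputes `P_min`/`P_max` per weight. The criteria scan, by
contrast, is purely post hoc over recorded final diagnostics of
non-terminating ensembles; its default grids are contact count 0-10 by
1, percentage 0-10% by 1, RMSD 0-30 A by 3, interface distance 0-10 A by
1 and energy 0 to -30 kT by 3.

## Trajectory analysis

RMSD to the native complex superposes the current receptor Calpha sites
onto their native positions (least-squares Kabsch fit) and reports the
RMSD of the ligand Calpha sites; this isolates the binding-pose error
from trivial global motion. An all-Calpha variant is available. Which
atom set published RMSD traces use is not stated, so the choice is
documented here and kept configurable. Ligand coordinates are first
unwrapped to the periodic image nearest the receptor, so a partner that
crossed the boundary is not scored as artificially distant. The same
receptor-frame transform maps final ligand centers of mass into the
native frame for spatial (cloud) analyses; the energy-RMSD correlation
over final configurations of all trajectories is the funnel-likeness
summary.

# Synthetic fixtures and what they do (and do not) show

`make_toy_dimer()` builds two straight virtual-Calpha chains (3.8 A
spacing) facing each other, with alternating residues pointing their
side-chain site at the partner; the first `n_contacts` facing pairs sit
at the prescribed SC-SC distance (default 4 A) and every other
inter-chain side-chain pair is beyond the 5.5 A criterion, so the native
contact map is exact by construction. A seeded 0.05 A out-of-plane
jitter makes fixtures deterministic per seed without changing the
contact map. The emitted PDB files re-parse through the standard loader,
so every fixture exercises the real input path.

`make_contact_library()` samples residue-pair contacts from the
distribution implied by a given table and mole fractions, and attaches
the asymptotically recoverable (`effective`) table, making
parameter-recovery error a pure sampling quantity for gauge-consistent
inputs.

The toy dimers reproduce the *mechanics* of the method - contact
restoration, funnel energetics, Metropolis sampling, the probability
pipeline - but not the geometry or energetics of real protein
interfaces: they are quasi-planar, have few contacts, no charge
complementarity unless requested, and idealized diffusion constants.
Passing tests on them validates the algorithms, not the accuracy of
predicted rates for real complexes, which additionally depends on the
contact-potential source library, `w_alpha`, and the diffusion model.

## The funnel study conditions

The quantitative toy study used by the tests and the acceptance script
runs a compact 8-residue, 4-contact dimer (fixture seed 3) in a 35 A box
with `omega = 0.6`, `w_alpha = 0.2` kT, hydrophobic cutoff 10 A, uniform
attractive tables of depth 1, 3 and 6 kT, diffusion overridden to
`D_t = 8` A^2/ns and `D_r = 0.3` rad^2/ns, `dt = 1` ns, and 150
trajectories per condition (1000 steps for the depth scan; 250, 1000 and
3000 steps for the time scan; a non-terminating 800-step ensemble for
the energy-RMSD correlation). The elevated rotational diffusion shortens
the orientational search that dominates capture for a small, sparse toy
interface; the box is small enough that encounters are frequent but
larger than twice every interaction cutoff so the minimum-image
convention stays valid. These sizes put every property comfortably
outside its sampling noise while keeping the whole study at desk scale.

# Numerical choices and degenerate inputs

* Energies in kT throughout; Coulomb constant expressed as
  `e^2/(4 pi eps0) = 560.5` kT A at 298.15 K, computed from CODATA
  constants rather than hard-coded.
* Minimum-image distances require the box to exceed twice the largest
  interaction cutoff; configurations are otherwise legal but the image
  convention is the caller's responsibility (the defaults satisfy it).
* Overlapping charged sites (r = 0) are a hard error; excluded volume
  makes them unreachable in sampling.
* A pair with `u_sc = 0` contributes nothing in every statistical mode
  (the sign functions are defined to vanish at 0).
* Zero-contact native maps, empty contact libraries, degenerate
  probability sets (`P_max = P_min`) and zero-variance correlations are
  all hard errors with diagnostic messages, not NaN propagation; the
  scans report NA rows for combinations that degenerate mid-scan.
* Residues missing every side-chain heavy atom fall back to SC = CA with
  a warning; unmappable non-standard residue names are rejected (a small
  alias table handles MSE and friends).

# Known limitations

* Rigid bodies only: no induced fit, no flexible loops, no
  folding-upon-binding (complexes of that kind are outside the method's
  domain).
* Two bodies only; no hydrodynamic interactions between them.
* The shipped contact potential is synthetic; quantitative rate
  prediction for real complexes requires deriving `u_sc` from a real
  interface library via `derive_usc()`.
* `w_alpha` has no universally correct value; it should be calibrated
  per benchmark.
* The probability-to-rate conversion is benchmark-relative by design:
  it reproduces rates on the scale anchored by `kon_min` and `N`, not
  absolute diffusion-limited rates.
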