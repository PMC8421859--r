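---
title: "Methods: a coarse-grained community model of calcium-calmodulin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coarse-grained community model of calcium-calmodulin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Calmodulin (CaM) is a 148-residue calcium sensor built from two EF-hand
domains joined by a central linker that is helical in the extended crystal
form but highly flexible in solution. The solution ensemble of
calcium-loaded CaM mixes extended (dumbbell-like) and collapsed
conformations; NMR places the collapsed population near 10%
(collapsed:extended ratio about 0.11), while SAXS puts the mean radius of
gyration in the 20.0-22.5 A range. `cgcam` implements a coarse-grained
"community" model of this ensemble: an AWSEM-style three-bead force field
whose bioinformatic bias is drawn from a whole library of CaM structures at
once, plus an implicit-calcium charge model grounded in EF-hand coordination
chemistry, the sampling protocols (simulated annealing, Rg-restrained
umbrella sampling), and the analysis stack (Rg, Qw, MBAR/WHAM free-energy
profiles and the collapsed:extended ratio).

Each residue is reduced to its Calpha, Cbeta and carbonyl-O atoms (glycine
has no Cbeta). The total potential is

    V = V_BB + V_PMF + V_DH + V_FM

with backbone terms `V_BB = V_con + V_chain + V_chi + V_rama + V_excl`,
many-body terms `V_PMF = V_contact + V_burial + V_HB` (the hydrogen-bond
part splits into `V_beta + V_P-AP + V_helical`), screened electrostatics
`V_DH`, and the fragment-memory bias `V_FM`. Units are kcal/mol, Angstrom,
elementary charges and Kelvin throughout; force constants quoted as
kcal/A^2 are read as kcal/mol/A^2.

### Term-level choices

The published description of this class of force field fixes the
*structure* of the physics-based terms but not all of their constants, which
live in an external parameter set we do not have. The package therefore
ships its own versioned plain-text parameter file
(`inst/extdata/forcefield/params.json`) implementing the canonical shapes:

- `V_con`: harmonic springs `k (r - r0)^2` on Calpha(i)-Calpha(i+1),
  Calpha(i)-O(i), O(i)-Calpha(i+1) and Calpha-Cbeta linkages
  (r0 = 3.816, 2.44, 2.83, 1.54 A; k = 60 kcal/mol/A^2).
- `V_chain`: harmonic in `cos(theta)` about each Calpha
  (theta0 = 114.6 degrees, between the helical ~91 and sheet ~125 degree
  regimes, so neither is frozen out).
- `V_chi`: harmonic in the (unnormalized) scalar triple product of the two
  backbone bonds and the Calpha-Cbeta bond; the target value 16.0 A^3 is
  the value this construction takes midway between the ideal-helix (18.1)
  and extended (14.2) fixtures, and the small force constant
  (0.2 kcal/mol/A^6) makes it a soft L-chirality bias. Glycine is skipped.
- `V_rama`: periodic basins `-A exp(kappa (cos(phi - phi0) - 1))` on the
  Calpha pseudo-dihedral, with a helical basin at +50 degrees and an
  extended basin at -170 degrees. Degenerate (collinear) quadruplets
  contribute nothing.
- `V_excl`: one-sided harmonic repulsion below 4.0 A between
  Calpha/Cbeta beads at sequence separation of at least 2; C1-continuous at
  its cutoff by construction.
- `V_contact`: direct (4.5-6.5 A) and water-mediated (6.5-9.5 A)
  tanh-switched distance wells between sidechain beads at separation of at
  least 5, with pair strengths `gamma_ij` generated from a normalized
  Kyte-Doolittle scale (`gamma_ij = 0.1 + 0.5 (h_i + h_j)/2`). This is the
  package's own parameterization, not a reproduction of any published
  gamma table; the density modulation of the water-mediated strength is
  left to the burial term.
- `V_burial`: a smooth local density `rho_i` (tanh kernel, 9 A range) scored
  against three density wells ([0,3], [3,6], [6,9]) with residue-type
  propensities that favor burying hydrophobic types.
- `V_helical`: a Gaussian well on the Calpha(i)-Calpha(i+4) distance at
  6.2 A (its ideal-helix value). `V_beta` places cooperative Gaussian pairs
  on strand-like (i,j)/(i+1,j-+1) contacts; `V_P-AP` is a weak switched
  well that pre-stabilizes distant pairings before full pairing forms.

Because these constants are the package's own, the test surface for the
physics-based terms is *invariants*, not specific energies: analytic forces
against central finite differences (relative error below 1e-5 at a 1e-5 A
step), exact invariance under rigid rotations and translations, continuity
at every cutoff, and limiting cases (ideal geometry gives zero backbone
strain; separated beads give zero contact energy).

### Electrostatics

`V_DH = K_Elec sum_{i<j} q_i q_j / (eps_r r_ij) exp(-r_ij / l_D)` with
`K_Elec = 332.24 kcal mol^-1 e^-2 A` and kappa = 1/l_D = 0.0127 1/A by
default. Aspartate/glutamate sidechain beads carry -1 e,
lysine/arginine +1 e; histidine is neutral and termini carry no extra
charge. The reference protocol leaves the relative dielectric open;
the default is 80 (aqueous), configurable. Two profiles are provided
because the protocol's literal 3.5 A cutoff is far below the Debye length
(1/0.0127 = 78.7 A) and is most plausibly a typo: `"as-printed"`
reproduces 3.5 A literally, `"physical"` extends the cutoff to four Debye
lengths capped at half the box edge. The potential is energy-shifted at
the cutoff so crossing it is continuous; an unshifted mode exists for
closed-form checks. Whether the original simulations shifted the potential
is unstated, so the shifted default is a package choice. Nonbonded pairs
use the minimum-image convention in a 400 A cubic box; at a few hundred
beads a plain O(N^2) pair sweep is faster than cell lists, so none are
built.

### The fragment-memory bias

    V_FM = -lambda_FM sum_m sum_n W_n^m sum_{3 <= |i-j| <= 9} gamma_ij
           exp( -(r_ij - r_ij^m)^2 / (2 sigma_ij^2) ),   sigma_ij = |i-j|^0.15

The memory library stores, for each of the (up to 60) memory structures and
each of three segments — N-domain (residues 5-76), central linker (77-81),
C-domain (82-147) — the distances of all Calpha/Cbeta pairs whose residues
fall inside one segment with sequence separation 3 to 9. Segmentation is
the mechanism that keeps the linker flexible: pairs spanning a segment
boundary carry no bias, so the two domains can reorient freely. Design
readings where the convention is ambiguous: the inner sum is taken over the
separation band 3-9 (matching the formula's subscript) rather than as a
sliding fragment window; `W_n^others = 1` applies per memory and per
segment; memories missing residues simply skip the affected pairs; the
residue-type strength `gamma_ij` defaults to 1 uniformly (the published
residue-type table is not available), with a matrix hook for custom
tables. The bundled manifest lists the 60 memory PDB IDs with their
reported Rg values (14.60 A for the most compact, 21.80 A for the extended
crystal structure at index 60); a fetch script downloads them when network
access exists, and nothing in the tests requires it.

Named weight presets reproduce the explored model grid: family I varies
`lambda_FM` in {1, 0.1, 0.01} with all local weights 1; family II raises
the extended-crystal memory's weight uniformly (II.k: W = k on all three
segments); family III pins the two domains at weight 5 and varies the
linker weight (III.k: W = (5, k, 5)). `III.8` (lambda_FM = 0.1,
W = (5, 8, 5)) is the default preset in run configurations. Only the
tabulated rows exist as presets; asking for any other id is an error.

### Implicit calcium

EF-hand loops coordinate Ca2+ in a pentagonal bipyramidal geometry through
the acidic residues at canonical loop positions 1, 3, 5, 7, 9 and 12. The
package derives each loop's coordinating set as the D/E residues at those
canonical positions, which reproduces the reference loop table exactly:
loops 1, 2 and 4 have four coordinators, loop 3 has three. Three charge
models are implemented for each occupied loop (each adds exactly +2 e):

- **Approach III** (default): each of the n coordinating acidic residues
  receives `-1 + 2/n` e; non-coordinating acidic residues keep -1 e.
  Charges are stored exactly (-1/3, not the display-rounded -0.33).
- **Approach II**: approach III plus a stiff harmonic restraint
  (k = 30 kcal/mol/A^2) on the radius of gyration of the coordinating
  sidechain beads; the equilibrium value is measured from the reference
  structure, which the protocol does not fix — the package uses the chain
  it is applied to (by default) or any supplied reference.
- **Approach I**: the +2 e is spread evenly over the negatively charged
  residues near the loop. The source text supports both a loop-local and a
  whole-protein reading; the default spreads over the D/E residues inside
  the 12-residue loop (the per-loop contrast in the results argues for a
  local reading), and a `spread = "protein"` switch implements the other.

Re-applying a model to an already-modified loop raises an error, and
removing the model restores the stored default charges bit-exactly.

## Sampling

Dynamics are BAOAB-split Langevin in the NVT ensemble, 2 fs nominal
timestep (the smooth CG landscape means a step maps to more physical time
than 2 fs; no time mapping is applied). The thermostat is a package choice
— the protocol specifies the NVT ensemble but not a thermostat — picked for seeded
bit-reproducibility; with zero friction the integrator reduces to velocity
Verlet and conserves energy, which the tests exercise. The default
friction is 0.005 1/fs (5 1/ps), configurable. Initial velocities are
Maxwell-Boltzmann (`<v^2> = 3 kB T / m` per bead). Masses default to the
full residue mass on the Calpha bead — the CG radius of gyration is defined
over Calpha beads only, so this keeps Rg mass-weighting faithful — with
nominal 10/16 amu on Cbeta/O for the dynamics; a uniform split is available.

Simulated annealing cools linearly (another package choice; only the
endpoints are specified) from 450 K to 280 K over 2,000,000 steps.
Umbrella sampling restrains the Calpha Rg with `0.5 k (Rg - Rg0)^2`,
k = 50 kcal/mol/A^2, at 53 equilibrium positions from 13.00 to 26.00 A in
0.25 A steps; each window runs 5 replicas of 2,000,000 steps from the same
initial structure (the recorded frame whose Rg is closest to the window
target, earliest frame on ties) with different velocity seeds derived
deterministically from the master seed and the (window, replica) index,
recording every 1,000 steps for 10,000 frames per window. The restraint
gradient is the exact chain rule through Rg
(`dRg/dr_i = m_i (r_i - com) / (M Rg)`), validated against finite
differences.

## Analysis

- `Rg`: mass-weighted RMS distance from the center of mass. CG mode uses
  Calpha beads only; PDB mode uses all protein atoms (hydrogens included
  when resolved, waters and ions excluded) with standard atomic masses.
- `Qw = 2/((N-2)(N-3)) sum exp(-(r_ij - r_ij^ref)^2 / (2 sigma_ij^2))`,
  `sigma_ij = (1 + |i-j|)^0.15`, over Calpha pair distances. The quoted
  pair set (separation of at least 2) is inconsistent with the quoted
  normalization, which counts pairs at separation of at least 3; since the
  defining property is that self-comparison is normalized to exactly 1, the
  default pair set is separation >= 3, and a strict-as-printed mode is
  provided (its self-comparison exceeds 1).
- Classification: collapsed if Rg < 18.5 A, extended otherwise (the
  boundary is extended).
- PMF estimation: samples are decorrelated per window by
  statistical-inefficiency subsampling (`g = 1 + 2 sum (1 - t/N) C(t)`,
  truncated at the first non-positive autocorrelation), neighboring
  windows are checked for Rg-range overlap (a gap is a hard error naming
  the two windows), and the pooled data are unbiased with the multistate
  Bennett acceptance ratio. The MBAR equations are solved by a short
  self-consistent warm-up followed by Newton-Raphson with step halving
  (the plain self-consistent map needs tens of thousands of sweeps for 53
  stiff windows; Newton converges in a handful), to a 1e-10 tolerance on
  the dimensionless free energies. Binned WHAM is the independent fallback
  estimator: because the bias varies by several kBT across one 0.25 A bin,
  its self-consistent equations are solved on a 5-fold refined internal
  grid (with the bias factor averaged within each fine bin) and aggregated
  back to the reporting grid. Per-bin standard errors and errors on the
  derived observables come from a bootstrap over the decorrelated samples
  (no error-estimation convention is prescribed). Profiles are reported in kBT
  with the minimum bin at zero; reporting bins default to the 0.25 A
  window spacing.
- Observables: `Rg_mean = sum_b p_b Rg_b` and
  `gamma_ce = P(Rg < 18.5) / P(Rg >= 18.5)`, both taken from the
  normalized PMF probabilities (consistent with profiles "evaluated from
  the PMF"); an empty extended population reports `Inf` with an explicit
  flag attribute rather than an error.

## Synthetic data

The fixture generators are first-class, tested code:

- `make_ideal_helix()` / `make_extended_chain()` write standard PDB files
  (helical Calpha trace at 2.3 A radius, 1.5 A rise, 100 degree twist;
  planar zig-zag at 3.8 A spacing), with carbonyl-O placed exactly at the
  ideal bond distances and Cbeta placed chirally out of the backbone
  plane. `make_ideal_geometry_chain()` builds a chain exactly at the force
  field's ideal bonds and angles to probe the harmonic minima.
- `make_double_well_samples()` draws exact Boltzmann samples (inverse-CDF
  on a 4001-point grid) from a quartic double well plus each window's
  bias, and attaches the analytic PMF and well-population ratio. This is
  the oracle for the MBAR/WHAM estimators: because sampling is exact and
  independent, any systematic deviation beyond the bootstrap errors is an
  estimator defect, not a sampling artifact.
- `make_mini_memory_set()` produces rescaled, jittered copies of a base
  structure emulating (at toy scale) a memory library's spread of
  compactness.

What passing these tests does *not* show: the fixtures contain no real
protein geometry beyond ideal secondary structure, the double-well oracle
is one-dimensional and exactly sampled (real umbrella data are correlated
and the reaction coordinate is a nonlinear function of all coordinates),
and the package's own contact/burial constants are not the published ones
— so quantitative ensemble observables for real CaM (per-model Rg_mean and
gamma_ce) are outside what the desk-scale suite can certify. Reproducing
those requires the full 53-window, 5-replica, 2M-step protocol and the
original parameter set.

## Problem sizes in the shipped checks

The test-suite runs everything at sizes chosen so the whole suite completes
on a single CPU: gradient and isometry checks on 12-14-residue chains; the
estimator oracle at 53 windows x 300 exact samples; equipartition on a
two-bead oscillator over 3x10^5 steps and thermostat accuracy on a 10-bead
helix over 6x10^4 steps; and an end-to-end umbrella smoke run on a
16-residue helix with 8 windows x 50,000 steps x 1 replica, which must
yield a finite PMF whose per-bin errors grow when half the data are
discarded. The all-atom Rg spot checks on the extended and compact crystal
structures require downloading those PDB files (a fetch script is
provided); without them that check reports failure rather than silently
passing.

## Known limitations

- No explicit solvent, ions or Ca2+ particles; no Mg2+; no protonation
  prediction.
- The contact term's water-mediated well uses a fixed strength rather than
  a density-modulated one (the burial term carries the many-body density
  dependence).
- No replica exchange, no GPU or external MD backends; the engine is
  in-package and intended for CG-scale systems.
- Rg_mean is a PMF expectation, not a raw trajectory average; 2-D
  profiles, kinetics and SAXS/NMR forward models are out of scope.
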