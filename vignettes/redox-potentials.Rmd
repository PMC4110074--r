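---
title: "Computing protein reduction potentials with redoxpot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing protein reduction potentials with redoxpot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(redoxpot)
```

## The model

A redox-active protein accepts an electron at its cofactor (here, the
cysteine-ligated [4Fe-4S] cluster, PDB residue names SF4/FS4).  The
standard reduction potential versus the standard hydrogen electrode
(SHE) is assembled from a four-state thermodynamic cycle:

$$E^\circ = -\frac{\Delta G_{in} + \Delta G_{out} + \Delta G_{SHE}}{nF}$$

with $F$ = 23.0605 kcal mol$^{-1}$ V$^{-1}$ per electron and $n = 1$
(multi-electron reductions are decomposed into sequential
single-electron runs; only one site is treated per run).

$\Delta G_{in}$ is the intrinsic reduction free energy of the isolated
site, a library quantity.  $\Delta G_{out}$ is computed from structure:

$$\Delta G_{out} = \Delta G_{solv}(A^{red}) - \Delta G_{solv}(A^{ox})$$

where each "solvation" free energy is the grid Poisson–Boltzmann (PB)
energy of the whole system in a three-dielectric model minus that of
the bare site in vacuum, on identical grids.  Solvation here means *by
the rest of the protein plus solvent*, not by water alone: the site and
the environment are explicitly separated into segments, and the four
parameterized states (oxidized/reduced protein, oxidized/reduced
reference) differ only in the site's partial charges.

**Sign convention.**  We store $\Delta G_{SHE}$ positive
(+102.16 kcal/mol, i.e. $-(-4.43\ \mathrm{eV})F$) so that, with
$\Delta G_{out}$ large-negative (the environment stabilizes the extra
negative charge), $E^\circ$ lands on the conventional reduction scale.
The convention is pinned operationally by the package's own outputs
rather than by any single algebraic source; all *differences* of
$E^\circ$ are independent of it.

## Structure preparation

1. **Reading** (`read_structure`): all ATOM/HETATM records; alternate
   locations resolve to the highest-occupancy conformer, ties keeping
   the first in file.
2. **Partitioning** (`partition_segments`): amino acids form the
   protein segment (`a-pro` style ids), library-recognized cofactors
   the redox segment (`a-bad`), other known heteroatoms the good-het
   segment.  Crystallographic waters and non-selected monomers are
   discarded by default (a config flag keeps waters); every discarded
   atom is counted in a report so the partition is verifiably total.
3. **Site assignment** (`assign_redox_site`): side chains with any
   atom within **2.6 Å** of a cofactor heteroatom are moved into the
   redox segment.  The cutoff covers Fe–S bonds (~2.3 Å) while
   excluding nonbonded contacts; it is a package choice, since "directly
   bonded" needs an operational definition.  A ligand count differing
   from the library entry (four cysteines for [4Fe-4S]) is an error
   that lists what was found.
4. **Parameterization** (`parameterize_system`): charges are
   CHARMM36-style all-atom template values written into the package
   (backbone −0.47/0.31/0.07/0.09/0.51/−0.51, etc.); radii are
   simplified per-element-class Rmin/2 values (C 2.0, N 1.85, O 1.7,
   S 2.0, polar H 0.2245 Å ...).  The radii coarsening moves the
   dielectric boundary by at most ~0.1 Å relative to the full
   per-atom-type table; given the package's dominant grid error it is
   not the accuracy bottleneck.  Missing hydrogens (crystal structures
   carry none) are built from ideal internal coordinates — tetrahedral
   or trigonal geometry, staggered methyl/hydroxyl torsions — and
   missing side-chain heavy atoms from per-residue Z-matrix templates
   (rings closed approximately; adequate for dielectric volume and
   template charges, not for force-field work).
5. **Protonation** (pH 7 defaults): Asp⁻, Glu⁻, Lys⁺, Arg⁺, neutral
   Cys/Tyr, and neutral histidine as the **δ-tautomer (HSD)** unless
   overridden.  The tautomer choice is open in principle; δ was chosen
   and documented because the package must pick one, and the hsp/hse
   alternatives are one `set_protonation()` call away.  Protonation
   states are user-asserted — there is no pKa prediction.

Edits used by the analyses: `set_protonation` rebuilds one residue's
hydrogens and charges in place (idempotent); `knockout_charges` zeroes
charges but leaves radii and coordinates (the cavity is unchanged, so
the difference isolates the electrostatic contribution);
`mutate_residue` re-templates a residue keeping backbone (and any
shared side-chain atoms, e.g. CB) fixed.  Truncations (X→Ala/Gly) are
exact in this scheme; growing mutations are placed from the ideal
template without repacking and flagged approximate, because structure
optimization is deliberately out of scope (no force field is
included).

## The PB engine and its numerical choices

* Linear PB only, default ionic strength 0 (the physiological-salt
  term is available: $\varepsilon_s\kappa^2$ applied at ion-accessible
  solvent nodes).
* Dielectric boundary = union of atomic van der Waals spheres — no
  solvent-probe reentrant surface in this version.  Region precedence
  core > protein > solvent.  Edge-centred dielectric values are
  obtained by sub-sampling each edge (`nsub = 3` points, optional
  transverse quadrature `ntrans`) and harmonically averaging, which
  places the interface to sub-grid accuracy; both knobs were tuned
  against the analytic Born oracle only.
* Charges spread trilinearly to 8 nodes; grid charge equals atomic
  charge to machine precision.
* Two-level focusing: a coarse grid (1.0 Å, ≥ 20 Å padding,
  Debye–Hückel/Coulomb boundary summed over the source charges) feeds
  boundary potentials to the fine grid (default 0.4 Å — the
  performance default; 0.2 Å for accuracy — covering the molecule
  plus 5 Å).  Uniform-dielectric (vacuum reference) legs skip
  focusing: their analytic Coulomb boundary is exact, which also makes
  the uniform-ε null identically zero.
* Solver: Jacobi-preconditioned conjugate gradient on the 7-point
  stencil, relative residual 1e−6, fixed sweep order — runs are
  deterministic, and `build_states` output is byte-reproducible.
* Units: kcal/mol, kcal/(mol·e), Å; Coulomb constant 332.0637
  kcal·Å/(mol·e²); 23.0605 kcal/mol per eV.
* Energies are ½Σqφ over nodes and therefore include the grid
  self-energy of every discretized charge.  This is deliberate: the
  reference legs run on the *same* grid with the *same* discretized
  site charges, so self-energies cancel in ΔG_solv, and the
  environment's own self-energy cancels between the oxidized and
  reduced legs of ΔG_out.  No energy in isolation is meaningful; only
  the cycle differences are.

Both 78 (default) and 78.54 are accepted for water; the analytic
benchmarks use 78.54 because their closed forms do.

## The parameter library

Entries are human-readable key/value text (`inst/extdata/
redox_library.txt`): site residue names, couple, n_electrons, ΔG_in,
ΔG_SHE, expected ligand composition, per-state residue names, and an
atom table (name, radius, oxidized/reduced charge) covering cofactor
plus ligating side-chain atoms.  Validation is total: charge sets must
sum to the formal couple charges within 1e−3 e, the couple must drop
by exactly n_electrons = 1, radii must be positive; a fuzzed entry
violating any single rule is rejected with the rule named.

**Provenance caveat.**  The shipped ΔG_in values and per-atom charge
sets are *synthetic placeholders*: physically motivated (the reduction
increment spread over Fe, inorganic S and thiolate S; ΔG_SHE from the
−4.43 eV absolute SHE estimate) and invariant-satisfying, but not the
published quantum-chemistry library values, which this package does
not compute (no DFT machinery — a non-goal).  Absolute potentials
therefore carry an unknown offset until a user supplies real entries;
every shift, knock-out contribution and mutation effect is exactly
independent of ΔG_in/ΔG_SHE by cancellation, which the test suite
asserts bit-exactly.

## What the synthetic fixtures establish — and what they don't

* **Born ion** (`make_born_ion`): one charged sphere; oracle
  $-(k_cq^2/2a)(1-1/\varepsilon)$.  Validates cavity placement,
  focusing and energy assembly; 0.42 % error at 0.25 Å focused
  spacing.
* **Kirkwood sphere** (`make_offcenter_sphere`): off-centre charge in
  a spherical cavity; the oracle is an independent implementation of
  the image-charge series (summed to 1e−8).  Validates asymmetric
  boundary handling; 0.18 % at 0.25 Å.
* **Toy site peptide** (`make_toy_site_peptide`): a four-atom charged
  site inside ~30 single-atom polar dummies plus a toggleable charged
  residue.  It carries *two-path* oracles: the knock-out contribution
  of the toggle residue must equal the shift computed by direct
  toggling, exactly, and all ΔG_in/ΔG_SHE cancellations must be
  bit-identical.  Deterministic under its seed, byte-for-byte.
* **Synthetic mini-HiPIP** (`make_synthetic_hipip`): a geometry-built
  SF4 cubane (Fe–S 2.3 Å) with four cysteine ligands and a 22-residue
  wrapping shell including a histidine, labelled synthetic throughout.
  It exercises the *entire* real-protein code path (PDB parsing
  through E°) with no downloads.

A green test on these fixtures establishes correctness of the
electrostatics, the cycle algebra and the structure editing.  It does
**not** establish agreement with measured potentials of real proteins:
the fixtures have no conformational strain, no buried waters, no
charge-model error, and the mini-protein's site is far more
solvent-exposed than a real HiPIP cluster.

## Known limitations

* **Grid sensitivity on exposed sites.**  Between 0.4 Å and 0.2 Å
  spacings the mini-protein's E° moves by ~0.07 V, above the ~0.05 V
  error scale expected for a buried cluster in a full-size protein.
  The floor is analytic: the Born benchmark alone shifts 0.4 kcal/mol
  between those spacings, and a q: −1→−2 couple multiplies Born-type
  errors by 3 (q² differencing), i.e. ~0.05 V before any environment
  enters.  For real, buried sites most of this cancels; for small
  exposed model systems it does not.  Use 0.2 Å (and `ntrans = 2`)
  when absolute numbers matter.
* Vacuum-sphere surface only (no solvent-excluded surface), linear PB
  only, no apolar solvation term.
* No force field: no minimization, no rotamer repacking, no "slight
  optimization" after mutation — growing mutations are approximate by
  construction.
* Hemes, rubredoxin and [2Fe-2S] sites are not in the shipped library
  (the format accommodates them).
* The lesson-style workflow on the real *Chromatium vinosum* HiPIP
  (PDB 1CKU, His42 protonation/knock-out/H42A) is implemented in
  `run_lesson()` and asserted in the acceptance tests, but the
  structure must be supplied by the user; it is not redistributed with
  the package and offline environments cannot fetch it.
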