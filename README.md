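# redoxpot

Reduction potentials of redox-active proteins from structure, by
continuum electrostatics.

## The problem

Electron-transfer proteins — ferredoxins, HiPIPs and their relatives —
carry cofactors such as the cysteine-ligated [4Fe-4S] cluster whose
tendency to accept an electron is measured by the standard reduction
potential E° (volts vs the standard hydrogen electrode, SHE).  The
protein matrix tunes E° over hundreds of millivolts: a buried charge,
a protonated histidine or a single point mutation can shift it by
10–100 mV.  Predicting those shifts from a crystal structure, fast
enough to scan every residue, is what this package does.

The free energy of reduction is decomposed over a four-state
thermodynamic cycle:

    E° = −(ΔG_in + ΔG_out + ΔG_SHE) / (nF)

* **ΔG_in** — intrinsic reduction free energy of the isolated redox
  site, a property of the cofactor/couple precomputed by quantum
  chemistry and stored in a parameter library;
* **ΔG_out** — environmental contribution,
  ΔG_solv(reduced) − ΔG_solv(oxidized), where the "solvation" of the
  site is by the rest of the protein plus solvent.  Each ΔG_solv is
  the difference between a Poisson–Boltzmann (PB) grid energy of the
  whole system in a three-dielectric model (ε_core = 1 inside the
  redox site, ε_protein = 4, ε_solvent = 78) and of the site alone in
  vacuum (ε ≡ 1), on identical grids so discretization self-energies
  cancel;
* **ΔG_SHE** — free energy of the electron in the SHE;
* **F** — Faraday constant, 23.0605 kcal·mol⁻¹·V⁻¹ per electron.

The PB equation is solved with a built-in deterministic
finite-difference engine (7-point stencil, harmonic edge-dielectric
sub-sampling, Debye–Hückel boundaries, two-level focusing,
Jacobi-preconditioned conjugate gradient; C++ via Rcpp).

On top of the cycle sit the three analyses used to find **sequence
determinants** of E°:

* protonation shifts — `set_protonation()` + `state_shift()`;
* charge knock-outs — `residue_contribution()` zeroes a residue's
  charges; |contribution| > 0.03 V flags a determinant;
* truncation mutations — `mutate_residue()` (e.g. His → Ala).

All three cancel ΔG_in and ΔG_SHE exactly, so they are reliable even
when the library values are approximate.

## Worked example

The package generates a fully synthetic, geometry-built mini-protein —
an SF4 cubane ligated by four cysteines inside a shell of 22 residues
including one histidine — so the whole pipeline runs with no downloads:

```r
library(redoxpot)

prep <- prepare_synthetic_hipip()        # partition + site + charges
res  <- redox_potential(prep$system, prep$entry,
                        pb_params(spacing_fine = 0.4))
print(res)
#> <redox_result> couple 1-/2-
#>   dG_solv(ox)  =   3431.703 kcal/mol
#>   dG_solv(red) =   3346.169 kcal/mol
#>   dG_out       =    -85.534 kcal/mol
#>   dG_in        =    -35.000 kcal/mol
#>   dG_SHE       =    102.160 kcal/mol
#>   E0           =      0.797 V vs SHE
```

The two ΔG_solv values contain large environment self-energies that
cancel in ΔG_out; ΔG_out ≈ −86 kcal/mol says the protein+solvent
environment stabilizes the extra electron strongly, and E° combines it
with the library terms.  (ΔG_in here is a placeholder — see the
vignette — so the absolute E° is illustrative; shifts below are not
affected by it.)

Protonate the histidine, measure its contribution, mutate it:

```r
p <- pb_params(spacing_fine = 0.4)
hsp <- set_protonation(prep$system, 42, "hsp")   # His42 -> +1
state_shift(prep$system, hsp, prep$entry, p)     # protonation shift
#> [1] 0.03072282                                 # +31 mV
residue_contribution(hsp, 42, prep$entry, p)     # knock-out
#> [1] 0.03596696, determinant flag TRUE          # +36 mV > 0.03 V
mut <- mutate_residue(hsp, 42, "ALA")            # H42A
```

A Born-ion sanity check against the closed form
−(332.0637·q²/2a)(1−1/ε):

```r
fx <- make_born_ion(-1, 2, eps_solvent = 78.54)
solvation_energy(fx$system, fx$reference,
                 pb_params(eps_solvent = 78.54, spacing_fine = 0.25))
#> [1] -82.30106       # analytic: -81.95894 (0.42 % error)
```

## Command line

`inst/cli/redoxpot` wires the same pipeline to the shell:

```sh
redoxpot redox   --pdb 1CKU.pdb --couple 1-/2- --monomer A --out wt.json
redoxpot redox   --pdb 1CKU.pdb --protonate 42:hsp --knockout "resid 42"
redoxpot contrib --pdb 1CKU.pdb --threshold 0.03
redoxpot build   --pdb my.pdb --out-dir states/   # wt-ox.pqr etc.
redoxpot fixture --kind born --q -1 --a 2 --out born.pqr
redoxpot lib validate inst/extdata/redox_library.txt
```

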