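# redoxpot parameter library
#
# One document per entry, `entry <id>` ... `end`.  Units: charges in e,
# radii in Angstrom, free energies in kcal/mol.  atom lines are
#   atom <name> <radius> <charge_ox> <charge_red> <count>
# and must cover the cofactor heteroatoms plus the ligating side-chain
# atoms; per-state sums must equal the formal couple charges.
#
# NOTE on provenance: the numeric dg_in values and the per-atom charge
# sets below are SYNTHETIC placeholders.  They are physically motivated
# (charge increment spread over Fe, inorganic S and thiolate S;
# dg_she from the -4.43 eV absolute SHE half-cell free energy) and
# satisfy all library invariants, but they are NOT the published DFT
# library values, which appear only in the companion literature.
# Replace them with the DFT values for quantitative absolute E0 work;
# every shift/contribution analysis is independent of dg_in and dg_she.

entry fs4_hipip
site_names: SF4 FS4
couple: 1-/2-
n_electrons: 1
ligand: CYS 4
dg_in: -35.0
dg_she: 102.16
resname_ox: FSO
resname_red: FSR
provenance: synthetic placeholder charge model for cysteine-ligated [4Fe-4S], HiPIP-type 1-/2- couple
provenance: dg_she = 4.43 eV x 23.0605 kcal/mol/eV (absolute SHE potential)
atom FE1 0.65 0.50 0.46 1
atom FE2 0.65 0.50 0.46 1
atom FE3 0.65 0.50 0.46 1
atom FE4 0.65 0.50 0.46 1
atom S1 2.00 -0.42 -0.50 1
atom S2 2.00 -0.42 -0.50 1
atom S3 2.00 -0.42 -0.50 1
atom S4 2.00 -0.42 -0.50 1
atom SG 2.00 -0.33 -0.46 4
atom CB 2.00 -0.18 -0.18 4
atom HB1 1.32 0.09 0.09 4
atom HB2 1.32 0.09 0.09 4
end

entry fs4_ferredoxin
site_names: SF4 FS4
couple: 2-/3-
n_electrons: 1
ligand: CYS 4
dg_in: 8.0
dg_she: 102.16
resname_ox: FSO
resname_red: FSR
provenance: synthetic placeholder charge model for cysteine-ligated [4Fe-4S], ferredoxin-type 2-/3- couple
provenance: dg_she = 4.43 eV x 23.0605 kcal/mol/eV (absolute SHE potential)
atom FE1 0.65 0.46 0.42 1
atom FE2 0.65 0.46 0.42 1
atom FE3 0.65 0.46 0.42 1
atom FE4 0.65 0.46 0.42 1
atom S1 2.00 -0.50 -0.58 1
atom S2 2.00 -0.50 -0.58 1
atom S3 2.00 -0.50 -0.58 1
atom S4 2.00 -0.50 -0.58 1
atom SG 2.00 -0.46 -0.59 4
atom CB 2.00 -0.18 -0.18 4
atom HB1 1.32 0.09 0.09 4
atom HB2 1.32 0.09 0.09 4
end
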