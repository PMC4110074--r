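# Shared helpers: small PDB texts written at test time, fast PB
# parameter sets, and a custom library entry builder.

# Coarse parameters for unit tests (analytic accuracy is exercised in
# test-acceptance.R at the stated spacings).
fast_params <- function(...) {
  pb_params(spacing_fine = 0.8, spacing_coarse = 2.0, padding = 20,
            fine_margin = 4, ...)
}

pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     occ = 1, altloc = " ", record = "ATOM  ",
                     element = "") {
  sprintf("%s%5d %-4s%s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resid,
          x, y, z, occ, 0, element)
}

# A 12-atom two-residue peptide fragment (ALA-GLY backbone + CB).
write_toy_pdb <- function(path) {
  lines <- c(
    pdb_line(1, " N  ", "ALA", "A", 1, 0.000, 0.000, 0.000),
    pdb_line(2, " CA ", "ALA", "A", 1, 1.458, 0.000, 0.000),
    pdb_line(3, " C  ", "ALA", "A", 1, 2.003, 1.420, 0.000),
    pdb_line(4, " O  ", "ALA", "A", 1, 1.246, 2.390, 0.000),
    pdb_line(5, " CB ", "ALA", "A", 1, 1.988, -0.773, -1.199),
    pdb_line(6, " N  ", "GLY", "A", 2, 3.332, 1.536, 0.000),
    pdb_line(7, " CA ", "GLY", "A", 2, 3.988, 2.839, 0.000),
    pdb_line(8, " C  ", "GLY", "A", 2, 5.496, 2.693, 0.000),
    pdb_line(9, " O  ", "GLY", "A", 2, 6.030, 1.583, 0.000),
    pdb_line(10, " O  ", "HOH", "A", 90, 8.0, 8.0, 8.0,
             record = "HETATM"),
    pdb_line(11, " S  ", "SO4", "A", 91, -6.0, 0.0, 0.0,
             record = "HETATM"),
    pdb_line(12, " O1 ", "SO4", "A", 91, -6.0, 1.45, 0.0,
             record = "HETATM"))
  writeLines(lines, path)
  path
}

# build a custom validated entry (internal constructor)
test_entry <- function(id, site_names, couple, atom_spec,
                       n_electrons = 1L, dg_in = 0, dg_she = 0,
                       ligand = NULL) {
  e <- list(id = id, site_names = site_names,
            couple = as.integer(couple), n_electrons = n_electrons,
            dg_in = dg_in, dg_she = dg_she,
            provenance = "test entry", atom_spec = atom_spec)
  if (!is.null(ligand)) e$ligand <- ligand
  redoxpot:::finalize_entry(e)
}

born_site_entry <- function(a = 2) {
  test_entry("born", "BRN", c(-1L, -2L),
             data.frame(name = "ION", radius = a, charge_ox = -1,
                        charge_red = -2, count = 1L))
}
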