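test_that("read_structure parses ATOM/HETATM records and counts atoms", {
  pdb <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"))
  sys <- read_structure(pdb)
  expect_s3_class(sys, "redox_system")
  expect_equal(nrow(sys$atoms), 12)
  expect_setequal(unique(sys$atoms$chain), "A")
})

test_that("read_structure rejects empty and missing files", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(), empty)
  expect_error(read_structure(empty), "empty structure")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               "cannot read")
})

test_that("altloc resolves to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, " CA ", "ALA", "A", 1, 0, 0, 0, occ = 0.4,
             altloc = "A"),
    pdb_line(2, " CA ", "ALA", "A", 1, 5, 0, 0, occ = 0.6,
             altloc = "B"),
    pdb_line(3, " CB ", "ALA", "A", 1, 1, 1, 1)), path)
  sys <- read_structure(path)
  expect_equal(nrow(sys$atoms), 2)
  ca <- sys$atoms[sys$atoms$atom_name == "CA", ]
  expect_equal(ca$x, 5)  # occupancy 0.6 conformer wins
})

test_that("altloc ties keep the first conformer in file", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, " CA ", "ALA", "A", 1, 0, 0, 0, occ = 0.5,
             altloc = "A"),
    pdb_line(2, " CA ", "ALA", "A", 1, 5, 0, 0, occ = 0.5,
             altloc = "B")), path)
  sys <- read_structure(path)
  expect_equal(sys$atoms$x, 0)
})

test_that("partition_segments separates protein, redox and good-het", {
  pdb <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"))
  raw <- read_structure(pdb)
  seg <- partition_segments(raw, monomer = "A")
  roles <- seg$roles[seg$atoms$segment_id]
  expect_true(all(roles[seg$atoms$residue_name %in%
                          c("ALA", "GLY")] == "protein"))
  expect_true(all(roles[seg$atoms$residue_name == "SO4"] ==
                    "good-het"))
  # waters discarded by default, counted in the report
  expect_false(any(seg$atoms$residue_name == "HOH"))
  expect_true(any(seg$discarded$residue_name == "HOH"))
  expect_equal(nrow(seg$atoms) + nrow(seg$discarded), 12)
})

test_that("SF4 goes to the redox segment, SO4 to good-het", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "FE1 ", "SF4", "A", 101, 0, 0, 0, record = "HETATM"),
    pdb_line(2, " S  ", "SO4", "A", 102, 9, 0, 0, record = "HETATM")),
    path)
  seg <- partition_segments(read_structure(path), monomer = "A")
  roles <- seg$roles[seg$atoms$segment_id]
  expect_equal(unname(roles[seg$atoms$residue_name == "SF4"]),
               "redox-site")
  expect_equal(unname(roles[seg$atoms$residue_name == "SO4"]),
               "good-het")
})

test_that("unknown heteroatoms are excluded with a warning", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " X1 ", "LIG", "A", 50, 5, 5, 5, record = "HETATM")),
    path)
  expect_warning(seg <- partition_segments(read_structure(path),
                                           monomer = "A"), "LIG")
  expect_false(any(seg$atoms$residue_name == "LIG"))
})

test_that("non-selected monomers are discarded", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
               pdb_line(2, " CA ", "ALA", "B", 1, 20, 0, 0)), path)
  seg <- partition_segments(read_structure(path), monomer = "A")
  expect_equal(nrow(seg$atoms), 1)
  expect_equal(seg$discarded$chain, "B")
  expect_error(partition_segments(read_structure(path), monomer = "C"),
               "not present")
})

test_that("assign_redox_site reassigns ligating side chains by distance", {
  # lone Fe cofactor with one Cys at bonding distance (SG 2.3 A) and
  # one at nonbonded distance (3.5 A)
  cys <- function(serial0, resid, sgx) c(
    pdb_line(serial0, " N  ", "CYS", "A", resid, sgx + 3.5, 2.0, 0),
    pdb_line(serial0 + 1, " CA ", "CYS", "A", resid, sgx + 2.8, 1.2, 0),
    pdb_line(serial0 + 2, " C  ", "CYS", "A", resid, sgx + 3.5, -0.1, 0),
    pdb_line(serial0 + 3, " O  ", "CYS", "A", resid, sgx + 4.7, -0.2, 0),
    pdb_line(serial0 + 4, " CB ", "CYS", "A", resid, sgx + 1.4, 0.9, 0),
    pdb_line(serial0 + 5, " SG ", "CYS", "A", resid, sgx, 0, 0))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "FE1 ", "SF4", "A", 101, 0, 0, 0,
                        record = "HETATM"),
               cys(2, 10, 2.3), cys(8, 20, -5.0)), path)
  entry <- test_entry("fe_test", "SF4", c(-1L, -2L),
                      data.frame(name = c("FE1", "SG", "CB", "HB1",
                                          "HB2"),
                                 radius = c(0.65, 2, 2, 1.32, 1.32),
                                 charge_ox = c(-1, 0, 0, 0, 0),
                                 charge_red = c(-2, 0, 0, 0, 0),
                                 count = 1L))
  seg <- partition_segments(read_structure(path), monomer = "A")
  out <- assign_redox_site(seg, entry)
  bad <- names(out$roles)[out$roles == "redox-site"]
  in_bad <- out$atoms$segment_id == bad
  # bonded Cys 10: side chain (CB, SG) moved; backbone stays
  expect_setequal(out$atoms$atom_name[in_bad &
                                        out$atoms$residue_id == 10],
                  c("CB", "SG"))
  expect_false(any(in_bad & out$atoms$residue_id == 20))
  expect_equal(out$site$ligand_residues, "10 CYS")
})

test_that("assign_redox_site enforces the expected ligand count", {
  prep_raw <- make_synthetic_hipip()
  lib <- default_library()
  entry <- get_entry(lib, "SF4", "1-/2-")
  seg <- partition_segments(prep_raw, monomer = "A", library = lib)
  # with the real 4-ligand entry this works
  out <- assign_redox_site(seg, entry)
  expect_length(out$site$ligand_residues, 4)
  # an entry demanding 5 ligands reports the found composition
  e5 <- entry; e5$n_ligands <- 5L
  expect_error(assign_redox_site(seg, e5),
               "ligand count inconsistent.*found 4")
})

test_that("cofactor with nothing in reach keeps heteroatoms only", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "FE1 ", "SF4", "A", 101, 0, 0, 0,
                        record = "HETATM"),
               pdb_line(2, " CA ", "ALA", "A", 1, 10, 0, 0)), path)
  entry <- test_entry("fe_bare", "SF4", c(-1L, -2L),
                      data.frame(name = "FE1", radius = 0.65,
                                 charge_ox = -1, charge_red = -2,
                                 count = 1L))
  seg <- partition_segments(read_structure(path), monomer = "A")
  out <- assign_redox_site(seg, entry)
  bad <- names(out$roles)[out$roles == "redox-site"]
  expect_equal(sum(out$atoms$segment_id == bad), 1)
})

test_that("selection mini-language parses bit-exactly", {
  atoms <- make_toy_site_peptide(seed = 1)$system$atoms
  expect_equal(which(select_atoms("resid 200", atoms)),
               which(atoms$residue_id == 200))
  expect_equal(which(select_atoms("resid 101:103", atoms)),
               which(atoms$residue_id %in% 101:103))
  expect_equal(which(select_atoms("segid t-bad", atoms)),
               which(atoms$segment_id == "t-bad"))
  expect_equal(which(select_atoms("name X1", atoms)),
               which(atoms$atom_name == "X1"))
  expect_equal(which(select_atoms("name *G", atoms)),
               which(endsWith(atoms$atom_name, "G")))
  expect_equal(which(select_atoms("segid t-pro and resid 200", atoms)),
               which(atoms$segment_id == "t-pro" &
                       atoms$residue_id == 200))
  expect_equal(sum(select_atoms("", atoms)), 0)
  expect_error(select_atoms("resid", atoms), "selection error")
  expect_error(select_atoms("chain A", atoms), "selection error")
  expect_error(select_atoms("resid 1:2:3", atoms), "selection error")
})

test_that("set_protonation switches templates and is idempotent", {
  prep <- prepare_synthetic_hipip()
  sys <- prep$system
  net <- function(s, id) sum(s$atoms$charge[s$atoms$residue_id == id])
  expect_equal(net(sys, 42), 0, tolerance = 1e-10)  # neutral HSD
  hsp <- set_protonation(sys, 42, "hsp")
  expect_equal(net(hsp, 42), 1, tolerance = 1e-10)
  # gains the second ring proton
  expect_true("HE2" %in%
                hsp$atoms$atom_name[hsp$atoms$residue_id == 42])
  expect_identical(set_protonation(hsp, 42, "hsp")$atoms, hsp$atoms)
  # Asp -> protonated: net -1 -> 0
  expect_equal(net(sys, 48), -1, tolerance = 1e-10)
  aspp <- set_protonation(sys, 48, "aspp")
  expect_equal(net(aspp, 48), 0, tolerance = 1e-10)
})

test_that("set_protonation validates labels and residues", {
  prep <- prepare_synthetic_hipip()
  expect_error(set_protonation(prep$system, 42, "zap"),
               "valid labels")
  expect_error(set_protonation(prep$system, 42, "aspp"),
               "not valid for HIS")
  expect_error(set_protonation(prep$system, 44, "hsp"),
               "not titratable")  # ALA
  expect_error(set_protonation(prep$system, 999, "hsp"), "not found")
})

test_that("knockout_charges zeroes charges, keeps radii/coords", {
  prep <- prepare_synthetic_hipip()
  sys <- set_protonation(prep$system, 42, "hsp")
  before <- total_charge(sys)
  res_q <- sum(sys$atoms$charge[sys$atoms$residue_id == 42])
  ko <- knockout_charges(sys, "resid 42")
  expect_equal(sum(ko$atoms$charge[ko$atoms$residue_id == 42]), 0)
  expect_identical(ko$atoms$x, sys$atoms$x)
  expect_identical(ko$atoms$radius, sys$atoms$radius)
  # total charge drops by exactly the residue's prior net charge
  expect_equal(total_charge(ko), before - res_q, tolerance = 1e-12)
  expect_identical(knockout_charges(sys, "")$atoms, sys$atoms)
})

test_that("mutate_residue preserves the backbone and CB (His -> Ala)", {
  prep <- prepare_synthetic_hipip()
  sys <- set_protonation(prep$system, 42, "hsp")
  mut <- mutate_residue(sys, 42, "ALA")
  for (nm in c("N", "CA", "C", "O", "CB")) {
    a <- sys$atoms[sys$atoms$residue_id == 42 &
                     sys$atoms$atom_name == nm, ]
    b <- mut$atoms[mut$atoms$residue_id == 42 &
                     mut$atoms$atom_name == nm, ]
    expect_equal(c(b$x, b$y, b$z), c(a$x, a$y, a$z), tolerance = 0,
                 label = nm)
  }
  expect_equal(mut$atoms$residue_name[mut$atoms$residue_id == 42][1],
               "ALA")
  expect_equal(sum(mut$atoms$charge[mut$atoms$residue_id == 42]), 0,
               tolerance = 1e-10)
})

test_that("same-residue mutation keeps heavy atoms unchanged", {
  prep <- prepare_synthetic_hipip()
  sys <- prep$system
  mut <- mutate_residue(sys, 44, "ALA")  # ALA -> ALA
  h1 <- sys$atoms[sys$atoms$residue_id == 44 &
                    sys$atoms$element != "H", ]
  h2 <- mut$atoms[mut$atoms$residue_id == 44 &
                    mut$atoms$element != "H", ]
  expect_equal(h2[order(h2$atom_name), c("x", "y", "z")],
               h1[order(h1$atom_name), c("x", "y", "z")],
               ignore_attr = TRUE)
})

test_that("growing mutations are flagged approximate; bad targets error", {
  prep <- prepare_synthetic_hipip()
  expect_message(mutate_residue(prep$system, 44, "LEU"),
                 "approximate")
  expect_error(mutate_residue(prep$system, 44, "XXX"),
               "unsupported mutation target")
  expect_error(mutate_residue(prep$system, 1, "ALA"),
               "ligates the redox site")
})

test_that("edits on disjoint residues commute", {
  prep <- prepare_synthetic_hipip()
  sys <- prep$system
  a <- knockout_charges(set_protonation(sys, 42, "hsp"), "resid 48")
  b <- set_protonation(knockout_charges(sys, "resid 48"), 42, "hsp")
  expect_identical(a$atoms, b$atoms)
})

test_that("parameterized total charge equals template sums plus site", {
  prep <- prepare_synthetic_hipip()
  # neutral-termini fragments: HIS(HSD) 0, ALA x3 0, ASP -1, SER 0,
  # 4 x CYS backbone 0, site formal charge -1 (oxidized)
  expect_equal(total_charge(prep$system), -2, tolerance = 1e-3)
  st <- build_states(prep$system, prep$entry)
  expect_equal(total_charge(st$protein_ox), -2, tolerance = 1e-3)
  expect_equal(total_charge(st$protein_red), -3, tolerance = 1e-3)
  expect_equal(total_charge(st$reference_ox), prep$entry$couple[1],
               tolerance = 1e-3)
})

test_that("build_states satisfies the four-state invariants", {
  prep <- prepare_synthetic_hipip()
  st <- build_states(prep$system, prep$entry)
  a <- st$protein_ox$atoms; b <- st$protein_red$atoms
  expect_identical(a[c("x", "y", "z")], b[c("x", "y", "z")])
  bad <- names(prep$system$roles)[prep$system$roles == "redox-site"]
  differ <- a$charge != b$charge
  expect_true(all(a$segment_id[differ] == bad))
  expect_true(any(differ))
  # references are exactly the redox segment, same coordinates
  expect_equal(st$reference_ox$atoms[c("x", "y", "z")],
               a[a$segment_id == bad, c("x", "y", "z")],
               ignore_attr = TRUE)
  # per-state residue renaming
  expect_true(all(st$protein_ox$atoms$residue_name[
    st$protein_ox$atoms$residue_name %in% c("FSO", "FSR")] == "FSO"))
  expect_true("FSR" %in% st$protein_red$atoms$residue_name)
})

test_that("build_states is deterministic (byte-identical PQR output)", {
  prep <- prepare_synthetic_hipip()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_states(build_states(prep$system, prep$entry), d1)
  write_states(build_states(prep$system, prep$entry), d2)
  for (f in c("wt-ox.pqr", "wt-red.pqr", "ref-ox.pqr", "ref-red.pqr"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("PQR round trip preserves the parameterized atoms", {
  prep <- prepare_synthetic_hipip()
  path <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(prep$system, path)
  back <- read_pqr(path)
  expect_equal(nrow(back$atoms), nrow(prep$system$atoms))
  expect_equal(back$atoms$charge, round(prep$system$atoms$charge, 4))
  expect_equal(back$atoms$x, round(prep$system$atoms$x, 3))
})
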