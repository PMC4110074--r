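# Synthetic fixtures with analytic (or two-path) oracles, so the full
# pipeline is testable with no external data.

#' Analytic Born solvation energy
#'
#' `-(k_c q^2 / 2a) (1 - 1/eps)` kcal/mol for a charge q centred in a
#' cavity of radius a.
#'
#' @param q charge, e.
#' @param a cavity radius, A.
#' @param eps solvent dielectric.
#' @return kcal/mol.
#' @export
born_energy <- function(q, a, eps = 78.54) {
  -(KCOUL * q^2 / (2 * a)) * (1 - 1 / eps)
}

#' Kirkwood reaction-field energy for an off-centre charge
#'
#' Image-charge series for a charge q at distance d from the centre of
#' a sphere of radius a with interior dielectric `eps_in` and exterior
#' `eps_out`, summed to relative tolerance `tol`.  The l = 0 term is
#' the Born value; the magnitude grows monotonically with d.
#'
#' @param q charge, e.
#' @param a sphere radius, A.
#' @param d off-centre displacement, A (0 <= d < a).
#' @param eps_in,eps_out dielectrics.
#' @param tol relative series truncation tolerance.
#' @return kcal/mol.
#' @export
kirkwood_energy <- function(q, a, d, eps_in = 1, eps_out = 78.54,
                            tol = 1e-8) {
  if (d < 0 || d >= a) stop("require 0 <= d < a")
  t <- (d / a)^2
  total <- 0
  l <- 0
  repeat {
    term <- (l + 1) * (eps_out - eps_in) /
      (eps_in * ((l + 1) * eps_out + l * eps_in)) * t^l
    total <- total + term
    if (l > 0 && (t == 0 || abs(term) < tol * abs(total))) break
    l <- l + 1
    if (l > 100000) stop("Kirkwood series failed to converge")
  }
  -(KCOUL * q^2 / (2 * a)) * total
}

fixture_system <- function(atoms, site_label, couple) {
  segs <- unique(atoms$segment_id)
  roles <- setNames(ifelse(grepl("bad$", segs), "redox-site",
                           "protein"), segs)
  sys <- redox_system(atoms, roles = roles, parameterized = TRUE)
  sys$site <- list(entry = site_label, couple = couple,
                   label = site_label,
                   ligand_residues = character())
  sys
}

#' Born ion fixture
#'
#' One atom of radius `a` and charge `q`, labelled redox-site, plus
#' its vacuum reference (the identical atom).  The analytic oracle is
#' attached as `$oracle`.
#'
#' @param q charge, e.
#' @param a cavity radius, A (> 0).
#' @param eps_solvent solvent dielectric for the oracle.
#' @return list with `system`, `reference`, `oracle` (kcal/mol).
#' @export
make_born_ion <- function(q, a, eps_solvent = 78.54) {
  if (a <= 0) stop("Born radius must be > 0")
  atoms <- new_atom_table(atom_name = "ION", element = "X",
                          residue_name = "BRN", residue_id = 1L,
                          chain = "F", segment_id = "f-bad",
                          x = 0, y = 0, z = 0, charge = q, radius = a,
                          occupancy = 1, altloc = "")
  qi <- as.integer(round(q))
  sys <- fixture_system(atoms, "born ion", c(qi, qi - 1L))
  list(system = sys, reference = sys,
       oracle = born_energy(q, a, eps_solvent))
}

#' Off-centre charge in a spherical cavity (Kirkwood fixture)
#'
#' A zero-charge dummy atom of radius `a` defines the cavity; the
#' point charge sits at distance `d` along x with zero radius.  The
#' oracle is the independent Kirkwood image series.
#'
#' @param q charge, e.
#' @param a cavity radius, A.
#' @param d off-centre displacement, A (0 <= d < a).
#' @param eps_solvent exterior dielectric for the oracle.
#' @return list with `system`, `reference`, `oracle` (kcal/mol).
#' @export
make_offcenter_sphere <- function(q, a, d, eps_solvent = 78.54) {
  if (d >= a || d < 0) stop("require 0 <= d < a")
  atoms <- new_atom_table(
    atom_name = c("CAV", "CHG"), element = c("X", "X"),
    residue_name = c("KWD", "KWD"), residue_id = c(1L, 1L),
    chain = c("F", "F"), segment_id = c("f-bad", "f-bad"),
    x = c(0, d), y = c(0, 0), z = c(0, 0), charge = c(0, q),
    radius = c(a, 0), occupancy = c(1, 1), altloc = c("", ""))
  qi <- as.integer(round(q))
  sys <- fixture_system(atoms, "kirkwood sphere", c(qi, qi - 1L))
  list(system = sys, reference = sys,
       oracle = kirkwood_energy(q, a, d, 1, eps_solvent))
}

#' Toy redox-site peptide fixture
#'
#' A four-atom charged "site" (tetrahedron, couple 1-/2-) wrapped by
#' ~30 single-atom neutral-to-polar dummy residues on an 8-12 A shell,
#' plus one titratable-like toggle residue (resid 200) whose charge
#' can be switched to exercise [state_shift()] and
#' [residue_contribution()] end to end.  Deterministic under `seed`.
#'
#' @param seed integer seed for the dummy-shell placement.
#' @param toggle_charge charge of the toggle residue, e.
#' @param n_env number of dummy environment residues.
#' @return list with `system` (parameterized, site assigned) and
#'   `entry` (a matching validated library entry).
#' @export
make_toy_site_peptide <- function(seed = 1, toggle_charge = 1,
                                  n_env = 30) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  s <- 1.4  # site tetrahedron half-edge
  site <- data.frame(
    name = c("X1", "X2", "X3", "X4"),
    x = c(s, s, -s, -s), y = c(s, -s, s, -s), z = c(s, -s, -s, s))
  # dummy shell: deterministic directions, jittered radius
  u <- matrix(rnorm(3 * n_env), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- runif(n_env, 8, 12)
  qe <- round(runif(n_env, -0.25, 0.25), 3)

  atoms <- rbind(
    new_atom_table(atom_name = site$name, element = "X",
                   residue_name = "TS4", residue_id = 500L,
                   chain = "T", segment_id = "t-bad",
                   x = site$x, y = site$y, z = site$z,
                   charge = -0.25, radius = 2.0, occupancy = 1,
                   altloc = ""),
    new_atom_table(atom_name = "DU", element = "X",
                   residue_name = "TOY",
                   residue_id = as.integer(100 + seq_len(n_env)),
                   chain = "T", segment_id = "t-pro",
                   x = u[, 1] * r, y = u[, 2] * r, z = u[, 3] * r,
                   charge = qe, radius = 1.7, occupancy = 1,
                   altloc = ""),
    new_atom_table(atom_name = "TG", element = "X",
                   residue_name = "TOG", residue_id = 200L,
                   chain = "T", segment_id = "t-pro",
                   x = 6.5, y = 0.5, z = -0.5,
                   charge = toggle_charge, radius = 1.7,
                   occupancy = 1, altloc = ""))
  sys <- fixture_system(atoms, "toy site", c(-1L, -2L))

  entry <- list(id = "toy_site", site_names = "TS4",
                couple = c(-1L, -2L), n_electrons = 1L,
                dg_in = -20, dg_she = 102.16,
                resname_ox = "TSO", resname_red = "TSR",
                provenance = "synthetic toy fixture",
                atom_spec = data.frame(
                  name = c("X1", "X2", "X3", "X4"),
                  radius = 2.0, charge_ox = -0.25,
                  charge_red = -0.5, count = 1L))
  entry <- finalize_entry(entry)
  list(system = sys, entry = entry)
}

# --- synthetic mini-HiPIP ------------------------------------------------

# Deterministic frame: two unit vectors orthogonal to u.
ortho_frame <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitv(cross3(u, ref))
  e2 <- cross3(u, e1)
  list(e1 = e1, e2 = e2)
}

# Backbone heavy atoms (N, CA, C, O) for a residue centred at CA with
# the side chain roughly along +u.
backbone_at <- function(CA, u) {
  f <- ortho_frame(u)
  N <- CA - 1.45 * f$e1
  cdir <- cos(111 * pi / 180) * (-f$e1) + sin(111 * pi / 180) * f$e2
  C <- CA + 1.52 * cdir
  O <- place_zmat_atom(C, CA, N, 1.23, 121, 180)
  rbind(N = N, CA = CA, C = C, O = O)
}

#' Synthetic cysteine-ligated [4Fe-4S] mini-protein (stand-in)
#'
#' A geometry-generated, heavy-atom-only PDB-style structure labelled
#' SYNTHETIC: an SF4 cubane (Fe-S 2.3 A) with four cysteine ligands
#' (SG placed 2.3 A from each Fe) and a small shell of environment
#' residues including one histidine (resid 42) for protonation /
#' knock-out / mutation analyses.  It is a desk-scale stand-in for a
#' real HiPIP crystal structure, NOT a real protein: use it to
#' exercise the pipeline, not to reproduce published potentials.
#'
#' @return an unparameterized `redox_system` (chain A), ready for
#'   [partition_segments()].
#' @export
make_synthetic_hipip <- function() {
  d <- 1.15
  fe <- rbind(c(d, d, d), c(d, -d, -d), c(-d, d, -d), c(-d, -d, d))
  ss <- rbind(c(-d, -d, -d), c(-d, d, d), c(d, -d, d), c(d, d, -d))
  rows <- list()
  add <- function(name, resname, resid, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, resname = resname, resid = as.integer(resid),
      x = p[1], y = p[2], z = p[3])
  }
  for (i in 1:4) add(paste0("FE", i), "SF4", 101, fe[i, ])
  for (i in 1:4) add(paste0("S", i), "SF4", 101, ss[i, ])

  # ligating cysteines built inward->outward along the Fe diagonals
  for (i in 1:4) {
    u <- unitv(fe[i, ])
    SG <- fe[i, ] + 2.3 * u
    f <- ortho_frame(u)
    CB <- SG + 1.82 * unitv(u + 0.4 * f$e1)
    CA <- CB + 1.53 * unitv(u + 0.5 * f$e2)
    bb <- backbone_at(CA, -u)
    rid <- 2 * i - 1   # resids 1,3,5,7: no spurious peptide adjacency
    add("N", "CYS", rid, bb["N", ]); add("CA", "CYS", rid, CA)
    add("C", "CYS", rid, bb["C", ]); add("O", "CYS", rid, bb["O", ])
    add("CB", "CYS", rid, CB); add("SG", "CYS", rid, SG)
  }

  # environment shell wrapping the cluster: 6 axis residues (one
  # titratable His, one Asp, one Ser), 12 edge-direction and 4
  # anti-diagonal alanines, so the site sits in a protein-like
  # dielectric cavity rather than naked solvent
  env <- list(
    list(resname = "HIS", resid = 42, u = c(1, 0, 0), r = 9.0),
    list(resname = "ALA", resid = 44, u = c(0, 1, 0), r = 8.5),
    list(resname = "ALA", resid = 46, u = c(0, 0, 1), r = 8.5),
    list(resname = "ASP", resid = 48, u = c(-1, 0, 0), r = 9.0),
    list(resname = "SER", resid = 50, u = c(0, -1, 0), r = 8.5),
    list(resname = "ALA", resid = 52, u = c(0, 0, -1), r = 8.5))
  edge_dirs <- rbind(
    c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
    c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
    c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  anti_dirs <- rbind(c(-1, -1, -1), c(-1, 1, 1), c(1, -1, 1),
                     c(1, 1, -1))
  rid <- 54
  for (i in seq_len(nrow(edge_dirs))) {
    env[[length(env) + 1]] <- list(resname = "ALA", resid = rid,
                                   u = unitv(edge_dirs[i, ]), r = 8.8)
    rid <- rid + 2
  }
  for (i in seq_len(nrow(anti_dirs))) {
    env[[length(env) + 1]] <- list(resname = "ALA", resid = rid,
                                   u = unitv(anti_dirs[i, ]), r = 9.5)
    rid <- rid + 2
  }
  for (e in env) {
    CA <- e$u * e$r
    bb <- backbone_at(CA, -unitv(e$u))  # side chain points inward
    for (nm in rownames(bb)) add(nm, e$resname, e$resid, bb[nm, ])
  }

  df <- do.call(rbind, rows)
  atoms <- new_atom_table(
    atom_name = df$name,
    element = guess_element(df$name, df$resname),
    residue_name = df$resname, residue_id = df$resid,
    chain = "A", segment_id = "A", x = df$x, y = df$y, z = df$z,
    charge = NA_real_, radius = NA_real_, occupancy = 1, altloc = "")
  redox_system(atoms)
}

#' Prepare the synthetic mini-HiPIP for redox calculations
#'
#' Partition, site assignment and parameterization (neutral termini:
#' the stand-in's residues are isolated fragments) in one call.
#'
#' @param couple redox couple label.
#' @return list with parameterized `system` and library `entry`.
#' @export
prepare_synthetic_hipip <- function(couple = "1-/2-") {
  lib <- default_library()
  entry <- get_entry(lib, "SF4", couple)
  raw <- make_synthetic_hipip()
  seg <- partition_segments(raw, monomer = "A", library = lib)
  seg <- assign_redox_site(seg, entry)
  sys <- parameterize_system(seg, entry, termini = "neutral")
  list(system = sys, entry = entry)
}
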