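#' Environmental contribution to the reduction free energy
#'
#' Runs the four Poisson-Boltzmann legs of the thermodynamic cycle
#' (oxidized/reduced protein against oxidized/reduced vacuum
#' reference) and returns
#' `dG_out = dG_solv(reduced) - dG_solv(oxidized)` in kcal/mol.
#' All four legs share one grid pair sized from the protein system,
#' and the dielectric maps are state-independent (identical
#' coordinates and radii), so shared discretization artifacts cancel.
#'
#' @param states a `four_states` object from [build_states()].
#' @param params a `pb_params`.
#' @param details return the per-leg energies as attributes.
#' @return kcal/mol (with attributes `dg_solv_ox`, `dg_solv_red`,
#'   `grid_meta` when `details = TRUE`).
#' @export
delta_g_out <- function(states, params = pb_params(),
                        details = TRUE) {
  grids <- make_grids(states$protein_ox$atoms, params)
  run_leg <- function(state, uniform, leg) {
    tryCatch(solve_state_energy(state, grids, params,
                                uniform = uniform)$energy,
             error = function(e)
               stop("PB leg '", leg, "' failed: ",
                    conditionMessage(e)))
  }
  g_po <- run_leg(states$protein_ox, NULL, "protein oxidized")
  g_pr <- run_leg(states$protein_red, NULL, "protein reduced")
  g_ro <- run_leg(states$reference_ox, 1, "reference oxidized")
  g_rr <- run_leg(states$reference_red, 1, "reference reduced")
  dg_ox <- g_po - g_ro
  dg_red <- g_pr - g_rr
  out <- dg_red - dg_ox
  if (details) {
    attr(out, "dg_solv_ox") <- dg_ox
    attr(out, "dg_solv_red") <- dg_red
    attr(out, "grid_meta") <- list(
      fine = grids$fine[c("spacing", "dims")],
      coarse = grids$coarse[c("spacing", "dims")])
  }
  out
}

#' Reduction potential from the cycle terms
#'
#' `E0 = -(dg_in + dg_out + dg_she) / (n F)` with the Faraday constant
#' expressed so that 1 V corresponds to 23.0605 kcal/mol per electron.
#' The sign convention is pinned operationally: with `dg_she` stored
#' positive (+102.16 kcal/mol for the -4.43 eV electron free energy in
#' the SHE) and `dg_out` large-negative, potentials come out on the
#' conventional reduction scale versus SHE.
#'
#' @param dg_in intrinsic site reduction free energy, kcal/mol.
#' @param dg_out environmental contribution, kcal/mol.
#' @param dg_she electron free energy term, kcal/mol.
#' @param n number of electrons transferred (>= 1).
#' @return E0, volts.
#' @export
reduction_potential <- function(dg_in, dg_out, dg_she, n = 1) {
  stopifnot(n >= 1)
  vals <- c(dg_in, dg_out, dg_she)
  if (any(!is.finite(vals))) stop("non-finite cycle term")
  -(dg_in + as.numeric(dg_out) + dg_she) / (n * KCAL_PER_EV)
}

#' Full reduction-potential calculation for one system
#'
#' Builds the four cycle states, runs the PB legs and assembles E0.
#'
#' @param system parameterized `redox_system` with site assigned.
#' @param entry library entry for the site/couple.
#' @param params a `pb_params`.
#' @return object of class `redox_result` with all cycle terms.
#' @export
redox_potential <- function(system, entry, params = pb_params()) {
  states <- build_states(system, entry)
  dg_out <- delta_g_out(states, params)
  e0 <- reduction_potential(entry$dg_in, dg_out, entry$dg_she,
                            entry$n_electrons)
  structure(list(dg_solv_ox = attr(dg_out, "dg_solv_ox"),
                 dg_solv_red = attr(dg_out, "dg_solv_red"),
                 dg_out = as.numeric(dg_out),
                 dg_in = entry$dg_in, dg_she = entry$dg_she,
                 n_electrons = entry$n_electrons, e0 = e0,
                 couple = couple_label(entry$couple),
                 entry_id = entry$id,
                 provenance = entry$provenance,
                 grid_meta = attr(dg_out, "grid_meta")),
            class = "redox_result")
}

#' @export
print.redox_result <- function(x, ...) {
  cat("<redox_result> couple ", x$couple, "\n", sep = "")
  cat(sprintf("  dG_solv(ox)  = %10.3f kcal/mol\n", x$dg_solv_ox))
  cat(sprintf("  dG_solv(red) = %10.3f kcal/mol\n", x$dg_solv_red))
  cat(sprintf("  dG_out       = %10.3f kcal/mol\n", x$dg_out))
  cat(sprintf("  dG_in        = %10.3f kcal/mol\n", x$dg_in))
  cat(sprintf("  dG_SHE       = %10.3f kcal/mol\n", x$dg_she))
  cat(sprintf("  E0           = %10.3f V vs SHE\n", x$e0))
  invisible(x)
}

#' Serialize a result report to JSON
#'
#' @param result a `redox_result`.
#' @param path output file; if NULL, the JSON string is returned.
#' @return path or JSON string.
#' @export
write_result <- function(result, path = NULL) {
  js <- jsonlite::toJSON(unclass(result), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Contribution of one residue to E0 by charge knock-out
#'
#' `E0(system) - E0(system with the residue's charges zeroed)`.
#' Residues with absolute contributions greater than the 0.03 V
#' threshold are flagged as sequence determinants.  The value is
#' independent of `dg_in`/`dg_she` (they cancel in the difference).
#'
#' @param system parameterized `redox_system` with site assigned.
#' @param residue_id residue whose charges are knocked out.
#' @param entry library entry.
#' @param params a `pb_params`.
#' @param threshold determinant flag threshold, volts.
#' @return volts, with attribute `determinant` (logical).
#' @export
residue_contribution <- function(system, residue_id, entry,
                                 params = pb_params(),
                                 threshold = 0.03) {
  atoms <- system$atoms
  ridx <- which(atoms$residue_id == residue_id)
  if (!length(ridx)) stop("residue ", residue_id, " not found")
  bad <- names(system$roles)[system$roles == "redox-site"]
  if (any(atoms$segment_id[ridx] == bad))
    stop("residue ", residue_id, " is part of the redox segment; ",
         "its charges define the couple and cannot be knocked out")
  ko <- knockout_charges(system, paste("resid", residue_id))
  contrib <- state_shift(ko, system, entry, params)
  attr(contrib, "determinant") <- abs(contrib) > threshold
  contrib
}

#' E0 shift between two systems sharing a redox site
#'
#' `E0(b) - E0(a)`; used for protonation shifts (wild-type vs
#' reprotonated) and mutation shifts.  Antisymmetric, and independent
#' of `dg_in`/`dg_she` by exact cancellation.
#'
#' @param system_a,system_b parameterized systems with the same site
#'   and couple.
#' @param entry library entry.
#' @param params a `pb_params`.
#' @return volts.
#' @export
state_shift <- function(system_a, system_b, entry,
                        params = pb_params()) {
  for (s in list(system_a, system_b)) {
    if (is.null(s$site)) stop("system lacks an assigned redox site")
    if (!identical(s$site$couple, entry$couple))
      stop("system couple ", couple_label(s$site$couple),
           " differs from entry couple ", couple_label(entry$couple))
  }
  dg_a <- delta_g_out(build_states(system_a, entry), params,
                      details = FALSE)
  dg_b <- delta_g_out(build_states(system_b, entry), params,
                      details = FALSE)
  # dg_in and dg_she cancel algebraically; only dg_out survives
  (as.numeric(dg_a) - as.numeric(dg_b)) /
    (entry$n_electrons * KCAL_PER_EV)
}

#' Run the full lesson-style workflow on a HiPIP structure
#'
#' Reproduces the teaching workflow on a cysteine-ligated [4Fe-4S]
#' protein: wild-type E0 at pH 7, E0 with a chosen histidine
#' protonated, the knocked-out contribution of that residue, and the
#' His -> Ala mutant E0.
#'
#' @param pdb_path PDB file of the protein (e.g. entry 1CKU for
#'   Chromatium vinosum HiPIP).
#' @param his_resid residue id of the titratable histidine (42 for
#'   1CKU).
#' @param monomer chain to keep.
#' @param couple redox couple label (default the HiPIP `"1-/2-"`).
#' @param params a `pb_params`.
#' @return list with `wt`, `hsp`, `knockout`, `mutant` results plus
#'   the derived shifts.
#' @export
run_lesson <- function(pdb_path, his_resid = 42, monomer = NULL,
                       couple = "1-/2-", params = pb_params()) {
  lib <- default_library()
  raw <- read_structure(pdb_path)
  seg <- partition_segments(raw, monomer = monomer, library = lib)
  site_res <- unique(unlist(lapply(lib, `[[`, "site_names")))
  found <- unique(seg$atoms$residue_name[
    seg$atoms$residue_name %in% site_res])
  entry <- get_entry(lib, found[1], couple)
  seg <- assign_redox_site(seg, entry)
  wt <- parameterize_system(seg, entry)

  hsp <- set_protonation(wt, his_resid, "hsp")
  mut <- mutate_residue(hsp, his_resid, "ALA")
  ko <- knockout_charges(hsp, paste("resid", his_resid))

  res <- list(wt = redox_potential(wt, entry, params),
              hsp = redox_potential(hsp, entry, params),
              knockout = redox_potential(ko, entry, params),
              mutant = redox_potential(mut, entry, params))
  res$protonation_shift <- res$hsp$e0 - res$wt$e0
  res$his_contribution <- res$hsp$e0 - res$knockout$e0
  res$mutation_shift <- res$mutant$e0 - res$wt$e0
  res
}
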