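#' Partition a raw structure into protein / good-het / redox segments
#'
#' Mirrors the three-segment decomposition used for redox
#' calculations: amino-acid residues of the selected monomer form the
#' protein segment (`<chain>-pro`), heteroatom residues whose names
#' appear in the redox parameter library form the redox-site segment
#' (`<chain>-bad`), and other recognized heteroatoms form the good-het
#' segment (`<chain>-good`).  Crystallographic waters and all other
#' chains are discarded by default and counted in the discard report.
#'
#' @param raw a `redox_system` from [read_structure()].
#' @param monomer chain identifier to keep (default: first chain).
#' @param library redox parameter library (list of entries from
#'   [load_library()]); used only for its site residue names.
#' @param keep_waters keep crystallographic waters as explicit good-het
#'   atoms instead of discarding them.
#' @return a `redox_system` with segment ids and roles assigned.
#' @export
partition_segments <- function(raw, monomer = NULL,
                               library = default_library(),
                               keep_waters = FALSE) {
  atoms <- raw$atoms
  if (is.null(monomer)) monomer <- atoms$chain[1]
  if (!monomer %in% atoms$chain)
    stop("monomer chain '", monomer, "' not present in structure")
  site_names <- unique(unlist(lapply(library, `[[`, "site_names")))
  water_names <- c("HOH", "WAT", "TIP3", "TIP", "SPC")

  discarded <- atoms[atoms$chain != monomer, ]
  atoms <- atoms[atoms$chain == monomer, ]
  seg <- tolower(monomer)
  pro <- paste0(seg, "-pro"); bad <- paste0(seg, "-bad")
  good <- paste0(seg, "-good")

  amino <- is_amino(atoms$residue_name)
  is_site <- atoms$residue_name %in% site_names
  is_water <- atoms$residue_name %in% water_names
  known_het <- atoms$residue_name %in% names(het_templates()) & !is_water

  atoms$segment_id[amino] <- pro
  atoms$segment_id[is_site] <- bad
  atoms$segment_id[known_het & !amino & !is_site] <- good
  if (keep_waters) {
    atoms$segment_id[is_water] <- good
    known_het <- known_het | is_water
  }

  unknown <- !amino & !is_site & !known_het & !(is_water & keep_waters)
  if (any(unknown)) {
    bad_res <- unique(atoms$residue_name[unknown & !is_water])
    if (length(bad_res))
      warning("unknown heteroatom residue(s) excluded: ",
              paste(bad_res, collapse = ", "))
    discarded <- rbind(discarded, atoms[unknown, ])
    atoms <- atoms[!unknown, ]
  }
  roles <- setNames(c("protein", "redox-site", "good-het"),
                    c(pro, bad, good))
  roles <- roles[names(roles) %in% atoms$segment_id]
  rownames(atoms) <- NULL
  redox_system(atoms, roles = roles, discarded = discarded)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "HN", "HA", "HA1", "HA2",
                    "OT1", "OT2", "OXT", "HT1", "HT2", "HT3", "H")

#' Assign ligating side chains to the redox site
#'
#' Protein side chains directly bonded to a cofactor heteroatom (any
#' side-chain atom within `cutoff` of a cofactor atom; default 2.6 A,
#' covering Fe-S bonds at ~2.3 A while excluding nonbonded contacts)
#' are reassigned from the protein segment to the redox-site segment.
#'
#' @param system a partitioned `redox_system`.
#' @param entry the [RedoxEntry][get_entry] for the site, used to check
#'   the ligand composition.
#' @param cutoff bond-detection distance, Angstrom.
#' @return the system with ligand side chains moved to the redox
#'   segment and `$site` metadata recorded.
#' @export
assign_redox_site <- function(system, entry, cutoff = 2.6) {
  atoms <- system$atoms
  roles <- system$roles
  bad <- names(roles)[roles == "redox-site"]
  if (!length(bad) || !any(atoms$segment_id == bad))
    stop("no redox-site segment; structure has no supported cofactor")
  co <- atoms$segment_id == bad
  if (!any(atoms$residue_name[co] %in% entry$site_names))
    stop("redox segment does not contain a ", entry$site_names[1],
         " cofactor")
  cxyz <- atom_xyz(atoms[co, ])

  pro <- atoms$segment_id %in% names(roles)[roles == "protein"]
  side <- pro & !(atoms$atom_name %in% BACKBONE_ATOMS)
  lig_res <- character()
  if (any(side)) {
    sxyz <- atom_xyz(atoms[side, ])
    d2 <- outer(rowSums(sxyz^2), rowSums(cxyz^2), "+") -
      2 * sxyz %*% t(cxyz)
    near <- apply(d2, 1, min) <= cutoff^2
    key <- paste(atoms$residue_id[side], atoms$residue_name[side])
    lig_res <- unique(key[near])
  }
  if (length(lig_res)) {
    found <- vapply(strsplit(lig_res, " "), `[`, "", 2)
    if (!is.null(entry$n_ligands) &&
        length(lig_res) != entry$n_ligands)
      stop("ligand count inconsistent with library entry: expected ",
           entry$n_ligands, " ", entry$ligand_resname,
           ", found ", length(lig_res), " (",
           paste(lig_res, collapse = "; "), ")")
    move <- side & paste(atoms$residue_id, atoms$residue_name) %in%
      lig_res
    atoms$segment_id[move] <- bad
  } else if (!is.null(entry$n_ligands) && entry$n_ligands > 0) {
    stop("ligand count inconsistent with library entry: expected ",
         entry$n_ligands, " ", entry$ligand_resname, ", found 0")
  }
  system$atoms <- atoms
  system$site <- list(entry = entry$id, couple = entry$couple,
                      label = sprintf("%s site (%s)",
                                      entry$site_names[1],
                                      couple_label(entry$couple)),
                      ligand_residues = lig_res)
  system
}
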