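#' Atom selections
#'
#' Grammar (documented, bit-exact):
#' \preformatted{
#'   selection := clause (" and " clause)*
#'   clause    := "resid" INT | "resid" INT ":" INT
#'              | "segid" ID | "name" NAME
#' }
#' `name` matches the atom name exactly, or by suffix when the pattern
#' starts with `*` (e.g. `name *G` matches `OG`, `SG`, `CG`).  The
#' empty selection resolves to zero atoms.
#'
#' @param selection selection string.
#' @param atoms atom table to resolve against.
#' @return logical mask over the rows of `atoms`.
#' @export
select_atoms <- function(selection, atoms) {
  selection <- trimws(selection)
  if (!nzchar(selection)) return(rep(FALSE, nrow(atoms)))
  clauses <- strsplit(selection, "\\s+and\\s+")[[1]]
  mask <- rep(TRUE, nrow(atoms))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) != 2)
      stop("selection error: malformed clause '", cl, "'")
    mask <- mask & switch(tok[1],
      resid = {
        rng <- strsplit(tok[2], ":", fixed = TRUE)[[1]]
        ids <- suppressWarnings(as.integer(rng))
        if (any(is.na(ids)) || length(ids) > 2)
          stop("selection error: bad resid '", tok[2], "'")
        if (length(ids) == 2) ids <- seq(ids[1], ids[2])
        atoms$residue_id %in% ids
      },
      segid = atoms$segment_id == tok[2],
      name = if (startsWith(tok[2], "*"))
        endsWith(atoms$atom_name, substr(tok[2], 2, nchar(tok[2])))
      else atoms$atom_name == tok[2],
      stop("selection error: unknown keyword '", tok[1], "'"))
  }
  mask
}

PROTONATION_STATES <- list(
  HIS = c(hsd = "HSD", hse = "HSE", hsp = "HSP"),
  ASP = c(asp = "ASP", aspp = "ASPP"),
  GLU = c(glu = "GLU", glup = "GLUP"),
  LYS = c(lys = "LYS", lsn = "LSN"),
  CYS = c(cys = "CYS", cym = "CYM"),
  TYR = c(tyr = "TYR", tyro = "TYRO"))

base_residue <- function(rn) {
  for (b in names(PROTONATION_STATES))
    if (rn %in% PROTONATION_STATES[[b]] || rn == b) return(b)
  NA_character_
}

#' Set the protonation state of a titratable residue
#'
#' Replaces the residue's hydrogens and template charges by those of
#' the requested state (e.g. `"hsp"` for doubly protonated histidine);
#' heavy-atom coordinates and all other residues are untouched.
#' Idempotent: reapplying the current state reproduces the system.
#'
#' @param system a parameterized `redox_system`.
#' @param residue_id residue to edit.
#' @param state protonation label; one of `hsd`, `hse`, `hsp`, `asp`,
#'   `aspp`, `glu`, `glup`, `lys`, `lsn`, `cys`, `cym`, `tyr`, `tyro`.
#' @return the edited system.
#' @export
set_protonation <- function(system, residue_id, state) {
  valid <- unlist(lapply(PROTONATION_STATES, names))
  state <- tolower(state)
  if (!state %in% valid)
    stop("unknown protonation state '", state, "'; valid labels: ",
         paste(valid, collapse = ", "))
  atoms <- system$atoms
  ridx <- which(atoms$residue_id == residue_id &
                  is_amino(atoms$residue_name))
  if (!length(ridx)) stop("residue ", residue_id, " not found")
  rn <- atoms$residue_name[ridx[1]]
  base <- base_residue(rn)
  if (is.na(base))
    stop("residue ", rn, " ", residue_id, " is not titratable")
  states <- PROTONATION_STATES[[base]]
  if (!state %in% names(states))
    stop("state '", state, "' not valid for ", base, "; valid: ",
         paste(names(states), collapse = ", "))
  retemplate_residue(system, residue_id, states[[state]])
}

# Strip a residue's hydrogens, swap its template, rebuild hydrogens
# and reassign charges/radii.  Heavy atoms shared with the new
# template keep their coordinates.
retemplate_residue <- function(system, residue_id, new_template,
                               keep_heavy = NULL) {
  atoms <- system$atoms
  ridx <- which(atoms$residue_id == residue_id &
                  is_amino(atoms$residue_name))
  res <- atoms[ridx, ]
  t <- templates()[[new_template]]
  nter <- any(startsWith(res$atom_name, "HT"))
  cter <- any(res$atom_name %in% c("OT1", "OT2"))
  heavy_names <- c(BACKBONE_ATOMS,
                   names(t$charges)[!grepl("^H", names(t$charges))])
  if (!is.null(keep_heavy)) heavy_names <- keep_heavy
  keep <- res$element != "H" & res$atom_name %in%
    c(heavy_names, if (cter) c("OT1", "OT2"))
  res <- res[keep, ]
  res$residue_name <- t$name
  res$charge <- NA_real_; res$radius <- NA_real_

  prev_C <- NULL
  pi_ <- which(atoms$residue_id == residue_id - 1 &
                 atoms$chain == res$chain[1] & atoms$atom_name == "C")
  if (length(pi_))
    prev_C <- c(atoms$x[pi_[1]], atoms$y[pi_[1]], atoms$z[pi_[1]])
  res <- param_amino(res, t, entry = NULL, ligating = FALSE,
                     nter = nter, cter = cter, prev_C = prev_C,
                     build_h = TRUE)
  before <- atoms[seq_len(min(ridx) - 1), , drop = FALSE]
  after <- if (max(ridx) < nrow(atoms))
    atoms[(max(ridx) + 1):nrow(atoms), , drop = FALSE]
  else atoms[0, ]
  system$atoms <- rbind(before, res, after)
  rownames(system$atoms) <- NULL
  system
}

#' Zero the partial charges of selected atoms
#'
#' The charge knock-out used for per-residue contribution analysis:
#' selected atoms keep their coordinates and radii (the dielectric
#' cavity is unchanged) but contribute no charge.
#'
#' @param system a parameterized `redox_system`.
#' @param selection selection string (see [select_atoms()]).
#' @return the edited system.
#' @export
knockout_charges <- function(system, selection) {
  mask <- select_atoms(selection, system$atoms)
  system$atoms$charge[mask] <- 0
  system
}

#' Mutate a residue by truncation / re-templating
#'
#' The backbone (and any side-chain atoms shared with the target
#' template, e.g. CB) keep their coordinates exactly; remaining target
#' atoms are rebuilt from ideal internal coordinates.  Truncations
#' (X -> Ala/Gly) are exact in this scheme; mutations that grow the
#' side chain are placed from the template without repacking and are
#' flagged approximate.
#'
#' @param system a parameterized `redox_system`.
#' @param residue_id residue to mutate.
#' @param target target residue type (template name, e.g. `"ALA"`).
#' @return the mutated system.
#' @export
mutate_residue <- function(system, residue_id, target) {
  target <- toupper(target)
  if (!target %in% template_residues())
    stop("unsupported mutation target '", target, "'")
  atoms <- system$atoms
  ridx <- which(atoms$residue_id == residue_id &
                  is_amino(atoms$residue_name))
  if (!length(ridx)) stop("residue ", residue_id, " not found")
  if (!is.null(system$site) &&
      paste(residue_id, atoms$residue_name[ridx[1]]) %in%
        system$site$ligand_residues)
    stop("residue ", residue_id,
         " ligates the redox site and cannot be mutated")
  src <- templates()[[PDB_TO_TEMPLATE[[atoms$residue_name[ridx[1]]]]]]
  tgt <- templates()[[target]]
  src_heavy <- names(src$charges)[!grepl("^H", names(src$charges))]
  tgt_heavy <- names(tgt$charges)[!grepl("^H", names(tgt$charges))]
  grown <- setdiff(tgt_heavy, src_heavy)
  if (length(grown))
    message("mutation ", src$name, residue_id, " -> ", target,
            " grows the side chain (", paste(grown, collapse = ", "),
            "); template placement is approximate")
  retemplate_residue(system, residue_id, target)
}
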