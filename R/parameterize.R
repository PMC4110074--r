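#' Assign charges, radii and hydrogens to a partitioned system
#'
#' Every atom receives a partial charge and radius: protein residues
#' from the residue templates at their current protonation state,
#' good heteroatoms from the het templates, and redox-site atoms
#' (cofactor plus ligating side chains) from the library entry's
#' oxidized-state charge set.  Missing hydrogens (and missing
#' side-chain heavy atoms) are built from ideal internal coordinates.
#'
#' @param system a `redox_system`, normally after
#'   [partition_segments()] and [assign_redox_site()].
#' @param entry library entry for the redox site (required if a redox
#'   segment is present).
#' @param termini `"charged"` applies NH3+/COO- patches to chain
#'   termini; `"neutral"` leaves the standard backbone charges (useful
#'   for synthetic fragment systems).
#' @param build_h build missing hydrogens (disable for pre-protonated
#'   input such as PQR files).
#' @return a parameterized `redox_system`.
#' @export
parameterize_system <- function(system, entry = NULL,
                                termini = c("charged", "neutral"),
                                build_h = TRUE) {
  termini <- match.arg(termini)
  atoms <- system$atoms
  atoms$atom_name <- normalize_atom_name(atoms$atom_name)
  roles <- system$roles
  role_of <- roles[atoms$segment_id]
  has_site <- any(role_of == "redox-site", na.rm = TRUE)
  if (has_site && is.null(entry))
    stop("redox segment present but no library entry supplied")
  lig <- if (!is.null(system$site)) system$site$ligand_residues else
    character()

  # residue blocks in file order (chain-keyed so a ligating residue
  # split across protein/redox segments stays one block)
  key <- paste(atoms$chain, atoms$residue_id, atoms$residue_name)
  blocks <- split(seq_len(nrow(atoms)), factor(key, unique(key)))
  tpl <- templates()
  het <- het_templates()

  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    idx <- blocks[[bi]]
    res <- atoms[idx, ]
    rn <- res$residue_name[1]
    role <- role_of[idx[1]]
    ligating <- paste(res$residue_id[1], rn) %in% lig ||
      (role == "redox-site" && is_amino(rn))

    if (!is.na(role) && role == "redox-site" && !ligating) {
      out[[bi]] <- param_cofactor(res, entry)
    } else if (is_amino(rn)) {
      tname <- if (ligating) "CYM" else PDB_TO_TEMPLATE[[rn]]
      t <- tpl[[tname]]
      is_first <- !any(atoms$residue_id == res$residue_id[1] - 1 &
                         atoms$chain == res$chain[1] &
                         is_amino(atoms$residue_name))
      is_last <- !any(atoms$residue_id == res$residue_id[1] + 1 &
                        atoms$chain == res$chain[1] &
                        is_amino(atoms$residue_name))
      prev_C <- NULL
      if (!is_first) {
        pi_ <- which(atoms$residue_id == res$residue_id[1] - 1 &
                       atoms$chain == res$chain[1] &
                       atoms$atom_name == "C")
        if (length(pi_))
          prev_C <- c(atoms$x[pi_[1]], atoms$y[pi_[1]], atoms$z[pi_[1]])
      }
      out[[bi]] <- param_amino(res, t, entry, ligating,
                               nter = is_first && termini == "charged" &&
                                 tname != "PRO",
                               cter = is_last && termini == "charged",
                               prev_C = prev_C, build_h = build_h)
    } else if (rn %in% names(het)) {
      out[[bi]] <- param_het(res, het[[rn]], build_h)
    } else {
      warning("no parameters for residue ", rn, "; atoms dropped")
      out[[bi]] <- NULL
    }
  }
  atoms <- do.call(rbind, out)
  rownames(atoms) <- NULL
  if (any(is.na(atoms$charge) | is.na(atoms$radius)))
    stop("internal error: unparameterized atoms remain")
  system$atoms <- atoms
  system$parameterized <- TRUE
  if (has_site && !is.null(entry))
    system$redox_state <- "oxidized"
  system
}

# one amino-acid residue: complete heavies, build H, assign q/r
param_amino <- function(res, t, entry, ligating, nter, cter, prev_C,
                        build_h) {
  proto <- res[1, ]
  addrow <- function(df, name, x, y, z) {
    r <- proto
    r$atom_name <- name; r$x <- x; r$y <- y; r$z <- z
    r$element <- element_of(name); r$altloc <- ""
    rbind(df, r)
  }
  # complete missing side-chain heavy atoms from the Z-matrix
  if (all(c("N", "CA", "C") %in% res$atom_name)) {
    miss <- build_sidechain_heavy(res, t)
    if (!is.null(miss))
      for (i in seq_len(nrow(miss)))
        res <- addrow(res, miss$name[i], miss$x[i], miss$y[i],
                      miss$z[i])
  }
  if (build_h) {
    hnew <- build_res_hydrogens(res, t, prev_C = prev_C, nter = nter)
    if (!is.null(hnew))
      for (i in seq_len(nrow(hnew)))
        res <- addrow(res, hnew$name[i], hnew$x[i], hnew$y[i],
                      hnew$z[i])
  }
  if (cter && !"OT2" %in% res$atom_name &&
      all(c("C", "CA", "O") %in% res$atom_name)) {
    p <- function(nm) {
      i <- match(nm, res$atom_name); c(res$x[i], res$y[i], res$z[i])
    }
    ot2 <- place_zmat_atom(p("C"), p("CA"), p("O"), 1.25, 118, 180)
    res <- addrow(res, "OT2", ot2[1], ot2[2], ot2[3])
  }
  q <- t$charges
  if (nter) {
    q <- q[setdiff(names(q), "HN")]
    q["N"] <- -0.30
    q[c("HT1", "HT2", "HT3")] <- 0.33
    if (t$name == "GLY") q["CA"] <- 0.13 else {
      q["CA"] <- 0.21; q["HA"] <- 0.10
    }
  }
  if (cter) {
    q <- q[setdiff(names(q), "O")]
    q["C"] <- 0.34
    q[c("OT1", "OT2")] <- -0.67
    res$atom_name[res$atom_name == "O"] <- "OT1"
  }
  known <- res$atom_name %in% names(q)
  if (any(!known)) {
    warning("residue ", t$name, " ", res$residue_id[1],
            ": dropping unmatched atom(s) ",
            paste(res$atom_name[!known], collapse = ", "))
    res <- res[known, ]
  }
  res$charge <- unname(q[res$atom_name])
  res$radius <- radius_for(res$atom_name, res$element, t)
  if (ligating && !is.null(entry)) {
    # side-chain charges/radii come from the library's oxidized set
    sp <- entry$atom_spec
    side <- !(res$atom_name %in% BACKBONE_ATOMS)
    m <- match(res$atom_name, sp$name)
    use <- side & !is.na(m)
    res$charge[use] <- sp$charge_ox[m[use]]
    res$radius[use] <- sp$radius[m[use]]
    # newly built side-chain hydrogens follow their heavy atoms into
    # the redox segment
    seg_bad <- res$segment_id[use & res$element != "H"]
    if (length(seg_bad)) res$segment_id[use] <- seg_bad[1]
  }
  if (!ligating) res$residue_name <- t$name
  res
}

param_cofactor <- function(res, entry) {
  sp <- entry$atom_spec
  m <- match(res$atom_name, sp$name)
  if (any(is.na(m)))
    stop("site atom name(s) not in library entry '", entry$id, "': ",
         paste(unique(res$atom_name[is.na(m)]), collapse = ", "))
  res$charge <- sp$charge_ox[m]
  res$radius <- sp$radius[m]
  res
}

param_het <- function(res, t, build_h) {
  if (build_h && length(t$hydrogens)) {
    miss <- setdiff(names(t$hydrogens), res$atom_name)
    if (length(miss)) {
      fake_tpl <- list(bonds = t$bonds, sp2 = t$sp2,
                       hydrogens = t$hydrogens)
      hnew <- build_res_hydrogens(res, fake_tpl)
      if (!is.null(hnew))
        for (i in seq_len(nrow(hnew))) {
          r <- res[1, ]
          r$atom_name <- hnew$name[i]
          r$x <- hnew$x[i]; r$y <- hnew$y[i]; r$z <- hnew$z[i]
          r$element <- "H"; r$altloc <- ""
          res <- rbind(res, r)
        }
    }
  }
  known <- res$atom_name %in% names(t$charges)
  res <- res[known, ]
  res$charge <- unname(t$charges[res$atom_name])
  res$radius <- radius_for(res$atom_name, res$element, t)
  res
}
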