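#' Read a protein structure from a PDB file
#'
#' Parses all `ATOM` and `HETATM` records.  Alternate locations are
#' resolved to the highest-occupancy conformer (ties: first in file);
#' chains are preserved.  The result is a raw (unparameterized)
#' [redox_system()] precursor with one segment per chain.
#'
#' @param path path to a PDB-format text file.
#' @return a `redox_system` with unassigned charges/radii.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("unreadable file: ", path))
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0)
    stop("empty structure: no ATOM/HETATM records in ", path)

  fx <- function(a, b) trimws(substr(lines, a, b))
  num <- function(a, b) suppressWarnings(as.numeric(fx(a, b)))
  atom_name <- fx(13, 16)
  altloc <- substr(lines, 17, 17)
  residue_name <- fx(18, 21)
  chain <- substr(lines, 22, 22)
  residue_id <- suppressWarnings(as.integer(fx(23, 26)))
  x <- num(31, 38); y <- num(39, 46); z <- num(47, 54)
  occ <- num(55, 60)
  occ[is.na(occ)] <- 1
  element <- fx(77, 78)
  element <- ifelse(element == "",
                    guess_element(atom_name, residue_name), element)
  element <- toupper(element)
  if (any(is.na(x) | is.na(y) | is.na(z)))
    stop("parse error: malformed coordinate fields in ", path)

  atoms <- new_atom_table(atom_name = atom_name, element = element,
                          residue_name = residue_name,
                          residue_id = residue_id, chain = chain,
                          segment_id = chain, x = x, y = y, z = z,
                          charge = NA_real_, radius = NA_real_,
                          occupancy = occ, altloc = trimws(altloc))
  atoms <- resolve_altloc(atoms)
  redox_system(atoms)
}

# Highest occupancy wins; ties keep the conformer seen first in file.
resolve_altloc <- function(atoms) {
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$residue_id, atoms$residue_name,
               atoms$atom_name)
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  sorted <- atoms[ord, ]
  keep <- !duplicated(paste(sorted$chain, sorted$residue_id,
                            sorted$residue_name, sorted$atom_name))
  out <- sorted[keep, ]
  out <- out[order(as.integer(rownames(out))), ]
  rownames(out) <- NULL
  out$altloc <- ""
  out
}

guess_element <- function(name, resname = NULL) {
  up <- toupper(trimws(name))
  el <- substr(gsub("[0-9']", "", up), 1, 1)
  # unambiguous two-letter metals (no protein atom starts with these)
  metals <- c("FE", "ZN", "MN", "CU", "NI")
  hit <- substr(up, 1, 2) %in% metals
  el[hit] <- substr(up[hit], 1, 2)
  # CA / NA / K / CL / MG are ions only when the residue IS the ion
  # (otherwise CA is an alpha carbon, NA part of a base name, ...)
  if (!is.null(resname)) {
    ion <- up %in% c("CA", "NA", "K", "CL", "MG") &
      toupper(trimws(resname)) == up
    el[ion] <- up[ion]
  }
  # hydrogen names like 1HB / HB1
  el[grepl("^[0-9]*H", up)] <- "H"
  el
}

#' Write a parameterized system to a PQR file
#'
#' PQR is PDB-like with per-atom charge and radius in place of
#' occupancy and B-factor (whitespace-delimited numeric fields).
#'
#' @param system a parameterized `redox_system`.
#' @param path output file path.
#' @export
write_pqr <- function(system, path) {
  a <- system$atoms
  if (any(is.na(a$charge) | is.na(a$radius)))
    stop("system is not parameterized; charges/radii missing")
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f %8.4f %7.4f  %s",
    seq_len(nrow(a)), substr(a$atom_name, 1, 4),
    substr(a$residue_name, 1, 4), a$residue_id, a$x, a$y, a$z,
    a$charge, a$radius, a$segment_id)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a system to a PDB-format file
#'
#' Standard fixed columns; charges/radii are not stored (use
#' [write_pqr()] for those).  Mainly useful for persisting synthetic
#' fixtures and feeding the command-line interface.
#'
#' @param system a `redox_system`.
#' @param path output file path.
#' @export
write_pdb <- function(system, path) {
  a <- system$atoms
  rec <- ifelse(is_amino(a$residue_name), "ATOM  ", "HETATM")
  name4 <- ifelse(nchar(a$atom_name) < 4,
                  sprintf(" %-3s", a$atom_name),
                  substr(a$atom_name, 1, 4))
  lines <- sprintf("%s%5d %s %-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), name4,
                   substr(a$residue_name, 1, 4), a$chain,
                   a$residue_id, a$x, a$y, a$z, a$occupancy, 0,
                   a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PQR file written by [write_pqr()]
#'
#' @param path PQR file path.
#' @param roles optional named role map for the segment ids found.
#' @return a parameterized `redox_system`.
#' @export
read_pqr <- function(path, roles = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(lines)) stop("empty PQR file: ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  n <- length(parts)
  get <- function(i) vapply(parts, `[[`, "", i)
  atoms <- new_atom_table(
    atom_name = get(3), element = guess_element(get(3), get(4)),
    residue_name = get(4), residue_id = as.integer(get(5)),
    chain = substr(get(11), 1, 1), segment_id = get(11),
    x = as.numeric(get(6)), y = as.numeric(get(7)),
    z = as.numeric(get(8)), charge = as.numeric(get(9)),
    radius = as.numeric(get(10)), occupancy = rep(1, n),
    altloc = rep("", n))
  if (is.null(roles)) {
    segs <- unique(atoms$segment_id)
    roles <- setNames(rep("protein", length(segs)), segs)
    roles[grepl("bad$|site", segs, ignore.case = TRUE)] <- "redox-site"
    roles[grepl("good$", segs, ignore.case = TRUE)] <- "good-het"
  }
  redox_system(atoms, roles = roles, parameterized = TRUE)
}
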