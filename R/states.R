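#' Build the four states of the thermodynamic cycle
#'
#' From one parameterized system with an assigned redox site, emits
#' the oxidized and reduced protein systems (identical coordinates,
#' differing only in the redox-segment charges) and the oxidized and
#' reduced reference systems (the redox segment alone, same
#' coordinates, for the vacuum legs).  The cofactor residue is renamed
#' per oxidation state.
#'
#' @param system parameterized `redox_system` with site assigned.
#' @param entry library entry for the site/couple.
#' @return object of class `four_states` with elements `protein_ox`,
#'   `protein_red`, `reference_ox`, `reference_red`.
#' @export
build_states <- function(system, entry) {
  if (!system$parameterized) stop("system is not parameterized")
  if (is.null(system$site)) stop("no redox site assigned")
  roles <- system$roles
  bad <- names(roles)[roles == "redox-site"]
  in_site <- system$atoms$segment_id == bad
  if (!any(in_site)) stop("redox segment is empty")

  protein_ox <- set_site_charges(system, entry, "oxidized")
  protein_red <- set_site_charges(system, entry, "reduced")

  subset_site <- function(s) {
    s$atoms <- s$atoms[s$atoms$segment_id == bad, ]
    rownames(s$atoms) <- NULL
    s$roles <- roles[bad]
    s
  }
  st <- structure(list(protein_ox = protein_ox,
                       protein_red = protein_red,
                       reference_ox = subset_site(protein_ox),
                       reference_red = subset_site(protein_red),
                       entry = entry),
                  class = "four_states")
  validate_four_states(st)
  st
}

set_site_charges <- function(system, entry, state) {
  atoms <- system$atoms
  bad <- names(system$roles)[system$roles == "redox-site"]
  in_site <- atoms$segment_id == bad
  sp <- entry$atom_spec
  qcol <- if (state == "oxidized") sp$charge_ox else sp$charge_red
  m <- match(atoms$atom_name[in_site], sp$name)
  if (any(is.na(m)))
    stop("site atom name(s) not matching library entry '", entry$id,
         "': ", paste(unique(atoms$atom_name[in_site][is.na(m)]),
                      collapse = ", "))
  atoms$charge[in_site] <- qcol[m]
  atoms$radius[in_site] <- sp$radius[m]
  resname <- if (state == "oxidized") entry$resname_ox else
    entry$resname_red
  if (!is.null(resname)) {
    cof <- in_site & atoms$residue_name %in% entry$site_names |
      in_site & atoms$residue_name %in%
        c(entry$resname_ox, entry$resname_red)
    atoms$residue_name[cof] <- resname
  }
  system$atoms <- atoms
  system$redox_state <- state
  system
}

validate_four_states <- function(st) {
  a <- st$protein_ox$atoms; b <- st$protein_red$atoms
  stopifnot(nrow(a) == nrow(b),
            all(a$atom_name == b$atom_name),
            all(a$x == b$x & a$y == b$y & a$z == b$z))
  bad <- names(st$protein_ox$roles)[st$protein_ox$roles == "redox-site"]
  differ <- abs(a$charge - b$charge) > 0
  if (any(differ & a$segment_id != bad))
    stop("four_states invariant violated: non-redox charges differ")
  for (ref in c("reference_ox", "reference_red")) {
    r <- st[[ref]]$atoms
    sub <- a[a$segment_id == bad, ]
    stopifnot(nrow(r) == nrow(sub),
              all(r$x == sub$x & r$y == sub$y & r$z == sub$z))
  }
  invisible(st)
}

#' Write the four cycle states as PQR files
#'
#' Files are named `wt-ox.pqr`, `wt-red.pqr`, `ref-ox.pqr`,
#' `ref-red.pqr` under `dir`.
#'
#' @param states a `four_states` object.
#' @param dir output directory (created if needed).
#' @return character vector of the four paths.
#' @export
write_states <- function(states, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("wt-ox.pqr", "wt-red.pqr", "ref-ox.pqr",
                            "ref-red.pqr"))
  names(paths) <- c("protein_ox", "protein_red", "reference_ox",
                    "reference_red")
  for (nm in names(paths)) write_pqr(states[[nm]], paths[[nm]])
  paths
}

#' @export
print.four_states <- function(x, ...) {
  cat("<four_states> couple ", couple_label(x$entry$couple), "\n",
      "  protein: ", nrow(x$protein_ox$atoms), " atoms; reference: ",
      nrow(x$reference_ox$atoms), " atoms\n", sep = "")
  invisible(x)
}
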