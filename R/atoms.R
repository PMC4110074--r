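#' Atom tables and redox systems
#'
#' Atoms are kept in a plain data frame, one row per atom, with columns
#' `atom_name`, `element`, `residue_name`, `residue_id`, `chain`,
#' `segment_id`, `x`, `y`, `z`, `charge`, `radius`, `occupancy`,
#' `altloc`.  A `redox_system` wraps the atom table together with the
#' segment role map (protein / good-het / redox-site) and bookkeeping.
#'
#' @name atoms
NULL

ATOM_COLS <- c("atom_name", "element", "residue_name", "residue_id",
               "chain", "segment_id", "x", "y", "z", "charge", "radius",
               "occupancy", "altloc")

new_atom_table <- function(atom_name = character(), element = character(),
                           residue_name = character(),
                           residue_id = integer(), chain = character(),
                           segment_id = character(), x = numeric(),
                           y = numeric(), z = numeric(),
                           charge = numeric(), radius = numeric(),
                           occupancy = numeric(), altloc = character()) {
  data.frame(atom_name = atom_name, element = element,
             residue_name = residue_name,
             residue_id = as.integer(residue_id), chain = chain,
             segment_id = segment_id, x = x, y = y, z = z,
             charge = charge, radius = radius, occupancy = occupancy,
             altloc = altloc, stringsAsFactors = FALSE)
}

validate_atom_table <- function(atoms) {
  stopifnot(is.data.frame(atoms), all(ATOM_COLS %in% names(atoms)))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!is.na(atoms$radius) & atoms$radius < 0))
    stop("negative atomic radius")
  invisible(atoms)
}

#' Construct a redox system
#'
#' @param atoms atom table (see [atoms]).
#' @param roles named character vector mapping `segment_id` values to
#'   one of `"protein"`, `"good-het"`, `"redox-site"`.
#' @param parameterized logical; `TRUE` once every atom carries a charge
#'   and radius.
#' @param site optional list describing the assigned redox site.
#' @param discarded atom table of atoms dropped during preparation
#'   (waters, other monomers), kept for the discard report.
#' @return object of class `redox_system`.
#' @export
redox_system <- function(atoms, roles = character(), parameterized = FALSE,
                         site = NULL, discarded = NULL) {
  validate_atom_table(atoms)
  if (parameterized && any(is.na(atoms$charge) | is.na(atoms$radius)))
    stop("parameterized system has atoms without charge or radius")
  structure(list(atoms = atoms, roles = roles,
                 parameterized = parameterized, site = site,
                 discarded = discarded),
            class = "redox_system")
}

#' @export
print.redox_system <- function(x, ...) {
  cat("<redox_system> ", nrow(x$atoms), " atoms",
      if (x$parameterized) ", parameterized" else "", "\n", sep = "")
  if (length(x$roles)) {
    for (s in names(x$roles)) {
      n <- sum(x$atoms$segment_id == s)
      cat("  segment ", s, " [", x$roles[[s]], "]: ", n, " atoms\n",
          sep = "")
    }
  }
  if (!is.null(x$site))
    cat("  redox site: ", x$site$label, "\n", sep = "")
  invisible(x)
}

#' Total charge of a system
#' @param system a `redox_system`
#' @return sum of partial charges, e
#' @export
total_charge <- function(system) {
  sum(system$atoms$charge, na.rm = TRUE)
}

atom_xyz <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

# Map segment roles onto an integer code per atom used by the solver:
# 0 solvent (never an atom), 1 protein/good-het, 2 redox-site core.
atom_region_role <- function(system) {
  role <- system$roles[system$atoms$segment_id]
  out <- ifelse(role == "redox-site", 2L, 1L)
  out[is.na(out)] <- 1L
  as.integer(out)
}
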