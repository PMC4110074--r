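#' Redox parameter library
#'
#' A library entry carries everything needed to turn a recognized
#' cofactor into a redox site: the PDB residue names it appears under,
#' the redox couple (formal site charges of the oxidized and reduced
#' states), the intrinsic reduction free energy `dg_in` (kcal/mol,
#' from quantum chemistry), the free energy of an electron in the
#' standard hydrogen electrode `dg_she` (kcal/mol), and per-atom
#' radii plus oxidized/reduced partial charge sets covering the
#' cofactor and its ligating side-chain atoms.
#'
#' The file format is human-readable key/value text, one `entry ...` /
#' `end` document per entry; see the shipped
#' `extdata/redox_library.txt` for a commented example.
#'
#' @name redox_library
NULL

couple_label <- function(couple) {
  fmt <- function(q) {
    if (q == 0) return("0")
    paste0(abs(q), if (q < 0) "-" else "+")
  }
  paste0(fmt(couple[1]), "/", fmt(couple[2]))
}

parse_couple <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("cannot parse couple '", x, "'")
  num <- function(p) {
    p <- trimws(p)
    sign <- if (endsWith(p, "-")) -1L else 1L
    as.integer(sub("[-+]$", "", p)) * sign
  }
  c(num(parts[1]), num(parts[2]))
}

#' Load and validate a redox parameter library file
#'
#' @param path library file; defaults to the library shipped with the
#'   package.
#' @return list of validated entries (class `redox_entry`).
#' @export
load_library <- function(path = system.file("extdata",
                                            "redox_library.txt",
                                            package = "redoxpot")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "entry")) {
      cur <- list(id = trimws(sub("^entry", "", ln)),
                  atom_spec = list(), provenance = character())
    } else if (ln == "end") {
      e <- finalize_entry(cur)
      entries[[e$id]] <- e
      cur <- NULL
    } else if (startsWith(ln, "atom ")) {
      p <- strsplit(ln, "\\s+")[[1]]
      if (length(p) != 6)
        stop("library parse error: bad atom line '", ln, "'")
      cur$atom_spec[[length(cur$atom_spec) + 1]] <-
        data.frame(name = p[2], radius = as.numeric(p[3]),
                   charge_ox = as.numeric(p[4]),
                   charge_red = as.numeric(p[5]),
                   count = as.integer(p[6]))
    } else {
      kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
      if (length(kv) != 2)
        stop("library parse error: '", ln, "'")
      key <- trimws(kv[1]); val <- trimws(kv[2])
      cur[[key]] <- switch(key,
        site_names = strsplit(val, "\\s+")[[1]],
        couple = parse_couple(val),
        n_electrons = as.integer(val),
        dg_in = as.numeric(val),
        dg_she = as.numeric(val),
        ligand = val,
        provenance = c(cur$provenance, val),
        val)
    }
  }
  if (!length(entries)) stop("library file contains no entries")
  entries
}

finalize_entry <- function(e) {
  if (!is.data.frame(e$atom_spec))
    e$atom_spec <- do.call(rbind, e$atom_spec)
  if (!is.null(e$ligand)) {
    p <- strsplit(e$ligand, "\\s+")[[1]]
    e$ligand_resname <- p[1]
    e$n_ligands <- as.integer(p[2])
    e$ligand <- NULL
  }
  validate_entry(e)
  class(e) <- "redox_entry"
  e
}

#' Validate one library entry against its invariants
#'
#' Checks: `q_red = q_ox - n_electrons`; single-electron couples only;
#' charge sets sum to the formal state charges within 1e-3 e; all
#' radii positive.
#'
#' @param e entry list.
#' @return the entry, invisibly; stops with the failed rule otherwise.
#' @export
validate_entry <- function(e) {
  fail <- function(rule)
    stop("library entry '", e$id, "' failed validation: ", rule)
  need <- c("site_names", "couple", "n_electrons", "dg_in", "dg_she",
            "atom_spec")
  for (f in need) if (is.null(e[[f]])) fail(paste("missing field", f))
  if (e$n_electrons != 1L)
    fail("n_electrons must be 1 (single-electron couples only)")
  if (e$couple[2] != e$couple[1] - e$n_electrons)
    fail("q_red must equal q_ox - n_electrons")
  if (any(e$atom_spec$radius <= 0)) fail("all radii must be > 0")
  sox <- sum(e$atom_spec$charge_ox * e$atom_spec$count)
  sred <- sum(e$atom_spec$charge_red * e$atom_spec$count)
  if (abs(sox - e$couple[1]) > 1e-3)
    fail(sprintf("oxidized charges sum to %.4f, not q_ox = %d",
                 sox, e$couple[1]))
  if (abs(sred - e$couple[2]) > 1e-3)
    fail(sprintf("reduced charges sum to %.4f, not q_red = %d",
                 sred, e$couple[2]))
  invisible(e)
}

#' Write a library back to its text format
#'
#' `load_library(write_library(lib, f))` reproduces the entries
#' exactly (full printed precision).
#'
#' @param entries list of entries.
#' @param path output path.
#' @export
write_library <- function(entries, path) {
  out <- c("# redoxpot parameter library")
  for (e in entries) {
    out <- c(out, paste("entry", e$id),
             paste("site_names:", paste(e$site_names, collapse = " ")),
             paste("couple:", couple_label(e$couple)),
             paste("n_electrons:", e$n_electrons),
             if (!is.null(e$n_ligands))
               paste("ligand:", e$ligand_resname, e$n_ligands),
             paste("dg_in:", format(e$dg_in, digits = 15)),
             paste("dg_she:", format(e$dg_she, digits = 15)),
             if (!is.null(e$resname_ox))
               paste("resname_ox:", e$resname_ox),
             if (!is.null(e$resname_red))
               paste("resname_red:", e$resname_red),
             paste("provenance:", e$provenance),
             sprintf("atom %s %s %s %s %d", e$atom_spec$name,
                     format(e$atom_spec$radius, digits = 15),
                     format(e$atom_spec$charge_ox, digits = 15),
                     format(e$atom_spec$charge_red, digits = 15),
                     e$atom_spec$count),
             "end")
  }
  writeLines(out, path)
  invisible(path)
}

#' Look up a library entry by site name and couple
#'
#' @param library list of entries from [load_library()].
#' @param site_name PDB residue name of the cofactor (aliases such as
#'   `"FS4"`/`"SF4"` resolve to the same entry).
#' @param couple redox couple, either a label like `"1-/2-"` or an
#'   integer vector `c(q_ox, q_red)`.
#' @return the matching `redox_entry`.
#' @export
get_entry <- function(library, site_name, couple) {
  couple <- parse_couple(couple)
  hit <- Filter(function(e) site_name %in% e$site_names &&
                  all(e$couple == couple), library)
  if (length(hit) == 0)
    stop("unsupported redox site: no library entry for ", site_name,
         " with couple ", couple_label(couple))
  if (length(hit) > 1)
    stop("ambiguous library: ", length(hit), " entries match ",
         site_name, " ", couple_label(couple))
  hit[[1]]
}

.lib_env <- new.env(parent = emptyenv())

#' The library shipped with the package (cached)
#' @return list of entries
#' @export
default_library <- function() {
  if (is.null(.lib_env$lib)) .lib_env$lib <- load_library()
  .lib_env$lib
}

#' @export
print.redox_entry <- function(x, ...) {
  cat("<redox_entry> ", x$id, ": ", paste(x$site_names, collapse = "/"),
      " ", couple_label(x$couple), "\n", sep = "")
  cat("  dg_in = ", x$dg_in, " kcal/mol; dg_she = ", x$dg_she,
      " kcal/mol\n", sep = "")
  cat("  ", sum(x$atom_spec$count), " site atoms\n", sep = "")
  invisible(x)
}
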