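#' Grid specification
#'
#' Node-centred cubic-lattice grid: node `(i,j,k)` (0-based) sits at
#' `origin + spacing * (i,j,k)`.
#'
#' @param origin numeric length-3, Angstrom.
#' @param spacing grid spacing, Angstrom.
#' @param dims integer length-3 node counts.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, dims) {
  stopifnot(spacing > 0, length(origin) == 3, length(dims) == 3,
            all(dims >= 2))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims)), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %dx%dx%d, h = %g A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Poisson-Boltzmann run parameters
#'
#' Defaults follow the three-dielectric redox setup: `eps_core = 1`
#' for the redox-site volume, `eps_protein = 4`, `eps_solvent = 78`
#' (78.54 selectable), fine spacing 0.4 A (0.2 A suggested for
#' accuracy), zero ionic strength.
#'
#' @param eps_core,eps_protein,eps_solvent region dielectrics (>= 1).
#' @param ionic_strength mol/L (linearized salt term; default 0).
#' @param temperature K.
#' @param spacing_fine,spacing_coarse grid spacings, A.
#' @param padding coarse-grid padding around the molecule, A (>= 20
#'   recommended for Debye-Hueckel boundaries).
#' @param fine_margin fine-grid margin around the molecule, A.
#' @param tol relative residual convergence tolerance.
#' @param max_iter iteration cap.
#' @param nsub edge sub-samples for dielectric smoothing.
#' @param ntrans transverse sub-sampling (1 = along-edge only; > 1
#'   adds a cross of quarter-step offsets for a finer interface).
#' @return object of class `pb_params`.
#' @export
pb_params <- function(eps_core = 1, eps_protein = 4, eps_solvent = 78,
                      ionic_strength = 0, temperature = 298.15,
                      spacing_fine = 0.4, spacing_coarse = 1.0,
                      padding = 20, fine_margin = 5, tol = 1e-6,
                      max_iter = 20000L, nsub = 3L, ntrans = 1L) {
  stopifnot(eps_core >= 1, eps_protein >= 1, eps_solvent >= 1,
            tol > 0, spacing_fine > 0, spacing_coarse > 0)
  structure(list(eps_core = eps_core, eps_protein = eps_protein,
                 eps_solvent = eps_solvent,
                 ionic_strength = ionic_strength,
                 temperature = temperature,
                 spacing_fine = spacing_fine,
                 spacing_coarse = spacing_coarse, padding = padding,
                 fine_margin = fine_margin, tol = tol,
                 max_iter = as.integer(max_iter),
                 nsub = as.integer(nsub),
                 ntrans = as.integer(ntrans)),
            class = "pb_params")
}

# eps_s * kappa^2 (A^-2) for the linearized salt term
salt_lambda <- function(params) {
  if (params$ionic_strength <= 0) return(0)
  rho_i <- params$ionic_strength * 6.02214e-4   # e/A^3 per mol/L
  8 * pi * KCOUL * rho_i / (0.0019872 * params$temperature)
}

debye_kappa <- function(params) {
  lam <- salt_lambda(params)
  if (lam <= 0) return(0)
  sqrt(lam / params$eps_solvent)
}

# Grid pair (coarse for boundary focusing, fine for energies) sized
# from the atom bounding box.
make_grids <- function(atoms, params) {
  lo <- c(min(atoms$x), min(atoms$y), min(atoms$z))
  hi <- c(max(atoms$x), max(atoms$y), max(atoms$z))
  rmax <- max(atoms$radius, na.rm = TRUE)
  mk <- function(margin, h, min_dim = 33L) {
    span <- (hi - lo) + 2 * (margin + rmax)
    dims <- pmax(as.integer(ceiling(span / h)) + 1L, min_dim)
    center <- (lo + hi) / 2
    origin <- center - (dims - 1) * h / 2
    grid_spec(origin, h, dims)
  }
  list(coarse = mk(params$padding, params$spacing_coarse, 17L),
       fine = mk(params$fine_margin, params$spacing_fine))
}

grid_points_boundary <- function(grid) {
  d <- grid$dims
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  on_b <- i == 0L | i == d[1] - 1L | j == 0L | j == d[2] - 1L |
    k == 0L | k == d[3] - 1L
  list(mask = on_b,
       pts = cbind(grid$origin[1] + i[on_b] * grid$spacing,
                   grid$origin[2] + j[on_b] * grid$spacing,
                   grid$origin[3] + k[on_b] * grid$spacing))
}

#' Write a scalar grid in OpenDX format
#'
#' @param grid a `grid_spec`.
#' @param values numeric vector, length `prod(grid$dims)`, x-fastest.
#' @param path output file.
#' @param name dataset label.
#' @export
write_dx <- function(grid, values, path, name = "redoxpot grid") {
  d <- grid$dims
  stopifnot(length(values) == prod(d))
  # OpenDX wants z-fastest ordering
  arr <- array(values, dim = d)
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  n <- length(vals)
  pad <- c(vals, rep(0, (3 - n %% 3) %% 3))
  rows <- matrix(pad, ncol = 3, byrow = TRUE)
  body <- sprintf("%.6e %.6e %.6e", rows[, 1], rows[, 2], rows[, 3])
  if (n %% 3 != 0) {
    last <- vals[(n - n %% 3 + 1):n]
    body[length(body)] <- paste(sprintf("%.6e", last), collapse = " ")
  }
  hdr <- c(sprintf("# %s", name),
           sprintf("object 1 class gridpositions counts %d %d %d",
                   d[1], d[2], d[3]),
           sprintf("origin %.6e %.6e %.6e", grid$origin[1],
                   grid$origin[2], grid$origin[3]),
           sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing),
           sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing),
           sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing),
           sprintf("object 2 class gridconnections counts %d %d %d",
                   d[1], d[2], d[3]),
           sprintf(paste0("object 3 class array type double rank 0",
                          " items %d data follows"), n))
  writeLines(c(hdr, body,
               'attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), path)
  invisible(path)
}
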