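#' Build the three-region dielectric map for a state
#'
#' Region precedence is core > protein > solvent: a point inside any
#' redox-site atom sphere gets `eps_core`; otherwise inside any
#' protein/het atom sphere, `eps_protein`; otherwise `eps_solvent`.
#' Values live on edge midpoints; each edge is sub-sampled and
#' harmonically averaged so the interface is placed to sub-grid
#' accuracy.  Passing `uniform` builds the flat map used for the
#' vacuum reference legs (`eps = 1` everywhere).
#'
#' @param state parameterized `redox_system`.
#' @param grid a `grid_spec`.
#' @param params a `pb_params`.
#' @param uniform if non-NULL, a single dielectric value for the whole
#'   grid.
#' @return object of class `dielectric_map` (edge arrays `ex`, `ey`,
#'   `ez`, node `region` codes, far-field dielectric `eps_far`).
#' @export
build_dielectric_map <- function(state, grid, params, uniform = NULL) {
  atoms <- state$atoms
  d <- grid$dims
  if (!is.null(uniform)) {
    n <- prod(d)
    return(structure(list(grid = grid, ex = rep(uniform, n),
                          ey = rep(uniform, n), ez = rep(uniform, n),
                          region = integer(n), eps_far = uniform),
                     class = "dielectric_map"))
  }
  check_atoms_in_grid(atoms, grid)
  role <- atom_region_role(state)
  xyz <- atom_xyz(atoms)
  ee <- cpp_edge_eps(grid$origin, grid$spacing, d, xyz, atoms$radius,
                     role, params$eps_core, params$eps_protein,
                     params$eps_solvent, params$nsub,
                     params$ntrans %||% 1L)
  region <- cpp_node_region(grid$origin, grid$spacing, d, xyz,
                            atoms$radius, role)
  structure(list(grid = grid, ex = ee$x, ey = ee$y, ez = ee$z,
                 region = region, eps_far = params$eps_solvent),
            class = "dielectric_map")
}

check_atoms_in_grid <- function(atoms, grid) {
  hi <- grid$origin + (grid$dims - 1) * grid$spacing
  r <- ifelse(is.na(atoms$radius), 0, atoms$radius)
  if (any(atoms$x - r < grid$origin[1] | atoms$x + r > hi[1] |
          atoms$y - r < grid$origin[2] | atoms$y + r > hi[2] |
          atoms$z - r < grid$origin[3] | atoms$z + r > hi[3]))
    stop("geometry error: atom sphere extends outside the grid box")
  invisible(TRUE)
}

#' Spread atomic charges onto grid nodes
#'
#' Trilinear weighting to the 8 surrounding nodes; total grid charge
#' equals total atomic charge to machine precision.
#'
#' @param state parameterized `redox_system`.
#' @param grid a `grid_spec`.
#' @return object of class `charge_grid` (node charges `rho` in e,
#'   plus the source atom coordinates/charges for boundary sums).
#' @export
spread_charges <- function(state, grid) {
  atoms <- state$atoms
  xyz <- atom_xyz(atoms)
  rho <- cpp_spread_charges(grid$origin, grid$spacing, grid$dims, xyz,
                            atoms$charge)
  structure(list(grid = grid, rho = rho, atoms_xyz = xyz,
                 atoms_q = atoms$charge),
            class = "charge_grid")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) && a$spacing == b$spacing &&
    all(a$dims == b$dims)
}

#' Solve the linear Poisson-Boltzmann equation on a grid
#'
#' Finite-difference 7-point discretization of
#' `div(eps grad phi) - eps_s kappa^2 phi = -4 pi k_c rho`, solved by
#' deterministic Jacobi-preconditioned conjugate gradient to the
#' requested relative residual.  Dirichlet boundary values come from a
#' Debye-Hueckel/Coulomb superposition over the source charges, or
#' from a coarser solve when `focus_from` is given (two-level
#' focusing).
#'
#' @param diel a `dielectric_map`.
#' @param rho a `charge_grid` on the same grid.
#' @param params a `pb_params`.
#' @param focus_from optional `potential_map` from a coarser solve
#'   enclosing this grid; its interpolated values become the boundary.
#' @return object of class `potential_map` with node potentials in
#'   kcal/(mol e).
#' @export
solve_pb <- function(diel, rho, params, focus_from = NULL) {
  if (!same_grid(diel$grid, rho$grid))
    stop("dielectric and charge grids differ")
  grid <- diel$grid
  bnd <- grid_points_boundary(grid)
  phi0 <- numeric(prod(grid$dims))
  if (is.null(focus_from)) {
    kappa <- if (diel$eps_far > 1) debye_kappa(params) else 0
    phi_b <- cpp_boundary_potential(grid$origin, grid$spacing,
                                    grid$dims, rho$atoms_xyz,
                                    rho$atoms_q, diel$eps_far, kappa)
    phi0 <- phi_b
  } else {
    phi0[bnd$mask] <- cpp_interp_grid(focus_from$grid$origin,
                                      focus_from$grid$spacing,
                                      focus_from$grid$dims,
                                      focus_from$values, bnd$pts)
  }
  lam <- salt_lambda(params)
  lamvec <- if (lam > 0) lam * (diel$region == 0L) else
    numeric(prod(grid$dims))
  sol <- cpp_solve_pb(grid$dims, grid$spacing, diel$ex, diel$ey,
                      diel$ez, lamvec, rho$rho, phi0, params$tol,
                      params$max_iter)
  if (!sol$converged)
    stop(sprintf(paste0("PB solve failed to converge in %d iterations",
                        " (relative residual %.3e)"),
                 params$max_iter, sol$residual))
  structure(list(grid = grid, values = sol$phi,
                 iterations = sol$iterations,
                 residual = sol$residual),
            class = "potential_map")
}

#' Grid electrostatic energy
#'
#' `0.5 * sum(q_node * phi_node)` in kcal/mol.  Contains the grid
#' self-energy of the discretized charges; it cancels in the
#' system-minus-reference differences taken downstream.
#'
#' @param phi a `potential_map`.
#' @param rho a `charge_grid` on the same grid.
#' @return energy, kcal/mol.
#' @export
grid_energy <- function(phi, rho) {
  if (!same_grid(phi$grid, rho$grid))
    stop("potential and charge grids differ")
  0.5 * sum(phi$values * rho$rho)
}

# One focused solve of a state: coarse (Debye-Hueckel boundary) then
# fine (boundary interpolated from coarse).  `uniform` runs the
# whole thing at a flat dielectric (vacuum reference), where the
# analytic Coulomb boundary is exact and no focusing is needed.
solve_state_energy <- function(state, grids, params, uniform = NULL) {
  fine <- grids$fine
  rho_f <- spread_charges(state, fine)
  # a degenerate all-equal dielectric needs no focusing: the analytic
  # boundary is exact, and using it keeps the uniform-eps null exact
  if (is.null(uniform) && params$eps_core == params$eps_protein &&
      params$eps_protein == params$eps_solvent)
    uniform <- params$eps_solvent
  if (is.null(uniform)) {
    diel_c <- build_dielectric_map(state, grids$coarse, params)
    rho_c <- spread_charges(state, grids$coarse)
    phi_c <- solve_pb(diel_c, rho_c, params)
    diel_f <- build_dielectric_map(state, fine, params)
    phi_f <- solve_pb(diel_f, rho_f, params, focus_from = phi_c)
  } else {
    diel_f <- build_dielectric_map(state, fine, params,
                                   uniform = uniform)
    phi_f <- solve_pb(diel_f, rho_f, params)
  }
  list(energy = grid_energy(phi_f, rho_f), phi = phi_f, rho = rho_f)
}

#' "Solvation" free energy of a state against its vacuum reference
#'
#' Returns `G_grid(system, three-region eps) - G_grid(reference,
#' uniform eps = 1)` on identical fine-grid geometry, so the grid
#' self-energies of the shared (redox-site) charges cancel.  Here
#' "solvation" is by the rest of the protein plus solvent, not water
#' alone.
#'
#' @param state_in_env parameterized system (site + environment).
#' @param state_reference reference system (site atoms only, same
#'   coordinates).
#' @param params a `pb_params`.
#' @param grids optional precomputed grid pair (must enclose both
#'   systems); defaults to grids sized from `state_in_env`.
#' @return kcal/mol.
#' @export
solvation_energy <- function(state_in_env, state_reference, params,
                             grids = NULL) {
  if (is.null(grids)) grids <- make_grids(state_in_env$atoms, params)
  g_env <- solve_state_energy(state_in_env, grids, params)
  g_ref <- solve_state_energy(state_reference, grids, params,
                              uniform = 1)
  g_env$energy - g_ref$energy
}
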