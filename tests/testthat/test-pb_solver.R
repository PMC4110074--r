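# Solver unit tests run at coarse spacings; the stated-accuracy
# analytic benchmarks live in test-acceptance.R.

test_that("dielectric map classifies Born-ion regions correctly", {
  fx <- make_born_ion(-1, 2)
  p <- pb_params(eps_solvent = 78.54)
  g <- grid_spec(origin = c(-8, -8, -8), spacing = 0.5,
                 dims = c(33, 33, 33))
  d <- build_dielectric_map(fx$system, g, p)
  reg <- array(d$region, dim = g$dims)
  # node inside the sphere -> core; node 50 A away would be solvent,
  # here the corner node (13.9 A off) stands in for "far"
  expect_equal(reg[17, 17, 17], 2)  # centre
  expect_equal(reg[1, 1, 1], 0)     # far corner
  # edge values bounded by the region dielectrics
  expect_true(all(d$ex >= 1 & d$ex <= 78.54))
  # deep-interior and far-field edges hit the pure region values
  expect_equal(max(d$ex), 78.54)
  expect_equal(min(d$ex), 1)
})

test_that("reference (uniform) dielectric map is flat 1", {
  fx <- make_born_ion(-1, 2)
  g <- grid_spec(c(-8, -8, -8), 0.5, c(33, 33, 33))
  d <- build_dielectric_map(fx$system, g, pb_params(), uniform = 1)
  expect_true(all(d$ex == 1) && all(d$ey == 1) && all(d$ez == 1))
})

test_that("atoms outside the grid raise a geometry error", {
  fx <- make_born_ion(-1, 2)
  g <- grid_spec(c(-1, -1, -1), 0.5, c(9, 9, 9))
  expect_error(build_dielectric_map(fx$system, g, pb_params()),
               "geometry error")
})

test_that("charge spreading conserves charge with trilinear weights", {
  g <- grid_spec(c(-4, -4, -4), 0.5, c(17, 17, 17))
  at <- function(x, y, z, q) {
    a <- make_born_ion(q, 0.5)$system
    a$atoms$x <- x; a$atoms$y <- y; a$atoms$z <- z
    a
  }
  # charge exactly on a node: all of it on that node
  rho <- spread_charges(at(0, 0, 0, -1), g)
  expect_equal(sum(rho$rho), -1, tolerance = 1e-12)
  expect_equal(sum(rho$rho != 0), 1)
  expect_equal(min(rho$rho), -1)
  # charge at a cell centre: 1/8 on each of 8 nodes
  rho <- spread_charges(at(0.25, 0.25, 0.25, 1), g)
  expect_equal(sort(rho$rho[rho$rho != 0]), rep(1 / 8, 8),
               tolerance = 1e-12)
  # general position still conserves
  rho <- spread_charges(at(0.13, -0.41, 0.07, 0.37), g)
  expect_equal(sum(rho$rho), 0.37, tolerance = 1e-12)
  # boundary layer is refused
  expect_error(spread_charges(at(-4, 0, 0, 1), g), "boundary")
})

test_that("uniform-dielectric solve reproduces Coulomb's law", {
  sys <- make_born_ion(1, 1)$system
  p <- pb_params(spacing_fine = 0.5, tol = 1e-8)
  g <- grid_spec(c(-12, -12, -12), 0.5, c(49, 49, 49))
  d <- build_dielectric_map(sys, g, p, uniform = 1)
  rho <- spread_charges(sys, g)
  phi <- solve_pb(d, rho, p)
  # phi at 8 A along x: node (40, 24, 24) 0-based
  arr <- array(phi$values, dim = g$dims)
  expect_equal(arr[41, 25, 25], 332.0637 / 8, tolerance = 0.02)
})

test_that("zero charges give the zero potential", {
  sys <- make_born_ion(0, 1)$system
  g <- grid_spec(c(-6, -6, -6), 0.5, c(25, 25, 25))
  p <- pb_params()
  d <- build_dielectric_map(sys, g, p, uniform = 1)
  rho <- spread_charges(sys, g)
  phi <- solve_pb(d, rho, p)
  expect_true(all(phi$values == 0))
  expect_equal(grid_energy(phi, rho), 0)
})

test_that("solutions are linear: doubling charges doubles phi", {
  s1 <- make_born_ion(-1, 2)$system
  s2 <- make_born_ion(-2, 2)$system
  p <- pb_params(spacing_fine = 0.5, tol = 1e-9)
  g <- grid_spec(c(-8, -8, -8), 0.5, c(33, 33, 33))
  d <- build_dielectric_map(s1, g, p)
  phi1 <- solve_pb(d, spread_charges(s1, g), p)
  phi2 <- solve_pb(d, spread_charges(s2, g), p)
  expect_equal(phi2$values, 2 * phi1$values, tolerance = 1e-6)
  # energies scale as q^2
  e1 <- grid_energy(phi1, spread_charges(s1, g))
  e2 <- grid_energy(phi2, spread_charges(s2, g))
  expect_equal(e2 / e1, 4, tolerance = 1e-6)
})

test_that("solvation energy is zero when both legs are uniform eps 1", {
  fx <- make_born_ion(-1, 2)
  p <- pb_params(eps_core = 1, eps_protein = 1, eps_solvent = 1,
                 spacing_fine = 0.5)
  e <- solvation_energy(fx$system, fx$reference, p)
  expect_equal(e, 0, tolerance = 1e-6)
})

test_that("Born error decreases monotonically with focused spacing", {
  fx <- make_born_ion(-1, 2)
  errs <- vapply(c(1.0, 0.5), function(h) {
    p <- pb_params(eps_solvent = 78.54, spacing_fine = h)
    abs(solvation_energy(fx$system, fx$reference, p) - fx$oracle) /
      abs(fx$oracle)
  }, 0)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.02)
})

test_that("shifting the system by one grid spacing is robust", {
  fx <- make_born_ion(-1, 2)
  p <- pb_params(eps_solvent = 78.54, spacing_fine = 0.5)
  e1 <- solvation_energy(fx$system, fx$reference, p)
  s2 <- fx$system
  s2$atoms$x <- s2$atoms$x + p$spacing_fine
  e2 <- solvation_energy(s2, s2, p)
  expect_lt(abs(e1 - e2), 0.1)
})

test_that("mismatched grids are refused", {
  sys <- make_born_ion(-1, 2)$system
  p <- pb_params()
  g1 <- grid_spec(c(-8, -8, -8), 0.5, c(33, 33, 33))
  g2 <- grid_spec(c(-8, -8, -8), 0.4, c(41, 41, 41))
  d <- build_dielectric_map(sys, g1, p)
  rho <- spread_charges(sys, g2)
  expect_error(solve_pb(d, rho, p), "grids differ")
  phi <- solve_pb(d, spread_charges(sys, g1), p)
  expect_error(grid_energy(phi, rho), "grids differ")
})

test_that("OpenDX output round-trips origin/dims and values", {
  g <- grid_spec(c(0, 0, 0), 1, c(3, 3, 3))
  vals <- seq_len(27) / 7
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, vals, path)
  txt <- readLines(path)
  expect_true(any(grepl("counts 3 3 3", txt)))
  nums <- scan(text = txt[grepl("^[0-9.e+-]+ ", txt) &
                            !grepl("object|origin|delta", txt)],
               quiet = TRUE)
  # z-fastest ordering: first value is [1,1,1], second is [1,1,2]
  expect_equal(nums[1], vals[1], tolerance = 1e-6)
  expect_equal(nums[2], vals[1 + 9], tolerance = 1e-6)
  expect_equal(length(nums), 27)
})

test_that("salt term matches the Debye length of 0.1 M water", {
  p <- pb_params(eps_solvent = 78.54, ionic_strength = 0.1)
  kappa <- redoxpot:::debye_kappa(p)
  expect_equal(1 / kappa, 9.63, tolerance = 0.01)
})
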