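test_that("Born fixture carries its analytic oracle", {
  fx <- make_born_ion(-1, 2, eps_solvent = 78.54)
  expect_equal(fx$oracle, -(332.0637 / 4) * (1 - 1 / 78.54))
  expect_equal(nrow(fx$system$atoms), 1)
  expect_equal(fx$system$atoms$charge, -1)
  expect_equal(fx$system$atoms$radius, 2)
  expect_identical(fx$system$roles[[fx$system$atoms$segment_id]],
                   "redox-site")
  expect_error(make_born_ion(-1, 0), "> 0")
})

test_that("zero-charge Born ion has zero solvation energy", {
  fx <- make_born_ion(0, 2)
  e <- solvation_energy(fx$system, fx$reference,
                        pb_params(spacing_fine = 0.5))
  expect_equal(e, 0, tolerance = 1e-9)
  expect_equal(fx$oracle, 0)
})

test_that("Kirkwood series reduces to Born at d = 0", {
  expect_equal(kirkwood_energy(1, 3, 0), born_energy(1, 3))
  expect_equal(kirkwood_energy(-1, 2, 0, eps_out = 40),
               born_energy(-1, 2, 40))
})

test_that("Kirkwood oracle magnitude grows monotonically with d", {
  d <- seq(0, 2.7, by = 0.3)
  vals <- vapply(d, function(x) kirkwood_energy(1, 3, x), 0)
  expect_true(all(diff(abs(vals)) > 0))
  expect_error(make_offcenter_sphere(1, 3, 3), "d < a")
  expect_error(kirkwood_energy(1, 3, -0.1), "d < a")
})

test_that("toy peptide fixture is byte-identical under a seed", {
  f1 <- withr::local_tempfile(fileext = ".pqr")
  f2 <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(make_toy_site_peptide(seed = 4)$system, f1)
  write_pqr(make_toy_site_peptide(seed = 4)$system, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed, different shell
  f3 <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(make_toy_site_peptide(seed = 5)$system, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(make_toy_site_peptide(seed = 4))
  expect_identical(rnorm(1), before)
})

test_that("toy entry validates and matches the site composition", {
  toy <- make_toy_site_peptide(seed = 1)
  expect_s3_class(toy$entry, "redox_entry")
  st <- build_states(toy$system, toy$entry)
  expect_setequal(st$reference_ox$atoms$atom_name,
                  toy$entry$atom_spec$name)
})

test_that("zeroing environment charges reduces to the bare site", {
  p <- pb_params(spacing_fine = 0.7, spacing_coarse = 1.6,
                 fine_margin = 4)
  toy <- make_toy_site_peptide(seed = 9, toggle_charge = 1)
  z <- toy$system
  z$atoms$charge[z$atoms$segment_id == "t-pro"] <- 0
  bare <- toy$system
  bare$atoms <- bare$atoms[bare$atoms$segment_id == "t-bad", ]
  dz <- as.numeric(delta_g_out(build_states(z, toy$entry), p,
                               details = FALSE))
  db <- as.numeric(delta_g_out(build_states(bare, toy$entry), p,
                               details = FALSE))
  # the env atoms still carve eps_protein pockets, so equality is to
  # ~1%, not machine precision
  expect_equal(dz, db, tolerance = 0.01)
})

test_that("synthetic mini-HiPIP builds, partitions and parameterizes", {
  raw <- make_synthetic_hipip()
  expect_true(all(is.na(raw$atoms$charge)))
  expect_equal(sum(raw$atoms$residue_name == "SF4"), 8)
  prep <- prepare_synthetic_hipip()
  expect_true(prep$system$parameterized)
  expect_length(prep$system$site$ligand_residues, 4)
  # all four SG within bonding distance of an Fe
  a <- prep$system$atoms
  fe <- a[startsWith(a$atom_name, "FE"), ]
  sg <- a[a$atom_name == "SG", ]
  for (i in seq_len(nrow(sg))) {
    dmin <- min(sqrt((fe$x - sg$x[i])^2 + (fe$y - sg$y[i])^2 +
                       (fe$z - sg$z[i])^2))
    expect_equal(dmin, 2.3, tolerance = 1e-6)
  }
  # built histidine ring is complete
  his <- a[a$residue_id == 42, ]
  expect_true(all(c("CB", "CG", "ND1", "CD2", "CE1", "NE2") %in%
                    his$atom_name))
})
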