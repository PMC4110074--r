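# Cycle algebra; PB legs run at coarse test spacings on small toys.

toy_pair <- function(...) {
  list(on = make_toy_site_peptide(seed = 11, toggle_charge = 1,
                                  n_env = 8),
       off = make_toy_site_peptide(seed = 11, toggle_charge = 0,
                                   n_env = 8))
}

test_that("reduction_potential implements the sign/unit convention", {
  expect_equal(reduction_potential(0, 0, 0), 0)
  expect_equal(reduction_potential(-23.0605, 0, 0), 1.000)
  expect_equal(reduction_potential(0, -23.0605, 0), 1.000)
  expect_equal(reduction_potential(-11.5, -11.5605, 0), 1.000)
  # n = 2 halves the potential per unit free energy
  expect_equal(reduction_potential(-46.121, 0, 0, n = 2), 1.000)
  expect_error(reduction_potential(Inf, 0, 0), "non-finite")
  expect_error(reduction_potential(0, 0, 0, n = 0))
})

test_that("identical ox/red charge sets give dg_out = 0 exactly", {
  toy <- make_toy_site_peptide(seed = 2, n_env = 8)
  st <- build_states(toy$system, toy$entry)
  st$protein_red <- st$protein_ox
  st$reference_red <- st$reference_ox
  p <- fast_params()
  expect_identical(as.numeric(delta_g_out(st, p, details = FALSE)), 0)
})

test_that("dg_in/dg_she cancel bit-exactly in shifts and contributions", {
  tp <- toy_pair()
  p <- fast_params()
  e1 <- tp$on$entry
  e2 <- e1; e2$dg_in <- 1234.5; e2$dg_she <- -77.7
  s_a <- state_shift(tp$off$system, tp$on$system, e1, p)
  s_b <- state_shift(tp$off$system, tp$on$system, e2, p)
  expect_identical(s_a, s_b)
  c_a <- residue_contribution(tp$on$system, 200, e1, p)
  c_b <- residue_contribution(tp$on$system, 200, e2, p)
  expect_identical(as.numeric(c_a), as.numeric(c_b))
})

test_that("state_shift is antisymmetric and zero on identical systems", {
  tp <- toy_pair()
  p <- fast_params()
  ab <- state_shift(tp$off$system, tp$on$system, tp$on$entry, p)
  ba <- state_shift(tp$on$system, tp$off$system, tp$on$entry, p)
  expect_identical(ab, -ba)
  expect_identical(
    state_shift(tp$on$system, tp$on$system, tp$on$entry, p), 0)
})

test_that("state_shift refuses mismatched couples / missing sites", {
  tp <- toy_pair()
  other <- tp$on$system
  other$site$couple <- c(-2L, -3L)
  expect_error(state_shift(other, tp$on$system, tp$on$entry,
                           fast_params()), "couple")
  bare <- tp$on$system; bare$site <- NULL
  expect_error(state_shift(bare, tp$on$system, tp$on$entry,
                           fast_params()), "redox site")
})

test_that("residue_contribution: zero-charge residue contributes 0 V", {
  toy <- make_toy_site_peptide(seed = 5, n_env = 8)
  sys <- toy$system
  rid <- 101  # first dummy residue
  sys$atoms$charge[sys$atoms$residue_id == rid] <- 0
  v <- residue_contribution(sys, rid, toy$entry, fast_params())
  expect_identical(as.numeric(v), 0)
  expect_false(attr(v, "determinant"))
})

test_that("residue_contribution refuses redox-segment residues", {
  toy <- make_toy_site_peptide(seed = 5, n_env = 8)
  expect_error(residue_contribution(toy$system, 500, toy$entry,
                                    fast_params()),
               "define the couple")
  expect_error(residue_contribution(toy$system, 999, toy$entry,
                                    fast_params()), "not found")
})

test_that("direct shift equals the difference of two full runs", {
  tp <- toy_pair()
  p <- fast_params()
  shift <- state_shift(tp$off$system, tp$on$system, tp$on$entry, p)
  r_on <- redox_potential(tp$on$system, tp$on$entry, p)
  r_off <- redox_potential(tp$off$system, tp$on$entry, p)
  expect_equal(shift, r_on$e0 - r_off$e0, tolerance = 1e-12)
})

test_that("redox_result carries the full cycle and serializes", {
  toy <- make_toy_site_peptide(seed = 3, n_env = 8)
  res <- redox_potential(toy$system, toy$entry, fast_params())
  expect_identical(res$dg_out, res$dg_solv_red - res$dg_solv_ox)
  expect_equal(res$e0,
               -(res$dg_in + res$dg_out + res$dg_she) / 23.0605)
  expect_true(is.finite(res$e0))
  path <- withr::local_tempfile(fileext = ".json")
  write_result(res, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$e0, res$e0)
  expect_equal(back$couple, "1-/2-")
  expect_output(print(res), "E0")
})
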