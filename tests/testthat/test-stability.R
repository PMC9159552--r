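test_that("lattice spectra classify solid, saddle and fluid states", {
  m <- hex_tiling(6)
  s <- hessian_spectrum(m, model_params(p0 = 3.5))
  expect_identical(s$n_trivial_zero, 2L)
  expect_identical(s$n_nontrivial_zero, 0L)
  expect_identical(s$n_negative, 0L)
  expect_gt(s$lowest_nontrivial, 0)
  expect_identical(classify_phase(s), "solid")
  # label robust to the zero tolerance over four decades
  for (zt in c(1e-12, 1e-10, 1e-8)) {
    expect_identical(hessian_spectrum(m, model_params(p0 = 3.5),
                                      zero_tol = zt)$phase, "solid")
  }
  s2 <- suppressWarnings(hessian_spectrum(m, model_params(p0 = 3.80)))
  expect_gt(s2$n_negative, 0L)
  expect_identical(classify_phase(s2), "unstable")
  pr <- model_params(p0 = 3.9)
  r <- prepare_fluid_state(m, pr, seed = 5)
  s3 <- hessian_spectrum(r$mesh, pr, zero_tol = 1e-8)
  expect_gt(s3$n_nontrivial_zero, 0L)
  expect_identical(classify_phase(s3), "fluid")
  # roughly half of all modes are floppy deep in the fluid
  frac <- (s3$n_nontrivial_zero + 2) / length(s3$eigenvalues)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.7)
})

test_that("a non-stationary mesh triggers a warning in the report", {
  m <- perturb_vertices(hex_tiling(4), 0.05, seed = 1)
  expect_warning(hessian_spectrum(m, model_params(p0 = 3.5)), "stationary")
})

test_that("the lowest eigenvalue decreases monotonically with p0", {
  m <- hex_tiling(6)
  lams <- vapply(seq(3.5, 3.75, by = 0.05), function(p0) {
    suppressWarnings(hessian_spectrum(m, model_params(p0 = p0)))$lowest_nontrivial
  }, numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("bisection finds the lattice critical point, shifted by pre-deformation", {
  pc <- find_critical_p0(a = 1, bracket = c(3.6, 3.8), nx = 6, tol = 1e-3)
  expect_equal(pc, p_hex, tolerance = 1e-3)
  pc95 <- find_critical_p0(a = 0.95, bracket = c(3.5, 3.72), nx = 6, tol = 5e-4)
  expect_equal(pc95, critical_p0_predeformed(0.95), tolerance = 1e-3)
  expect_lt(pc95, pc)
  expect_error(find_critical_p0(bracket = c(3.0, 3.2), nx = 4), "bracket")
})

test_that("phase labels agree with the rheological solid/fluid signature", {
  # solid: positive lowest eigenvalue and a nonzero quasistatic G'
  m <- hex_tiling(6)
  pr_s <- model_params(p0 = 3.6)
  expect_identical(hessian_spectrum(m, pr_s)$phase, "solid")
  expect_gt(analytic_shear_quasistatic(pr_s), 0)
  # fluid: nontrivial zero modes and a vanishing static shear stiffness
  pr_f <- model_params(p0 = 3.9)
  r <- prepare_fluid_state(m, pr_f, seed = 5)
  rep <- hessian_spectrum(r$mesh, pr_f, zero_tol = 1e-8)
  expect_identical(rep$phase, "fluid")
  expect_lt(r$energy, 1e-12) # degenerate zero-energy ground states
})
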