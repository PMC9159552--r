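test_that("Euler steps descend the energy and are consistent", {
  pr <- model_params(p0 = 3.65)
  m0 <- hex_tiling(4)
  expect_equal(euler_step(m0, pr, dt = 0.00866)$x, m0$x) # forces vanish
  mp <- perturb_vertices(m0, 0.01, seed = 3)
  e0 <- tissue_energy(mp, pr)
  m1 <- euler_step(mp, pr, dt = 0.00866)
  expect_lt(tissue_energy(m1, pr), e0)
  # two half steps agree with one full step to O(dt^2): the gap shrinks
  # linearly with dt (first-order consistency)
  gap <- function(dt) {
    full <- euler_step(mp, pr, dt = dt)
    half <- euler_step(euler_step(mp, pr, dt = dt / 2), pr, dt = dt / 2)
    max(abs(half$x - full$x))
  }
  expect_lt(gap(0.00866), 0.05 * max(abs(m1$x - mp$x)))
  expect_equal(gap(0.00866) / gap(0.00433), 4, tolerance = 0.2) # ~ dt^2
})

test_that("FIRE finds the hexagonal ground state in the solid phase", {
  pr <- model_params(p0 = 3.6)
  m <- hex_tiling(6)
  r0 <- fire_minimize(m, pr) # already a minimum
  expect_true(r0$converged)
  expect_lt(max(abs(r0$mesh$x - m$x)), 1e-9)
  r <- prepare_fluid_state(m, pr, seed = 3) # kick relaxes back
  expect_true(r$converged)
  si <- cell_geometry(r$mesh)$shape_index
  expect_lt(max(abs(si - p_hex)), 1e-6)
})

test_that("above the transition the lattice is a saddle with many minima", {
  pr <- model_params(p0 = 3.85)
  m <- hex_tiling(6)
  e_hex <- tissue_energy(m, pr)
  r1 <- prepare_fluid_state(m, pr, seed = 3)
  r2 <- prepare_fluid_state(m, pr, seed = 4)
  expect_true(r1$converged && r2$converged)
  expect_lt(r1$energy, e_hex)
  expect_identical(length(r1$mesh$cells), length(m$cells))
  expect_gt(max(abs(r1$mesh$x - r2$mesh$x)), 1e-4) # distinct minima
  # zero kick stays on the (unstable) stationary lattice
  r0 <- prepare_fluid_state(m, pr, sigma = 0, seed = 1)
  expect_lt(max(abs(r0$mesh$x - m$x)), 1e-9)
})

test_that("uniaxial pre-deformation rescales areas and softens the lattice", {
  m <- hex_tiling(4)
  expect_equal(apply_predeformation(m, 1), apply_affine(m, diag(2), update_ref = TRUE))
  md <- apply_predeformation(m, 0.95)
  expect_equal(cell_geometry(md)$area, rep(0.95, length(m$cells)),
               tolerance = 1e-12)
  expect_equal(md$box_ref, md$box)
  pr <- model_params(p0 = 3.70)
  l1 <- suppressWarnings(hessian_spectrum(m, pr))$lowest_nontrivial
  l2 <- suppressWarnings(hessian_spectrum(md, pr))$lowest_nontrivial
  expect_lt(l2, l1) # compression lowers the lowest eigenvalue
})

test_that("the oscillatory driver produces a clean strain channel", {
  m <- hex_tiling(4)
  pr <- model_params(p0 = 3.65)
  proto <- deformation_protocol("shear", omega0 = 1, eps0 = 1e-7,
                                max_blocks = 4)
  s <- run_oscillatory(m, pr, proto)
  expect_true(attr(s, "converged"))
  blen <- proto$samples_per_cycle * proto$cycles_per_block
  amp <- block_fourier(s$strain, s$time, 1, 1, blen)
  expect_lt(abs(Mod(amp) - 1e-7 / 2) / (1e-7 / 2), 1e-3)
  expect_identical(nrow(s) %% proto$samples_per_cycle, 0L)
})

test_that("stress response is linear in the driving amplitude", {
  m <- hex_tiling(6)
  pr <- model_params(p0 = 3.6)
  g <- vapply(c(1e-7, 2e-7, 1e-6), function(e0) {
    s <- run_oscillatory(m, pr, deformation_protocol("shear", omega0 = 1,
                                                     eps0 = e0))
    as.complex(dynamic_modulus(s))
  }, complex(1))
  expect_lt(Mod(g[2] - g[1]) / Mod(g[1]), 1e-3)
  expect_lt(Mod(g[3] - g[1]) / Mod(g[1]), 1e-3)
})

test_that("solid-phase biaxial response is in phase with the drive", {
  m <- hex_tiling(6)
  pr <- model_params(p0 = 3.65)
  s <- run_oscillatory(m, pr, deformation_protocol("biaxial", omega0 = 0.5))
  B <- dynamic_modulus(s)
  expect_lt(abs(Im(B)) / Re(B), 1e-6) # loss bulk modulus is numerically zero
})
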