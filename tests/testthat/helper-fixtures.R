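# Shared fixtures and oracles. Heavier objects are computed once per test run
# and cached, so several test files can reuse the same relaxed states.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small perturbed hexagonal patch, generic positions
fix_perturbed_hex <- function(p0 = 3.65) {
  m <- hex_tiling(4)
  perturb_vertices(m, 0.05, seed = 7)
}

fix_small_disordered <- function() {
  cached("disordered_small", disordered_tiling(n = 24, L = 5, seed = 2))
}

# central finite-difference gradient of the energy (the independent oracle
# for the analytic forces)
fd_forces <- function(mesh, params, h = 1e-6) {
  g <- matrix(0, nrow(mesh$x), 2)
  for (v in seq_len(nrow(mesh$x))) {
    for (c in 1:2) {
      mp <- mesh; mp$x[v, c] <- mp$x[v, c] + h
      mm <- mesh; mm$x[v, c] <- mm$x[v, c] - h
      g[v, c] <- -(tissue_energy(mp, params) - tissue_energy(mm, params)) / (2 * h)
    }
  }
  g
}

# strain-derivative oracle for one stress component
strain_derivative_stress <- function(mesh, params, mode = "shear",
                                     eps = 1e-7) {
  Fmat <- function(e) {
    if (mode == "shear") matrix(c(1, 0, e, 1), 2, 2) else diag(c(1 + e, 1 + e))
  }
  A_box <- abs(det(mesh$box))
  dE <- (tissue_energy(apply_affine(mesh, Fmat(eps)), params) -
           tissue_energy(apply_affine(mesh, Fmat(-eps)), params)) / (2 * eps)
  if (mode == "shear") dE / A_box else dE / (2 * A_box)
}

# build a stress_series object from closed-form channels, for the
# dynamic-modulus fixtures
make_series <- function(omega0, eps0 = 1e-7, spc = 25, cpb = 3, blocks = 4,
                        stress_fun) {
  pr <- deformation_protocol("shear", omega0 = omega0, eps0 = eps0,
                             samples_per_cycle = spc, cycles_per_block = cpb)
  T0 <- 2 * pi / omega0
  t <- seq_len(spc * cpb * blocks) * (T0 / spc)
  strain <- eps0 * sin(omega0 * t)
  sxy <- stress_fun(t)
  structure(
    data.frame(time = t, strain = strain, sxx = 0, sxy = sxy, syy = 0),
    class = c("stress_series", "data.frame"),
    protocol = pr, converged = TRUE, blocks = blocks, t1_events = 0L)
}

p_hex <- sqrt(8 * sqrt(3)) # shape index of the regular hexagon

with_seed <- vertexrheo:::with_seed
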