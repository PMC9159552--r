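test_that("hexagonal tilings have the closed-form counts and geometry", {
  for (nx in 2:8) {
    m <- hex_tiling(nx)
    ny <- 2 * ceiling(nx / 2)
    expect_identical(length(m$cells), as.integer(nx * ny))
    expect_true(all(vapply(m$cells, nrow, integer(1)) == 6L))
    coord <- table(unlist(lapply(m$cells, function(x) x[, 1])))
    expect_true(all(coord == 3L))
    g <- cell_geometry(m)
    expect_equal(g$area, rep(1, nx * ny), tolerance = 1e-12)
    expect_equal(g$shape_index, rep(6 / sqrt(3 * sqrt(3) / 2), nx * ny),
                 tolerance = 1e-12)
    expect_silent(validate_mesh(m))
  }
  # printed study sizes
  expect_identical(length(hex_tiling(15)$cells), 240L)
  expect_identical(length(hex_tiling(37)$cells), 1406L)
  expect_error(hex_tiling(1), "nx")
})

test_that("disordered tilings partition the box and are reproducible", {
  m <- disordered_tiling(n = 200, L = 15, seed = 1)
  expect_identical(length(m$cells), 200L)
  expect_equal(m$meta$a0, 1.125)
  g <- cell_geometry(m)
  expect_equal(mean(g$area), 15^2 / 200, tolerance = 1e-12)
  expect_equal(sum(g$area), 15^2, tolerance = 1e-12)
  expect_silent(validate_mesh(m))
  expect_identical(m, disordered_tiling(n = 200, L = 15, seed = 1))
  m2 <- disordered_tiling(n = 200, L = 15, seed = 2)
  expect_false(isTRUE(all.equal(m$x, m2$x)))
})

test_that("RSA respects the exclusion distance and reports saturation", {
  pts <- rsa_points(50, 10, d_min = 1, seed = 3)
  dx <- abs(outer(pts[, 1], pts[, 1], "-")); dx <- pmin(dx, 10 - dx)
  dy <- abs(outer(pts[, 2], pts[, 2], "-")); dy <- pmin(dy, 10 - dy)
  d <- sqrt(dx^2 + dy^2); diag(d) <- Inf
  expect_true(min(d) >= 1)
  expect_error(rsa_points(200, 5, d_min = 1, seed = 1, max_attempts = 2000),
               "saturated")
})

test_that("vertex perturbation has the right statistics and zero is a no-op", {
  m <- hex_tiling(15) # 480 vertices
  expect_identical(perturb_vertices(m, 0), m)
  sigma <- 1.5e-4
  mp <- perturb_vertices(m, sigma, seed = 5)
  d <- mp$x - m$x
  expect_lt(abs(sd(d) - sigma) / sigma, 0.2)
  mq <- perturb_vertices(m, sigma, seed = 6)
  expect_false(isTRUE(all.equal(mp$x, mq$x)))
  expect_identical(mp$cells, mq$cells)
})

test_that("affine maps scale areas by det(F) and shear preserves them", {
  m <- fix_small_disordered()
  g0 <- cell_geometry(m)
  expect_equal(apply_affine(m, diag(2)), m)
  eps <- 0.05
  g1 <- cell_geometry(apply_affine(m, diag(c(1 + eps, 1 + eps))))
  expect_equal(g1$area, (1 + eps)^2 * g0$area, tolerance = 1e-12)
  g2 <- cell_geometry(apply_affine(m, matrix(c(1, 0, eps, 1), 2, 2)))
  expect_equal(g2$area, g0$area, tolerance = 1e-12)
  expect_error(apply_affine(m, diag(c(-1, 1))), "det")
})

test_that("geometry is invariant under the choice of canonical vertex copy", {
  m <- hex_tiling(4)
  g0 <- cell_geometry(m)
  # move a vertex to a different periodic copy and compensate the offsets
  v <- 5L
  m$x[v, ] <- m$x[v, ] + m$box[, 1]
  m$cells <- lapply(m$cells, function(cl) {
    hit <- cl[, 1] == v
    cl[hit, 2] <- cl[hit, 2] - 1L
    cl
  })
  expect_equal(cell_geometry(m), g0, tolerance = 1e-12)
  expect_silent(validate_mesh(m))
})

test_that("boundary-spanning cells measure the same as their unwrapped copies", {
  m <- disordered_tiling(n = 24, L = 5, seed = 2)
  g <- cell_geometry(m)
  for (ci in seq_along(m$cells)) {
    cl <- m$cells[[ci]]
    p <- m$x[cl[, 1], , drop = FALSE] + cl[, 2:3] %*% t(m$box)
    n <- nrow(p); k1 <- c(2:n, 1)
    area <- sum(p[, 1] * p[k1, 2] - p[k1, 1] * p[, 2]) / 2
    expect_equal(area, g$area[ci], tolerance = 1e-12)
  }
  # at least one cell actually crosses the boundary in this fixture
  crosses <- vapply(m$cells, function(cl) any(cl[, 2:3] != 0L), logical(1))
  expect_true(any(crosses))
})

test_that("mesh JSON and VTK exports round-trip / are well-formed", {
  m <- fix_small_disordered()
  f <- tempfile(fileext = ".json")
  write_mesh_json(m, f)
  m2 <- read_mesh_json(f)
  expect_equal(m2$x, m$x)
  expect_equal(m2$cells, m$cells)
  expect_equal(m2$box, m$box)
  expect_silent(validate_mesh(m2))
  v <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, v)
  lines <- readLines(v)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POLYGONS", lines)))
  expect_true(any(grepl("SCALARS neighbors", lines)))
})
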