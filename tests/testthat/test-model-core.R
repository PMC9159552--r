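test_that("energy matches closed forms on the hexagonal lattice", {
  m <- hex_tiling(4)
  n <- length(m$cells)
  # preferred perimeter equal to the actual hexagon perimeter: E = 0
  p0_hex <- 6 / sqrt(3 * sqrt(3) / 2)
  expect_equal(tissue_energy(m, model_params(p0 = p0_hex)), 0,
               tolerance = 1e-20)
  # Gamma = 0 and all areas at A0: E = 0 regardless of perimeter target
  expect_equal(tissue_energy(m, model_params(p0 = 3.0, gamma_p = 0)), 0,
               tolerance = 1e-20)
  # all cells identical: E = N * (Gamma/2) (P_hex - P0)^2
  pr <- model_params(p0 = 3.65)
  expect_equal(tissue_energy(m, pr),
               n * pr$gamma_p / 2 * (p_hex - 3.65)^2, tolerance = 1e-12)
})

test_that("forces are the exact gradient and vanish on the lattice", {
  pr <- model_params(p0 = 3.65)
  expect_lt(max(abs(tissue_forces(hex_tiling(4), pr))), 1e-12)
  for (mesh in list(fix_perturbed_hex(), fix_small_disordered())) {
    a0 <- if (is.null(mesh$meta$a0)) 1 else mesh$meta$a0
    params <- model_params(p0 = 3.7, a0 = a0, gamma_p = 0.289 * a0)
    F <- tissue_forces(mesh, params)
    expect_lt(max(abs(colSums(F))), 1e-12) # translation invariance
    fd <- fd_forces(mesh, params)
    expect_lt(max(abs(F - fd)) / max(abs(F)), 1e-5)
  }
})

test_that("tissue stress matches the strain-derivative (virial) oracle", {
  for (mesh in list(fix_perturbed_hex(), fix_small_disordered())) {
    a0 <- if (is.null(mesh$meta$a0)) 1 else mesh$meta$a0
    params <- model_params(p0 = 3.6, a0 = a0, gamma_p = 0.289 * a0)
    s <- tissue_stress(mesh, params)
    expect_lt(abs(s[1, 2] - s[2, 1]), 1e-12)
    sxy_fd <- strain_derivative_stress(mesh, params, "shear")
    expect_lt(abs(s[1, 2] - sxy_fd) / abs(sxy_fd), 1e-4)
    hyd_fd <- strain_derivative_stress(mesh, params, "biaxial")
    expect_lt(abs(hydrostatic(s) - hyd_fd) / abs(hyd_fd), 1e-4)
  }
})

test_that("lattice stress is isotropic with residual hydrostatic part", {
  s <- tissue_stress(hex_tiling(4), model_params(p0 = 3.6))
  expect_lt(abs(s[1, 2]), 1e-12)
  expect_lt(abs(s[1, 1] - s[2, 2]), 1e-12)
  expect_gt(abs(hydrostatic(s)), 1e-3) # perimeter mismatch leaves prestress
  # a mesh with A = A0 and P = P0 everywhere is stress-free
  s0 <- tissue_stress(hex_tiling(4), model_params(p0 = p_hex))
  expect_lt(max(abs(s0)), 1e-12)
})

test_that("Hessian matches the force-gradient oracle and has translation nulls", {
  mesh <- fix_perturbed_hex()
  params <- model_params(p0 = 3.7)
  H <- vm_hessian(mesh, params)
  expect_lt(max(abs(H - t(H))), 1e-12)
  nv <- nrow(mesh$x)
  for (tvec in list(rep(c(1, 0), nv), rep(c(0, 1), nv))) {
    expect_lt(max(abs(H %*% tvec)), 1e-10)
  }
  h <- 1e-6
  for (dof in c(3L, 10L)) {
    v <- (dof + 1L) %/% 2L
    cc <- 2L - dof %% 2L
    mp <- mesh; mp$x[v, cc] <- mp$x[v, cc] + h
    mm <- mesh; mm$x[v, cc] <- mm$x[v, cc] - h
    col_fd <- -as.vector(t((tissue_forces(mp, params) -
                              tissue_forces(mm, params)) / (2 * h)))
    expect_lt(max(abs(H[, dof] - col_fd)) / max(abs(col_fd)), 1e-5)
  }
})

test_that("energy and spectrum are invariant under cell relabeling", {
  mesh <- fix_perturbed_hex()
  params <- model_params(p0 = 3.7)
  perm <- with_seed(9, sample(length(mesh$cells)))
  mesh2 <- mesh
  mesh2$cells <- mesh$cells[perm]
  expect_equal(tissue_energy(mesh2, params), tissue_energy(mesh, params))
  expect_equal(tissue_forces(mesh2, params), tissue_forces(mesh, params))
  expect_equal(sort(eigen(vm_hessian(mesh2, params), symmetric = TRUE,
                          only.values = TRUE)$values),
               sort(eigen(vm_hessian(mesh, params), symmetric = TRUE,
                          only.values = TRUE)$values), tolerance = 1e-9)
})

test_that("T1 flips exchange adjacency through the canonical quad fixture", {
  m <- hex_tiling(4)
  et <- vertexrheo:::edge_table(m)
  r1 <- et[1, ]
  i <- r1$v1; j <- r1$v2
  a <- m$box
  evec <- m$x[j, ] - m$x[i, ] +
    c(r1$dm1 * a[1, 1] + r1$dm2 * a[1, 2], r1$dm1 * a[2, 1] + r1$dm2 * a[2, 2])
  len <- sqrt(sum(evec^2)); u <- evec / len
  mid <- m$x[i, ] + u * len / 2
  m$x[i, ] <- mid - u * 0.0025
  m$x[j, ] <- mid + u * 0.0025 -
    c(r1$dm1 * a[1, 1] + r1$dm2 * a[1, 2], r1$dm1 * a[2, 1] + r1$dm2 * a[2, 2])

  et2 <- vertexrheo:::edge_table(m)
  old_cells <- sort(et2$cell[et2$key == et2$key[match(TRUE, et2$v1 == i & et2$v2 == j | et2$v1 == j & et2$v2 == i)]])
  res <- detect_and_apply_t1(m, l_t1 = 0.01)
  expect_identical(nrow(res$events), 1L)
  expect_true(res$events$applied)
  m2 <- res$mesh
  expect_silent(validate_mesh(m2))
  et3 <- vertexrheo:::edge_table(m2)
  k <- which((et3$v1 == i & et3$v2 == j) | (et3$v1 == j & et3$v2 == i))
  new_cells <- sort(unique(et3$cell[k]))
  expect_identical(length(new_cells), 2L)
  expect_identical(length(intersect(new_cells, old_cells)), 0L)
  lens <- vertexrheo:::edge_lengths(m2, et3)
  expect_equal(unique(round(lens[k], 12)), 0.015)
  # side counts: the two former edge-cells lose a side, the gainers add one
  expect_identical(sort(unique(vapply(m2$cells, nrow, integer(1)))), c(5L, 6L, 7L))
})

test_that("T1 detection is a no-op when every junction is long", {
  m <- hex_tiling(3)
  res <- detect_and_apply_t1(m, l_t1 = 0.01)
  expect_identical(nrow(res$events), 0L)
  expect_identical(res$mesh, m)
})
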