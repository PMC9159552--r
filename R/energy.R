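#' Tissue energy
#'
#' Total vertex-model energy: for each cell a quadratic penalty on the area
#' deviation from `A0` (stiffness `K`) plus a quadratic penalty on the
#' perimeter deviation from `P0` (stiffness `Gamma`). Units `K*A0^2`.
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [model_params()].
#' @return Scalar energy.
#' @export
tissue_energy <- function(mesh, params) {
  fl <- mesh_flat(mesh)
  cpp_energy(mesh$x, fl$ptr, fl$cv, mesh$box,
             params$k, params$gamma_p, params$a0, params$P0)
}

#' Vertex forces
#'
#' Exact analytic gradient `F_i = -dE/dr_i` of the tissue energy (shoelace
#' area gradient plus unit-edge-vector perimeter gradient, summed over the
#' cells incident to each vertex). Translation invariance makes the forces
#' sum to zero.
#'
#' @inheritParams tissue_energy
#' @return An `nv x 2` matrix of forces.
#' @export
tissue_forces <- function(mesh, params) {
  fl <- mesh_flat(mesh)
  cpp_forces(mesh$x, fl$ptr, fl$cv, mesh$box,
             params$k, params$gamma_p, params$a0, params$P0)
}

#' Tissue stress tensor
#'
#' Per-cell Cauchy stress `sigma_C = -Pi_C I + (1/2A_C) sum_e T_e (x) l_e`
#' with cell pressure `Pi_C = -K (A_C - A0)` and junction tension
#' `T_e = Gamma (P_C - P0) l_e/|l_e|` (each shared junction contributes to
#' both incident cells with that cell's own tension), averaged with area
#' weights `w_C = A_C / sum(A_C)`. Units `K*A0`.
#'
#' @inheritParams tissue_energy
#' @param per_cell if `TRUE`, also return the per-cell stress components.
#' @return A symmetric 2x2 matrix (attribute `per_cell` optionally holds a
#'   data frame with `sxx`, `sxy`, `syy`, `area` per cell).
#' @export
tissue_stress <- function(mesh, params, per_cell = FALSE) {
  fl <- mesh_flat(mesh)
  s <- cpp_stress(mesh$x, fl$ptr, fl$cv, mesh$box, fl$enb,
                  params$k, params$gamma_p, params$a0, params$P0)
  out <- matrix(c(s[1], s[2], s[2], s[3]), 2, 2)
  if (per_cell) {
    pc <- cpp_cell_stress(mesh$x, fl$ptr, fl$cv, mesh$box, fl$enb,
                          params$k, params$gamma_p, params$a0, params$P0)
    attr(out, "per_cell") <- data.frame(sxx = pc[, 1], sxy = pc[, 2],
                                        syy = pc[, 3], area = pc[, 4])
  }
  out
}

#' Hydrostatic part of a stress tensor
#' @param sigma 2x2 stress tensor.
#' @return `(sigma_xx + sigma_yy)/2`.
#' @export
hydrostatic <- function(sigma) (sigma[1, 1] + sigma[2, 2]) / 2

#' Energy Hessian
#'
#' Analytic second derivatives `d2E/dr_i dr_j` of the tissue energy,
#' assembled per cell (rank-one gradient outer products plus the constant
#' area curvature and the per-junction perimeter curvature), returned as a
#' dense symmetric `2nv x 2nv` matrix with interleaved (x1, y1, x2, y2, ...)
#' ordering. Rigid translations are exact null vectors.
#'
#' @inheritParams tissue_energy
#' @return A symmetric numeric matrix.
#' @export
vm_hessian <- function(mesh, params) {
  fl <- mesh_flat(mesh)
  cpp_hessian(mesh$x, fl$ptr, fl$cv, mesh$box,
              params$k, params$gamma_p, params$a0, params$P0)
}

#' Detect and apply T1 transitions
#'
#' Flips every junction shorter than `l_t1` that joins two 3-fold vertices:
#' the two cells sharing the short junction lose adjacency, the two cells
#' meeting it only at a vertex gain adjacency, and the new junction is placed
#' perpendicular to the old one through its midpoint with length `l_new`.
#' At most one flip per junction per call; a flip that would create a
#' two-sided cell is skipped and logged.
#'
#' @param mesh a [tissue_mesh()].
#' @param l_t1 junction-collapse threshold (default `0.01*sqrt(A0)`-scale).
#' @param l_new length of the reopened junction (default `1.5 * l_t1`).
#' @return A list with the updated `mesh` and a data frame `events`
#'   (columns `v1`, `v2`, `length`, `applied`).
#' @export
detect_and_apply_t1 <- function(mesh, l_t1 = 0.01, l_new = 1.5 * l_t1) {
  stopifnot(l_t1 > 0, l_new > l_t1)
  events <- data.frame(v1 = integer(), v2 = integer(), length = numeric(),
                       applied = logical())
  et <- edge_table(mesh)
  # unfolded edge lengths
  lens <- edge_lengths(mesh, et)
  short <- unique(et$key[lens < l_t1])
  for (key in short) {
    rows <- et[et$key == key, ]
    len <- lens[match(key, et$key)]
    res <- try(t1_flip(mesh, rows, l_new), silent = TRUE)
    ok <- !inherits(res, "try-error")
    if (ok) mesh <- res
    events <- rbind(events, data.frame(v1 = rows$v1[1], v2 = rows$v2[1],
                                       length = len, applied = ok))
    if (ok) { # topology changed; re-derive remaining candidates
      et <- edge_table(mesh)
      lens <- edge_lengths(mesh, et)
    }
  }
  list(mesh = mesh, events = events)
}

edge_lengths <- function(mesh, et = edge_table(mesh)) {
  a <- mesh$box
  ex <- mesh$x[et$v2, 1] - mesh$x[et$v1, 1] + et$dm1 * a[1, 1] + et$dm2 * a[1, 2]
  ey <- mesh$x[et$v2, 2] - mesh$x[et$v1, 2] + et$dm1 * a[2, 1] + et$dm2 * a[2, 2]
  sqrt(ex^2 + ey^2)
}

# Perform one T1 flip given the two edge-table rows of the short junction.
t1_flip <- function(mesh, rows, l_new) {
  stopifnot(nrow(rows) == 2)
  i <- rows$v1[1]; j <- rows$v2[1]
  cellA <- rows$cell[1]; cellB <- rows$cell[2]
  has_i <- vapply(mesh$cells, function(m) i %in% m[, 1], logical(1))
  has_j <- vapply(mesh$cells, function(m) j %in% m[, 1], logical(1))
  cellC <- setdiff(which(has_i), c(cellA, cellB))
  cellD <- setdiff(which(has_j), c(cellA, cellB))
  if (length(cellC) != 1 || length(cellD) != 1) {
    stop("T1 requires two 3-fold vertices")
  }
  if (nrow(mesh$cells[[cellA]]) <= 3 || nrow(mesh$cells[[cellB]]) <= 3) {
    stop("flip would create a two-sided cell")
  }

  unfold <- function(ci) {
    m <- mesh$cells[[ci]]
    mesh$x[m[, 1], , drop = FALSE] + m[, 2:3] %*% t(mesh$box)
  }
  # work in cell A's frame
  mA <- mesh$cells[[cellA]]
  kA <- rows$pos[1]
  pA <- unfold(cellA)
  pi_old <- pA[kA, ]
  kA1 <- if (kA == nrow(mA)) 1L else kA + 1L
  pj_old <- pA[kA1, ]
  mid <- (pi_old + pj_old) / 2
  u <- (pj_old - pi_old) / sqrt(sum((pj_old - pi_old)^2))
  perp <- c(-u[2], u[1])
  centA <- colMeans(pA)
  # vertex i stays with cell A: put it on A's side of the new junction
  if (sum((centA - mid) * perp) < 0) perp <- -perp
  pi_new <- mid + perp * l_new / 2
  pj_new <- mid - perp * l_new / 2

  # move canonical copies by the (small) displacement; offsets stay valid
  off_iA <- mA[kA, 2:3]
  off_jA <- mA[kA1, 2:3]
  mesh$x[i, ] <- pi_new - drop(mesh$box %*% off_iA)
  mesh$x[j, ] <- pj_new - drop(mesh$box %*% off_jA)

  drop_vertex <- function(ci, v) {
    m <- mesh$cells[[ci]]
    m[m[, 1] != v, , drop = FALSE]
  }
  insert_vertex <- function(ci, vnew, vanchor) {
    m <- mesh$cells[[ci]]
    p <- unfold(ci)
    ka <- match(vanchor, m[, 1])
    target <- if (vnew == j) pj_new else pi_new
    anchorA <- if (vanchor == i) pi_new else pj_new
    # translate from cell A's frame into this cell's frame via the anchor
    shift <- p[ka, ] - anchorA
    moff <- round(solve(mesh$box, target + shift - mesh$x[vnew, ]))
    rbind(m, c(vnew, moff))
  }
  mesh$cells[[cellA]] <- drop_vertex(cellA, j)
  mesh$cells[[cellB]] <- drop_vertex(cellB, i)
  mesh$cells[[cellC]] <- insert_vertex(cellC, j, i)
  mesh$cells[[cellD]] <- insert_vertex(cellD, i, j)

  # restore CCW ordering of the four touched cells by angle about the centroid
  for (ci in c(cellA, cellB, cellC, cellD)) {
    m <- mesh$cells[[ci]]
    p <- mesh$x[m[, 1], , drop = FALSE] + m[, 2:3] %*% t(mesh$box)
    cen <- colMeans(p)
    ord <- order(atan2(p[, 2] - cen[2], p[, 1] - cen[1]))
    mesh$cells[[ci]] <- m[ord, , drop = FALSE]
  }
  g <- cell_geometry(mesh)
  if (any(g$area[c(cellA, cellB, cellC, cellD)] <= 0)) {
    stop("flip produced a degenerate cell")
  }
  mesh
}
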