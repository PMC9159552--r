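#' Periodic tissue mesh
#'
#' A `tissue_mesh` represents a confluent polygonal tiling of a deformable
#' periodic box. Vertex positions are stored once (canonical copies); each
#' cell is an ordered, counterclockwise list of incidences `(vertex id, m1,
#' m2)` whose corner sits at `x[v, ] + m1*a1 + m2*a2`, so every polygon can be
#' reconstructed contiguously even when it spans the periodic boundary.
#'
#' @param x numeric matrix (`nv x 2`) of canonical vertex positions.
#' @param cells list of integer matrices (`k x 3`): vertex id (1-based), wrap
#'   offsets `m1`, `m2`, in counterclockwise order.
#' @param box 2x2 matrix whose columns are the box vectors `a1`, `a2`.
#' @param box_ref reference (pre-deformation) box; defaults to `box`.
#' @param meta list of provenance fields (tiling kind, seed, preferred area).
#' @return An object of class `tissue_mesh`.
#' @export
tissue_mesh <- function(x, cells, box, box_ref = box, meta = list()) {
  stopifnot(is.matrix(x), ncol(x) == 2, is.list(cells))
  box <- matrix(as.numeric(box), 2, 2)
  if (box_area(box) <= 0) stop("box area must be positive")
  structure(
    list(x = x, cells = cells, box = box, box_ref = matrix(as.numeric(box_ref), 2, 2),
         meta = meta),
    class = "tissue_mesh"
  )
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %d cells, %d vertices, box area %.4f\n",
              length(x$cells), nrow(x$x), box_area(x$box)))
  if (!is.null(x$meta$kind)) cat("  kind:", x$meta$kind, "\n")
  invisible(x)
}

box_area <- function(box) abs(box[1, 1] * box[2, 2] - box[1, 2] * box[2, 1])

n_cells <- function(mesh) length(mesh$cells)
n_vertices <- function(mesh) nrow(mesh$x)

# Flatten to the 0-based layout shared with the compiled kernels. `enb` maps
# each cv row (the junction from that corner to the next) to the 0-based
# index of the cell on the other side of the junction.
mesh_flat <- function(mesh) {
  nverts <- vapply(mesh$cells, nrow, integer(1))
  cv <- do.call(rbind, mesh$cells)
  storage.mode(cv) <- "integer"
  nrows <- nrow(cv)
  cellidx <- rep(seq_along(nverts), nverts)
  last <- cumsum(nverts)
  first <- c(1L, utils::head(last, -1) + 1L)
  nxt <- seq_len(nrows) + 1L
  nxt[last] <- first
  v1 <- cv[, 1]; v2 <- cv[nxt, 1]
  dm1 <- cv[nxt, 2] - cv[, 2]
  dm2 <- cv[nxt, 3] - cv[, 3]
  swap <- v1 > v2 | (v1 == v2 & (dm1 < 0 | (dm1 == 0 & dm2 < 0)))
  key <- paste(ifelse(swap, v2, v1), ifelse(swap, v1, v2),
               ifelse(swap, -dm1, dm1), ifelse(swap, -dm2, dm2))
  o <- order(key)
  if (nrows %% 2L != 0L) stop("invalid mesh: odd junction count")
  partner <- integer(nrows)
  partner[o[seq(1, nrows, 2)]] <- o[seq(2, nrows, 2)]
  partner[o[seq(2, nrows, 2)]] <- o[seq(1, nrows, 2)]
  cv0 <- cv
  cv0[, 1] <- cv0[, 1] - 1L
  list(ptr = as.integer(c(0L, last)), cv = cv0,
       enb = as.integer(cellidx[partner] - 1L))
}

#' Build a regular hexagonal (honeycomb) tiling
#'
#' Constructs `nx` columns of regular hexagons in the orientation with two
#' vertical junctions per cell (junction vectors proportional to (0,1) and
#' (+-sqrt(3)/2, 1/2)), inside a periodic box. The row count is `nx` rounded
#' up to the next even integer, the choice consistent with cell counts
#' N = 240, 1406 and 2652 at nx = 15, 37 and 51. Every cell has area `a0`
#' exactly.
#'
#' @param nx number of cells in the horizontal direction (>= 2).
#' @param a0 cell area; all lengths come out in units of `sqrt(a0)`.
#' @return A [tissue_mesh()].
#' @export
hex_tiling <- function(nx, a0 = 1) {
  if (!is.numeric(nx) || nx < 2 || nx != round(nx)) {
    stop("nx must be an integer >= 2")
  }
  nx <- as.integer(nx)
  ny <- as.integer(2 * ceiling(nx / 2)) # even row count
  s <- sqrt(2 * a0 / (3 * sqrt(3)))     # junction length for unit cell area a0
  w <- sqrt(3) * s                      # horizontal cell spacing
  h <- 1.5 * s                          # vertical row spacing
  Lx <- nx * w
  Ly <- ny * h
  box <- matrix(c(Lx, 0, 0, Ly), 2, 2)

  # local hexagon corners (pointy-top, two vertical edges), CCW
  hx <- c(w / 2, w / 2, 0, -w / 2, -w / 2, 0)
  hy <- c(-s / 2, s / 2, s, s / 2, -s / 2, -s)

  polys <- vector("list", nx * ny)
  idx <- 1L
  for (j in seq_len(ny) - 1L) {
    xoff <- (j %% 2L) * w / 2
    cy <- j * h + s
    for (i in seq_len(nx) - 1L) {
      cx <- i * w + xoff + w / 2
      polys[[idx]] <- cbind(cx + hx, cy + hy)
      idx <- idx + 1L
    }
  }
  mesh <- polygons_to_mesh(polys, box)
  mesh$meta <- list(kind = "hexagonal", nx = nx, ny = ny, a0 = a0)
  mesh
}

# Assemble a tissue_mesh from unfolded CCW polygons: wrap each corner into the
# box and merge coincident canonical vertices (periodic-aware, tolerance
# `tol` in fractional coordinates) via a grid hash, recording per-incidence
# wrap offsets. The tolerance sits far above clipping round-off (~1e-13) and
# far below any physical vertex separation.
polygons_to_mesh <- function(polys, box, tol = 1e-7) {
  binv <- solve(box)
  gsz <- 1e-3 # grid spacing for the spatial hash (>> tol)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  vfrac <- matrix(NA_real_, 64, 2)
  nvert <- 0L
  cells <- vector("list", length(polys))

  wrap01 <- function(u) u - floor(u)
  lookup <- function(fw) {
    gx <- floor(fw[1] / gsz)
    gy <- floor(fw[2] / gsz)
    ng <- floor(1 / gsz)
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(((gx + dx) %% ng), ((gy + dy) %% ng))
      ids <- grid[[key]]
      for (vid in ids) {
        d1 <- abs(vfrac[vid, 1] - fw[1]); d1 <- min(d1, 1 - d1)
        d2 <- abs(vfrac[vid, 2] - fw[2]); d2 <- min(d2, 1 - d2)
        if (d1 < tol && d2 < tol) return(vid)
      }
    }
    NULL
  }
  insert <- function(fw, vid) {
    key <- paste(floor(fw[1] / gsz), floor(fw[2] / gsz))
    grid[[key]] <- c(grid[[key]], vid)
  }

  for (ci in seq_along(polys)) {
    p <- polys[[ci]]
    fr <- t(binv %*% t(p)) # fractional coordinates, unfolded
    inc <- matrix(0L, nrow(p), 3)
    for (k in seq_len(nrow(p))) {
      fw <- wrap01(fr[k, ])
      vid <- lookup(fw)
      if (is.null(vid)) {
        nvert <- nvert + 1L
        if (nvert > nrow(vfrac)) {
          vfrac <- rbind(vfrac, matrix(NA_real_, nrow(vfrac), 2))
        }
        vfrac[nvert, ] <- fw
        vid <- nvert
        insert(fw, vid)
      }
      # wrap offset: canonical + m * a = unfolded (periodic-aware difference)
      m <- round(fr[k, ] - vfrac[vid, ])
      inc[k, ] <- as.integer(c(vid, m[1], m[2]))
    }
    cells[[ci]] <- inc
  }
  x <- t(box %*% t(vfrac[seq_len(nvert), , drop = FALSE]))
  tissue_mesh(x = x, cells = cells, box = box)
}

#' Per-cell geometry
#'
#' Area (shoelace formula on the wrap-reconstructed polygon), perimeter, and
#' shape index `P/sqrt(A)` for one cell or all cells.
#'
#' @param mesh a [tissue_mesh()].
#' @param cell cell index, or `NULL` for all cells.
#' @return For a single cell, a list with `area`, `perimeter`, `shape_index`;
#'   otherwise a data frame with one row per cell.
#' @export
cell_geometry <- function(mesh, cell = NULL) {
  fl <- mesh_flat(mesh)
  g <- cpp_cell_geometry(mesh$x, fl$ptr, fl$cv, mesh$box)
  if (any(g$area <= 0)) stop("degenerate geometry: non-positive cell area")
  si <- g$perimeter / sqrt(g$area)
  if (is.null(cell)) {
    return(data.frame(area = g$area, perimeter = g$perimeter, shape_index = si))
  }
  stopifnot(cell >= 1, cell <= n_cells(mesh))
  list(area = g$area[cell], perimeter = g$perimeter[cell], shape_index = si[cell])
}

#' Apply an affine deformation
#'
#' Maps vertex positions and box vectors by a 2x2 deformation gradient `F`
#' (each position r becomes `F r`, each box vector `a_k` becomes `F a_k`);
#' wrap offsets are unchanged, so periodic
#' images deform consistently with the box.
#'
#' @param mesh a [tissue_mesh()].
#' @param F 2x2 deformation gradient with positive determinant.
#' @param update_ref if `TRUE`, the reference box is also mapped (used by
#'   pre-deformation, where subsequent strain is measured about the new state).
#' @return The deformed [tissue_mesh()].
#' @export
apply_affine <- function(mesh, F, update_ref = FALSE) {
  F <- matrix(as.numeric(F), 2, 2)
  if (det(F) <= 0) stop("invalid deformation: det(F) must be positive")
  mesh$x <- t(F %*% t(mesh$x))
  mesh$box <- F %*% mesh$box
  if (update_ref) mesh$box_ref <- mesh$box
  mesh
}

#' Gaussian vertex perturbation
#'
#' Displaces every vertex independently by zero-mean Gaussian noise of
#' standard deviation `sigma` in x and y; topology is unchanged. This is the
#' kick used to take a lattice off an unstable stationary state before energy
#' minimization.
#'
#' @param mesh a [tissue_mesh()].
#' @param sigma displacement standard deviation (length units).
#' @param seed integer seed for reproducibility.
#' @return The perturbed [tissue_mesh()].
#' @export
perturb_vertices <- function(mesh, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mesh)
  nv <- n_vertices(mesh)
  d <- with_seed(seed, matrix(stats::rnorm(2 * nv, sd = sigma), nv, 2))
  mesh$x <- mesh$x + d
  mesh
}

# Evaluate seeded expressions without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Validate mesh invariants
#'
#' Checks the structural contract of a periodic tiling: positive cell areas,
#' every junction shared by exactly two cells with opposite orientation,
#' vertex coordination at least 3, the Euler relation on the torus
#' (Nv - Ne + Nc = 0), and that cell areas partition the box area.
#'
#' @param mesh a [tissue_mesh()].
#' @param tol relative tolerance for the area partition check.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_mesh <- function(mesh, tol = 1e-8) {
  g <- cell_geometry(mesh)
  if (any(g$area <= 0)) stop("cell with non-positive area")
  ek <- edge_table(mesh)
  tab <- table(ek$key)
  if (any(tab != 2)) stop("junction not shared by exactly two cells")
  dir_tab <- table(ek$dkey)
  if (any(dir_tab != 1)) stop("junction traversed twice in the same direction")
  coord <- table(unlist(lapply(mesh$cells, function(m) m[, 1])))
  if (any(coord < 3)) stop("vertex with coordination < 3")
  nvv <- n_vertices(mesh)
  nee <- length(tab)
  ncc <- n_cells(mesh)
  if (nvv - nee + ncc != 0) stop("Euler relation Nv - Ne + Nc = 0 violated")
  if (abs(sum(g$area) - box_area(mesh$box)) > tol * box_area(mesh$box)) {
    stop("cell areas do not partition the box area")
  }
  invisible(TRUE)
}

# Undirected/directed junction keys: endpoints plus relative wrap offset, so
# boundary-crossing junctions match their partner in the neighbouring cell.
edge_table <- function(mesh) {
  nverts <- vapply(mesh$cells, nrow, integer(1))
  cv <- do.call(rbind, mesh$cells)
  cellidx <- rep(seq_along(nverts), nverts)
  last <- cumsum(nverts)
  first <- c(1L, utils::head(last, -1) + 1L)
  nxt <- seq_len(nrow(cv)) + 1L
  nxt[last] <- first
  v1 <- cv[, 1]; v2 <- cv[nxt, 1]
  dm1 <- cv[nxt, 2] - cv[, 2]
  dm2 <- cv[nxt, 3] - cv[, 3]
  swap <- v1 > v2 | (v1 == v2 & (dm1 < 0 | (dm1 == 0 & dm2 < 0)))
  key <- ifelse(swap,
                paste(v2, v1, -dm1, -dm2),
                paste(v1, v2, dm1, dm2))
  data.frame(cell = cellidx, v1 = v1, v2 = v2, dm1 = dm1, dm2 = dm2,
             key = key, dkey = paste(v1, v2, dm1, dm2),
             pos = sequence(nverts))
}
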