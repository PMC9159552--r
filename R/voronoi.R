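#' Random sequential addition of seed points
#'
#' Places `n` points uniformly in the periodic square `[0, L)^2`, rejecting
#' candidates closer than `d_min` (minimum-image distance) to any accepted
#' point. Insertion order is fixed by the draw order, so a given seed yields
#' a byte-identical point set.
#'
#' @param n number of points.
#' @param L box side.
#' @param d_min hard-core exclusion distance.
#' @param seed RNG seed.
#' @param max_attempts total draw budget before reporting saturation.
#' @return An `n x 2` matrix of points.
#' @export
rsa_points <- function(n, L, d_min, seed = 1L, max_attempts = 1e6) {
  stopifnot(n >= 1, L > 0, d_min >= 0)
  with_seed(seed, {
    pts <- matrix(NA_real_, n, 2)
    placed <- 0L
    attempts <- 0L
    d2 <- d_min^2
    while (placed < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- stats::runif(2, 0, L)
      ok <- TRUE
      if (placed > 0L) {
        dx <- abs(pts[seq_len(placed), 1] - cand[1])
        dy <- abs(pts[seq_len(placed), 2] - cand[2])
        dx <- pmin(dx, L - dx)
        dy <- pmin(dy, L - dy)
        ok <- all(dx * dx + dy * dy >= d2)
      }
      if (ok) {
        placed <- placed + 1L
        pts[placed, ] <- cand
      }
    }
    if (placed < n) {
      stop(sprintf("RSA saturated: placed %d of %d points within %g attempts",
                   placed, n, max_attempts))
    }
    pts
  })
}

# Voronoi cell of seeds[i, ] among the 3x3 periodic images, by successive
# half-plane (perpendicular-bisector) clipping of a bounding square. Exact
# construction of the periodic Voronoi polygon for well-separated seeds.
voronoi_cell_clip <- function(i, seeds, L, reach) {
  p <- seeds[i, ]
  offs <- as.matrix(expand.grid(mx = -1:1, my = -1:1))
  nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
    sweep(seeds, 2, -c(offs[k, 1] * L, offs[k, 2] * L))
  }))
  d2 <- (nb[, 1] - p[1])^2 + (nb[, 2] - p[2])^2
  nb <- nb[d2 > 1e-18 & d2 < (2 * reach)^2, , drop = FALSE]
  nb <- nb[order((nb[, 1] - p[1])^2 + (nb[, 2] - p[2])^2), , drop = FALSE]
  # CCW bounding square around the seed
  poly <- cbind(p[1] + c(-reach, reach, reach, -reach),
                p[2] + c(-reach, -reach, reach, reach))
  for (k in seq_len(nrow(nb))) {
    q <- nb[k, ]
    mid <- (p + q) / 2
    nrm <- q - p # keep half-plane (x - mid) . nrm <= 0
    keepv <- (poly[, 1] - mid[1]) * nrm[1] + (poly[, 2] - mid[2]) * nrm[2]
    if (all(keepv <= 0)) next
    poly <- clip_halfplane(poly, keepv)
    if (nrow(poly) < 3) stop("Voronoi cell clipped away; seeds too close")
  }
  poly
}

# Sutherland-Hodgman step for one half-plane; `keepv` is the signed distance
# (negative = kept) of each polygon vertex.
clip_halfplane <- function(poly, keepv) {
  n <- nrow(poly)
  out <- matrix(NA_real_, n + 4, 2)
  m <- 0L
  for (k in seq_len(n)) {
    k1 <- if (k == n) 1L else k + 1L
    a_in <- keepv[k] <= 0
    b_in <- keepv[k1] <= 0
    if (a_in) {
      m <- m + 1L
      out[m, ] <- poly[k, ]
    }
    if (xor(a_in, b_in)) {
      t <- keepv[k] / (keepv[k] - keepv[k1])
      m <- m + 1L
      out[m, ] <- poly[k, ] + t * (poly[k1, ] - poly[k, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

#' Build a disordered periodic tiling
#'
#' Seeds `n` points by random sequential addition in a periodic square box of
#' side `L`, builds the periodic Voronoi tessellation (from the 3x3 periodic
#' images, folded back to one periodic copy), and returns it as a
#' [tissue_mesh()]. The natural preferred cell area for this construction is
#' `L^2/n`, stored in `meta$a0`.
#'
#' @param n number of cells (>= 4).
#' @param L box side.
#' @param d_min RSA exclusion distance; default `0.5 * sqrt(L^2/n)`.
#' @param seed RNG seed.
#' @param max_attempts RSA draw budget.
#' @return A [tissue_mesh()] with `n` cells.
#' @export
disordered_tiling <- function(n = 200, L = 15, d_min = 0.5 * sqrt(L^2 / n),
                              seed = 1L, max_attempts = 1e6) {
  stopifnot(n >= 4)
  seeds <- rsa_points(n, L, d_min, seed = seed, max_attempts = max_attempts)
  reach <- 4 * L / sqrt(n)
  repeat {
    polys <- lapply(seq_len(n), voronoi_cell_clip, seeds = seeds, L = L,
                    reach = reach)
    # every Voronoi vertex must lie well inside the clipping square,
    # otherwise the reach was too small and the cell is truncated
    maxr <- max(vapply(seq_len(n), function(i) {
      max(abs(sweep(polys[[i]], 2, seeds[i, ])))
    }, numeric(1)))
    if (maxr < 0.95 * reach) break
    reach <- 2 * reach
  }
  box <- matrix(c(L, 0, 0, L), 2, 2)
  mesh <- polygons_to_mesh(polys, box)
  mesh$meta <- list(kind = "disordered", n = n, L = L, d_min = d_min,
                    seed = as.integer(seed), a0 = L^2 / n)
  mesh
}
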