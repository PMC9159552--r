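#' Write a mesh snapshot as legacy VTK PolyData
#'
#' Exports the tiling as an ASCII VTK polygon soup (each cell's corners
#' unfolded across the periodic boundary, so polygons render contiguously)
#' with a `neighbors` cell scalar carrying each cell's side count.
#'
#' @param mesh a [tissue_mesh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  pts <- list()
  polys <- character(length(mesh$cells))
  npt <- 0L
  for (ci in seq_along(mesh$cells)) {
    m <- mesh$cells[[ci]]
    p <- mesh$x[m[, 1], , drop = FALSE] + m[, 2:3] %*% t(mesh$box)
    n <- nrow(p)
    pts[[ci]] <- p
    polys[ci] <- paste(c(n, npt + seq_len(n) - 1L), collapse = " ")
    npt <- npt + n
  }
  allp <- do.call(rbind, pts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tissue mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", npt)), con)
  writeLines(sprintf("%.10g %.10g 0", allp[, 1], allp[, 2]), con)
  nsides <- vapply(mesh$cells, nrow, integer(1))
  writeLines(sprintf("POLYGONS %d %d", length(polys),
                     length(polys) + sum(nsides)), con)
  writeLines(polys, con)
  writeLines(c(sprintf("CELL_DATA %d", length(polys)),
               "SCALARS neighbors int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(nsides), con)
  invisible(path)
}

#' Save / load a mesh as JSON
#'
#' Round-trippable plain-text serialization: canonical vertex positions,
#' cells with wrap offsets, box and reference box vectors, metadata.
#'
#' @param mesh a [tissue_mesh()].
#' @param path file path.
#' @return `write_mesh_json()`: `path` invisibly; `read_mesh_json()`: the
#'   [tissue_mesh()].
#' @export
write_mesh_json <- function(mesh, path) {
  obj <- list(
    x = unname(mesh$x),
    cells = lapply(mesh$cells, unname),
    box = unname(mesh$box),
    box_ref = unname(mesh$box_ref),
    meta = mesh$meta
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells_raw <- obj$cells
  if (is.array(cells_raw) && length(dim(cells_raw)) == 3) {
    # cells of equal size get simplified to one nc x k x 3 array
    cells <- lapply(seq_len(dim(cells_raw)[1]), function(i) {
      matrix(as.integer(cells_raw[i, , ]), ncol = 3)
    })
  } else {
    cells <- lapply(cells_raw, function(m) matrix(as.integer(as.matrix(m)),
                                                  ncol = 3))
  }
  mesh <- tissue_mesh(x = matrix(as.numeric(obj$x), ncol = 2), cells = cells,
                      box = matrix(as.numeric(obj$box), 2, 2),
                      box_ref = matrix(as.numeric(obj$box_ref), 2, 2),
                      meta = as.list(obj$meta))
  mesh
}

#' Write / read a stress time series as CSV (+ JSON metadata)
#'
#' @param series a `stress_series` from [run_oscillatory()].
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stress_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  pr <- attr(series, "protocol")
  meta <- list(protocol = unclass(pr),
               converged = attr(series, "converged"),
               blocks = attr(series, "blocks"),
               t1_events = attr(series, "t1_events"),
               dt = attr(series, "dt"))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write / read a modulus curve as CSV (+ JSON metadata)
#'
#' @param curve a [modulus_curve()].
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `write_modulus_curve()`: `path` invisibly; `read_modulus_curve()`:
#'   the [modulus_curve()].
#' @export
write_modulus_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  meta <- list(mode = attr(curve, "mode"), meta = attr(curve, "meta"))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_modulus_curve
#' @export
read_modulus_curve <- function(path) {
  d <- utils::read.csv(path)
  meta <- list(mode = "shear", meta = list())
  mj <- paste0(path, ".json")
  if (file.exists(mj)) meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
  modulus_curve(d$omega, complex(real = d$storage, imaginary = d$loss),
                converged = d$converged, blocks = as.integer(d$blocks),
                mode = meta$mode, meta = as.list(meta$meta))
}
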