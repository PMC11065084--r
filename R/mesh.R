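#' Structured hexahedral mesh of the quarter skin block
#'
#' Builds a structured grid of 8-node hexahedra over the quarter model of the
#' skin block. The full block is twice the quarter in both in-plane
#' directions; the two mirror symmetry planes of the rectangular expander are
#' the faces `x = 0` and `y = 0`. Default quarter extents are
#' 50 x 37.5 x 3 mm with the skin surface at `z = dims[3]`.
#'
#' @param nx,ny,nz Element counts along x, y, z; all >= 1.
#' @param dims Quarter-block extents in mm, `c(Lx, Ly, Lz)`.
#' @return An object of class `skin_mesh`: list with `nodes` (n x 3 reference
#'   coordinates, mm), `hexes` (e x 8 connectivity, 1-based), node-set
#'   indices for the symmetry faces (`sym_x`, `sym_y`), the outer lateral
#'   faces (`outer_x`, `outer_y`), `bottom` and `top` faces, `top_quads`
#'   (top-surface connectivity) and `top_elems` (indices of the top layer of
#'   elements with their in-plane element centroids).
#' @examples
#' m <- build_quarter_mesh(20, 15, 3)
#' nrow(m$hexes)  # 900
#' @export
build_quarter_mesh <- function(nx = 20L, ny = 15L, nz = 3L,
                               dims = c(50, 37.5, 3)) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 1L)) stop("element counts must be >= 1")
  stopifnot(length(dims) == 3L, all(dims > 0))
  xs <- seq(0, dims[1], length.out = nx + 1L)
  ys <- seq(0, dims[2], length.out = ny + 1L)
  zs <- seq(0, dims[3], length.out = nz + 1L)
  # node numbering: x fastest, then y, then z
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) (k - 1L) * (nx + 1L) * (ny + 1L) +
    (j - 1L) * (nx + 1L) + i
  ne <- nx * ny * nz
  hexes <- matrix(0L, ne, 8L)
  el <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    el <- el + 1L
    hexes[el, ] <- c(nid(i, j, k), nid(i + 1L, j, k),
                     nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                     nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                     nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  }
  tolxyz <- 1e-9 * max(dims)
  sym_x <- which(abs(nodes[, 1]) < tolxyz)
  sym_y <- which(abs(nodes[, 2]) < tolxyz)
  outer_x <- which(abs(nodes[, 1] - dims[1]) < tolxyz)
  outer_y <- which(abs(nodes[, 2] - dims[2]) < tolxyz)
  bottom <- which(abs(nodes[, 3]) < tolxyz)
  top <- which(abs(nodes[, 3] - dims[3]) < tolxyz)
  # top-surface quads and the top element layer (for growth post-processing)
  ntq <- nx * ny
  top_quads <- matrix(0L, ntq, 4L)
  q <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    q <- q + 1L
    top_quads[q, ] <- c(nid(i, j, nz + 1L), nid(i + 1L, j, nz + 1L),
                        nid(i + 1L, j + 1L, nz + 1L), nid(i, j + 1L, nz + 1L))
  }
  top_layer <- (nx * ny * (nz - 1L) + 1L):(nx * ny * nz)
  dx <- dims[1] / nx; dy <- dims[2] / ny
  cx <- rep((seq_len(nx) - 0.5) * dx, times = ny)
  cy <- rep((seq_len(ny) - 0.5) * dy, each = nx)
  structure(list(
    nodes = nodes, hexes = hexes, dims = dims,
    nx = nx, ny = ny, nz = nz,
    sym_x = sym_x, sym_y = sym_y, outer_x = outer_x, outer_y = outer_y,
    bottom = bottom, top = top,
    top_quads = top_quads,
    top_elems = data.frame(elem = top_layer, cx = cx, cy = cy,
                           area = dx * dy)
  ), class = "skin_mesh")
}

#' @export
print.skin_mesh <- function(x, ...) {
  cat(sprintf("Quarter skin block mesh: %g x %g x %g mm, %d x %d x %d hexes (%d nodes)\n",
              x$dims[1], x$dims[2], x$dims[3], x$nx, x$ny, x$nz,
              nrow(x$nodes)))
  invisible(x)
}

# dof index helper: 3 dofs per node, x-fastest
.dof <- function(node, comp) 3L * (node - 1L) + comp

#' Export a mesh and nodal/element fields as legacy ASCII VTK
#'
#' Writes an unstructured-grid VTK file (plain text) with the deformed
#' coordinates and optional point/cell data, for inspection in ParaView.
#'
#' @param mesh A [build_quarter_mesh()] mesh.
#' @param path Output file path.
#' @param displacement Optional length `3 * n_nodes` displacement vector (mm).
#' @param cell_data Optional named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, displacement = NULL, cell_data = NULL) {
  stopifnot(inherits(mesh, "skin_mesh"))
  nn <- nrow(mesh$nodes)
  coords <- mesh$nodes
  if (!is.null(displacement)) {
    stopifnot(length(displacement) == 3L * nn)
    coords <- coords + matrix(displacement, ncol = 3L, byrow = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "skinwave quarter skin block", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(format(coords, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  ne <- nrow(mesh$hexes)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9L), con)
  utils::write.table(cbind(8L, mesh$hexes - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  if (!is.null(displacement)) {
    writeLines(c(sprintf("POINT_DATA %d", nn),
                 "VECTORS displacement double"), con)
    utils::write.table(format(matrix(displacement, ncol = 3L, byrow = TRUE),
                              digits = 10, scientific = TRUE, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(cell_data) && length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 10, trim = TRUE), con)
    }
  }
  invisible(path)
}
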