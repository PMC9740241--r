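# Kuhn 6-tetrahedron decomposition of the unit cube.  Vertices are numbered
# 1..8 by binary (x, y, z) offsets; every tet contains the main diagonal
# 1-8, so shared cube faces are split along matching diagonals and the
# triangulation is conforming across neighbouring cubes.
kuhn_corner_offsets <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))

kuhn_tets <- rbind(
  c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
  c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))

#' Convert an aligned femur mask into a tetrahedral mesh
#'
#' Structured meshing: the mask is optionally coarsened by an integer factor
#' (chosen from `target_edge_mm`), each retained cell becomes a hexahedron
#' split into 6 tetrahedra (Kuhn decomposition, conforming and volume-exact),
#' and each element receives the calcium-equivalent density sampled
#' trilinearly at its centroid, clamped at zero.
#'
#' @param aligned an `aligned_femur` from [align_and_crop()], or a list with
#'   `mask` and `volume` entries on a common grid.
#' @param target_edge_mm requested cell edge length; the actual factor is
#'   `round(target_edge_mm / spacing)` per axis, at least 1.
#' @param min_fill fraction of in-mask fine voxels required to keep a coarse
#'   cell (default 0.5).
#' @return a `tet_mesh`: list of `nodes` (n x 3 mm), `elements` (m x 4,
#'   1-based), `element_density_mg_cm3`, `cell_mm` (cell edge lengths).
#' @export
voxels_to_tets <- function(aligned, target_edge_mm = NULL, min_fill = 0.5) {
  mask <- aligned$mask
  vol <- aligned$volume
  if (!any(mask$voxels)) stop("empty mask: nothing to mesh")
  sp <- mask$spacing
  f <- if (is.null(target_edge_mm)) c(1L, 1L, 1L)
       else pmax(1L, as.integer(round(target_edge_mm / sp)))
  d <- dim(mask$voxels)
  nc <- as.integer(ceiling(d / f))
  # mean mask occupancy per coarse cell
  fill <- coarse_cell_means(mask$voxels * 1.0, f, nc)
  keep <- which(fill >= min_fill, arr.ind = TRUE)
  if (nrow(keep) == 0) stop("empty mask: no cell reaches the fill fraction")
  cell_mm <- sp * f
  # node lattice: corner (i,j,k) of cell (I,J,K) has lattice coords I-1..I
  nxn <- nc + 1L
  node_id <- array(0L, dim = nxn)
  corn <- kuhn_corner_offsets
  corner_idx <- do.call(rbind, lapply(seq_len(8), function(c8) {
    cbind(keep[, 1] + corn[c8, 1], keep[, 2] + corn[c8, 2],
          keep[, 3] + corn[c8, 3])
  }))
  lin <- (corner_idx[, 3] - 1) * nxn[1] * nxn[2] +
    (corner_idx[, 2] - 1) * nxn[1] + corner_idx[, 1]
  used <- sort(unique(lin))
  node_id[used] <- seq_along(used)
  # lattice coords of used nodes -> world coordinates (cell corners sit on
  # voxel boundaries: lattice l corresponds to 0-based fine index l*f - 0.5)
  uk <- (used - 1) %/% (nxn[1] * nxn[2])
  rem <- (used - 1) %% (nxn[1] * nxn[2])
  uj <- rem %/% nxn[1]
  ui <- rem %% nxn[1]
  frac_idx <- cbind(ui * f[1] + 0.5, uj * f[2] + 0.5, uk * f[3] + 0.5)
  nodes <- voxel_to_world(mask, frac_idx)
  # elements: 6 tets per kept cell
  cell_nodes <- matrix(node_id[lin], nrow = nrow(keep), ncol = 8)
  elements <- do.call(rbind, lapply(seq_len(6), function(t6) {
    cell_nodes[, kuhn_tets[t6, ], drop = FALSE]
  }))
  # enforce positive orientation (identical geometry in every cell, so one
  # parity check per tet template suffices, applied uniformly)
  g <- tet_grads_cpp(nodes, elements)
  neg <- g$vols < 0
  if (any(neg)) {
    elements[neg, c(3, 4)] <- elements[neg, c(4, 3)]
    g <- tet_grads_cpp(nodes, elements)
  }
  if (any(g$vols <= 0)) stop("degenerate (zero-volume) element produced")
  centroids <- (nodes[elements[, 1], ] + nodes[elements[, 2], ] +
                nodes[elements[, 3], ] + nodes[elements[, 4], ]) / 4
  dens <- pmax(0, sample_trilinear(vol, centroids, fill = 0))
  structure(list(nodes = nodes, elements = elements,
                 element_density_mg_cm3 = dens, cell_mm = cell_mm,
                 volumes_mm3 = g$vols),
            class = "tet_mesh")
}

coarse_cell_means <- function(arr, f, nc) {
  # block mean over f-sized cells; trailing partial blocks are zero-padded
  a <- array(0, dim = nc * f)
  a[seq_len(dim(arr)[1]), seq_len(dim(arr)[2]), seq_len(dim(arr)[3])] <- arr
  dim(a) <- c(f[1], nc[1], f[2], nc[2], f[3], nc[3])
  apply(a, c(2, 4, 6), mean)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tetrahedra, total volume %.1f mm^3\n",
              nrow(x$nodes), nrow(x$elements), sum(x$volumes_mm3)))
  invisible(x)
}

#' Total mesh volume
#' @param mesh a `tet_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume_mm3 <- function(mesh) sum(mesh$volumes_mm3)

#' Boundary faces of a tetrahedral mesh
#'
#' @param mesh a `tet_mesh`.
#' @return integer matrix (k x 3) of node indices of faces belonging to
#'   exactly one element.
#' @export
surface_faces <- function(mesh) {
  el <- mesh$elements
  faces <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)],
                 el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  key <- face_keys(faces, nrow(mesh$nodes))
  shared <- duplicated(key) | duplicated(key, fromLast = TRUE)
  faces[!shared, , drop = FALSE]
}

# order-independent numeric key per triangular face (exact for < 2^17 nodes)
face_keys <- function(faces, n_nodes) {
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  K <- as.numeric(n_nodes) + 1
  (as.numeric(lo) * K + mid) * K + hi
}

#' Export a mesh as legacy ASCII VTK
#'
#' Writes an unstructured-grid file with per-element scalar fields.
#'
#' @param mesh a `tet_mesh`.
#' @param path output path (".vtk").
#' @param cell_data named list of per-element numeric vectors; the element
#'   densities are always included.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0", "tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  utils::write.table(format(mesh$nodes, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elements - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  cell_data <- c(list(density_mg_cm3 = mesh$element_density_mg_cm3),
                 cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(cell_data[[nm]], trim = TRUE), con)
  }
  invisible(path)
}
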