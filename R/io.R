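#' Write a triangle mesh as ASCII STL
#'
#' @param mesh A `tri_mesh`.
#' @param path Output path.
#' @param name Solid name.
#' @return `path` invisibly.
#' @export
write_stl <- function(mesh, path, name = "bill") {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (t in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                       nx[t] / nn[t], ny[t] / nn[t], nz[t] / nn[t]), con)
    writeLines("    outer loop", con)
    for (c in 1:3)
      writeLines(sprintf("      vertex %.9g %.9g %.9g",
                         v[f[t, c], 1], v[f[t, c], 2], v[f[t, c], 3]), con)
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Write a triangle mesh or point set as ASCII PLY
#'
#' @param mesh A `tri_mesh`, or a bare matrix of points (point cloud).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_ply <- function(mesh, path) {
  if (is.matrix(mesh)) mesh <- list(vertices = mesh, faces = NULL)
  v <- mesh$vertices
  nf <- if (is.null(mesh$faces)) 0L else nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(v, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (nf > 0L)
    utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tetrahedral mesh as legacy ASCII VTK
#'
#' Emits the corner connectivity (VTK_TETRA) with the `region` cell-data
#' field (1 = shell, 2 = core) and optional per-element scalar fields (e.g.
#' von Mises stress) for visualization.
#'
#' @param mesh A `tet_mesh`.
#' @param path Output path.
#' @param cell_data Optional named list of per-element numeric vectors.
#' @return `path` invisibly.
#' @export
write_vtk_tet <- function(mesh, path, cell_data = list()) {
  nodes <- mesh$nodes; el <- mesh$elems[, 1:4, drop = FALSE]
  m <- nrow(el)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tetrahedral bill mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nodes))), con)
  utils::write.table(format(nodes, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, el - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  fields <- c(list(region = as.numeric(mesh$region %||% rep(2, m))),
              cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(fields[[nm]], digits = 9, trim = TRUE), con)
  }
  invisible(path)
}

#' Write labeled contour curves to CSV
#'
#' Columns: specimen_id, curve_label, point_index, x, y, z.
#'
#' @param specimens List of `bill_specimen` objects.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_contours_csv <- function(specimens, path) {
  rows <- lapply(specimens, function(sp) {
    do.call(rbind, lapply(names(sp$contours), function(lab) {
      pts <- sp$contours[[lab]]
      data.frame(specimen_id = sp$id, curve_label = lab,
                 point_index = seq_len(nrow(pts)),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read labeled contour curves from CSV
#'
#' Inverse of [write_contours_csv()].
#'
#' @param path CSV path.
#' @return Named list (by specimen id) of contour lists.
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(df$specimen_id)) {
    sub <- df[df$specimen_id == id, ]
    out[[as.character(id)]] <- lapply(split(sub, sub$curve_label), function(s) {
      as.matrix(s[order(s$point_index), c("x", "y", "z")])
    })
  }
  out
}

#' Write ground-truth parameters of a population as JSON
#'
#' @param specimens List of synthetic `bill_specimen` objects with `truth`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_truth_json <- function(specimens, path) {
  truths <- lapply(specimens, function(sp) {
    c(list(id = sp$id, sex = sp$sex), unclass(sp$truth))
  })
  jsonlite::write_json(truths, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
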