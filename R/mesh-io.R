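# Mesh and map I/O: Wavefront OBJ read/write and legacy-VTK export with
# point-data arrays. (Plain-text formats; no binary dependencies.)

#' Read a triangulated mesh from a Wavefront OBJ file
#'
#' Supports `v` and `f` records (triangular faces; `f` entries may carry
#' `/`-separated texture/normal indices, which are ignored).
#'
#' @param path file path.
#' @return List with `vertices` (n x 3) and `triangles` (m x 3, 1-based).
#' @export
read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  if (!length(vs) || !length(fs)) stop("no vertices/faces found in ", path)
  vertices <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"),
                                    function(x) as.numeric(x[1:3])))
  triangles <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fs)), "\\s+"),
                                     function(x) {
    idx <- as.integer(sub("/.*", "", x))
    if (length(idx) != 3) stop("non-triangular face in ", path)
    idx
  }))
  list(vertices = vertices, triangles = triangles)
}

#' Write a mesh to a Wavefront OBJ file
#'
#' @param mesh list with `vertices` and `triangles` (e.g. an `la_geometry`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6g %.6g %.6g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  invisible(path)
}

#' Write a mesh with point-data arrays as legacy ASCII VTK
#'
#' @param mesh list with `vertices` and `triangles`.
#' @param path output path.
#' @param point_data named list of per-vertex numeric vectors (e.g. region,
#'   ACh, lesion, voltage).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "atriagp surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%.6g %.6g %.6g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), nrow(tr) * 4), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L),
             con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_data)) {
      x <- as.numeric(point_data[[nm]])
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.6g", x), con)
    }
  }
  invisible(path)
}
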