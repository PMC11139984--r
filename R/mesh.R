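#' Shared-vertex triangle mesh
#'
#' The basic container for a dental surface scan: an `n x 3` matrix of vertex
#' coordinates in millimetres and an `m x 3` integer matrix of faces, each row
#' indexing three distinct vertices. Edges are implicit as face boundaries.
#' Meshes may be non-manifold or disconnected (intraoral scans routinely carry
#' unconnected cheek or lip flaps); all downstream processing is per-vertex.
#'
#' @param vertices numeric matrix (or coercible) with 3 columns, coordinates
#'   in mm. All coordinates must be finite.
#' @param faces integer matrix with 3 columns of 1-based vertex indices. May
#'   have zero rows. No face may repeat a vertex index within itself.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices` and `faces`.
#' @examples
#' tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                     rbind(c(1L, 2L, 3L)))
#' tri
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  dimnames(faces) <- NULL
  if (nrow(faces) == 0L) faces <- matrix(integer(0), ncol = 3L)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    stop("'vertices' must have 3 columns (x, y, z in mm)")
  if (ncol(faces) != 3L)
    stop("'faces' must have 3 columns of vertex indices")
  if (nrow(vertices) > 0L && !all(is.finite(vertices)))
    stop("all vertex coordinates must be finite")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, ", nrow(vertices), "]")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
            faces[, 2L] == faces[, 3L]))
      stop("a face repeats a vertex index within itself")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  if (nrow(x$vertices) > 0L) {
    rng <- apply(x$vertices, 2L, range)
    cat(sprintf("  bbox x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f] mm\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Number of vertices / faces in a mesh
#' @param mesh a [surface_mesh()]
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Merge coincident corner points of a triangle soup into shared vertices.
# Coordinates matching within `tol` per axis (on a tol-spaced grid) are fused;
# the first occurrence's coordinates are kept, so no coordinate moves by more
# than tol. Faces that collapse (repeated index after welding) are dropped and
# counted in attr "dropped_faces".
weld_mesh <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1L] / tol),
               round(vertices[, 2L] / tol),
               round(vertices[, 3L] / tol))
  keep_first <- !duplicated(key)
  map <- match(key, key[keep_first])
  verts <- vertices[keep_first, , drop = FALSE]
  f <- matrix(map[faces], ncol = 3L)
  ok <- f[, 1L] != f[, 2L] & f[, 1L] != f[, 3L] & f[, 2L] != f[, 3L]
  mesh <- surface_mesh(verts, f[ok, , drop = FALSE])
  attr(mesh, "dropped_faces") <- sum(!ok)
  mesh
}
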