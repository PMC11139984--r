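#' Read an STL dental scan
#'
#' Parses binary or ASCII STL (dialect auto-detected) and welds the triangle
#' soup into a shared-vertex [surface_mesh()]. Coordinates are taken as
#' millimetres, unchanged. Facet normals stored in the file are ignored:
#' orientation is handled geometrically downstream, never from normals.
#'
#' Welding merges corner points whose coordinates agree within `tol` per axis.
#' Scanner exports duplicate corner coordinates bit-identically, so the
#' default tolerance of 1e-6 mm only fuses true duplicates and cannot erase
#' fine occlusal detail. Degenerate (zero-area) triangles are kept; only faces
#' that collapse to a repeated vertex index under welding are dropped (their
#' count is stored in `attr(mesh, "dropped_faces")`).
#'
#' @param path path to an STL file.
#' @param tol weld tolerance in mm.
#' @return A [surface_mesh()].
#' @seealso [write_stl()]
#' @export
read_stl <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.size(path)
  raw <- readBin(path, "raw", n = size)
  if (is_binary_stl(raw)) read_stl_binary(raw, path, tol)
  else read_stl_ascii(path, tol)
}

# A file is binary STL iff its size matches 84 + 50 * triangle-count exactly.
# ASCII files cannot satisfy this by construction of the keyword grammar
# except with vanishing probability, and binary files always do.
is_binary_stl <- function(raw) {
  if (length(raw) < 84L) return(FALSE)
  count <- readBin(raw[81:84], "integer", n = 1L, size = 4L, endian = "little")
  count >= 0L && length(raw) == 84L + 50L * as.numeric(count)
}

read_stl_binary <- function(raw, path, tol) {
  count <- readBin(raw[81:84], "integer", n = 1L, size = 4L, endian = "little")
  if (count == 0L) stop("empty STL solid (0 triangles): ", path)
  body <- matrix(raw[-(1:84)], nrow = 50L)
  # each 50-byte record: 12 bytes normal (ignored), 36 bytes = 9 float32
  # corner coordinates, 2 bytes attribute (ignored)
  coords <- readBin(as.vector(body[13:48, , drop = FALSE]), "numeric",
                    n = 9L * count, size = 4L, endian = "little")
  if (!all(is.finite(coords)))
    stop("corrupt binary STL (non-finite coordinate) near byte ",
         84L + 50L * (which(!is.finite(coords))[1L] %/% 9L), ": ", path)
  vertices <- matrix(coords, ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * count), ncol = 3L, byrow = TRUE)
  weld_mesh(vertices, faces, tol)
}

read_stl_ascii <- function(path, tol) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^\\s*solid", lines[1L]))
    stop("not an STL file (no binary size match, no 'solid' header): ", path)
  vidx <- grep("^\\s*vertex\\b", lines)
  if (length(vidx) == 0L) stop("empty STL solid (no vertices): ", path)
  if (length(vidx) %% 3L != 0L)
    stop("corrupt ASCII STL: vertex count ", length(vidx),
         " not a multiple of 3 (last vertex at line ", vidx[length(vidx)],
         "): ", path)
  nfacet <- length(grep("^\\s*facet\\s+normal\\b", lines))
  if (nfacet != length(vidx) %/% 3L)
    stop("corrupt ASCII STL: ", nfacet, " facet blocks but ",
         length(vidx) %/% 3L, " vertex triples: ", path)
  toks <- strsplit(trimws(lines[vidx]), "\\s+")
  bad <- which(lengths(toks) != 4L)
  if (length(bad))
    stop("corrupt ASCII STL at line ", vidx[bad[1L]],
         ": expected 'vertex x y z'")
  nums <- suppressWarnings(
    as.numeric(unlist(lapply(toks, `[`, 2:4), use.names = FALSE)))
  if (anyNA(nums))
    stop("corrupt ASCII STL at line ", vidx[(which(is.na(nums))[1L] - 1L) %/% 3L + 1L],
         ": unparseable coordinate")
  vertices <- matrix(nums, ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(nrow(vertices)), ncol = 3L, byrow = TRUE)
  weld_mesh(vertices, faces, tol)
}

#' Write a mesh to STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param dialect `"binary"` (80-byte header, uint32 count, 50-byte
#'   little-endian records) or `"ascii"`. ASCII coordinates are printed with
#'   17 significant digits so a write/read round trip reproduces the welded
#'   vertex coordinates exactly; binary STL stores float32 by definition of
#'   the format, so coordinates round-trip to float32 precision.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) > 0L) {
    p1 <- v[f[, 1L], , drop = FALSE]
    p2 <- v[f[, 2L], , drop = FALSE]
    p3 <- v[f[, 3L], , drop = FALSE]
    nrm <- cross3(p2 - p1, p3 - p1)
    len <- sqrt(rowSums(nrm^2))
    nrm <- nrm / ifelse(len > 0, len, 1)  # degenerate facets get 0-normal
    nrm[len == 0, ] <- 0
  } else {
    p1 <- p2 <- p3 <- nrm <- matrix(numeric(0), ncol = 3L)
  }
  if (dialect == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid gridcut", con)
    if (nrow(f) > 0L) {
      fmt <- paste0(" facet normal %.17g %.17g %.17g\n  outer loop\n",
                    "   vertex %.17g %.17g %.17g\n",
                    "   vertex %.17g %.17g %.17g\n",
                    "   vertex %.17g %.17g %.17g\n",
                    "  endloop\n endfacet")
      writeLines(sprintf(fmt, nrm[, 1], nrm[, 2], nrm[, 3],
                         p1[, 1], p1[, 2], p1[, 3],
                         p2[, 1], p2[, 2], p2[, 3],
                         p3[, 1], p3[, 2], p3[, 3]), con)
    }
    writeLines("endsolid gridcut", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("%-80s", "gridcut binary STL")), con)
    writeBin(nrow(f), con, size = 4L, endian = "little")
    if (nrow(f) > 0L) {
      # interleave: per facet 12 float32 (normal + 3 corners) + uint16 attr
      dat <- t(cbind(nrm, p1, p2, p3))  # 12 x m
      fl <- writeBin(as.vector(dat), raw(), size = 4L, endian = "little")
      rec <- matrix(raw(0L), nrow = 50L, ncol = nrow(f))
      rec[1:48, ] <- matrix(fl, nrow = 48L)
      rec[49:50, ] <- as.raw(0L)
      writeBin(as.vector(rec), con)
    }
  }
  invisible(path)
}

cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Read / write a per-vertex label sidecar
#'
#' Plain-text companion file for synthetic scans: one label per line, values
#' `tooth` or `soft`, in the same order as the welded mesh vertices.
#'
#' @param path file path.
#' @param labels character vector of `"tooth"` / `"soft"`.
#' @return `read_labels` returns the character vector of labels.
#' @export
read_labels <- function(path) {
  labels <- readLines(path, warn = FALSE)
  bad <- which(!labels %in% c("tooth", "soft"))
  if (length(bad))
    stop("invalid label '", labels[bad[1L]], "' at line ", bad[1L], ": ", path)
  labels
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(labels %in% c("tooth", "soft")))
  writeLines(labels, path)
  invisible(path)
}
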