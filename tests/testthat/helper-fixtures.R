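# Fixture generators, built in code at test time.

# round coordinates to exact float32 values (what binary STL can store)
snap_f32 <- function(x) {
  dims <- dim(x)
  out <- readBin(writeBin(as.vector(x), raw(), size = 4L, endian = "little"),
                 "numeric", size = 4L, n = length(x), endian = "little")
  dim(out) <- dims
  out
}

# random point cloud in a 30 x 20 x 10 mm box with random triangles; geometry
# is irrelevant to the per-vertex crop, so triangle soup connectivity is fine
random_box_mesh <- function(n_vertices = 500, n_faces = n_vertices, seed = 1) {
  set.seed(seed)
  v <- cbind(runif(n_vertices, 0, 30), runif(n_vertices, 0, 20),
             runif(n_vertices, 0, 10))
  f <- t(replicate(n_faces, sample.int(n_vertices, 3L)))
  surface_mesh(v, f)
}

# flat plate (z = 0) over [0,30] x [0,20] at 1 mm pitch with six spike cusps,
# one per occlusal section; cusp apexes lie on the plane z = a x + b y + c
# unless explicit heights are given
cusp_plate <- function(a = 0, b = 0, c = 8, heights = NULL,
                       cusp_xy = cbind(x = c(5, 15, 25, 5, 15, 25),
                                       y = c(5, 5, 5, 15, 15, 15)),
                       extra_vertices = NULL) {
  g <- as.matrix(expand.grid(x = 0:30, y = 0:20))
  v <- cbind(g, 0)
  nxg <- 31L
  idx <- function(i, j) (j - 1L) * nxg + i      # i along x, j along y
  i <- rep(1:30, times = 20)
  j <- rep(1:20, each = 30)
  faces <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                 cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  if (is.null(heights))
    heights <- a * cusp_xy[, 1] + b * cusp_xy[, 2] + c
  apex_ids <- nrow(v) + seq_len(nrow(cusp_xy))
  v <- rbind(v, cbind(cusp_xy, heights))
  for (k in seq_len(nrow(cusp_xy)))
    faces <- rbind(faces, c(apex_ids[k],
                            idx(cusp_xy[k, 1] + 1L, cusp_xy[k, 2] + 1L),
                            idx(cusp_xy[k, 1] + 2L, cusp_xy[k, 2] + 1L)))
  if (!is.null(extra_vertices)) {
    extra_ids <- nrow(v) + seq_len(nrow(extra_vertices))
    v <- rbind(v, extra_vertices)
    for (k in extra_ids) faces <- rbind(faces, c(k, idx(1L, 1L), idx(2L, 1L)))
  }
  list(mesh = surface_mesh(v, faces), apex_ids = apex_ids)
}

# the 12 corner triangles of the unit cube, as a triangle soup (36 corners)
cube_soup <- function() {
  q <- list(  # each quad as 4 corners, split into 2 triangles
    rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),  # z = 0
    rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1)),  # z = 1
    rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1)),  # y = 0
    rbind(c(0,1,0), c(1,1,0), c(1,1,1), c(0,1,1)),  # y = 1
    rbind(c(0,0,0), c(0,1,0), c(0,1,1), c(0,0,1)),  # x = 0
    rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1)))  # x = 1
  tris <- lapply(q, function(m) rbind(m[c(1, 2, 3), ], m[c(1, 3, 4), ]))
  do.call(rbind, tris)   # 36 x 3, consecutive triples are triangles
}

# hand-rolled binary STL writer (independent of write_stl) for parser tests
write_binary_stl_raw <- function(corners, path) {
  stopifnot(nrow(corners) %% 3 == 0)
  n <- nrow(corners) / 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 80L), con)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  for (t in seq_len(n)) {
    writeBin(rep(0, 3), con, size = 4L, endian = "little")  # normal, ignored
    for (k in 1:3)
      writeBin(as.numeric(corners[3L * (t - 1L) + k, ]), con, size = 4L,
               endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(path)
}

# hand-rolled ASCII STL writer, likewise independent of the package
write_ascii_stl_raw <- function(corners, path) {
  stopifnot(nrow(corners) %% 3 == 0)
  lines <- "solid fixture"
  for (t in seq_len(nrow(corners) / 3L)) {
    rows <- corners[3L * (t - 1L) + 1:3, , drop = FALSE]
    lines <- c(lines, "facet normal 0 0 0", "outer loop",
               sprintf("vertex %.17g %.17g %.17g", rows[, 1], rows[, 2], rows[, 3]),
               "endloop", "endfacet")
  }
  writeLines(c(lines, "endsolid fixture"), path)
  invisible(path)
}

# canonical form for comparing meshes up to vertex reindexing: faces as the
# exact coordinate strings of their three corners (winding preserved), plus
# the multiset of referenced vertex coordinates
canon_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  cs <- function(ids) sprintf("%.17g %.17g %.17g", v[ids, 1], v[ids, 2], v[ids, 3])
  list(faces = sort(paste(cs(f[, 1]), cs(f[, 2]), cs(f[, 3]))),
       vertices = sort(cs(sort(unique(as.vector(f))))))
}
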