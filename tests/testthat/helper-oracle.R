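# Straight-line reference implementation of the grid-cutting pipeline, used
# as the independent oracle. Written with plain loops and lm(); it shares no
# code with the package (the package uses QR normal equations and vectorised
# square bookkeeping).

oracle_plane_lm <- function(points) {
  df <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3])
  co <- coef(lm(z ~ x + y, data = df))
  c(a = unname(co["x"]), b = unname(co["y"]), c = unname(co["(Intercept)"]))
}

oracle_perp_dist <- function(pl, p) {
  (p[3] - pl["a"] * p[1] - pl["b"] * p[2] - pl["c"]) /
    sqrt(pl["a"]^2 + pl["b"]^2 + 1)
}

# occlusal-plane approximation by exhaustive enumeration
oracle_occlusal <- function(vertices) {
  pl <- oracle_plane_lm(vertices)
  n <- nrow(vertices)
  d <- numeric(n)
  for (k in seq_len(n)) d[k] <- oracle_perp_dist(pl, vertices[k, ])
  surv <- which(d >= 0)
  xs <- vertices[surv, 1]; ys <- vertices[surv, 2]
  x1 <- min(xs) + (max(xs) - min(xs)) / 3
  x2 <- min(xs) + 2 * (max(xs) - min(xs)) / 3
  y1 <- min(ys) + (max(ys) - min(ys)) / 2
  reps <- integer(0)
  for (r in 1:2) for (cc in 1:3) {
    best <- NA_integer_; bestd <- -Inf
    for (k in seq_along(surv)) {
      col <- if (xs[k] >= x2) 3L else if (xs[k] >= x1) 2L else 1L
      row <- if (ys[k] >= y1) 2L else 1L
      if (col == cc && row == r && d[surv[k]] > bestd) {
        bestd <- d[surv[k]]; best <- surv[k]
      }
    }
    if (!is.na(best)) reps <- c(reps, best)
  }
  stopifnot(length(reps) >= 4)
  reps <- reps[order(-vertices[reps, 3], reps)]
  four <- reps[1:4]
  list(plane = oracle_plane_lm(vertices[four, , drop = FALSE]),
       fitting = pl, chosen = sort(four))
}

oracle_grid_cut <- function(mesh, jaw, G, I, R) {
  vertices <- mesh$vertices
  if (jaw == "maxilla") {
    ctr <- colMeans(vertices)
    vertices[, 2] <- 2 * ctr[2] - vertices[, 2]
    vertices[, 3] <- 2 * ctr[3] - vertices[, 3]
  }
  occ <- oracle_occlusal(vertices)$plane
  nrm <- c(-occ["a"], -occ["b"], 1)
  nrm <- nrm / sqrt(sum(nrm^2))
  zr <- max(vertices[, 3]) - min(vertices[, 3])
  xmin <- min(vertices[, 1]); ymin <- min(vertices[, 2])
  nx <- max(1, ceiling((max(vertices[, 1]) - xmin) / G - 1e-9))
  ny <- max(1, ceiling((max(vertices[, 2]) - ymin) / G - 1e-9))
  n <- nrow(vertices)
  cols <- integer(n); rows <- integer(n)
  for (k in seq_len(n)) {
    cols[k] <- min(nx - 1, max(0, floor((vertices[k, 1] - xmin) / G)))
    rows[k] <- min(ny - 1, max(0, floor((vertices[k, 2] - ymin) / G)))
  }
  kept <- logical(n)
  for (ci in 0:(nx - 1)) for (ri in 0:(ny - 1)) {
    members <- which(cols == ci & rows == ri)
    if (length(members) == 0L) next
    ep <- members[1]
    for (k in members) if (vertices[k, 3] > vertices[ep, 3]) ep <- k
    d_ep <- -oracle_perp_dist(occ, vertices[ep, ])
    if (d_ep > R * zr) next
    thr <- vertices[ep, 3] - I * nrm[3]
    for (k in members) if (vertices[k, 3] >= thr) kept[k] <- TRUE
  }
  remap <- cumsum(kept)
  f <- mesh$faces
  fkeep <- kept[f[, 1]] & kept[f[, 2]] & kept[f[, 3]]
  list(kept = which(kept),
       vertices = vertices[kept, , drop = FALSE],
       faces = matrix(remap[f[fkeep, , drop = FALSE]], ncol = 3))
}
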