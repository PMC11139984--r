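#' A fitted plane z = a x + b y + c
#'
#' Stores the coefficients of a non-vertical plane together with its unit
#' normal, the z-component forced positive. Used both for the initial
#' least-squares fitting plane over the whole scan and for the approximated
#' occlusal plane (whose unit normal drives the per-square inclusion
#' threshold).
#'
#' @param a,b,c plane coefficients, mm where applicable.
#' @return Object of class `plane_fit`: list with `a`, `b`, `c` and `normal`
#'   (unit vector, `normal[3] > 0`).
#' @export
plane_fit <- function(a, b, c) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  n <- c(-a, -b, 1)
  structure(list(a = a, b = b, c = c, normal = n / sqrt(sum(n^2))),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("plane_fit: z = %.6g x + %.6g y + %.6g  (normal %.4f %.4f %.4f)\n",
              x$a, x$b, x$c, x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Least-squares plane fit
#'
#' Fits z = a x + b y + c by ordinary least squares with z as the response
#' (minimising the mean squared z-residual). The scan is processed z-up and
#' every later comparison is z-based, so z-residual least squares — not total
#' least squares — is the consistent reading of a mean-squared-error plane
#' fit here.
#'
#' @param points numeric matrix with >= 3 rows and columns x, y, z (mm); the
#'   xy-projections must not be collinear.
#' @return A [plane_fit()].
#' @export
fit_plane_mse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("plane fit needs at least 3 points")
  A <- cbind(points[, 1L], points[, 2L], 1)
  dec <- qr(A)
  if (dec$rank < 3L)
    stop("degenerate plane fit: xy-projections are collinear")
  coefs <- qr.coef(dec, points[, 3L])
  plane_fit(coefs[1L], coefs[2L], coefs[3L])
}

#' Signed perpendicular distance from points to a plane
#'
#' Positive on the +normal (upper) side, negative below, in mm.
#'
#' @param plane a [plane_fit()].
#' @param points numeric matrix (n x 3) or a single point of length 3.
#' @return numeric vector of signed distances.
#' @export
point_plane_distance <- function(plane, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  (points[, 3L] - plane$a * points[, 1L] - plane$b * points[, 2L] - plane$c) /
    sqrt(plane$a^2 + plane$b^2 + 1)
}

#' Orient a dental scan occlusal-side up
#'
#' Mandibular scans are already occlusal-up and are returned unchanged.
#' Maxillary scans are rotated 180 degrees about the x-axis through the mesh
#' centroid, flipping the upper jaw upside down so both jaws are processed
#' identically. A rigid rotation (not a z-mirror) is used so chirality — the
#' patient's left/right anatomy — is preserved.
#'
#' @param mesh a [surface_mesh()].
#' @param jaw `"maxilla"` or `"mandible"`.
#' @return The oriented [surface_mesh()]; connectivity unchanged.
#' @export
orient_mesh <- function(mesh, jaw = c("mandible", "maxilla")) {
  jaw <- match.arg(jaw)
  if (jaw == "mandible") return(mesh)
  ctr <- colMeans(mesh$vertices)
  v <- mesh$vertices
  v[, 2L] <- 2 * ctr[2L] - v[, 2L]
  v[, 3L] <- 2 * ctr[3L] - v[, 3L]
  surface_mesh(v, mesh$faces)
}

#' Approximate the occlusal plane of an oriented dental scan
#'
#' The occlusal plane — the imaginary plane touching the occlusal surfaces of
#' the posterior teeth and the incisal edges of the front teeth — is
#' approximated in four steps: (1) a least-squares fitting plane over all
#' vertices; (2) vertices strictly below that plane are set aside for the
#' remainder of this operation (cusps and incisal edges survive, most gingiva
#' and vestibulum do not); (3) the survivors' xy-bounding box is split into
#' 3 x 2 = 6 sections (two section planes at thirds of the x-extent, one at
#' half the y-extent) and each non-empty section contributes the vertex with
#' the largest perpendicular distance above the fitting plane as its section
#' representative; (4) of the representatives, the four with the largest
#' z-coordinate are fitted with the same least-squares routine, giving the
#' approximated occlusal plane. The input mesh is not modified.
#'
#' Ties (equal distance within a section, or equal z among representatives)
#' resolve to the lowest vertex index, so results are order-stable.
#'
#' @param mesh an oriented [surface_mesh()] (occlusal side towards +z; see
#'   [orient_mesh()]).
#' @return A list of class `occlusal_fit` with elements `plane` (the
#'   approximated occlusal plane, a [plane_fit()]), `fitting_plane` (the
#'   initial whole-scan fit) and `sections` (the section report: a data frame
#'   with one row per section giving its bounds, representative vertex id,
#'   coordinates, distance to the fitting plane and whether it was chosen).
#' @export
approximate_occlusal_plane <- function(mesh) {
  v <- mesh$vertices
  if (nrow(v) < 3L) stop("mesh too small for occlusal-plane approximation")
  fitting <- fit_plane_mse(v)
  d <- point_plane_distance(fitting, v)
  ids <- which(d >= 0)          # on-plane vertices are kept (non-strict)
  sv <- v[ids, , drop = FALSE]
  xr <- range(sv[, 1L]); yr <- range(sv[, 2L])
  xcut <- xr[1L] + diff(xr) * c(1, 2) / 3
  ycut <- yr[1L] + diff(yr) / 2
  # half-open section assignment: boundary vertices go to the higher section
  col <- 1L + (sv[, 1L] >= xcut[1L]) + (sv[, 1L] >= xcut[2L])
  row <- 1L + (sv[, 2L] >= ycut)
  sec <- (row - 1L) * 3L + col
  xb <- c(xr[1L], xcut, xr[2L]); yb <- c(yr[1L], ycut, yr[2L])
  rep_df <- data.frame(section = 1:6,
                       x_lo = xb[c(1:3, 1:3)], x_hi = xb[c(2:4, 2:4)],
                       y_lo = yb[rep(1:2, each = 3L)],
                       y_hi = yb[rep(2:3, each = 3L)],
                       vertex = NA_integer_, x = NA_real_, y = NA_real_,
                       z = NA_real_, distance = NA_real_, chosen = FALSE)
  for (s in 1:6) {
    members <- which(sec == s)   # ascending vertex order -> stable ties
    if (length(members) == 0L) next
    best <- members[which.max(d[ids][members])]
    rep_df$vertex[s] <- ids[best]
    rep_df[s, c("x", "y", "z")] <- v[ids[best], ]
    rep_df$distance[s] <- d[ids[best]]
  }
  filled <- which(!is.na(rep_df$vertex))
  if (length(filled) < 4L)
    stop("occlusal-plane approximation failed: only ", length(filled),
         " of 6 sections contain vertices above the fitting plane (empty: ",
         paste(setdiff(1:6, filled), collapse = ", "), ")")
  ord <- filled[order(-rep_df$z[filled], rep_df$vertex[filled])]
  chosen <- ord[1:4]
  rep_df$chosen[chosen] <- TRUE
  occ <- fit_plane_mse(as.matrix(rep_df[chosen, c("x", "y", "z")]))
  structure(list(plane = occ, fitting_plane = fitting, sections = rep_df),
            class = "occlusal_fit")
}

#' @export
print.occlusal_fit <- function(x, ...) {
  cat("occlusal_fit\n  fitting plane:     ")
  print(x$fitting_plane)
  cat("  occlusal plane:    ")
  print(x$plane)
  cat("  chosen sections:  ",
      paste(x$sections$section[x$sections$chosen], collapse = ", "), "\n")
  invisible(x)
}
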