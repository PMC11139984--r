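#' Grid-cutting parameters
#'
#' The three user variables of the grid-cutting method plus the jaw side.
#'
#' @param G grid square edge length in mm (> 0). Smaller squares give a more
#'   fine-grained crop. Default 1 mm.
#' @param I inclusion criterion in mm (>= 0): how far below each square's
#'   evaluation point (along the occlusal-plane unit normal) surface is still
#'   kept. Default 7 mm.
#' @param R ratio of inclusion, a fraction in (0, 1]: squares whose highest
#'   vertex lies further below the occlusal plane than `R` times the scan's
#'   total z-range are discarded outright (they contain no teeth). Default
#'   0.33.
#' @param jaw `"maxilla"` or `"mandible"`; required, no auto-detection.
#' @return Object of class `crop_params`.
#' @export
crop_params <- function(G = 1, I = 7, R = 0.33, jaw = c("mandible", "maxilla")) {
  jaw <- match.arg(jaw)
  if (!is.numeric(G) || length(G) != 1L || !is.finite(G) || G <= 0)
    stop("grid size G must be a single positive number (mm)")
  if (!is.numeric(I) || length(I) != 1L || is.na(I) || I < 0)
    stop("inclusion criterion I must be a single number >= 0 (mm)")
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0 || R > 1)
    stop("ratio of inclusion R must lie in (0, 1]")
  structure(list(G = G, I = I, R = R, jaw = jaw), class = "crop_params")
}

#' @export
print.crop_params <- function(x, ...) {
  cat(sprintf("crop_params: G = %g mm, I = %g mm, R = %g, jaw = %s\n",
              x$G, x$I, x$R, x$jaw))
  invisible(x)
}

# internal constructor; exported build_frame() is the user entry point
new_scan_frame <- function(origin, G, nx, ny, z_min, z_max, plane) {
  structure(list(origin = origin, G = G, nx = nx, ny = ny,
                 z_min = z_min, z_max = z_max, z_range = z_max - z_min,
                 plane = plane),
            class = "scan_frame")
}

#' Build the xy-grid frame over an oriented scan
#'
#' Anchors a grid of `G` x `G` mm squares at the xy-bounding-box minimum of
#' the mesh. Square `(c, r)` (0-based) covers
#' `[x_min + cG, x_min + (c+1)G) x [y_min + rG, y_min + (r+1)G)`, with the
#' last column/row closed above, so every vertex belongs to exactly one
#' square. The scan's total z-range is computed here, once, over all vertices
#' and is never recomputed after cropping.
#'
#' @param mesh oriented [surface_mesh()] (non-empty).
#' @param occlusal the approximated occlusal plane, a [plane_fit()].
#' @param G grid square edge length, mm.
#' @return Object of class `scan_frame` with the grid origin, column/row
#'   counts `nx`, `ny`, `z_min`, `z_max`, `z_range` and the occlusal plane.
#' @export
build_frame <- function(mesh, occlusal, G) {
  v <- mesh$vertices
  if (nrow(v) == 0L) stop("cannot build a grid frame over an empty mesh")
  if (G <= 0) stop("grid size G must be positive")
  xr <- range(v[, 1L]); yr <- range(v[, 2L]); zr <- range(v[, 3L])
  # tiny backoff so an extent that is an exact multiple of G (up to float
  # noise) does not gain a spurious empty column
  nx <- max(1L, as.integer(ceiling(diff(xr) / G - 1e-9)))
  ny <- max(1L, as.integer(ceiling(diff(yr) / G - 1e-9)))
  new_scan_frame(c(xr[1L], yr[1L]), G, nx, ny, zr[1L], zr[2L], occlusal)
}

#' @export
print.scan_frame <- function(x, ...) {
  cat(sprintf("scan_frame: %d x %d squares of %g mm, origin (%.3f, %.3f), z-range %.3f mm\n",
              x$nx, x$ny, x$G, x$origin[1], x$origin[2], x$z_range))
  invisible(x)
}

# 1-based linear square id per vertex; half-open intervals, last col/row closed
square_index <- function(frame, vertices) {
  col <- pmin(frame$nx - 1L,
              pmax(0L, floor((vertices[, 1L] - frame$origin[1L]) / frame$G)))
  row <- pmin(frame$ny - 1L,
              pmax(0L, floor((vertices[, 2L] - frame$origin[2L]) / frame$G)))
  as.integer(row * frame$nx + col + 1L)
}

#' Analyse one grid square
#'
#' The square's evaluation point `E_p` is its member vertex with the highest
#' z-value (lowest id on ties). Let `d` be the perpendicular distance from
#' `E_p` down to the occlusal plane (`d <= 0` when `E_p` is on or above it).
#' If `d > R * z_range` the square's highest point is far below the occlusal
#' plane — it contains no teeth — and every member is excluded
#' (`excluded_far`). Otherwise the inclusion threshold point is placed `I` mm
#' from `E_p` along the occlusal-plane unit normal, on the side away from the
#' plane, and any member whose z-value is at least the threshold's z-value is
#' kept (`cropped`). The keep rule is non-strict, so `E_p` itself survives
#' even at `I = 0`.
#'
#' @param members integer vertex ids of the square's members (may be empty).
#' @param vertices the oriented scan's vertex matrix.
#' @param frame a [build_frame()] result.
#' @param params a [crop_params()].
#' @param col,row optional 0-based square coordinates, recorded in the
#'   decision.
#' @return Object of class `square_decision`: list with `col`, `row`,
#'   `members`, `ep_id`, `ep` (coordinates), `distance` (`d`, mm),
#'   `verdict` (`excluded_empty`, `excluded_far` or `cropped`),
#'   `threshold_z` (mm, `NA` unless cropped) and `kept` (vertex ids).
#' @export
analyse_square <- function(members, vertices, frame, params,
                           col = NA_integer_, row = NA_integer_) {
  members <- sort(as.integer(members))
  if (length(members) == 0L)
    return(structure(list(col = col, row = row, members = members,
                          ep_id = NA_integer_, ep = NULL, distance = NA_real_,
                          verdict = "excluded_empty", threshold_z = NA_real_,
                          kept = integer(0)),
                     class = "square_decision"))
  z <- vertices[members, 3L]
  ep_id <- members[which.max(z)]           # first max = lowest id on ties
  ep <- vertices[ep_id, ]
  d <- -point_plane_distance(frame$plane, ep)   # > 0 when E_p below the plane
  if (d > params$R * frame$z_range)             # strict: "larger than"
    return(structure(list(col = col, row = row, members = members,
                          ep_id = ep_id, ep = ep, distance = d,
                          verdict = "excluded_far", threshold_z = NA_real_,
                          kept = integer(0)),
                     class = "square_decision"))
  threshold_z <- ep[3L] - params$I * frame$plane$normal[3L]
  structure(list(col = col, row = row, members = members, ep_id = ep_id,
                 ep = ep, distance = d, verdict = "cropped",
                 threshold_z = threshold_z,
                 kept = members[z >= threshold_z]),
            class = "square_decision")
}

#' Grid-cut a dental scan
#'
#' The unified soft-tissue removal pipeline: orient the scan occlusal-side up
#' ([orient_mesh()]), approximate the occlusal plane
#' ([approximate_occlusal_plane()]), lay the grid ([build_frame()]), analyse
#' every square independently ([analyse_square()]), then delete all vertices
#' not kept by any square, drop every face with at least one deleted vertex,
#' and reindex. Fully deterministic: identical input and parameters give an
#' identical result.
#'
#' The cropped mesh is returned in the oriented (processing) frame — a
#' maxilla stays flipped — so that downstream comparison of scans is uniform;
#' the command-line interface can restore the original frame on request.
#'
#' @param mesh a [surface_mesh()] in scanner coordinates (mm).
#' @param params a [crop_params()].
#' @return Object of class `crop_result`: list with `mesh` (the cropped
#'   [surface_mesh()]), `frame` (the [build_frame()] result), `occlusal` (the
#'   full `occlusal_fit`), `decisions` (data frame, one row per grid square,
#'   with list-columns `members` and `kept`), `kept_ids` (vertex ids of the
#'   oriented input that survive), `removed` (count), `params`, and `empty`
#'   (`TRUE` with a warning if every square was excluded).
#' @examples
#' arch <- make_arch(arch_spec(seed = 1))
#' res <- grid_cut(arch$mesh, crop_params(G = 1, I = 7, R = 0.33))
#' res
#' @export
grid_cut <- function(mesh, params) {
  stopifnot(inherits(params, "crop_params"))
  oriented <- orient_mesh(mesh, params$jaw)
  occ <- approximate_occlusal_plane(oriented)
  frame <- build_frame(oriented, occ$plane, params$G)
  idx <- square_index(frame, oriented$vertices)
  membership <- split(seq_len(nrow(oriented$vertices)), idx)
  nsq <- frame$nx * frame$ny
  occupied <- as.integer(names(membership))
  decisions <- vector("list", nsq)
  for (k in seq_along(occupied)) {
    s <- occupied[k]
    decisions[[s]] <- analyse_square(membership[[k]], oriented$vertices,
                                     frame, params,
                                     col = (s - 1L) %% frame$nx,
                                     row = (s - 1L) %/% frame$nx)
  }
  for (s in setdiff(seq_len(nsq), occupied))
    decisions[[s]] <- analyse_square(integer(0), oriented$vertices, frame,
                                     params, col = (s - 1L) %% frame$nx,
                                     row = (s - 1L) %/% frame$nx)
  kept_ids <- sort(unlist(lapply(decisions, `[[`, "kept"), use.names = FALSE))
  keep <- logical(nrow(oriented$vertices))
  keep[kept_ids] <- TRUE
  f <- oriented$faces
  fkeep <- keep[f[, 1L]] & keep[f[, 2L]] & keep[f[, 3L]]  # any dead vertex kills the face
  remap <- integer(nrow(oriented$vertices))
  remap[kept_ids] <- seq_along(kept_ids)
  cropped <- surface_mesh(oriented$vertices[kept_ids, , drop = FALSE],
                          matrix(remap[f[fkeep, , drop = FALSE]], ncol = 3L))
  is_empty <- length(kept_ids) == 0L
  if (is_empty)
    warning("grid-cut removed every vertex: all squares excluded")
  dec_df <- data.frame(
    col = vapply(decisions, `[[`, integer(1), "col"),
    row = vapply(decisions, `[[`, integer(1), "row"),
    n_members = vapply(decisions, function(d) length(d$members), integer(1)),
    ep_id = vapply(decisions, `[[`, integer(1), "ep_id"),
    ep_z = vapply(decisions, function(d) if (is.null(d$ep)) NA_real_ else d$ep[3L], numeric(1)),
    distance = vapply(decisions, `[[`, numeric(1), "distance"),
    verdict = vapply(decisions, `[[`, character(1), "verdict"),
    threshold_z = vapply(decisions, `[[`, numeric(1), "threshold_z"),
    n_kept = vapply(decisions, function(d) length(d$kept), integer(1)))
  dec_df$members <- I(lapply(decisions, `[[`, "members"))
  dec_df$kept <- I(lapply(decisions, `[[`, "kept"))
  structure(list(mesh = cropped, frame = frame, occlusal = occ,
                 decisions = dec_df, kept_ids = kept_ids,
                 removed = nrow(oriented$vertices) - length(kept_ids),
                 params = params, empty = is_empty),
            class = "crop_result")
}

#' @export
print.crop_result <- function(x, ...) {
  tab <- table(factor(x$decisions$verdict,
                      levels = c("cropped", "excluded_far", "excluded_empty")))
  cat("crop_result\n")
  print(x$params)
  cat(sprintf("  occlusal plane: z = %.4g x + %.4g y + %.4g\n",
              x$frame$plane$a, x$frame$plane$b, x$frame$plane$c))
  cat(sprintf("  squares: %d cropped, %d excluded (far), %d empty\n",
              tab[["cropped"]], tab[["excluded_far"]], tab[["excluded_empty"]]))
  cat(sprintf("  vertices kept %d / removed %d; faces out %d\n",
              length(x$kept_ids), x$removed, nrow(x$mesh$faces)))
  invisible(x)
}
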