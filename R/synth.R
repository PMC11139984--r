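#' Specification for a synthetic labelled dental arch
#'
#' Describes a parametric dental arch used as a test fixture: a parabolic
#' gingival band carrying smooth crown-like elevations (truncated Gaussian
#' bumps) at the tooth positions, with a gingival skirt falling away on both
#' sides of the ridge. Options emulate the conditions that matter for
#' height-based soft-tissue removal: missing teeth, a partly erupted/ectopic
#' third molar sitting far below the occlusal plane, and a retromolar
#' soft-tissue flap rising at one distal end. The geometry is deliberately
#' analytic rather than anatomical — the grid-cutting method only consumes
#' heights, so anatomical realism adds nothing testable.
#'
#' @param n_teeth number of tooth positions laid out along the arch (<= 16).
#' @param missing integer vector of positions (1..`n_teeth`) left without a
#'   crown (gap in the arch).
#' @param tooth_height crown relief above the gingival ridge, mm.
#' @param arch_width,arch_depth overall arch dimensions, mm.
#' @param gingiva_drop how far the soft-tissue skirt falls below the ridge
#'   crest at the band edges, mm.
#' @param band_width width of the gingival band across the arch, mm.
#' @param mesh_resolution target edge length of the generated mesh, mm.
#' @param ectopic_molar `NULL`, or `list(side = "left"|"right",
#'   eruption_fraction ∈ (0, 1], tilt = degrees)`: an extra low molar beyond
#'   one distal end, erupted to the given fraction of `tooth_height`.
#' @param retromolar_flap `NULL`, or `list(side = "left"|"right", height =
#'   mm)`: a soft-tissue flap rising behind the last molar.
#' @param jitter amplitude of seeded uniform z-noise, mm (scanner noise).
#' @param seed integer seed; generation is fully deterministic given the
#'   seed.
#' @return Object of class `arch_spec`.
#' @export
arch_spec <- function(n_teeth = 14, missing = integer(0), tooth_height = 8,
                      arch_width = 50, arch_depth = 45, gingiva_drop = 6,
                      band_width = 10, mesh_resolution = 0.8,
                      ectopic_molar = NULL, retromolar_flap = NULL,
                      jitter = 0.05, seed = 1) {
  n_teeth <- as.integer(n_teeth)
  missing <- as.integer(missing)
  if (n_teeth < 1L || n_teeth > 16L) stop("n_teeth must be in 1..16")
  if (length(missing) && (anyDuplicated(missing) ||
                          !all(missing %in% seq_len(n_teeth))))
    stop("'missing' must be distinct positions in 1..n_teeth")
  for (len in c(tooth_height, arch_width, arch_depth, gingiva_drop,
                band_width, mesh_resolution))
    if (!is.numeric(len) || len <= 0) stop("all lengths must be > 0")
  if (!is.null(ectopic_molar)) {
    stopifnot(ectopic_molar$side %in% c("left", "right"),
              ectopic_molar$eruption_fraction > 0,
              ectopic_molar$eruption_fraction <= 1)
    if (is.null(ectopic_molar$tilt)) ectopic_molar$tilt <- 0
  }
  if (!is.null(retromolar_flap))
    stopifnot(retromolar_flap$side %in% c("left", "right"),
              retromolar_flap$height > 0)
  structure(list(n_teeth = n_teeth, missing = missing,
                 tooth_height = tooth_height, arch_width = arch_width,
                 arch_depth = arch_depth, gingiva_drop = gingiva_drop,
                 band_width = band_width, mesh_resolution = mesh_resolution,
                 ectopic_molar = ectopic_molar,
                 retromolar_flap = retromolar_flap,
                 jitter = jitter, seed = as.integer(seed)),
            class = "arch_spec")
}

#' Generate a labelled synthetic dental arch
#'
#' Builds the mesh described by an [arch_spec()]: a structured band surface
#' swept along a parabolic arch centreline, with the gingival base dropping
#' `gingiva_drop` mm towards the band edges and a truncated Gaussian crown
#' bump (sd 1.8 mm, cut at 3 sd) of height `tooth_height` at every present
#' tooth position. Crown bumps combine by maximum, so overlapping crowns
#' never exceed `tooth_height`. A vertex is labelled `tooth` when it lies in
#' the upper half of some crown bump (bump contribution >= half that crown's
#' height); everything else, including any retromolar flap, is `soft`. The
#' crown-only label is deliberately conservative: the method's success
#' criterion is tooth preservation, not gingival-margin accuracy.
#'
#' The arch is generated occlusal-side up (mandible convention); flip it with
#' [orient_mesh()] to fake a maxillary scan.
#'
#' @param spec an [arch_spec()].
#' @return Object of class `labeled_arch`: list with `mesh` (a
#'   [surface_mesh()]), `labels` (per-vertex `"tooth"`/`"soft"`), `tooth_of`
#'   (per-vertex tooth number, `NA` for soft tissue), `apexes` (data frame:
#'   tooth number, apex vertex id and coordinates) and `spec`.
#' @export
make_arch <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  W <- spec$arch_width; D <- spec$arch_depth
  half <- spec$band_width / 2
  res <- spec$mesh_resolution

  # centreline x = u W/2, y = D (1 - u^2), reparameterised by arc length;
  # the band extends 8 mm beyond the tooth-bearing arc at both distal ends
  # (retromolar surface, where the ectopic molar / flap options live)
  ext <- 8
  uf <- seq(-1.4, 1.4, length.out = 8001L)
  cx <- uf * W / 2; cy <- D * (1 - uf^2)
  arc <- c(0, cumsum(sqrt(diff(cx)^2 + diff(cy)^2)))
  a_start <- stats::approx(uf, arc, xout = -1)$y   # arc coord of tooth region
  a_end <- stats::approx(uf, arc, xout = 1)$y
  L <- a_end - a_start
  a_lo <- a_start - ext; a_hi <- a_end + ext
  n_u <- as.integer(ceiling((a_hi - a_lo) / res)) + 1L
  n_v <- as.integer(ceiling(spec$band_width / res)) + 1L
  a_of_v <- seq(a_lo, a_hi, length.out = n_u)
  u <- stats::approx(arc, uf, xout = a_of_v)$y
  px <- u * W / 2; py <- D * (1 - u^2)
  tx <- rep(W / 2, n_u); ty <- -2 * D * u          # d/du of the centreline
  tl <- sqrt(tx^2 + ty^2)
  nxv <- ty / tl; nyv <- -tx / tl                  # unit xy-normal to the band

  s <- seq(-half, half, length.out = n_v)
  X <- outer(px, s * 0 + 1) + outer(nxv, s)        # n_u x n_v grids
  Y <- outer(py, s * 0 + 1) + outer(nyv, s)
  S <- outer(rep(1, n_u), s)
  x <- as.vector(t(X)); y <- as.vector(t(Y)); sv <- as.vector(t(S))
  nvert <- length(x)

  # gingival base: ridge crest flat within |s| <= s0, quadratic drop outside
  s0 <- 2.6
  tfall <- pmin(1, pmax(0, (abs(sv) - s0) / (half - s0)))
  base <- -spec$gingiva_drop * tfall^2

  # crown bumps at present tooth positions (equal arc spacing)
  sigma <- 1.8
  centers_arc <- a_start + L * (seq_len(spec$n_teeth) - 0.5) / spec$n_teeth
  cu <- stats::approx(arc, uf, xout = centers_arc)$y
  tooth_x <- cu * W / 2; tooth_y <- D * (1 - cu^2)
  present <- setdiff(seq_len(spec$n_teeth), spec$missing)

  # a point on the centreline `beyond` mm distal of the tooth region, plus
  # the local unit lateral (band-normal) direction
  distal_point <- function(side, beyond) {
    a <- if (side == "right") a_end + beyond else a_start - beyond
    uu <- stats::approx(arc, uf, xout = a)$y
    tt <- c(W / 2, -2 * D * uu); tt <- tt / sqrt(sum(tt^2))
    list(p = c(uu * W / 2, D * (1 - uu^2)), lateral = c(tt[2], -tt[1]))
  }
  teeth <- data.frame(tooth = present, x = tooth_x[present],
                      y = tooth_y[present],
                      h = rep(spec$tooth_height, length(present)),
                      sigma = rep(sigma, length(present)))
  if (!is.null(spec$ectopic_molar)) {
    em <- spec$ectopic_molar
    e <- distal_point(em$side, 4)
    ctr <- e$p + 2 * sin(em$tilt * pi / 180) * e$lateral
    teeth <- rbind(teeth, data.frame(tooth = spec$n_teeth + 1L,
                                     x = ctr[1], y = ctr[2],
                                     h = em$eruption_fraction * spec$tooth_height,
                                     sigma = sigma))
  }

  bump <- matrix(0, nvert, nrow(teeth))
  for (k in seq_len(nrow(teeth))) {
    r2 <- (x - teeth$x[k])^2 + (y - teeth$y[k])^2
    b <- teeth$h[k] * exp(-r2 / (2 * teeth$sigma[k]^2))
    b[r2 > (3 * teeth$sigma[k])^2] <- 0
    bump[, k] <- b
  }
  relief <- if (ncol(bump)) do.call(pmax, c(asplit(bump, 2), list(0))) else 0

  if (!is.null(spec$retromolar_flap)) {
    rf <- spec$retromolar_flap
    ctr <- distal_point(rf$side, 6)$p
    r2 <- (x - ctr[1])^2 + (y - ctr[2])^2
    fb <- rf$height * exp(-r2 / (2 * 3^2))
    fb[r2 > 81] <- 0
    relief <- pmax(relief, fb)
  }

  z <- base + relief + stats::runif(nvert, -spec$jitter, spec$jitter)

  # labels: upper half of a crown bump (incl. the ectopic molar) is tooth
  is_tooth_k <- sweep(bump, 2L, teeth$h / 2, `>=`)
  tooth_of <- rep(NA_integer_, nvert)
  any_tooth <- rowSums(is_tooth_k) > 0
  if (any(any_tooth)) {
    best <- max.col(bump[any_tooth, , drop = FALSE], ties.method = "first")
    tooth_of[any_tooth] <- teeth$tooth[best]
  }
  labels <- ifelse(any_tooth, "tooth", "soft")

  counts <- table(factor(tooth_of, levels = teeth$tooth))
  if (any(counts < 8L))
    stop("mesh_resolution ", res, " mm too coarse: tooth position(s) ",
         paste(teeth$tooth[counts < 8L], collapse = ", "),
         " realised with < 8 vertices")

  apexes <- data.frame(tooth = teeth$tooth, vertex = NA_integer_,
                       x = NA_real_, y = NA_real_, z = NA_real_)
  for (k in seq_len(nrow(teeth))) {
    vid <- which.max(bump[, k])   # closest realised vertex to the crown apex
    apexes[k, c("vertex", "x", "y", "z")] <- c(vid, x[vid], y[vid], z[vid])
  }

  # two triangles per structured quad; vertex id (i, j) -> (i-1) n_v + j
  i <- rep(seq_len(n_u - 1L), each = n_v - 1L)
  j <- rep(seq_len(n_v - 1L), times = n_u - 1L)
  v00 <- (i - 1L) * n_v + j
  v01 <- v00 + 1L
  v10 <- v00 + n_v
  v11 <- v10 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  structure(list(mesh = surface_mesh(cbind(x, y, z), faces),
                 labels = labels, tooth_of = tooth_of,
                 apexes = apexes, spec = spec),
            class = "labeled_arch")
}

#' @export
print.labeled_arch <- function(x, ...) {
  cat("labeled_arch:", nrow(x$apexes), "teeth,",
      sum(x$labels == "tooth"), "tooth /", sum(x$labels == "soft"),
      "soft vertices\n")
  print(x$mesh)
  invisible(x)
}

#' Score a grid-cut against the arch's ground-truth labels
#'
#' Operationalises "soft tissue removed without removing teeth" as counts
#' over the generator's per-vertex labels: how many tooth-labelled vertices
#' the crop removed, how many teeth lost at least one grid square entirely
#' (a square counts as lost for a tooth when it contained vertices of that
#' tooth and kept none of them), and what fraction of soft-tissue vertices
#' survived.
#'
#' @param arch a [make_arch()] result.
#' @param result a [grid_cut()] result computed from `arch$mesh`.
#' @return Object of class `crop_metrics`: list with
#'   `tooth_vertices_removed`, `teeth_damaged`, `soft_retained_fraction` and
#'   `per_tooth` (data frame: tooth, vertex/removed counts, squares touched
#'   and lost).
#' @export
evaluate_crop <- function(arch, result) {
  stopifnot(inherits(arch, "labeled_arch"), inherits(result, "crop_result"))
  n <- nrow(arch$mesh$vertices)
  if (sum(result$decisions$n_members) != n)
    stop("mesh/label mismatch: crop covers ", sum(result$decisions$n_members),
         " vertices, arch has ", n)
  kept <- logical(n)
  kept[result$kept_ids] <- TRUE
  sq_of <- integer(n)
  for (srow in seq_len(nrow(result$decisions)))
    sq_of[result$decisions$members[[srow]]] <- srow
  teeth <- arch$apexes$tooth
  per <- data.frame(tooth = teeth, n_vertices = 0L, n_removed = 0L,
                    squares = 0L, squares_lost = 0L)
  for (k in seq_along(teeth)) {
    vt <- which(!is.na(arch$tooth_of) & arch$tooth_of == teeth[k])
    per$n_vertices[k] <- length(vt)
    per$n_removed[k] <- sum(!kept[vt])
    sqs <- unique(sq_of[vt])
    per$squares[k] <- length(sqs)
    per$squares_lost[k] <- sum(vapply(sqs, function(s)
      !any(kept[vt[sq_of[vt] == s]]), logical(1)))
  }
  soft <- arch$labels == "soft"
  structure(list(
    tooth_vertices_removed = sum(!kept & arch$labels == "tooth"),
    teeth_damaged = sum(per$squares_lost >= 1L),
    soft_retained_fraction = if (any(soft)) sum(kept & soft) / sum(soft) else NA_real_,
    per_tooth = per), class = "crop_metrics")
}

#' @export
print.crop_metrics <- function(x, ...) {
  cat(sprintf("crop_metrics: %d tooth vertices removed, %d teeth damaged, %.1f%% soft tissue retained\n",
              x$tooth_vertices_removed, x$teeth_damaged,
              100 * x$soft_retained_fraction))
  invisible(x)
}
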