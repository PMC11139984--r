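test_that("crop parameters are validated with the documented defaults", {
  p <- crop_params(jaw = "mandible")
  expect_equal(p$G, 1)
  expect_equal(p$I, 7)
  expect_equal(p$R, 0.33)
  expect_error(crop_params(G = 0), "positive")
  expect_error(crop_params(G = -1), "positive")
  expect_error(crop_params(I = -0.1), ">= 0")
  expect_error(crop_params(R = 0), "\\(0, 1\\]")
  expect_error(crop_params(R = 1.5), "\\(0, 1\\]")
  expect_silent(crop_params(R = 1))
})

test_that("the grid frame has ceil(extent/G) columns and rows", {
  v <- rbind(c(0, 0, 0), c(10, 5, 1), c(10, 0, 2), c(0, 5, 3))
  mesh <- surface_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4)))
  plane <- plane_fit(0, 0, 3)
  f1 <- build_frame(mesh, plane, G = 1)
  expect_equal(c(f1$nx, f1$ny), c(10L, 5L))
  f4 <- build_frame(mesh, plane, G = 4)
  expect_equal(c(f4$nx, f4$ny), c(3L, 2L))
  expect_equal(f1$z_range, 3)
  expect_error(build_frame(surface_mesh(matrix(numeric(0), ncol = 3),
                                        matrix(integer(0), ncol = 3)),
                           plane, 1), "empty")
})

test_that("every vertex maps to exactly one square, matching a brute-force loop", {
  set.seed(21)
  v <- cbind(runif(1000, -5, 20), runif(1000, 3, 17), runif(1000, 0, 8))
  mesh <- surface_mesh(v, t(replicate(300, sample.int(1000, 3))))
  frame <- build_frame(mesh, plane_fit(0, 0, 8), G = 2.5)
  idx <- gridcut:::square_index(frame, v)
  expect_true(all(idx >= 1L & idx <= frame$nx * frame$ny))
  xmin <- min(v[, 1]); ymin <- min(v[, 2])
  for (k in sample(1000, 200)) {   # spot-check against a double loop
    hit <- NULL
    for (ci in 0:(frame$nx - 1)) for (ri in 0:(frame$ny - 1)) {
      inx <- v[k, 1] >= xmin + ci * 2.5 &
        (v[k, 1] < xmin + (ci + 1) * 2.5 | ci == frame$nx - 1)
      iny <- v[k, 2] >= ymin + ri * 2.5 &
        (v[k, 2] < ymin + (ri + 1) * 2.5 | ri == frame$ny - 1)
      if (inx && iny) hit <- c(hit, ri * frame$nx + ci + 1)
    }
    expect_identical(as.integer(idx[k]), as.integer(hit))
  }
})

test_that("square analysis applies the exclusion and inclusion rules", {
  vertices <- rbind(c(0.5, 0.5, 5), c(0.2, 0.2, 5), c(0.8, 0.2, 5),  # 1-3
                    c(0.5, 0.5, 4.9),                                 # 4
                    c(0.3, 0.3, 10), c(0.4, 0.4, 6),                  # 5-6
                    c(0.5, 0.5, 3.5), c(0.6, 0.6, 2.9))               # 7-8
  params <- crop_params(G = 1, I = 7, R = 0.33)

  # everything within I of the evaluation point: all kept
  fr5 <- gridcut:::new_scan_frame(c(0, 0), 1, 1L, 1L, 0, 5, plane_fit(0, 0, 5))
  d1 <- analyse_square(1:3, vertices, fr5, params)
  expect_equal(d1$verdict, "cropped")
  expect_identical(d1$kept, 1:3)
  expect_lt(d1$threshold_z, 5)

  # highest point 5.1 mm below a z=10 plane, R * z_range = 4.95: excluded
  fr10 <- gridcut:::new_scan_frame(c(0, 0), 1, 1L, 1L, 0, 15, plane_fit(0, 0, 10))
  d2 <- analyse_square(4L, vertices, fr10, params)
  expect_equal(d2$verdict, "excluded_far")
  expect_identical(d2$kept, integer(0))
  expect_gt(d2$distance, 0.33 * 15)

  # threshold z = 10 - 7 = 3: vertices at 10, 6, 3.5 kept, 2.9 removed
  d3 <- analyse_square(c(5:8), vertices, fr10, params)
  expect_equal(d3$verdict, "cropped")
  expect_equal(d3$ep_id, 5L)
  expect_equal(d3$threshold_z, 3)
  expect_identical(d3$kept, 5:7)

  # empty square
  d4 <- analyse_square(integer(0), vertices, fr10, params)
  expect_equal(d4$verdict, "excluded_empty")
  expect_identical(d4$kept, integer(0))
})

test_that("the evaluation point is always kept, even at I = 0", {
  arch <- make_arch(arch_spec(seed = 5, mesh_resolution = 1.2))
  res <- grid_cut(arch$mesh, crop_params(I = 0))
  cropped <- res$decisions[res$decisions$verdict == "cropped", ]
  for (k in seq_len(nrow(cropped)))
    expect_true(cropped$ep_id[k] %in% cropped$kept[[k]])
})

test_that("grid-cut removes no coordinates, only vertices, and keeps faces valid", {
  mesh <- random_box_mesh(800, seed = 13)
  res <- grid_cut(mesh, crop_params())
  expect_equal(res$mesh$vertices, mesh$vertices[res$kept_ids, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(nrow(res$mesh$vertices) + res$removed, n_vertices(mesh))
  if (n_faces(res$mesh) > 0)
    expect_true(all(res$mesh$faces >= 1 & res$mesh$faces <= nrow(res$mesh$vertices)))
  # faces survive only if all three vertices survive
  kept_orig <- logical(n_vertices(mesh))
  kept_orig[res$kept_ids] <- TRUE
  expect_equal(n_faces(res$mesh),
               sum(rowSums(matrix(kept_orig[mesh$faces], ncol = 3)) == 3))
})

test_that("grid-cut is deterministic", {
  mesh <- random_box_mesh(600, seed = 17)
  r1 <- grid_cut(mesh, crop_params(jaw = "maxilla"))
  r2 <- grid_cut(mesh, crop_params(jaw = "maxilla"))
  expect_identical(r1$mesh, r2$mesh)
  expect_identical(r1$kept_ids, r2$kept_ids)
  expect_identical(r1$decisions$verdict, r2$decisions$verdict)
})

test_that("kept sets grow monotonically in I and in R", {
  mesh <- random_box_mesh(700, seed = 23)
  kept_I <- lapply(c(0, 2, 5), function(I)
    grid_cut(mesh, crop_params(I = I))$kept_ids)
  expect_true(all(kept_I[[1]] %in% kept_I[[2]]))
  expect_true(all(kept_I[[2]] %in% kept_I[[3]]))
  kept_R <- lapply(c(0.15, 0.5, 1), function(R)
    grid_cut(mesh, crop_params(R = R))$kept_ids)
  expect_true(all(kept_R[[1]] %in% kept_R[[2]]))
  expect_true(all(kept_R[[2]] %in% kept_R[[3]]))
})

test_that("translation of the input translates the output identically", {
  mesh <- random_box_mesh(500, seed = 29)
  t3 <- c(7.25, -3.5, 1.75)
  shifted <- surface_mesh(sweep(mesh$vertices, 2, t3, `+`), mesh$faces)
  r0 <- grid_cut(mesh, crop_params())
  r1 <- grid_cut(shifted, crop_params())
  expect_identical(r0$kept_ids, r1$kept_ids)
  expect_equal(r1$mesh$vertices, sweep(r0$mesh$vertices, 2, t3, `+`),
               tolerance = 1e-9)
  expect_identical(r0$mesh$faces, r1$mesh$faces)
})

test_that("maxillary scans are processed in the flipped frame", {
  arch <- make_arch(arch_spec(seed = 6, mesh_resolution = 1.2))
  # fake a maxillary scan: the arch flipped upside down
  fake_max <- orient_mesh(arch$mesh, "maxilla")
  r_max <- grid_cut(fake_max, crop_params(jaw = "maxilla"))
  r_man <- grid_cut(arch$mesh, crop_params(jaw = "mandible"))
  expect_identical(r_max$kept_ids, r_man$kept_ids)
  expect_equal(r_max$mesh$vertices, r_man$mesh$vertices, tolerance = 1e-9)
})

test_that("disabling both filters (huge I, R = 1) returns the oriented input", {
  deep <- rbind(c(15.2, 10.2, -10))
  plate <- cusp_plate(a = 0, b = 0, c = 9, extra_vertices = deep)
  res <- grid_cut(plate$mesh, crop_params(I = 1e6, R = 1))
  expect_identical(res$kept_ids, seq_len(n_vertices(plate$mesh)))
  expect_equal(res$mesh$vertices, plate$mesh$vertices, ignore_attr = TRUE)
  expect_identical(res$mesh$faces, plate$mesh$faces)
  expect_equal(res$removed, 0L)
})

test_that("a tiny ratio of inclusion discards nearly everything below the plane", {
  # near-flat cloud with four coplanar corner spikes: the occlusal plane is
  # the spikes' plane (z = 100), so with R = 0.01 every non-spike square is
  # excluded_far and only the spikes themselves survive the threshold
  mesh <- random_box_mesh(300, seed = 31)
  v <- mesh$vertices
  v[, 3] <- v[, 3] * 1e-3
  v <- rbind(v, c(0, 0, 100), c(30, 0, 100), c(0, 20, 100), c(30, 20, 100))
  flatmesh <- surface_mesh(v, mesh$faces)
  res <- grid_cut(flatmesh, crop_params(R = 0.01))
  expect_equal(c(res$frame$plane$a, res$frame$plane$b, res$frame$plane$c),
               c(0, 0, 100), tolerance = 1e-8)
  expect_true(res$removed > 0.9 * n_vertices(flatmesh))
  expect_true(all(res$decisions$verdict %in%
                    c("cropped", "excluded_far", "excluded_empty")))
  expect_false(res$empty)
})
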