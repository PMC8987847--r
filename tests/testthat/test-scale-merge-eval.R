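make_cloud_solution <- function(points) {
  # minimal solution-like object for scale fitting
  list(points = points,
       poses = list(list(look_at_pose(c(1000, 0, 0), c(0, 0, 0)))),
       intrinsics = list(camera_intrinsics(60, 3.91, c(6000, 4000))))
}

test_that("scale fitting recovers exact and least-squares factors", {
  pts <- data.frame(id = 1:4, x = c(0, 100, 0, 50), y = c(0, 0, 200, 70),
                    z = c(0, 0, 0, 300), kind = "coded_target_center")
  refs <- data.frame(id_a = c(1, 1), id_b = c(2, 3),
                     distance_mm = c(100, 200))
  sol <- make_cloud_solution(pts)
  fit <- fit_scale(sol, refs)
  expect_equal(fit$scale, 1, tolerance = 1e-12)
  # a uniformly shrunk model needs the inverse factor
  half <- sol
  half$points[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] * 0.5
  expect_equal(fit_scale(half, refs)$scale, 2, tolerance = 1e-12)
  # single pair: exact ratio
  one <- fit_scale(half, refs[1, ])
  expect_equal(one$scale, 2, tolerance = 1e-12)
  expect_equal(one$pair_errors_mm, 0, tolerance = 1e-10)
  # camera centers are scaled with the points
  expect_equal(fit_scale(half, refs)$solution$poses[[1]][[1]]$center_mm,
               c(2000, 0, 0))
  # no reconstructed endpoint -> error
  expect_error(fit_scale(sol, data.frame(id_a = 99, id_b = 98,
                                         distance_mm = 10)),
               "no reference pair")
})

test_that("scale fitting is equivariant under pre-scaling", {
  set.seed(20)
  pts <- data.frame(id = 1:10, x = rnorm(10, 0, 300), y = rnorm(10, 0, 300),
                    z = runif(10, 0, 800), kind = "random_dot")
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  refs <- data.frame(id_a = 1:5, id_b = 6:10,
                     distance_mm = sqrt(rowSums((xyz[1:5, ] - xyz[6:10, ])^2)) *
                       runif(5, 0.98, 1.02))
  s0 <- fit_scale(make_cloud_solution(pts), refs)$scale
  for (cc in c(0.2, 3.7)) {
    scaled <- pts
    scaled[, c("x", "y", "z")] <- xyz * cc
    expect_equal(fit_scale(make_cloud_solution(scaled), refs)$scale,
                 s0 / cc, tolerance = 1e-12)
  }
})

test_that("similarity alignment recovers a known transform", {
  set.seed(8)
  X <- matrix(rnorm(60, 0, 100), ncol = 3)
  R <- rot_from_axis_angle(c(0.3, -0.5, 0.9)); s <- 1.42; tr <- c(10, -40, 7)
  Y <- sweep(s * X %*% t(R), 2, tr, `+`)
  al <- align_similarity(X, Y)
  expect_equal(al$s, s, tolerance = 1e-10)
  expect_equal(al$R, R, tolerance = 1e-10)
  expect_equal(al$t, tr, tolerance = 1e-8)
  expect_equal(al$transform(X), Y, tolerance = 1e-8)
})

test_that("noisy reconstructions scale to sub-0.2 mm mean pair error", {
  errs <- vapply(c("noisy72", "selfcal101"), function(key) {
    sc <- if (key == "noisy72") noisy_fixture() else
      cached(key, solve_bar_scene(seed = 101, sigma = 0.3, n_steps = 36,
                                  step_deg = 10))
    fit <- fit_scale(sc$solution, sc$sim$truth$reference_distances)
    mean(fit$pair_errors_mm)
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.2)
})

test_that("background-mask voting removes floaters and keeps the plant", {
  cams <- mid_rig(distortion = c())
  spec <- scene_spec(cams, 15, 24, bar = list(n_dots = 60, height_mm = 600),
                     plant = list(height_mm = 500, n_leaves = 4,
                                  density_per_mm2 = 0.004),
                     noise = list(sigma_px = 0, outlier_frac = 0), seed = 4)
  sim <- simulate_capture(spec)
  masks <- generate_masks(sim$truth, downsample = 8)
  set.seed(9)
  cand <- data.frame(id = 90000 + 1:800,
                     x = runif(800, -900, 900), y = runif(800, -900, 900),
                     z = runif(800, 0, 900), kind = "noise")
  xyz_true <- as.matrix(sim$truth$points[, c("x", "y", "z")])
  d2 <- apply(as.matrix(cand[, 2:4]), 1,
              function(p) min(colSums((t(xyz_true) - p)^2)))
  noise_pts <- cand[d2 > 60^2, ][1:500, ]
  cloud <- scene_point_cloud(rbind(sim$truth$points, noise_pts),
                             scale_applied = TRUE)
  filt <- apply_background_mask(cloud, masks, sim$truth$poses,
                                sim$truth$intrinsics, min_votes = 2)
  removed <- 1 - sum(filt$points$kind == "noise") / nrow(noise_pts)
  kept_plant <- sum(filt$points$kind == "plant_surface") /
    sum(cloud$points$kind == "plant_surface")
  expect_gte(removed, 0.99)
  expect_gte(kept_plant, 0.99)
  # the filter never adds points
  expect_lte(nrow(filt$points), nrow(cloud$points))
  # all-foreground masks keep every point visible in enough frames
  all_fg <- lapply(masks, function(m) {
    m2 <- m; m2[] <- TRUE
    attributes(m2) <- attributes(m); m2
  })
  ident <- apply_background_mask(cloud, all_fg, sim$truth$poses,
                                 sim$truth$intrinsics, min_votes = 2)
  n_vis <- integer(nrow(cloud$points))
  xyz <- as.matrix(cloud$points[, c("x", "y", "z")])
  for (k in 1:2) {
    sp <- sim$truth$intrinsics[[k]]$sensor_px
    for (p in sim$truth$poses[[k]]) {
      px <- project_points(xyz, p, sim$truth$intrinsics[[k]], behind = "na")
      n_vis <- n_vis + as.integer(!is.na(px[, 1]) & px[, 1] >= 0 &
                                    px[, 1] <= sp[1] & px[, 2] >= 0 &
                                    px[, 2] <= sp[2])
    }
  }
  expect_equal(nrow(ident$points), sum(n_vis >= 2))
  # impossible vote count empties the cloud (documented degenerate)
  none <- apply_background_mask(cloud, masks, sim$truth$poses,
                                sim$truth$intrinsics, min_votes = 10000)
  expect_equal(nrow(none$points), 0)
  # missing mask for a referenced frame is an error
  expect_error(apply_background_mask(cloud, masks[-1], sim$truth$poses,
                                     sim$truth$intrinsics),
               "missing background mask")
})

test_that("cloud merging deduplicates without moving points far", {
  set.seed(6)
  pts <- data.frame(id = 1:300, x = runif(300, -400, 400),
                    y = runif(300, -400, 400), z = runif(300, 0, 800),
                    kind = "plant_surface")
  c1 <- scene_point_cloud(pts, camera_id = 1, scale_applied = TRUE)
  expect_equal(nrow(merge_clouds(list(c1), 0.5)$points), 300)
  # disjoint clouds concatenate
  far <- pts; far$x <- far$x + 5000
  c2 <- scene_point_cloud(far, camera_id = 2, scale_applied = TRUE)
  expect_equal(nrow(merge_clouds(list(c1, c2), 0.5)$points), 600)
  # a jittered copy collapses back onto the original
  jit <- pts
  jit[, c("x", "y", "z")] <- jit[, c("x", "y", "z")] +
    matrix(runif(900, -0.05, 0.05), ncol = 3)
  c3 <- scene_point_cloud(jit, camera_id = 2, scale_applied = TRUE)
  merged <- merge_clouds(list(c1, c3), 0.5)
  expect_lte(abs(nrow(merged$points) - 300) / 300, 0.01)
  # merged coordinates moved by at most the merge radius
  m <- match(merged$points$id, pts$id)
  moved <- sqrt(rowSums((as.matrix(merged$points[, c("x", "y", "z")]) -
                         as.matrix(pts[m, c("x", "y", "z")]))^2))
  expect_lte(max(moved), 0.5)
  # provenance is preserved as a set
  expect_true(any(grepl("1\\+2", merged$points$camera_id)))
  # unscaled input refuses to merge
  raw <- scene_point_cloud(pts, camera_id = 1, scale_applied = FALSE)
  expect_error(merge_clouds(list(raw), 0.5), "scaled")
})

test_that("length reports are exact on truth and self-consistent", {
  pts <- data.frame(id = 1:5, x = c(0, 100, 0, 0, 30),
                    y = c(0, 0, 250, 0, 40), z = c(0, 0, 0, 420, 50),
                    kind = "coded_target_center")
  cloud <- scene_point_cloud(pts, scale_applied = TRUE)
  pairs <- data.frame(id_a = c(1, 1, 1), id_b = c(2, 3, 4),
                      true_mm = c(100, 250, 420))
  rep0 <- evaluate_lengths(cloud, pairs)
  expect_equal(rep0$pairs$error_mm, rep(0, 3))
  expect_equal(rep0$mean_error_mm, 0)
  # aggregates recompute from the per-pair rows
  pairs$true_mm <- pairs$true_mm + c(-1, 0.5, 2)
  rep1 <- evaluate_lengths(cloud, pairs)
  expect_equal(rep1$mean_error_mm, mean(rep1$pairs$error_mm))
  expect_equal(rep1$sd_error_mm, sd(rep1$pairs$error_mm))
  expect_equal(rep1$mean_abs_error_mm, mean(abs(rep1$pairs$error_mm)))
  expect_equal(rep1$n_pairs, nrow(rep1$pairs))
  # missing markers are listed and their pairs skipped
  pairs2 <- rbind(pairs, data.frame(id_a = 1, id_b = 99, true_mm = 10))
  rep2 <- evaluate_lengths(cloud, pairs2)
  expect_equal(rep2$missing, 99)
  expect_equal(rep2$n_pairs, 3)
})

test_that("residual maps flag sensor regions the bar never reached", {
  sc <- noisy_fixture()
  rmap <- residual_map(sc$solution, grid_size = 8)
  expect_gte(min(rmap$covered_fraction), 0.95)
  # constructed: observations only in the lower half of the sensor
  sol <- sc$solution
  lower <- sol$observations$y_px > 2000 & sol$observations$camera_id == 1
  sol2 <- sol
  keep <- lower | sol$observations$camera_id != 1
  sol2$observations <- sol$observations[keep, ]
  sol2$residuals <- sol$residuals[keep, ]
  rmap2 <- residual_map(sol2, grid_size = 8)
  top_rows <- rmap2$maps[[1]][rmap2$maps[[1]]$row <= 4, ]
  expect_true(all(!top_rows$covered))
  # empty solution: all cells uncovered
  sol3 <- sol
  sol3$observations <- sol$observations[0, ]
  sol3$residuals <- sol$residuals[0, ]
  expect_equal(residual_map(sol3)$covered_fraction, c(0, 0))
  # cell means recompute from the raw residuals
  cell <- rmap$maps[[1]]
  cell <- cell[cell$n > 0, ][5, ]
  sp <- sol$intrinsics[[1]]$sensor_px
  sel <- sol$observations$camera_id == 1 &
    ceiling(sol$observations$x_px / sp[1] * 8) == cell$col &
    ceiling(sol$observations$y_px / sp[2] * 8) == cell$row
  expect_equal(mean(sol$residuals$dx[sel]), cell$mean_dx, tolerance = 1e-10)
})

test_that("PLY files round-trip coordinates and provenance", {
  pts <- data.frame(id = 1:4, x = c(0.125, -3.5, 2e3, 1),
                    y = c(1, 2, 3, -4.25), z = c(9, 8, 7, 6),
                    kind = c("coded_target_center", "random_dot",
                             "plant_surface", "noise"))
  cloud <- scene_point_cloud(pts, scale_applied = TRUE)
  f <- tempfile(fileext = ".ply")
  write_ply(cloud, f)
  back <- read_ply(f)
  expect_equal(back[, c("x", "y", "z", "kind")],
               pts[, c("x", "y", "z", "kind")])
})
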