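test_that("axial points project to the principal point", {
  intr <- camera_intrinsics(60, 3.91, c(6000, 4000))
  pose <- look_at_pose(c(1000, 0, 500), c(0, 0, 500))
  for (d in c(200, 1000, 5000)) {
    px <- project_points(c(1000 - d, 0, 500), pose, intr)
    expect_equal(as.numeric(px), intr$principal_point_px, tolerance = 1e-9)
  }
})

test_that("projection with distortion inverts back to the pinhole model", {
  d <- c(k1 = -0.12, k2 = 0.02, k3 = 0.002, p1 = 3e-4, p2 = -2e-4)
  intr_d <- camera_intrinsics(60, 3.91, c(6000, 4000), distortion = d)
  intr_0 <- camera_intrinsics(60, 3.91, c(6000, 4000))
  pose <- look_at_pose(c(2300, 0, 800), c(0, 0, 500))
  set.seed(1)
  X <- cbind(runif(50, -400, 400), runif(50, -400, 400), runif(50, 0, 1000))
  px_d <- project_points(X, pose, intr_d)
  fpx <- focal_px(intr_d)
  xn <- sweep(px_d, 2, intr_d$principal_point_px) / fpx
  xu <- invert_distortion(xn, d)
  undistorted <- sweep(xu * fpx, 2, intr_0$principal_point_px, `+`)
  expect_equal(undistorted, project_points(X, pose, intr_0),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("points at or behind the camera plane are signalled", {
  intr <- camera_intrinsics(60, 3.91, c(6000, 4000))
  pose <- look_at_pose(c(1000, 0, 0), c(0, 0, 0))
  expect_error(project_points(c(2000, 0, 0), pose, intr), "behind")
  px <- project_points(rbind(c(2000, 0, 0), c(0, 0, 0)), pose, intr,
                       behind = "na")
  expect_true(is.na(px[1, 1]) && !is.na(px[2, 1]))
})

test_that("distortion round trip is exact within the model region", {
  expect_equal(apply_distortion(cbind(0.3, -0.2),
                                c(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0)),
               cbind(0.3, -0.2))
  # pure k1 displaces radially by 1 + k1 r^2
  d1 <- c(k1 = -0.1, k2 = 0, k3 = 0, p1 = 0, p2 = 0)
  p <- c(0.3, 0.4)  # radius 0.5
  expect_equal(as.numeric(apply_distortion(rbind(p), d1)),
               p * (1 - 0.1 * 0.25), tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:5) {
    d <- c(k1 = runif(1, -0.1, 0.1), k2 = runif(1, -0.02, 0.02),
           k3 = runif(1, -0.005, 0.005), p1 = runif(1, -5e-4, 5e-4),
           p2 = runif(1, -5e-4, 5e-4))
    xy <- matrix(runif(2000, -0.6, 0.6), ncol = 2)
    rt <- invert_distortion(apply_distortion(xy, d), d)
    expect_lt(max(abs(rt - xy)), 1e-8)
  }
})

test_that("turntable poses close the loop and respect symmetry", {
  intr <- camera_intrinsics(60, 3.91, c(6000, 4000))
  base <- camera_at(intr, 2300, 1372, 25)$base_pose
  expect_equal(turntable_pose(base, 0, 5), base)
  full <- turntable_pose(base, 72, 5)
  expect_lt(max(abs(full$rotation - base$rotation)), 1e-10)
  expect_lt(max(abs(full$center_mm - base$center_mm)), 1e-9)
  # 180 degrees mirrors the camera center through the table axis
  half <- turntable_pose(base, 36, 5)
  expect_equal(half$center_mm[1:2], -base$center_mm[1:2], tolerance = 1e-9)
  expect_equal(half$center_mm[3], base$center_mm[3])
  # a camera aimed at the axis keeps the axis point fixed in the image
  target <- c(0, 0, 1372 - 2300 * tan(25 * pi / 180))
  p0 <- project_points(target, base, intr)
  for (j in c(7, 23, 55)) {
    pj <- project_points(target, turntable_pose(base, j, 5), intr)
    expect_equal(pj, p0, tolerance = 1e-7)
  }
})

test_that("simulator detections at zero noise reproduce direct projection", {
  sc <- bar_scene(seed = 3, sigma = 0, n_steps = 12, step_deg = 30,
                  n_dots = 40)
  obs <- sc$sim$observations
  truth <- sc$sim$truth
  xyz <- as.matrix(truth$points[match(obs$point_id, truth$points$id),
                                c("x", "y", "z")])
  for (k in 1:2) {
    for (j in unique(obs$step_index[obs$camera_id == k])) {
      sel <- obs$camera_id == k & obs$step_index == j
      px <- project_points(xyz[sel, , drop = FALSE], truth$poses[[k]][[j + 1]],
                           truth$intrinsics[[k]])
      expect_lt(max(abs(px - cbind(obs$x_px[sel], obs$y_px[sel]))), 1e-9)
    }
  }
})

test_that("rotation helpers invert each other and stay on SO(3)", {
  set.seed(11)
  for (rep in 1:20) {
    w <- rnorm(3) * runif(1, 0, 3)
    R <- rot_from_axis_angle(w)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    th <- sqrt(sum(w^2))
    if (th < pi) expect_equal(axis_angle_from_rot(R), w, tolerance = 1e-8)
  }
  # orthonormalize projects a perturbed rotation back
  R <- rot_from_axis_angle(c(0.4, -0.2, 1.1)) + matrix(rnorm(9, 0, 1e-4), 3)
  O <- orthonormalize(R)
  expect_lt(max(abs(crossprod(O) - diag(3))), 1e-12)
})

test_that("observation tables and camera files round-trip through disk", {
  obs <- data.frame(point_id = c(1, 1, 2), camera_id = c(1, 2, 1),
                    step_index = c(0, 0, 3),
                    x_px = c(100.25, 200.5, 3000.125),
                    y_px = c(50.75, 60.25, 1999.5),
                    target_code = c(5, 5, NA))
  f <- tempfile(fileext = ".csv")
  write_observations(obs, f)
  expect_equal(read_observations(f), obs)
  expect_error(read_observations(write_observations(obs[, 1:3], f)),
               "missing columns")

  intr <- camera_intrinsics(60, 3.91, c(6000, 4000),
                            distortion = c(k1 = -0.08, p1 = 1e-4))
  cams <- list(intrinsics = list(intr),
               poses = list(list(camera_at(intr, 2300, 1372, 25)$base_pose,
                                 turntable_pose(camera_at(intr, 2300, 1372,
                                                          25)$base_pose,
                                                1, 5))))
  fj <- tempfile(fileext = ".json")
  write_cameras(cams, fj)
  back <- read_cameras(fj)
  expect_equal(back$intrinsics[[1]]$focal_length_mm, 60)
  expect_equal(back$intrinsics[[1]]$distortion, intr$distortion)
  expect_equal(back$poses[[1]][[2]]$rotation, cams$poses[[1]][[2]]$rotation,
               tolerance = 1e-12)
  expect_equal(back$poses[[1]][[2]]$center_mm, cams$poses[[1]][[2]]$center_mm)
})

test_that("constructors reject malformed inputs", {
  expect_error(camera_intrinsics(-60, 3.91), "focal_length_mm")
  expect_error(camera_pose(matrix(1:9, 3), c(0, 0, 0)), "orthonormal")
  expect_error(turntable_pose(look_at_pose(c(1, 0, 0), c(0, 0, 0)), 1, -5))
  expect_error(look_at_pose(c(0, 0, 100), c(0, 0, 0)), "parallel")
})
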