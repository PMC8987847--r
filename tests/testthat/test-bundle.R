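test_that("triangulation recovers exact points from noiseless views", {
  cams <- mid_rig(distortion = c(k1 = -0.05, p1 = 1e-4))
  poses <- lapply(cams, function(cc) list(cc$base_pose))
  intrinsics <- lapply(cams, `[[`, "intrinsics")
  X <- c(150, -80, 420)
  track <- do.call(rbind, lapply(1:2, function(k) {
    px <- project_points(X, poses[[k]][[1]], intrinsics[[k]])
    data.frame(point_id = 1, camera_id = k, step_index = 0,
               x_px = px[1], y_px = px[2])
  }))
  expect_equal(triangulate(track, poses, intrinsics), X, tolerance = 1e-6)
  # a single ray duplicated is degenerate
  bad <- track[c(1, 1), ]
  bad$camera_id <- 1
  expect_error(triangulate(bad, poses, intrinsics), "degenerate baseline")
  expect_error(triangulate(track[1, , drop = FALSE], poses, intrinsics),
               "fewer than 2")
})

test_that("many-view triangulation error is bounded by the depth resolution", {
  sc <- bar_scene(seed = 23, sigma = 0.3, n_steps = 72, step_deg = 5,
                  n_dots = 10)
  truth <- sc$sim$truth
  dz <- studio_geometry(2300, 25, 60, 3.91, s_deg = 15)$delta_z_mm
  ids <- truth$target_codes$id
  errs <- vapply(ids, function(id) {
    trk <- sc$sim$observations[sc$sim$observations$point_id == id, ]
    if (nrow(trk) < 10) return(NA_real_)
    X <- triangulate(trk, truth$poses, truth$intrinsics)
    sqrt(sum((X - unlist(truth$points[truth$points$id == id,
                                      c("x", "y", "z")]))^2))
  }, numeric(1))
  errs <- errs[!is.na(errs)]
  expect_gt(length(errs), 5)
  # 72-view tracks at sigma = 0.3 px: well inside one single-pair delta_z
  expect_lt(mean(errs), dz)
})

test_that("initialization from the true geometry starts at the noise level", {
  # distortion-free cameras: the nameplate seed then equals the truth
  sc <- bar_scene(seed = 61, sigma = 0.3, n_steps = 24, step_deg = 15,
                  distortion = c())
  prob <- initialize_turntable(nameplate_config(sc$cams, 15, 24),
                               sc$sim$observations)
  init_rms <- bundle_adjust(prob, max_iter = 0)$rms_px
  expect_equal(init_rms, 0.3, tolerance = 0.1)
})

test_that("initialization validates camera references and coverage", {
  sc <- bar_scene(seed = 3, sigma = 0, n_steps = 6, step_deg = 60)
  cfg <- nameplate_config(sc$cams, 60, 6)
  obs_bad <- sc$sim$observations
  obs_bad$camera_id[1] <- 9
  expect_error(initialize_turntable(cfg, obs_bad), "missing from the studio")
  cfg1 <- cfg; cfg1$cameras <- cfg$cameras[1]
  expect_error(initialize_turntable(cfg1, sc$sim$observations),
               "missing from the studio")
  # a configured camera with no observations is starved
  obs1 <- sc$sim$observations[sc$sim$observations$camera_id == 1, ]
  expect_error(initialize_turntable(cfg, obs1), "insufficient coverage")
})

test_that("a truth-seeded noiseless bundle is a fixed point", {
  sc0 <- bar_scene(seed = 9, sigma = 0, n_steps = 12, step_deg = 30,
                   n_dots = 60)
  truth <- sc0$sim$truth
  prob <- structure(list(
    observations = sc0$sim$observations,
    intrinsics = truth$intrinsics,
    poses = truth$poses,
    points = truth$points[truth$points$id %in%
                            sc0$sim$observations$point_id, ],
    huber_px = 2,
    intrinsic_free = c(f_px = TRUE, cx = TRUE, cy = TRUE, k1 = TRUE,
                       k2 = TRUE, k3 = FALSE, p1 = TRUE, p2 = TRUE),
    turntable_step_deg = 30, n_steps = 12, gauge = "first_pose"),
    class = "bundle_problem")
  sol <- bundle_adjust(prob)
  expect_lt(sol$rms_px, 1e-8)
  expect_true(sol$converged)
  # parameters unchanged (up to the solver's numerical floor)
  expect_equal(sol$intrinsics[[1]]$focal_length_mm, 60, tolerance = 1e-9)
  expect_equal(sol$intrinsics[[1]]$distortion, truth$intrinsics[[1]]$distortion,
               tolerance = 1e-7)
})

test_that("solved noisy bundles settle at the injected noise level", {
  sc <- noisy_fixture()
  expect_true(sc$solution$converged)
  expect_gt(sc$solution$rms_px, 0.25)
  expect_lt(sc$solution$rms_px, 0.35)
  # reported RMS is self-consistent with stored residuals
  r <- sc$solution$residuals
  expect_equal(sc$solution$rms_px,
               sqrt(mean(c(r$dx, r$dy)^2)), tolerance = 1e-12)
  # rotations stay orthonormal through all optimizer updates
  for (k in 1:2) {
    for (p in sc$solution$poses[[k]][c(1, 20, 72)]) {
      expect_lt(max(abs(crossprod(p$rotation) - diag(3))), 1e-10)
      expect_equal(det(p$rotation), 1, tolerance = 1e-12)
    }
  }
  # gauge: the first camera's first-step pose is frozen at its seed
  expect_equal(sc$solution$poses[[1]][[1]]$rotation,
               sc$problem$poses[[1]][[1]]$rotation)
  expect_equal(sc$solution$poses[[1]][[1]]$center_mm,
               sc$problem$poses[[1]][[1]]$center_mm)
})

test_that("self-calibration recovers the true radial distortion", {
  # >= 2 coded targets + >= 100 dots over a full revolution; k1 within 5%
  seeds <- c(101, 202, 303)
  k1_err <- vapply(seeds, function(s) {
    sol <- cached(paste0("selfcal", s),
                  solve_bar_scene(seed = s, sigma = 0.3, n_steps = 36,
                                  step_deg = 10))$solution
    max(abs(vapply(sol$intrinsics, function(ii)
      ii$distortion[["k1"]], numeric(1)) - (-0.08)) / 0.08)
  }, numeric(1))
  expect_lt(max(k1_err), 0.05)
})

test_that("the cost is invariant under a global similarity (gauge freedom)", {
  sc <- bar_scene(seed = 3, sigma = 0.5, n_steps = 6, step_deg = 60,
                  n_dots = 40)
  prob <- initialize_turntable(nameplate_config(sc$cams, 60, 6),
                               sc$sim$observations)
  st <- turnsfm:::ba_state(prob)
  cost_of <- function(s) sum(turnsfm:::ba_residuals(s)^2)
  c0 <- cost_of(st)
  Rg <- rot_from_axis_angle(c(0.2, -0.1, 0.3)); sg <- 1.37; tg <- c(80, -40, 25)
  st2 <- st
  st2$X <- sweep(sg * st$X %*% t(Rg), 2, tg, `+`)
  for (p in seq_len(st$P)) {
    Rp <- matrix(st$Rmat[p, ], 3, 3)
    st2$Rmat[p, ] <- as.vector(Rp %*% t(Rg))
    st2$Cs[p, ] <- sg * as.numeric(Rg %*% st$Cs[p, ]) + tg
  }
  expect_equal(cost_of(st2), c0, tolerance = 1e-9)
})

test_that("outlier rejection prunes mismatches and fixes cleanly", {
  sc <- cached("outlier24",
               solve_bar_scene(seed = 33, sigma = 0.3, outlier_frac = 0.02,
                               n_steps = 24, step_deg = 15))
  sol <- sc$solution
  rho <- sqrt(sol$residuals$dx^2 + sol$residuals$dy^2)
  # threshold at infinity is the identity
  pr_inf <- reject_outliers(sol, Inf)
  expect_equal(nrow(pr_inf$observations), nrow(sol$observations))
  # 3 x mean-norm threshold prunes >= 95% of injected mismatches
  pruned <- reject_outliers(sol, 3.2 * median(rho))
  sol2 <- bundle_adjust(pruned)
  out_key <- with(sc$sim$observations[sc$sim$observations$is_outlier, ],
                  paste(point_id, camera_id, step_index))
  kept_key <- with(sol2$observations, paste(point_id, camera_id, step_index))
  expect_lt(mean(out_key %in% kept_key), 0.05)
  expect_gt(sol2$rms_px, 0.2); expect_lt(sol2$rms_px, 0.4)
  # excessive pruning aborts with a diagnostic
  expect_error(reject_outliers(sol, 1e-9), "aborting")
})

test_that("clean data survives a three-sigma rejection almost untouched", {
  sc <- noisy_fixture()  # 0% injected outliers
  rho <- sqrt(sc$solution$residuals$dx^2 + sc$solution$residuals$dy^2)
  pruned <- reject_outliers(sc$solution, 3 * mean(rho))
  false_prune <- 1 - nrow(pruned$observations) / nrow(sc$solution$observations)
  expect_lte(false_prune, 0.003)
})

test_that("closed-loop residual measures revolution consistency", {
  sc <- noisy_fixture()
  truth <- sc$sim$truth
  truth_sol <- list(poses = truth$poses, turntable_step_deg = 5, n_steps = 72)
  expect_lt(closed_loop_residual(truth_sol, 1), 1e-10)
  expect_lt(closed_loop_residual(sc$solution, 1), 0.05)
  expect_lt(closed_loop_residual(sc$solution, 2), 0.05)
  # breaking the last pose by 5 degrees is reported as ~5 degrees
  broken <- truth_sol
  S <- length(broken$poses[[1]])
  last <- broken$poses[[1]][[S]]
  broken$poses[[1]][[S]] <- camera_pose(last$rotation %*% rot_z(5 * pi / 180),
                                        last$center_mm)
  expect_equal(closed_loop_residual(broken, 1), 5, tolerance = 0.2)
  # an incomplete revolution cannot be checked
  part <- list(poses = list(truth$poses[[1]][1:10]),
               turntable_step_deg = 5, n_steps = 10)
  expect_error(closed_loop_residual(part, 1), "full revolution")
})

test_that("analytic Jacobians match central finite differences", {
  sc <- bar_scene(seed = 3, sigma = 0.5, n_steps = 3, step_deg = 45,
                  n_dots = 20, bar_height = 600,
                  distortion = c(k1 = -0.05, k2 = 0.008, p1 = 1e-4,
                                 p2 = -2e-4))
  prob <- initialize_turntable(nameplate_config(sc$cams, 45, 3),
                               sc$sim$observations)
  st <- turnsfm:::ba_state(prob)
  lay <- turnsfm:::ba_layout(st, prob$intrinsic_free, fixed_pose = 1L)
  J <- turnsfm:::ba_jacobian(st, lay)
  eps <- 1e-6
  set.seed(44)
  for (j in sample(lay$n_par, 50)) {
    d <- numeric(lay$n_par); d[j] <- eps
    rp <- turnsfm:::ba_residuals(turnsfm:::ba_apply_step(st, lay, d))
    rm_ <- turnsfm:::ba_residuals(turnsfm:::ba_apply_step(st, lay, -d))
    fd <- (rp - rm_) / (2 * eps)
    expect_lt(max(abs(fd - as.numeric(J[, j]))) / max(abs(fd), 1e-3), 1e-5)
  }
})

test_that("triangulate_tracks reconstructs tracks against fixed cameras", {
  sc <- bar_scene(seed = 12, sigma = 0, n_steps = 12, step_deg = 30,
                  n_dots = 30)
  truth <- sc$sim$truth
  pts <- triangulate_tracks(sc$sim$observations, truth$poses,
                            truth$intrinsics)
  m <- match(pts$id, truth$points$id)
  err <- sqrt(rowSums((as.matrix(pts[, c("x", "y", "z")]) -
                       as.matrix(truth$points[m, c("x", "y", "z")]))^2))
  expect_lt(max(err), 1e-6)
})
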