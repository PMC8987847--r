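# Shared fixture builders. Everything is generated in code at test time;
# expensive solves are cached per session so several tests can share one.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Mid-size working distance (H0 = 2300 mm, f = 60 mm, pitch 3.91 um) with an
# upper camera looking down and a lower camera looking up at an overlapping
# band of the measurement volume.
mid_rig <- function(distortion = c(k1 = -0.08, k2 = 0.01,
                                   p1 = 2e-4, p2 = -1e-4)) {
  intr <- camera_intrinsics(60, 3.91, c(6000, 4000), distortion = distortion)
  list(camera_at(intr, 2300, 1372, 25),
       camera_at(intr, 2300, 95, -10))
}

nameplate_config <- function(cams, step_deg, n_steps) {
  list(cameras = lapply(cams, function(cc) {
    ii <- cc$intrinsics
    list(intrinsics = camera_intrinsics(ii$focal_length_mm, ii$pixel_pitch_um,
                                        ii$sensor_px),
         base_pose = cc$base_pose)
  }), H0_mm = 2300, turntable_step_deg = step_deg, n_steps = n_steps)
}

bar_scene <- function(seed, sigma = 0.3, outlier_frac = 0,
                      step_deg = 5, n_steps = 72, n_dots = 150,
                      bar_height = 800, markers = NULL,
                      distortion = c(k1 = -0.08, k2 = 0.01,
                                     p1 = 2e-4, p2 = -1e-4)) {
  cams <- mid_rig(distortion)
  spec <- scene_spec(cams, turntable_step_deg = step_deg, n_steps = n_steps,
                     bar = list(n_dots = n_dots, height_mm = bar_height),
                     markers = markers,
                     noise = list(sigma_px = sigma,
                                  outlier_frac = outlier_frac),
                     seed = seed)
  list(cams = cams, spec = spec, sim = simulate_capture(spec))
}

solve_bar_scene <- function(seed, sigma = 0.3, outlier_frac = 0, ...) {
  sc <- bar_scene(seed, sigma, outlier_frac, ...)
  prob <- initialize_turntable(
    nameplate_config(sc$cams, sc$spec$turntable_step_deg, sc$spec$n_steps),
    sc$sim$observations)
  sol <- bundle_adjust(prob)
  c(sc, list(problem = prob, solution = sol))
}

# one moderately sized noisy solved scene shared across test files
noisy_fixture <- function() {
  cached("noisy72", solve_bar_scene(seed = 21, sigma = 0.3))
}

# small rendering camera for detector tests
render_cam <- function() {
  list(intr = camera_intrinsics(8, 10, c(400, 300)),
       pose = look_at_pose(c(500, 0, 100), c(0, 0, 100)))
}
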