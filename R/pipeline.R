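#' End-to-end reconstruction pipeline
#'
#' Orchestrates simulate -> initialize -> bundle-adjust -> reject/re-adjust
#' -> closed-loop diagnostics -> metric scaling -> per-camera clouds ->
#' background-mask filtering -> merge -> length evaluation, writing every
#' stage artifact plus a JSON-lines log into a run directory. Identical
#' config and seed give identical outputs; per-camera stages are
#' independent of each other and of execution order.
#'
#' @param config a run configuration list (see Details) or the path to a
#'   YAML file holding one
#' @param out_dir output directory (created); overrides `config$out_dir`
#'
#' @details The configuration mirrors the studio layout plus solver knobs:
#' \describe{
#'   \item{seed}{integer; all stochastic stages derive from it}
#'   \item{studio}{`H0_mm`, `turntable_step_deg`, `n_steps`, `s_deg`, and
#'     `cameras`: a list of `mount_height_mm`, `tilt_deg`, `f_mm`,
#'     `pixel_pitch_um`, `sensor_px`, optional `distortion`}
#'   \item{bar, plant, noise}{passed to [scene_spec()]}
#'   \item{init}{optional initialization perturbation (`pose_deg`,
#'     `focal_frac`) and `intrinsic_free` overrides, e.g.
#'     `list(intrinsic_free = FALSE)` to hold nameplate intrinsics fixed}
#'   \item{solver}{`huber_px`, `tol`, `max_iter`, `outlier_threshold_px`,
#'     `reject_rounds`}
#'   \item{merge}{`min_votes`, `voxel_mm`, `mask_downsample`}
#' }
#' @return list with the solution, scale fit, merged cloud, length report,
#'   residual map, closed-loop residuals and the run directory path
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.jsonl")
  unlink(log_path)
  log_stage <- function(stage, ...) {
    entry <- list(stage = stage, elapsed_s = NULL, ...)
    cat(jsonlite::toJSON(entry[!vapply(entry, is.null, logical(1))],
                         auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  fail <- function(stage, msg) {
    log_stage(stage, error = msg)
    stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
  }
  if (is.null(config$seed)) fail("config", "seed is mandatory")
  st <- config$studio
  if (is.null(st)) fail("config", "studio section missing")

  # --- scene ---------------------------------------------------------------
  cams <- lapply(st$cameras, function(cc) {
    intr <- camera_intrinsics(cc$f_mm, cc$pixel_pitch_um,
                              unlist(cc$sensor_px),
                              distortion = unlist(cc$distortion))
    camera_at(intr, st$H0_mm, cc$mount_height_mm, cc$tilt_deg)
  })
  spec <- scene_spec(cams, turntable_step_deg = st$turntable_step_deg,
                     n_steps = if (is.null(st$n_steps))
                       round(360 / st$turntable_step_deg) else st$n_steps,
                     bar = if (is.null(config$bar)) list() else config$bar,
                     plant = config$plant, markers = config$markers,
                     noise = if (is.null(config$noise)) list() else config$noise,
                     seed = config$seed)
  sim <- simulate_capture(spec)
  write_observations(sim$observations[, c("point_id", "camera_id",
                                          "step_index", "x_px", "y_px",
                                          "target_code")],
                     file.path(out_dir, "observations.csv"))
  log_stage("simulate", n_observations = nrow(sim$observations),
            n_points = nrow(sim$truth$points),
            n_frames = length(spec$cameras) * spec$n_steps)

  # --- initialize ----------------------------------------------------------
  init_cfg <- config$init
  init_cams <- cams
  if (!is.null(init_cfg$pose_deg) && init_cfg$pose_deg != 0) {
    init_cams <- with_seed(config$seed + 7L, lapply(cams, function(cc) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      Rp <- rot_from_axis_angle(ax * deg2rad(init_cfg$pose_deg))
      cc$base_pose <- camera_pose(cc$base_pose$rotation %*% Rp,
                                  cc$base_pose$center_mm)
      cc
    }))
  }
  if (!is.null(init_cfg$focal_frac) && init_cfg$focal_frac != 0) {
    init_cams <- lapply(init_cams, function(cc) {
      ii <- cc$intrinsics
      cc$intrinsics <- camera_intrinsics(
        ii$focal_length_mm * (1 + init_cfg$focal_frac), ii$pixel_pitch_um,
        ii$sensor_px, ii$principal_point_px)
      cc
    })
  } else {
    # nameplate guess: no distortion, principal point at sensor center
    init_cams <- lapply(init_cams, function(cc) {
      ii <- cc$intrinsics
      cc$intrinsics <- camera_intrinsics(ii$focal_length_mm,
                                         ii$pixel_pitch_um, ii$sensor_px)
      cc
    })
  }
  sol_cfg <- config$solver
  huber <- if (is.null(sol_cfg$huber_px)) 2 else sol_cfg$huber_px
  ifree <- c(f_px = TRUE, cx = TRUE, cy = TRUE, k1 = TRUE, k2 = TRUE,
             k3 = FALSE, p1 = TRUE, p2 = TRUE)
  if (!is.null(init_cfg$intrinsic_free)) {
    if (is.logical(init_cfg$intrinsic_free) &&
        length(init_cfg$intrinsic_free) == 1) {
      ifree[] <- init_cfg$intrinsic_free
    } else ifree[names(init_cfg$intrinsic_free)] <-
        unlist(init_cfg$intrinsic_free)
  }
  problem <- tryCatch(
    initialize_turntable(list(cameras = init_cams, H0_mm = st$H0_mm,
                              turntable_step_deg = st$turntable_step_deg,
                              n_steps = spec$n_steps),
                         sim$observations, huber_px = huber,
                         intrinsic_free = ifree),
    error = function(e) fail("initialize", conditionMessage(e)))
  log_stage("initialize", n_tracks = nrow(problem$points))

  # --- bundle adjustment + outlier rejection -------------------------------
  tol <- if (is.null(sol_cfg$tol)) 1e-10 else sol_cfg$tol
  max_iter <- if (is.null(sol_cfg$max_iter)) 100 else sol_cfg$max_iter
  sol <- bundle_adjust(problem, tol = tol, max_iter = max_iter)
  rounds <- if (is.null(sol_cfg$reject_rounds)) 2 else sol_cfg$reject_rounds
  for (r in seq_len(rounds)) {
    # robust threshold: 3.2 x median residual norm (~ 3 x the Rayleigh mean)
    rho <- sqrt(sol$residuals$dx^2 + sol$residuals$dy^2)
    thr <- if (is.null(sol_cfg$outlier_threshold_px))
      max(3.2 * stats::median(rho), 1e-6) else sol_cfg$outlier_threshold_px
    pruned <- reject_outliers(sol, thr)
    if (nrow(pruned$observations) == nrow(sol$observations)) break
    sol <- bundle_adjust(pruned, tol = tol, max_iter = max_iter)
  }
  log_stage("bundle", rms_px = sol$rms_px, converged = sol$converged,
            iterations = sol$iterations,
            n_observations = nrow(sol$observations))
  if (!sol$converged) fail("bundle", "bundle adjustment did not converge")
  utils::write.csv(sol$residuals, file.path(out_dir, "residuals.csv"),
                   row.names = FALSE, quote = FALSE)

  loop <- vapply(seq_along(sol$intrinsics), function(k)
    closed_loop_residual(sol, k), numeric(1))
  log_stage("closed_loop", residual_deg = loop)

  # --- metric scale --------------------------------------------------------
  refs <- config$reference_distances
  if (is.null(refs)) refs <- sim$truth$reference_distances
  refs <- as.data.frame(refs)
  if (!nrow(refs)) fail("scale", "no reference distances configured")
  sc <- tryCatch(fit_scale(sol, refs),
                 error = function(e) fail("scale", conditionMessage(e)))
  log_stage("scale", scale = sc$scale,
            mean_pair_error_mm = mean(sc$pair_errors_mm))
  write_cameras(list(intrinsics = sc$solution$intrinsics,
                     poses = sc$solution$poses),
                file.path(out_dir, "cameras.json"))

  # --- per-camera clouds, masks, merge -------------------------------------
  mg <- config$merge
  ds <- if (is.null(mg$mask_downsample)) 8 else mg$mask_downsample
  min_votes <- if (is.null(mg$min_votes)) 2 else mg$min_votes
  geom <- studio_geometry(st$H0_mm, st$cameras[[1]]$tilt_deg,
                          st$cameras[[1]]$f_mm, st$cameras[[1]]$pixel_pitch_um,
                          s_deg = if (is.null(st$s_deg)) 15 else st$s_deg,
                          turntable_step_deg = st$turntable_step_deg)
  voxel <- if (is.null(mg$voxel_mm)) geom$delta_xy_mm else mg$voxel_mm
  truth_scaled <- sim$truth
  masks <- generate_masks(truth_scaled, downsample = ds)
  obs <- sol$observations
  kinds <- sim$truth$points$kind[match(sol$points$id, sim$truth$points$id)]
  per_cam <- lapply(seq_along(sol$intrinsics), function(k) {
    ok <- obs$camera_id == k
    tc <- table(obs$point_id[ok])
    ids <- as.numeric(names(tc)[tc >= 2])
    Xs <- lapply(ids, function(id) {
      trk <- obs[ok & obs$point_id == id, ]
      tryCatch(triangulate(trk, sc$solution$poses, sc$solution$intrinsics),
               error = function(e) NULL)
    })
    got <- !vapply(Xs, is.null, logical(1))
    pts <- data.frame(id = ids[got], do.call(rbind, Xs[got]))
    names(pts) <- c("id", "x", "y", "z")
    pts$kind <- sim$truth$points$kind[match(pts$id, sim$truth$points$id)]
    cl <- scene_point_cloud(pts, camera_id = k, scale_applied = TRUE)
    apply_background_mask(cl, masks, sc$solution$poses,
                          sc$solution$intrinsics, min_votes = min_votes)
  })
  merged <- merge_clouds(per_cam, radius_mm = voxel)
  write_ply(merged, file.path(out_dir, "cloud.ply"))
  log_stage("merge", n_points = nrow(merged$points), voxel_mm = voxel)

  # --- evaluation ----------------------------------------------------------
  bundle_cloud <- scene_point_cloud(
    cbind(sc$solution$points, camera_id = NA)[, c("id", "x", "y", "z", "kind")],
    scale_applied = TRUE)
  marker_pairs <- if (!is.null(sim$truth$marker_pairs))
    sim$truth$marker_pairs else
    data.frame(id_a = refs$id_a, id_b = refs$id_b, true_mm = refs$distance_mm)
  report <- evaluate_lengths(bundle_cloud, marker_pairs)
  write_length_report(report, file.path(out_dir, "lengths.csv"))
  bar_ids <- sim$truth$points$id[sim$truth$points$kind %in%
                                   c("random_dot")]
  bar_ids <- c(bar_ids, sim$truth$target_codes$id)
  rmap <- residual_map(sol, point_ids = bar_ids)
  write_residual_map(rmap, file.path(out_dir, "residual_map.csv"))
  log_stage("evaluate", mean_abs_error_mm = report$mean_abs_error_mm,
            n_pairs = report$n_pairs)
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(solution = sol, scale = sc, cloud = merged,
                 lengths = report, residual_map = rmap,
                 closed_loop_deg = loop, truth = sim$truth,
                 out_dir = out_dir))
}

#' Studio settings report
#'
#' Thin wrapper over [plan_cameras()]: computes the per-camera settings
#' table (height, angle, per-camera planar and depth resolution) for a
#' studio configuration and optionally writes it as CSV.
#'
#' @param studio list: `plant_height_mm`, `target_resolution_mm`, `H0_mm`,
#'   `f_mm`, `pixel_pitch_um`, `sensor_px`, `tilt_upper_deg`,
#'   `tilt_lower_deg`, `n_cameras`, `s_deg`, `turntable_step_deg`
#' @param path optional CSV output path
#' @return the `camera_plan`
#' @export
plan_command <- function(studio, path = NULL) {
  if (is.character(studio)) studio <- yaml::read_yaml(studio)
  need <- c("plant_height_mm", "target_resolution_mm", "H0_mm", "f_mm",
            "pixel_pitch_um")
  miss <- setdiff(need, names(studio))
  if (length(miss))
    stop("studio config missing fields: ", paste(miss, collapse = ", "))
  intr <- camera_intrinsics(studio$f_mm, studio$pixel_pitch_um,
                            if (is.null(studio$sensor_px)) c(6000, 4000)
                            else unlist(studio$sensor_px))
  plan <- plan_cameras(
    studio$plant_height_mm, studio$target_resolution_mm, intr, studio$H0_mm,
    tilt_upper_deg = if (is.null(studio$tilt_upper_deg)) 25
      else studio$tilt_upper_deg,
    tilt_lower_deg = if (is.null(studio$tilt_lower_deg)) -25
      else studio$tilt_lower_deg,
    s_deg = if (is.null(studio$s_deg)) 15 else studio$s_deg,
    turntable_step_deg = if (is.null(studio$turntable_step_deg)) 5
      else studio$turntable_step_deg,
    n_cameras = studio$n_cameras)
  if (!is.null(path)) write_plan(plan, path)
  plan
}
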