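#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic turntable studio scene
#'
#' Describes everything the simulator needs to emulate a capture session:
#' the measurement bar (pillars carrying circular coded targets at known
#' spacings plus a random-dot texture), a parametric plant, the camera set
#' with its turntable motion, and the detection noise model. The measurement
#' bar sits on the turntable and rotates with the plant; all coordinates are
#' in the object (turntable) frame, millimeters, +Z up.
#'
#' @param cameras list of per-camera lists, each with elements `intrinsics`
#'   (a [camera_intrinsics()]) and `base_pose` (a [camera_pose()] at step 0)
#' @param turntable_step_deg rotation increment per frame (degrees)
#' @param n_steps number of frames per camera (default: one full revolution)
#' @param bar list: `pillar_radius_mm` distance of pillars from the axis,
#'   `n_pillars`, `height_mm` bar height, `targets_per_pillar` coded targets
#'   spaced evenly over the height, `n_dots` random dots over all pillars,
#'   `pillar_halfwidth_mm` half-width of the square pillar cross-section,
#'   `target_radius_mm` physical outer radius of each coded target
#' @param plant list passed to [build_plant()] (NULL for a bar-only scene)
#' @param markers NULL, or a list describing evaluation rulers at the table
#'   center (`n_points`, `height_mm`, `radius_mm`): marker points with known
#'   inter-marker distances used for length-accuracy evaluation, independent
#'   of the calibration bar
#' @param noise list: `sigma_px` Gaussian detection noise, `outlier_frac`
#'   fraction of detections replaced by uniform mismatches,
#'   `outlier_px` unused (outliers are uniform over the sensor)
#' @param seed integer seed; fixed seed gives identical scenes
#' @return an object of class `scene_spec`
#' @export
scene_spec <- function(cameras, turntable_step_deg = 5,
                       n_steps = round(360 / turntable_step_deg),
                       bar = list(), plant = NULL, markers = NULL,
                       noise = list(), seed = 1) {
  stopifnot(length(cameras) >= 1)
  for (cam in cameras) {
    stopifnot(inherits(cam$intrinsics, "camera_intrinsics"),
              inherits(cam$base_pose, "camera_pose"))
  }
  bar_def <- list(pillar_radius_mm = 450, n_pillars = 4, height_mm = 1000,
                  targets_per_pillar = 3, n_dots = 160,
                  pillar_halfwidth_mm = 25, target_radius_mm = 20)
  bar_def[names(bar)] <- bar
  noise_def <- list(sigma_px = 0.3, outlier_frac = 0.02)
  noise_def[names(noise)] <- noise
  if (bar_def$n_pillars * bar_def$targets_per_pillar < 2)
    stop("the bar needs at least 2 coded targets to carry a reference distance")
  if (!is.null(markers)) {
    mk_def <- list(n_points = 7, height_mm = 1000, radius_mm = 120)
    mk_def[names(markers)] <- markers
    markers <- mk_def
  }
  structure(list(cameras = cameras, turntable_step_deg = turntable_step_deg,
                 n_steps = as.integer(n_steps), bar = bar_def,
                 plant = plant, markers = markers, noise = noise_def,
                 seed = seed),
            class = "scene_spec")
}

# evaluation rulers: two vertical lines of marker points near the table
# center, known spacings, reconstructed by the bundle like any other point
build_markers <- function(markers, id_offset = 0L) {
  n <- markers$n_points
  z <- markers$height_mm * (seq_len(n) - 0.5) / n
  xyz <- rbind(cbind(markers$radius_mm, 0, z),
               cbind(-markers$radius_mm, 0, z))
  pts <- new_point_set(id_offset + seq_len(2 * n), xyz, "coded_target_center")
  pairs <- list()
  for (s in 0:1) {
    ids <- pts$id[s * n + seq_len(n)]
    for (j in seq_len(n - 1))
      pairs[[length(pairs) + 1L]] <- c(ids[j], ids[j + 1])
    pairs[[length(pairs) + 1L]] <- c(ids[1], ids[n])
  }
  pr <- do.call(rbind, pairs)
  d <- sqrt(rowSums((xyz[match(pr[, 1], pts$id), , drop = FALSE] -
                     xyz[match(pr[, 2], pts$id), , drop = FALSE])^2))
  list(points = pts,
       marker_pairs = data.frame(id_a = pr[, 1], id_b = pr[, 2],
                                 true_mm = d))
}

#' Build the measurement bar point set
#'
#' Vertical pillars at fixed radius around the turntable, each carrying
#' coded targets at known heights (exact coordinates) and a share of
#' random dots scattered over its outward-facing surface. Reference
#' distances are the true Euclidean distances between consecutive targets
#' on each pillar, the lengths the coded targets make measurable.
#'
#' @param spec a `scene_spec`
#' @return list with `points` (data.frame id, x, y, z, kind),
#'   `target_codes` (data.frame id, target_code, normal angle),
#'   `reference_distances` (data.frame id_a, id_b, distance_mm)
#' @export
build_measurement_bar <- function(spec) {
  b <- spec$bar
  n_targets <- b$n_pillars * b$targets_per_pillar
  if (n_targets < 2) stop("fewer than 2 coded targets on the bar")
  with_seed(spec$seed, {
    az <- 2 * pi * (seq_len(b$n_pillars) - 1) / b$n_pillars
    # coded-target centers: evenly spaced up each pillar, on the outward face
    tz <- b$height_mm * (seq_len(b$targets_per_pillar) - 0.5) / b$targets_per_pillar
    face_r <- b$pillar_radius_mm + b$pillar_halfwidth_mm
    tgt <- do.call(rbind, lapply(seq_len(b$n_pillars), function(p) {
      cbind(face_r * cos(az[p]), face_r * sin(az[p]), tz,
            p, seq_len(b$targets_per_pillar))
    }))
    tgt_ids <- seq_len(nrow(tgt))
    # random dots on the outward faces, uniform over height and face width
    nd <- b$n_dots
    dp <- sample.int(b$n_pillars, nd, replace = TRUE)
    du <- stats::runif(nd, -b$pillar_halfwidth_mm, b$pillar_halfwidth_mm)
    dz <- stats::runif(nd, 0, b$height_mm)
    # tangential direction of each pillar's face
    tx <- -sin(az[dp]); ty <- cos(az[dp])
    dot_xyz <- cbind(face_r * cos(az[dp]) + du * tx,
                     face_r * sin(az[dp]) + du * ty,
                     dz)
    dot_ids <- nrow(tgt) + seq_len(nd)
    points <- rbind(
      new_point_set(tgt_ids, tgt[, 1:3], "coded_target_center"),
      new_point_set(dot_ids, dot_xyz, "random_dot"))
    target_codes <- data.frame(id = tgt_ids,
                               target_code = tgt_ids,
                               azimuth_rad = az[tgt[, 4]])
    # reference distances: consecutive targets on each pillar, plus the
    # bottom-target chord between neighboring pillars
    refs <- list()
    for (p in seq_len(b$n_pillars)) {
      ids <- tgt_ids[tgt[, 4] == p]
      if (length(ids) >= 2) {
        for (j in seq_len(length(ids) - 1))
          refs[[length(refs) + 1L]] <- c(ids[j], ids[j + 1])
      }
    }
    if (b$n_pillars >= 2) {
      first_per_pillar <- vapply(seq_len(b$n_pillars),
                                 function(p) tgt_ids[tgt[, 4] == p][1], numeric(1))
      for (p in seq_len(b$n_pillars - 1))
        refs[[length(refs) + 1L]] <- c(first_per_pillar[p], first_per_pillar[p + 1])
    }
    if (!length(refs)) {
      refs[[1]] <- tgt_ids[1:2]
    }
    rd <- do.call(rbind, refs)
    xyz <- point_xyz(points)
    d <- sqrt(rowSums((xyz[rd[, 1], , drop = FALSE] -
                       xyz[rd[, 2], , drop = FALSE])^2))
    list(points = points,
         target_codes = target_codes,
         reference_distances = data.frame(id_a = rd[, 1], id_b = rd[, 2],
                                          distance_mm = d))
  })
}

#' Build a parametric plant point set
#'
#' Surface samples of a simple plant: a cylindrical stem plus elliptical
#' leaf discs attached at phyllotaxis angles up the stem. Geometric
#' complexity is enough for visibility, masking and merging tests without a
#' renderer; it does not emulate real leaf shape or texture.
#'
#' @param plant list: `height_mm` stem height, `stem_radius_mm`,
#'   `n_leaves`, `leaf_length_mm`, `leaf_width_mm`,
#'   `phyllotaxis_deg` azimuth increment between leaves (default 137.5),
#'   `density_per_mm2` surface sample density
#' @param seed integer seed
#' @param id_offset first point id minus one
#' @return data.frame of `plant_surface` points
#' @export
build_plant <- function(plant, seed = 1, id_offset = 0L) {
  p <- list(height_mm = 1000, stem_radius_mm = 8, n_leaves = 6,
            leaf_length_mm = 180, leaf_width_mm = 90,
            phyllotaxis_deg = 137.5, density_per_mm2 = 0.002)
  p[names(plant)] <- plant
  with_seed(seed, {
    stem_area <- 2 * pi * p$stem_radius_mm * p$height_mm
    n_stem <- max(1L, round(stem_area * p$density_per_mm2))
    a <- stats::runif(n_stem, 0, 2 * pi)
    z <- stats::runif(n_stem, 0, p$height_mm)
    stem <- cbind(p$stem_radius_mm * cos(a), p$stem_radius_mm * sin(a), z)
    leaves <- NULL
    if (p$n_leaves > 0) {
      leaf_area <- pi * (p$leaf_length_mm / 2) * (p$leaf_width_mm / 2)
      n_leaf <- max(1L, round(leaf_area * p$density_per_mm2))
      leaves <- do.call(rbind, lapply(seq_len(p$n_leaves), function(i) {
        az <- deg2rad((i - 1) * p$phyllotaxis_deg)
        hz <- p$height_mm * i / (p$n_leaves + 1)
        droop <- deg2rad(20)  # leaves angle slightly downward
        # uniform samples on the unit disc -> ellipse in the leaf plane
        r <- sqrt(stats::runif(n_leaf)); t <- stats::runif(n_leaf, 0, 2 * pi)
        u <- r * cos(t) * p$leaf_length_mm / 2 + p$leaf_length_mm / 2
        v <- r * sin(t) * p$leaf_width_mm / 2
        # leaf axes: e1 radial (drooping), e2 tangential
        e1 <- c(cos(az) * cos(droop), sin(az) * cos(droop), -sin(droop))
        e2 <- c(-sin(az), cos(az), 0)
        base <- c(p$stem_radius_mm * cos(az), p$stem_radius_mm * sin(az), hz)
        cbind(base[1] + u * e1[1] + v * e2[1],
              base[2] + u * e1[2] + v * e2[2],
              base[3] + u * e1[3] + v * e2[3])
      }))
    }
    xyz <- rbind(stem, leaves)
    xyz[, 3] <- pmin(xyz[, 3], p$height_mm)  # declared height bound
    xyz[, 3] <- pmax(xyz[, 3], 0)
    new_point_set(id_offset + seq_len(nrow(xyz)), xyz, "plant_surface")
  })
}

#' Simulate a multi-camera turntable capture
#'
#' Projects every scene point through the true intrinsics and per-step true
#' poses of every camera, drops points behind the camera or outside the
#' sensor, adds Gaussian detection noise, and replaces a fraction of
#' detections with uniform outliers (emulating feature mismatches).
#' Correspondence is simulated as solved: a track is all detections of one
#' physical point.
#'
#' @param spec a `scene_spec`
#' @return list with `observations` (data.frame point_id, camera_id,
#'   step_index, x_px, y_px, target_code, is_outlier) and `truth` (list:
#'   `points`, `intrinsics`, `poses` (list per camera of per-step
#'   `camera_pose`), `reference_distances`, `target_codes`,
#'   `noiseless` observations)
#' @export
simulate_capture <- function(spec) {
  bar <- build_measurement_bar(spec)
  points <- bar$points
  marker_pairs <- NULL
  if (!is.null(spec$markers)) {
    mk <- build_markers(spec$markers, id_offset = max(points$id))
    points <- rbind(points, mk$points)
    marker_pairs <- mk$marker_pairs
  }
  if (!is.null(spec$plant)) {
    plant <- build_plant(spec$plant, seed = spec$seed + 1L,
                         id_offset = max(points$id))
    points <- rbind(points, plant)
  }
  xyz <- point_xyz(points)
  n_cam <- length(spec$cameras)
  poses <- lapply(seq_len(n_cam), function(k) {
    lapply(seq_len(spec$n_steps) - 1L, function(j)
      turntable_pose(spec$cameras[[k]]$base_pose, j, spec$turntable_step_deg))
  })
  obs_list <- vector("list", n_cam * spec$n_steps)
  idx <- 0L
  for (k in seq_len(n_cam)) {
    intr <- spec$cameras[[k]]$intrinsics
    w <- intr$sensor_px[1]; h <- intr$sensor_px[2]
    for (j in seq_len(spec$n_steps)) {
      px <- project_points(xyz, poses[[k]][[j]], intr, behind = "na")
      vis <- !is.na(px[, 1]) &
        px[, 1] >= 0 & px[, 1] <= w & px[, 2] >= 0 & px[, 2] <= h
      idx <- idx + 1L
      if (!any(vis)) {
        warning(sprintf("no point visible for camera %d step %d; frame kept empty",
                        k, j - 1L))
        next
      }
      obs_list[[idx]] <- data.frame(
        point_id = points$id[vis], camera_id = k, step_index = j - 1L,
        x_px = px[vis, 1], y_px = px[vis, 2])
    }
  }
  noiseless <- do.call(rbind, obs_list)
  tc <- bar$target_codes$target_code[match(noiseless$point_id,
                                           bar$target_codes$id)]
  noiseless$target_code <- tc
  obs <- noiseless
  with_seed(spec$seed + 2L, {
    n <- nrow(obs)
    if (spec$noise$sigma_px > 0) {
      obs$x_px <- obs$x_px + stats::rnorm(n, 0, spec$noise$sigma_px)
      obs$y_px <- obs$y_px + stats::rnorm(n, 0, spec$noise$sigma_px)
    }
    obs$is_outlier <- FALSE
    if (spec$noise$outlier_frac > 0) {
      n_out <- round(spec$noise$outlier_frac * n)
      if (n_out > 0) {
        pick <- sample.int(n, n_out)
        for (k in seq_len(n_cam)) {
          sel <- pick[obs$camera_id[pick] == k]
          if (!length(sel)) next
          sp <- spec$cameras[[k]]$intrinsics$sensor_px
          obs$x_px[sel] <- stats::runif(length(sel), 0, sp[1])
          obs$y_px[sel] <- stats::runif(length(sel), 0, sp[2])
        }
        obs$is_outlier[pick] <- TRUE
      }
    }
  })
  list(observations = obs,
       truth = list(points = points,
                    intrinsics = lapply(spec$cameras, `[[`, "intrinsics"),
                    poses = poses,
                    reference_distances = bar$reference_distances,
                    marker_pairs = marker_pairs,
                    target_codes = bar$target_codes,
                    noiseless = noiseless))
}
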