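#' Camera intrinsics
#'
#' Interior orientation of one physical camera: principal distance (focal
#' length), principal point, pixel pitch, sensor size, and Brown-Conrady
#' lens distortion (radial k1, k2, k3; tangential p1, p2). Units are
#' millimeters for the focal length, micrometers for the pixel pitch, and
#' pixels for sensor dimensions and principal point.
#'
#' @param focal_length_mm principal distance in mm (> 0)
#' @param pixel_pitch_um sensor pixel size in micrometers (> 0)
#' @param sensor_px integer 2-vector, sensor width and height in pixels
#' @param principal_point_px 2-vector in pixels; defaults to sensor center
#' @param distortion named numeric vector with elements k1, k2, k3, p1, p2
#' @return an object of class `camera_intrinsics`
#' @examples
#' intr <- camera_intrinsics(60, 3.91, c(6000, 4000))
#' focal_px(intr)
#' @export
camera_intrinsics <- function(focal_length_mm, pixel_pitch_um,
                              sensor_px = c(6000, 4000),
                              principal_point_px = sensor_px / 2,
                              distortion = c(k1 = 0, k2 = 0, k3 = 0,
                                             p1 = 0, p2 = 0)) {
  stopifnot(is.numeric(focal_length_mm), length(focal_length_mm) == 1,
            focal_length_mm > 0)
  stopifnot(is.numeric(pixel_pitch_um), length(pixel_pitch_um) == 1,
            pixel_pitch_um > 0)
  stopifnot(length(sensor_px) == 2, all(sensor_px > 0))
  stopifnot(length(principal_point_px) == 2)
  d <- c(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0)
  if (length(distortion)) {
    if (is.null(names(distortion))) {
      stopifnot(length(distortion) <= 5)
      names(distortion) <- c("k1", "k2", "k3", "p1", "p2")[seq_along(distortion)]
    }
    stopifnot(all(names(distortion) %in% names(d)))
    d[names(distortion)] <- distortion
  }
  structure(list(focal_length_mm = focal_length_mm,
                 pixel_pitch_um = pixel_pitch_um,
                 sensor_px = as.numeric(sensor_px),
                 principal_point_px = as.numeric(principal_point_px),
                 distortion = d),
            class = "camera_intrinsics")
}

#' Principal distance in pixel units
#' @param intr a `camera_intrinsics` object
#' @export
focal_px <- function(intr) {
  intr$focal_length_mm / (intr$pixel_pitch_um * 1e-3)
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: f = %.3f mm (%.1f px), pitch = %.3f um, sensor %d x %d px\n",
              x$focal_length_mm, focal_px(x), x$pixel_pitch_um,
              x$sensor_px[1], x$sensor_px[2]))
  cat(sprintf("  principal point (%.2f, %.2f) px; distortion k1=%.2e k2=%.2e k3=%.2e p1=%.2e p2=%.2e\n",
              x$principal_point_px[1], x$principal_point_px[2],
              x$distortion["k1"], x$distortion["k2"], x$distortion["k3"],
              x$distortion["p1"], x$distortion["p2"]))
  invisible(x)
}

#' Camera pose (exterior orientation)
#'
#' Rotation maps object-frame coordinates to the camera frame
#' (`x_cam = R (X - C)`); `center_mm` is the camera center C in the object
#' frame. The object frame is right-handed, origin at the turntable center,
#' +Z up along the rotation axis, millimeters throughout.
#'
#' @param rotation 3x3 orthonormal matrix, det +1
#' @param center_mm camera center, 3-vector in mm
#' @return an object of class `camera_pose`
#' @export
camera_pose <- function(rotation, center_mm) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(center_mm) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation has negative determinant")
  structure(list(rotation = rotation, center_mm = as.numeric(center_mm)),
            class = "camera_pose")
}

#' @export
print.camera_pose <- function(x, ...) {
  aa <- axis_angle_from_rot(x$rotation)
  cat(sprintf("camera_pose: center (%.1f, %.1f, %.1f) mm, axis-angle (%.4f, %.4f, %.4f) rad\n",
              x$center_mm[1], x$center_mm[2], x$center_mm[3],
              aa[1], aa[2], aa[3]))
  invisible(x)
}

#' Pose of a camera looking at a point
#'
#' Builds the exterior orientation of a camera at `center_mm` whose optical
#' axis passes through `target_mm`, with the image x-axis horizontal.
#'
#' @param center_mm camera center (mm)
#' @param target_mm point on the optical axis (mm)
#' @return a `camera_pose`
#' @export
look_at_pose <- function(center_mm, target_mm) {
  z <- target_mm - center_mm
  nz <- sqrt(sum(z^2))
  if (nz < 1e-9) stop("target coincides with camera center")
  z <- z / nz
  up <- c(0, 0, 1)
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("optical axis parallel to the turntable axis")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  camera_pose(rbind(x, y, z, deparse.level = 0), center_mm)
}

#' Apply Brown-Conrady distortion to normalized image coordinates
#'
#' @param xy n x 2 matrix of undistorted normalized coordinates
#' @param distortion named vector k1, k2, k3, p1, p2
#' @return n x 2 matrix of distorted normalized coordinates
#' @export
apply_distortion <- function(xy, distortion) {
  xy <- rbind(xy)
  x <- xy[, 1]; y <- xy[, 2]
  k1 <- distortion[["k1"]]; k2 <- distortion[["k2"]]; k3 <- distortion[["k3"]]
  p1 <- distortion[["p1"]]; p2 <- distortion[["p2"]]
  r2 <- x^2 + y^2
  rad <- 1 + r2 * (k1 + r2 * (k2 + r2 * k3))
  cbind(x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x^2),
        y * rad + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y)
}

#' Invert Brown-Conrady distortion
#'
#' Fixed-point iteration refined by a Newton step; converges for radii within
#' the model's monotone region.
#'
#' @param xy_d n x 2 matrix of distorted normalized coordinates
#' @param distortion named vector k1, k2, k3, p1, p2
#' @param tol convergence tolerance on the forward-model residual
#' @param max_iter iteration cap
#' @return n x 2 matrix of undistorted normalized coordinates
#' @export
invert_distortion <- function(xy_d, distortion, tol = 1e-12, max_iter = 50) {
  xy_d <- rbind(xy_d)
  xy <- xy_d
  for (i in seq_len(max_iter)) {
    f <- apply_distortion(xy, distortion)
    err <- xy_d - f
    if (max(abs(err)) < tol) return(xy)
    # fixed-point with unit Jacobian approximation
    xy <- xy + err
  }
  f <- apply_distortion(xy, distortion)
  if (max(abs(xy_d - f)) > 1e-6)
    stop("invert_distortion: no convergence (radius outside the model region)")
  xy
}

#' Project 3D points through a camera
#'
#' Collinearity model: rotate into the camera frame, perspective divide,
#' Brown-Conrady distortion, then pixel mapping through the principal
#' distance (in pixels) and principal point.
#'
#' @param xyz n x 3 matrix of object-frame points (mm)
#' @param pose a `camera_pose`
#' @param intr a `camera_intrinsics`
#' @param behind how to treat points at or behind the camera plane:
#'   `"error"` (default) signals a condition, `"na"` returns NA rows
#' @return n x 2 matrix of pixel coordinates
#' @export
project_points <- function(xyz, pose, intr, behind = c("error", "na")) {
  behind <- match.arg(behind)
  xyz <- rbind(xyz)
  d <- sweep(xyz, 2, pose$center_mm)
  Xc <- d %*% t(pose$rotation)
  z <- Xc[, 3]
  bad <- z <= 1e-9
  if (any(bad)) {
    if (behind == "error")
      stop("project_points: point at or behind the camera plane")
    z[bad] <- NA_real_
  }
  xy <- cbind(Xc[, 1] / z, Xc[, 2] / z)
  xyd <- apply_distortion(xy, intr$distortion)
  fpx <- focal_px(intr)
  cbind(fpx * xyd[, 1] + intr$principal_point_px[1],
        fpx * xyd[, 2] + intr$principal_point_px[2])
}

#' Turntable pose for a rotation step
#'
#' Object rotation by `step_index * step_deg` about the table axis (+Z
#' through the origin) expressed as the equivalent camera orbit: the object
#' stays fixed and the camera pose is conjugated by the step rotation.
#' Composing `360 / step_deg` steps returns the base pose.
#'
#' @param base_pose the camera's `camera_pose` at step 0
#' @param step_index integer step number (0-based)
#' @param step_deg turntable increment per step in degrees (> 0)
#' @return a `camera_pose`
#' @export
turntable_pose <- function(base_pose, step_index, step_deg) {
  stopifnot(step_deg > 0)
  a <- deg2rad(step_index * step_deg)
  Rz <- rot_z(a)
  # object rotates +a; equivalently the camera orbits by -a
  camera_pose(base_pose$rotation %*% Rz, t(Rz) %*% base_pose$center_mm)
}

new_point_set <- function(id, xyz, kind) {
  xyz <- rbind(xyz)
  stopifnot(length(id) == nrow(xyz))
  if (anyDuplicated(id)) stop("point ids must be unique within a scene")
  data.frame(id = as.integer(id), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             kind = as.character(kind))
}

point_xyz <- function(points) as.matrix(points[, c("x", "y", "z")])

#' Read / write observation tables
#'
#' Observation tables hold one row per 2D detection with columns
#' `point_id, camera_id, step_index, x_px, y_px, target_code` (target_code
#' empty for untagged points). A track is the set of rows sharing one
#' `point_id`.
#'
#' @param path CSV file path
#' @return data.frame of observations
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("point_id", "camera_id", "step_index", "x_px", "y_px")
  if (!all(need %in% names(obs)))
    stop("observation table missing columns: ",
         paste(setdiff(need, names(obs)), collapse = ", "))
  if (!"target_code" %in% names(obs)) obs$target_code <- NA_integer_
  obs
}

#' @rdname read_observations
#' @param obs observation data.frame
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write camera files
#'
#' Cameras are serialized as JSON: per camera the intrinsics fields (mm and
#' micrometers as in [camera_intrinsics()]) and, optionally, a list of poses
#' (rotation as axis-angle in degrees, center in mm) keyed by step index.
#'
#' @param cameras named list with elements `intrinsics` (list of
#'   `camera_intrinsics`) and optionally `poses` (list of lists of
#'   `camera_pose`)
#' @param path JSON file path
#' @export
write_cameras <- function(cameras, path) {
  ser <- lapply(seq_along(cameras$intrinsics), function(k) {
    intr <- cameras$intrinsics[[k]]
    out <- list(camera_id = k,
                focal_length_mm = intr$focal_length_mm,
                pixel_pitch_um = intr$pixel_pitch_um,
                sensor_px = intr$sensor_px,
                principal_point_px = intr$principal_point_px,
                distortion = as.list(intr$distortion))
    if (!is.null(cameras$poses)) {
      out$poses <- lapply(seq_along(cameras$poses[[k]]), function(j) {
        p <- cameras$poses[[k]][[j]]
        list(step_index = j - 1L,
             axis_angle_deg = rad2deg(axis_angle_from_rot(p$rotation)),
             center_mm = p$center_mm)
      })
    }
    out
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cameras
#' @export
read_cameras <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  intrinsics <- lapply(ser, function(s)
    camera_intrinsics(s$focal_length_mm, s$pixel_pitch_um, s$sensor_px,
                      s$principal_point_px, unlist(s$distortion)))
  poses <- NULL
  if (!is.null(ser[[1]]$poses)) {
    poses <- lapply(ser, function(s)
      lapply(s$poses, function(p)
        camera_pose(rot_from_axis_angle(deg2rad(unlist(p$axis_angle_deg))),
                    unlist(p$center_mm))))
  }
  list(intrinsics = intrinsics, poses = poses)
}
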