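#' Studio geometry for resolution planning
#'
#' Collects the quantities that determine the measurement resolution of a
#' turntable studio: the horizontal camera-to-axis distance H0, the camera
#' tilt angle, the effective stereo baseline angle s (the turntable rotation
#' between the two views of a stereo pair, an integer multiple of the
#' turntable step), the lens focal length and the sensor pixel pitch.
#' Derived members: the slant photographing distance H, the height offset c
#' of the optical-axis intersection, the stereo baseline B, and the planar
#' and depth resolutions at the object.
#'
#' @param H0_mm horizontal distance from camera to turntable axis (mm, > 0)
#' @param theta_deg camera tilt in degrees (positive = looking down), |theta| < 90
#' @param f_mm lens focal length in mm
#' @param pixel_pitch_um sensor pixel size in micrometers
#' @param s_deg effective stereo baseline angle in degrees (0 < s < 180);
#'   defaults to three 5-degree turntable steps
#' @param turntable_step_deg turntable increment (s must be a multiple of it)
#' @return an object of class `studio_geometry` with derived fields
#'   `c_mm`, `H_mm`, `B_mm`, `delta_xy_mm`, `delta_z_mm`
#' @examples
#' g <- studio_geometry(2300, 25, 60, 3.91)
#' c(g$delta_xy_mm, g$delta_z_mm)
#' @export
studio_geometry <- function(H0_mm, theta_deg, f_mm, pixel_pitch_um,
                            s_deg = 15, turntable_step_deg = 5) {
  stopifnot(H0_mm > 0, f_mm > 0, pixel_pitch_um > 0,
            s_deg > 0, s_deg < 180, turntable_step_deg > 0)
  if (abs(theta_deg) >= 90) stop("invalid geometry: |theta| must be < 90 degrees")
  k <- s_deg / turntable_step_deg
  if (abs(k - round(k)) > 1e-9)
    stop("s_deg must be an integer multiple of turntable_step_deg")
  sl <- slant_distance(H0_mm, theta_deg)
  B <- baseline(sl[["H_mm"]], s_deg)
  g <- structure(list(H0_mm = H0_mm, theta_deg = theta_deg, f_mm = f_mm,
                      pixel_pitch_um = pixel_pitch_um, s_deg = s_deg,
                      turntable_step_deg = turntable_step_deg,
                      c_mm = sl[["c_mm"]], H_mm = sl[["H_mm"]], B_mm = B),
                 class = "studio_geometry")
  g$delta_xy_mm <- xy_resolution(g)
  g$delta_z_mm <- depth_resolution(g)
  g
}

#' @export
print.studio_geometry <- function(x, ...) {
  cat(sprintf("studio_geometry: H0 = %.0f mm, theta = %+.1f deg, f = %.1f mm, pitch = %.2f um, s = %.1f deg\n",
              x$H0_mm, x$theta_deg, x$f_mm, x$pixel_pitch_um, x$s_deg))
  cat(sprintf("  H = %.1f mm, B = %.1f mm, c = %.1f mm, delta_xy = %.4f mm, delta_z = %.4f mm\n",
              x$H_mm, x$B_mm, x$c_mm, x$delta_xy_mm, x$delta_z_mm))
  invisible(x)
}

#' Slant photographing distance of a tilted camera
#'
#' For a camera tilted by theta whose horizontal distance to the object is
#' H0, the optical-axis intersection sits `c = H0 tan(theta)` below (or
#' above) the mount and the photographing distance along the axis is
#' `H = H0 / cos(theta)`.
#'
#' @inheritParams studio_geometry
#' @return named vector with `c_mm` and `H_mm`
#' @export
slant_distance <- function(H0_mm, theta_deg) {
  stopifnot(H0_mm > 0)
  if (abs(theta_deg) >= 90) stop("invalid geometry: |theta| must be < 90 degrees")
  th <- deg2rad(theta_deg)
  c(c_mm = H0_mm * tan(th), H_mm = H0_mm / cos(th))
}

#' Stereo baseline from the turntable rotation angle
#'
#' Two views separated by a turntable rotation of s degrees at photographing
#' distance H form a stereo pair with baseline `B = 2 H sin(s/2)` (the chord
#' of the camera orbit).
#'
#' @param H_mm photographing distance (mm)
#' @param s_deg rotation angle between the two views (degrees, 0 < s < 360)
#' @return baseline in mm
#' @export
baseline <- function(H_mm, s_deg) {
  stopifnot(s_deg > 0, s_deg < 360)
  2 * H_mm * sin(deg2rad(s_deg) / 2)
}

#' Planar (xy) measurement resolution
#'
#' `delta_xy = H0 * delta_p / (f cos(theta))`: the object-space footprint of
#' one pixel for a camera tilted by theta at horizontal distance H0. At
#' theta = 0 this reduces to the level-camera form `H delta_p / f`.
#'
#' @param geom a `studio_geometry`
#' @return resolution in mm
#' @export
xy_resolution <- function(geom) {
  dp_mm <- geom$pixel_pitch_um * 1e-3
  geom$H0_mm * dp_mm / (geom$f_mm * cos(deg2rad(geom$theta_deg)))
}

#' Depth (z) measurement resolution
#'
#' `delta_z = H^2 * delta_p / (f B)` evaluated with the slant distance
#' `H = H0 / cos(theta)` and baseline `B = 2 H sin(s/2)`; algebraically equal
#' to `H0 * delta_p / (2 f sin(s/2) cos(theta))`.
#'
#' @param geom a `studio_geometry`
#' @return resolution in mm
#' @export
depth_resolution <- function(geom) {
  if (geom$s_deg <= 0) stop("degenerate baseline: s_deg must be positive")
  dp_mm <- geom$pixel_pitch_um * 1e-3
  geom$H_mm^2 * dp_mm / (geom$f_mm * geom$B_mm)
}

#' Round half away from zero (table convention)
#' @param x numeric
#' @param digits decimal places
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Images per turntable revolution
#'
#' @param turntable_step_deg turntable increment; must divide 360
#' @param n_cameras number of cameras
#' @return named vector `per_camera`, `total`
#' @examples
#' images_per_revolution(5, 4)  # 72 per camera, 288 total
#' @export
images_per_revolution <- function(turntable_step_deg, n_cameras = 1) {
  per <- 360 / turntable_step_deg
  if (abs(per - round(per)) > 1e-9)
    stop("turntable step must divide 360 degrees")
  c(per_camera = as.integer(round(per)),
    total = as.integer(round(per) * n_cameras))
}

#' Plan a vertical multi-camera arrangement
#'
#' Lays out symmetric upper/lower camera rows covering the plant from table
#' level to `plant_height_mm`: upper cameras tilt down (positive angle),
#' lower cameras tilt up, and each upper camera is paired with the lower
#' camera viewing the same height band so their imaging ranges overlap (the
#' pairing used when per-camera clouds are merged). The vertical field of
#' view of each camera (full sensor height, pinhole model) determines how
#' many pairs are needed.
#'
#' @param plant_height_mm height of the tallest plant to cover (mm, > 0)
#' @param target_resolution_mm required resolution (both delta_xy and
#'   delta_z must be at or below it)
#' @param intr a `camera_intrinsics` (focal length, pitch, sensor size)
#' @param H0_mm horizontal camera-to-axis distance (mm)
#' @param tilt_upper_deg tilt of the upper row (degrees, positive down)
#' @param tilt_lower_deg tilt of the lower row (degrees, negative = up)
#' @param s_deg effective stereo baseline angle (degrees)
#' @param turntable_step_deg turntable increment (degrees)
#' @param n_cameras optional fixed total camera count (even); when supplied
#'   the planner uses `n_cameras / 2` pairs regardless of coverage need
#' @return a `camera_plan`: data.frame with one row per camera
#'   (camera, row, mount_height_mm, tilt_deg, delta_xy_mm, delta_z_mm,
#'   paired_with) plus attributes `H0_mm`, `achieved`, `message`
#' @export
plan_cameras <- function(plant_height_mm, target_resolution_mm, intr, H0_mm,
                         tilt_upper_deg = 25, tilt_lower_deg = -25,
                         s_deg = 15, turntable_step_deg = 5,
                         n_cameras = NULL) {
  stopifnot(plant_height_mm >= 0, target_resolution_mm > 0)
  stopifnot(tilt_upper_deg > 0, tilt_lower_deg < 0)
  g_up <- studio_geometry(H0_mm, tilt_upper_deg, intr$focal_length_mm,
                          intr$pixel_pitch_um, s_deg, turntable_step_deg)
  g_lo <- studio_geometry(H0_mm, tilt_lower_deg, intr$focal_length_mm,
                          intr$pixel_pitch_um, s_deg, turntable_step_deg)
  worst <- max(g_up$delta_xy_mm, g_up$delta_z_mm,
               g_lo$delta_xy_mm, g_lo$delta_z_mm)
  achieved <- worst <= target_resolution_mm
  msg <- if (achieved) "target resolution achievable" else
    sprintf("target %.2f mm not achievable at this geometry; achievable resolution is %.2f mm",
            target_resolution_mm, worst)

  # vertical band (mm of plant height) covered by one camera: full sensor
  # height footprint at the object, pinhole model
  band_mm <- intr$sensor_px[2] * g_up$delta_xy_mm
  if (is.null(n_cameras)) {
    n_pairs <- max(1L, as.integer(ceiling(plant_height_mm / band_mm)))
  } else {
    if (n_cameras %% 2 != 0) stop("n_cameras must be even (upper/lower pairs)")
    n_pairs <- as.integer(n_cameras / 2)
  }
  # band centers from table level to plant height
  centers <- (seq_len(n_pairs) - 0.5) / n_pairs * max(plant_height_mm, band_mm)
  upper <- data.frame(
    camera = seq_len(n_pairs),
    row = "upper",
    mount_height_mm = centers + g_up$c_mm,
    tilt_deg = tilt_upper_deg,
    delta_xy_mm = round_half_up(g_up$delta_xy_mm, 2),
    delta_z_mm = round_half_up(g_up$delta_z_mm, 2),
    paired_with = seq_len(n_pairs) + n_pairs)
  lower <- data.frame(
    camera = seq_len(n_pairs) + n_pairs,
    row = "lower",
    mount_height_mm = centers + g_lo$c_mm,
    tilt_deg = tilt_lower_deg,
    delta_xy_mm = round_half_up(g_lo$delta_xy_mm, 2),
    delta_z_mm = round_half_up(g_lo$delta_z_mm, 2),
    paired_with = seq_len(n_pairs))
  plan <- rbind(upper[order(-upper$mount_height_mm), ],
                lower[order(-lower$mount_height_mm), ])
  rownames(plan) <- NULL
  structure(plan, H0_mm = H0_mm, achieved = achieved, message = msg,
            class = c("camera_plan", "data.frame"))
}

#' Place a camera on the studio frame
#'
#' Builds the step-0 pose of a camera mounted at height `mount_height_mm`,
#' horizontal distance `H0_mm` from the turntable axis, tilted by
#' `tilt_deg` (positive = looking down): its optical axis intersects the
#' table axis at height `mount_height_mm - H0_mm tan(tilt)`.
#'
#' @param intr a `camera_intrinsics`
#' @param H0_mm horizontal distance to the table axis (mm)
#' @param mount_height_mm camera height above the table (mm)
#' @param tilt_deg tilt in degrees (positive down)
#' @param azimuth_deg azimuth of the mount around the table (degrees)
#' @return list with `intrinsics` and `base_pose`, the camera element used
#'   by [scene_spec()] and [initialize_turntable()]
#' @export
camera_at <- function(intr, H0_mm, mount_height_mm, tilt_deg,
                      azimuth_deg = 0) {
  az <- deg2rad(azimuth_deg)
  center <- c(H0_mm * cos(az), H0_mm * sin(az), mount_height_mm)
  target <- c(0, 0, mount_height_mm - H0_mm * tan(deg2rad(tilt_deg)))
  list(intrinsics = intr, base_pose = look_at_pose(center, target))
}

#' Write a camera plan report
#'
#' One CSV row per camera: height, tilt angle, and per-camera resolutions —
#' the shape of a studio settings table.
#'
#' @param plan a `camera_plan`
#' @param path CSV path
#' @export
write_plan <- function(plan, path) {
  out <- data.frame(camera = plan$camera,
                    height_mm = plan$mount_height_mm,
                    angle_deg = plan$tilt_deg,
                    delta_xy_mm = plan$delta_xy_mm,
                    delta_z_mm = plan$delta_z_mm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
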