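#' Raster images and masks
#'
#' Images are numeric matrices in `[0, 1]`, dimension `height x width`,
#' `img[r, c]` covering the pixel whose center has continuous coordinates
#' `(x, y) = (c - 0.5, r - 0.5)` — the same pixel frame [project_points()]
#' reports. PNG I/O goes through the png package.
#'
#' @name raster_images
NULL

# ring-code pattern radii as fractions of the target's outer radius
TARGET_DISC_FRAC <- 0.40
TARGET_RING_IN <- 0.55
TARGET_RING_OUT <- 0.85

#' Render circular coded targets into an image
#'
#' Exact perspective rendering by inverse mapping: every pixel (supersampled)
#' is cast as a ray through the camera model (distortion inverted), the ray
#' is intersected with each target's plane, and the local pattern — white
#' central disc, black gap, 12-sector ring code — is evaluated at the hit
#' point. Anti-aliasing comes from the subpixel supersampling average.
#' Targets facing away from the camera are skipped.
#'
#' @param targets data.frame with columns `target_code`, `cx, cy, cz`
#'   (center, mm), `nx, ny, nz` (outward unit normal), `radius_mm`
#' @param pose a `camera_pose`
#' @param intr a `camera_intrinsics`; its `sensor_px` sets the image size
#'   unless `width`/`height` are given
#' @param width,height image size in pixels
#' @param supersample subpixel grid per axis (3 = 9 samples per pixel)
#' @param background background intensity
#' @return image matrix (height x width) in `[0, 1]`
#' @export
render_targets <- function(targets, pose, intr,
                           width = intr$sensor_px[1],
                           height = intr$sensor_px[2],
                           supersample = 3, background = 0) {
  img <- matrix(background, nrow = height, ncol = width)
  if (!nrow(targets)) return(img)
  R <- pose$rotation; C <- pose$center_mm
  off <- (seq_len(supersample) - 0.5) / supersample - 0.5
  sub <- expand.grid(dx = off, dy = off)
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    X0 <- c(tg$cx, tg$cy, tg$cz)
    n <- c(tg$nx, tg$ny, tg$nz); n <- n / sqrt(sum(n^2))
    view <- C - X0
    if (sum(n * view) / sqrt(sum(view^2)) < 0.05) next  # facing away / grazing
    # local in-plane basis
    e1 <- if (abs(n[3]) < 0.9) c(-n[2], n[1], 0) else c(1, 0, 0)
    e1 <- e1 - sum(e1 * n) * n; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2],
            n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    # bounding box from projected rim samples
    a <- seq(0, 2 * pi, length.out = 17)[-17]
    rim <- t(X0 + tg$radius_mm * (outer(e1, cos(a)) + outer(e2, sin(a))))
    rim_px <- project_points(rim, pose, intr, behind = "na")
    if (all(is.na(rim_px[, 1]))) next
    x0 <- max(1L, floor(min(rim_px[, 1], na.rm = TRUE)) - 1L)
    x1 <- min(width, ceiling(max(rim_px[, 1], na.rm = TRUE)) + 2L)
    y0 <- max(1L, floor(min(rim_px[, 2], na.rm = TRUE)) - 1L)
    y1 <- min(height, ceiling(max(rim_px[, 2], na.rm = TRUE)) + 2L)
    if (x1 < x0 || y1 < y0) next
    cols <- x0:x1; rows <- y0:y1
    px <- expand.grid(x = cols - 0.5, y = rows - 0.5)
    bits <- encode_ring_code(tg$target_code)
    acc <- numeric(nrow(px))
    fpx <- focal_px(intr)
    for (s in seq_len(nrow(sub))) {
      xs <- px$x + sub$dx[s]; ys <- px$y + sub$dy[s]
      xn <- cbind((xs - intr$principal_point_px[1]) / fpx,
                  (ys - intr$principal_point_px[2]) / fpx)
      xu <- invert_distortion(xn, intr$distortion)
      # ray in world frame
      dirs <- cbind(xu, 1) %*% R
      denom <- dirs %*% n
      tt <- sum(n * (X0 - C)) / denom
      hit <- sweep(dirs * as.numeric(tt), 2, C, `+`)
      du <- sweep(hit, 2, X0)
      u <- du %*% e1; v <- du %*% e2
      r <- sqrt(u^2 + v^2) / tg$radius_mm
      phi <- atan2(v, u) %% (2 * pi)
      sector <- pmin(floor(phi / (2 * pi / RING_BITS)) + 1, RING_BITS)
      val <- numeric(length(r))
      val[r <= TARGET_DISC_FRAC] <- 1
      in_ring <- r > TARGET_RING_IN & r <= TARGET_RING_OUT
      val[in_ring] <- bits[sector[in_ring]]
      val[tt <= 0] <- 0
      acc <- acc + val
    }
    acc <- acc / nrow(sub)
    block <- matrix(acc, nrow = length(cols), ncol = length(rows))
    # accumulate with max so overlapping targets stay white-on-black
    img[rows, cols] <- pmax(img[rows, cols], t(block))
  }
  img
}

#' Targets of a scene's measurement bar, in renderable form
#'
#' @param spec a `scene_spec`
#' @param bar optionally a prebuilt [build_measurement_bar()] result
#' @return data.frame accepted by [render_targets()]
#' @export
bar_render_targets <- function(spec, bar = build_measurement_bar(spec)) {
  tc <- bar$target_codes
  pts <- bar$points[match(tc$id, bar$points$id), ]
  data.frame(target_code = tc$target_code,
             cx = pts$x, cy = pts$y, cz = pts$z,
             nx = cos(tc$azimuth_rad), ny = sin(tc$azimuth_rad), nz = 0,
             radius_mm = spec$bar$target_radius_mm)
}

#' Render one capture frame's coded targets
#'
#' Renders the measurement-bar targets as seen by one camera at one
#' turntable step (blank background elsewhere); used to exercise the target
#' detector against known geometry.
#'
#' @param spec a `scene_spec`
#' @param camera_id camera index
#' @param step_index 0-based turntable step
#' @param ... passed to [render_targets()] (e.g. `width`, `height`)
#' @export
render_frame <- function(spec, camera_id, step_index, ...) {
  cam <- spec$cameras[[camera_id]]
  pose <- turntable_pose(cam$base_pose, step_index, spec$turntable_step_deg)
  render_targets(bar_render_targets(spec), pose, cam$intrinsics, ...)
}

#' Write / read grayscale PNG images
#' @param img image matrix in `[0,1]`
#' @param path PNG path
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Analytic background masks for a simulated scene
#'
#' Builds a per-frame foreground mask by projecting every true scene point
#' and dilating its footprint; pixels never touched by a projected point are
#' background. This stands in for a photographed background mask: it is
#' exact with respect to the synthetic scene rather than measured.
#'
#' @param truth the `truth` element of [simulate_capture()]
#' @param downsample mask grid cell size in pixels (masks are stored at
#'   `sensor / downsample` resolution to keep them small)
#' @param dilate_px footprint radius in (full-resolution) pixels
#' @return list of masks keyed `"<camera>_<step>"`, each a logical matrix
#'   with attributes `downsample` and `sensor_px`
#' @export
generate_masks <- function(truth, downsample = 8, dilate_px = 8) {
  xyz <- point_xyz(truth$points)
  masks <- list()
  rad <- max(1L, ceiling(dilate_px / downsample))
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2, ]
  for (k in seq_along(truth$poses)) {
    intr <- truth$intrinsics[[k]]
    nc <- ceiling(intr$sensor_px[1] / downsample)
    nr <- ceiling(intr$sensor_px[2] / downsample)
    for (j in seq_along(truth$poses[[k]])) {
      px <- project_points(xyz, truth$poses[[k]][[j]], intr, behind = "na")
      ok <- !is.na(px[, 1]) & px[, 1] >= 0 & px[, 1] <= intr$sensor_px[1] &
        px[, 2] >= 0 & px[, 2] <= intr$sensor_px[2]
      m <- matrix(FALSE, nr, nc)
      if (any(ok)) {
        cc <- pmin(pmax(ceiling(px[ok, 1] / downsample), 1L), nc)
        rr <- pmin(pmax(ceiling(px[ok, 2] / downsample), 1L), nr)
        for (o in seq_len(nrow(offs))) {
          r2 <- pmin(pmax(rr + offs$dr[o], 1L), nr)
          c2 <- pmin(pmax(cc + offs$dc[o], 1L), nc)
          m[cbind(r2, c2)] <- TRUE
        }
      }
      attr(m, "downsample") <- downsample
      attr(m, "sensor_px") <- intr$sensor_px
      masks[[sprintf("%d_%d", k, j - 1L)]] <- m
    }
  }
  masks
}
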