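#' Metric scale recovery from reference distances
#'
#' A bundle solution is defined only up to a global similarity; the known
#' distances between coded targets on the measurement bar fix the scale.
#' The least-squares scale minimizes `sum((s * d_model - d_true)^2)` over
#' the reconstructed reference pairs; with a single pair it is the exact
#' ratio. The scale is applied to all points and all camera centers.
#'
#' @param solution a `bundle_solution`
#' @param reference_distances data.frame `id_a`, `id_b`, `distance_mm`
#' @return list: `scale`, the scaled `solution`, and `pair_errors_mm`
#'   (per-pair signed errors after scaling)
#' @export
fit_scale <- function(solution, reference_distances) {
  pts <- solution$points
  ia <- match(reference_distances$id_a, pts$id)
  ib <- match(reference_distances$id_b, pts$id)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok))
    stop("no reference pair has both endpoints reconstructed; cannot fix scale")
  xyz <- point_xyz(pts)
  d_model <- sqrt(rowSums((xyz[ia[ok], , drop = FALSE] -
                           xyz[ib[ok], , drop = FALSE])^2))
  d_true <- reference_distances$distance_mm[ok]
  s <- sum(d_true * d_model) / sum(d_model^2)
  scaled <- solution
  scaled$points[, c("x", "y", "z")] <- xyz * s
  scaled$poses <- lapply(solution$poses, function(pl)
    lapply(pl, function(p) camera_pose(p$rotation, p$center_mm * s)))
  scaled$scale_applied <- TRUE
  list(scale = s, solution = scaled,
       pair_errors_mm = s * d_model - d_true)
}

#' Least-squares similarity alignment (Horn's method)
#'
#' Finds scale, rotation and translation mapping `from` onto `to`
#' (`to ~ s R from + t`); used to compare a gauge-free reconstruction with
#' ground truth.
#'
#' @param from,to n x 3 matrices of corresponding points
#' @return list `s`, `R`, `t`, and `transform(x)` applying the map
#' @export
align_similarity <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), nrow(from) >= 3)
  mf <- colMeans(from); mt <- colMeans(to)
  A <- sweep(from, 2, mf); B <- sweep(to, 2, mt)
  S <- t(A) %*% B
  sv <- svd(S)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  s <- sum(diag(D) * sv$d) / sum(A^2)
  t_vec <- mt - s * as.numeric(R %*% mf)
  list(s = s, R = R, t = t_vec,
       transform = function(x) sweep(s * (rbind(x) %*% t(R)), 2, t_vec, `+`))
}

#' A scene point cloud with provenance
#'
#' @param points data.frame `id, x, y, z, kind`
#' @param camera_id source camera per point (recycled)
#' @param scale_applied whether metric scale has been applied
#' @return object of class `scene_point_cloud`
#' @export
scene_point_cloud <- function(points, camera_id = NA_integer_,
                              scale_applied = FALSE) {
  pts <- points
  pts$camera_id <- camera_id
  structure(list(points = pts, scale_applied = scale_applied, units = "mm"),
            class = "scene_point_cloud")
}

#' @export
print.scene_point_cloud <- function(x, ...) {
  cat(sprintf("scene_point_cloud: %d points (%s), %s\n", nrow(x$points),
              paste(sprintf("%s: %d", names(table(x$points$kind)),
                            table(x$points$kind)), collapse = ", "),
              if (x$scale_applied) "metric scale applied" else "unscaled"))
  invisible(x)
}

#' Filter a cloud through per-frame background masks
#'
#' A point is kept iff it projects into the foreground region in at least
#' `min_votes` of the frames where it is visible (in front of the camera and
#' inside the sensor). Floating noise reconstructed in the background region
#' is removed; the filter never adds points.
#'
#' @param cloud a `scene_point_cloud`
#' @param masks per-frame masks from [generate_masks()] (named
#'   `"<camera>_<step>"`)
#' @param poses list per camera of per-step `camera_pose`
#' @param intrinsics list of `camera_intrinsics`
#' @param min_votes minimum foreground votes
#' @return the filtered `scene_point_cloud`
#' @export
apply_background_mask <- function(cloud, masks, poses, intrinsics,
                                  min_votes = 2) {
  xyz <- point_xyz(cloud$points)
  votes <- integer(nrow(xyz))
  for (k in seq_along(poses)) {
    intr <- intrinsics[[k]]
    for (j in seq_along(poses[[k]])) {
      key <- sprintf("%d_%d", k, j - 1L)
      m <- masks[[key]]
      if (is.null(m))
        stop("missing background mask for frame ", key)
      ds <- attr(m, "downsample")
      px <- project_points(xyz, poses[[k]][[j]], intr, behind = "na")
      vis <- !is.na(px[, 1]) & px[, 1] >= 0 & px[, 1] <= intr$sensor_px[1] &
        px[, 2] >= 0 & px[, 2] <= intr$sensor_px[2]
      if (!any(vis)) next
      cc <- pmin(pmax(ceiling(px[vis, 1] / ds), 1L), ncol(m))
      rr <- pmin(pmax(ceiling(px[vis, 2] / ds), 1L), nrow(m))
      votes[vis] <- votes[vis] + as.integer(m[cbind(rr, cc)])
    }
  }
  out <- cloud
  out$points <- cloud$points[votes >= min_votes, ]
  out
}

#' Merge per-camera point clouds
#'
#' Concatenates clouds already expressed in the shared (scaled) bundle frame
#' and suppresses duplicates: points falling in the same voxel of side
#' `radius_mm` are merged to their centroid, provenance kept as the set of
#' contributing cameras. No coordinate is moved by more than the voxel
#' radius.
#'
#' @param clouds list of `scene_point_cloud`s (all scaled)
#' @param radius_mm voxel size; a natural choice is the studio's delta_xy
#' @return a merged `scene_point_cloud`
#' @export
merge_clouds <- function(clouds, radius_mm = 0.5) {
  if (inherits(clouds, "scene_point_cloud")) clouds <- list(clouds)
  if (!all(vapply(clouds, function(cl) isTRUE(cl$scale_applied), logical(1))))
    stop("all clouds must be scaled before merging")
  pts <- do.call(rbind, lapply(clouds, function(cl) cl$points))
  if (!nrow(pts)) return(scene_point_cloud(pts, scale_applied = TRUE))
  # grid-hashed greedy clustering: a point joins the first accepted
  # representative within radius (searched over the 27 neighboring voxels),
  # else becomes a new representative; duplicates across cell boundaries
  # therefore still merge
  vx <- floor(pts$x / radius_mm); vy <- floor(pts$y / radius_mm)
  vz <- floor(pts$z / radius_mm)
  cells <- new.env(parent = emptyenv(), size = nrow(pts))
  grp <- integer(nrow(pts))
  n_grp <- 0L
  reps <- matrix(0, nrow(pts), 3)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (i in seq_len(nrow(pts))) {
    found <- 0L
    for (o in seq_len(27L)) {
      key <- paste(vx[i] + offs[o, 1], vy[i] + offs[o, 2], vz[i] + offs[o, 3],
                   pts$kind[i], sep = "|")
      cand <- cells[[key]]
      if (!is.null(cand)) {
        d2 <- (reps[cand, 1] - pts$x[i])^2 + (reps[cand, 2] - pts$y[i])^2 +
          (reps[cand, 3] - pts$z[i])^2
        hit <- which(d2 <= radius_mm^2)
        if (length(hit)) { found <- cand[hit[1]]; break }
      }
    }
    if (found) {
      grp[i] <- found
    } else {
      n_grp <- n_grp + 1L
      grp[i] <- n_grp
      reps[n_grp, ] <- c(pts$x[i], pts$y[i], pts$z[i])
      key <- paste(vx[i], vy[i], vz[i], pts$kind[i], sep = "|")
      cells[[key]] <- c(cells[[key]], n_grp)
    }
  }
  agg <- function(v) as.numeric(tapply(v, grp, mean))
  first <- !duplicated(grp)
  ord <- order(grp[first])
  merged <- data.frame(id = pts$id[first][ord],
                       x = agg(pts$x), y = agg(pts$y), z = agg(pts$z),
                       kind = pts$kind[first][ord])
  cam <- tapply(pts$camera_id, grp, function(v)
    paste(sort(unique(v)), collapse = "+"))
  merged$camera_id <- as.character(cam)
  scene_point_cloud(merged, camera_id = merged$camera_id,
                    scale_applied = TRUE)
}

#' Length-accuracy evaluation against reference pairs
#'
#' Measures the Euclidean distance between marker points in the cloud for
#' every evaluation pair with a known true length, the protocol used with
#' rulers fixed at the table center: per-pair errors plus their mean,
#' mean absolute value and standard deviation. Pairs with a missing marker
#' are listed and skipped.
#'
#' @param cloud a `scene_point_cloud` (scaled)
#' @param marker_pairs data.frame `id_a`, `id_b`, `true_mm`
#' @return object of class `length_report`: `pairs` data.frame
#'   (id_a, id_b, true_mm, measured_mm, error_mm), `missing` (ids not in the
#'   cloud), `mean_error_mm`, `mean_abs_error_mm`, `sd_error_mm`, `n_pairs`
#' @export
evaluate_lengths <- function(cloud, marker_pairs) {
  pts <- cloud$points
  ia <- match(marker_pairs$id_a, pts$id)
  ib <- match(marker_pairs$id_b, pts$id)
  ok <- !is.na(ia) & !is.na(ib)
  missing <- unique(c(marker_pairs$id_a[is.na(ia)],
                      marker_pairs$id_b[is.na(ib)]))
  xyz <- point_xyz(pts)
  measured <- sqrt(rowSums((xyz[ia[ok], , drop = FALSE] -
                            xyz[ib[ok], , drop = FALSE])^2))
  pairs <- data.frame(id_a = marker_pairs$id_a[ok],
                      id_b = marker_pairs$id_b[ok],
                      true_mm = marker_pairs$true_mm[ok],
                      measured_mm = measured,
                      error_mm = measured - marker_pairs$true_mm[ok])
  structure(list(pairs = pairs, missing = missing,
                 mean_error_mm = mean(pairs$error_mm),
                 mean_abs_error_mm = mean(abs(pairs$error_mm)),
                 sd_error_mm = stats::sd(pairs$error_mm),
                 n_pairs = nrow(pairs)),
            class = "length_report")
}

#' @export
print.length_report <- function(x, ...) {
  cat(sprintf("length_report: %d pairs; mean error %+.4f mm, mean |error| %.4f mm, sd %.4f mm\n",
              x$n_pairs, x$mean_error_mm, x$mean_abs_error_mm, x$sd_error_mm))
  if (length(x$missing))
    cat("  missing markers:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Write a length report to CSV
#' @param report a `length_report`
#' @param path CSV path
#' @export
write_length_report <- function(report, path) {
  utils::write.csv(report$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sensor-plane residual map of a solved bundle
#'
#' Grids each camera's sensor and averages the calibration residual vectors
#' of the observations falling in every cell. Cells no observation ever
#' touched are flagged uncovered — regions of the sensor that never saw the
#' measurement bar cannot be calibrated there.
#'
#' @param solution a `bundle_solution`
#' @param grid_size cells per axis
#' @param point_ids optionally restrict the map to these point ids (e.g.
#'   the measurement-bar points, to show where the bar calibrated the
#'   sensor)
#' @return object of class `residual_map`: per camera a data.frame
#'   (row, col, n, mean_dx, mean_dy, covered) plus `covered_fraction`
#' @export
residual_map <- function(solution, grid_size = 8, point_ids = NULL) {
  res <- solution$residuals
  obs <- solution$observations
  if (!is.null(point_ids)) {
    keep <- obs$point_id %in% point_ids
    res <- res[keep, ]; obs <- obs[keep, ]
  }
  maps <- list()
  for (k in seq_along(solution$intrinsics)) {
    sp <- solution$intrinsics[[k]]$sensor_px
    sel <- res$camera_id == k
    cells <- expand.grid(row = seq_len(grid_size), col = seq_len(grid_size))
    cells$n <- 0L; cells$mean_dx <- NA_real_; cells$mean_dy <- NA_real_
    if (any(sel)) {
      cx <- pmin(pmax(ceiling(obs$x_px[sel] / sp[1] * grid_size), 1L), grid_size)
      cy <- pmin(pmax(ceiling(obs$y_px[sel] / sp[2] * grid_size), 1L), grid_size)
      ci <- (cx - 1L) * grid_size + cy
      cnt <- tabulate(ci, nbins = grid_size^2)
      sdx <- rep(0, grid_size^2); sdy <- rep(0, grid_size^2)
      sdx[sort(unique(ci))] <- tapply(res$dx[sel], ci, sum)
      sdy[sort(unique(ci))] <- tapply(res$dy[sel], ci, sum)
      cells$n <- cnt[(cells$col - 1L) * grid_size + cells$row]
      nz <- cells$n > 0
      lin <- (cells$col - 1L) * grid_size + cells$row
      cells$mean_dx[nz] <- sdx[lin[nz]] / cells$n[nz]
      cells$mean_dy[nz] <- sdy[lin[nz]] / cells$n[nz]
    }
    cells$covered <- cells$n > 0
    maps[[k]] <- cells
  }
  structure(list(maps = maps, grid_size = grid_size,
                 covered_fraction = vapply(maps, function(m) mean(m$covered),
                                           numeric(1))),
            class = "residual_map")
}

#' @export
print.residual_map <- function(x, ...) {
  cat(sprintf("residual_map: %d cameras, %dx%d grid; covered fraction %s\n",
              length(x$maps), x$grid_size, x$grid_size,
              paste(sprintf("%.2f", x$covered_fraction), collapse = ", ")))
  invisible(x)
}

#' Write a residual map to CSV
#' @param rmap a `residual_map`
#' @param path CSV path
#' @export
write_residual_map <- function(rmap, path) {
  out <- do.call(rbind, lapply(seq_along(rmap$maps), function(k)
    cbind(camera_id = k, rmap$maps[[k]])))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read point clouds as PLY
#'
#' ASCII PLY with double-precision coordinates (mm) and a uchar provenance
#' property encoding the point kind.
#'
#' @param cloud a `scene_point_cloud` (or a points data.frame)
#' @param path PLY path
#' @export
write_ply <- function(cloud, path) {
  pts <- if (inherits(cloud, "scene_point_cloud")) cloud$points else cloud
  kinds <- c(coded_target_center = 0L, random_dot = 1L, plant_surface = 2L,
             noise = 3L)
  kv <- kinds[pts$kind]
  kv[is.na(kv)] <- 255L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pts)),
               "property double x", "property double y", "property double z",
               "property uchar kind", "end_header"), con)
  writeLines(sprintf("%.10g %.10g %.10g %d", pts$x, pts$y, pts$z, kv), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  body <- utils::read.table(text = lines[(hdr_end + 1):(hdr_end + nv)])
  kinds <- c("coded_target_center", "random_dot", "plant_surface", "noise")
  kind <- ifelse(body$V4 < 4, kinds[body$V4 + 1L], "unknown")
  data.frame(id = seq_len(nv), x = body$V1, y = body$V2, z = body$V3,
             kind = kind)
}
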