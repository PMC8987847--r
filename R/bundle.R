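#' Self-calibrating bundle adjustment
#'
#' Joint least-squares refinement of interior orientation (principal
#' distance, principal point, Brown-Conrady distortion), one exterior
#' orientation per camera per turntable step, and the 3D coordinates of
#' every observed point, from 2D image observations alone. Per-step poses
#' are free parameters — turntable accuracy is never assumed; the closed
#' loop over a revolution is a post-hoc diagnostic, not a constraint. The
#' gauge is fixed by freezing the first camera's step-0 pose; the global
#' scale stays free until [fit_scale()].
#'
#' @name sfm_bundle
NULL

INTR_NAMES <- c("f_px", "cx", "cy", "k1", "k2", "k3", "p1", "p2")

# ---- internal optimization state -------------------------------------------

# Packs the problem into flat arrays: intr (K x 8), Rmat (P x 9, columns
# R11..R33 row-major by name Rij = R[i,j]), Cs (P x 3), X (N x 3), and
# per-observation index vectors ki (camera), pi (pose), ni (point).
ba_state <- function(problem) {
  obs <- problem$observations
  K <- length(problem$intrinsics)
  steps <- sort(unique(obs$step_index))
  pose_keys <- character(0)
  Rmat <- NULL; Cs <- NULL
  pk <- 0L
  pose_index <- new.env(parent = emptyenv())
  Rlist <- list(); Clist <- list()
  for (k in seq_len(K)) {
    for (j in seq_along(problem$poses[[k]])) {
      pk <- pk + 1L
      assign(sprintf("%d_%d", k, j - 1L), pk, envir = pose_index)
      Rlist[[pk]] <- problem$poses[[k]][[j]]$rotation
      Clist[[pk]] <- problem$poses[[k]][[j]]$center_mm
    }
  }
  Rmat <- do.call(rbind, lapply(Rlist, as.vector))  # column-major: R11 R21 R31 R12 ...
  Cs <- do.call(rbind, Clist)
  ids <- sort(unique(obs$point_id))
  ni <- match(obs$point_id, ids)
  pts <- problem$points
  X <- point_xyz(pts)[match(ids, pts$id), , drop = FALSE]
  pi_ <- vapply(sprintf("%d_%d", obs$camera_id, obs$step_index),
                function(key) get(key, envir = pose_index), numeric(1))
  intr <- t(vapply(problem$intrinsics, function(ii)
    c(focal_px(ii), ii$principal_point_px, ii$distortion), numeric(8)))
  colnames(intr) <- INTR_NAMES
  list(K = K, P = pk, N = length(ids), ids = ids,
       intr = intr, Rmat = Rmat, Cs = Cs, X = X,
       ki = obs$camera_id, pi = as.integer(pi_), ni = ni,
       u = obs$x_px, v = obs$y_px,
       pitch_um = vapply(problem$intrinsics, `[[`, numeric(1), "pixel_pitch_um"),
       sensor = lapply(problem$intrinsics, `[[`, "sensor_px"),
       kinds = pts$kind[match(ids, pts$id)])
}

# Predicted pixel coordinates and all intermediates needed by the Jacobian.
ba_forward <- function(st) {
  ki <- st$ki; pi_ <- st$pi; ni <- st$ni
  R <- st$Rmat
  d1 <- st$X[ni, 1] - st$Cs[pi_, 1]
  d2 <- st$X[ni, 2] - st$Cs[pi_, 2]
  d3 <- st$X[ni, 3] - st$Cs[pi_, 3]
  # Rmat columns (column-major of 3x3): 1:R11 2:R21 3:R31 4:R12 5:R22 6:R32 7:R13 8:R23 9:R33
  Xc1 <- R[pi_, 1] * d1 + R[pi_, 4] * d2 + R[pi_, 7] * d3
  Xc2 <- R[pi_, 2] * d1 + R[pi_, 5] * d2 + R[pi_, 8] * d3
  Xc3 <- R[pi_, 3] * d1 + R[pi_, 6] * d2 + R[pi_, 9] * d3
  x <- Xc1 / Xc3; y <- Xc2 / Xc3
  k1 <- st$intr[ki, "k1"]; k2 <- st$intr[ki, "k2"]; k3 <- st$intr[ki, "k3"]
  p1 <- st$intr[ki, "p1"]; p2 <- st$intr[ki, "p2"]
  fpx <- st$intr[ki, "f_px"]
  r2 <- x^2 + y^2
  rad <- 1 + r2 * (k1 + r2 * (k2 + r2 * k3))
  xd <- x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * rad + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  list(d1 = d1, d2 = d2, d3 = d3, z = Xc3, x = x, y = y,
       r2 = r2, rad = rad, xd = xd, yd = yd, fpx = fpx,
       k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2,
       pu = fpx * xd + st$intr[ki, "cx"],
       pv = fpx * yd + st$intr[ki, "cy"])
}

# residuals (predicted - measured), length 2n interleaved (u1 v1 u2 v2 ...)
ba_residuals <- function(st, fw = ba_forward(st)) {
  r <- numeric(2 * length(st$u))
  r[c(TRUE, FALSE)] <- fw$pu - st$u
  r[c(FALSE, TRUE)] <- fw$pv - st$v
  r
}

huber_weights <- function(r, delta) {
  ru <- r[c(TRUE, FALSE)]; rv <- r[c(FALSE, TRUE)]
  rho <- sqrt(ru^2 + rv^2)
  w <- rep(1, length(rho))
  over <- rho > delta
  w[over] <- delta / rho[over]
  cost <- sum(ifelse(over, delta * (rho - delta / 2), rho^2 / 2))
  list(w = w, cost = cost, rho = rho)
}

# Parameter layout: free intrinsics per camera, then 6 per non-fixed pose
# (axis-angle increment, center), then 3 per point.
ba_layout <- function(st, intrinsic_free, fixed_pose = 1L) {
  free_idx <- which(intrinsic_free)
  n_int <- length(free_idx)
  intr_off <- (seq_len(st$K) - 1L) * n_int  # param offset per camera
  pose_free <- setdiff(seq_len(st$P), fixed_pose)
  pose_col <- rep(NA_integer_, st$P)
  pose_col[pose_free] <- st$K * n_int + (seq_along(pose_free) - 1L) * 6L
  pt_off <- st$K * n_int + length(pose_free) * 6L
  list(intrinsic_free = intrinsic_free, free_idx = free_idx, n_int = n_int,
       intr_off = intr_off, fixed_pose = fixed_pose, pose_col = pose_col,
       pt_off = pt_off, n_par = pt_off + 3L * st$N)
}

# Sparse Jacobian of the (unweighted) residual vector.
ba_jacobian <- function(st, layout, fw = ba_forward(st)) {
  n <- length(st$u)
  ki <- st$ki; pi_ <- st$pi; ni <- st$ni
  R <- st$Rmat
  z <- fw$z; x <- fw$x; y <- fw$y
  drad <- fw$k1 + fw$r2 * (2 * fw$k2 + 3 * fw$k3 * fw$r2)
  D11 <- fw$rad + 2 * x^2 * drad + 2 * fw$p1 * y + 6 * fw$p2 * x
  D22 <- fw$rad + 2 * y^2 * drad + 6 * fw$p1 * y + 2 * fw$p2 * x
  D12 <- 2 * x * y * drad + 2 * fw$p1 * x + 2 * fw$p2 * y
  # G = B R, rows of d(x,y)/dX (world)
  G11 <- (R[pi_, 1] - x * R[pi_, 3]) / z
  G12 <- (R[pi_, 4] - x * R[pi_, 6]) / z
  G13 <- (R[pi_, 7] - x * R[pi_, 9]) / z
  G21 <- (R[pi_, 2] - y * R[pi_, 3]) / z
  G22 <- (R[pi_, 5] - y * R[pi_, 6]) / z
  G23 <- (R[pi_, 8] - y * R[pi_, 9]) / z
  fpx <- fw$fpx
  M11 <- fpx * (D11 * G11 + D12 * G21)
  M12 <- fpx * (D11 * G12 + D12 * G22)
  M13 <- fpx * (D11 * G13 + D12 * G23)
  M21 <- fpx * (D12 * G11 + D22 * G21)
  M22 <- fpx * (D12 * G12 + D22 * G22)
  M23 <- fpx * (D12 * G13 + D22 * G23)
  rows_u <- 2 * seq_len(n) - 1L
  rows_v <- 2 * seq_len(n)
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, v) {
    m <- length(ii) + 1L
    ii[[m]] <<- i; jj[[m]] <<- j; xx[[m]] <<- v
  }
  # points
  pc <- layout$pt_off + 3L * (ni - 1L)
  add(rows_u, pc + 1L, M11); add(rows_u, pc + 2L, M12); add(rows_u, pc + 3L, M13)
  add(rows_v, pc + 1L, M21); add(rows_v, pc + 2L, M22); add(rows_v, pc + 3L, M23)
  # poses (skip gauge-fixed)
  pf <- !is.na(layout$pose_col[pi_])
  if (any(pf)) {
    pcol <- layout$pose_col[pi_][pf]
    d1 <- fw$d1[pf]; d2 <- fw$d2[pf]; d3 <- fw$d3[pf]
    ru <- rows_u[pf]; rv <- rows_v[pf]
    m11 <- M11[pf]; m12 <- M12[pf]; m13 <- M13[pf]
    m21 <- M21[pf]; m22 <- M22[pf]; m23 <- M23[pf]
    # J_omega = -M [d]x  (local increment R <- R exp([w]x))
    add(ru, pcol + 1L, -(m12 * d3 - m13 * d2))
    add(ru, pcol + 2L, -(m13 * d1 - m11 * d3))
    add(ru, pcol + 3L, -(m11 * d2 - m12 * d1))
    add(rv, pcol + 1L, -(m22 * d3 - m23 * d2))
    add(rv, pcol + 2L, -(m23 * d1 - m21 * d3))
    add(rv, pcol + 3L, -(m21 * d2 - m22 * d1))
    # J_center = -M
    add(ru, pcol + 4L, -m11); add(ru, pcol + 5L, -m12); add(ru, pcol + 6L, -m13)
    add(rv, pcol + 4L, -m21); add(rv, pcol + 5L, -m22); add(rv, pcol + 6L, -m23)
  }
  # intrinsics
  if (layout$n_int > 0) {
    du <- list(f_px = fw$xd, cx = rep(1, n), cy = rep(0, n),
               k1 = fpx * x * fw$r2, k2 = fpx * x * fw$r2^2,
               k3 = fpx * x * fw$r2^3,
               p1 = fpx * 2 * x * y, p2 = fpx * (fw$r2 + 2 * x^2))
    dv <- list(f_px = fw$yd, cx = rep(0, n), cy = rep(1, n),
               k1 = fpx * y * fw$r2, k2 = fpx * y * fw$r2^2,
               k3 = fpx * y * fw$r2^3,
               p1 = fpx * (fw$r2 + 2 * y^2), p2 = fpx * 2 * x * y)
    for (m in seq_along(layout$free_idx)) {
      nm <- INTR_NAMES[layout$free_idx[m]]
      col <- layout$intr_off[ki] + m
      add(rows_u, col, du[[nm]])
      add(rows_v, col, dv[[nm]])
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2L * n, layout$n_par))
}

# Applies a packed parameter increment to a state.
ba_apply_step <- function(st, layout, delta) {
  st2 <- st
  if (layout$n_int > 0) {
    for (k in seq_len(st$K)) {
      dk <- delta[layout$intr_off[k] + seq_len(layout$n_int)]
      st2$intr[k, layout$free_idx] <- st$intr[k, layout$free_idx] + dk
    }
  }
  for (p in seq_len(st$P)) {
    col <- layout$pose_col[p]
    if (is.na(col)) next
    w <- delta[col + 1:3]
    Rp <- matrix(st$Rmat[p, ], 3, 3)
    st2$Rmat[p, ] <- as.vector(orthonormalize(Rp %*% rot_from_axis_angle(w)))
    st2$Cs[p, ] <- st$Cs[p, ] + delta[col + 4:6]
  }
  dX <- matrix(delta[(layout$pt_off + 1L):layout$n_par], ncol = 3, byrow = TRUE)
  st2$X <- st$X + dX
  st2
}

ba_unpack <- function(st, problem) {
  intrinsics <- lapply(seq_len(st$K), function(k) {
    old <- problem$intrinsics[[k]]
    camera_intrinsics(
      focal_length_mm = unname(st$intr[k, "f_px"]) * old$pixel_pitch_um * 1e-3,
      pixel_pitch_um = old$pixel_pitch_um,
      sensor_px = old$sensor_px,
      principal_point_px = unname(st$intr[k, c("cx", "cy")]),
      distortion = st$intr[k, c("k1", "k2", "k3", "p1", "p2")])
  })
  poses <- list(); p <- 0L
  for (k in seq_len(st$K)) {
    poses[[k]] <- lapply(seq_along(problem$poses[[k]]), function(j) {
      camera_pose(orthonormalize(matrix(st$Rmat[p + j, ], 3, 3)),
                  st$Cs[p + j, ])
    })
    p <- p + length(problem$poses[[k]])
  }
  points <- data.frame(id = st$ids, x = st$X[, 1], y = st$X[, 2],
                       z = st$X[, 3], kind = st$kinds)
  list(intrinsics = intrinsics, poses = poses, points = points)
}

# ---- public operations -----------------------------------------------------

#' Initialize a bundle problem from nominal turntable geometry
#'
#' Seeds every per-step pose from the nominal studio layout (mount height,
#' tilt, horizontal distance, turntable step — only a starting guess, never
#' trusted), seeds intrinsics from the nameplate focal length and sensor
#' center, and triangulates every track with enough baseline for initial 3D
#' coordinates.
#'
#' @param config list: `cameras` — list per camera with `intrinsics` (a
#'   [camera_intrinsics()]) and either `base_pose` or the nominal mount
#'   (`mount_height_mm`, `tilt_deg`); `H0_mm`; `turntable_step_deg`;
#'   `n_steps` (default full revolution)
#' @param observations observation data.frame (see [read_observations()])
#' @param huber_px robust-loss scale in pixels
#' @param intrinsic_free logical 8-vector naming which interior parameters
#'   are estimated (`f_px, cx, cy, k1, k2, k3, p1, p2`); `k3` is off by
#'   default
#' @param min_track_detections tracks with fewer detections are dropped
#' @return an object of class `bundle_problem`
#' @export
initialize_turntable <- function(config, observations, huber_px = 2,
                                 intrinsic_free = c(f_px = TRUE, cx = TRUE,
                                                    cy = TRUE, k1 = TRUE,
                                                    k2 = TRUE, k3 = FALSE,
                                                    p1 = TRUE, p2 = TRUE),
                                 min_track_detections = 2L) {
  cams <- sort(unique(observations$camera_id))
  if (any(cams > length(config$cameras)) || any(cams < 1))
    stop("observations reference a camera missing from the studio config")
  n_steps <- config$n_steps
  if (is.null(n_steps)) n_steps <- max(observations$step_index) + 1L
  step <- config$turntable_step_deg
  intrinsics <- lapply(config$cameras, function(cc) cc$intrinsics)
  poses <- lapply(config$cameras, function(cc) {
    base <- cc$base_pose
    if (is.null(base)) {
      base <- camera_at(cc$intrinsics, config$H0_mm, cc$mount_height_mm,
                        cc$tilt_deg)$base_pose
    }
    lapply(seq_len(n_steps) - 1L, function(j) turntable_pose(base, j, step))
  })
  # drop starved tracks, then triangulate initial structure
  tc <- table(observations$point_id)
  keep <- names(tc)[tc >= min_track_detections]
  obs <- observations[observations$point_id %in% as.numeric(keep), ]
  tracks <- split(obs, obs$point_id)
  ids <- as.numeric(names(tracks))
  ord <- order(ids)
  tracks <- tracks[ord]; ids <- ids[ord]
  Xs <- matrix(NA_real_, length(ids), 3)
  ok <- logical(length(ids))
  for (i in seq_along(ids)) {
    Xi <- try(triangulate(tracks[[i]], poses, intrinsics), silent = TRUE)
    if (!inherits(Xi, "try-error")) { Xs[i, ] <- Xi; ok[i] <- TRUE }
  }
  obs <- obs[obs$point_id %in% ids[ok], ]
  points <- data.frame(id = ids[ok], x = Xs[ok, 1], y = Xs[ok, 2],
                       z = Xs[ok, 3],
                       kind = ifelse(is.na(obs$target_code[match(ids[ok], obs$point_id)]),
                                     "random_dot", "coded_target_center"))
  # coverage diagnostic: every configured camera needs enough tracks
  n_tracks <- vapply(seq_along(config$cameras), function(k)
    length(unique(obs$point_id[obs$camera_id == k])), numeric(1))
  starved <- which(n_tracks < 6)
  if (length(starved))
    stop("insufficient coverage: cameras with < 6 tracks: ",
         paste(sprintf("camera %d (%d)", starved, n_tracks[starved]),
               collapse = ", "))
  structure(list(observations = obs, intrinsics = intrinsics, poses = poses,
                 points = points, huber_px = huber_px,
                 intrinsic_free = intrinsic_free,
                 turntable_step_deg = step, n_steps = n_steps,
                 gauge = "first_pose"),
            class = "bundle_problem")
}

#' Triangulate one track
#'
#' Linear DLT estimate from all detections (rays through the undistorted
#' normalized coordinates) refined by Gauss-Newton on the reprojection
#' error. Requires at least two detections whose viewing rays subtend more
#' than `min_angle_deg`.
#'
#' @param track data.frame with `camera_id`, `step_index`, `x_px`, `y_px`
#' @param poses list per camera of per-step `camera_pose`
#' @param intrinsics list of `camera_intrinsics`
#' @param min_angle_deg minimum baseline angle between some ray pair
#' @return 3-vector, object-frame mm
#' @export
triangulate <- function(track, poses, intrinsics, min_angle_deg = 0.5) {
  m <- nrow(track)
  if (m < 2) stop("untriangulatable track: fewer than 2 detections")
  A <- matrix(0, 2 * m, 3); b <- numeric(2 * m)
  dirs <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    k <- track$camera_id[i]
    p <- poses[[k]][[track$step_index[i] + 1L]]
    intr <- intrinsics[[k]]
    fpx <- focal_px(intr)
    xn <- c((track$x_px[i] - intr$principal_point_px[1]) / fpx,
            (track$y_px[i] - intr$principal_point_px[2]) / fpx)
    xu <- invert_distortion(rbind(xn), intr$distortion)
    R <- p$rotation
    r1 <- R[1, ] - xu[1] * R[3, ]
    r2 <- R[2, ] - xu[2] * R[3, ]
    A[2 * i - 1, ] <- r1; b[2 * i - 1] <- sum(r1 * p$center_mm)
    A[2 * i, ] <- r2; b[2 * i] <- sum(r2 * p$center_mm)
    d <- as.numeric(t(R) %*% c(xu[1], xu[2], 1))
    dirs[i, ] <- d / sqrt(sum(d^2))
  }
  ang <- 0
  for (i in seq_len(m - 1)) {
    ca <- dirs[(i + 1):m, , drop = FALSE] %*% dirs[i, ]
    ang <- max(ang, rad2deg(acos(pmin(pmax(ca, -1), 1))))
  }
  if (ang < min_angle_deg)
    stop("untriangulatable track: degenerate baseline (max ray angle ",
         sprintf("%.3f", ang), " deg)")
  X <- qr.solve(A, b)
  # Gauss-Newton refinement on reprojection error (vectorized over views)
  Rall <- t(vapply(seq_len(m), function(i)
    as.vector(poses[[track$camera_id[i]]][[track$step_index[i] + 1L]]$rotation),
    numeric(9)))
  Call <- t(vapply(seq_len(m), function(i)
    poses[[track$camera_id[i]]][[track$step_index[i] + 1L]]$center_mm,
    numeric(3)))
  ki <- track$camera_id
  fpx <- vapply(intrinsics, focal_px, numeric(1))[ki]
  ppx <- t(vapply(intrinsics, `[[`, numeric(2), "principal_point_px"))[ki, , drop = FALSE]
  dco <- t(vapply(intrinsics, `[[`, numeric(5), "distortion"))[ki, , drop = FALSE]
  reproj <- function(X) {
    d1 <- X[1] - Call[, 1]; d2 <- X[2] - Call[, 2]; d3 <- X[3] - Call[, 3]
    z <- Rall[, 3] * d1 + Rall[, 6] * d2 + Rall[, 9] * d3
    x <- (Rall[, 1] * d1 + Rall[, 4] * d2 + Rall[, 7] * d3) / z
    y <- (Rall[, 2] * d1 + Rall[, 5] * d2 + Rall[, 8] * d3) / z
    r2 <- x^2 + y^2
    rad <- 1 + r2 * (dco[, 1] + r2 * (dco[, 2] + r2 * dco[, 3]))
    xd <- x * rad + 2 * dco[, 4] * x * y + dco[, 5] * (r2 + 2 * x^2)
    yd <- y * rad + dco[, 4] * (r2 + 2 * y^2) + 2 * dco[, 5] * x * y
    drad <- dco[, 1] + r2 * (2 * dco[, 2] + 3 * dco[, 3] * r2)
    D11 <- rad + 2 * x^2 * drad + 2 * dco[, 4] * y + 6 * dco[, 5] * x
    D22 <- rad + 2 * y^2 * drad + 6 * dco[, 4] * y + 2 * dco[, 5] * x
    D12 <- 2 * x * y * drad + 2 * dco[, 4] * x + 2 * dco[, 5] * y
    G11 <- (Rall[, 1] - x * Rall[, 3]) / z
    G12 <- (Rall[, 4] - x * Rall[, 6]) / z
    G13 <- (Rall[, 7] - x * Rall[, 9]) / z
    G21 <- (Rall[, 2] - y * Rall[, 3]) / z
    G22 <- (Rall[, 5] - y * Rall[, 6]) / z
    G23 <- (Rall[, 8] - y * Rall[, 9]) / z
    J <- matrix(0, 2 * m, 3)
    J[c(TRUE, FALSE), ] <- fpx * cbind(D11 * G11 + D12 * G21,
                                       D11 * G12 + D12 * G22,
                                       D11 * G13 + D12 * G23)
    J[c(FALSE, TRUE), ] <- fpx * cbind(D12 * G11 + D22 * G21,
                                       D12 * G12 + D22 * G22,
                                       D12 * G13 + D22 * G23)
    r <- numeric(2 * m)
    r[c(TRUE, FALSE)] <- fpx * xd + ppx[, 1] - track$x_px
    r[c(FALSE, TRUE)] <- fpx * yd + ppx[, 2] - track$y_px
    list(r = r, J = J)
  }
  f0 <- reproj(X)
  for (it in 1:8) {
    dX <- try(qr.solve(f0$J, -f0$r), silent = TRUE)
    if (inherits(dX, "try-error")) break
    fn <- reproj(X + dX)
    if (sum(fn$r^2) >= sum(f0$r^2)) break
    X <- X + dX; f0 <- fn
    if (sqrt(sum(dX^2)) < 1e-10) break
  }
  as.numeric(X)
}

#' Triangulate many tracks against fixed cameras
#'
#' Forward intersection of every requested track using already-calibrated
#' poses and intrinsics (e.g. reconstructing plant or ruler points after the
#' measurement-bar calibration). Untriangulatable tracks are skipped.
#'
#' @param observations observation data.frame
#' @param poses list per camera of per-step `camera_pose`
#' @param intrinsics list of `camera_intrinsics`
#' @param point_ids tracks to triangulate (default: all)
#' @param kinds optional named kind lookup (`id -> kind`)
#' @return data.frame `id, x, y, z, kind`
#' @export
triangulate_tracks <- function(observations, poses, intrinsics,
                               point_ids = NULL, kinds = NULL) {
  if (!is.null(point_ids))
    observations <- observations[observations$point_id %in% point_ids, ]
  tracks <- split(observations, observations$point_id)
  ids <- as.numeric(names(tracks))
  out <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    Xi <- try(triangulate(tracks[[i]], poses, intrinsics), silent = TRUE)
    if (!inherits(Xi, "try-error")) out[[i]] <- c(ids[i], Xi)
  }
  got <- !vapply(out, is.null, logical(1))
  m <- do.call(rbind, out[got])
  if (is.null(m)) return(data.frame(id = numeric(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0),
                                    kind = character(0)))
  kind <- if (is.null(kinds)) "unknown" else unname(kinds[as.character(m[, 1])])
  data.frame(id = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4], kind = kind)
}

#' Solve a bundle problem by Levenberg-Marquardt
#'
#' Minimizes the total Huber-robustified reprojection error over intrinsics,
#' poses and points with sparse normal equations. The cost is monotone
#' non-increasing over accepted iterations; termination on relative cost
#' change below `tol`, an RMS floor, or `max_iter`.
#'
#' @param problem a `bundle_problem`
#' @param tol relative cost-change tolerance
#' @param max_iter iteration cap
#' @param rms_floor_px stop when the (per-coordinate) RMS residual falls
#'   below this (noiseless problems)
#' @param verbose print per-iteration cost
#' @return an object of class `bundle_solution`: refined `intrinsics`,
#'   `poses`, `points`, per-observation `residuals` (dx, dy, px),
#'   `rms_px` (per-coordinate RMS), `cost`, `converged`, `iterations`,
#'   plus the surviving `observations` and problem metadata
#' @export
bundle_adjust <- function(problem, tol = 1e-10, max_iter = 300,
                          rms_floor_px = 1e-8, verbose = FALSE) {
  st <- ba_state(problem)
  layout <- ba_layout(st, problem$intrinsic_free, fixed_pose = 1L)
  delta_h <- problem$huber_px
  r <- ba_residuals(st)
  hw <- huber_weights(r, delta_h)
  cost <- hw$cost
  lambda <- 1e-4
  nu <- 2
  converged <- FALSE
  iters <- 0L
  n <- length(st$u)
  for (it in seq_len(max_iter)) {
    iters <- it
    fw <- ba_forward(st)
    J <- ba_jacobian(st, layout, fw)
    sw <- sqrt(rep(hw$w, each = 2))
    Jw <- J * sw
    rw <- r * sw
    g <- as.numeric(Matrix::crossprod(Jw, rw))
    H <- Matrix::crossprod(Jw)
    dH <- Matrix::diag(H)
    dH[dH < 1e-12] <- 1e-12
    accepted <- FALSE
    for (try_i in 1:40) {
      Haug <- H + lambda * Matrix::Diagonal(x = dH)
      delta <- try(as.numeric(Matrix::solve(Haug, -g)), silent = TRUE)
      if (!inherits(delta, "try-error") && all(is.finite(delta))) {
        st_try <- ba_apply_step(st, layout, delta)
        r_try <- try(ba_residuals(st_try), silent = TRUE)
        if (!inherits(r_try, "try-error") && all(is.finite(r_try))) {
          hw_try <- huber_weights(r_try, delta_h)
          if (hw_try$cost < cost) {
            # Nielsen gain-ratio damping update
            pred <- 0.5 * sum(delta * (lambda * dH * delta - g))
            rho <- (cost - hw_try$cost) / max(pred, 1e-300)
            st <- st_try; r <- r_try; hw <- hw_try
            rel <- (cost - hw_try$cost) / max(cost, 1e-300)
            cost <- hw_try$cost
            lambda <- max(lambda * max(1 / 3, 1 - (2 * rho - 1)^3), 1e-14)
            nu <- 2
            accepted <- TRUE
            if (verbose)
              message(sprintf("iter %3d cost %.6e rms %.3e lambda %.1e",
                              it, cost, sqrt(sum(r^2) / (2 * n)), lambda))
            if (rel < tol || sqrt(sum(r^2) / (2 * n)) < rms_floor_px)
              converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * nu
      nu <- 2 * nu
      if (lambda > 1e12) break
    }
    if (!accepted) { converged <- cost < Inf; break }
    if (converged) break
  }
  out <- ba_unpack(st, problem)
  resid <- data.frame(problem$observations[, c("point_id", "camera_id",
                                               "step_index")],
                      dx = r[c(TRUE, FALSE)], dy = r[c(FALSE, TRUE)])
  structure(list(intrinsics = out$intrinsics, poses = out$poses,
                 points = out$points, residuals = resid,
                 rms_px = sqrt(sum(r^2) / (2 * n)), cost = cost,
                 converged = converged, iterations = iters,
                 observations = problem$observations,
                 huber_px = problem$huber_px,
                 intrinsic_free = problem$intrinsic_free,
                 turntable_step_deg = problem$turntable_step_deg,
                 n_steps = problem$n_steps, gauge = problem$gauge),
            class = "bundle_solution")
}

#' @export
print.bundle_solution <- function(x, ...) {
  cat(sprintf("bundle_solution: %d cameras, %d poses, %d points, %d observations\n",
              length(x$intrinsics), sum(lengths(x$poses)), nrow(x$points),
              nrow(x$residuals)))
  cat(sprintf("  RMS residual %.4g px; cost %.6g; %s after %d iterations\n",
              x$rms_px, x$cost,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Remove high-residual observations from a solved bundle
#'
#' Detections whose residual norm exceeds `threshold_px` are dropped, tracks
#' falling under 2 detections are removed entirely, and a new problem seeded
#' at the current solution is returned for re-adjustment. Iterating
#' reject/re-adjust reaches a fixed point.
#'
#' @param solution a `bundle_solution`
#' @param threshold_px residual-norm cutoff in pixels (e.g. 3 x the noise)
#' @param max_prune_frac abort if more than this fraction would be pruned
#' @return a `bundle_problem`
#' @export
reject_outliers <- function(solution, threshold_px, max_prune_frac = 0.5) {
  rho <- sqrt(solution$residuals$dx^2 + solution$residuals$dy^2)
  keep <- rho <= threshold_px
  if (mean(!keep) > max_prune_frac)
    stop(sprintf("outlier rejection would prune %.0f%% of observations; aborting",
                 100 * mean(!keep)))
  obs <- solution$observations[keep, ]
  tc <- table(obs$point_id)
  obs <- obs[obs$point_id %in% as.numeric(names(tc)[tc >= 2]), ]
  points <- solution$points[solution$points$id %in% obs$point_id, ]
  structure(list(observations = obs, intrinsics = solution$intrinsics,
                 poses = solution$poses, points = points,
                 huber_px = solution$huber_px,
                 intrinsic_free = solution$intrinsic_free,
                 turntable_step_deg = solution$turntable_step_deg,
                 n_steps = solution$n_steps, gauge = solution$gauge),
            class = "bundle_problem")
}

#' Closed-loop rotation residual of a solved revolution
#'
#' Per-step relative rotations of one camera are composed around the full
#' revolution; the wrap-around step (last back to first) is compared with
#' the chordal mean of the interior steps. On a consistent solution the two
#' agree; a pose broken by some angle shows up as that angle.
#'
#' @param solution a `bundle_solution` (or any list with `poses`,
#'   `turntable_step_deg`, `n_steps`)
#' @param camera_id which camera's revolution to check
#' @return angular misfit in degrees
#' @export
closed_loop_residual <- function(solution, camera_id = 1) {
  poses <- solution$poses[[camera_id]]
  S <- length(poses)
  if (abs(S * solution$turntable_step_deg - 360) > 1e-6)
    stop("closed loop requires a full revolution of steps")
  Rs <- lapply(poses, `[[`, "rotation")
  Qs <- lapply(seq_len(S - 1), function(j) Rs[[j + 1]] %*% t(Rs[[j]]))
  Qhat <- mean_rotation(Qs)
  Qwrap <- Rs[[1]] %*% t(Rs[[S]])
  rotation_angle_deg(Qwrap, Qhat)
}
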