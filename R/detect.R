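#' Bilinear sampling of an image at continuous pixel coordinates
#' @param img image matrix (height x width)
#' @param x,y pixel coordinates (pixel `img[r, c]` centered at `(c-.5, r-.5)`)
#' @keywords internal
sample_bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  cc <- pmin(pmax(x + 0.5, 1), nc)
  rr <- pmin(pmax(y + 0.5, 1), nr)
  c0 <- pmin(floor(cc), nc - 1); r0 <- pmin(floor(rr), nr - 1)
  fc <- cc - c0; fr <- rr - r0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Detect and decode circular coded targets
#'
#' Pipeline: global threshold (Otsu) -> connected components (EBImage) ->
#' solid elliptical blobs kept as central-disc candidates -> subpixel center
#' and ellipse from intensity-weighted moments -> code ring sampled along
#' the moment ellipse scaled to the ring radius -> cyclic decoding. A
#' detection is emitted only when the ring decodes to a code-book ID with a
#' confidence margin at or above `quality_min`; at most one detection per ID
#' per image (the best-quality one).
#'
#' @param img grayscale image matrix in `[0, 1]` (height x width)
#' @param min_area_px minimum central-disc area in pixels
#' @param quality_min minimum decoding confidence in `[0, 1]`
#' @param oversample ring samples per code bit
#' @return data.frame with columns `target_code`, `x_px`, `y_px`,
#'   `semi_major_px`, `semi_minor_px`, `theta_rad`, `quality`
#' @export
detect_targets <- function(img, min_area_px = 10, quality_min = 0.25,
                           oversample = 5) {
  empty <- data.frame(target_code = integer(0), x_px = numeric(0),
                      y_px = numeric(0), semi_major_px = numeric(0),
                      semi_minor_px = numeric(0), theta_rad = numeric(0),
                      quality = numeric(0))
  rng <- range(img)
  if (diff(rng) < 1e-6) return(empty)
  thr <- EBImage::otsu(EBImage::Image(t(img)))
  bin <- img > thr
  lab <- t(EBImage::bwlabel(EBImage::Image(t(bin))))
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  det <- empty
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- (idx - 1) %% nrow(img) + 1
  cols <- (idx - 1) %/% nrow(img) + 1
  for (l in seq_len(nlab)) {
    sel <- labs == l
    area <- sum(sel)
    if (area < min_area_px) next
    r <- rows[sel]; c <- cols[sel]
    # binary moments for the solidity test
    xb <- c - 0.5; yb <- r - 0.5
    mx <- mean(xb); my <- mean(yb)
    Sxx <- mean((xb - mx)^2); Syy <- mean((yb - my)^2)
    Sxy <- mean((xb - mx) * (yb - my))
    ev <- eigen(matrix(c(Sxx, Sxy, Sxy, Syy), 2, 2), symmetric = TRUE)
    lam <- pmax(ev$values, 1e-9)
    # uniform ellipse: eigenvalues = (semi-axis)^2 / 4
    a_bin <- 2 * sqrt(lam[1]); b_bin <- 2 * sqrt(lam[2])
    fill <- area / (pi * a_bin * b_bin)
    if (fill < 0.85 || fill > 1.25) next  # not a solid ellipse (ring arc etc.)
    # subpixel refinement: intensity-weighted moments over the blob plus its
    # anti-aliased border (pixels unassigned to any other component)
    r0 <- max(1L, min(r) - 2L); r1 <- min(nrow(img), max(r) + 2L)
    c0 <- max(1L, min(c) - 2L); c1 <- min(ncol(img), max(c) + 2L)
    wr <- r0:r1; wc <- c0:c1
    wlab <- lab[wr, wc, drop = FALSE]
    wimg <- img[wr, wc, drop = FALSE]
    wimg[wlab != 0 & wlab != l] <- 0
    # threshold-subtracted weights: zero-mean background contributes nothing,
    # so the centroid stays unbiased on lifted backgrounds
    wimg <- pmax(wimg - thr, 0)
    W <- sum(wimg)
    if (W <= 0) next
    gx <- outer(rep(1, length(wr)), wc - 0.5)
    gy <- outer(wr - 0.5, rep(1, length(wc)))
    cx <- sum(wimg * gx) / W; cy <- sum(wimg * gy) / W
    Cxx <- sum(wimg * (gx - cx)^2) / W
    Cyy <- sum(wimg * (gy - cy)^2) / W
    Cxy <- sum(wimg * (gx - cx) * (gy - cy)) / W
    ev <- eigen(matrix(c(Cxx, Cxy, Cxy, Cyy), 2, 2), symmetric = TRUE)
    lam <- pmax(ev$values, 1e-9)
    a <- 2 * sqrt(lam[1]); b <- 2 * sqrt(lam[2])
    theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    # affine map unit circle -> disc ellipse (symmetric square root)
    V <- ev$vectors
    A <- V %*% diag(2 * sqrt(lam)) %*% t(V)
    circ <- function(scale, n_ang) {
      ta <- (seq_len(n_ang) - 0.5) / n_ang * 2 * pi
      t(A %*% rbind(cos(ta), sin(ta))) * scale
    }
    # local intensity references: disc interior (white) and the dark gap
    # between disc and code ring; both must be uniform for a real target
    inter <- rbind(circ(0.35, 16), circ(0.7, 16))
    white_s <- sample_bilinear(img, cx + inter[, 1], cy + inter[, 2])
    gap_scale <- (TARGET_DISC_FRAC + TARGET_RING_IN) / 2 / TARGET_DISC_FRAC
    gap <- circ(gap_scale, 24)
    black_s <- sample_bilinear(img, cx + gap[, 1], cy + gap[, 2])
    white <- mean(white_s); black <- mean(black_s)
    contrast <- white - black
    if (contrast < 0.15) next
    mid <- (white + black) / 2
    if (min(white_s) < mid || max(black_s) > mid) next  # not disc + dark gap
    ring_scale <- (TARGET_RING_IN + TARGET_RING_OUT) / 2 / TARGET_DISC_FRAC
    nb <- RING_BITS * oversample
    ring_xy <- circ(ring_scale, nb)
    vals <- sample_bilinear(img, cx + ring_xy[, 1], cy + ring_xy[, 2])
    bit_means <- colMeans(matrix(vals, nrow = oversample))
    bits <- as.integer(bit_means > mid)
    quality <- max(0, min(1, min(abs(bit_means - mid)) / (contrast / 2)))
    code <- decode_ring_code(bits)
    if (is.na(code) || quality < quality_min) next
    det <- rbind(det, data.frame(target_code = code, x_px = cx, y_px = cy,
                                 semi_major_px = a, semi_minor_px = b,
                                 theta_rad = theta, quality = quality))
  }
  if (nrow(det) > 1) {
    det <- det[order(-det$quality), ]
    det <- det[!duplicated(det$target_code), ]
    det <- det[order(det$target_code), ]
    rownames(det) <- NULL
  }
  det
}

#' Write target detections to CSV
#' @param det detections data.frame from [detect_targets()]
#' @param image_id identifier stored in the first column
#' @param path CSV path
#' @export
write_detections <- function(det, image_id, path) {
  out <- cbind(image_id = image_id,
               det[, c("target_code", "x_px", "y_px", "quality")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
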