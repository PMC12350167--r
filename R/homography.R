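# Projective refinement of registration: corner keypoints matched by local
# phase correlation, robust consensus fit of a homography.
# Coordinates are (row, col), 0-based, per the package-wide convention.

#' Warp an image by a projective transform
#'
#' `H` maps moving-image coordinates `(row, col, 1)` to reference
#' coordinates. The output is rendered in the reference frame by inverse
#' mapping with bilinear interpolation; out-of-field pixels are 0.
#'
#' @param x Numeric matrix (moving image).
#' @param H 3 x 3 projective matrix.
#' @return Warped matrix of the same shape.
#' @export
warp_projective <- function(x, H) {
  stopifnot(all(dim(H) == c(3, 3)))
  Hi <- solve(H)
  nr <- nrow(x); nc <- ncol(x)
  r <- rep(seq_len(nr) - 1, times = nc)
  cc <- rep(seq_len(nc) - 1, each = nr)
  src <- Hi %*% rbind(r, cc, 1)
  sr <- src[1, ] / src[3, ]
  sc <- src[2, ] / src[3, ]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(ri, ci) {
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    v <- numeric(length(ri))
    v[ok] <- x[cbind(ri[ok] + 1, ci[ok] + 1)]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  matrix(out, nr, nc)
}

# Harris corner detector; returns 0-based (row, col) coordinates ordered by
# decreasing corner response, excluding a border margin.
harris_keypoints <- function(x, max_points = 200L, margin = 16L,
                             sigma = 1.5, kappa = 0.05,
                             rel_threshold = 0.01) {
  nr <- nrow(x); nc <- ncol(x)
  gx <- (rbind(x[-1, , drop = FALSE], x[nr, , drop = FALSE]) -
           rbind(x[1, , drop = FALSE], x[-nr, , drop = FALSE])) / 2
  gy <- (cbind(x[, -1, drop = FALSE], x[, nc, drop = FALSE]) -
           cbind(x[, 1, drop = FALSE], x[, -nc, drop = FALSE])) / 2
  Sxx <- gaussian_blur(gx * gx, sigma)
  Syy <- gaussian_blur(gy * gy, sigma)
  Sxy <- gaussian_blur(gx * gy, sigma)
  R <- Sxx * Syy - Sxy^2 - kappa * (Sxx + Syy)^2
  if (max(R) <= 0) return(matrix(numeric(0), ncol = 2))
  # 3x3 local maxima
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (R >= apply_shift(R, c(dr, dc)))
  }
  keep <- is_max & R > rel_threshold * max(R)
  keep[seq_len(min(margin, nr)), ] <- FALSE
  keep[seq(max(1, nr - margin + 1), nr), ] <- FALSE
  keep[, seq_len(min(margin, nc))] <- FALSE
  keep[, seq(max(1, nc - margin + 1), nc)] <- FALSE
  idx <- which(keep)
  if (!length(idx)) return(matrix(numeric(0), ncol = 2))
  ord <- order(R[idx], decreasing = TRUE)
  idx <- idx[ord][seq_len(min(max_points, length(idx)))]
  cbind((idx - 1) %% nr, (idx - 1) %/% nr)
}

# Subpixel keypoint matching: around each reference keypoint, a
# Hann-windowed, mean-removed patch is phase-correlated against the
# corresponding patch of the moving image. A second pass re-centres the
# moving patch on the integer part of the first estimate, removing the
# shrinkage bias the spatial window induces on off-centre content. Returns
# a list with matrices `ref` and `mov` of matched 0-based coordinates.
match_keypoints <- function(reference, moving, keypoints, half_window = 16L,
                            upsample = 20L, max_disp = 6) {
  nr <- nrow(reference); nc <- ncol(reference)
  n <- 2L * half_window + 1L
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  win <- outer(hann, hann)
  patch_shift <- function(r, c, off) {
    rw <- (r + off[1] - half_window):(r + off[1] + half_window)
    cw <- (c + off[2] - half_window):(c + off[2] + half_window)
    if (rw[1] < 1 || rw[n] > nr || cw[1] < 1 || cw[n] > nc) return(NULL)
    wr <- reference[(r - half_window):(r + half_window),
                    (c - half_window):(c + half_window)]
    wm <- moving[rw, cw]
    if (sd(wr) == 0 || sd(wm) == 0) return(NULL)
    d <- tryCatch(
      detect_shift((wr - mean(wr)) * win, (wm - mean(wm)) * win,
                   upsample = upsample),
      error = function(e) NULL
    )
    if (is.null(d)) NULL else d + off
  }
  ref_pts <- NULL; mov_pts <- NULL
  for (i in seq_len(nrow(keypoints))) {
    p <- keypoints[i, ]
    r <- p[1] + 1; c <- p[2] + 1
    d1 <- patch_shift(r, c, c(0L, 0L))
    if (is.null(d1) || any(abs(d1) > max_disp)) next
    d <- patch_shift(r, c, as.integer(round(d1)))
    if (is.null(d) || any(abs(d) > max_disp)) d <- d1
    ref_pts <- rbind(ref_pts, p)
    mov_pts <- rbind(mov_pts, p + d)
  }
  list(ref = ref_pts, mov = mov_pts)
}

# Normalized direct linear transform homography from >= 4 correspondences.
dlt_homography <- function(src, dst) {
  normalize_pts <- function(p) {
    mu <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, mu)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- rbind(c(s, 0, -s * mu[1]), c(0, s, -s * mu[2]), c(0, 0, 1))
    pn <- t(T %*% rbind(t(p), 1))[, 1:2, drop = FALSE]
    list(p = pn, T = T)
  }
  ns <- normalize_pts(src); nd <- normalize_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  H / H[3, 3]
}

project_pts <- function(H, p) {
  q <- H %*% rbind(t(p), 1)
  t(q[1:2, , drop = FALSE] / rep(q[3, ], each = 2))
}

# Random-consensus homography fit; reprojection tolerance in pixels.
ransac_homography <- function(src, dst, tol = 3, iterations = 500L, seed = 42L) {
  n <- nrow(src)
  fallback <- structure(diag(3), fallback = TRUE)
  if (is.null(src) || n < 4L) return(fallback)
  best_inliers <- integer(0)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      pick <- sample.int(n, 4L)
      H <- tryCatch(dlt_homography(src[pick, , drop = FALSE],
                                   dst[pick, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H) || any(!is.finite(H))) next
      err <- sqrt(rowSums((project_pts(H, src) - dst)^2))
      inl <- which(err < tol)
      if (length(inl) > length(best_inliers)) best_inliers <- inl
    }
  })
  if (length(best_inliers) < 4L) return(fallback)
  H <- dlt_homography(src[best_inliers, , drop = FALSE],
                      dst[best_inliers, , drop = FALSE])
  attr(H, "n_inliers") <- length(best_inliers)
  H
}

#' Detect a projective transform between two images
#'
#' Corner keypoints are detected on the reference, matched at subpixel
#' precision by local phase correlation against the moving image, and a
#' homography mapping moving to reference coordinates is fitted with a
#' random-consensus estimator (reprojection tolerance 3 px, fixed seed).
#' Intended as a refinement after shift correction, so residual
#' displacements are assumed small. With fewer than 4 robust matches the
#' identity matrix is returned with attribute `fallback = TRUE` (shift-only
#' registration).
#'
#' @param reference,moving Numeric matrices of identical shape.
#' @param max_points Maximum number of corner keypoints.
#' @param tol RANSAC reprojection tolerance in pixels.
#' @param seed Seed of the consensus sampler (recorded for reproducibility).
#' @return 3 x 3 matrix mapping moving `(row, col, 1)` to reference
#'   coordinates; attribute `fallback` is set when estimation degenerated.
#' @export
detect_homography <- function(reference, moving, max_points = 200L,
                              tol = 3, seed = 42L) {
  stopifnot(all(dim(reference) == dim(moving)))
  kp <- harris_keypoints(reference, max_points = max_points)
  if (!nrow(kp)) return(structure(diag(3), fallback = TRUE))
  m <- match_keypoints(reference, moving, kp)
  ransac_homography(m$mov, m$ref, tol = tol, seed = seed)
}
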