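#' Preprocess a registration reference image
#'
#' Standard conditioning chain for nuclear or pan-protein reference channels
#' before shift detection: percentile clipping, z-scoring, min-max scaling to
#' \[0, 1\], Gaussian blurring, and zeroing of all values below a percentile
#' of the blurred image to sharpen the contrast between stained structures
#' and background.
#'
#' @param x Numeric matrix (reference channel).
#' @param clip_low_pct,clip_high_pct Clipping percentiles (defaults 1 and
#'   99.9).
#' @param blur_sigma Gaussian blur sigma in pixels (default 1; 0 disables).
#' @param zero_below_pct Percentile of the blurred image below which values
#'   are set to 0 (default 70).
#' @return Preprocessed matrix in \[0, 1\]. A constant input returns all
#'   zeros with a warning.
#' @export
preprocess_reference <- function(x, clip_low_pct = 1, clip_high_pct = 99.9,
                                 blur_sigma = 1, zero_below_pct = 70) {
  stopifnot(clip_low_pct >= 0, clip_high_pct <= 100,
            clip_low_pct < clip_high_pct)
  b <- percentile(x, c(clip_low_pct, clip_high_pct))
  y <- pmin(pmax(x, b[1]), b[2])
  dim(y) <- dim(x)
  if (max(y) - min(y) <= 0) {
    warning("constant reference image: returning zeros")
    return(y * 0)
  }
  y <- zscore(y)
  y <- rescale01(y)
  y <- gaussian_blur(y, blur_sigma)
  th <- percentile(y, zero_below_pct)
  y[y < th] <- 0
  y
}

#' Match an image's histogram to a reference
#'
#' Monotone quantile mapping: each intensity of `moving` is replaced by the
#' reference value at the same empirical quantile, so the output's sorted
#' values approximate the reference's distribution.
#'
#' @param moving,reference Numeric matrices (shapes may differ).
#' @return Matrix shaped like `moving`.
#' @export
match_histogram <- function(moving, reference) {
  if (!length(moving) || !length(reference)) stop("empty image")
  mv <- as.vector(moving)
  uv <- sort(unique(mv))
  cnt <- tabulate(match(mv, uv), nbins = length(uv))
  m_quant <- cumsum(cnt) / length(mv)
  rv <- sort(as.vector(reference))
  r_quant <- seq_along(rv) / length(rv)
  mapped <- stats::approx(r_quant, rv, xout = m_quant, rule = 2, ties = "ordered")$y
  out <- mapped[match(mv, uv)]
  dim(out) <- dim(moving)
  out
}

fft_freqs <- function(n) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Detect the translation between two images by phase cross-correlation
#'
#' Returns the offset `d = (d_row, d_col)` of `moving` relative to
#' `reference`, i.e. `moving` looks like `reference` translated by `+d`.
#' Subpixel resolution `1/upsample` is achieved by evaluating the
#' cross-correlation on a locally upsampled discrete Fourier transform
#' around the integer peak.
#'
#' @param reference,moving Numeric matrices of identical shape, comparably
#'   preprocessed.
#' @param upsample Integer >= 1 subpixel upsampling factor.
#' @return Numeric `(d_row, d_col)`.
#' @export
detect_shift <- function(reference, moving, upsample = 1L) {
  stopifnot(all(dim(reference) == dim(moving)))
  upsample <- as.integer(upsample)
  stopifnot(upsample >= 1L)
  if (all(reference == 0) || all(moving == 0)) {
    stop("degenerate input: all-zero image in shift detection")
  }
  H <- nrow(reference); W <- ncol(reference)
  Q <- stats::fft(reference) * Conj(stats::fft(moving))
  mag <- Mod(Q)
  Q <- Q / pmax(mag, .Machine$double.eps)
  cc <- stats::fft(Q, inverse = TRUE)
  peak <- which.max(Mod(cc)) - 1L
  sr <- peak %% H
  sc <- peak %/% H
  if (sr > H / 2) sr <- sr - H
  if (sc > W / 2) sc <- sc - W
  s <- as.numeric(c(sr, sc)) # peak position; offset d = -s
  if (upsample > 1L) {
    # refine by evaluating the correlation on a 1/upsample grid around s
    half <- ceiling(1.5 * upsample) / upsample
    gr <- seq(s[1] - half, s[1] + half, by = 1 / upsample)
    gc <- seq(s[2] - half, s[2] + half, by = 1 / upsample)
    kr <- fft_freqs(H); kc <- fft_freqs(W)
    Er <- exp(2i * pi * outer(gr, kr) / H)     # |gr| x H
    Ec <- exp(2i * pi * outer(kc, gc) / W)     # W x |gc|
    CC <- Er %*% Q %*% Ec
    idx <- which.max(Mod(CC))
    s <- c(gr[(idx - 1) %% length(gr) + 1], gc[(idx - 1) %/% length(gr) + 1])
  }
  -s
}

gaussian_kernel2d <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity index (SSIM) between two images
#'
#' Mean local SSIM with a Gaussian weighting window, used to grade
#' registration quality before and after alignment.
#'
#' @param a,b Numeric matrices of identical shape.
#' @param size,sigma Window size and Gaussian sigma (defaults 11, 1.5).
#' @param data_range Dynamic range `L`; defaults to the joint range of both
#'   images.
#' @return Scalar in \[-1, 1\].
#' @export
ssim <- function(a, b, size = 11L, sigma = 1.5, data_range = NULL) {
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(data_range)) {
    data_range <- max(a, b) - min(a, b)
  }
  if (data_range <= 0) return(1)
  k <- gaussian_kernel2d(size, sigma)
  smooth <- function(x) as.matrix(EBImage::filter2(EBImage::Image(x), k))
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_a <- smooth(a); mu_b <- smooth(b)
  var_a <- smooth(a * a) - mu_a^2
  var_b <- smooth(b * b) - mu_b^2
  cov_ab <- smooth(a * b) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2)
  mean(num / den)
}

#' Registration quality flags
#'
#' Applies the four acceptance rules used for manual-review triage of
#' aligned imaging cycles: the SSIM decreased after registration; the SSIM
#' after registration is below 0.3; any shift component exceeds 300 pixels;
#' or the SSIM after registration is below 0.8 while the improvement is
#' below 0.05.
#'
#' @param ssim_before,ssim_after SSIM values before/after alignment.
#' @param shift Correction `(d_row, d_col)`.
#' @return Character vector of raised flags (empty when accepted), a subset
#'   of `c("decreased", "low_ssim", "large_offset",
#'   "low_ssim_small_improvement")`.
#' @export
registration_flags <- function(ssim_before, ssim_after, shift) {
  flags <- character()
  if (ssim_after < ssim_before) flags <- c(flags, "decreased")
  if (ssim_after < 0.3) flags <- c(flags, "low_ssim")
  if (any(abs(shift) > 300)) flags <- c(flags, "large_offset")
  if (ssim_after < 0.8 && (ssim_after - ssim_before) < 0.05) {
    flags <- c(flags, "low_ssim_small_improvement")
  }
  flags
}

#' Registration result
#'
#' @param shift Correction `(d_row, d_col)` applied to the moving cycle.
#' @param ssim_before,ssim_after SSIM versus the reference before/after.
#' @param homography Optional 3 x 3 projective matrix (moving to reference,
#'   applied after the shift).
#' @param flags Character vector from [registration_flags()].
#' @return An object of class `pp_registration`; `accepted` is `TRUE` iff no
#'   flags were raised.
#' @export
registration_result <- function(shift, ssim_before, ssim_after,
                                homography = NULL, flags = NULL) {
  if (is.null(flags)) flags <- registration_flags(ssim_before, ssim_after, shift)
  stopifnot(all(is.finite(shift)))
  structure(
    list(shift = as.numeric(shift), homography = homography,
         ssim_before = ssim_before, ssim_after = ssim_after,
         flags = flags, accepted = length(flags) == 0L),
    class = "pp_registration"
  )
}

#' Evaluate a registration against the reference
#'
#' Computes before/after SSIM and applies the QC flag rules.
#'
#' @param reference Reference image (first cycle).
#' @param moving_before Moving image before alignment.
#' @param moving_after Moving image after alignment.
#' @param shift Applied correction `(d_row, d_col)`.
#' @return A [registration_result()].
#' @export
evaluate_registration <- function(reference, moving_before, moving_after, shift) {
  sb <- ssim(reference, moving_before)
  sa <- ssim(reference, moving_after)
  registration_result(shift, sb, sa)
}

#' Translate an image by a (possibly fractional) shift
#'
#' Positive `d_row` moves content down, positive `d_col` moves content
#' right. Integer shifts are exact; fractional shifts use bilinear
#' interpolation. Out-of-field pixels are filled with 0.
#'
#' @param x Numeric matrix.
#' @param shift `(d_row, d_col)`.
#' @return Shifted matrix of the same shape.
#' @export
apply_shift <- function(x, shift) {
  if (all(shift == round(shift))) {
    d <- as.integer(round(shift))
    H <- nrow(x); W <- ncol(x)
    out <- matrix(0, H, W)
    src_r <- seq_len(H) - d[1]
    src_c <- seq_len(W) - d[2]
    ok_r <- src_r >= 1 & src_r <= H
    ok_c <- src_c >= 1 & src_c <= W
    out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c], drop = FALSE]
    return(out)
  }
  Hm <- diag(3)
  Hm[1, 3] <- shift[1]
  Hm[2, 3] <- shift[2]
  warp_projective(x, Hm)
}

#' Apply a registration result to a whole image stack
#'
#' All channels of the stack are transformed identically: first the shift
#' correction, then the optional projective refinement. Out-of-field pixels
#' are filled with 0.
#'
#' @param stack A [multiplex_image()] (typically all channels of one cycle).
#' @param result A [registration_result()].
#' @return A transformed `pp_image`.
#' @export
apply_transform <- function(stack, result) {
  stopifnot(inherits(stack, "pp_image"), inherits(result, "pp_registration"))
  data <- stack$data
  for (ch in seq_len(dim(data)[3])) {
    plane <- apply_shift(data[, , ch], result$shift)
    if (!is.null(result$homography)) {
      plane <- warp_projective(plane, result$homography)
    }
    data[, , ch] <- plane
  }
  multiplex_image(data, stack$channels, stack$mask, stack$fov_id, stack$sample_id)
}

#' Common crop window after registration
#'
#' Two policies: `global_max_offset` removes `ceil(max |shift|)` pixels from
#' all four sides (yielding equally inset frames), `per_fov_overlap` keeps
#' the intersection rectangle of all shifted fields.
#'
#' @param shifts List (or n x 2 matrix) of applied corrections
#'   `(d_row, d_col)`.
#' @param mode `"global_max_offset"` or `"per_fov_overlap"`.
#' @param shape `(H, W)` of the frames.
#' @param fov_id Identifier used in error messages.
#' @return List with integer ranges `rows = c(first, last)`,
#'   `cols = c(first, last)` (1-based, inclusive).
#' @export
crop_to_overlap <- function(shifts, mode = c("global_max_offset", "per_fov_overlap"),
                            shape, fov_id = "?") {
  mode <- match.arg(mode)
  if (is.list(shifts)) shifts <- do.call(rbind, shifts)
  shifts <- matrix(as.numeric(shifts), ncol = 2)
  if (!nrow(shifts)) stop("at least one shift required")
  H <- shape[1]; W <- shape[2]
  if (mode == "global_max_offset") {
    m <- ceiling(max(abs(shifts)))
    rows <- c(m + 1, H - m)
    cols <- c(m + 1, W - m)
  } else {
    rows <- c(1 + max(0, ceiling(max(shifts[, 1]))),
              H + min(0, floor(min(shifts[, 1]))))
    cols <- c(1 + max(0, ceiling(max(shifts[, 2]))),
              W + min(0, floor(min(shifts[, 2]))))
  }
  if (rows[1] > rows[2] || cols[1] > cols[2]) {
    stop("empty overlap after registration for FOV ", fov_id)
  }
  list(rows = as.integer(rows), cols = as.integer(cols))
}

crop_stack <- function(stack, window) {
  data <- stack$data[window$rows[1]:window$rows[2],
                     window$cols[1]:window$cols[2], , drop = FALSE]
  mask <- stack$mask
  if (!is.null(mask)) {
    mask <- mask[window$rows[1]:window$rows[2], window$cols[1]:window$cols[2]]
  }
  out <- multiplex_image(data, stack$channels, mask, stack$fov_id, stack$sample_id)
  out$crop <- window
  out
}

#' Register all cycles of a field of view to the first cycle
#'
#' For every cycle after the first, the cycle's reference channel is
#' preprocessed ([preprocess_reference()]), histogram-matched to the
#' first-cycle reference, shift-detected by phase correlation (optionally
#' refined by a projective keypoint fit), quality-controlled by SSIM, and
#' the resulting transform is applied to all channels of that cycle.
#' Finally all channels are cropped to a common window.
#'
#' @param stack A [multiplex_image()] holding all cycles/channels of a FOV.
#' @param upsample Phase-correlation upsampling factor (default 5).
#' @param homography Also fit a projective refinement per cycle.
#' @param crop Crop policy: `"global_max_offset"`, `"per_fov_overlap"` or
#'   `"none"`.
#' @param hist_match Histogram-match later references to the first cycle.
#' @param drop_flagged Zero out cycles whose registration was flagged
#'   (default `FALSE`: flags are reported for manual review, not enforced).
#' @param ... Passed to [preprocess_reference()].
#' @return List with `stack` (aligned, cropped `pp_image` carrying `$crop`),
#'   `qc` (per-cycle data frame with shifts, SSIMs and flags) and `results`
#'   (list of [registration_result()] per cycle).
#' @export
register_fov <- function(stack, upsample = 5L, homography = FALSE,
                         crop = c("global_max_offset", "per_fov_overlap", "none"),
                         hist_match = TRUE, drop_flagged = FALSE, ...) {
  crop <- match.arg(crop)
  ch <- stack$channels
  cycles <- sort(unique(ch$cycle))
  ref_idx <- vapply(cycles, function(cy) {
    i <- which(ch$cycle == cy & ch$is_reference)
    if (!length(i)) stop("cycle ", cy, " has no reference channel")
    i[1]
  }, integer(1))
  pre <- function(i) preprocess_reference(stack$data[, , i], ...)
  p1 <- pre(ref_idx[1])
  data <- stack$data
  results <- list()
  qc <- NULL
  shifts <- matrix(0, nrow = length(cycles), ncol = 2)
  for (j in seq_along(cycles)[-1]) {
    cy <- cycles[j]
    pj <- pre(ref_idx[j])
    if (hist_match) pj <- match_histogram(pj, p1)
    d <- detect_shift(p1, pj, upsample = upsample)
    correction <- -d
    Hm <- NULL
    aligned_ref <- apply_shift(pj, correction)
    if (homography) {
      Hm <- detect_homography(p1, aligned_ref)
      if (isTRUE(attr(Hm, "fallback"))) Hm <- NULL
      if (!is.null(Hm)) aligned_ref <- warp_projective(aligned_ref, Hm)
    }
    sb <- ssim(p1, pj)
    sa <- ssim(p1, aligned_ref)
    res <- registration_result(correction, sb, sa, homography = Hm)
    results[[as.character(cy)]] <- res
    shifts[j, ] <- correction
    cyc_ch <- which(ch$cycle == cy)
    for (i in cyc_ch) {
      plane <- apply_shift(data[, , i], correction)
      if (!is.null(Hm)) plane <- warp_projective(plane, Hm)
      if (drop_flagged && !res$accepted) plane[] <- 0
      data[, , i] <- plane
    }
    qc <- rbind(qc, data.frame(
      fov_id = stack$fov_id, cycle = cy,
      d_row = correction[1], d_col = correction[2],
      ssim_before = sb, ssim_after = sa,
      flags = paste(res$flags, collapse = ";"),
      accepted = res$accepted, stringsAsFactors = FALSE
    ))
  }
  out <- multiplex_image(data, ch, stack$mask, stack$fov_id, stack$sample_id)
  if (crop != "none" && length(cycles) > 1L) {
    window <- crop_to_overlap(shifts, crop, dim(data)[1:2], stack$fov_id)
    out <- crop_stack(out, window)
  } else {
    out$crop <- list(rows = c(1L, dim(data)[1]), cols = c(1L, dim(data)[2]))
  }
  list(stack = out, qc = qc, results = results)
}
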