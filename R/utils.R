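#' Percentile with linear interpolation between order statistics
#'
#' Thin wrapper around [stats::quantile()] type 7 (the linear-interpolation
#' convention used throughout the package, fixed for reproducibility).
#'
#' @param x Numeric vector.
#' @param p Percentile(s) in \[0, 100\].
#' @return Numeric vector of percentile values.
#' @export
percentile <- function(x, p) {
  stopifnot(all(p >= 0 & p <= 100))
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

#' Min-max rescale to \[0, 1\]
#'
#' Constant input maps to all zeros (with a warning) rather than NaN.
#' @param x Numeric array.
#' @return Array of the same shape with range \[0, 1\].
#' @export
rescale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] - r[1] <= 0) {
    warning("constant image: rescale01() returns zeros")
    return(array(0, dim = dim(x) %||% length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Z-score standardization (population standard deviation)
#'
#' @param x Numeric vector or array.
#' @return Standardized values with mean 0 and population s.d. 1. A constant
#'   input returns zeros with a warning.
#' @export
zscore <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s <= 0) {
    warning("constant input: zscore() returns zeros")
    return(x * 0)
  }
  (x - mu) / s
}

#' Otsu threshold of a grayscale image
#'
#' Rescales to \[0, 1\] and applies Otsu's between-class-variance criterion at
#' 256 histogram levels (via EBImage), mapping the threshold back to the
#' input scale. Warns when the histogram looks unimodal (threshold still
#' returned).
#'
#' @param x Numeric matrix.
#' @param levels Number of histogram bins.
#' @return Scalar threshold on the input intensity scale; pixels strictly
#'   above it are foreground.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  r <- range(x, finite = TRUE)
  if (r[2] - r[1] <= 0) {
    warning("constant image: Otsu threshold degenerate")
    return(r[1])
  }
  y <- (x - r[1]) / (r[2] - r[1])
  th <- EBImage::otsu(EBImage::Image(y), range = c(0, 1), levels = levels)
  th * (r[2] - r[1]) + r[1]
}

# Gaussian blur that tolerates sigma = 0 and plain matrices.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  y <- EBImage::gblur(EBImage::Image(x), sigma = sigma)
  matrix(as.numeric(y), nrow(x), ncol(x))
}

# internal: stable RNG scope. Runs expr with a local seed without disturbing
# the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
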