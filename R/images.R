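#' Read a single-channel TIFF as a numeric matrix
#'
#' Integer TIFFs (8/16-bit) are returned at their native integer values
#' converted to double; no implicit rescaling to \[0, 1\] is performed. Float
#' TIFFs are returned as stored.
#'
#' @param path Path to a TIFF file.
#' @return Numeric matrix (rows x cols).
#' @export
read_tiff_channel <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (is.list(x)) x <- x[[1]]
  if (length(dim(x)) == 3L) x <- x[, , 1]
  storage.mode(x) <- "double"
  x
}

#' Write a numeric matrix as a 16-bit unsigned-integer TIFF
#'
#' Values are rounded to integers; they must fit 0..65535.
#'
#' @param x Numeric matrix of nonnegative intensities.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiff_uint16 <- function(x, path) {
  x <- round(x)
  if (min(x) < 0 || max(x) > 65535) {
    stop("intensities outside the unsigned 16-bit range")
  }
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Multichannel image stack
#'
#' Container for an aligned (or raw) H x W x C intensity stack with ordered
#' channel metadata, an optional analysis mask and identifiers.
#'
#' @param data Numeric H x W x C array of finite, nonnegative intensities.
#' @param channels Channel table ([channel_meta()]) with C rows, in stack
#'   order.
#' @param mask Optional H x W logical matrix (`TRUE` = analysable tissue).
#' @param fov_id,sample_id Identifiers.
#' @return An object of class `pp_image`.
#' @export
multiplex_image <- function(data, channels, mask = NULL,
                            fov_id = NA_character_, sample_id = NA_character_) {
  if (length(dim(data)) == 2L) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3] != nrow(channels)) {
    stop("channel count mismatch: data has ", dim(data)[3],
         " planes, metadata has ", nrow(channels), " rows")
  }
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(data)[1:2]))
  }
  structure(
    list(data = data, channels = channels, mask = mask,
         fov_id = fov_id, sample_id = sample_id),
    class = "pp_image"
  )
}

#' @export
print.pp_image <- function(x, ...) {
  d <- dim(x$data)
  cat("Multiplex image ", x$fov_id, ": ", d[1], "x", d[2], " px, ",
      d[3], " channels", if (!is.null(x$mask)) ", masked", "\n", sep = "")
  invisible(x)
}

#' Read the full image stack of a field of view
#'
#' Loads every channel file listed in the manifest for `fov_id`, in manifest
#' channel order, into one H x W x C stack. Integer data are converted to
#' double at their native values.
#'
#' @param manifest A `pp_manifest`.
#' @param fov_id FOV identifier present in the manifest.
#' @return A [multiplex_image()].
#' @export
read_image_stack <- function(manifest, fov_id) {
  i <- match(fov_id, manifest$fovs$fov_id)
  if (is.na(i)) stop("unknown FOV: ", fov_id)
  keys <- channel_key(manifest$channels$cycle, manifest$channels$name)
  paths <- file.path(manifest$base_dir, manifest$files[[fov_id]][keys])
  planes <- vector("list", length(keys))
  for (j in seq_along(keys)) {
    if (!file.exists(paths[j])) {
      stop("missing image for FOV ", fov_id, ", channel ", keys[j])
    }
    planes[[j]] <- read_tiff_channel(paths[j])
  }
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("channel images of FOV ", fov_id, " have mismatched shapes")
  }
  data <- array(unlist(planes, use.names = FALSE),
                c(dims[1, 1], dims[2, 1], length(planes)))
  multiplex_image(data, manifest$channels, fov_id = fov_id,
                  sample_id = manifest$fovs$sample_id[i])
}

#' Downscale an image by local block means
#'
#' Each output pixel is the arithmetic mean of a `factor` x `factor` block of
#' input pixels. Trailing rows/columns that do not fill a block are dropped.
#' The global mean is conserved exactly when `factor` divides both
#' dimensions.
#'
#' @param x Numeric matrix.
#' @param factor Integer >= 1.
#' @return Matrix of shape `(nrow(x) %/% factor, ncol(x) %/% factor)`.
#' @export
downscale_local_mean <- function(x, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(x)
  H <- nrow(x) %/% factor
  W <- ncol(x) %/% factor
  if (H < 1L || W < 1L) stop("factor larger than image")
  x <- x[seq_len(H * factor), seq_len(W * factor), drop = FALSE]
  dim(x) <- c(factor, H, factor, W)
  out <- apply(x, c(2, 4), mean)
  matrix(out, H, W)
}

#' Cluster label image
#'
#' Integer H x W label map; `-1` marks masked/background pixels, analysable
#' pixels carry labels `0 .. n_clusters - 1`.
#'
#' @param labels Integer matrix.
#' @param fov_id Identifier.
#' @param n_clusters Number of clusters (labels must lie in
#'   `{-1} U [0, n_clusters)`); inferred from the data when `NULL`.
#' @return An object of class `pp_cluster_image`.
#' @export
cluster_image <- function(labels, fov_id = NA_character_, n_clusters = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(n_clusters)) n_clusters <- max(labels, -1L) + 1L
  if (any(labels < -1L) || any(labels >= n_clusters)) {
    stop("labels must lie in {-1} U [0, n_clusters)")
  }
  structure(list(labels = labels, fov_id = fov_id,
                 n_clusters = as.integer(n_clusters)),
            class = "pp_cluster_image")
}

#' Write / read a cluster label image as an integer-label TIFF
#'
#' Labels (including the `-1` mask sentinel) are stored losslessly in a
#' 16-bit raster with a +1 offset; round-tripping returns identical labels.
#'
#' @param x A `pp_cluster_image`.
#' @param path Output path.
#' @return `write_cluster_image()` returns `path` invisibly;
#'   `read_cluster_image()` returns a `pp_cluster_image`.
#' @export
write_cluster_image <- function(x, path) {
  stopifnot(inherits(x, "pp_cluster_image"))
  if (x$n_clusters > 65534L) stop("too many clusters for 16-bit label raster")
  write_tiff_uint16(x$labels + 1L, path)
}

#' @rdname write_cluster_image
#' @param fov_id Identifier attached to the read image.
#' @export
read_cluster_image <- function(path, fov_id = NA_character_) {
  lab <- read_tiff_channel(path) - 1
  storage.mode(lab) <- "integer"
  cluster_image(lab, fov_id = fov_id)
}

#' Write / read a delimited table
#'
#' CSV with header, no row names; a zero-row table yields a header-only file.
#'
#' @param table A `data.frame`.
#' @param path File path.
#' @return `write_table()` returns `path` invisibly; `read_table()` the
#'   `data.frame`.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
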