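# Weighted stratified subsampling and per-channel intensity normalization.

# Equal-weight largest-remainder allocation of `total` draws over `ids`;
# the remainder goes to the lexicographically first ids (documented
# tie-break).
allocate_counts <- function(total, ids) {
  ids <- sort(unique(as.character(ids)))
  n <- length(ids)
  base <- total %/% n
  rem <- total %% n
  counts <- rep(base, n)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  setNames(as.integer(counts), ids)
}

#' Weighted stratified pixel subsample
#'
#' Draws `total_n` pixel positions per imaging plate, allocated top-down
#' with equal weights at every hierarchy level (condition, then sample,
#' then FOV) using largest-remainder rounding with a lexicographic
#' tie-break, so that no condition or sample dominates the training data.
#' Within a FOV, positions are drawn uniformly without replacement from the
#' analysis mask.
#'
#' @param manifest A `pp_manifest`.
#' @param masks Named list (by `fov_id`) of H x W logical analysis masks.
#' @param total_n Number of pixel positions per plate.
#' @param seed RNG seed; identical seeds reproduce identical coordinates.
#' @return `data.frame` with columns `plate_id`, `condition`, `sample_id`,
#'   `fov_id`, `row`, `col` (1-based coordinates into the masks).
#' @export
weighted_subsample <- function(manifest, masks, total_n, seed = 1L) {
  sm <- manifest$samples
  fv <- manifest$fovs
  out <- vector("list", 0)
  with_seed(seed, {
    for (plate in sort(unique(sm$plate_id))) {
      plate_samples <- sm[sm$plate_id == plate, , drop = FALSE]
      cond_alloc <- allocate_counts(total_n, plate_samples$condition)
      for (cond in names(cond_alloc)) {
        cs <- plate_samples$sample_id[plate_samples$condition == cond]
        samp_alloc <- allocate_counts(cond_alloc[[cond]], cs)
        for (sid in names(samp_alloc)) {
          fids <- fv$fov_id[fv$sample_id == sid]
          if (!length(fids)) stop("sample ", sid, " has no FOVs")
          fov_alloc <- allocate_counts(samp_alloc[[sid]], fids)
          for (fid in names(fov_alloc)) {
            n_i <- fov_alloc[[fid]]
            if (n_i == 0L) next
            m <- masks[[fid]]
            if (is.null(m)) stop("no mask provided for FOV ", fid)
            avail <- which(m)
            if (!length(avail)) {
              stop("stratum has zero analysable pixels: plate ", plate,
                   " / condition ", cond, " / sample ", sid, " / FOV ", fid)
            }
            if (n_i > length(avail)) {
              stop("requested ", n_i, " pixels but only ", length(avail),
                   " analysable in FOV ", fid)
            }
            pick <- sample(avail, n_i, replace = FALSE)
            out[[length(out) + 1L]] <- data.frame(
              plate_id = plate, condition = cond, sample_id = sid,
              fov_id = fid,
              row = (pick - 1L) %% nrow(m) + 1L,
              col = (pick - 1L) %/% nrow(m) + 1L,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  })
  do.call(rbind, out)
}

#' Extract channel values at subsampled coordinates
#'
#' @param stacks Named list (by `fov_id`) of aligned [multiplex_image()]s.
#' @param coords Output of [weighted_subsample()].
#' @param channels Optional character vector restricting/ordering the
#'   extracted channels (default: all channels of the first stack).
#' @return N x C numeric matrix with marker names as column names.
#' @export
subsample_values <- function(stacks, coords, channels = NULL) {
  first <- stacks[[1]]
  if (is.null(channels)) channels <- first$channels$name
  ch_idx <- match(channels, first$channels$name)
  if (anyNA(ch_idx)) stop("unknown channel(s): ",
                          paste(channels[is.na(ch_idx)], collapse = ", "))
  out <- matrix(NA_real_, nrow(coords), length(channels),
                dimnames = list(NULL, channels))
  for (fid in unique(coords$fov_id)) {
    rows <- which(coords$fov_id == fid)
    st <- stacks[[fid]]
    if (is.null(st)) stop("no stack provided for FOV ", fid)
    for (j in seq_along(ch_idx)) {
      out[rows, j] <- st$data[, , ch_idx[j]][cbind(coords$row[rows], coords$col[rows])]
    }
  }
  out
}

#' Fit per-channel clipping bounds
#'
#' Percentile mode derives `(low, high)` bounds from the pooled subsample
#' per channel (defaults: 50th and 99.7th percentiles); absolute mode takes
#' user-specified bounds.
#'
#' @param values N x C matrix of subsampled channel intensities (columns
#'   named by marker).
#' @param p_lo,p_hi Percentiles for percentile mode.
#' @param absolute Optional 2-row matrix / data.frame of `(low, high)` per
#'   channel for absolute mode.
#' @return A `pp_clip` object: `data.frame(channel, low, high)` plus the
#'   `source` attribute.
#' @export
fit_clip <- function(values, p_lo = 50, p_hi = 99.7, absolute = NULL) {
  chn <- colnames(values)
  if (is.null(chn)) chn <- paste0("ch", seq_len(ncol(values)))
  if (!is.null(absolute)) {
    ab <- as.matrix(absolute)
    spec <- data.frame(channel = chn, low = unname(ab[1, ]),
                       high = unname(ab[2, ]), stringsAsFactors = FALSE)
    source <- "absolute"
  } else {
    lo <- unname(apply(values, 2, percentile, p = p_lo))
    hi <- unname(apply(values, 2, percentile, p = p_hi))
    spec <- data.frame(channel = chn, low = lo, high = hi,
                       stringsAsFactors = FALSE)
    source <- sprintf("percentile(%g,%g)", p_lo, p_hi)
  }
  bad <- spec$low >= spec$high
  if (any(bad)) {
    stop("degenerate clip bounds (low >= high) for channel(s): ",
         paste(spec$channel[bad], collapse = ", "))
  }
  structure(spec, source = source, class = c("pp_clip", "data.frame"))
}

clip_bounds_for <- function(spec, channels) {
  i <- match(channels, spec$channel)
  if (anyNA(i)) stop("clip spec lacks channel(s): ",
                     paste(channels[is.na(i)], collapse = ", "))
  spec[i, , drop = FALSE]
}

#' Apply clipping / normalization
#'
#' `apply_clip()` replaces values outside `[low, high]` by the bound
#' (idempotent); `apply_normalize()` maps `[low, high]` affinely onto
#' `[0, 1]`. Both accept an N x C matrix (columns named by marker) or a
#' [multiplex_image()].
#'
#' @param x Matrix or `pp_image`.
#' @param spec A `pp_clip` from [fit_clip()].
#' @return Same type as `x`.
#' @export
apply_clip <- function(x, spec) {
  if (inherits(x, "pp_image")) {
    b <- clip_bounds_for(spec, x$channels$name)
    for (j in seq_len(nrow(b))) {
      x$data[, , j] <- pmin(pmax(x$data[, , j], b$low[j]), b$high[j])
    }
    return(x)
  }
  b <- clip_bounds_for(spec, colnames(x))
  for (j in seq_len(ncol(x))) {
    x[, j] <- pmin(pmax(x[, j], b$low[j]), b$high[j])
  }
  x
}

#' @rdname apply_clip
#' @export
apply_normalize <- function(x, spec) {
  if (inherits(x, "pp_image")) {
    b <- clip_bounds_for(spec, x$channels$name)
    for (j in seq_len(nrow(b))) {
      x$data[, , j] <- (x$data[, , j] - b$low[j]) / (b$high[j] - b$low[j])
    }
    return(x)
  }
  b <- clip_bounds_for(spec, colnames(x))
  for (j in seq_len(ncol(x))) {
    x[, j] <- (x[, j] - b$low[j]) / (b$high[j] - b$low[j])
  }
  x
}

#' Clip then normalize in one step
#'
#' @param x Matrix or `pp_image`.
#' @param spec A `pp_clip`.
#' @return Same type as `x`, channel values in \[0, 1\].
#' @export
preprocess_intensities <- function(x, spec) {
  apply_normalize(apply_clip(x, spec), spec)
}

#' Serialize / restore a clip specification as JSON
#'
#' @param spec A `pp_clip`.
#' @param path File path.
#' @return `read_clip()` returns a `pp_clip`.
#' @export
write_clip <- function(spec, path) {
  jsonlite::write_json(
    list(source = attr(spec, "source"), channels = as.data.frame(spec)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_clip
#' @export
read_clip <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(doc$channels, source = doc$source,
            class = c("pp_clip", "data.frame"))
}
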