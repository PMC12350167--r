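#' Tissue foreground mask from per-cycle pan-protein references
#'
#' The aligned reference images of all cycles are combined by minimum
#' projection, so any area that lifted (lost tissue) in at least one cycle
#' drops out, and the projection is binarized by Otsu thresholding.
#'
#' @param reference_stack H x W x n_cycles array, or list of matrices, of
#'   aligned pan-protein reference images.
#' @return H x W logical matrix, `TRUE` where tissue is present in every
#'   cycle.
#' @export
compute_foreground_mask <- function(reference_stack) {
  if (is.list(reference_stack)) {
    reference_stack <- array(unlist(reference_stack),
                             c(dim(reference_stack[[1]]), length(reference_stack)))
  }
  if (length(dim(reference_stack)) == 2L) {
    reference_stack <- array(reference_stack, c(dim(reference_stack), 1L))
  }
  proj <- apply(reference_stack, c(1, 2), min)
  th <- otsu_threshold(proj)
  proj > th
}

#' Erythrocyte (RBC) mask from an RBC marker channel
#'
#' Channel intensities are clipped between the 90th and 99.5th percentiles,
#' Otsu-binarized, cleaned by removing connected components smaller than
#' `min_size` pixels (8-connectivity), dilated twice with a 3 x 3 cross and
#' hole-filled.
#'
#' @param rbc_channel Numeric matrix of the erythrocyte marker.
#' @param clip_low_pct,clip_high_pct Clipping percentiles (90 / 99.5).
#' @param min_size Minimum object size in pixels (default 72).
#' @param dilations Number of binary dilation passes (default 2).
#' @return H x W logical matrix.
#' @export
compute_rbc_mask <- function(rbc_channel, clip_low_pct = 90,
                             clip_high_pct = 99.5, min_size = 72L,
                             dilations = 2L) {
  b <- percentile(rbc_channel, c(clip_low_pct, clip_high_pct))
  y <- pmin(pmax(rbc_channel, b[1]), b[2])
  dim(y) <- dim(rbc_channel)
  if (max(y) - min(y) <= 0) {
    return(matrix(FALSE, nrow(rbc_channel), ncol(rbc_channel)))
  }
  mask <- y > otsu_threshold(y)
  lab <- cpp_label_components(mask)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_size)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) return(mask)
  img <- EBImage::Image(mask * 1)
  cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  for (i in seq_len(dilations)) img <- EBImage::dilate(img, cross)
  img <- EBImage::fillHull(img)
  as.matrix(img) > 0
}

#' Bundle foreground / RBC masks into an analysis mask
#'
#' @param foreground,rbc H x W logical matrices (a missing RBC mask means
#'   all-`FALSE`).
#' @return List with `foreground`, `rbc` and `analysis`
#'   (`foreground & !rbc`), class `pp_masks`.
#' @export
mask_set <- function(foreground, rbc = NULL) {
  if (is.null(rbc)) rbc <- matrix(FALSE, nrow(foreground), ncol(foreground))
  stopifnot(all(dim(foreground) == dim(rbc)))
  structure(list(foreground = foreground, rbc = rbc,
                 analysis = foreground & !rbc),
            class = "pp_masks")
}

#' Estimate per-pixel autofluorescence for a primary cycle
#'
#' Linear pixelwise interpolation, in cycle index, between the nearest
#' preceding and nearest subsequent secondary-only images of the same
#' wavelength; single-sided cases use the nearest available image
#' (constant extrapolation).
#'
#' @param primary_cycle Cycle index of the primary-antibody channel.
#' @param wavelength Wavelength band of the channel.
#' @param secondaries List of entries `list(cycle =, wavelength =, image =)`
#'   for secondary-only channels.
#' @return H x W autofluorescence estimate.
#' @export
estimate_autofluorescence <- function(primary_cycle, wavelength, secondaries) {
  wl <- vapply(secondaries, function(s) as.character(s$wavelength), "")
  sel <- which(wl == as.character(wavelength))
  if (!length(sel)) {
    stop("no secondary-only cycle at wavelength ", wavelength,
         "; available bands: ", paste(unique(wl), collapse = ", "))
  }
  cyc <- vapply(secondaries[sel], function(s) as.integer(s$cycle), 0L)
  imgs <- lapply(secondaries[sel], `[[`, "image")
  o <- order(cyc)
  cyc <- cyc[o]; imgs <- imgs[o]
  exact <- which(cyc == primary_cycle)
  if (length(exact)) return(imgs[[exact[1]]])
  before <- which(cyc < primary_cycle)
  after <- which(cyc > primary_cycle)
  if (!length(before)) return(imgs[[after[1]]])
  if (!length(after)) return(imgs[[before[length(before)]]])
  i0 <- before[length(before)]; i1 <- after[1]
  w <- (primary_cycle - cyc[i0]) / (cyc[i1] - cyc[i0])
  imgs[[i0]] * (1 - w) + imgs[[i1]] * w
}

#' Subtract an autofluorescence estimate with clipping at zero
#'
#' @param channel,af Numeric matrices of identical shape.
#' @return `pmax(channel - af, 0)`.
#' @export
subtract_autofluorescence <- function(channel, af) {
  stopifnot(all(dim(channel) == dim(af)))
  out <- pmax(channel - af, 0)
  dim(out) <- dim(channel)
  out
}

#' Autofluorescence-correct all primary channels of an aligned stack
#'
#' For every primary (non-secondary, non-reference) channel, an
#' autofluorescence field is interpolated from the stack's secondary-only
#' channels at the same wavelength ([estimate_autofluorescence()]) and
#' subtracted with clipping at zero. Channels whose wavelength has no
#' secondary-only cycle are left untouched.
#'
#' @param stack An aligned [multiplex_image()].
#' @return The corrected `pp_image`.
#' @export
correct_autofluorescence <- function(stack) {
  ch <- stack$channels
  sec_idx <- which(ch$is_secondary_only)
  if (!length(sec_idx)) return(stack)
  secondaries <- lapply(sec_idx, function(i) {
    list(cycle = ch$cycle[i], wavelength = ch$wavelength[i],
         image = stack$data[, , i])
  })
  data <- stack$data
  for (i in which(!ch$is_secondary_only & !ch$is_reference)) {
    af <- tryCatch(
      estimate_autofluorescence(ch$cycle[i], ch$wavelength[i], secondaries),
      error = function(e) NULL
    )
    if (!is.null(af)) data[, , i] <- subtract_autofluorescence(data[, , i], af)
  }
  multiplex_image(data, ch, stack$mask, stack$fov_id, stack$sample_id)
}

#' Elution quality control for one primary channel
#'
#' Compares the channel's 50th and 99.95th intensity percentiles against the
#' percentile-wise maxima over all matched secondary-only images. A primary
#' whose percentile is equal to or lower than the secondary baseline is
#' flagged for manual review (incomplete elution or a genuinely sparse
#' marker).
#'
#' @param primary Numeric matrix of the primary channel.
#' @param secondaries List of numeric matrices (secondary-only images at the
#'   same wavelength, directed against the same host species).
#' @param mask Optional logical matrix restricting the compared pixels
#'   (default: full frame).
#' @return One-row `data.frame` with the compared percentiles and `flagged`.
#' @export
elution_qc <- function(primary, secondaries, mask = NULL) {
  if (!length(secondaries)) stop("at least one secondary-only image required")
  pick <- function(x) if (is.null(mask)) as.vector(x) else x[mask]
  pp <- percentile(pick(primary), c(50, 99.95))
  sec <- vapply(secondaries, function(s) percentile(pick(s), c(50, 99.95)),
                numeric(2))
  s50 <- max(sec[1, ]); s9995 <- max(sec[2, ])
  data.frame(
    p50_primary = pp[1], p9995_primary = pp[2],
    p50_secondary_max = s50, p9995_secondary_max = s9995,
    flagged = (pp[1] <= s50) || (pp[2] <= s9995)
  )
}

#' Elution QC report for a whole stack
#'
#' Runs [elution_qc()] for every primary channel against the stack's
#' secondary-only channels matched on wavelength and host species.
#'
#' @param stack A [multiplex_image()].
#' @param mask Optional logical matrix restricting compared pixels (default:
#'   the stack's analysis mask, if present).
#' @return `data.frame` with one row per primary channel.
#' @export
elution_qc_stack <- function(stack, mask = stack$mask) {
  ch <- stack$channels
  out <- NULL
  for (i in which(!ch$is_secondary_only & !ch$is_reference)) {
    j <- which(ch$is_secondary_only &
                 ch$wavelength == ch$wavelength[i] &
                 ch$host_species == ch$host_species[i])
    if (!length(j)) next
    rep_i <- elution_qc(stack$data[, , i],
                        lapply(j, function(k) stack$data[, , k]), mask)
    out <- rbind(out, cbind(
      data.frame(name = ch$name[i], cycle = ch$cycle[i],
                 wavelength = ch$wavelength[i], stringsAsFactors = FALSE),
      rep_i
    ))
  }
  out
}
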