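# Synthetic cyclic multiplexed immunofluorescence experiments with known
# ground truth: planted co-expression signatures arranged in spatial blobs,
# per-cycle rigid shifts, shared autofluorescence per wavelength,
# erythrocyte-like high-autofluorescence blobs, and empty background.

#' Configuration of a synthetic experiment
#'
#' Defaults describe a compact two-condition study: 8 markers carrying 6
#' planted co-expression signatures in spatial blobs over empty background,
#' 2 conditions x 3 samples x 4 FOVs of 256 x 256 px, per-cycle integer
#' shifts up to 5 px, additive autofluorescence shared across cycles within
#' a wavelength group (3 markers per group, so interpolation across
#' secondary-only cycles is exercised), occasional erythrocyte-like blobs,
#' Gaussian noise with s.d. 0.05 of the signature intensity scale, and a
#' 2-fold abundance multiplier for pattern 1 in the second condition.
#'
#' @param n_markers Number of signature markers.
#' @param n_patterns Number of planted co-expression patterns.
#' @param signatures Optional n_patterns x n_markers matrix in \[0, 1\];
#'   generated from `seed` when `NULL` (two defining markers >= 0.7 per
#'   pattern, off-markers <= 0.08, pairwise cosine < 0.95 enforced).
#' @param conditions Named list of per-pattern abundance multipliers.
#' @param n_samples Samples per condition.
#' @param n_fovs FOVs per sample.
#' @param fov_shape `(H, W)` in pixels.
#' @param blobs_per_pattern Mean blob count per pattern per FOV (Poisson).
#' @param blob_radius Range of blob radii in pixels.
#' @param tissue_cv Lognormal coefficient of variation of the per-FOV
#'   tissue coverage (a shared factor on all patterns' blob counts,
#'   emulating field-to-field differences in tissue content).
#' @param shift_range Max absolute per-cycle integer shift in pixels.
#' @param rotation_range Max absolute per-cycle rotation in degrees
#'   (default 0).
#' @param intensity_scale Counts corresponding to signature value 1.
#' @param af_amplitude Autofluorescence amplitude in counts per wavelength
#'   group.
#' @param rbc_per_fov Mean erythrocyte blob count per FOV (Poisson).
#' @param rbc_intensity Counts added to every channel inside RBC blobs.
#' @param noise_sd Gaussian noise s.d. as a fraction of `intensity_scale`.
#' @param pixel_size_um Micrometres per pixel.
#' @param seed Master seed; everything derives deterministically from it.
#' @return List of class `pp_synth_config`.
#' @export
synthetic_config <- function(n_markers = 8L, n_patterns = 6L,
                             signatures = NULL,
                             conditions = list(control = rep(1, n_patterns),
                                               disease = c(2, rep(1, n_patterns - 1L))),
                             n_samples = 3L, n_fovs = 4L,
                             fov_shape = c(256L, 256L),
                             blobs_per_pattern = 12, blob_radius = c(4, 9),
                             tissue_cv = 0.2,
                             shift_range = 5L, rotation_range = 0,
                             intensity_scale = 8000, af_amplitude = 800,
                             rbc_per_fov = 0.5, rbc_intensity = 4000,
                             noise_sd = 0.05, pixel_size_um = 0.4,
                             seed = 1L) {
  if (is.null(signatures)) {
    signatures <- with_seed(seed, {
      if (n_patterns > choose(n_markers, 2)) {
        stop("too many patterns for distinct defining marker pairs")
      }
      sig <- matrix(stats::runif(n_patterns * n_markers, 0, 0.08),
                    n_patterns, n_markers)
      # each pattern gets a unique pair of defining markers, chosen greedily
      # to balance marker usage so no marker dominates the panel
      use <- rep(0L, n_markers)
      taken <- matrix(FALSE, n_markers, n_markers)
      for (p in seq_len(n_patterns)) {
        ord <- order(use, seq_len(n_markers))
        found <- FALSE
        for (ai in seq_len(n_markers - 1)) {
          for (bi in seq(ai + 1, n_markers)) {
            a <- ord[ai]; b <- ord[bi]
            if (!taken[a, b]) {
              sig[p, c(a, b)] <- stats::runif(2, 0.7, 1)
              taken[a, b] <- taken[b, a] <- TRUE
              use[a] <- use[a] + 1L
              use[b] <- use[b] + 1L
              found <- TRUE
              break
            }
          }
          if (found) break
        }
      }
      sig
    })
  }
  signatures <- as.matrix(signatures)
  stopifnot(nrow(signatures) == n_patterns, ncol(signatures) == n_markers)
  dimnames(signatures) <- list(paste0("p", seq_len(n_patterns)),
                               paste0("M", seq_len(n_markers)))
  sn <- signatures / sqrt(rowSums(signatures^2))
  cs <- sn %*% t(sn)
  diag(cs) <- 0
  if (max(cs) >= 0.95) stop("planted signatures too similar (cosine >= 0.95)")
  for (cond in conditions) {
    stopifnot(length(cond) == n_patterns, all(cond > 0))
  }
  structure(
    list(n_markers = n_markers, n_patterns = n_patterns,
         signatures = signatures, conditions = conditions,
         n_samples = n_samples, n_fovs = n_fovs, fov_shape = fov_shape,
         blobs_per_pattern = blobs_per_pattern, blob_radius = blob_radius,
         tissue_cv = tissue_cv,
         shift_range = shift_range, rotation_range = rotation_range,
         intensity_scale = intensity_scale, af_amplitude = af_amplitude,
         rbc_per_fov = rbc_per_fov, rbc_intensity = rbc_intensity,
         noise_sd = noise_sd, pixel_size_um = pixel_size_um, seed = seed),
    class = "pp_synth_config"
  )
}

# wavelength groups of three markers; within a group, members are spread
# over consecutive primary cycles so autofluorescence must be interpolated
synthetic_layout <- function(config) {
  n <- config$n_markers
  group <- (seq_len(n) - 1L) %/% 3L + 1L
  within <- (seq_len(n) - 1L) %% 3L + 1L
  n_primary <- max(within)
  data.frame(
    marker = paste0("M", seq_len(n)),
    wavelength = paste0("w", group),
    cycle = within + 1L, # primary cycles sit between the secondary-only ones
    stringsAsFactors = FALSE
  )
}

draw_blobs <- function(shape, n_blobs, radius_range, occupied, max_tries = 200L) {
  # returns a logical mask of non-overlapping discs avoiding `occupied`
  H <- shape[1]; W <- shape[2]
  mask <- matrix(FALSE, H, W)
  placed <- 0L
  tries <- 0L
  while (placed < n_blobs && tries < max_tries * max(n_blobs, 1L)) {
    tries <- tries + 1L
    r <- stats::runif(1, radius_range[1], radius_range[2])
    cr <- stats::runif(1, 1 + r, H - r)
    cc <- stats::runif(1, 1 + r, W - r)
    rr <- pmax(1, floor(cr - r)):pmin(H, ceiling(cr + r))
    ccs <- pmax(1, floor(cc - r)):pmin(W, ceiling(cc + r))
    disc <- outer(rr - cr, ccs - cc, function(a, b) a^2 + b^2 <= r^2)
    if (any(occupied[rr, ccs] & disc) || any(mask[rr, ccs] & disc)) next
    mask[rr, ccs] <- mask[rr, ccs] | disc
    placed <- placed + 1L
  }
  mask
}

smooth_field <- function(shape, sigma = NULL) {
  # blur kernel must fit the frame
  if (is.null(sigma)) sigma <- min(25, floor((min(shape) - 1) / 8))
  f <- matrix(stats::runif(prod(shape)), shape[1], shape[2])
  f <- gaussian_blur(f, sigma)
  0.5 + 0.5 * rescale01(f)
}

#' Generate a complete synthetic experiment on disk
#'
#' Writes one 16-bit TIFF per channel per cycle per FOV plus a YAML
#' manifest, and returns the manifest together with the full ground truth.
#' Pixel intensity composes as
#' `signature[pattern, marker] * intensity_scale + autofluorescence(wavelength, cycle) + rbc + noise`,
#' geometrically perturbed by the cycle's true shift. Secondary-only cycles
#' (the first and last cycle) contain autofluorescence, erythrocyte signal
#' and noise only. A pan-protein reference channel with fixed speckle
#' texture is emitted for every cycle, and an erythrocyte marker channel
#' (`GYPA`) in the first primary cycle. Deterministic given the config
#' seed.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with `manifest` (a `pp_manifest`) and `truth`: per-FOV
#'   pattern label maps (0 = background) and RBC masks, per-FOV true cycle
#'   shifts, the true per-FOV abundance table, autofluorescence fields and
#'   cycle factors, and the planted signatures.
#' @export
generate_experiment <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lay <- synthetic_layout(config)
  n_primary <- max(lay$cycle)
  cycles <- seq_len(n_primary + 2L) # 1 and last are secondary-only
  sec_cycles <- c(1L, n_primary + 2L)
  wavelengths <- unique(lay$wavelength)
  H <- config$fov_shape[1]; W <- config$fov_shape[2]

  # channel table: reference every cycle, markers per layout, RBC marker,
  # secondary-only channels per wavelength in the first and last cycle
  ch <- rbind(
    data.frame(name = "NHS-E", cycle = cycles, wavelength = "ref",
               host_species = "none", is_secondary_only = FALSE,
               is_reference = TRUE, stringsAsFactors = FALSE),
    data.frame(name = lay$marker, cycle = lay$cycle, wavelength = lay$wavelength,
               host_species = "rabbit", is_secondary_only = FALSE,
               is_reference = FALSE, stringsAsFactors = FALSE),
    data.frame(name = "GYPA", cycle = 2L, wavelength = "rbc",
               host_species = "mouse", is_secondary_only = FALSE,
               is_reference = FALSE, stringsAsFactors = FALSE),
    expand.grid(cycle = sec_cycles, wavelength = wavelengths,
                stringsAsFactors = FALSE) |>
      transform(name = paste0("sec-", wavelength),
                host_species = "rabbit", is_secondary_only = TRUE,
                is_reference = FALSE)
  )
  ch <- ch[order(ch$cycle, ch$name), ]
  channels <- channel_meta(ch$name, ch$cycle, ch$wavelength, ch$host_species,
                           ch$is_secondary_only, ch$is_reference)

  conds <- names(config$conditions)
  samples <- do.call(rbind, lapply(conds, function(cd) {
    data.frame(sample_id = paste0(cd, "_s", seq_len(config$n_samples)),
               condition = cd, plate_id = "plate1", stringsAsFactors = FALSE)
  }))
  fovs <- do.call(rbind, lapply(samples$sample_id, function(sid) {
    data.frame(sample_id = sid,
               fov_id = paste0(sid, "_f", seq_len(config$n_fovs)),
               region_class = "tissue", stringsAsFactors = FALSE)
  }))

  truth <- list(label_maps = list(), rbc_masks = list(), shifts = list(),
                abundance = NULL, af_fields = list(), af_cycle_factor = NULL,
                signatures = config$signatures, config = config)
  files <- list()
  sig <- config$signatures
  scale <- config$intensity_scale
  nsd <- config$noise_sd * scale

  with_seed(config$seed, {
    # shared autofluorescence spatial pattern per wavelength; the amplitude
    # drifts linearly across cycles
    af_fields <- setNames(lapply(wavelengths, function(w) {
      config$af_amplitude * smooth_field(c(H, W))
    }), wavelengths)
    af_factor <- 0.8 + 0.4 * (cycles - 1) / (max(cycles) - 1)
    truth$af_fields <- af_fields
    truth$af_cycle_factor <- setNames(af_factor, cycles)

    for (fi in seq_len(nrow(fovs))) {
      fid <- fovs$fov_id[fi]
      sid <- fovs$sample_id[fi]
      cd <- samples$condition[match(sid, samples$sample_id)]
      mult <- config$conditions[[cd]]

      # pattern blobs over empty background; a shared lognormal factor per
      # FOV emulates varying tissue coverage across fields, and the
      # condition multipliers scale individual patterns' expected counts
      labels <- matrix(0L, H, W)
      occupied <- matrix(FALSE, H, W)
      tissue_factor <- exp(stats::rnorm(1, -config$tissue_cv^2 / 2,
                                        config$tissue_cv))
      for (p in seq_len(config$n_patterns)) {
        nb <- stats::rpois(1, config$blobs_per_pattern * mult[p] * tissue_factor)
        bl <- draw_blobs(c(H, W), nb, config$blob_radius, occupied)
        labels[bl] <- p
        occupied <- occupied | bl
      }
      rbc <- draw_blobs(c(H, W), stats::rpois(1, config$rbc_per_fov),
                        c(5, 8), occupied)
      occupied <- occupied | rbc

      # fixed pan-protein texture (identical across cycles up to the shift)
      texture <- matrix(stats::runif(H * W, 0.55, 1), H, W)
      ref_base <- 0.75 * scale * texture * (labels > 0) +
        0.9 * scale * texture * rbc

      # true per-cycle rigid shifts (cycle 1 is the reference)
      shifts <- matrix(0, length(cycles), 2,
                       dimnames = list(cycles, c("d_row", "d_col")))
      if (config$shift_range > 0) {
        shifts[-1, ] <- sample(seq(-config$shift_range, config$shift_range),
                               2 * (length(cycles) - 1), replace = TRUE)
      }
      rots <- rep(0, length(cycles))
      if (config$rotation_range > 0) {
        rots[-1] <- stats::runif(length(cycles) - 1,
                                 -config$rotation_range, config$rotation_range)
      }

      perturb <- function(img, ci) {
        out <- img
        if (rots[ci] != 0) {
          th <- rots[ci] * pi / 180
          cr <- (H - 1) / 2; cc <- (W - 1) / 2
          R <- rbind(c(cos(th), -sin(th), cr - cos(th) * cr + sin(th) * cc),
                     c(sin(th), cos(th), cc - sin(th) * cr - cos(th) * cc),
                     c(0, 0, 1))
          out <- warp_projective(out, R)
        }
        apply_shift(out, shifts[ci, ])
      }

      fov_dir <- file.path(out_dir, fid)
      dir.create(fov_dir, showWarnings = FALSE)
      fv <- character(0)
      for (i in seq_len(nrow(channels))) {
        nm <- channels$name[i]; cy <- channels$cycle[i]
        wl <- channels$wavelength[i]
        base <- matrix(0, H, W)
        if (channels$is_reference[i]) {
          base <- ref_base
        } else if (channels$is_secondary_only[i]) {
          base <- af_fields[[wl]] * af_factor[cy] + config$rbc_intensity * rbc
        } else if (nm == "GYPA") {
          base <- scale * rbc
        } else {
          m <- match(nm, lay$marker)
          vals <- c(0, sig[, m])[labels + 1L] * scale
          base <- vals + af_fields[[wl]] * af_factor[cy] +
            config$rbc_intensity * rbc
        }
        img <- perturb(base, cy)
        img <- img + matrix(stats::rnorm(H * W, 0, nsd), H, W)
        img <- pmin(pmax(img, 0), 65535)
        rel <- file.path(fid, paste0(channel_key(cy, nm), ".tif"))
        write_tiff_uint16(img, file.path(out_dir, rel))
        fv[channel_key(cy, nm)] <- rel
      }
      files[[fid]] <- fv
      truth$label_maps[[fid]] <- labels
      truth$rbc_masks[[fid]] <- rbc
      truth$shifts[[fid]] <- shifts
      fg <- labels[labels > 0L]
      ab <- tabulate(fg, nbins = config$n_patterns) / max(length(fg), 1L)
      truth$abundance <- rbind(truth$abundance, data.frame(
        fov_id = fid, sample_id = sid, condition = cd,
        as.data.frame(setNames(as.list(ab),
                               paste0("p", seq_len(config$n_patterns)))),
        stringsAsFactors = FALSE
      ))
    }
  })

  manifest <- experiment_manifest(samples, fovs, channels, files,
                                  config$pixel_size_um, base_dir = out_dir)
  write_manifest(manifest, file.path(out_dir, "manifest.yaml"))
  list(manifest = manifest, truth = truth)
}

#' Match recovered cluster signatures to planted signatures
#'
#' One-to-one assignment of recovered cluster mean vectors to planted
#' signatures maximizing total cosine similarity (exhaustive over
#' assignments when feasible, greedy otherwise).
#'
#' @param cluster_means K_rec x C matrix of recovered cluster mean vectors.
#' @param signatures K_true x C matrix of planted signatures.
#' @return `data.frame` with `pattern`, `cluster` (0-based recovered id)
#'   and `cosine`.
#' @export
match_signatures <- function(cluster_means, signatures) {
  cm <- as.matrix(cluster_means); sg <- as.matrix(signatures)
  if (!is.null(colnames(cm)) && !is.null(colnames(sg)) &&
      setequal(colnames(cm), colnames(sg))) {
    cm <- cm[, colnames(sg), drop = FALSE] # align channels by name
  }
  norm_rows <- function(X) {
    n <- sqrt(rowSums(X^2)); n[n == 0] <- 1
    X / n
  }
  S <- norm_rows(sg) %*% t(norm_rows(cm)) # true x rec cosine
  kt <- nrow(sg); kr <- nrow(cm)
  if (kr < kt) stop("fewer recovered clusters (", kr, ") than signatures (", kt, ")")
  n_assign <- prod(kr - seq_len(kt) + 1)
  if (n_assign <= 2e5) {
    perms <- function(v, k) {
      if (k == 0) return(list(integer(0)))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i], k - 1)) out[[length(out) + 1L]] <- c(v[i], rest)
      }
      out
    }
    best <- NULL; best_val <- -Inf
    for (a in perms(seq_len(kr), kt)) {
      val <- sum(S[cbind(seq_len(kt), a)])
      if (val > best_val) { best_val <- val; best <- a }
    }
    assign <- best
  } else {
    assign <- integer(kt)
    taken <- logical(kr)
    Sx <- S
    for (step in seq_len(kt)) {
      idx <- which(Sx == max(Sx), arr.ind = TRUE)[1, ]
      assign[idx[1]] <- idx[2]
      Sx[idx[1], ] <- -Inf; Sx[, idx[2]] <- -Inf
      taken[idx[2]] <- TRUE
    }
  }
  data.frame(pattern = seq_len(kt), cluster = assign - 1L,
             cosine = S[cbind(seq_len(kt), assign)])
}

#' Score pipeline outputs against the synthetic ground truth
#'
#' @param cluster_images Named list (by `fov_id`) of recovered
#'   [cluster_image()]s; each may carry a `$crop` window (rows/cols of the
#'   registered frame) which is applied to the truth label maps.
#' @param truth Ground truth from [generate_experiment()].
#' @param crops Optional named list of crop windows (overrides `$crop`).
#' @param cluster_means Optional K_rec x C matrix for signature matching.
#' @param detected_shifts Optional named list of detected correction
#'   matrices (rows = cycles) to score against the planted shifts
#'   (`correction = -true shift`).
#' @return List with `pixel_ari`, `signature_match` (+`min_cosine`) and
#'   `shift_rmse`, where computable.
#' @export
score_against_truth <- function(cluster_images, truth, crops = NULL,
                                cluster_means = NULL, detected_shifts = NULL) {
  report <- list()
  if (!is.null(cluster_images)) {
    t_all <- integer(0); r_all <- integer(0)
    for (fid in names(cluster_images)) {
      ci <- cluster_images[[fid]]
      lm <- truth$label_maps[[fid]]
      if (is.null(lm)) stop("no ground truth for FOV ", fid)
      win <- crops[[fid]] %||% ci$crop
      if (!is.null(win)) {
        lm <- lm[win$rows[1]:win$rows[2], win$cols[1]:win$cols[2]]
      }
      stopifnot(all(dim(lm) == dim(ci$labels)))
      keep <- lm > 0L & ci$labels >= 0L
      t_all <- c(t_all, lm[keep])
      r_all <- c(r_all, ci$labels[keep])
    }
    report$pixel_ari <- mclust::adjustedRandIndex(t_all, r_all)
  }
  if (!is.null(cluster_means)) {
    sm <- match_signatures(cluster_means, truth$signatures)
    report$signature_match <- sm
    report$min_cosine <- min(sm$cosine)
  }
  if (!is.null(detected_shifts)) {
    sq <- c()
    for (fid in names(detected_shifts)) {
      true_corr <- -truth$shifts[[fid]]
      det <- detected_shifts[[fid]]
      rows <- seq_len(min(nrow(det), nrow(true_corr)))
      sq <- c(sq, as.numeric((det[rows, ] - true_corr[rows, ])^2))
    }
    report$shift_rmse <- sqrt(mean(sq))
  }
  report
}
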