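# End-to-end orchestration: register -> mask/correct -> subsample ->
# normalize -> SOM -> graph/Leiden -> label -> statistics -> spatial.

#' Pipeline run configuration
#'
#' Collects every stage parameter with desk-scale defaults. The named
#' presets mirror three full-scale parameterizations (`cgn`: Euclidean SOM
#' 500^2, k = 40, Leiden resolution 1.0 / 10000 iterations; `dkd`: 500^2,
#' batch-balanced k = 40, resolution 2.5 / 10000; `early-t2d`: 400^2,
#' cosine, k = 50, resolution 2.0 / 1000) and a `desk` preset (32^2 grid,
#' 100k subsample, k = 15, resolution 1.0) sized for interactive use and
#' continuous testing.
#'
#' @param preset `"desk"`, `"cgn"`, `"dkd"` or `"early-t2d"`.
#' @param ... Overrides of individual fields (see Details in the package
#'   vignette); unknown names are rejected.
#' @return List of class `pp_run_config`.
#' @export
run_config <- function(preset = "desk", ...) {
  base <- list(
    # registration
    upsample = 5L, homography = FALSE, crop = "global_max_offset",
    clip_low_pct = 1, clip_high_pct = 99.9, blur_sigma = 1,
    zero_below_pct = 70, hist_match = TRUE, drop_flagged = FALSE,
    # masks / correction; without a foreground mask, background pixels are
    # clustered too and empty areas form their own cluster(s)
    foreground_mask = TRUE,
    rbc_channel = NULL, autofluorescence = TRUE, elution_qc = TRUE,
    # subsample + normalization
    subsample_n = 100000L, clip_pct = c(50, 99.7), clip_abs = NULL,
    # clustering
    grid_side = 32L, metric = "euclidean", som_iterations = 50L,
    lr_init = 1, lr_final = 1, sigma_final = 1e-3,
    k = 15L, resolution = 1.0, leiden_iterations = 10L,
    min_frequency = 0.001,
    # statistics
    condition_test = NULL, condition_ref = NULL, correction = "bh",
    alpha = 0.05,
    # spatial
    min_edge = 0.075,
    # seeds
    seed_subsample = 1L, seed_som = 2L, seed_leiden = 3L,
    preset = preset
  )
  presets <- list(
    desk = list(),
    cgn = list(grid_side = 500L, subsample_n = 5000000L, k = 40L,
               resolution = 1.0, leiden_iterations = 10000L,
               metric = "euclidean"),
    dkd = list(grid_side = 500L, subsample_n = 5000000L, k = 40L,
               resolution = 2.5, leiden_iterations = 10000L,
               metric = "euclidean"),
    `early-t2d` = list(grid_side = 400L, subsample_n = 10000000L, k = 50L,
                       resolution = 2.0, leiden_iterations = 1000L,
                       metric = "cosine")
  )
  if (!preset %in% names(presets)) {
    stop("unknown preset; available: ", paste(names(presets), collapse = ", "))
  }
  cfg <- modifyList(base, presets[[preset]])
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  structure(modifyList(cfg, dots), class = "pp_run_config")
}

marker_channels <- function(manifest, rbc_channel = NULL) {
  ch <- manifest$channels
  keep <- !ch$is_reference & !ch$is_secondary_only
  if (!is.null(rbc_channel)) keep <- keep & ch$name != rbc_channel
  unique(ch$name[keep])
}

#' Run the full pixel-clustering pipeline
#'
#' Stages, in fixed order: per-FOV registration of all cycles to the first
#' ([register_fov()]); foreground/RBC masking ([compute_foreground_mask()],
#' [compute_rbc_mask()]); autofluorescence correction
#' ([correct_autofluorescence()]) and elution QC ([elution_qc_stack()]);
#' weighted stratified subsampling ([weighted_subsample()]); per-channel
#' clip + normalization fitted on the subsample ([fit_clip()]); batch SOM
#' training per plate ([train_som()]); kNN (or batch-balanced kNN across
#' plates) graph + Leiden over the pooled nodes; pixel labeling of every
#' FOV ([label_pixels()]); abundance and differential statistics; and
#' join-count vicinity graphs per condition. Re-running with an identical
#' config and inputs reproduces identical tables.
#'
#' @param manifest A `pp_manifest`.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for CSV/TIFF/GraphML artifacts.
#' @return List with the registered stacks, masks, QC tables, subsample,
#'   clip spec, SOM(s), cluster model, per-FOV cluster images, abundance
#'   tables, differential results, contributor statistics, foreground
#'   filter and vicinity graphs.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir = NULL) {
  ch <- manifest$channels
  fids <- manifest$fovs$fov_id
  markers <- marker_channels(manifest, config$rbc_channel)

  # --- registration + masking + correction ------------------------------
  stacks <- list(); masks <- list(); reg_qc <- NULL; elution <- NULL
  shifts <- list()
  for (fid in fids) {
    raw <- read_image_stack(manifest, fid)
    reg <- register_fov(raw, upsample = config$upsample,
                        homography = config$homography, crop = config$crop,
                        hist_match = config$hist_match,
                        drop_flagged = config$drop_flagged,
                        clip_low_pct = config$clip_low_pct,
                        clip_high_pct = config$clip_high_pct,
                        blur_sigma = config$blur_sigma,
                        zero_below_pct = config$zero_below_pct)
    st <- reg$stack
    reg_qc <- rbind(reg_qc, reg$qc)
    cyc <- sort(unique(ch$cycle))
    sh <- matrix(0, length(cyc), 2, dimnames = list(cyc, c("d_row", "d_col")))
    for (cy in names(reg$results)) sh[cy, ] <- reg$results[[cy]]$shift
    shifts[[fid]] <- sh
    fg <- if (config$foreground_mask) {
      ref_planes <- lapply(which(st$channels$is_reference),
                           function(i) st$data[, , i])
      compute_foreground_mask(ref_planes)
    } else {
      matrix(TRUE, dim(st$data)[1], dim(st$data)[2])
    }
    rbc <- NULL
    if (!is.null(config$rbc_channel)) {
      i <- which(st$channels$name == config$rbc_channel)[1]
      if (!is.na(i)) rbc <- compute_rbc_mask(st$data[, , i])
    }
    ms <- mask_set(fg, rbc)
    st$mask <- ms$analysis
    crop_win <- st$crop
    if (config$elution_qc) {
      # compared before autofluorescence subtraction: both primaries and
      # secondary-only channels still carry the shared autofluorescence
      eq <- elution_qc_stack(st)
      if (!is.null(eq)) elution <- rbind(elution, cbind(fov_id = fid, eq))
    }
    if (config$autofluorescence) st <- correct_autofluorescence(st)
    st$crop <- crop_win
    stacks[[fid]] <- st
    masks[[fid]] <- ms$analysis
  }

  # --- subsample + normalization ----------------------------------------
  coords <- weighted_subsample(manifest, masks, config$subsample_n,
                               seed = config$seed_subsample)
  values <- subsample_values(stacks, coords, channels = markers)
  clip <- if (is.null(config$clip_abs)) {
    fit_clip(values, p_lo = config$clip_pct[1], p_hi = config$clip_pct[2])
  } else {
    fit_clip(values, absolute = config$clip_abs)
  }
  norm_values <- preprocess_intensities(values, clip)

  # --- SOM per plate, pooled graph, Leiden ------------------------------
  plates <- sort(unique(manifest$samples$plate_id))
  soms <- list(); node_rows <- list()
  for (pl in plates) {
    rows <- which(coords$plate_id == pl)
    soms[[pl]] <- train_som(norm_values[rows, , drop = FALSE],
                            grid_side = config$grid_side,
                            metric = config$metric,
                            iterations = config$som_iterations,
                            lr_init = config$lr_init,
                            lr_final = config$lr_final,
                            sigma_final = config$sigma_final,
                            seed = config$seed_som)
  }
  pooled <- do.call(rbind, lapply(plates, function(pl) soms[[pl]]$weights))
  node_plate <- rep(plates, each = config$grid_side^2)
  if (length(plates) > 1L) {
    graph <- build_bbknn_graph(pooled, node_plate, k_per_batch = config$k,
                               metric = config$metric)
    batch_mode <- "balanced"
  } else {
    graph <- build_knn_graph(pooled, k = config$k, metric = config$metric)
    batch_mode <- "none"
  }
  model <- leiden_cluster(graph, resolution = config$resolution,
                          iterations = config$leiden_iterations,
                          seed = config$seed_leiden, batch_mode = batch_mode)

  # --- label every pixel -------------------------------------------------
  cluster_images <- list()
  for (fid in fids) {
    st <- stacks[[fid]]
    pl <- manifest_plate_of(manifest, st$sample_id)
    idx <- match(markers, st$channels$name)
    sub <- multiplex_image(st$data[, , idx, drop = FALSE],
                           st$channels[idx, ], st$mask, fid, st$sample_id)
    sub <- preprocess_intensities(sub, clip)
    offset <- (match(pl, plates) - 1L) * config$grid_side^2
    plate_model <- model
    plate_model$node_labels <- model$node_labels[offset + seq_len(config$grid_side^2)]
    ci <- label_pixels(sub, soms[[pl]], plate_model)
    ci$crop <- st$crop
    cluster_images[[fid]] <- ci
  }

  # --- statistics --------------------------------------------------------
  abundance <- abundance_table(cluster_images, manifest, model$n_clusters)
  by_sample <- aggregate_by_sample(abundance)
  conds <- unique(manifest$samples$condition)
  cond_test <- config$condition_test %||% conds[length(conds)]
  cond_ref <- config$condition_ref %||% conds[1]
  differential <- NULL
  if (cond_test != cond_ref &&
      sum(abundance$condition == cond_test) >= 2L &&
      sum(abundance$condition == cond_ref) >= 2L) {
    differential <- differential_abundance(abundance, cond_test, cond_ref,
                                           correction = config$correction,
                                           alpha = config$alpha)
  }
  contributors <- cluster_contributors(pooled, model$node_labels,
                                       correction = "holm_sidak")
  total_counts <- Reduce(`+`, lapply(cluster_images, function(ci) {
    tabulate(ci$labels[ci$labels >= 0L] + 1L, nbins = model$n_clusters)
  }))
  frequencies <- total_counts / sum(total_counts)
  foreground <- filter_foreground_clusters(frequencies, config$min_frequency)

  # --- spatial -----------------------------------------------------------
  vicinity <- list()
  for (cd in conds) {
    cd_fids <- fids[manifest_condition_of(manifest, manifest$fovs$sample_id) == cd]
    mats <- lapply(cluster_images[cd_fids], vicinity_composition,
                   n_clusters = model$n_clusters)
    vicinity[[cd]] <- tryCatch(
      aggregate_and_normalize(mats, condition = cd,
                              edge_display_threshold = config$min_edge),
      error = function(e) NULL
    )
  }

  result <- list(
    manifest = manifest, config = config, stacks = stacks, masks = masks,
    registration_qc = reg_qc, shifts = shifts, elution_qc = elution,
    subsample = coords, subsample_values = norm_values, clip = clip,
    soms = soms, model = model, node_plate = node_plate,
    node_weights = pooled, cluster_images = cluster_images,
    abundance = abundance, abundance_by_sample = by_sample,
    differential = differential, contributors = contributors,
    frequencies = frequencies, foreground = foreground,
    vicinity = vicinity
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(result$registration_qc, file.path(out_dir, "registration_qc.csv"))
  if (!is.null(result$elution_qc)) {
    write_table(result$elution_qc, file.path(out_dir, "elution_qc.csv"))
  }
  write_table(result$abundance, file.path(out_dir, "abundance_fov.csv"))
  write_table(result$abundance_by_sample,
              file.path(out_dir, "abundance_sample.csv"))
  if (!is.null(result$differential)) {
    diff <- result$differential
    diff$neg_log10_p_adjusted <- -log10(pmax(diff$p_adjusted, 1e-300))
    write_table(diff, file.path(out_dir, "differential_abundance.csv"))
  }
  write_table(result$contributors, file.path(out_dir, "contributors.csv"))
  write_clip(result$clip, file.path(out_dir, "clip_spec.json"))
  dir.create(file.path(out_dir, "clusters"), showWarnings = FALSE)
  for (fid in names(result$cluster_images)) {
    write_cluster_image(result$cluster_images[[fid]],
                        file.path(out_dir, "clusters", paste0(fid, ".tif")))
  }
  for (cd in names(result$vicinity)) {
    v <- result$vicinity[[cd]]
    if (is.null(v)) next
    write_table(as.data.frame(v$normalized),
                file.path(out_dir, paste0("vicinity_", cd, ".csv")))
    write_display_graph(build_display_graph(v),
                        file.path(out_dir, paste0("vicinity_", cd, ".graphml")))
  }
  cfg <- result$config
  cfg$clip_abs <- NULL
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}
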