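#' Channel metadata table
#'
#' Builds and validates the per-channel metadata of an experiment. Each row
#' describes one acquired channel: the marker it measures, the staining cycle
#' it was acquired in, its emission wavelength band, the host species of the
#' primary antibody, whether the cycle was a secondary-antibody-only
#' (autofluorescence / elution control) round, and whether the channel is the
#' registration reference (nuclear or pan-protein stain) of its cycle.
#'
#' @param name Character vector of marker identifiers.
#' @param cycle Integer vector of acquisition cycles (>= 1).
#' @param wavelength Character or numeric wavelength band labels.
#' @param host_species Host species of the primary antibody (used to match
#'   secondary-only control channels in elution QC).
#' @param is_secondary_only Logical; `TRUE` for secondary-antibody-only
#'   channels.
#' @param is_reference Logical; `TRUE` for the registration reference channel
#'   of a cycle. At most one reference per cycle.
#' @return A `data.frame` with one row per channel.
#' @export
channel_meta <- function(name, cycle, wavelength,
                         host_species = "unknown",
                         is_secondary_only = FALSE,
                         is_reference = FALSE) {
  df <- data.frame(
    name = as.character(name),
    cycle = as.integer(cycle),
    wavelength = as.character(wavelength),
    host_species = as.character(host_species),
    is_secondary_only = as.logical(is_secondary_only),
    is_reference = as.logical(is_reference),
    stringsAsFactors = FALSE
  )
  if (any(df$cycle < 1L)) stop("channel cycles must be >= 1")
  key <- paste(df$cycle, df$name)
  if (anyDuplicated(key)) {
    stop("duplicated (cycle, name) channel entries: ",
         paste(key[duplicated(key)], collapse = ", "))
  }
  nref <- tapply(df$is_reference, df$cycle, sum)
  if (any(nref > 1L)) stop("more than one reference channel in a cycle")
  df
}

channel_key <- function(cycle, name) sprintf("c%d.%s", as.integer(cycle), name)

#' Assemble an experiment manifest
#'
#' The manifest ties together samples (with condition and imaging-plate
#' labels), fields of view (FOVs) with their per-channel image files, channel
#' metadata and the physical pixel size. It is the single input object of the
#' pipeline.
#'
#' @param samples `data.frame` with columns `sample_id`, `condition`,
#'   `plate_id`.
#' @param fovs `data.frame` with columns `sample_id`, `fov_id` and optionally
#'   `region_class`.
#' @param channels Channel table from [channel_meta()].
#' @param files Named list: `files[[fov_id]]` is a named character vector of
#'   image paths keyed by `"c<cycle>.<name>"`, one entry per channel.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param base_dir Directory that relative file paths are resolved against.
#' @param check_files Verify at build time that every referenced file exists.
#' @return An object of class `pp_manifest`.
#' @export
experiment_manifest <- function(samples, fovs, channels, files, pixel_size_um,
                                base_dir = ".", check_files = TRUE) {
  stopifnot(is.data.frame(samples), is.data.frame(fovs))
  stopifnot(all(c("sample_id", "condition", "plate_id") %in% names(samples)))
  stopifnot(all(c("sample_id", "fov_id") %in% names(fovs)))
  if (is.null(fovs$region_class)) fovs$region_class <- NA_character_
  if (any(!nzchar(samples$condition)) || any(is.na(samples$condition))) {
    stop("every sample needs a non-empty condition")
  }
  if (any(is.na(samples$plate_id)) || any(!nzchar(samples$plate_id))) {
    stop("every sample needs a plate_id (single-plate runs use one constant id)")
  }
  if (!all(fovs$sample_id %in% samples$sample_id)) {
    stop("fovs reference unknown sample ids")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0")
  }
  keys <- channel_key(channels$cycle, channels$name)
  for (fid in fovs$fov_id) {
    fv <- files[[fid]]
    if (is.null(fv)) stop("no files listed for FOV ", fid)
    missing_ch <- setdiff(keys, names(fv))
    if (length(missing_ch)) {
      stop("FOV ", fid, " lacks files for channels: ",
           paste(missing_ch, collapse = ", "))
    }
    if (check_files) {
      paths <- file.path(base_dir, fv[keys])
      absent <- !file.exists(paths)
      if (any(absent)) {
        stop("missing image file(s) for FOV ", fid, ", channel(s) ",
             paste(keys[absent], collapse = ", "))
      }
    }
  }
  structure(
    list(samples = samples, fovs = fovs, channels = channels, files = files,
         pixel_size_um = pixel_size_um, base_dir = base_dir),
    class = "pp_manifest"
  )
}

#' Read an experiment manifest from YAML
#'
#' File paths inside the manifest are interpreted relative to the manifest's
#' own directory, keeping experiment configurations relocatable.
#'
#' @param path Path to a YAML manifest.
#' @param check_files Verify referenced image files exist.
#' @return A `pp_manifest`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  doc <- yaml::read_yaml(path)
  to_df <- function(x) {
    do.call(rbind, lapply(x, function(row) as.data.frame(row, stringsAsFactors = FALSE)))
  }
  samples <- to_df(doc$samples)
  ch <- to_df(doc$channels)
  channels <- channel_meta(ch$name, ch$cycle, ch$wavelength, ch$host_species,
                           ch$is_secondary_only, ch$is_reference)
  fovs <- do.call(rbind, lapply(doc$fovs, function(f) {
    data.frame(sample_id = f$sample_id, fov_id = f$fov_id,
               region_class = f$region_class %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  files <- setNames(
    lapply(doc$fovs, function(f) unlist(f$files)),
    vapply(doc$fovs, `[[`, "", "fov_id")
  )
  experiment_manifest(samples, fovs, channels, files, doc$pixel_size_um,
                      base_dir = dirname(path), check_files = check_files)
}

#' Write an experiment manifest to YAML
#'
#' @param manifest A `pp_manifest`.
#' @param path Output path; file paths are written as stored (relative to the
#'   manifest directory).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  doc <- list(
    pixel_size_um = manifest$pixel_size_um,
    samples = lapply(seq_len(nrow(manifest$samples)), function(i) {
      as.list(manifest$samples[i, ])
    }),
    channels = lapply(seq_len(nrow(manifest$channels)), function(i) {
      as.list(manifest$channels[i, ])
    }),
    fovs = lapply(seq_len(nrow(manifest$fovs)), function(i) {
      f <- manifest$fovs[i, ]
      list(sample_id = f$sample_id, fov_id = f$fov_id,
           region_class = f$region_class,
           files = as.list(manifest$files[[f$fov_id]]))
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.pp_manifest <- function(x, ...) {
  cat("Experiment manifest:",
      nrow(x$samples), "samples,",
      nrow(x$fovs), "FOVs,",
      nrow(x$channels), "channels,",
      "pixel size", x$pixel_size_um, "um\n")
  cat("Conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

# internal helpers used across modules
manifest_condition_of <- function(manifest, sample_id) {
  manifest$samples$condition[match(sample_id, manifest$samples$sample_id)]
}

manifest_plate_of <- function(manifest, sample_id) {
  manifest$samples$plate_id[match(sample_id, manifest$samples$sample_id)]
}
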