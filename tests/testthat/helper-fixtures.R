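# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# broadband speckle texture (suitable for phase correlation)
speckle_texture <- function(n = 128, sigma = 1, seed = 42) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- matrix(runif(n * n), n, n)
  y <- EBImage::gblur(EBImage::Image(x), sigma)
  matrix(as.numeric(y), n, n)
}

# circular roll (periodic shift) of a matrix by d = (d_row, d_col)
roll_matrix <- function(x, d) {
  H <- nrow(x); W <- ncol(x)
  x[((seq_len(H) - 1 - d[1]) %% H) + 1, ((seq_len(W) - 1 - d[2]) %% W) + 1]
}

# minimal two-cycle manifest + TIFFs on disk; returns the manifest
tiny_manifest <- function(dir, n = 32, seed = 7) {
  set.seed(seed)
  channels <- channel_meta(
    name = c("NHS-E", "A", "NHS-E", "B"),
    cycle = c(1, 1, 2, 2),
    wavelength = c("ref", "w1", "ref", "w1"),
    is_reference = c(TRUE, FALSE, TRUE, FALSE)
  )
  samples <- data.frame(sample_id = "s1", condition = "control",
                        plate_id = "p1", stringsAsFactors = FALSE)
  fovs <- data.frame(sample_id = "s1", fov_id = "f1",
                     region_class = NA, stringsAsFactors = FALSE)
  files <- list(f1 = c())
  dir.create(file.path(dir, "f1"), showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(channels))) {
    key <- sprintf("c%d.%s", channels$cycle[i], channels$name[i])
    img <- matrix(round(runif(n * n, 0, 4000)), n, n)
    rel <- file.path("f1", paste0(key, ".tif"))
    write_tiff_uint16(img, file.path(dir, rel))
    files$f1[key] <- rel
  }
  experiment_manifest(samples, fovs, channels, files, pixel_size_um = 0.2,
                      base_dir = dir)
}

# small synthetic experiment shared by the slower end-to-end tests
small_synth <- function(dir, seed = 11) {
  cfg <- synthetic_config(fov_shape = c(96L, 96L), n_samples = 2L,
                          n_fovs = 2L, blobs_per_pattern = 5, seed = seed)
  generate_experiment(cfg, dir)
}
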