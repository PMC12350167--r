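# Ground-truth consistency of the synthetic experiment generator.

test_that("noise-free, shift-free generation reproduces signatures exactly", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(fov_shape = c(64L, 64L), n_samples = 1L, n_fovs = 1L,
                          blobs_per_pattern = 3, noise_sd = 0, shift_range = 0L,
                          af_amplitude = 0, rbc_per_fov = 0, tissue_cv = 0,
                          seed = 5)
  gen <- generate_experiment(cfg, dir)
  st <- read_image_stack(gen$manifest, gen$manifest$fovs$fov_id[1])
  lm <- gen$truth$label_maps[[1]]
  lay <- st$channels[!st$channels$is_reference & !st$channels$is_secondary_only &
                       st$channels$name != "GYPA", ]
  for (p in seq_len(cfg$n_patterns)) {
    px <- which(lm == p)
    if (!length(px)) next
    for (j in seq_len(nrow(lay))) {
      ch_idx <- which(st$channels$name == lay$name[j] &
                        st$channels$cycle == lay$cycle[j])
      m <- match(lay$name[j], colnames(gen$truth$signatures))
      expected <- round(gen$truth$signatures[p, m] * cfg$intensity_scale)
      vals <- st$data[, , ch_idx][px]
      expect_true(all(abs(vals - expected) <= 1)) # 16-bit rounding only
    }
  }
  # background is exactly zero
  expect_true(all(st$data[, , which(st$channels$name == "M1")][lm == 0] == 0))
})

test_that("generation is deterministic given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- synthetic_config(fov_shape = c(48L, 48L), n_samples = 1L, n_fovs = 2L,
                          blobs_per_pattern = 3, seed = 9)
  g1 <- generate_experiment(cfg, d1)
  g2 <- generate_experiment(synthetic_config(fov_shape = c(48L, 48L),
                                             n_samples = 1L, n_fovs = 2L,
                                             blobs_per_pattern = 3, seed = 9), d2)
  expect_identical(g1$truth$label_maps, g2$truth$label_maps)
  expect_identical(g1$truth$shifts, g2$truth$shifts)
  f <- gen_files <- list.files(d1, recursive = TRUE, pattern = "tif$")
  for (fn in f) {
    expect_identical(readBin(file.path(d1, fn), "raw", 1e6),
                     readBin(file.path(d2, fn), "raw", 1e6))
  }
})

test_that("ground-truth abundance matches a recount of the label maps", {
  dir <- withr::local_tempdir()
  gen <- small_synth(dir, seed = 13)
  cfg <- gen$truth$config
  for (i in seq_len(nrow(gen$truth$abundance))) {
    fid <- gen$truth$abundance$fov_id[i]
    lm <- gen$truth$label_maps[[fid]]
    fg <- lm[lm > 0]
    recount <- tabulate(fg, nbins = cfg$n_patterns) / length(fg)
    expect_equal(unlist(gen$truth$abundance[i, paste0("p", 1:cfg$n_patterns)]),
                 recount, ignore_attr = TRUE)
  }
})

test_that("scoring reports perfect and chance-level label maps correctly", {
  dir <- withr::local_tempdir()
  gen <- small_synth(dir, seed = 17)
  fid <- names(gen$truth$label_maps)[1]
  lm <- gen$truth$label_maps[[fid]]
  perfect <- cluster_image(lm - 1L, fov_id = fid,
                           n_clusters = max(lm)) # background -1, patterns 0..
  rep <- score_against_truth(setNames(list(perfect), fid), gen$truth)
  expect_equal(rep$pixel_ari, 1)
  set.seed(1)
  rnd <- cluster_image(matrix(sample(0:5, length(lm), TRUE), nrow(lm)),
                       fov_id = fid, n_clusters = 6L)
  rep2 <- score_against_truth(setNames(list(rnd), fid), gen$truth)
  expect_lt(abs(rep2$pixel_ari), 0.05)
  # exact shifts give zero RMSE
  rep3 <- score_against_truth(NULL, gen$truth,
                              detected_shifts = lapply(gen$truth$shifts, function(s) -s))
  expect_equal(rep3$shift_rmse, 0)
  # signature matching identifies planted signatures from themselves
  sm <- match_signatures(gen$truth$signatures, gen$truth$signatures)
  expect_equal(sm$cluster, seq_len(nrow(gen$truth$signatures)) - 1L)
  expect_true(all(sm$cosine > 0.999))
})

test_that("stronger noise degrades recovered signature similarity", {
  # monotone trend of node-signature cosine with noise, fixed seeds
  cos_min <- sapply(c(0.02, 0.3), function(ns) {
    dir <- withr::local_tempdir()
    cfg <- synthetic_config(fov_shape = c(64L, 64L), n_samples = 1L,
                            n_fovs = 2L, blobs_per_pattern = 4,
                            noise_sd = ns, shift_range = 0L, rbc_per_fov = 0,
                            seed = 21)
    gen <- generate_experiment(cfg, dir)
    rc <- run_config(subsample_n = 1500L, grid_side = 8L, k = 6L,
                     elution_qc = FALSE)
    res <- run_pipeline(gen$manifest, rc)
    means <- cluster_mean_profiles(res$node_weights, res$model$node_labels)
    means <- means[, colnames(gen$truth$signatures), drop = FALSE]
    # per-pattern best cosine to any recovered cluster (clusters may merge)
    nm <- means / sqrt(rowSums(means^2))
    ns <- gen$truth$signatures / sqrt(rowSums(gen$truth$signatures^2))
    mean(apply(ns %*% t(nm), 1, max))
  })
  expect_gt(cos_min[1], cos_min[2])
})
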