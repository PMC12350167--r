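# Abundance quantification, differential testing, multiple-testing
# corrections, contributor statistics, plate concordance.

test_that("count_clusters normalizes over unmasked pixels", {
  ci <- cluster_image(matrix(c(0L, 0L, 1L, 2L), 2, 2, byrow = TRUE),
                      n_clusters = 3L)
  expect_equal(count_clusters(ci), c(0.5, 0.25, 0.25))
  half <- cluster_image(rbind(matrix(-1L, 2, 4), matrix(0:1, 2, 4)),
                        n_clusters = 2L)
  expect_equal(count_clusters(half), c(0.5, 0.5))
  set.seed(1)
  rnd <- cluster_image(matrix(sample(c(-1L, 0:6), 400, TRUE), 20, 20),
                       n_clusters = 7L)
  expect_equal(sum(count_clusters(rnd)), 1, tolerance = 1e-12)
  empty <- cluster_image(matrix(-1L, 3, 3), n_clusters = 2L)
  expect_error(count_clusters(empty), "unmasked")
})

test_that("sample aggregation is the unweighted FOV mean and preserves row sums", {
  tb <- structure(data.frame(
    fov_id = c("f1", "f2", "f3"), sample_id = c("s1", "s1", "s2"),
    condition = "c", plate_id = "p",
    c0 = c(0.2, 0.4, 1), c1 = c(0.8, 0.6, 0),
    stringsAsFactors = FALSE
  ), class = c("pp_abundance", "data.frame"))
  agg <- aggregate_by_sample(tb)
  expect_equal(agg$c0[agg$sample_id == "s1"], 0.3)
  expect_equal(agg$c0[agg$sample_id == "s2"], 1) # single-FOV sample unchanged
  expect_equal(rowSums(agg[, c("c0", "c1")]), rep(1, 2), ignore_attr = TRUE)
})

test_that("differential abundance matches the closed-form Welch oracle", {
  tb <- structure(data.frame(
    fov_id = paste0("f", 1:6), sample_id = paste0("s", 1:6),
    condition = rep(c("A", "B"), each = 3), plate_id = "p",
    c0 = c(0.20, 0.22, 0.18, 0.10, 0.12, 0.08),
    c1 = c(0.80, 0.78, 0.82, 0.90, 0.88, 0.92),
    stringsAsFactors = FALSE
  ), class = c("pp_abundance", "data.frame"))
  res <- differential_abundance(tb, "A", "B", correction = "none")
  r0 <- res[res$cluster == 0, ]
  expect_equal(r0$log2fc, 1)
  expect_equal(r0$t_statistic, 6.123724, tolerance = 1e-5)
  # closed form: 2 * pt(-6.123724, df = 4)
  expect_equal(r0$p_value, 0.003602233, tolerance = 1e-6)
  # identical groups: log2fc 0 and p = 1
  tb2 <- tb
  tb2[4:6, c("c0", "c1")] <- tb2[1:3, c("c0", "c1")]
  res2 <- differential_abundance(tb2, "A", "B", correction = "none")
  expect_equal(res2$log2fc, c(0, 0))
  expect_true(all(res2$p_value > 0.9))
  expect_error(differential_abundance(tb[c(1, 4:6), ], "A", "B"), ">= 2")
})

test_that("BH and Holm-Sidak corrections match independent oracles", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04), "bh"),
               c(0.03, 0.03, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm_sidak"),
               c(1 - 0.99^2, 0.04))
  expect_equal(adjust_pvalues(0.03, "bh"), 0.03) # m = 1 unchanged
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
  # oracle equivalence on random vectors; monotone, bounded, >= input
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    adj <- pmin(cummin(p[o] * m / (m:1)), 1)
    adj[order(o)]
  }
  hs_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- pmin(cummax(1 - (1 - p[o])^(m - seq_len(m) + 1)), 1)
    adj[order(o)]
  }
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))^2
    bh <- adjust_pvalues(p, "bh")
    hs <- adjust_pvalues(p, "holm_sidak")
    expect_equal(bh, bh_oracle(p), tolerance = 1e-12)
    expect_equal(hs, hs_oracle(p), tolerance = 1e-12)
    for (adj in list(bh, hs)) {
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      expect_equal(order(adj[order(p)]), seq_along(p)) # order-preserving
    }
  }
})

test_that("contributor statistics implement the high-contributor gates", {
  set.seed(3)
  n <- 120
  labels <- rep(0:2, each = n / 3)
  vals <- matrix(runif(n * 3, 0, 0.1), n, 3,
                 dimnames = list(NULL, c("mA", "mB", "mC")))
  vals[labels == 0, "mA"] <- runif(n / 3, 0.7, 0.9) # defining marker
  vals[labels == 1, "mB"] <- runif(n / 3, 0.22, 0.28) # modest but specific
  stats <- cluster_contributors(vals, labels, correction = "holm_sidak")
  a <- stats[stats$cluster == 0 & stats$marker == "mA", ]
  expect_true(a$is_high_contributor)
  expect_gte(a$mean_norm_intensity, 0.2)
  expect_gte(a$log2fc, 1)
  expect_lt(a$p_adjusted, 0.05)
  expect_equal(a$rank_score, a$mean_norm_intensity * a$log2fc)
  # marker below the mean gate is never a high contributor
  c_rows <- stats[stats$marker == "mC", ]
  expect_false(any(c_rows$is_high_contributor))
  # log2fc examples: mean 0.8 in vs 0.2 out -> exactly 2
  v2 <- matrix(c(rep(0.8, 5), rep(0.2, 10)), ncol = 1,
               dimnames = list(NULL, "m"))
  s2 <- cluster_contributors(v2, c(rep(0, 5), rep(1, 10)), correction = "none")
  expect_equal(s2$log2fc[s2$cluster == 0], 2)
  # singleton cluster: p is NA, flagged, never a high contributor
  s3 <- cluster_contributors(v2, c(0, rep(1, 14)), correction = "none")
  expect_true(all(is.na(s3$p_value[s3$cluster == 0])))
  expect_true(all(s3$singleton[s3$cluster == 0]))
  expect_false(any(s3$is_high_contributor[s3$cluster == 0]))
})

test_that("plate concordance pairs per-plate fold changes", {
  base <- data.frame(
    fov_id = paste0("f", 1:8), sample_id = paste0("s", 1:8),
    condition = rep(c("A", "B"), 4),
    plate_id = rep(c("p1", "p2"), each = 4),
    c0 = rep(c(0.3, 0.1, 0.3, 0.1), 2),
    c1 = rep(c(0.7, 0.9, 0.7, 0.9), 2),
    stringsAsFactors = FALSE
  )
  tb <- structure(base, class = c("pp_abundance", "data.frame"))
  pc <- plate_concordance(tb, "A", "B")
  expect_equal(pc$pairs$log2fc_p1, pc$pairs$log2fc_p2)
  expect_equal(pc$correlation, 1)
  # single cluster: correlation undefined -> NaN
  tb1 <- structure(base[, setdiff(names(base), "c1")],
                   class = c("pp_abundance", "data.frame"))
  expect_true(is.nan(plate_concordance(tb1, "A", "B")$correlation))
  # missing condition on a plate errors
  tb3 <- structure(base[base$condition == "A" | base$plate_id == "p1", ],
                   class = c("pp_abundance", "data.frame"))
  expect_error(plate_concordance(tb3, "A", "B"), "plate")
})
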