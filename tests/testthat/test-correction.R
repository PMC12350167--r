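# Foreground / RBC masking, autofluorescence estimation and elution QC.

test_that("foreground mask excludes lifted areas via minimum projection", {
  set.seed(1)
  base <- matrix(0, 40, 40)
  base[10:30, 10:30] <- 200
  base <- base + matrix(runif(1600, 0, 10), 40, 40)
  lifted <- base
  lifted[1:20, 21:40] <- runif(400, 0, 10) # quadrant lost in one cycle
  lifted[10:20, 21:30] <- runif(110, 0, 10)
  mask <- compute_foreground_mask(list(base, base, lifted))
  expect_false(any(mask[10:20, 21:30])) # lifted tissue area excluded
  expect_true(all(mask[21:30, 10:20])) # stable tissue retained
  # all cycles identical: equals the single-image Otsu mask
  m1 <- compute_foreground_mask(list(base))
  m3 <- compute_foreground_mask(list(base, base, base))
  expect_identical(m1, m3)
})

test_that("otsu threshold separates a two-component intensity mixture", {
  set.seed(2)
  x <- matrix(c(rnorm(700, 10, 3), rnorm(300, 200, 20)), 25, 40)
  th <- otsu_threshold(x)
  expect_gt(th, 10)
  expect_lt(th, 200)
  # exhaustive between-class-variance oracle over the same 256-bin grid:
  # the returned threshold must attain the maximal between-class variance
  # (the optimum is a plateau across the empty gap between the components)
  r <- range(x)
  bins <- cut(as.vector(x), breaks = seq(r[1], r[2], length.out = 257),
              include.lowest = TRUE, labels = FALSE)
  h <- tabulate(bins, 256)
  bcv <- vapply(1:255, function(t) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) return(0)
    mu0 <- sum((1:t) * h[1:t]) / w0
    mu1 <- sum(((t + 1):256) * h[(t + 1):256]) / w1
    w0 * w1 * (mu0 - mu1)^2
  }, numeric(1))
  th_bin <- min(max(floor((th - r[1]) / diff(r) * 256), 1), 255)
  expect_gte(bcv[th_bin], 0.999 * max(bcv))
})

test_that("rbc mask removes small objects, dilates and fills holes", {
  set.seed(3)
  ch <- matrix(rnorm(64 * 64, 50, 5), 64, 64)
  # 200-px blob with an internal hole
  blob <- outer((1:64) - 20, (1:64) - 20, function(a, b) a^2 + b^2 <= 64)
  hole <- outer((1:64) - 20, (1:64) - 20, function(a, b) a^2 + b^2 <= 2)
  ch[blob & !hole] <- 4000
  # 50-px blob: below the 72-px object threshold
  small <- outer((1:64) - 50, (1:64) - 50, function(a, b) a^2 + b^2 <= 15)
  ch[small] <- 4000
  mask <- compute_rbc_mask(ch)
  expect_true(all(mask[blob])) # hole filled, blob kept (and dilated)
  expect_false(any(mask[small])) # small object removed
  # blank channel: all false
  expect_false(any(compute_rbc_mask(matrix(rnorm(400, 10, 1), 20, 20))))
  # invariance to adding a constant
  expect_identical(compute_rbc_mask(ch), compute_rbc_mask(ch + 1000))
})

test_that("analysis mask is foreground AND NOT rbc", {
  set.seed(4)
  for (i in 1:5) {
    fg <- matrix(runif(100) > 0.5, 10, 10)
    rbc <- matrix(runif(100) > 0.8, 10, 10)
    ms <- mask_set(fg, rbc)
    expect_identical(ms$analysis, fg & !rbc)
  }
})

test_that("autofluorescence interpolates linearly across secondary cycles", {
  u <- function(v) matrix(v, 4, 4)
  secs <- list(list(cycle = 3, wavelength = "w1", image = u(10)),
               list(cycle = 7, wavelength = "w1", image = u(20)),
               list(cycle = 5, wavelength = "w2", image = u(99)))
  expect_equal(estimate_autofluorescence(5, "w1", secs), u(15))
  expect_equal(estimate_autofluorescence(3, "w1", secs), u(10)) # exact cycle
  expect_equal(estimate_autofluorescence(2, "w1", secs), u(10)) # extrapolation
  expect_equal(estimate_autofluorescence(9, "w1", secs), u(20))
  expect_error(estimate_autofluorescence(5, "w9", secs), "w1")
  # subtraction clips at zero and is identity for zero AF
  ch <- matrix(c(12, 100, 0, 40), 2, 2)
  expect_equal(subtract_autofluorescence(ch, matrix(15, 2, 2)),
               matrix(c(0, 85, 0, 25), 2, 2))
  expect_equal(subtract_autofluorescence(ch, matrix(0, 2, 2)), ch)
  set.seed(5)
  rnd <- matrix(runif(64, 0, 100), 8, 8)
  af <- matrix(runif(64, 0, 100), 8, 8)
  expect_true(all(subtract_autofluorescence(rnd, af) >= 0))
})

test_that("elution QC flags primaries at or below the secondary baseline", {
  set.seed(6)
  primary <- matrix(rexp(2500, 1 / 50), 50, 50)
  weak <- primary * 0.5
  strong <- primary * 3
  sec1 <- matrix(rexp(2500, 1 / 40), 50, 50)
  sec2 <- matrix(rexp(2500, 1 / 30), 50, 50)
  # clearly above both percentiles: not flagged
  expect_false(elution_qc(strong, list(sec1, sec2))$flagged)
  # identical to a secondary: equality counts as flagged
  expect_true(elution_qc(sec1, list(sec1, sec2))$flagged)
  # p50 above but p99.95 below the secondary maximum: flagged
  rep <- elution_qc(weak, list(strong))
  expect_true(rep$flagged)
  # aggregation across secondaries is the percentile-wise maximum
  expect_equal(rep$p50_secondary_max, percentile(strong, 50))
})
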