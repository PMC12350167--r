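# Cluster abundance quantification, differential abundance testing and
# per-cluster marker contributor statistics.

abundance_cols <- function(table) grep("^c[0-9]+$", names(table), value = TRUE)

# epsilon-stabilized log2 ratio; the stabilizer is only engaged when a mean
# is zero, so strictly positive means give the exact ratio.
log2_ratio <- function(a, b, eps) {
  if (a <= 0 || b <= 0) log2((a + eps) / (b + eps)) else log2(a / b)
}

# Welch t-test that tolerates zero-variance groups: identical constant
# groups give (t = 0, p = 1), constant but different groups (t = +-Inf,
# p = 0).
welch_test <- function(a, b) {
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Normalized cluster abundance of one label image
#'
#' Pixel counts per cluster over the unmasked (`label >= 0`) pixels,
#' normalized to sum to 1.
#'
#' @param x A [cluster_image()].
#' @param n_clusters Number of clusters (defaults to the image's).
#' @return Numeric vector of length `n_clusters` summing to 1.
#' @export
count_clusters <- function(x, n_clusters = x$n_clusters) {
  lab <- x$labels[x$labels >= 0L]
  if (!length(lab)) stop("no unmasked pixels in FOV ", x$fov_id)
  counts <- tabulate(lab + 1L, nbins = n_clusters)
  counts / sum(counts)
}

#' Per-FOV cluster abundance table
#'
#' One row per FOV with its sample, condition and plate metadata and one
#' column `c<k>` per cluster holding the normalized abundance (each row
#' sums to 1 over the counted clusters).
#'
#' @param cluster_images Named list (by `fov_id`) of [cluster_image()]s.
#' @param manifest A `pp_manifest`.
#' @param n_clusters Number of clusters (defaults to the first image's).
#' @return `data.frame` of class `pp_abundance`.
#' @export
abundance_table <- function(cluster_images, manifest,
                            n_clusters = cluster_images[[1]]$n_clusters) {
  rows <- lapply(names(cluster_images), function(fid) {
    i <- match(fid, manifest$fovs$fov_id)
    if (is.na(i)) stop("FOV ", fid, " not in manifest")
    sid <- manifest$fovs$sample_id[i]
    ab <- count_clusters(cluster_images[[fid]], n_clusters)
    cbind(
      data.frame(fov_id = fid, sample_id = sid,
                 condition = manifest_condition_of(manifest, sid),
                 plate_id = manifest_plate_of(manifest, sid),
                 stringsAsFactors = FALSE),
      as.data.frame(setNames(as.list(ab), paste0("c", seq_len(n_clusters) - 1L)))
    )
  })
  structure(do.call(rbind, rows), class = c("pp_abundance", "data.frame"))
}

#' Aggregate FOV abundances to sample level
#'
#' Unweighted mean over each sample's FOVs, per cluster; row sums remain 1.
#'
#' @param table A `pp_abundance` table.
#' @return Sample-level `pp_abundance` (one row per sample).
#' @export
aggregate_by_sample <- function(table) {
  cols <- abundance_cols(table)
  rows <- lapply(unique(table$sample_id), function(sid) {
    sub <- table[table$sample_id == sid, , drop = FALSE]
    out <- sub[1, c("sample_id", "condition", "plate_id"), drop = FALSE]
    out[cols] <- as.list(colMeans(sub[, cols, drop = FALSE]))
    out
  })
  structure(do.call(rbind, rows), class = c("pp_abundance", "data.frame"))
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up false-discovery-rate adjustment or
#' Holm-Sidak step-down adjustment; both are monotone and clipped to 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"bh"` or `"holm_sidak"` (or `"none"`).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "holm_sidak", "none")) {
  method <- match.arg(method)
  ok <- is.finite(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  if (method == "none") return(p)
  if (method == "bh") return(stats::p.adjust(p, method = "BH"))
  # Holm-Sidak: ascending p, adj_i = 1 - (1 - p_(i))^(m - i + 1), running max
  out <- rep(NA_real_, length(p))
  idx <- which(ok)
  pv <- p[idx]
  m <- length(pv)
  o <- order(pv)
  adj <- 1 - (1 - pv[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out[idx[o]] <- adj
  out
}

#' Differential cluster abundance between two conditions
#'
#' Per cluster: log2 fold change of mean abundance (test vs reference) and
#' a two-sided Welch t-test over per-observation abundances, followed by
#' multiple-testing correction across clusters. The log2 fold change uses
#' an epsilon stabilizer (half the smallest positive abundance in the
#' table) only when a group mean is zero.
#'
#' @param table A `pp_abundance` table (FOV- or sample-level; the rows of
#'   the chosen level are the statistical units).
#' @param condition_a Test condition.
#' @param condition_b Reference condition.
#' @param correction `"bh"`, `"holm_sidak"` or `"none"`.
#' @param alpha Significance level applied to adjusted p-values.
#' @return `data.frame` with per-cluster `log2fc`, `t_statistic`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
differential_abundance <- function(table, condition_a, condition_b,
                                   correction = c("bh", "holm_sidak", "none"),
                                   alpha = 0.05) {
  correction <- match.arg(correction)
  cols <- abundance_cols(table)
  A <- table[table$condition == condition_a, cols, drop = FALSE]
  B <- table[table$condition == condition_b, cols, drop = FALSE]
  if (nrow(A) < 2L || nrow(B) < 2L) {
    stop("need >= 2 observations per condition")
  }
  all_ab <- as.matrix(table[cols])
  pos <- all_ab[all_ab > 0]
  eps <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  res <- lapply(cols, function(cl) {
    a <- A[[cl]]; b <- B[[cl]]
    ht <- welch_test(a, b)
    data.frame(
      cluster = as.integer(sub("^c", "", cl)),
      mean_a = mean(a), mean_b = mean(b),
      log2fc = log2_ratio(mean(a), mean(b), eps),
      t_statistic = ht$statistic, p_value = ht$p.value
    )
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- adjust_pvalues(out$p_value, correction)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  attr(out, "epsilon") <- eps
  attr(out, "conditions") <- c(condition_a, condition_b)
  out
}

#' Marker contributor statistics per cluster
#'
#' For every (cluster, marker) pair: the in-cluster mean normalized
#' intensity, the log2 fold change versus the out-of-cluster mean, a
#' two-tailed Welch t-test (in vs out) corrected across markers within the
#' cluster, the ranking score `mean x log2fc`, and the high-contributor
#' gate (mean >= 0.2, adjusted p < 0.05, log2fc >= 1).
#'
#' @param values N x C matrix of normalized intensities in \[0, 1\]
#'   (subsampled pixels or SOM node weights), columns named by marker.
#' @param labels Integer vector (0-based cluster ids) of length N.
#' @param correction `"holm_sidak"` (default), `"bh"` or `"none"`.
#' @return `data.frame` with one row per (cluster, marker), ordered by
#'   cluster then decreasing `rank_score`.
#' @export
cluster_contributors <- function(values, labels,
                                 correction = c("holm_sidak", "bh", "none")) {
  correction <- match.arg(correction)
  values <- as.matrix(values)
  markers <- colnames(values) %||% paste0("ch", seq_len(ncol(values)))
  pos <- values[values > 0]
  eps <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  out <- NULL
  for (cl in sort(unique(labels))) {
    inside <- labels == cl
    singleton <- sum(inside) < 2L
    rows <- lapply(seq_along(markers), function(j) {
      vi <- values[inside, j]; vo <- values[!inside, j]
      l2 <- log2_ratio(mean(vi), mean(vo), eps)
      pv <- if (singleton || length(vo) < 2L) {
        NA_real_
      } else {
        welch_test(vi, vo)$p.value
      }
      data.frame(cluster = cl, marker = markers[j],
                 mean_norm_intensity = mean(vi), out_mean = mean(vo),
                 log2fc = l2, p_value = pv, singleton = singleton,
                 stringsAsFactors = FALSE)
    })
    sub <- do.call(rbind, rows)
    sub$p_adjusted <- adjust_pvalues(sub$p_value, correction)
    sub$rank_score <- sub$mean_norm_intensity * sub$log2fc
    sub$is_high_contributor <- !is.na(sub$p_adjusted) &
      sub$mean_norm_intensity >= 0.2 & sub$p_adjusted < 0.05 & sub$log2fc >= 1
    sub <- sub[order(-sub$rank_score), ]
    out <- rbind(out, sub)
  }
  rownames(out) <- NULL
  out
}

#' Mean channel profile of each cluster
#'
#' @param values N x C matrix (SOM node weights or subsampled pixels),
#'   columns named by marker.
#' @param labels Integer vector of 0-based cluster ids, length N.
#' @return K x C matrix of per-cluster column means (rows ordered by
#'   cluster id).
#' @export
cluster_mean_profiles <- function(values, labels) {
  values <- as.matrix(values)
  ids <- sort(unique(labels))
  out <- t(vapply(ids, function(k) {
    colMeans(values[labels == k, , drop = FALSE])
  }, numeric(ncol(values))))
  rownames(out) <- ids
  out
}

#' Between-plate concordance of differential abundance
#'
#' Computes the per-cluster log2 fold change between two conditions within
#' each plate independently and reports the paired values with their
#' Pearson correlation — a QC for batch integration.
#'
#' @param table A `pp_abundance` table covering both plates.
#' @param condition_a,condition_b Conditions compared (both must be present
#'   on every plate).
#' @return List with `pairs` (`data.frame`: cluster, one log2fc column per
#'   plate) and `correlation` (`NaN` when fewer than 2 clusters).
#' @export
plate_concordance <- function(table, condition_a, condition_b) {
  cols <- abundance_cols(table)
  plates <- sort(unique(table$plate_id))
  all_ab <- as.matrix(table[cols])
  pos <- all_ab[all_ab > 0]
  eps <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  fc <- sapply(plates, function(pl) {
    sub <- table[table$plate_id == pl, , drop = FALSE]
    if (!all(c(condition_a, condition_b) %in% sub$condition)) {
      stop("condition missing on plate ", pl)
    }
    vapply(cols, function(cl) {
      log2_ratio(mean(sub[[cl]][sub$condition == condition_a]),
                 mean(sub[[cl]][sub$condition == condition_b]), eps)
    }, numeric(1))
  })
  fc <- matrix(fc, ncol = length(plates),
               dimnames = list(cols, paste0("log2fc_", plates)))
  corr <- if (nrow(fc) < 2L || length(plates) < 2L) {
    NaN
  } else {
    suppressWarnings(stats::cor(fc[, 1], fc[, 2]))
  }
  list(pairs = data.frame(cluster = as.integer(sub("^c", "", cols)), fc,
                          row.names = NULL),
       correlation = if (is.na(corr)) NaN else corr)
}
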