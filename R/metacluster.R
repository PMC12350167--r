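# Cell-level metaclustering: pixel-cluster composition inside discs around
# externally segmented nucleus centroids.

#' Cell regions around nucleus centroids
#'
#' All nuclei of a FOV share one disc radius: the smaller of `max_radius_um`
#' (5 um) and half the shortest Delaunay-triangulation edge between
#' centroids. The shortest Delaunay edge connects the closest pair of
#' points, so it equals the minimum pairwise centroid distance. With fewer
#' than 3 non-collinear centroids the triangulation is degenerate and the
#' radius falls back to `max_radius_um` with a warning. A pixel belongs to
#' a disc if its centre lies within the radius (inclusive); discs are
#' clipped to the frame.
#'
#' @param centroids n x 2 matrix of nucleus centroids `(row, col)`, 1-based
#'   pixel coordinates.
#' @param pixel_size_um Micrometres per pixel.
#' @param fov_shape `(H, W)`.
#' @param max_radius_um Radius cap in micrometres (default 5).
#' @return List with `radius_um`, `radius_px` and `cells` — a list of
#'   per-cell matrices of `(row, col)` pixel coordinates.
#' @export
cell_regions <- function(centroids, pixel_size_um, fov_shape,
                         max_radius_um = 5) {
  centroids <- matrix(as.numeric(centroids), ncol = 2)
  n <- nrow(centroids)
  if (anyDuplicated(centroids) > 0) stop("duplicate nucleus centroids")
  collinear <- function(p) {
    if (nrow(p) < 3L) return(TRUE)
    q <- sweep(p, 2, colMeans(p))
    qr(q)$rank < 2L
  }
  if (collinear(centroids)) {
    warning("fewer than 3 non-collinear centroids; using the ",
            max_radius_um, " um fallback radius")
    radius_um <- max_radius_um
  } else {
    dmin <- min(stats::dist(centroids)) * pixel_size_um
    radius_um <- min(max_radius_um, 0.5 * dmin)
  }
  radius_px <- radius_um / pixel_size_um
  cells <- lapply(seq_len(n), function(i) {
    cr <- centroids[i, 1]; cc <- centroids[i, 2]
    rr <- max(1, ceiling(cr - radius_px)):min(fov_shape[1], floor(cr + radius_px))
    ccs <- max(1, ceiling(cc - radius_px)):min(fov_shape[2], floor(cc + radius_px))
    grid <- expand.grid(row = rr, col = ccs)
    keep <- (grid$row - cr)^2 + (grid$col - cc)^2 <= radius_px^2
    as.matrix(grid[keep, , drop = FALSE])
  })
  list(radius_um = radius_um, radius_px = radius_px, cells = cells)
}

#' Pixel-cluster composition of each cell
#'
#' Per cell, the fraction of in-disc unmasked pixels belonging to each
#' pixel-level cluster. Cells whose disc is entirely masked are dropped
#' with a message.
#'
#' @param x A [cluster_image()].
#' @param regions Output of [cell_regions()].
#' @return `data.frame` with `cell_id`, `fov_id`, `radius_um` and one
#'   fraction column `c<k>` per cluster (rows sum to 1).
#' @export
cell_cluster_fractions <- function(x, regions) {
  K <- x$n_clusters
  rows <- list()
  for (i in seq_along(regions$cells)) {
    px <- regions$cells[[i]]
    lab <- x$labels[px]
    lab <- lab[lab >= 0L]
    if (!length(lab)) {
      message("cell ", i, " in FOV ", x$fov_id, " entirely masked; dropped")
      next
    }
    fr <- tabulate(lab + 1L, nbins = K)
    fr <- fr / sum(fr)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(cell_id = i, fov_id = x$fov_id,
                 radius_um = regions$radius_um, stringsAsFactors = FALSE),
      as.data.frame(setNames(as.list(fr), paste0("c", seq_len(K) - 1L)))
    )
  }
  do.call(rbind, rows)
}

#' Group cells into metaclusters
#'
#' k-nearest-neighbour graph over the cells' pixel-cluster composition
#' vectors followed by Leiden community detection.
#'
#' @param features cells x K matrix of cluster fractions (e.g. the `c<k>`
#'   columns of [cell_cluster_fractions()]).
#' @param k Neighbour count (default 50).
#' @param resolution Leiden resolution (default 1).
#' @param seed RNG seed.
#' @return Integer vector of 0-based metacluster labels, one per cell.
#' @export
metacluster_cells <- function(features, k = 50L, resolution = 1, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k + 1L) stop("need at least k + 1 cells (have ", n, ")")
  g <- build_knn_graph(features, k = k, metric = "euclidean")
  model <- leiden_cluster(g, resolution = resolution, iterations = 10L,
                          seed = seed)
  model$node_labels
}

#' Condition test of metacluster abundance
#'
#' Metacluster relative abundances are computed per image, averaged to the
#' patient (sample) level, and compared between two conditions with a
#' two-sided Mann-Whitney U-test per metacluster, Bonferroni-corrected
#' across metaclusters.
#'
#' @param cells `data.frame` with columns `fov_id`, `metacluster`.
#' @param fov_meta `data.frame` with columns `fov_id`, `sample_id`,
#'   `condition`.
#' @param condition_a,condition_b The two conditions compared.
#' @param alpha Significance level on adjusted p-values.
#' @return `data.frame` with per-metacluster mean abundances, `p_value`,
#'   `p_adjusted` (Bonferroni) and `significant`.
#' @export
metacluster_condition_test <- function(cells, fov_meta, condition_a,
                                       condition_b, alpha = 0.05) {
  stopifnot(all(c("fov_id", "metacluster") %in% names(cells)))
  mc_ids <- sort(unique(cells$metacluster))
  # per-image relative abundance of each metacluster
  img <- lapply(unique(cells$fov_id), function(fid) {
    lab <- cells$metacluster[cells$fov_id == fid]
    fr <- vapply(mc_ids, function(m) mean(lab == m), numeric(1))
    data.frame(fov_id = fid, t(fr))
  })
  img <- do.call(rbind, img)
  names(img)[-1] <- paste0("m", mc_ids)
  img <- merge(img, fov_meta, by = "fov_id")
  # patient-level means
  pat <- lapply(unique(img$sample_id), function(sid) {
    sub <- img[img$sample_id == sid, , drop = FALSE]
    out <- data.frame(sample_id = sid, condition = sub$condition[1],
                      stringsAsFactors = FALSE)
    out[paste0("m", mc_ids)] <- as.list(colMeans(sub[paste0("m", mc_ids)]))
    out
  })
  pat <- do.call(rbind, pat)
  nA <- sum(pat$condition == condition_a)
  nB <- sum(pat$condition == condition_b)
  if (nA < 2L || nB < 2L) stop("need >= 2 samples per condition")
  res <- lapply(mc_ids, function(m) {
    a <- pat[pat$condition == condition_a, paste0("m", m)]
    b <- pat[pat$condition == condition_b, paste0("m", m)]
    pv <- if (all(a == b[1]) && all(b == b[1])) {
      1
    } else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    data.frame(metacluster = m, mean_a = mean(a), mean_b = mean(b),
               p_value = pv)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(out$p_value * length(mc_ids), 1)
  out$significant <- out$p_adjusted < alpha
  out
}
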