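# SOM training, node assignment, kNN / bbknn graphs, Leiden, pixel labeling.

planted_data <- function(n = 2000, noise = 0.02, seed = 3) {
  set.seed(seed)
  sig <- diag(4)
  lab <- sample(1:4, n, TRUE)
  X <- sig[lab, ] + matrix(rnorm(n * 4, 0, noise), n, 4)
  colnames(X) <- paste0("M", 1:4)
  list(X = X, labels = lab, signatures = sig)
}

# re-derive the seeded initialization used by train_som
with_seed_rows <- function(X, M, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  X[sample.int(nrow(X), M, replace = nrow(X) < M), , drop = FALSE]
}

test_that("batch SOM recovers well-separated one-hot signatures", {
  d <- planted_data()
  som <- train_som(d$X, grid_side = 2, iterations = 50, seed = 1)
  dist_to_best <- apply(som$weights, 1, function(w) {
    min(sqrt(colSums((t(d$signatures) - w)^2)))
  })
  expect_lt(max(dist_to_best), 0.1)
  # zero iterations leaves the initialization untouched
  som0 <- train_som(d$X, grid_side = 2, iterations = 0, seed = 1)
  init <- with_seed_rows(d$X, 4, seed = 1)
  expect_equal(unname(som0$weights), unname(init))
  # training reduces the quantization error
  expect_lt(quantization_error(d$X, som), quantization_error(d$X, som0))
})

test_that("assign_to_nodes matches an exhaustive nearest-node scan", {
  d <- planted_data(300)
  som <- train_som(d$X, grid_side = 3, iterations = 20, seed = 2)
  idx <- assign_to_nodes(d$X, som)
  brute <- apply(d$X, 1, function(x) {
    which.min(colSums((t(som$weights) - x)^2))
  })
  expect_equal(idx, unname(brute))
  # a pixel equal to a node's weight vector maps to that node
  expect_equal(assign_to_nodes(som$weights[5, , drop = FALSE], som), 5L)
  # cosine metric is scale-invariant
  somc <- train_som(d$X, grid_side = 3, metric = "cosine", iterations = 20,
                    seed = 2)
  w <- somc$weights[7, , drop = FALSE]
  expect_equal(assign_to_nodes(2 * w, somc), assign_to_nodes(w, somc))
})

test_that("knn graph symmetrizes by union and handles edge cases", {
  # 3 collinear points, k = 1: middle connects to both ends
  pts <- matrix(c(0, 1, 2.1, 0, 0, 0), ncol = 2)
  g <- build_knn_graph(pts, k = 1)
  expect_equal(sort(igraph::degree(g)), c(1, 1, 2))
  expect_true(igraph::are_adjacent(g, 1, 2))
  expect_true(igraph::are_adjacent(g, 2, 3))
  expect_false(igraph::are_adjacent(g, 1, 3))
  # k = n - 1 gives the complete graph
  set.seed(4)
  p2 <- matrix(rnorm(20), 10, 2)
  gc <- build_knn_graph(p2, k = 9)
  expect_equal(igraph::ecount(gc), choose(10, 2))
  # single batch bbknn reduces to knn
  gb <- build_bbknn_graph(p2, rep("b1", 10), k_per_batch = 3)
  gk <- build_knn_graph(p2, k = 3)
  expect_true(igraph::identical_graphs(igraph::simplify(gb), igraph::simplify(gk)) ||
                all(igraph::as_adjacency_matrix(gb) == igraph::as_adjacency_matrix(gk)))
})

test_that("bbknn forces cross-batch edges and links planted duplicates", {
  set.seed(5)
  b1 <- matrix(rnorm(40), 20, 2)
  b2 <- matrix(rnorm(40, 5), 20, 2)
  nodes <- rbind(b1, b2)
  batch <- rep(c("p1", "p2"), each = 20)
  g <- build_bbknn_graph(nodes, batch, k_per_batch = 1)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  cross <- adj[1:20, 21:40]
  expect_true(all(rowSums(cross) >= 1)) # every node has a cross-batch edge
  # planted identical pairs across batches connect to each other
  nodes2 <- rbind(b1, b1)
  g2 <- build_bbknn_graph(nodes2, batch, k_per_batch = 1)
  for (i in 1:20) expect_true(igraph::are_adjacent(g2, i, i + 20))
})

test_that("leiden clustering separates components and planted blobs", {
  # two disjoint 10-cliques -> exactly 2 clusters
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  m <- leiden_cluster(g, resolution = 1, seed = 1)
  expect_equal(m$n_clusters, 2L)
  expect_length(unique(m$node_labels[1:10]), 1)
  # complete graph at resolution -> 0 collapses to one cluster
  m1 <- leiden_cluster(igraph::make_full_graph(20), resolution = 1e-4, seed = 1)
  expect_equal(m1$n_clusters, 1L)
  # 5 well-separated Gaussian blobs recovered (ARI > 0.9)
  set.seed(6)
  centers <- matrix(rnorm(10, sd = 20), 5, 2)
  pts <- do.call(rbind, lapply(1:5, function(i) {
    sweep(matrix(rnorm(90, 0, 0.5), 45, 2), 2, centers[i, ], `+`)
  }))
  gk <- build_knn_graph(pts, k = 10)
  mk <- leiden_cluster(gk, resolution = 1, seed = 2)
  ari <- mclust::adjustedRandIndex(rep(1:5, each = 45), mk$node_labels)
  expect_gt(ari, 0.9)
  # determinism given the seed
  mk2 <- leiden_cluster(gk, resolution = 1, seed = 2)
  expect_identical(mk$node_labels, mk2$node_labels)
  expect_error(leiden_cluster(igraph::make_empty_graph(0)), "empty")
})

test_that("label_pixels maps masked pixels to -1 and respects channel names", {
  d <- planted_data(500)
  som <- train_som(d$X, grid_side = 2, iterations = 30, seed = 7)
  model <- leiden_cluster(build_knn_graph(som$weights, k = 2), seed = 3)
  img_data <- array(0, c(10, 10, 4))
  set.seed(8)
  truth <- matrix(sample(1:4, 100, TRUE), 10, 10)
  for (ch in 1:4) img_data[, , ch] <- (truth == ch) + rnorm(100, 0, 0.02)
  img <- multiplex_image(img_data, channel_meta(paste0("M", 1:4), 1, "w"),
                         fov_id = "f")
  ci <- label_pixels(img, som, model)
  expect_s3_class(ci, "pp_cluster_image")
  expect_true(all(ci$labels >= 0))
  # deterministic and consistent: same truth pattern -> same label
  for (ch in 1:4) {
    expect_length(unique(ci$labels[truth == ch]), 1)
  }
  # full mask -> all -1
  mask <- matrix(FALSE, 10, 10)
  expect_true(all(label_pixels(img, som, model, mask)$labels == -1L))
  # channel name mismatch errors
  bad <- multiplex_image(img_data, channel_meta(paste0("X", 1:4), 1, "w"))
  expect_error(label_pixels(bad, som, model), "channel")
})

test_that("foreground cluster filter retains clusters above the frequency cut", {
  f <- c(0.30, 0.0009, 0.0011)
  out <- filter_foreground_clusters(f, 0.001)
  expect_equal(out$retained, c(0L, 2L))
  expect_equal(out$flagged, 1L)
  expect_equal(filter_foreground_clusters(f, 0)$retained, 0:2)
  # 140 equal clusters at ~0.714% each all survive the 0.1% cut
  f140 <- rep(1 / 140, 140)
  expect_length(filter_foreground_clusters(f140, 0.001)$retained, 140)
})
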