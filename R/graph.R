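# Similarity graphs over SOM nodes and Leiden community detection.

pairwise_dissimilarity <- function(X, metric) {
  if (metric == "euclidean") {
    as.matrix(stats::dist(X))
  } else {
    Xn <- metric_rows(as.matrix(X), metric)
    1 - Xn %*% t(Xn) # cosine / Pearson dissimilarity
  }
}

knn_edges <- function(D, k, rows = seq_len(nrow(D)), cols = seq_len(ncol(D))) {
  # k nearest columns for every row; ties broken by lowest column index
  el <- NULL
  for (ii in seq_along(rows)) {
    i <- rows[ii]
    d <- D[i, ]
    cand <- cols[cols != i]
    ord <- cand[order(d[cand], cand)]
    nn <- ord[seq_len(min(k, length(ord)))]
    if (length(nn)) el <- rbind(el, cbind(i, nn))
  }
  el
}

#' Build a symmetrized k-nearest-neighbour graph
#'
#' Edge `(i, j)` is present iff `j` is among `i`'s `k` nearest neighbours or
#' vice versa (union symmetrization). Self-edges are excluded; duplicate
#' (zero-distance) points are allowed. Ties are broken by lowest index.
#'
#' @param nodes N x C matrix (e.g. SOM node weights).
#' @param k Number of neighbours, `k < N`.
#' @param metric `"euclidean"`, `"cosine"` or `"pearson"`.
#' @return An undirected [igraph::graph] with N vertices.
#' @export
build_knn_graph <- function(nodes, k, metric = c("euclidean", "cosine", "pearson")) {
  metric <- match.arg(metric)
  nodes <- as.matrix(nodes)
  n <- nrow(nodes)
  stopifnot(k >= 1, k < n)
  D <- pairwise_dissimilarity(nodes, metric)
  el <- knn_edges(D, k)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::simplify(g)
}

#' Build a batch-balanced k-nearest-neighbour graph
#'
#' Each node receives `k_per_batch` nearest neighbours within every batch
#' (including its own), forcing cross-batch connectivity so that plates mix
#' in the subsequent community detection. With a single batch this reduces
#' to [build_knn_graph()] with `k = k_per_batch`.
#'
#' @param nodes N x C matrix.
#' @param batch Vector of batch (plate) labels, length N.
#' @param k_per_batch Neighbours per batch.
#' @param metric Distance metric.
#' @return An undirected [igraph::graph] with N vertices.
#' @export
build_bbknn_graph <- function(nodes, batch, k_per_batch,
                              metric = c("euclidean", "cosine", "pearson")) {
  metric <- match.arg(metric)
  nodes <- as.matrix(nodes)
  n <- nrow(nodes)
  stopifnot(length(batch) == n)
  D <- pairwise_dissimilarity(nodes, metric)
  el <- NULL
  for (b in sort(unique(as.character(batch)))) {
    members <- which(as.character(batch) == b)
    kb <- k_per_batch
    if (length(members) <= kb) {
      if (length(members) < k_per_batch + 1L) {
        warning("batch ", b, " has fewer than k_per_batch + 1 nodes; using all")
      }
    }
    for (i in seq_len(n)) {
      cand <- members[members != i]
      if (!length(cand)) next
      ord <- cand[order(D[i, cand], cand)]
      nn <- ord[seq_len(min(kb, length(ord)))]
      el <- rbind(el, cbind(i, nn))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::simplify(g)
}

#' Leiden community detection over a node graph
#'
#' Runs the Leiden algorithm with the modularity objective at the given
#' resolution; deterministic given `seed`. Cluster labels are compacted to
#' `0 .. n_clusters - 1`.
#'
#' @param graph An undirected [igraph::graph].
#' @param resolution Modularity resolution parameter.
#' @param iterations Maximum Leiden iterations.
#' @param seed RNG seed.
#' @param batch_mode Provenance marker stored in the model (`"none"` or
#'   `"balanced"`).
#' @return An object of class `pp_cluster_model`: `node_labels` (0-based
#'   integer vector, one per vertex), `n_clusters`, and the configuration.
#' @export
leiden_cluster <- function(graph, resolution = 1, iterations = 10L, seed = 1L,
                           batch_mode = "none") {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  args <- list(graph, objective_function = "modularity",
               n_iterations = as.integer(iterations))
  nm <- names(formals(igraph::cluster_leiden))
  if ("resolution" %in% nm) {
    args$resolution <- resolution
  } else {
    args$resolution_parameter <- resolution
  }
  comm <- with_seed(seed, do.call(igraph::cluster_leiden, args))
  memb <- igraph::membership(comm)
  labels <- as.integer(factor(memb, levels = sort(unique(memb)))) - 1L
  structure(
    list(node_labels = labels, n_clusters = max(labels) + 1L,
         resolution = resolution, iterations = as.integer(iterations),
         seed = seed, batch_mode = batch_mode),
    class = "pp_cluster_model"
  )
}

#' @export
print.pp_cluster_model <- function(x, ...) {
  cat("Cluster model: ", length(x$node_labels), " nodes -> ", x$n_clusters,
      " clusters (resolution ", x$resolution, ")\n", sep = "")
  invisible(x)
}

#' Label every pixel of an image with its co-expression cluster
#'
#' Channels are matched to the SOM by name (an error is raised on a name
#' mismatch, not silently by position). Preprocessed pixel vectors are
#' assigned to their best-matching SOM node and inherit the node's cluster
#' label; masked-out pixels receive `-1`.
#'
#' @param image A preprocessed [multiplex_image()] (values in \[0, 1\]).
#' @param som A `pp_som`.
#' @param model A `pp_cluster_model` over the SOM's nodes.
#' @param mask Optional H x W logical matrix overriding `image$mask`
#'   (`TRUE` = analyse).
#' @return A [cluster_image()].
#' @export
label_pixels <- function(image, som, model, mask = NULL) {
  stopifnot(inherits(image, "pp_image"))
  if (is.null(mask)) mask <- image$mask
  idx <- match(som$channels, image$channels$name)
  if (anyNA(idx)) {
    stop("image lacks channel(s) required by the SOM: ",
         paste(som$channels[is.na(idx)], collapse = ", "))
  }
  d <- dim(image$data)
  labels <- matrix(-1L, d[1], d[2])
  sel <- if (is.null(mask)) rep(TRUE, d[1] * d[2]) else as.vector(mask)
  if (any(sel)) {
    X <- matrix(NA_real_, sum(sel), length(idx))
    for (j in seq_along(idx)) {
      plane <- image$data[, , idx[j]]
      X[, j] <- plane[sel]
    }
    nodes <- assign_to_nodes(X, som)
    labels[sel] <- model$node_labels[nodes]
  }
  cluster_image(labels, fov_id = image$fov_id, n_clusters = model$n_clusters)
}

#' Retain clusters that occupy a minimum share of foreground pixels
#'
#' Clusters at or below the frequency threshold are not deleted, only
#' flagged for expert review.
#'
#' @param frequencies Numeric vector of per-cluster foreground frequencies
#'   (fractions summing to 1); names default to cluster ids `0 .. K-1`.
#' @param min_frequency Retention threshold (default 0.001, i.e. >0.1%).
#' @return List with integer cluster ids `retained` and `flagged`.
#' @export
filter_foreground_clusters <- function(frequencies, min_frequency = 0.001) {
  ids <- names(frequencies) %||% as.character(seq_along(frequencies) - 1L)
  keep <- frequencies > min_frequency
  list(retained = as.integer(ids[keep]), flagged = as.integer(ids[!keep]))
}
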