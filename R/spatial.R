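# Queen-neighbourhood join counts between pixel clusters and condition-level
# vicinity graphs.

#' Join counts of neighbouring clusters in a label image
#'
#' For every unmasked pixel, the up-to-eight in-bounds unmasked neighbours
#' at Chebyshev distance 1 (first-order queen neighbourhood) are counted
#' into a directed K x K matrix (row = focal cluster, column = neighbour
#' cluster). Since the queen neighbourhood is symmetric, the raw matrix is
#' symmetric. Masked (`-1`) pixels are skipped entirely — neither focal nor
#' neighbour. Border pixels use only in-bounds neighbours.
#'
#' @param x A [cluster_image()] or an integer label matrix with `-1` for
#'   masked pixels.
#' @param n_clusters Number of clusters K.
#' @return K x K integer matrix of raw join counts.
#' @export
vicinity_composition <- function(x, n_clusters = NULL) {
  if (inherits(x, "pp_cluster_image")) {
    if (is.null(n_clusters)) n_clusters <- x$n_clusters
    x <- x$labels
  }
  if (is.null(n_clusters)) n_clusters <- max(x, -1L) + 1L
  storage.mode(x) <- "integer"
  m <- cpp_vicinity_composition(x, as.integer(n_clusters))
  dimnames(m) <- list(paste0("c", seq_len(n_clusters) - 1L),
                      paste0("c", seq_len(n_clusters) - 1L))
  m
}

#' Aggregate join-count matrices into a vicinity graph
#'
#' Raw matrices (typically one per FOV of a condition) are summed
#' elementwise; self-connections (the diagonal) are discarded and the
#' remaining counts normalized to \[0, 1\] by the global off-diagonal
#' maximum. Row-relative neighbourhood shares (used by the display
#' threshold) are kept alongside.
#'
#' @param matrices List of K x K raw count matrices (or a single matrix).
#' @param drop_self Zero the diagonal before normalization (default TRUE).
#' @param condition Condition label carried on the graph.
#' @param edge_display_threshold Default minimum row-relative share for
#'   display edges (default 0.075).
#' @return Object of class `pp_vicinity` with `raw` (summed counts, with
#'   diagonal), `normalized` (diagonal zeroed, global max 1) and `shares`
#'   (row-stochastic off-diagonal shares).
#' @export
aggregate_and_normalize <- function(matrices, drop_self = TRUE,
                                    condition = NA_character_,
                                    edge_display_threshold = 0.075) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  K <- nrow(matrices[[1]])
  for (m in matrices) stopifnot(all(dim(m) == c(K, K)))
  raw <- Reduce(`+`, lapply(matrices, function(m) {
    storage.mode(m) <- "numeric"
    m
  }))
  off <- raw
  if (drop_self) diag(off) <- 0
  mx <- max(off)
  if (mx <= 0) stop("no off-diagonal (heterophilic) adjacencies to normalize")
  normalized <- off / mx
  rs <- rowSums(off)
  shares <- off / ifelse(rs > 0, rs, 1)
  structure(
    list(raw = raw, normalized = normalized, shares = shares,
         condition = condition,
         edge_display_threshold = edge_display_threshold),
    class = "pp_vicinity"
  )
}

#' @export
print.pp_vicinity <- function(x, ...) {
  cat("Vicinity graph (", nrow(x$raw), " clusters, condition ",
      x$condition, ")\n", sep = "")
  invisible(x)
}

#' Build the directed display graph of a vicinity structure
#'
#' Edge `i -> j` is included iff cluster `j` makes up at least `min_edge`
#' of cluster `i`'s off-diagonal neighbourhood (row-relative share). Edges
#' carry both the share and the globally normalized weight.
#'
#' @param graph A `pp_vicinity`.
#' @param min_edge Minimum neighbourhood share (default: the graph's
#'   display threshold, 0.075).
#' @return A directed [igraph::graph] whose vertices are clusters.
#' @export
build_display_graph <- function(graph, min_edge = graph$edge_display_threshold) {
  K <- nrow(graph$normalized)
  ids <- rownames(graph$normalized) %||% paste0("c", seq_len(K) - 1L)
  keep <- which(graph$shares >= min_edge & graph$shares > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = K, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(keep)) {
    g <- igraph::add_edges(g, t(keep))
    g <- igraph::set_edge_attr(g, "share", value = graph$shares[keep])
    g <- igraph::set_edge_attr(g, "weight", value = graph$normalized[keep])
  }
  g
}

#' Write a display graph to GraphML
#'
#' @param g An [igraph::graph] (e.g. from [build_display_graph()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_display_graph <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
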