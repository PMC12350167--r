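# Batch self-organizing map over pixel channel vectors. The SOM compresses
# millions of pixels to a small lattice of prototype vectors ahead of graph
# clustering; nodes are indexed row-major on the lattice, 1-based.

som_metrics <- c("euclidean", "cosine", "pearson")

# pre-transform rows for the dot-product BMU used by cosine / pearson
metric_rows <- function(X, metric) {
  if (metric == "pearson") X <- X - rowMeans(X)
  if (metric != "euclidean") {
    nrm <- sqrt(rowSums(X^2))
    nz <- nrm > 0
    X[nz, ] <- X[nz, , drop = FALSE] / nrm[nz]
  }
  X
}

#' Train a batch self-organizing map
#'
#' Standard batch SOM: each iteration assigns every point to its
#' best-matching node under the chosen metric, then moves each node toward
#' the Gaussian-lattice-neighbourhood-weighted mean of its assigned points.
#' The neighbourhood sigma decays exponentially from its initial to final
#' value across iterations; in the batch formulation this annealing plays
#' the role the learning rate plays in online training, so the default
#' update is the classic full-replacement rule (`lr_init = lr_final = 1`).
#' Setting a learning-rate schedule below 1 blends each node toward its
#' batch target instead (damped update). Node weights are initialized from
#' randomly drawn data rows; training itself is deterministic.
#'
#' @param data N x C matrix in \[0, 1\], columns named by marker.
#' @param grid_side Lattice side length G (G^2 nodes).
#' @param metric `"euclidean"`, `"cosine"` or `"pearson"` (1 - correlation
#'   on mean-centred vectors).
#' @param iterations Number of batch iterations (default 50).
#' @param lr_init,lr_final Optional damping schedule (defaults 1, i.e.
#'   undamped batch updates).
#' @param sigma_init,sigma_final Neighbourhood sigma schedule in lattice
#'   units (defaults `grid_side / 2` and 1e-3).
#' @param seed Seed for weight initialization.
#' @return An object of class `pp_som` with fields `weights` (G^2 x C),
#'   `grid_side`, `metric`, `channels` and the training configuration.
#' @export
train_som <- function(data, grid_side, metric = c("euclidean", "cosine", "pearson"),
                      iterations = 50L, lr_init = 1, lr_final = 1,
                      sigma_init = grid_side / 2, sigma_final = 1e-3,
                      seed = 1L) {
  metric <- match.arg(metric)
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("non-finite values in SOM training data")
  M <- as.integer(grid_side)^2
  if (nrow(data) < M / 10) {
    warning("fewer than grid_side^2 / 10 training points; SOM may be underdetermined")
  }
  W0 <- with_seed(seed, {
    data[sample.int(nrow(data), M, replace = nrow(data) < M), , drop = FALSE]
  })
  W <- if (iterations > 0L) {
    cpp_som_train(data, W0, as.integer(grid_side), as.integer(iterations),
                  lr_init, lr_final, sigma_init, sigma_final,
                  match(metric, som_metrics) - 1L)
  } else {
    W0
  }
  colnames(W) <- colnames(data)
  structure(
    list(weights = W, grid_side = as.integer(grid_side), metric = metric,
         channels = colnames(data),
         training = list(iterations = as.integer(iterations),
                         lr_init = lr_init, lr_final = lr_final,
                         sigma_init = sigma_init, sigma_final = sigma_final,
                         seed = seed)),
    class = "pp_som"
  )
}

#' @export
print.pp_som <- function(x, ...) {
  cat("Self-organizing map: ", x$grid_side, "x", x$grid_side, " nodes, ",
      length(x$channels), " channels, metric ", x$metric, "\n", sep = "")
  invisible(x)
}

#' Assign points to their best-matching SOM nodes
#'
#' Each row is assigned to the node minimizing the model's distance metric
#' (maximal similarity for cosine/Pearson); ties resolve to the lowest node
#' index.
#'
#' @param pixels M x C matrix with the SOM's channel count.
#' @param som A `pp_som`.
#' @return Integer vector of 1-based node indices.
#' @export
assign_to_nodes <- function(pixels, som) {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != ncol(som$weights)) {
    stop("channel count mismatch: data has ", ncol(pixels),
         ", model expects ", ncol(som$weights))
  }
  metric <- som$metric
  if (metric == "euclidean") {
    idx <- cpp_bmu(pixels, som$weights, 0L)
  } else {
    idx <- cpp_bmu(metric_rows(pixels, metric),
                   metric_rows(som$weights, metric), 1L)
  }
  as.integer(idx) + 1L
}

#' Mean quantization error of a SOM
#'
#' Mean Euclidean distance between each point and its best-matching node; a
#' monitoring metric for training progress.
#'
#' @param data N x C matrix.
#' @param som A `pp_som`.
#' @return Scalar mean quantization error.
#' @export
quantization_error <- function(data, som) {
  data <- as.matrix(data)
  bmu <- assign_to_nodes(data, som) - 1L
  mean(cpp_quantization_error(data, som$weights, bmu))
}
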