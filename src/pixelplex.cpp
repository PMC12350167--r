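#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Best-matching unit search. X: N x C data, W: M x C node weights.
// mode 0: minimal squared Euclidean distance; mode 1: maximal dot product
// (rows are pre-normalized in R for cosine / Pearson metrics).
// Ties resolve to the lowest node index. Returns 0-based indices.
// [[Rcpp::export]]
arma::uvec cpp_bmu(const arma::mat& X, const arma::mat& W, const int mode) {
  const arma::uword n = X.n_rows;
  const arma::uword chunk = 8192;
  arma::uvec out(n);
  arma::vec w2 = arma::sum(arma::square(W), 1);
  for (arma::uword start = 0; start < n; start += chunk) {
    arma::uword end = std::min(start + chunk, n) - 1;
    arma::mat D = X.rows(start, end) * W.t(); // n_c x M dot products
    if (mode == 0) {
      D.each_row() -= 0.5 * w2.t(); // argmin ||x-w||^2 == argmax x.w - |w|^2/2
    }
    for (arma::uword i = 0; i < D.n_rows; ++i) {
      out(start + i) = D.row(i).index_max();
    }
  }
  return out;
}

// Squared Euclidean quantization error of each point to its BMU.
// [[Rcpp::export]]
arma::vec cpp_quantization_error(const arma::mat& X, const arma::mat& W,
                                 const arma::uvec& bmu) {
  arma::vec out(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    arma::rowvec d = X.row(i) - W.row(bmu(i));
    out(i) = std::sqrt(arma::dot(d, d));
  }
  return out;
}

static arma::mat lattice_kernel(const int g, const double sigma) {
  // 1D Gaussian kernel over lattice coordinates, g x g matrix.
  arma::mat K(g, g);
  const double s2 = 2.0 * sigma * sigma;
  for (int i = 0; i < g; ++i) {
    for (int j = 0; j < g; ++j) {
      const double d = static_cast<double>(i - j);
      K(i, j) = std::exp(-(d * d) / s2);
    }
  }
  return K;
}

// Batch self-organizing map training.
// X: N x C in [0, 1]; W0: (G*G) x C initial weights, node index = row-major
// (node = r * G + c on the lattice). metric 0 = Euclidean, 1 = cosine,
// 2 = Pearson. Learning rate and neighbourhood sigma decay exponentially
// from their initial to final values across iterations. Deterministic.
// [[Rcpp::export]]
arma::mat cpp_som_train(const arma::mat& X, const arma::mat& W0, const int grid_side,
                        const int iterations, const double lr_init, const double lr_final,
                        const double sigma_init, const double sigma_final,
                        const int metric) {
  arma::mat W = W0;
  const int g = grid_side;
  const arma::uword M = W.n_rows, C = W.n_cols;
  arma::mat Xm = X;
  if (metric == 2) { // Pearson: centre rows once
    for (arma::uword i = 0; i < Xm.n_rows; ++i) Xm.row(i) -= arma::mean(Xm.row(i));
  }
  arma::mat Xn = Xm;
  if (metric != 0) { // row-normalize for dot-product BMU
    for (arma::uword i = 0; i < Xn.n_rows; ++i) {
      double nrm = arma::norm(Xn.row(i));
      if (nrm > 0) Xn.row(i) /= nrm;
    }
  }
  const int denom = std::max(iterations - 1, 1);
  for (int t = 0; t < iterations; ++t) {
    const double frac = static_cast<double>(t) / denom;
    const double lr = lr_init * std::pow(lr_final / lr_init, frac);
    const double sigma = sigma_init * std::pow(sigma_final / sigma_init, frac);
    // BMU assignment under the chosen metric
    arma::mat Wq = W;
    if (metric == 2) {
      for (arma::uword j = 0; j < M; ++j) Wq.row(j) -= arma::mean(Wq.row(j));
    }
    if (metric != 0) {
      for (arma::uword j = 0; j < M; ++j) {
        double nrm = arma::norm(Wq.row(j));
        if (nrm > 0) Wq.row(j) /= nrm;
      }
    }
    arma::uvec bmu = cpp_bmu(metric == 0 ? X : Xn, Wq, metric == 0 ? 0 : 1);
    // per-node sums and counts (updates always use raw data X)
    arma::mat S(M, C, arma::fill::zeros);
    arma::vec cnt(M, arma::fill::zeros);
    for (arma::uword i = 0; i < X.n_rows; ++i) {
      S.row(bmu(i)) += X.row(i);
      cnt(bmu(i)) += 1.0;
    }
    // neighbourhood smoothing, separable over the lattice axes
    arma::mat K = lattice_kernel(g, sigma);
    arma::mat num(M, C);
    // node index is row-major on the lattice (node = r * g + c); arma
    // reshapes column-major, giving a transposed grid. K is symmetric and
    // applied on both axes, so K * grid * K smooths correctly either way.
    for (arma::uword ch = 0; ch < C; ++ch) {
      arma::mat Sg(S.colptr(ch), g, g, false); // (lattice col, lattice row)
      arma::mat sm = K * Sg * K;               // smooth both axes
      num.col(ch) = arma::vectorise(sm);
    }
    arma::mat cg(cnt.memptr(), g, g, false);
    arma::mat den_g = K * cg * K;
    arma::vec den = arma::vectorise(den_g);
    for (arma::uword j = 0; j < M; ++j) {
      if (den(j) > 1e-12) {
        W.row(j) += lr * (num.row(j) / den(j) - W.row(j));
      }
    }
  }
  return W;
}

// 8-connectivity connected component labelling of a logical matrix.
// Returns integer labels (0 = background, components numbered from 1).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r0, c0));
      lab(r0, c0) = next;
      while (!stack.empty()) {
        const int r = stack.back().first, c = stack.back().second;
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Queen-neighbourhood (Chebyshev distance 1) join counts on a label image.
// labels: H x W integers, -1 = masked. K: number of clusters. Returns K x K
// directed counts; row = focal cluster, column = neighbouring cluster.
// [[Rcpp::export]]
IntegerMatrix cpp_vicinity_composition(const IntegerMatrix& labels, const int K) {
  const int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix out(K, K);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int li = labels(r, c);
      if (li < 0) continue;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          const int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          const int lj = labels(rr, cc);
          if (lj < 0) continue;
          out(li, lj) += 1;
        }
      }
    }
  }
  return out;
}
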