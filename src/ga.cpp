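// Fitness kernel and genetic-algorithm search for gene-set selection.
//
// A candidate gene set S of size N is scored by fitting, for every
// stress independently, the linear model dg = X_S' alpha + beta by
// minimum-norm least squares on the training strains and taking the
// pooled Pearson correlation between fitted and observed growth changes
// over all training cells.  Because the per-stress design matrix is
// shared (same training strains, same genes), one thin SVD per set
// suffices: fitted values are the orthogonal projection U_r U_r' Y.
// Missing growth cells are handled by a per-stress fallback path.

#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

static const double NEG_FITNESS = -std::numeric_limits<double>::infinity();

// Pooled Pearson correlation over non-missing cells of F vs Y.
static double pooled_cor(const arma::mat& F, const arma::mat& Y) {
  arma::uvec ok = arma::find_finite(Y);
  if (ok.n_elem < 3) return NEG_FITNESS;
  arma::vec f = F.elem(ok), y = Y.elem(ok);
  double mf = arma::mean(f), my = arma::mean(y);
  f -= mf; y -= my;
  double vf = arma::dot(f, f), vy = arma::dot(y, y);
  if (vf <= 0.0 || vy <= 0.0) return NEG_FITNESS;
  return arma::dot(f, y) / std::sqrt(vf * vy);
}

// Projection of the columns of Y onto the column space of A (min-norm
// least-squares fitted values), rank-truncated as in base R's svd path.
static arma::mat project_fit(const arma::mat& A, const arma::mat& Y) {
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd_econ(U, s, V, A, "left"))
    stop("SVD failed in fitness kernel");
  double tol = std::max(A.n_rows, A.n_cols) *
    std::numeric_limits<double>::epsilon() * (s.n_elem ? s.max() : 0.0);
  arma::uvec keep = arma::find(s > tol);
  if (keep.n_elem == 0) return arma::zeros(Y.n_rows, Y.n_cols);
  arma::mat Ur = U.cols(keep);
  return Ur * (Ur.t() * Y);
}

// Fitness of one gene set (0-based indices into the rows of Xc).
// Xc: candidates x training strains; Y: training strains x stresses.
static double set_fitness(const arma::mat& Xc, const arma::mat& Y,
                          const arma::uvec& set, bool has_na) {
  arma::mat A(Y.n_rows, set.n_elem + 1);
  A.col(0).ones();
  for (arma::uword i = 0; i < set.n_elem; ++i)
    A.col(i + 1) = Xc.row(set[i]).t();
  if (!has_na)
    return pooled_cor(project_fit(A, Y), Y);
  // missing cells: fit each stress on its present rows
  arma::mat F(Y.n_rows, Y.n_cols);
  F.fill(arma::datum::nan);
  for (arma::uword k = 0; k < Y.n_cols; ++k) {
    arma::uvec rows = arma::find_finite(Y.col(k));
    if (rows.n_elem == 0) continue;
    arma::mat Fk = project_fit(A.rows(rows), Y.submat(rows,
                               arma::uvec{k}));
    for (arma::uword r = 0; r < rows.n_elem; ++r)
      F(rows[r], k) = Fk(r, 0);
  }
  arma::mat Ymask = Y;
  return pooled_cor(F, Ymask);
}

// [[Rcpp::export]]
NumericVector fitness_sets_cpp(const arma::mat& Xc, const arma::mat& Y,
                               const IntegerMatrix& sets) {
  bool has_na = Y.has_nan();
  NumericVector out(sets.ncol());
  for (int j = 0; j < sets.ncol(); ++j) {
    arma::uvec set(sets.nrow());
    for (int i = 0; i < sets.nrow(); ++i)
      set[i] = sets(i, j) - 1;
    out[j] = set_fitness(Xc, Y, set, has_na);
  }
  return out;
}

// [[Rcpp::export]]
List ga_search_cpp(const arma::mat& Xc, const arma::mat& Y,
                   int N, int pop_size, int n_elite, int cycles,
                   int seed) {
  const int G = Xc.n_rows;
  if (N > G) stop("gene-set size exceeds candidate pool");
  if (n_elite < 1 || n_elite > pop_size) stop("invalid elite count");
  bool has_na = Y.has_nan();
  std::mt19937 rng(static_cast<unsigned int>(seed));
  auto rint = [&](int n) {  // uniform on 0..n-1
    return static_cast<int>(std::uniform_int_distribution<int>(0, n - 1)(rng));
  };

  // initial population: random N-subsets (partial Fisher-Yates)
  std::vector<std::vector<int>> pop(pop_size);
  std::vector<int> universe(G);
  for (int g = 0; g < G; ++g) universe[g] = g;
  for (int p = 0; p < pop_size; ++p) {
    std::vector<int> u = universe;
    std::vector<int> s(N);
    for (int i = 0; i < N; ++i) {
      int j = i + rint(G - i);
      std::swap(u[i], u[j]);
      s[i] = u[i];
    }
    pop[p] = s;
  }
  std::vector<double> fit(pop_size);
  arma::uvec tmp(N);
  auto eval = [&](const std::vector<int>& s) {
    for (int i = 0; i < N; ++i) tmp[i] = s[i];
    return set_fitness(Xc, Y, tmp, has_na);
  };
  for (int p = 0; p < pop_size; ++p) fit[p] = eval(pop[p]);

  std::vector<int> ord(pop_size);
  NumericVector trace(cycles + 1);
  auto best_of = [&]() {
    int b = 0;
    for (int p = 1; p < pop_size; ++p) if (fit[p] > fit[b]) b = p;
    return b;
  };
  int b = best_of();
  std::vector<int> best_set = pop[b];
  double best_fit = fit[b];
  trace[0] = best_fit;

  std::vector<std::vector<int>> next(pop_size);
  std::vector<double> next_fit(pop_size);
  for (int c = 0; c < cycles; ++c) {
    for (int p = 0; p < pop_size; ++p) ord[p] = p;
    std::partial_sort(ord.begin(), ord.begin() + n_elite, ord.end(),
                      [&](int a, int bb) { return fit[a] > fit[bb]; });
    // elitism: parents carried unchanged
    for (int e = 0; e < n_elite; ++e) {
      next[e] = pop[ord[e]];
      next_fit[e] = fit[ord[e]];
    }
    for (int p = n_elite; p < pop_size; ++p) {
      std::vector<int> s = next[rint(n_elite)];
      if (N < G) {   // N == G: the full pool, nothing to replace
        int drop = rint(N);
        int gene;
        bool member;
        do {
          gene = rint(G);
          member = false;
          for (int i = 0; i < N; ++i)
            if (s[i] == gene) { member = true; break; }
        } while (member);
        s[drop] = gene;
      }
      next[p] = s;
      next_fit[p] = eval(s);
    }
    pop.swap(next);
    fit.swap(next_fit);
    b = best_of();
    if (fit[b] > best_fit) { best_fit = fit[b]; best_set = pop[b]; }
    trace[c + 1] = best_fit;
  }

  IntegerVector best(N);
  for (int i = 0; i < N; ++i) best[i] = best_set[i] + 1;
  return List::create(_["best"] = best, _["fitness"] = best_fit,
                      _["trace"] = trace);
}
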