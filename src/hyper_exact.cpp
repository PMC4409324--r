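#include <Rcpp.h>
#include <cstdint>

// Exact hypergeometric upper tail for small populations.
// Binomials by Pascal's triangle in int64; every C(N, k) with N <= 62
// fits in a signed 64-bit integer (C(62,31) ~ 4.5e17 < 2^63), and the
// tail numerator sums to C(N, n), so sums cannot overflow either.

// [[Rcpp::export]]
double hyper_tail_exact_cpp(int h, int n, int K, int N) {
  if (N > 62 || N < 0 || n < 0 || n > N || K < 0 || K > N ||
      h < 0 || h > n || h > K)
    Rcpp::stop("infeasible or oversized counts for exact enumeration");
  std::vector<std::vector<int64_t>> C(N + 1);
  for (int i = 0; i <= N; ++i) {
    C[i].assign(i + 1, 1);
    for (int j = 1; j < i; ++j) C[i][j] = C[i - 1][j - 1] + C[i - 1][j];
  }
  auto choose = [&](int a, int b) -> int64_t {
    if (b < 0 || b > a) return 0;
    return C[a][b];
  };
  int64_t num = 0;
  int kmax = std::min(n, K);
  for (int k = h; k <= kmax; ++k)
    num += choose(K, k) * choose(N - K, n - k);
  return static_cast<double>(num) / static_cast<double>(choose(N, n));
}

// Exhaustive sweep helper: exact tails for every feasible configuration
// with population size <= n_max, returned alongside the configuration
// columns so a second implementation can be compared against them.

// [[Rcpp::export]]
Rcpp::List hyper_tail_exact_sweep_cpp(int n_max) {
  if (n_max > 62) Rcpp::stop("n_max must be <= 62");
  std::vector<int> hs, ns, Ks, Ns;
  std::vector<double> ps;
  for (int N = 1; N <= n_max; ++N) {
    std::vector<std::vector<int64_t>> C(N + 1);
    for (int i = 0; i <= N; ++i) {
      C[i].assign(i + 1, 1);
      for (int j = 1; j < i; ++j) C[i][j] = C[i - 1][j - 1] + C[i - 1][j];
    }
    auto choose = [&](int a, int b) -> int64_t {
      if (b < 0 || b > a) return 0;
      return C[a][b];
    };
    for (int n = 1; n <= N; ++n) {
      for (int K = 0; K <= N; ++K) {
        int kmax = std::min(n, K);
        int kmin = std::max(0, n + K - N);
        // accumulate the tail from the top so each h needs one addition
        int64_t num = 0;
        std::vector<int64_t> tail(kmax - kmin + 2, 0);
        for (int k = kmax; k >= kmin; --k) {
          num += choose(K, k) * choose(N - K, n - k);
          tail[k - kmin] = num;
        }
        int64_t den = choose(N, n);
        for (int h = kmin; h <= kmax; ++h) {
          hs.push_back(h); ns.push_back(n); Ks.push_back(K); Ns.push_back(N);
          ps.push_back(static_cast<double>(tail[h - kmin]) /
                       static_cast<double>(den));
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("h") = hs, Rcpp::Named("n") = ns,
                            Rcpp::Named("K") = Ks, Rcpp::Named("N") = Ns,
                            Rcpp::Named("p") = ps);
}
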