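#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double THETA_EPS = 1e-12;

// compressed adjacency built from an i<j edge list
struct Adj {
  std::vector<int> ptr;
  std::vector<int> idx;
};

Adj build_adj(const IntegerMatrix& edges, int N) {
  const int E = edges.nrow();
  std::vector<int> deg(N, 0);
  for (int e = 0; e < E; ++e) {
    deg[edges(e, 0)]++;
    deg[edges(e, 1)]++;
  }
  Adj a;
  a.ptr.assign(N + 1, 0);
  for (int i = 0; i < N; ++i) a.ptr[i + 1] = a.ptr[i] + deg[i];
  a.idx.resize(a.ptr[N]);
  std::vector<int> pos(a.ptr.begin(), a.ptr.end() - 1);
  for (int e = 0; e < E; ++e) {
    const int i = edges(e, 0), j = edges(e, 1);
    a.idx[pos[i]++] = j;
    a.idx[pos[j]++] = i;
  }
  return a;
}

inline double clamp_theta(double th) {
  if (th < THETA_EPS) return THETA_EPS;
  if (th > 1.0 - THETA_EPS) return 1.0 - THETA_EPS;
  return th;
}

// E[r,s]: unordered edges between r and s summed over layers (symmetric,
// each unordered pair counted once per layer); P[r,s]: possible pairs,
// L*n_r*n_s off-diagonal, L*n_r*(n_r-1)/2 on the diagonal.
void count_pairs(const std::vector<IntegerMatrix>& em, const std::vector<int>& z,
                 const std::vector<int>& n, int K, int L,
                 std::vector<double>& E, std::vector<double>& P) {
  std::fill(E.begin(), E.end(), 0.0);
  for (int l = 0; l < L; ++l) {
    const IntegerMatrix& ed = em[l];
    const int m = ed.nrow();
    for (int e = 0; e < m; ++e) {
      int r = z[ed(e, 0)], s = z[ed(e, 1)];
      if (r > s) std::swap(r, s);
      E[r + s * K] += 1.0;
    }
  }
  for (int s = 0; s < K; ++s)
    for (int r = 0; r < s; ++r) E[s + r * K] = E[r + s * K];
  for (int s = 0; s < K; ++s)
    for (int r = 0; r < K; ++r)
      P[r + s * K] = (r == s) ? L * (double)n[r] * (n[r] - 1) / 2.0
                              : L * (double)n[r] * n[s];
}

// one systematic-scan sweep of the label full conditionals; each unordered
// pair enters the conditional once per layer
void sweep_z(const std::vector<Adj>& adj, std::vector<int>& z,
             const std::vector<double>& log_pi,
             const std::vector<double>& logt, const std::vector<double>& log1mt,
             std::vector<int>& n, int K) {
  const int N = (int)z.size();
  const int L = (int)adj.size();
  std::vector<double> m(L * K), lp(K);
  for (int i = 0; i < N; ++i) {
    std::fill(m.begin(), m.end(), 0.0);
    for (int l = 0; l < L; ++l)
      for (int p = adj[l].ptr[i]; p < adj[l].ptr[i + 1]; ++p)
        m[l * K + z[adj[l].idx[p]]] += 1.0;
    n[z[i]]--;  // counts now exclude spot i
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double s = log_pi[k];
      for (int l = 0; l < L; ++l) {
        const double* ml = &m[l * K];
        for (int c = 0; c < K; ++c) {
          const double mc = ml[c];
          s += mc * logt[k + c * K] + ((double)n[c] - mc) * log1mt[k + c * K];
        }
      }
      lp[k] = s;
      if (s > mx) mx = s;
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      lp[k] = std::exp(lp[k] - mx);
      tot += lp[k];
    }
    const double u = unif_rand() * tot;
    int k = 0;
    double cum = lp[0];
    while (u > cum && k < K - 1) {
      ++k;
      cum += lp[k];
    }
    z[i] = k;
    n[k]++;
  }
}

// permutation sending each label to its rank of first occurrence; labels
// absent from z fill the remaining slots in ascending original order
void canonical_map(const std::vector<int>& z, int K, std::vector<int>& map) {
  map.assign(K, -1);
  int next = 0;
  for (size_t i = 0; i < z.size() && next < K; ++i)
    if (map[z[i]] < 0) map[z[i]] = next++;
  for (int k = 0; k < K; ++k)
    if (map[k] < 0) map[k] = next++;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_sweep_z(List edge_list, int N, IntegerVector z_cur,
                          NumericVector pi, NumericMatrix theta) {
  const int L = edge_list.size();
  const int K = pi.size();
  std::vector<Adj> adj;
  for (int l = 0; l < L; ++l) {
    IntegerMatrix e = edge_list[l];
    adj.push_back(build_adj(e, N));
  }
  std::vector<int> z(N);
  std::vector<int> n(K, 0);
  for (int i = 0; i < N; ++i) {
    z[i] = z_cur[i] - 1;
    n[z[i]]++;
  }
  std::vector<double> log_pi(K), logt(K * K), log1mt(K * K);
  for (int k = 0; k < K; ++k) log_pi[k] = std::log(std::max((double)pi[k], 1e-300));
  for (int s = 0; s < K; ++s)
    for (int r = 0; r < K; ++r) {
      const double th = clamp_theta(theta(r, s));
      logt[r + s * K] = std::log(th);
      log1mt[r + s * K] = std::log1p(-th);
    }
  sweep_z(adj, z, log_pi, logt, log1mt, n, K);
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = z[i] + 1;
  return out;
}

// Full Gibbs chain: per iteration, draw pi | z, then theta | z, then sweep z,
// evaluate the joint log posterior, and apply the canonical relabeling to
// (z, pi, theta) before storage. RNG call order matches the R-level update
// functions composed in the same sequence.
// [[Rcpp::export]]
List cpp_gibbs_chain(List edge_list, int N, int K, NumericVector alpha,
                     double beta1, double beta2, int n_iter, int burn,
                     IntegerVector z_init, bool verbose) {
  const int L = edge_list.size();
  std::vector<IntegerMatrix> em;
  std::vector<Adj> adj;
  for (int l = 0; l < L; ++l) {
    IntegerMatrix e = edge_list[l];
    em.push_back(e);
    adj.push_back(build_adj(e, N));
  }
  std::vector<int> z(N);
  for (int i = 0; i < N; ++i) z[i] = z_init[i] - 1;
  const int n_keep = n_iter - burn;
  IntegerMatrix z_chain(n_keep, N);
  NumericMatrix pi_chain(n_keep, K), theta_chain(n_keep, K * K);
  NumericVector log_post(n_iter);

  std::vector<double> pi(K), theta(K * K), logt(K * K), log1mt(K * K);
  std::vector<double> log_pi(K), E(K * K), P(K * K), pi2(K), th2(K * K);
  std::vector<int> n(K), map(K);

  double alpha_sum = 0.0, dir_const = 0.0;
  for (int k = 0; k < K; ++k) alpha_sum += alpha[k];
  dir_const = std::lgamma(alpha_sum);
  for (int k = 0; k < K; ++k) dir_const -= std::lgamma(alpha[k]);
  const double lbeta_const = R::lbeta(beta1, beta2);

  for (int it = 0; it < n_iter; ++it) {
    std::fill(n.begin(), n.end(), 0);
    for (int i = 0; i < N; ++i) n[z[i]]++;

    // pi | z  ~  Dirichlet(alpha_k + n_k)
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      pi[k] = R::rgamma(alpha[k] + n[k], 1.0);
      tot += pi[k];
    }
    for (int k = 0; k < K; ++k) pi[k] /= tot;

    // theta_rs | z  ~  Beta(beta1 + E_rs, beta2 + P_rs - E_rs), r <= s
    count_pairs(em, z, n, K, L, E, P);
    for (int s = 0; s < K; ++s)
      for (int r = 0; r <= s; ++r) {
        const int c = r + s * K;
        double th = R::rbeta(beta1 + E[c], beta2 + P[c] - E[c]);
        th = clamp_theta(th);
        theta[c] = theta[s + r * K] = th;
      }
    for (int c = 0; c < K * K; ++c) {
      logt[c] = std::log(theta[c]);
      log1mt[c] = std::log1p(-theta[c]);
    }
    for (int k = 0; k < K; ++k) log_pi[k] = std::log(std::max(pi[k], 1e-300));

    sweep_z(adj, z, log_pi, logt, log1mt, n, K);

    // joint log posterior at the current (z, pi, theta)
    count_pairs(em, z, n, K, L, E, P);
    double lp = dir_const;
    for (int k = 0; k < K; ++k) {
      if (alpha[k] != 1.0) lp += (alpha[k] - 1.0) * log_pi[k];
      lp += (double)n[k] * log_pi[k];
    }
    for (int s = 0; s < K; ++s)
      for (int r = 0; r <= s; ++r) {
        const int c = r + s * K;
        lp += E[c] * logt[c] + (P[c] - E[c]) * log1mt[c];
        lp += (beta1 - 1.0) * logt[c] + (beta2 - 1.0) * log1mt[c] - lbeta_const;
      }
    log_post[it] = lp;

    // canonical projection: first occurrences of labels in increasing order
    canonical_map(z, K, map);
    for (int i = 0; i < N; ++i) z[i] = map[z[i]];
    for (int k = 0; k < K; ++k) pi2[map[k]] = pi[k];
    for (int s = 0; s < K; ++s)
      for (int r = 0; r < K; ++r) th2[map[r] + map[s] * K] = theta[r + s * K];
    pi = pi2;
    theta = th2;

    if (it >= burn) {
      const int t = it - burn;
      for (int i = 0; i < N; ++i) z_chain(t, i) = z[i] + 1;
      for (int k = 0; k < K; ++k) pi_chain(t, k) = pi[k];
      for (int c = 0; c < K * K; ++c) theta_chain(t, c) = theta[c];
    }

    if (verbose && ((it + 1) % 100 == 0)) {
      int occ = 0;
      for (int k = 0; k < K; ++k)
        if (n[k] > 0) ++occ;
      Rcout << "iter " << (it + 1) << " log_post " << lp
            << " occupied " << occ << "\n";
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["z_chain"] = z_chain, _["pi_chain"] = pi_chain,
                      _["theta_chain"] = theta_chain, _["log_post"] = log_post);
}
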