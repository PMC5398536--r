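#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Identity-based sequence weights: w_m = 1 / |{m' : id(m, m') >= x}|,
// identity counted over all L columns (gap symbols compare like any state).
// [[Rcpp::export]]
NumericVector cpp_sequence_weights(const IntegerMatrix& seqs, double x) {
  const int M = seqs.nrow(), L = seqs.ncol();
  std::vector<int> nnb(M, 1); // each sequence matches itself
  const int thr_num = (int)std::ceil(x * L - 1e-9);
  for (int a = 0; a < M; ++a) {
    for (int b = a + 1; b < M; ++b) {
      int same = 0;
      for (int k = 0; k < L; ++k) same += (seqs(a, k) == seqs(b, k));
      if (same >= thr_num) { ++nnb[a]; ++nnb[b]; }
    }
    if (a % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector w(M);
  for (int m = 0; m < M; ++m) w[m] = 1.0 / nnb[m];
  return w;
}

// Weighted, pseudocounted single and pair frequencies.
// States in seqs are 1-based (1..q).  Returns fi (L x q) and fij as a
// flat vector with dim (q, q, L, L); fij[a,b,i,j] for column pair (i,j).
// Diagonal blocks carry f_ii(a,b) = delta(a,b) * f_i(a).
// [[Rcpp::export]]
List cpp_frequencies(const IntegerMatrix& seqs, const NumericVector& w,
                     int q, double lambda) {
  const int M = seqs.nrow(), L = seqs.ncol();
  double meff = 0.0;
  for (int m = 0; m < M; ++m) meff += w[m];
  const double denom = lambda + meff;

  NumericMatrix fi(L, q);
  for (int m = 0; m < M; ++m)
    for (int i = 0; i < L; ++i)
      fi(i, seqs(m, i) - 1) += w[m];
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < q; ++a)
      fi(i, a) = (lambda / q + fi(i, a)) / denom;

  NumericVector fij((R_xlen_t)q * q * L * L); // dim (q, q, L, L) set in R
  double* F = REAL(fij);
  const size_t qq = (size_t)q * q;
  // accumulate weighted pair counts for i < j
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < L; ++i) {
      const int a = seqs(m, i) - 1;
      for (int j = i + 1; j < L; ++j) {
        const int b = seqs(m, j) - 1;
        F[a + q * b + qq * (i + (size_t)L * j)] += w[m];
      }
    }
    if (m % 256 == 0) Rcpp::checkUserInterrupt();
  }
  const double pc = lambda / (double)(q * q);
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      for (int b = 0; b < q; ++b)
        for (int a = 0; a < q; ++a) {
          size_t up = a + q * b + qq * (i + (size_t)L * j);
          double v = (pc + F[up]) / denom;
          F[up] = v;
          F[b + q * a + qq * (j + (size_t)L * i)] = v; // symmetric block
        }
    }
    // diagonal block: f_ii(a,a) = f_i(a)
    for (int a = 0; a < q; ++a)
      F[a + q * a + qq * (i + (size_t)L * i)] = fi(i, a);
  }
  return List::create(_["fi"] = fi, _["fij"] = fij, _["Meff"] = meff);
}

// Gibbs sampler for a pairwise Potts model
// P(s) propto exp( sum_i h_i(s_i) + sum_{planted (i,j)} J_ij * delta(s_i, s_j) ).
// pairs: npair x 2 (1-based site indices); strengths: J per pair.
// Uses R's RNG (unif_rand), so set.seed() on the R side fixes the output.
// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_potts(int L, int q, int M,
                              const IntegerMatrix& pairs,
                              const NumericVector& strengths,
                              const NumericMatrix& h,
                              int burnin_sweeps, int thin_sweeps) {
  // adjacency lists
  std::vector<std::vector<std::pair<int, double> > > nbr(L);
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    nbr[i].push_back(std::make_pair(j, strengths[p]));
    nbr[j].push_back(std::make_pair(i, strengths[p]));
  }
  std::vector<int> s(L);
  for (int i = 0; i < L; ++i) s[i] = (int)(unif_rand() * q);
  std::vector<double> prob(q);
  IntegerMatrix out(M, L);

  auto sweep = [&]() {
    for (int i = 0; i < L; ++i) {
      double z = 0.0;
      for (int a = 0; a < q; ++a) {
        double e = h(i, a);
        for (size_t k = 0; k < nbr[i].size(); ++k)
          if (s[nbr[i][k].first] == a) e += nbr[i][k].second;
        prob[a] = std::exp(e);
        z += prob[a];
      }
      double u = unif_rand() * z, c = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; ++a) { c += prob[a]; if (u <= c) { pick = a; break; } }
      s[i] = pick;
    }
  };

  for (int t = 0; t < burnin_sweeps; ++t) {
    sweep();
    if (t % 512 == 0) Rcpp::checkUserInterrupt();
  }
  for (int m = 0; m < M; ++m) {
    for (int t = 0; t < thin_sweeps; ++t) sweep();
    for (int i = 0; i < L; ++i) out(m, i) = s[i] + 1;
    if (m % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
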