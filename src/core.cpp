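// Hot loops of the GRN evolution model: recurrent development, the
// strong-selection/weak-mutation hill climber, Classify-and-Count epoch
// measurements, and the rate-of-adaptation assay.
//
// All stochastic draws come from R's RNG (unif_rand / norm_rand) so every
// routine is reproducible under set.seed().  Draw order within a generation
// is fixed: (1) environmental noise on the target (kappa > 0 only),
// (2) G point mutation (gene index, then step), (3) B mutation gate and,
// if open, N^2 element steps.

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// one developmental trajectory: P(0) = G, T steps of
//   P <- (1 - tau2) * P + tau1 * tanh(B %*% P)
// writes the NORMALISED adult phenotype (P(T) * tau2/tau1) into out.
static void develop_core(const double* G, const double* B, int N,
                         double tau1, double tau2, int T,
                         double* out, double* work) {
  double* P = out;
  for (int i = 0; i < N; ++i) P[i] = G[i];
  const double keep = 1.0 - tau2;
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) work[i] = 0.0;
    for (int j = 0; j < N; ++j) {          // column-major matvec
      const double pj = P[j];
      if (pj == 0.0) continue;
      const double* col = B + (size_t)j * N;
      for (int i = 0; i < N; ++i) work[i] += col[i] * pj;
    }
    for (int i = 0; i < N; ++i) P[i] = keep * P[i] + tau1 * std::tanh(work[i]);
  }
  const double norm = tau2 / tau1;
  for (int i = 0; i < N; ++i) P[i] *= norm;
}

// [[Rcpp::export]]
NumericMatrix cpp_develop_batch(NumericMatrix Gs, NumericMatrix B,
                                double tau1, double tau2, int T) {
  const int n = Gs.nrow(), N = Gs.ncol();
  if (B.nrow() != N || B.ncol() != N) stop("B must be %d x %d", N, N);
  NumericMatrix out(n, N);
  std::vector<double> g(N), p(N), work(N);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < N; ++i) g[i] = Gs(r, i);
    develop_core(g.data(), B.begin(), N, tau1, tau2, T, p.data(), work.data());
    for (int i = 0; i < N; ++i) out(r, i) = p[i];
  }
  return out;
}

// sign pattern as bit code: bit i set iff trait i >= 0 (tie 0 -> +1)
static inline uint32_t sign_code(const double* P, int N) {
  uint32_t code = 0;
  for (int i = 0; i < N; ++i)
    if (P[i] >= 0.0) code |= (1u << i);
  return code;
}

static inline uint32_t fold_code(uint32_t code, uint32_t mask) {
  // canonical representative has first trait +1 (bit 0 set)
  return (code & 1u) ? code : (code ^ mask);
}

// [[Rcpp::export]]
IntegerVector cpp_sign_codes(NumericMatrix P) {
  const int n = P.nrow(), N = P.ncol();
  if (N > 30) stop("sign codes support at most 30 traits");
  IntegerVector out(n);
  std::vector<double> row(N);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < N; ++i) row[i] = P(r, i);
    out[r] = (int)sign_code(row.data(), N);
  }
  return out;
}

static double conn_cost(const double* B, int N, int norm) {
  if (norm == 0) return 0.0;
  double s = 0.0;
  const size_t n2 = (size_t)N * N;
  if (norm == 1) { for (size_t k = 0; k < n2; ++k) s += std::fabs(B[k]); }
  else           { for (size_t k = 0; k < n2; ++k) s += B[k] * B[k]; }
  return s / (double)n2;
}

struct EpochStats {
  double training_error, test_error, entropy_bits;
  int coverage;
};

// Classify-and-Count over a fixed sample of embryonic states
static EpochStats measure_distribution(
    const NumericMatrix& measG, const double* B, int N,
    double tau1, double tau2, int T,
    const std::vector<uint32_t>& class_folded,
    const std::vector<int>& train_rows, double cov_threshold) {
  const int n = measG.nrow();
  const uint32_t mask = (N >= 32) ? 0xffffffffu : ((1u << N) - 1u);
  std::unordered_map<uint32_t, int> unfolded;
  std::unordered_map<uint32_t, int> folded;
  std::vector<double> g(N), p(N), work(N);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < N; ++i) g[i] = measG(r, i);
    develop_core(g.data(), B, N, tau1, tau2, T, p.data(), work.data());
    uint32_t code = sign_code(p.data(), N);
    ++unfolded[code];
    ++folded[fold_code(code, mask)];
  }
  EpochStats st;
  st.entropy_bits = 0.0;
  for (auto& kv : unfolded) {
    double f = (double)kv.second / n;
    st.entropy_bits -= f * std::log2(f);
  }
  // chi-squared against uniform expectation over the respective set;
  // observed frequencies are NOT renormalised over the set
  const int n_class = (int)class_folded.size();
  const double E_test = 1.0 / n_class;
  st.test_error = 0.0;
  st.coverage = 0;
  std::vector<double> class_freq(n_class, 0.0);
  for (int k = 0; k < n_class; ++k) {
    auto it = folded.find(class_folded[k]);
    double O = (it == folded.end()) ? 0.0 : (double)it->second / n;
    class_freq[k] = O;
    st.test_error += (O - E_test) * (O - E_test) / E_test;
    if (O >= cov_threshold) ++st.coverage;
  }
  const int n_train = (int)train_rows.size();
  const double E_train = 1.0 / n_train;
  st.training_error = 0.0;
  for (int k = 0; k < n_train; ++k) {
    double O = class_freq[train_rows[k]];
    st.training_error += (O - E_train) * (O - E_train) / E_train;
  }
  return st;
}

// [[Rcpp::export]]
List cpp_run_evolution(
    NumericVector G0, NumericMatrix B0,
    IntegerMatrix targets,      // N_T x N rows of +/-1
    IntegerVector block_idx,    // 0-based target row per K-block
    int K, double total_gens_d,
    double lam, int cost_norm,  // 0 none, 1 L1, 2 L2
    double kappa,
    double g_step, double b_prob, double b_step,
    double tau1, double tau2, int T,
    NumericMatrix measG,        // embryonic sample for epoch measurement
    IntegerMatrix class_mat,    // full class, n_class x N rows of +/-1
    IntegerVector train_rows0,  // 0-based class rows forming the training set
    double cov_threshold,
    int cadence_gens,           // measure every this many generations
    int snapshot_every,         // in cadence units; 0 = none
    int noise_independent) {    // 1: parent and mutant see separate draws
  const int N = G0.size();
  const long long total_gens = (long long)total_gens_d;
  if (B0.nrow() != N || B0.ncol() != N) stop("B0 must be N x N");
  if (targets.ncol() != N || class_mat.ncol() != N)
    stop("target/class width must equal N");
  if (N > 30) stop("at most 30 traits supported");
  const uint32_t mask = (1u << N) - 1u;

  std::vector<double> G(G0.begin(), G0.end());
  std::vector<double> B(B0.begin(), B0.end());
  std::vector<double> Gm(N), Bm((size_t)N * N);
  std::vector<double> Pn(N), Pm(N), work(N), Seff(N), Seff2(N);
  std::vector<uint32_t> class_folded(class_mat.nrow());
  for (int k = 0; k < class_mat.nrow(); ++k) {
    uint32_t code = 0;
    for (int i = 0; i < N; ++i) if (class_mat(k, i) > 0) code |= (1u << i);
    class_folded[k] = fold_code(code, mask);
  }
  std::vector<int> train_rows(train_rows0.begin(), train_rows0.end());

  develop_core(G.data(), B.data(), N, tau1, tau2, T, Pn.data(), work.data());
  double cost_par = conn_cost(B.data(), N, cost_norm);

  const int n_rec = (cadence_gens > 0) ? (int)(total_gens / cadence_gens) : 0;
  NumericVector rec_train(n_rec), rec_test(n_rec), rec_entropy(n_rec),
      rec_benefit(n_rec);
  IntegerVector rec_cov(n_rec), rec_gen(n_rec);
  List snapshots;
  double benefit_acc = 0.0;
  long long benefit_n = 0;
  int rec_i = 0;
  long long accepted_b_mut = 0;

  for (long long g = 0; g < total_gens; ++g) {
    const long long block = g / K;
    const int srow = block_idx[(R_xlen_t)block];
    // effective (possibly noisy) target for this generation
    double dot_par = 0.0, dot_par_clean = 0.0;
    if (kappa > 0.0) {
      for (int i = 0; i < N; ++i)
        Seff[i] = (double)targets(srow, i) + kappa * norm_rand();
      if (noise_independent) {
        for (int i = 0; i < N; ++i)
          Seff2[i] = (double)targets(srow, i) + kappa * norm_rand();
      } else {
        Seff2 = Seff;
      }
    } else {
      for (int i = 0; i < N; ++i) Seff[i] = (double)targets(srow, i);
      Seff2 = Seff;
    }
    for (int i = 0; i < N; ++i) {
      dot_par += Pn[i] * Seff[i];
      dot_par_clean += Pn[i] * (double)targets(srow, i);
    }
    const double fit_par = 0.5 * (1.0 + dot_par / N) - lam * cost_par;

    // mutant: always a single-gene G mutation, clamped to [-1, 1]
    for (int i = 0; i < N; ++i) Gm[i] = G[i];
    int gene = (int)(unif_rand() * N);
    if (gene >= N) gene = N - 1;
    double u = (2.0 * unif_rand() - 1.0) * g_step;
    double gi = Gm[gene] + u;
    Gm[gene] = (gi > 1.0) ? 1.0 : ((gi < -1.0) ? -1.0 : gi);
    // B mutation with probability b_prob: every element perturbed
    const bool bmut = (unif_rand() < b_prob);
    double cost_mut = cost_par;
    const double* Bmut = B.data();
    if (bmut) {
      const size_t n2 = (size_t)N * N;
      for (size_t k = 0; k < n2; ++k)
        Bm[k] = B[k] + (2.0 * unif_rand() - 1.0) * b_step;
      Bmut = Bm.data();
      cost_mut = conn_cost(Bmut, N, cost_norm);
    }
    develop_core(Gm.data(), Bmut, N, tau1, tau2, T, Pm.data(), work.data());
    double dot_mut = 0.0;
    for (int i = 0; i < N; ++i) dot_mut += Pm[i] * Seff2[i];
    const double fit_mut = 0.5 * (1.0 + dot_mut / N) - lam * cost_mut;

    if (fit_mut > fit_par) {  // strict improvement; ties are rejected
      std::swap(G, Gm);
      if (bmut) { std::swap(B, Bm); ++accepted_b_mut; }
      std::swap(Pn, Pm);
      cost_par = cost_mut;
      dot_par_clean = 0.0;
      for (int i = 0; i < N; ++i)
        dot_par_clean += Pn[i] * (double)targets(srow, i);
    }
    benefit_acc += 0.5 * (1.0 + dot_par_clean / N);
    ++benefit_n;

    if (cadence_gens > 0 && ((g + 1) % cadence_gens == 0)) {
      EpochStats st = measure_distribution(measG, B.data(), N, tau1, tau2, T,
                                           class_folded, train_rows,
                                           cov_threshold);
      rec_gen[rec_i] = (int)(g + 1);
      rec_train[rec_i] = st.training_error;
      rec_test[rec_i] = st.test_error;
      rec_entropy[rec_i] = st.entropy_bits;
      rec_cov[rec_i] = st.coverage;
      rec_benefit[rec_i] = benefit_acc / benefit_n;
      benefit_acc = 0.0; benefit_n = 0;
      if (snapshot_every > 0 && ((rec_i + 1) % snapshot_every == 0)) {
        NumericMatrix snap(N, N);
        std::copy(B.begin(), B.end(), snap.begin());
        snapshots.push_back(snap);
      }
      ++rec_i;
    }
    if ((g & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector Gout(G.begin(), G.end());
  NumericMatrix Bout(N, N);
  std::copy(B.begin(), B.end(), Bout.begin());
  return List::create(
      _["generation"] = rec_gen, _["training_error"] = rec_train,
      _["test_error"] = rec_test, _["entropy_bits"] = rec_entropy,
      _["class_coverage"] = rec_cov, _["mean_benefit"] = rec_benefit,
      _["G"] = Gout, _["B"] = Bout, _["snapshots"] = snapshots,
      _["accepted_b_mutations"] = (double)accepted_b_mut);
}

// [[Rcpp::export]]
int cpp_time_to_target(NumericMatrix Bmat, IntegerVector S,
                       double tau1, double tau2, int T,
                       double g_step, int max_gen, NumericVector G0,
                       double benefit_threshold) {
  const int N = S.size();
  if (Bmat.nrow() != N || Bmat.ncol() != N) stop("B must be N x N");
  std::vector<double> G(N), Pn(N), Pm(N), work(N);
  if (G0.size() == N) {
    for (int i = 0; i < N; ++i) G[i] = G0[i];
  } else {
    for (int i = 0; i < N; ++i) G[i] = 2.0 * unif_rand() - 1.0;
  }
  const double* B = Bmat.begin();
  develop_core(G.data(), B, N, tau1, tau2, T, Pn.data(), work.data());
  uint32_t target = 0;
  for (int i = 0; i < N; ++i) if (S[i] > 0) target |= (1u << i);
  double dot_par = 0.0;
  for (int i = 0; i < N; ++i) dot_par += Pn[i] * (double)S[i];
  // success test: discrete sign-pattern match (default), or benefit
  // reaching a threshold when benefit_threshold > 0
  const bool use_benefit = (benefit_threshold > 0.0);
  if (use_benefit) {
    if (0.5 * (1.0 + dot_par / N) >= benefit_threshold) return 1;
  } else {
    if (sign_code(Pn.data(), N) == target) return 1;
  }
  for (int gen = 2; gen <= max_gen; ++gen) {
    int gene = (int)(unif_rand() * N);
    if (gene >= N) gene = N - 1;
    double u = (2.0 * unif_rand() - 1.0) * g_step;
    double old = G[gene];
    double gi = old + u;
    G[gene] = (gi > 1.0) ? 1.0 : ((gi < -1.0) ? -1.0 : gi);
    develop_core(G.data(), B, N, tau1, tau2, T, Pm.data(), work.data());
    double dot_mut = 0.0;
    for (int i = 0; i < N; ++i) dot_mut += Pm[i] * (double)S[i];
    if (dot_mut > dot_par) {  // benefit-only fitness, B frozen
      dot_par = dot_mut;
      std::swap(Pn, Pm);
      if (use_benefit) {
        if (0.5 * (1.0 + dot_par / N) >= benefit_threshold) return gen;
      } else {
        if (sign_code(Pn.data(), N) == target) return gen;
      }
    } else {
      G[gene] = old;
    }
  }
  return max_gen;
}
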