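#include <Rcpp.h>
using namespace Rcpp;

// Flat-array scaled forward pass; alpha (T x S, row-major) and scale c are
// optional outputs.  Returns the sequence log-likelihood.
static double forward_flat(const double* pi, const double* A,
                           const double* B, int S, int V,
                           const int* obs, int T, double* alpha,
                           double* cvec) {
  std::vector<double> abuf;
  double* a;
  if (alpha) a = alpha;
  else { abuf.resize((size_t)T * S); a = abuf.data(); }
  double logL = 0.0;
  for (int t = 0; t < T; ++t) {
    double* at = a + (size_t)t * S;
    const int o = obs[t];
    if (t == 0) {
      for (int i = 0; i < S; ++i) at[i] = pi[i] * B[i * V + o];
    } else {
      const double* ap = a + (size_t)(t - 1) * S;
      for (int j = 0; j < S; ++j) {
        double s = 0.0;
        for (int i = 0; i < S; ++i) s += ap[i] * A[i * S + j];
        at[j] = s * B[j * V + o];
      }
    }
    double c = 0.0;
    for (int i = 0; i < S; ++i) c += at[i];
    if (c <= 0.0)
      stop("observation sequence has zero probability under the model (t=%d)",
           t + 1);
    const double inv = 1.0 / c;
    for (int i = 0; i < S; ++i) at[i] *= inv;
    logL += std::log(c);
    if (cvec) cvec[t] = c;
  }
  return logL;
}

// copy an R model into row-major flat arrays
static void flatten(const NumericVector& pi, const NumericMatrix& A,
                    const NumericMatrix& B, std::vector<double>& pf,
                    std::vector<double>& Af, std::vector<double>& Bf) {
  const int S = pi.size(), V = B.ncol();
  pf.assign(pi.begin(), pi.end());
  Af.resize((size_t)S * S);
  Bf.resize((size_t)S * V);
  for (int i = 0; i < S; ++i) {
    for (int j = 0; j < S; ++j) Af[i * S + j] = A(i, j);
    for (int v = 0; v < V; ++v) Bf[i * V + v] = B(i, v);
  }
}

// [[Rcpp::export]]
double hmm_loglik_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
                      List seqs) {
  const int S = pi.size(), V = B.ncol();
  std::vector<double> pf, Af, Bf;
  flatten(pi, A, B, pf, Af, Bf);
  double logL = 0.0;
  for (int s = 0; s < seqs.size(); ++s) {
    IntegerVector obs = seqs[s];
    if (obs.size() == 0) continue;
    logL += forward_flat(pf.data(), Af.data(), Bf.data(), S, V,
                         INTEGER(obs), obs.size(), nullptr, nullptr);
  }
  return logL;
}

// One full Baum-Welch fit over a list of 0-based symbol sequences.
// Returns updated pi/A/B, the per-iteration log-likelihood trace (each
// entry is the log-likelihood of the model *entering* that iteration), and
// the log-likelihood of the returned model.
// [[Rcpp::export]]
List bw_fit_cpp(NumericVector pi0, NumericMatrix A0, NumericMatrix B0,
                List seqs, int max_iter, double tol, double em_floor) {
  const int S = pi0.size(), V = B0.ncol(), nseq = seqs.size();
  std::vector<double> pi, A, B;
  flatten(pi0, A0, B0, pi, A, B);
  std::vector<double> trace;
  trace.reserve(max_iter);
  double prev = R_NegInf;

  size_t maxT = 0;
  for (int s = 0; s < nseq; ++s) {
    IntegerVector obs = seqs[s];
    maxT = std::max(maxT, (size_t)obs.size());
  }
  std::vector<double> alpha(maxT * S), beta(maxT * S), cvec(maxT);
  std::vector<double> pi_acc(S), xi_acc((size_t)S * S), gB((size_t)S * V),
      gA(S);

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(pi_acc.begin(), pi_acc.end(), 0.0);
    std::fill(xi_acc.begin(), xi_acc.end(), 0.0);
    std::fill(gB.begin(), gB.end(), 0.0);
    std::fill(gA.begin(), gA.end(), 0.0);
    double logL = 0.0;

    for (int s = 0; s < nseq; ++s) {
      IntegerVector oseq = seqs[s];
      const int T = oseq.size();
      if (T == 0) continue;
      const int* obs = INTEGER(oseq);
      logL += forward_flat(pi.data(), A.data(), B.data(), S, V, obs, T,
                           alpha.data(), cvec.data());
      // scaled backward pass
      double* bT = beta.data() + (size_t)(T - 1) * S;
      for (int i = 0; i < S; ++i) bT[i] = 1.0;
      for (int t = T - 2; t >= 0; --t) {
        const double* bn = beta.data() + (size_t)(t + 1) * S;
        double* bt = beta.data() + (size_t)t * S;
        const int o = obs[t + 1];
        const double inv = 1.0 / cvec[t + 1];
        for (int i = 0; i < S; ++i) {
          double sum = 0.0;
          const double* Ai = A.data() + (size_t)i * S;
          for (int j = 0; j < S; ++j) sum += Ai[j] * B[j * V + o] * bn[j];
          bt[i] = sum * inv;
        }
      }
      // gamma accumulation (scaling makes alpha*beta normalized per t)
      for (int t = 0; t < T; ++t) {
        const double* at = alpha.data() + (size_t)t * S;
        const double* bt = beta.data() + (size_t)t * S;
        const int o = obs[t];
        for (int i = 0; i < S; ++i) {
          const double g = at[i] * bt[i];
          if (t == 0) pi_acc[i] += g;
          gB[i * V + o] += g;
          if (t < T - 1) gA[i] += g;
        }
      }
      // xi accumulation
      for (int t = 0; t < T - 1; ++t) {
        const double* at = alpha.data() + (size_t)t * S;
        const double* bn = beta.data() + (size_t)(t + 1) * S;
        const int o = obs[t + 1];
        const double inv = 1.0 / cvec[t + 1];
        for (int i = 0; i < S; ++i) {
          const double ai = at[i] * inv;
          if (ai == 0.0) continue;
          const double* Ai = A.data() + (size_t)i * S;
          double* Xi = xi_acc.data() + (size_t)i * S;
          for (int j = 0; j < S; ++j) Xi[j] += ai * Ai[j] * B[j * V + o] * bn[j];
        }
      }
    }
    trace.push_back(logL);
    if (iter > 0 && logL - prev < tol) break;
    prev = logL;

    // M-step
    double psum = 0.0;
    for (int i = 0; i < S; ++i) psum += pi_acc[i];
    for (int i = 0; i < S; ++i)
      pi[i] = psum > 0 ? pi_acc[i] / psum : 1.0 / S;
    for (int i = 0; i < S; ++i) {
      double* Ai = A.data() + (size_t)i * S;
      if (gA[i] > 0) {
        const double inv = 1.0 / gA[i];
        for (int j = 0; j < S; ++j) Ai[j] = xi_acc[i * S + j] * inv;
      }
      double rs = 0.0;
      for (int j = 0; j < S; ++j) rs += Ai[j];
      if (rs > 0) for (int j = 0; j < S; ++j) Ai[j] /= rs;
      // emissions with a floor: many of the 2^n symbols are unseen and a
      // hard zero would lock the state out of them permanently
      double* Bi = B.data() + (size_t)i * V;
      double bs = 0.0;
      for (int v = 0; v < V; ++v) bs += gB[i * V + v];
      for (int v = 0; v < V; ++v) {
        double b = bs > 0 ? gB[i * V + v] / bs : 1.0 / V;
        Bi[v] = b < em_floor ? em_floor : b;
      }
      double bn = 0.0;
      for (int v = 0; v < V; ++v) bn += Bi[v];
      for (int v = 0; v < V; ++v) Bi[v] /= bn;
    }
  }
  NumericVector piR(S);
  NumericMatrix AR(S, S), BR(S, V);
  for (int i = 0; i < S; ++i) {
    piR[i] = pi[i];
    for (int j = 0; j < S; ++j) AR(i, j) = A[i * S + j];
    for (int v = 0; v < V; ++v) BR(i, v) = B[i * V + v];
  }
  double final_ll = hmm_loglik_cpp(piR, AR, BR, seqs);
  return List::create(_["pi"] = piR, _["A"] = AR, _["B"] = BR,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["loglik"] = final_ll);
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// Returns a 0-based state path.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
                          IntegerVector obs) {
  const int T = obs.size(), S = pi.size();
  if (T == 0) return IntegerVector(0);
  std::vector<double> lA((size_t)S * S), lB((size_t)S * B.ncol());
  const int V = B.ncol();
  for (int i = 0; i < S; ++i) {
    for (int j = 0; j < S; ++j) lA[i * S + j] = std::log(A(i, j));
    for (int v = 0; v < V; ++v) lB[i * V + v] = std::log(B(i, v));
  }
  std::vector<double> dprev(S), dcur(S);
  std::vector<int> psi((size_t)T * S);
  for (int i = 0; i < S; ++i) dprev[i] = std::log(pi[i]) + lB[i * V + obs[0]];
  for (int t = 1; t < T; ++t) {
    const int o = obs[t];
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < S; ++i) {
        double v = dprev[i] + lA[i * S + j];
        if (v > best) { best = v; arg = i; } // strict > keeps lowest index
      }
      dcur[j] = best + lB[j * V + o];
      psi[(size_t)t * S + j] = arg;
    }
    dprev = dcur;
  }
  double best = R_NegInf;
  int arg = 0;
  for (int i = 0; i < S; ++i)
    if (dprev[i] > best) { best = dprev[i]; arg = i; }
  if (!R_finite(best))
    stop("all state paths have zero probability for this sequence");
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi[(size_t)(t + 1) * S + path[t + 1]];
  return path;
}

// Discrete Frechet distance between two polylines (rows = points), via the
// standard dynamic program over monotone couplings.
// [[Rcpp::export]]
double frechet_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (n == 0 || m == 0) stop("curves must be nonempty");
  if (b.ncol() != d) stop("curves must share a dimension");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dist = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = a(i, k) - b(j, k);
        dist += diff * diff;
      }
      dist = std::sqrt(dist);
      double reach;
      if (i == 0 && j == 0) reach = dist;
      else if (i == 0) reach = std::max(cur[j - 1], dist);
      else if (j == 0) reach = std::max(prev[0], dist);
      else {
        double m3 = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
        reach = std::max(m3, dist);
      }
      cur[j] = reach;
    }
    prev = cur;
  }
  return prev[m - 1];
}
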