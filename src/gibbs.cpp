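#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampling for LDA.
//
// Count layout: n_wt is indexed [w * T + t] (topic fastest) so the inner
// loop over topics stays in one cache line.  All randomness comes from R's
// RNG (unif_rand), so results are reproducible under set.seed().

static double log_joint_counts(const std::vector<int> &n_wt,
                               const std::vector<int> &n_dt,
                               const std::vector<int> &n_t,
                               const std::vector<int> &doc_len,
                               int W, int T, int D,
                               double alpha, double delta) {
  // Sparse evaluation: words with n_wt == 0 contribute
  // lgamma(delta) - lgamma(delta) = 0, so only nonzero cells are visited.
  double lj = T * R::lgammafn(W * delta);
  for (int t = 0; t < T; ++t)
    lj -= R::lgammafn(n_t[t] + W * delta);
  for (int w = 0; w < W; ++w)
    for (int t = 0; t < T; ++t)
      if (n_wt[w * T + t] > 0)
        lj += R::lgammafn(n_wt[w * T + t] + delta) - R::lgammafn(delta);
  lj += D * (R::lgammafn(T * alpha) - T * R::lgammafn(alpha));
  for (int d = 0; d < D; ++d) {
    lj -= R::lgammafn(doc_len[d] + T * alpha);
    for (int t = 0; t < T; ++t)
      lj += R::lgammafn(n_dt[d * T + t] + alpha);
  }
  return lj;
}

// [[Rcpp::export]]
List gibbs_fit_cpp(List docs, int n_words, int n_topics,
                   double alpha, double delta,
                   int n_iter, int burn_in,
                   bool track_tokens, bool track_history,
                   int trace_every, bool average,
                   Nullable<IntegerVector> init_z = R_NilValue) {
  const int D = docs.size();
  const int W = n_words;
  const int T = n_topics;

  std::vector<int> wid, did, doc_len(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector v = docs[d];
    doc_len[d] = v.size();
    for (int q = 0; q < v.size(); ++q) {
      wid.push_back(v[q] - 1);
      did.push_back(d);
    }
  }
  const int Q = (int)wid.size();

  std::vector<int> n_wt((size_t)W * T, 0), n_dt((size_t)D * T, 0),
      n_t(T, 0), z(Q);

  // token topics: warm start from a previous state, or uniform random
  if (init_z.isNotNull()) {
    IntegerVector z0(init_z);
    if (z0.size() != Q) stop("init_z length does not match token count");
    for (int q = 0; q < Q; ++q) {
      int t = z0[q];
      if (t < 0 || t >= T) stop("init_z entries must be in [0, T)");
      z[q] = t;
      ++n_wt[(size_t)wid[q] * T + t];
      ++n_dt[(size_t)did[q] * T + t];
      ++n_t[t];
    }
  } else {
    for (int q = 0; q < Q; ++q) {
      int t = (int)(unif_rand() * T);
      if (t >= T) t = T - 1;
      z[q] = t;
      ++n_wt[(size_t)wid[q] * T + t];
      ++n_dt[(size_t)did[q] * T + t];
      ++n_t[t];
    }
  }

  const int n_keep = n_iter - burn_in;
  std::vector<double> phi_sum, theta_sum;
  if (average) {
    phi_sum.assign((size_t)W * T, 0.0);
    theta_sum.assign((size_t)D * T, 0.0);
  }
  NumericMatrix token_prob(track_tokens ? Q : 0, track_tokens ? T : 0);
  IntegerMatrix history(track_history ? n_keep : 0, track_history ? Q : 0);
  NumericVector lj_trace(trace_every > 0 ? n_iter : 0);

  std::vector<double> p(T);
  const double Wd = W * delta;

  for (int it = 0; it < n_iter; ++it) {
    bool keep = it >= burn_in;
    for (int q = 0; q < Q; ++q) {
      const int w = wid[q], d = did[q], old = z[q];
      int *wrow = &n_wt[(size_t)w * T];
      int *drow = &n_dt[(size_t)d * T];
      --wrow[old]; --drow[old]; --n_t[old];
      double total = 0.0;
      for (int t = 0; t < T; ++t) {
        p[t] = (wrow[t] + delta) / (n_t[t] + Wd) * (drow[t] + alpha);
        total += p[t];
      }
      double u = unif_rand() * total, acc = 0.0;
      int t_new = T - 1;
      for (int t = 0; t < T; ++t) {
        acc += p[t];
        if (u <= acc) { t_new = t; break; }
      }
      z[q] = t_new;
      ++wrow[t_new]; ++drow[t_new]; ++n_t[t_new];
      if (keep && track_tokens)
        for (int t = 0; t < T; ++t)
          token_prob(q, t) += p[t] / total;
    }
    if (keep && track_history)
      for (int q = 0; q < Q; ++q)
        history(it - burn_in, q) = z[q] + 1;
    if (keep && average) {
      for (int w = 0; w < W; ++w)
        for (int t = 0; t < T; ++t)
          phi_sum[(size_t)w * T + t] +=
            (n_wt[(size_t)w * T + t] + delta) / (n_t[t] + Wd);
      for (int d = 0; d < D; ++d)
        for (int t = 0; t < T; ++t)
          theta_sum[(size_t)d * T + t] +=
            (n_dt[(size_t)d * T + t] + alpha) / (doc_len[d] + T * alpha);
    }
    if (trace_every > 0) {
      lj_trace[it] = ((it + 1) % trace_every == 0 || it == n_iter - 1)
        ? log_joint_counts(n_wt, n_dt, n_t, doc_len, W, T, D, alpha, delta)
        : NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }

  if (track_tokens && n_keep > 0)
    for (int q = 0; q < Q; ++q)
      for (int t = 0; t < T; ++t)
        token_prob(q, t) /= n_keep;

  IntegerMatrix n_wt_out(W, T), n_dt_out(D, T);
  for (int w = 0; w < W; ++w)
    for (int t = 0; t < T; ++t) n_wt_out(w, t) = n_wt[(size_t)w * T + t];
  for (int d = 0; d < D; ++d)
    for (int t = 0; t < T; ++t) n_dt_out(d, t) = n_dt[(size_t)d * T + t];

  SEXP phi_avg = R_NilValue, theta_avg = R_NilValue;
  if (average && n_keep > 0) {
    NumericMatrix pa(T, W), ta(D, T);
    for (int w = 0; w < W; ++w)
      for (int t = 0; t < T; ++t)
        pa(t, w) = phi_sum[(size_t)w * T + t] / n_keep;
    for (int d = 0; d < D; ++d)
      for (int t = 0; t < T; ++t)
        ta(d, t) = theta_sum[(size_t)d * T + t] / n_keep;
    phi_avg = pa; theta_avg = ta;
  }

  return List::create(
      _["z"] = IntegerVector(z.begin(), z.end()),
      _["phi_avg"] = phi_avg,
      _["theta_avg"] = theta_avg,
      _["n_wt"] = n_wt_out,
      _["n_dt"] = n_dt_out,
      _["n_t"] = IntegerVector(n_t.begin(), n_t.end()),
      _["doc_len"] = IntegerVector(doc_len.begin(), doc_len.end()),
      _["token_prob"] = track_tokens ? (SEXP)token_prob : R_NilValue,
      _["history"] = track_history ? (SEXP)history : R_NilValue,
      _["log_joint_trace"] = trace_every > 0 ? (SEXP)lj_trace : R_NilValue);
}

// Fold-in: Gibbs over one held-out document with phi (T x W) frozen.
// Returns the Rao-Blackwellised posterior mean of theta over retained sweeps.

// [[Rcpp::export]]
NumericVector gibbs_infer_cpp(IntegerVector tokens, NumericMatrix phi,
                              double alpha, int n_iter, int burn_in) {
  const int T = phi.nrow();
  const int Q = tokens.size();
  std::vector<int> n_t(T, 0), z(Q);
  for (int q = 0; q < Q; ++q) {
    int t = (int)(unif_rand() * T);
    if (t >= T) t = T - 1;
    z[q] = t;
    ++n_t[t];
  }
  std::vector<double> p(T);
  NumericVector theta(T);
  const int n_keep = n_iter - burn_in;
  for (int it = 0; it < n_iter; ++it) {
    for (int q = 0; q < Q; ++q) {
      const int w = tokens[q] - 1, old = z[q];
      --n_t[old];
      double total = 0.0;
      for (int t = 0; t < T; ++t) {
        p[t] = phi(t, w) * (n_t[t] + alpha);
        total += p[t];
      }
      double u = unif_rand() * total, acc = 0.0;
      int t_new = T - 1;
      for (int t = 0; t < T; ++t) {
        acc += p[t];
        if (u <= acc) { t_new = t; break; }
      }
      z[q] = t_new;
      ++n_t[t_new];
    }
    if (it >= burn_in)
      for (int t = 0; t < T; ++t)
        theta[t] += (n_t[t] + alpha) / (Q + T * alpha);
  }
  for (int t = 0; t < T; ++t) theta[t] /= n_keep;
  return theta;
}
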