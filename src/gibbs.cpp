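#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model on binary (haploid-coded) dominant
// band phenotypes. X is N x L with entries 1 (band), 0 (no band), -1
// (missing). Missing cells contribute no likelihood term: their origin is
// drawn from the membership prior alone and they are skipped when counting
// for the frequency update and when recording the log-likelihood.
//
// Sweep structure:
//   (1) f_kl ~ Beta(1 + #present, 1 + #absent) over current assignments
//   (2) z_il ~ Categorical( q_ik * f_kl^x * (1-f_kl)^(1-x) )
//   (3) q_i  ~ Dirichlet(alpha + per-cluster assignment counts)
//   (4) alpha by a Metropolis step (normal proposal, uniform prior)
// After burn-in the mixture log-likelihood sum_{il} log sum_k q_ik P(x|f_kl)
// and alpha are recorded, and q and f are accumulated for posterior means.

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix X, int K, int burnin, int sweeps,
                         double alpha_init, double alpha_sd,
                         double alpha_max) {
  const int N = X.nrow(), L = X.ncol();
  const double FEPS = 1e-12;

  IntegerMatrix Z(N, L);
  NumericMatrix f(K, L), q(N, K);
  NumericMatrix q_sum(N, K), f_sum(K, L);
  NumericVector lnlik_trace(sweeps), alpha_trace(sweeps);
  std::vector<double> w(K);
  std::vector<int> n1(K), n0(K), cnt(K);
  double alpha = alpha_init;

  for (int i = 0; i < N; ++i) {
    for (int l = 0; l < L; ++l)
      Z(i, l) = (int)std::floor(unif_rand() * K);
    for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
  }

  const int total = burnin + sweeps;
  for (int t = 0; t < total; ++t) {
    // (1) cluster band frequencies
    for (int l = 0; l < L; ++l) {
      std::fill(n1.begin(), n1.end(), 0);
      std::fill(n0.begin(), n0.end(), 0);
      for (int i = 0; i < N; ++i) {
        const int x = X(i, l);
        if (x < 0) continue;
        if (x == 1) ++n1[Z(i, l)]; else ++n0[Z(i, l)];
      }
      for (int k = 0; k < K; ++k) {
        double fk = R::rbeta(1.0 + n1[k], 1.0 + n0[k]);
        if (fk < FEPS) fk = FEPS;
        if (fk > 1.0 - FEPS) fk = 1.0 - FEPS;
        f(k, l) = fk;
      }
    }

    // (2) origin assignments + (3) memberships, individual by individual.
    // The categorical normaliser s is the mixture likelihood of the cell,
    // so the recorded log-likelihood falls out of this loop for free.
    const bool record = t >= burnin;
    double ll = 0.0;
    std::vector<double> qi(K);
    for (int i = 0; i < N; ++i) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int k = 0; k < K; ++k) qi[k] = q(i, k);
      for (int l = 0; l < L; ++l) {
        const int x = X(i, l);
        const double *fcol = &f(0, l);
        double s = 0.0;
        if (x == 1) {
          for (int k = 0; k < K; ++k) s += (w[k] = qi[k] * fcol[k]);
        } else if (x == 0) {
          for (int k = 0; k < K; ++k) s += (w[k] = qi[k] * (1.0 - fcol[k]));
        } else {
          for (int k = 0; k < K; ++k) s += (w[k] = qi[k]);
        }
        double u = unif_rand() * s;
        int k = 0;
        double acc = w[0];
        while (k < K - 1 && u > acc) acc += w[++k];
        Z(i, l) = k;
        ++cnt[k];
        if (record && x >= 0) ll += std::log(s);
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        w[k] = R::rgamma(alpha + cnt[k], 1.0);
        s += w[k];
      }
      if (s <= 0.0) {  // all gamma draws underflowed; fall back to uniform
        for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
      } else {
        for (int k = 0; k < K; ++k) {
          double qk = w[k] / s;
          q(i, k) = (qk < FEPS) ? FEPS : qk;
        }
      }
    }

    // (4) Metropolis update of the admixture parameter
    if (K > 1) {
      const double prop = alpha + norm_rand() * alpha_sd;
      if (prop > 0.0 && prop < alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(q(i, k));
        const double logr =
          N * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) -
          N * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
          (prop - alpha) * slq;
        if (std::log(unif_rand()) < logr) alpha = prop;
      }
    }

    if (record) {
      const int r = t - burnin;
      lnlik_trace[r] = ll;
      alpha_trace[r] = alpha;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) q_sum(i, k) += q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) f_sum(k, l) += f(k, l);
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) q_sum(i, k) /= sweeps;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) f_sum(k, l) /= sweeps;

  return List::create(_["q_mean"] = q_sum, _["f_mean"] = f_sum,
                      _["ln_like_trace"] = lnlik_trace,
                      _["alpha_trace"] = alpha_trace);
}
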