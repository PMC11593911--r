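// Diploid Li-Stephens haplotype-copying HMM: exact forward-backward
// genotype posteriors.
//
// Hidden state at site m is the ordered pair (i, j) of copied reference
// haplotypes; the two chains switch independently with probability
// tau_m = 1 - exp(-4 * ne * (d_cm / 100) / k) per inter-site interval,
// jumping to a uniformly chosen haplotype.  Emissions use a per-allele
// miscopy probability eps.  Messages are rescaled per site, so there is
// no underflow at any length; memory is kept at O(sqrt(L) * k^2) by
// checkpointing the forward messages every ~sqrt(L) sites and
// recomputing within blocks during the backward sweep (a full store
// would need L * k^2 doubles).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix ls_fb_cpp(IntegerMatrix alleles, IntegerVector obs,
                        NumericVector dcm, double ne, double eps) {
  const int k = alleles.nrow();
  const int L = alleles.ncol();
  NumericMatrix out(L, 3);
  if (L == 0) return out;
  if (k < 2) stop("panel must have at least 2 haplotypes");
  if (obs.size() != L || dcm.size() != L)
    stop("obs and dcm must have one entry per panel site");
  const size_t k2 = (size_t)k * k;

  // genotype predictive P(g | a1, a2, eps); also the emission table
  double etab[3][2][2];
  const double q0[2] = {1.0 - eps, eps};  // P(copied allele = 0 | a)
  for (int a = 0; a < 2; ++a) {
    for (int b = 0; b < 2; ++b) {
      double p0 = q0[a] * q0[b];
      double p2 = (1.0 - q0[a]) * (1.0 - q0[b]);
      etab[0][a][b] = p0;
      etab[1][a][b] = 1.0 - p0 - p2;
      etab[2][a][b] = p2;
    }
  }

  std::vector<double> tau(L, 0.0);
  for (int m = 1; m < L; ++m) {
    if (dcm[m] < 0) stop("negative genetic distance at site %d", m + 1);
    tau[m] = 1.0 - std::exp(-0.04 * ne * dcm[m] / k);
  }

  const int B = std::max(1, (int)std::ceil(std::sqrt((double)L)));
  const int nb = (L + B - 1) / B;
  std::vector<double> cp((size_t)nb * k2);
  std::vector<double> scales(L);
  std::vector<double> F(k2), R(k), C(k);

  // X <- (A kron A) X for one haploid smoothing matrix
  // A = (1 - tau) I + (tau / k) J; expands to
  // X'(i,j) = a^2 X(i,j) + a b (R_i + C_j) + b^2 s
  auto apply_transition = [&](std::vector<double>& X, double t) {
    if (t <= 0.0) return;
    const double a = 1.0 - t, b = t / k;
    std::fill(R.begin(), R.end(), 0.0);
    double s = 0.0;
    for (int j = 0; j < k; ++j) {
      const double* col = &X[(size_t)j * k];
      double cs = 0.0;
      for (int i = 0; i < k; ++i) {
        R[i] += col[i];
        cs += col[i];
      }
      C[j] = cs;
      s += cs;
    }
    const double a2 = a * a, ab = a * b, b2s = b * b * s;
    for (int j = 0; j < k; ++j) {
      double* col = &X[(size_t)j * k];
      const double cj = ab * C[j] + b2s;
      for (int i = 0; i < k; ++i) col[i] = a2 * col[i] + ab * R[i] + cj;
    }
  };

  // X <- X .* E_m, returning the total sum of X afterwards
  auto apply_emission = [&](std::vector<double>& X, int m) -> double {
    const int g = obs[m];
    double s = 0.0;
    if (g >= 0) {
      const int* am = &alleles(0, m);
      for (int j = 0; j < k; ++j) {
        double* col = &X[(size_t)j * k];
        const int aj = am[j];
        for (int i = 0; i < k; ++i) {
          col[i] *= etab[g][am[i]][aj];
          s += col[i];
        }
      }
    } else {
      for (size_t t = 0; t < k2; ++t) s += X[t];
    }
    return s;
  };

  // ---- forward pass with checkpoints ----
  std::fill(F.begin(), F.end(), 1.0 / (double)k2);
  double s = apply_emission(F, 0);
  if (!(s > 0.0)) stop("zero likelihood at site 1 (eps too small?)");
  scales[0] = s;
  for (size_t t = 0; t < k2; ++t) F[t] /= s;
  std::copy(F.begin(), F.end(), cp.begin());
  for (int m = 1; m < L; ++m) {
    apply_transition(F, tau[m]);
    s = apply_emission(F, m);
    if (!(s > 0.0)) stop("zero likelihood at site %d (eps too small?)", m + 1);
    scales[m] = s;
    for (size_t t = 0; t < k2; ++t) F[t] /= s;
    if (m % B == 0) std::copy(F.begin(), F.end(), cp.begin() + (size_t)(m / B) * k2);
  }

  // ---- backward pass with in-block forward recomputation ----
  std::vector<double> Bt(k2, 1.0);
  std::vector<double> buf((size_t)B * k2);
  std::vector<double> G(k2);
  for (int b = nb - 1; b >= 0; --b) {
    const int start = b * B;
    const int end = std::min(L, start + B) - 1;
    std::copy(cp.begin() + (size_t)b * k2, cp.begin() + (size_t)(b + 1) * k2,
              buf.begin());
    for (int m = start + 1; m <= end; ++m) {
      double* cur = &buf[(size_t)(m - start) * k2];
      std::copy(&buf[(size_t)(m - start - 1) * k2],
                &buf[(size_t)(m - start) * k2], cur);
      std::vector<double> tmp(cur, cur + k2);
      apply_transition(tmp, tau[m]);
      double sm = apply_emission(tmp, m);
      for (size_t t = 0; t < k2; ++t) cur[t] = tmp[t] / sm;
    }
    for (int m = end; m >= start; --m) {
      const double* Fm = &buf[(size_t)(m - start) * k2];
      double sg = 0.0;
      for (size_t t = 0; t < k2; ++t) {
        G[t] = Fm[t] * Bt[t];
        sg += G[t];
      }
      double w[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
      const int* am = &alleles(0, m);
      for (int j = 0; j < k; ++j) {
        const double* gcol = &G[(size_t)j * k];
        const int aj = am[j];
        double w0 = 0.0, w1 = 0.0;
        for (int i = 0; i < k; ++i) {
          if (am[i] == 0) w0 += gcol[i]; else w1 += gcol[i];
        }
        w[0][aj] += w0;
        w[1][aj] += w1;
      }
      double p[3];
      for (int g = 0; g < 3; ++g) {
        p[g] = w[0][0] * etab[g][0][0] + w[0][1] * etab[g][0][1] +
               w[1][0] * etab[g][1][0] + w[1][1] * etab[g][1][1];
      }
      const double tot = p[0] + p[1] + p[2];
      if (!(tot > 0.0) || !std::isfinite(sg))
        stop("posterior degenerate at site %d", m + 1);
      out(m, 0) = p[0] / tot;
      out(m, 1) = p[1] / tot;
      out(m, 2) = p[2] / tot;
      if (m > 0) {
        apply_emission(Bt, m);
        apply_transition(Bt, tau[m]);
        const double cm = scales[m];
        for (size_t t = 0; t < k2; ++t) Bt[t] /= cm;
      }
    }
  }

  double ll = 0.0;
  for (int m = 0; m < L; ++m) ll += std::log(scales[m]);
  out.attr("loglik") = ll;
  return out;
}
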