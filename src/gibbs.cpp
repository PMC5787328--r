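// Single-site Gibbs sampler for the directional-dominance SNP model
//
//   y = 1 mu + h b + X t + W r + Q c + Z a + K d + e
//
// Flat priors on mu, b and parity effects t (first parity is the reference
// level); Gaussian priors on contemporary-group effects r, permanent-
// environment effects c and additive SNP effects a; skew-Gaussian prior on
// dominance SNP effects d expressed through half-normal auxiliary variables
// u_j >= 0:
//
//   d_j | u_j ~ N(lambda * u_j, sigma2_d),   u_j ~ |N(0, 1)|,
//
// with a flat prior on the asymmetry parameter lambda.  All variances carry
// scaled inverse chi-square priors.
//
// Genotype codes are stored once per animal; record-level cross-products for
// a SNP are obtained from per-animal record counts and running animal
// residual sums, so one SNP update costs O(n_animals), not O(n_records).
// The record residual vector e is maintained incrementally through every
// update and reconciled against a from-scratch recomputation at checkpoints.
//
// All randomness goes through R's RNG (RNGScope), so set.seed() in R makes
// a chain bit-reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Draw from N(mean, sd^2) truncated to [0, inf).  Naive rejection while the
// standardised lower bound is small; Robert's (1995) exponential rejection
// covers the far tail so draws stay finite and cheap for mean << 0.
static double rtnorm0(double mean, double sd) {
  double a = -mean / sd;  // standardised lower bound
  double z;
  if (a < 0.45) {
    do {
      z = norm_rand();
    } while (z < a);
  } else {
    double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
    double rho;
    do {
      z = a + exp_rand() / alpha;
      rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
    } while (unif_rand() > rho);
  }
  return mean + sd * z;
}

// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(NumericVector y,
                 IntegerVector animal,   // 0-based, length n_rec
                 IntegerVector parity,   // 0-based levels 0..3, 0 = reference
                 IntegerVector group,    // 0-based, length n_rec
                 NumericMatrix Z,        // n_ind x m additive codes
                 NumericMatrix K,        // n_ind x m dominance codes
                 NumericVector h,        // n_ind average homozygosity
                 bool include_b,
                 bool include_lambda,
                 bool use_parity,
                 bool use_group,
                 bool use_perm,
                 NumericVector nu,       // prior df:     r, c, a, d, e
                 NumericVector S2,       // prior scales: r, c, a, d, e
                 NumericVector init_var, // initial variances, same order
                 double init_mu,
                 int n_iter, int burn_in, int thin,
                 bool fixed_variance,
                 bool fixed_u,
                 bool translation_move,
                 bool store_fitted,
                 int check_every) {
  const int n_rec = y.size();
  const int n_ind = Z.nrow();
  const int m = Z.ncol();
  int n_grp = 0;
  for (int k = 0; k < n_rec; ++k) if (group[k] + 1 > n_grp) n_grp = group[k] + 1;

  IntegerVector n_per_ind(n_ind), n_per_grp(n_grp), n_per_par(4);
  for (int k = 0; k < n_rec; ++k) {
    n_per_ind[animal[k]]++;
    n_per_grp[group[k]]++;
    n_per_par[parity[k]]++;
  }
  std::vector<double> n_ind_d(n_ind);
  for (int i = 0; i < n_ind; ++i) n_ind_d[i] = n_per_ind[i];

  // per-SNP record-weighted cross-products sum_i n_i * code_ij^2 (constant)
  NumericVector zWz(m), kWk(m);
  for (int j = 0; j < m; ++j) {
    const double* zj = &Z(0, j);
    const double* kj = &K(0, j);
    double sz = 0.0, sk = 0.0;
    for (int i = 0; i < n_ind; ++i) {
      sz += n_per_ind[i] * zj[i] * zj[i];
      sk += n_per_ind[i] * kj[i] * kj[i];
    }
    zWz[j] = sz;
    kWk[j] = sk;
  }
  double hWh = 0.0;
  for (int k = 0; k < n_rec; ++k) hWh += h[animal[k]] * h[animal[k]];
  if (include_b && hWh <= 0.0)
    stop("homozygosity covariate has zero cross-product; b is not estimable");

  // Translation-group move (Liu-Sabatti): a common shift delta in all d_j,
  // compensated through b (when present) and mu, walks the near-collinear
  // direction between the dominance-effect mean and the homozygosity
  // regression in one Gibbs step instead of a slow single-site random walk.
  // Residual design of the move per animal:
  //   w_i = sum_j K_ij + c_b * h_i - (m - S2pq),  c_b = m if b is in the
  // model else 0; with complete genotypes and b present w_i == 0 (the move
  // is likelihood-invariant and driven purely by the prior on d).
  double S2pq = 0.0;
  {
    // recover sum_j 2 p_j q_j from the dominance codes: for a complete
    // column, sum_i K_ij = n_het_j - n_ind * 2 p_j q_j; we only need the
    // per-animal row sums, so compute those directly.
  }
  std::vector<double> Ksum(n_ind, 0.0);
  for (int j = 0; j < m; ++j) {
    const double* kj = &K(0, j);
    for (int i = 0; i < n_ind; ++i) Ksum[i] += kj[i];
  }
  // S2pq enters only through the mu compensation; infer it from the mean
  // relation mean_i(Ksum) = m * (1 - mean(h)) - S2pq, which is exact for
  // complete genotypes and first-order for mean-imputed ones.
  {
    double mK = 0.0, mh = 0.0;
    for (int i = 0; i < n_ind; ++i) { mK += Ksum[i]; mh += h[i]; }
    mK /= n_ind; mh /= n_ind;
    S2pq = m * (1.0 - mh) - mK;
  }
  const double cb = include_b ? (double)m : 0.0;
  std::vector<double> wmove(n_ind);
  double wWw = 0.0;
  for (int i = 0; i < n_ind; ++i) {
    wmove[i] = Ksum[i] + cb * h[i] - ((double)m - S2pq);
    wWw += n_per_ind[i] * wmove[i] * wmove[i];
  }

  // state
  double mu = init_mu, b = 0.0, lambda = 0.0;
  std::vector<double> t_eff(4, 0.0), r_eff(n_grp, 0.0), c_eff(n_ind, 0.0);
  std::vector<double> a(m, 0.0), d(m, 0.0), u(m, 0.0);
  double s2_r = init_var[0], s2_c = init_var[1], s2_a = init_var[2],
         s2_d = init_var[3], s2_e = init_var[4];
  if (include_lambda) std::fill(u.begin(), u.end(), std::sqrt(2.0 / M_PI));

  std::vector<double> e(n_rec);      // record residuals, always current
  std::vector<double> Rsum(n_ind);   // animal sums of residuals
  std::vector<double> gdelta(n_ind); // per-animal genomic change in a sweep
  for (int k = 0; k < n_rec; ++k) e[k] = y[k] - mu;

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  const int n_scal = 11;  // mu b lambda t2 t3 t4 s2_r s2_c s2_a s2_d s2_e
  NumericMatrix scal(n_keep, n_scal);
  NumericMatrix a_draws(n_keep, m), d_draws(n_keep, m);
  NumericMatrix fitted(store_fitted ? n_rec : 1, store_fitted ? n_keep : 1);
  double max_resid_diff = 0.0;
  int kept = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // --- general mean (flat prior)
    {
      double s = 0.0;
      for (int k = 0; k < n_rec; ++k) s += e[k];
      double newv = R::rnorm(s / n_rec + mu, std::sqrt(s2_e / n_rec));
      double del = newv - mu;
      mu = newv;
      for (int k = 0; k < n_rec; ++k) e[k] -= del;
    }
    // --- homozygosity regression b (flat prior)
    if (include_b) {
      double s = 0.0;
      for (int k = 0; k < n_rec; ++k) s += h[animal[k]] * e[k];
      double newv = R::rnorm(s / hWh + b, std::sqrt(s2_e / hWh));
      double del = newv - b;
      b = newv;
      for (int k = 0; k < n_rec; ++k) e[k] -= del * h[animal[k]];
    }
    // --- parity effects, levels 2..4 (level 1 reference, flat priors)
    if (use_parity) {
      for (int l = 1; l < 4; ++l) {
        if (n_per_par[l] == 0) continue;
        double s = 0.0;
        for (int k = 0; k < n_rec; ++k) if (parity[k] == l) s += e[k];
        double nl = n_per_par[l];
        double newv = R::rnorm(s / nl + t_eff[l], std::sqrt(s2_e / nl));
        double del = newv - t_eff[l];
        t_eff[l] = newv;
        for (int k = 0; k < n_rec; ++k) if (parity[k] == l) e[k] -= del;
      }
    }
    // --- contemporary-group effects (Gaussian prior, precision 1/s2_r)
    if (use_group) {
      std::vector<double> gs(n_grp, 0.0), gdel(n_grp, 0.0);
      for (int k = 0; k < n_rec; ++k) gs[group[k]] += e[k];
      double ratio = s2_e / s2_r;
      for (int g = 0; g < n_grp; ++g) {
        if (n_per_grp[g] == 0) continue;
        double denom = n_per_grp[g] + ratio;
        double mean = (gs[g] + r_eff[g] * n_per_grp[g]) / denom;
        double newv = R::rnorm(mean, std::sqrt(s2_e / denom));
        gdel[g] = newv - r_eff[g];
        r_eff[g] = newv;
      }
      for (int k = 0; k < n_rec; ++k) e[k] -= gdel[group[k]];
    }
    // --- permanent-environment effects (Gaussian prior, precision 1/s2_c)
    if (use_perm) {
      std::vector<double> cs(n_ind, 0.0), cdel(n_ind, 0.0);
      for (int k = 0; k < n_rec; ++k) cs[animal[k]] += e[k];
      double ratio = s2_e / s2_c;
      for (int i = 0; i < n_ind; ++i) {
        if (n_per_ind[i] == 0) continue;
        double denom = n_per_ind[i] + ratio;
        double mean = (cs[i] + c_eff[i] * n_per_ind[i]) / denom;
        double newv = R::rnorm(mean, std::sqrt(s2_e / denom));
        cdel[i] = newv - c_eff[i];
        c_eff[i] = newv;
      }
      for (int k = 0; k < n_rec; ++k) e[k] -= cdel[animal[k]];
    }

    // --- hierarchical-centering translation moves.  Each shifts a random-
    // effect block along a direction the likelihood cannot see (the
    // compensating change in mu or b keeps every fitted value identical),
    // sampling the shift from the exact Gaussian conditional implied by the
    // block's prior.  They cost O(n) and remove the slow random walk
    // between mu/b and the block means.
    if (translation_move) {
      if (use_group && n_grp > 1) {      // mu vs group-effect mean
        double rbar = 0.0;
        for (int g = 0; g < n_grp; ++g) rbar += r_eff[g];
        rbar /= n_grp;
        double del = R::rnorm(rbar, std::sqrt(s2_r / n_grp));
        for (int g = 0; g < n_grp; ++g) r_eff[g] -= del;
        mu += del;
      }
      if (use_perm && n_ind > 1) {       // mu vs permanent-environment mean
        double cbar = 0.0;
        for (int i = 0; i < n_ind; ++i) cbar += c_eff[i];
        cbar /= n_ind;
        double del = R::rnorm(cbar, std::sqrt(s2_c / n_ind));
        for (int i = 0; i < n_ind; ++i) c_eff[i] -= del;
        mu += del;
      }
      if (use_perm && include_b) {       // b vs h-projection of c
        double hc = 0.0, hh = 0.0;
        for (int i = 0; i < n_ind; ++i) {
          hc += h[i] * c_eff[i];
          hh += h[i] * h[i];
        }
        double del = R::rnorm(hc / hh, std::sqrt(s2_c / hh));
        for (int i = 0; i < n_ind; ++i) c_eff[i] -= del * h[i];
        b += del;
      }
    }

    // --- SNP sweep: additive then dominance effects, ascending SNP order
    std::fill(Rsum.begin(), Rsum.end(), 0.0);
    for (int k = 0; k < n_rec; ++k) {
      if (!R_finite(e[k]))
        stop("non-finite residual at iteration %d (record %d)", it + 1, k + 1);
      Rsum[animal[k]] += e[k];
    }
    std::fill(gdelta.begin(), gdelta.end(), 0.0);

    double ra = s2_e / s2_a;
    {
      const double* Zp = Z.begin();
      double* __restrict Rp = Rsum.data();
      double* __restrict gp = gdelta.data();
      const double* __restrict np = n_ind_d.data();
      for (int j = 0; j < m; ++j) {
        const double* __restrict zj = Zp + (size_t)j * n_ind;
        double zy = 0.0;
        for (int i = 0; i < n_ind; ++i) zy += zj[i] * Rp[i];
        zy += a[j] * zWz[j];
        double denom = zWz[j] + ra;
        double newv = R::rnorm(zy / denom, std::sqrt(s2_e / denom));
        double del = newv - a[j];
        a[j] = newv;
        for (int i = 0; i < n_ind; ++i) {
          double dz = del * zj[i];
          Rp[i] -= dz * np[i];
          gp[i] += dz;
        }
      }
      const double* Kp = K.begin();
      for (int j = 0; j < m; ++j) {
        const double* __restrict kj = Kp + (size_t)j * n_ind;
        double ky = 0.0;
        for (int i = 0; i < n_ind; ++i) ky += kj[i] * Rp[i];
        ky += d[j] * kWk[j];
        double v = 1.0 / (kWk[j] / s2_e + 1.0 / s2_d);
        double mean = v * (ky / s2_e + lambda * u[j] / s2_d);
        double newv = R::rnorm(mean, std::sqrt(v));
        double del = newv - d[j];
        d[j] = newv;
        for (int i = 0; i < n_ind; ++i) {
          double dk = del * kj[i];
          Rp[i] -= dk * np[i];
          gp[i] += dk;
        }
      }
    }
    for (int k = 0; k < n_rec; ++k) e[k] -= gdelta[animal[k]];

    // --- translation move on the dominance-effect mean
    if (translation_move) {
      double we = 0.0;
      for (int k = 0; k < n_rec; ++k) we += wmove[animal[k]] * e[k];
      double prior_pull = 0.0;  // sum_j (lambda u_j - d_j) / s2_d
      for (int j = 0; j < m; ++j) prior_pull += lambda * u[j] - d[j];
      double v = 1.0 / (wWw / s2_e + (double)m / s2_d);
      double delta = R::rnorm(v * (we / s2_e + prior_pull / s2_d),
                              std::sqrt(v));
      for (int j = 0; j < m; ++j) d[j] += delta;
      if (include_b) b += delta * m;
      mu -= delta * ((double)m - S2pq);
      for (int k = 0; k < n_rec; ++k) e[k] -= delta * wmove[animal[k]];
    }

    // --- auxiliary variables and asymmetry parameter
    if (include_lambda) {
      if (!fixed_u) {
        double v = 1.0 / (1.0 + lambda * lambda / s2_d);
        double sdv = std::sqrt(v);
        for (int j = 0; j < m; ++j)
          u[j] = rtnorm0(v * lambda * d[j] / s2_d, sdv);
      }
      double su2 = 0.0, sud = 0.0;
      for (int j = 0; j < m; ++j) { su2 += u[j] * u[j]; sud += u[j] * d[j]; }
      if (su2 <= 0.0) stop("degenerate lambda conditional: sum(u^2) = 0");
      lambda = R::rnorm(sud / su2, std::sqrt(s2_d / su2));
    }

    // --- variances (scaled inverse chi-square full conditionals)
    if (!fixed_variance) {
      if (use_group) {
        double ss = 0.0;
        for (int g = 0; g < n_grp; ++g) ss += r_eff[g] * r_eff[g];
        s2_r = (ss + nu[0] * S2[0]) / R::rchisq(n_grp + nu[0]);
      }
      if (use_perm) {
        double ss = 0.0;
        for (int i = 0; i < n_ind; ++i) ss += c_eff[i] * c_eff[i];
        s2_c = (ss + nu[1] * S2[1]) / R::rchisq(n_ind + nu[1]);
      }
      {
        double ss = 0.0;
        for (int j = 0; j < m; ++j) ss += a[j] * a[j];
        s2_a = (ss + nu[2] * S2[2]) / R::rchisq(m + nu[2]);
      }
      {
        double ss = 0.0;
        for (int j = 0; j < m; ++j) {
          double dev = d[j] - lambda * u[j];
          ss += dev * dev;
        }
        s2_d = (ss + nu[3] * S2[3]) / R::rchisq(m + nu[3]);
      }
      {
        double ss = 0.0;
        for (int k = 0; k < n_rec; ++k) ss += e[k] * e[k];
        s2_e = (ss + nu[4] * S2[4]) / R::rchisq(n_rec + nu[4]);
      }
    }

    // --- residual-consistency checkpoint: recompute e from scratch
    if (check_every > 0 && (it + 1) % check_every == 0) {
      std::vector<double> gchk(n_ind, 0.0);
      for (int j = 0; j < m; ++j) {
        const double* zj = &Z(0, j);
        const double* kj = &K(0, j);
        for (int i = 0; i < n_ind; ++i)
          gchk[i] += zj[i] * a[j] + kj[i] * d[j];
      }
      double mx = 0.0;
      for (int k = 0; k < n_rec; ++k) {
        int i = animal[k];
        double fit = mu + gchk[i];
        if (use_parity) fit += t_eff[parity[k]];
        if (include_b) fit += b * h[i];
        if (use_group) fit += r_eff[group[k]];
        if (use_perm) fit += c_eff[i];
        double exact = y[k] - fit;
        double diff = std::fabs(e[k] - exact);
        if (diff > mx) mx = diff;
        e[k] = exact;
      }
      if (mx > max_resid_diff) max_resid_diff = mx;
    }

    // --- store thinned post-burn-in draw
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      scal(kept, 0) = mu;
      scal(kept, 1) = b;
      scal(kept, 2) = lambda;
      scal(kept, 3) = t_eff[1];
      scal(kept, 4) = t_eff[2];
      scal(kept, 5) = t_eff[3];
      scal(kept, 6) = s2_r;
      scal(kept, 7) = s2_c;
      scal(kept, 8) = s2_a;
      scal(kept, 9) = s2_d;
      scal(kept, 10) = s2_e;
      for (int j = 0; j < m; ++j) {
        a_draws(kept, j) = a[j];
        d_draws(kept, j) = d[j];
      }
      if (store_fitted)
        for (int k = 0; k < n_rec; ++k) fitted(k, kept) = y[k] - e[k];
      kept++;
    }

    if ((it + 1) % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["scalars"] = scal,
                      _["a"] = a_draws,
                      _["d"] = d_draws,
                      _["fitted"] = fitted,
                      _["max_resid_diff"] = max_resid_diff,
                      _["n_keep"] = kept);
}

// [[Rcpp::export(name = ".rtnorm0_cpp")]]
NumericVector rtnorm0_cpp(int n, double mean, double sd) {
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm0(mean, sd);
  return out;
}
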