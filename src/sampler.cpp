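#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for Gaussian / binary-probit / categorical-probit animal
// models.
//
// The additive genetic term is parameterized through the eigenstructure of
// the relationship matrix: a = G z + w with G = U diag(sqrt(lambda - c)),
// z ~ N(0, Va I), and the isotropic remainder w ~ N(0, c Va I) analytically
// folded into the residual (residual variance ve = 1 + c Va for the
// threshold models, with c the smallest eigenvalue of A).  Without this
// marginalization the individual-specific part of the breeding values is
// confounded with the fixed unit residual in one-record-per-individual
// threshold designs and the augmented sampler effectively never moves Va.
// Variance components get half-normal (default), half-Cauchy, or
// inverse-gamma priors and are updated on both the sufficient and the
// ancillary side (interweaving) via slice sampling on the log variance.

static double rtnorm_lower(double mu, double sd, double a) {
  // N(mu, sd^2) truncated to (a, inf)
  double z = (a - mu) / sd;
  if (z < 4.0) {
    double p = R::pnorm(z, 0.0, 1.0, 1, 0);
    double u = R::runif(p, 1.0);
    if (u >= 1.0) u = 1.0 - 1e-16;
    return mu + sd * R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  // far tail: Robert (1995) exponential rejection
  double alpha = 0.5 * (z + std::sqrt(z * z + 4.0));
  for (;;) {
    double e = R::exp_rand() / alpha;
    double x = z + e;
    double rho = std::exp(-0.5 * (x - alpha) * (x - alpha));
    if (R::unif_rand() < rho) return mu + sd * x;
  }
}

static double rtnorm_upper(double mu, double sd, double b) {
  return -rtnorm_lower(-mu, sd, -b);
}

static double rinvgamma(double shape, double rate) {
  double g = R::rgamma(shape, 1.0 / rate);
  if (g < 1e-300) g = 1e-300;
  return 1.0 / g;
}

// slice sampler on theta = log(sigma2), Neal's stepping-out and shrinkage
template <class F>
static double slice_logvar(double th0, const F& logp) {
  double ly = logp(th0) - R::exp_rand();
  double w = 1.0;
  double L = th0 - w * R::unif_rand(), Rr = L + w;
  for (int s = 0; s < 40 && logp(L) > ly; ++s) L -= w;
  for (int s = 0; s < 40 && logp(Rr) > ly; ++s) Rr += w;
  double th1 = th0;
  for (int s = 0; s < 100; ++s) {
    th1 = L + (Rr - L) * R::unif_rand();
    if (logp(th1) >= ly) return th1;
    if (th1 < th0) L = th1; else Rr = th1;
  }
  return th0;
}

// P(category | eta1, eta2) for argmax(0, eta1+e1, eta2+e2), e ~ N(0, I):
// p_j = int_0^inf dnorm(t - eta_j) pnorm(t - eta_other) dt
static double cat_tail_prob(double ea, double eb,
                            const std::vector<double>& gx,
                            const std::vector<double>& gw) {
  double s = 0.0;
  for (size_t k = 0; k < gx.size(); ++k) {
    double t = gx[k] / (1.0 - gx[k]);
    double jac = 1.0 / ((1.0 - gx[k]) * (1.0 - gx[k]));
    s += gw[k] * jac * R::dnorm(t - ea, 0.0, 1.0, 0) *
         R::pnorm(t - eb, 0.0, 1.0, 1, 0);
  }
  return s;
}

// [[Rcpp::export(name = ".gibbs_animal")]]
List gibbs_animal(NumericVector y, int response, NumericMatrix X,
                  List z_index, IntegerVector z_nlev,
                  IntegerVector anim_index, NumericMatrix G, double c_split,
                  double prior_fixed_var, int prior_code,
                  double ig_shape, double ig_rate, double hc_scale,
                  int n_iter, int burn_in, int thin,
                  NumericVector gl_nodes, NumericVector gl_weights) {
  const int n = y.size();
  const int p = X.ncol();
  const int K = z_index.size();            // iid random terms
  const bool has_anim = anim_index.size() > 0;
  const int q = has_anim ? G.nrow() : 0;   // animal levels
  const int rr = has_anim ? G.ncol() : 0;  // genetic dimensions kept
  const int D = (response == 2) ? 2 : 1;
  const bool gaussian = (response == 0);

  std::vector<IntegerVector> zi(K);
  std::vector<int> nlev(K);
  for (int k = 0; k < K; ++k) {
    zi[k] = as<IntegerVector>(z_index[k]);
    nlev[k] = z_nlev[k];
  }
  std::vector< std::vector<double> > lev_n(K);
  for (int k = 0; k < K; ++k) {
    lev_n[k].assign(nlev[k], 0.0);
    for (int i = 0; i < n; ++i) lev_n[k][zi[k][i]] += 1.0;
  }
  std::vector<double> an_n(q, 0.0);
  if (has_anim) for (int i = 0; i < n; ++i) an_n[anim_index[i]] += 1.0;
  // per-column Sum_l n_l G(l,j)^2
  std::vector<double> gj2(rr, 0.0);
  for (int j = 0; j < rr; ++j)
    for (int l = 0; l < q; ++l) gj2[j] += an_n[l] * G(l, j) * G(l, j);
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  std::vector<double> gx(gl_nodes.begin(), gl_nodes.end());
  std::vector<double> gw(gl_weights.begin(), gl_weights.end());

  // log prior of a variance component at theta = log(sigma2), including
  // the Jacobian of sigma -> theta, up to constants
  auto prior_log = [&](double th) -> double {
    if (prior_code == 0)        // half-Cauchy(hc_scale) on the sd
      return 0.5 * th - std::log1p(std::exp(th) / (hc_scale * hc_scale));
    if (prior_code == 1)        // inverse-gamma on the variance
      return -ig_shape * th - ig_rate / std::exp(th);
    // half-normal(hc_scale) on the sd
    return 0.5 * th - std::exp(th) / (2.0 * hc_scale * hc_scale);
  };

  // state
  std::vector< std::vector<double> > beta(D, std::vector<double>(p, 0.0));
  std::vector< std::vector< std::vector<double> > > u(D);
  std::vector< std::vector<double> > s2(D, std::vector<double>(K, 0.1));
  std::vector< std::vector<double> > zg(D, std::vector<double>(rr, 0.0));
  std::vector< std::vector<double> > banim(D, std::vector<double>(q, 0.0));
  std::vector<double> va(D, 0.1);
  std::vector<double> ve(D, 1.0);            // gaussian residual
  std::vector< std::vector<double> > ystar(D, std::vector<double>(n, 0.0));
  std::vector< std::vector<double> > r(D, std::vector<double>(n, 0.0));
  for (int d = 0; d < D; ++d) {
    u[d].resize(K);
    for (int k = 0; k < K; ++k) u[d][k].assign(nlev[k], 0.0);
  }
  // effective residual variance (link or environmental residual, plus the
  // marginalized isotropic genetic remainder c * Va)
  auto ve_eff = [&](int d) -> double {
    double base = gaussian ? ve[0] : 1.0;
    return base + (has_anim ? c_split * va[d] : 0.0);
  };
  if (gaussian) {
    for (int i = 0; i < n; ++i) { ystar[0][i] = y[i]; r[0][i] = y[i]; }
    double m = 0.0; for (int i = 0; i < n; ++i) m += y[i] / n;
    double vv = 0.0; for (int i = 0; i < n; ++i) vv += (y[i] - m) * (y[i] - m);
    ve[0] = std::max(vv / std::max(n - 1, 1), 1e-6);
    va[0] = std::max(0.1 * ve[0], 1e-8);
  } else if (response == 1) {
    for (int i = 0; i < n; ++i) {
      ystar[0][i] = (y[i] > 0.5) ? 0.5 : -0.5;
      r[0][i] = ystar[0][i];
    }
  } else {
    for (int i = 0; i < n; ++i) {
      int c = (int) y[i];
      ystar[0][i] = (c == 1) ? 0.5 : -0.5;
      ystar[1][i] = (c == 2) ? 0.5 : -0.5;
      r[0][i] = ystar[0][i];
      r[1][i] = ystar[1][i];
    }
  }

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  const int n_par = D * (p + (has_anim ? 1 : 0) + K + 1);
  NumericMatrix draws(n_keep, n_par);
  NumericVector dev_draws(n_keep);
  NumericMatrix eta_mean(n, D);   // standardized for threshold models
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- latent data augmentation ---
    if (response == 1) {
      double sd0 = std::sqrt(ve_eff(0));
      for (int i = 0; i < n; ++i) {
        double eta = ystar[0][i] - r[0][i];
        double neu = (y[i] > 0.5) ? rtnorm_lower(eta, sd0, 0.0)
                                  : rtnorm_upper(eta, sd0, 0.0);
        r[0][i] += neu - ystar[0][i];
        ystar[0][i] = neu;
      }
    } else if (response == 2) {
      double sd1 = std::sqrt(ve_eff(0)), sd2 = std::sqrt(ve_eff(1));
      for (int i = 0; i < n; ++i) {
        int c = (int) y[i];
        double eta1 = ystar[0][i] - r[0][i];
        double eta2 = ystar[1][i] - r[1][i];
        double w1 = ystar[0][i], w2 = ystar[1][i];
        if (c == 0) {
          w1 = rtnorm_upper(eta1, sd1, 0.0);
          w2 = rtnorm_upper(eta2, sd2, 0.0);
        } else if (c == 1) {
          w1 = rtnorm_lower(eta1, sd1, std::max(0.0, w2));
          w2 = rtnorm_upper(eta2, sd2, w1);
        } else {
          w1 = rtnorm_upper(eta1, sd1, w2);
          w2 = rtnorm_lower(eta2, sd2, std::max(0.0, w1));
        }
        r[0][i] += w1 - ystar[0][i]; ystar[0][i] = w1;
        r[1][i] += w2 - ystar[1][i]; ystar[1][i] = w2;
      }
    }

    for (int d = 0; d < D; ++d) {
      double ved = ve_eff(d);
      // --- fixed effects ---
      for (int j = 0; j < p; ++j) {
        double old = beta[d][j];
        double sxr = 0.0;
        for (int i = 0; i < n; ++i) sxr += X(i, j) * (r[d][i] + X(i, j) * old);
        double prec = xtx[j] / ved + 1.0 / prior_fixed_var;
        double mean = (sxr / ved) / prec;
        double neu = mean + R::norm_rand() / std::sqrt(prec);
        double delta = neu - old;
        for (int i = 0; i < n; ++i) r[d][i] -= X(i, j) * delta;
        beta[d][j] = neu;
      }

      // --- additive genetic term ---
      if (has_anim) {
        std::vector<double> sres(q, 0.0);
        for (int i = 0; i < n; ++i) sres[anim_index[i]] += r[d][i];
        std::vector<double> dban(q, 0.0);
        for (int j = 0; j < rr; ++j) {
          double old = zg[d][j];
          double sgr = 0.0;
          for (int l = 0; l < q; ++l) sgr += G(l, j) * sres[l];
          sgr += old * gj2[j];
          double prec = gj2[j] / ved + 1.0 / va[d];
          double mean = (sgr / ved) / prec;
          double neu = mean + R::norm_rand() / std::sqrt(prec);
          double delta = neu - old;
          zg[d][j] = neu;
          for (int l = 0; l < q; ++l) {
            double dl = G(l, j) * delta;
            sres[l] -= an_n[l] * dl;
            dban[l] += dl;
          }
        }
        for (int l = 0; l < q; ++l) banim[d][l] += dban[l];
        for (int i = 0; i < n; ++i) r[d][i] -= dban[anim_index[i]];

        // Va, sufficient side (z held fixed); for the threshold models the
        // marginalized remainder keeps Va in the residual variance too
        double Sz = 0.0;
        for (int j = 0; j < rr; ++j) Sz += zg[d][j] * zg[d][j];
        double SSE = 0.0;
        for (int i = 0; i < n; ++i) SSE += r[d][i] * r[d][i];
        {
          auto logp = [&](double th) -> double {
            double s2v = std::exp(th);
            double base = gaussian ? ve[0] : 1.0;
            double vr = base + c_split * s2v;
            return prior_log(th) - 0.5 * rr * th - 0.5 * Sz / s2v
              - 0.5 * n * std::log(vr) - 0.5 * SSE / vr;
          };
          va[d] = std::exp(slice_logvar(std::log(va[d]), logp));
        }
        // Va, ancillary side: rescale the genetic values holding a/sd fixed
        {
          double sig_old = std::sqrt(va[d]);
          double S0 = 0.0, S1 = 0.0, S2c = 0.0;
          for (int i = 0; i < n; ++i) {
            double bi = banim[d][anim_index[i]];
            double r0 = r[d][i] + bi;
            double c = bi / sig_old;
            S0 += r0 * r0;
            S1 += r0 * c;
            S2c += c * c;
          }
          auto logp = [&](double th) -> double {
            double sg = std::exp(0.5 * th);
            double base = gaussian ? ve[0] : 1.0;
            double vr = base + c_split * std::exp(th);
            double sse = S0 - 2.0 * sg * S1 + sg * sg * S2c;
            return prior_log(th) - 0.5 * sse / vr - 0.5 * n * std::log(vr);
          };
          double th1 = slice_logvar(std::log(va[d]), logp);
          double scale = std::exp(0.5 * th1) / sig_old;
          if (scale != 1.0) {
            for (int j = 0; j < rr; ++j) zg[d][j] *= scale;
            for (int l = 0; l < q; ++l) banim[d][l] *= scale;
            for (int i = 0; i < n; ++i)
              r[d][i] -= (scale - 1.0) / scale * banim[d][anim_index[i]];
            va[d] = std::exp(th1);
          }
        }
        ved = ve_eff(d);
      }

      // --- iid random terms ---
      for (int k = 0; k < K; ++k) {
        std::vector<double>& uk = u[d][k];
        std::vector<double> sres(nlev[k], 0.0);
        for (int i = 0; i < n; ++i) sres[zi[k][i]] += r[d][i];
        std::vector<double> delta(nlev[k]);
        for (int l = 0; l < nlev[k]; ++l) {
          double add_back = sres[l] + lev_n[k][l] * uk[l];
          double prec = lev_n[k][l] / ved + 1.0 / s2[d][k];
          double mean = (add_back / ved) / prec;
          double neu = mean + R::norm_rand() / std::sqrt(prec);
          delta[l] = neu - uk[l];
          uk[l] = neu;
        }
        for (int i = 0; i < n; ++i) r[d][i] -= delta[zi[k][i]];
        double ss = 0.0;
        for (int l = 0; l < nlev[k]; ++l) ss += uk[l] * uk[l];
        {
          auto logp = [&](double th) -> double {
            return prior_log(th) - 0.5 * nlev[k] * th -
              0.5 * ss / std::exp(th);
          };
          s2[d][k] = std::exp(slice_logvar(std::log(s2[d][k]), logp));
        }
        // ancillary-side rescale (interweaving)
        if (ss > 0) {
          double sig_old = std::sqrt(s2[d][k]);
          double S0 = 0.0, S1 = 0.0, S2c = 0.0;
          for (int i = 0; i < n; ++i) {
            double ui = uk[zi[k][i]];
            double r0 = r[d][i] + ui;
            double c = ui / sig_old;
            S0 += r0 * r0;
            S1 += r0 * c;
            S2c += c * c;
          }
          auto logp = [&](double th) -> double {
            double sg = std::exp(0.5 * th);
            double sse = S0 - 2.0 * sg * S1 + sg * sg * S2c;
            return prior_log(th) - 0.5 * sse / ved;
          };
          double th1 = slice_logvar(std::log(s2[d][k]), logp);
          double scale = std::exp(0.5 * th1) / sig_old;
          if (scale != 1.0) {
            for (int l = 0; l < nlev[k]; ++l) uk[l] *= scale;
            for (int i = 0; i < n; ++i)
              r[d][i] -= (scale - 1.0) / scale * uk[zi[k][i]];
            s2[d][k] = std::exp(th1);
          }
        }
      }

      // --- gaussian environmental residual variance ---
      if (gaussian) {
        double ss = 0.0;
        for (int i = 0; i < n; ++i) ss += r[d][i] * r[d][i];
        double cva = has_anim ? c_split * va[d] : 0.0;
        if (cva == 0.0) {
          ve[d] = rinvgamma(0.001 + 0.5 * n, 0.001 + 0.5 * ss);
        } else {
          auto logp = [&](double th) -> double {
            double vr = std::exp(th) + cva;
            return -0.001 * th - 0.001 / std::exp(th)
              - 0.5 * n * std::log(vr) - 0.5 * ss / vr;
          };
          ve[d] = std::exp(slice_logvar(std::log(ve[d]), logp));
        }
      }
    }

    // --- record ---
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      int col = 0;
      for (int d = 0; d < D; ++d) {
        for (int j = 0; j < p; ++j) draws(kept, col++) = beta[d][j];
        if (has_anim) draws(kept, col++) = va[d];
        for (int k = 0; k < K; ++k) draws(kept, col++) = s2[d][k];
        draws(kept, col++) = gaussian ? ve[d] : 1.0;
      }
      double dev = 0.0;
      if (gaussian) {
        double sd0 = std::sqrt(ve_eff(0));
        for (int i = 0; i < n; ++i) {
          double eta = ystar[0][i] - r[0][i];
          dev += -2.0 * R::dnorm(y[i], eta, sd0, 1);
          eta_mean(i, 0) += eta;
        }
      } else if (response == 1) {
        double sd0 = std::sqrt(ve_eff(0));
        for (int i = 0; i < n; ++i) {
          double eta = (ystar[0][i] - r[0][i]) / sd0;
          double pr = R::pnorm(eta, 0.0, 1.0, 1, 0);
          pr = std::min(std::max(pr, 1e-12), 1.0 - 1e-12);
          dev += -2.0 * ((y[i] > 0.5) ? std::log(pr) : std::log(1.0 - pr));
          eta_mean(i, 0) += eta;
        }
      } else {
        double sd1 = std::sqrt(ve_eff(0)), sd2 = std::sqrt(ve_eff(1));
        for (int i = 0; i < n; ++i) {
          double eta1 = (ystar[0][i] - r[0][i]) / sd1;
          double eta2 = (ystar[1][i] - r[1][i]) / sd2;
          int c = (int) y[i];
          double pr;
          if (c == 0) {
            pr = R::pnorm(-eta1, 0.0, 1.0, 1, 0) *
                 R::pnorm(-eta2, 0.0, 1.0, 1, 0);
          } else if (c == 1) {
            pr = cat_tail_prob(eta1, eta2, gx, gw);
          } else {
            pr = cat_tail_prob(eta2, eta1, gx, gw);
          }
          pr = std::min(std::max(pr, 1e-12), 1.0 - 1e-12);
          dev += -2.0 * std::log(pr);
          eta_mean(i, 0) += eta1;
          eta_mean(i, 1) += eta2;
        }
      }
      dev_draws[kept] = dev;
      ++kept;
    }
  }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < D; ++d) eta_mean(i, d) /= std::max(kept, 1);

  return List::create(_["draws"] = draws, _["deviance"] = dev_draws,
                      _["eta_mean"] = eta_mean, _["n_kept"] = kept);
}
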