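// Gibbs sampler core for the terminal-cross mixed model.
//
// The coefficient matrix is represented once as a union sparsity pattern
// (CSC, full symmetric storage) plus one value vector per variance
// component; per iteration the current matrix is the weighted sum of the
// components.  Location effects are sampled single-site from their scalar
// normal conditionals (a Gauss-Seidel-style sweep); variance components
// from their scaled inverse-chi-square / inverse-Wishart conditionals
// under flat priors.  All randomness comes from R's RNG, so set.seed()
// in R makes chains reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// role codes, must match .ROLE_CODES in R/mme.R
enum Role { R_EA = 0, R_EC = 1, R_G11 = 2, R_G12 = 3, R_G22 = 4,
            R_BC = 5, R_PA = 6, R_PC = 7, R_GA = 8, R_GAC = 9 };

struct VC {
  double s2A, sAAC, s2AC, s2BC, s2pA, s2pC, s2eA, s2eC;
};

static void role_weights(const IntegerVector& roles, const VC& v,
                         std::vector<double>& w) {
  double det = v.s2A * v.s2AC - v.sAAC * v.sAAC;
  double g0i11 = v.s2AC / det, g0i12 = -v.sAAC / det, g0i22 = v.s2A / det;
  for (int k = 0; k < roles.size(); ++k) {
    switch (roles[k]) {
      case R_EA:  w[k] = 1.0 / v.s2eA; break;
      case R_EC:  w[k] = 1.0 / v.s2eC; break;
      case R_G11: w[k] = g0i11; break;
      case R_G12: w[k] = g0i12; break;
      case R_G22: w[k] = g0i22; break;
      case R_BC:  w[k] = 1.0 / v.s2BC; break;
      case R_PA:  w[k] = 1.0 / v.s2pA; break;
      case R_PC:  w[k] = 1.0 / v.s2pC; break;
      case R_GA:  w[k] = 1.0 / v.s2A; break;
      case R_GAC: w[k] = 1.0 / v.s2AC; break;
      default: stop("unknown role code");
    }
  }
}

// quadratic form u' K v for symmetric K in CSC (full storage)
static double quad(const IntegerVector& Kp, const IntegerVector& Ki,
                   const NumericVector& Kx, const std::vector<double>& u,
                   const std::vector<double>& v) {
  double s = 0.0;
  int n = Kp.size() - 1;
  for (int j = 0; j < n; ++j) {
    double vj = v[j];
    if (vj == 0.0) {
      // still need u side; cannot skip because u[i]*K*v[j] uses v[j] only
      continue;
    }
    for (int k = Kp[j]; k < Kp[j + 1]; ++k) s += Kx[k] * u[Ki[k]] * vj;
  }
  return s;
}

// residual sum of squares y - M theta for CSC M (records x n)
static double rss(const IntegerVector& Mp, const IntegerVector& Mi,
                  const NumericVector& Mx, const NumericVector& y,
                  const std::vector<double>& theta, int nrec) {
  std::vector<double> e(nrec);
  for (int r = 0; r < nrec; ++r) e[r] = y[r];
  int n = Mp.size() - 1;
  for (int j = 0; j < n; ++j) {
    double tj = theta[j];
    if (tj == 0.0) continue;
    for (int k = Mp[j]; k < Mp[j + 1]; ++k) e[Mi[k]] -= Mx[k] * tj;
  }
  double s = 0.0;
  for (int r = 0; r < nrec; ++r) s += e[r] * e[r];
  return s;
}

static double draw_scalar_var(double scale, int df) {
  if (df < 1) stop("variance conditional has df < 1");
  return scale / R::rchisq((double) df);
}

// G0 ~ IW_2(nu, S): draw W ~ Wishart_2(nu, S^-1) by Bartlett, invert.
static void draw_iw2(double S11, double S12, double S22, int nu,
                     double& g11, double& g12, double& g22) {
  if (nu < 2) stop("inverse-Wishart conditional has nu < 2");
  double det = S11 * S22 - S12 * S12;
  if (det <= 0 || S11 <= 0) {
    // numerical guard: jitter the scale matrix
    S11 += 1e-12; S22 += 1e-12;
    det = S11 * S22 - S12 * S12;
    if (det <= 0) stop("singular scale matrix in G0 conditional");
  }
  double si11 = S22 / det, si12 = -S12 / det, si22 = S11 / det;
  double l11 = std::sqrt(si11);
  double l21 = si12 / l11;
  double l22 = std::sqrt(si22 - l21 * l21);
  for (int tries = 0; tries < 20; ++tries) {
    double c11 = std::sqrt(R::rchisq((double) nu));
    double c22 = std::sqrt(R::rchisq((double) (nu - 1)));
    double c21 = norm_rand();
    // T = L * A (both lower triangular)
    double t11 = l11 * c11;
    double t21 = l21 * c11 + l22 * c21;
    double t22 = l22 * c22;
    double w11 = t11 * t11;
    double w12 = t11 * t21;
    double w22 = t21 * t21 + t22 * t22;
    double dw = w11 * w22 - w12 * w12;
    if (dw > 0 && w11 > 0) {
      g11 = w22 / dw; g12 = -w12 / dw; g22 = w11 / dw;
      if (g11 > 0 && g22 > 0 && g11 * g22 - g12 * g12 > 0) return;
    }
  }
  stop("could not draw a positive definite G0 after 20 attempts");
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(int n,
                IntegerVector Pp, IntegerVector Pi, NumericMatrix V,
                IntegerVector roles,
                NumericVector rA, NumericVector rC,
                List MA, NumericVector yA,
                List MC, NumericVector yC,
                List KA, IntegerVector idx_uAA, IntegerVector idx_uAC,
                List KB, IntegerVector idx_uBC,
                IntegerVector idx_penA, IntegerVector idx_penC,
                List cfg) {
  int niter  = as<int>(cfg["iterations"]);
  int burnin = as<int>(cfg["burn_in"]);
  int thin   = as<int>(cfg["thin"]);
  int mode   = as<int>(cfg["mode"]);     // 0 bivariate, 1 uni PB, 2 uni CB
  int dfoff_s = as<int>(cfg["dfoff_scalar"]);
  int dfoff_w = as<int>(cfg["dfoff_wishart"]);
  bool s_loc = as<bool>(cfg["sample_location"]);
  bool s_g0  = as<bool>(cfg["sample_genetic"]);
  bool s_bc  = as<bool>(cfg["sample_bc"]);
  bool s_pA  = as<bool>(cfg["sample_pen_a"]);
  bool s_pC  = as<bool>(cfg["sample_pen_c"]);
  bool s_eA  = as<bool>(cfg["sample_resid_a"]);
  bool s_eC  = as<bool>(cfg["sample_resid_c"]);
  NumericVector start = as<NumericVector>(cfg["start"]);

  VC vc;
  vc.s2A = start[0]; vc.sAAC = start[1]; vc.s2AC = start[2];
  vc.s2BC = start[3]; vc.s2pA = start[4]; vc.s2pC = start[5];
  vc.s2eA = start[6]; vc.s2eC = start[7];
  if (vc.s2pA <= 0) vc.s2pA = 1e-300;
  if (vc.s2pC <= 0) vc.s2pC = 1e-300;

  std::vector<double> theta(n, 0.0);
  if (cfg.containsElementNamed("theta_start") &&
      !Rf_isNull(cfg["theta_start"])) {
    NumericVector th = as<NumericVector>(cfg["theta_start"]);
    if (th.size() != n) stop("theta_start has wrong length");
    for (int i = 0; i < n; ++i) theta[i] = th[i];
  }

  IntegerVector MAp = MA["p"], MAi = MA["i"];
  NumericVector MAx = MA["x"];
  int nrecA = as<int>(MA["nrow"]);
  IntegerVector MCp = MC["p"], MCi = MC["i"];
  NumericVector MCx = MC["x"];
  int nrecC = as<int>(MC["nrow"]);

  bool hasKA = KA.size() > 0;
  IntegerVector KAp, KAi; NumericVector KAx;
  if (hasKA) { KAp = KA["p"]; KAi = KA["i"]; KAx = KA["x"]; }
  bool hasKB = KB.size() > 0;
  IntegerVector KBp, KBi; NumericVector KBx;
  if (hasKB) { KBp = KB["p"]; KBi = KB["i"]; KBx = KB["x"]; }

  int nA = std::max(idx_uAA.size(), idx_uAC.size());
  int nB = idx_uBC.size();
  int nnz = Pi.size();
  int K = roles.size();
  std::vector<double> w(K), cval(nnz);

  // Pair partner map for joint (u_AA, u_AC) updates in the bivariate
  // model: sampling each animal's two genetic effects from their 2x2
  // bivariate conditional keeps the inverse-Wishart scale matrix full
  // rank (single-site updates let it degenerate when most animals carry
  // prior-only information).
  std::vector<int> partner(n, -1);
  bool pair_blocks = (mode == 0) &&
    idx_uAA.size() == idx_uAC.size() && idx_uAA.size() > 0;
  if (pair_blocks) {
    for (int a = 0; a < idx_uAA.size(); ++a) {
      int j1 = idx_uAA[a] - 1, j2 = idx_uAC[a] - 1;
      partner[j1] = j2;
      partner[j2] = -2;  // handled together with its pair
    }
  }

  int nsave = 0;
  for (int it = 1; it <= niter; ++it) {
    if (it > burnin && (it - burnin) % thin == 0) ++nsave;
  }
  NumericMatrix draws(nsave, 8);
  IntegerVector stamps(nsave);
  NumericVector theta_mean(n);
  int nmean = 0;

  std::vector<double> uAA(nA), uAC(nA), uBC(nB);

  int isave = 0;
  for (int it = 1; it <= niter; ++it) {
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
    // ---- location effects ------------------------------------------
    if (s_loc) {
      role_weights(roles, vc, w);
      // current coefficient values: cval = V %*% w, streamed column-wise
      const double* Vp = REAL(V);
      std::fill(cval.begin(), cval.end(), 0.0);
      for (int k = 0; k < K; ++k) {
        const double wk = w[k];
        const double* col = Vp + (size_t) k * nnz;
        double* cv = cval.data();
        for (int z = 0; z < nnz; ++z) cv[z] += col[z] * wk;
      }
      const int* pp = INTEGER(Pp);
      const int* pi = INTEGER(Pi);
      const double* cv = cval.data();
      const double* ra = REAL(rA);
      const double* rc = REAL(rC);
      double* th = theta.data();
      double weA = 1.0 / vc.s2eA, weC = 1.0 / vc.s2eC;
      for (int j = 0; j < n; ++j) {
        int j2 = partner[j];
        if (j2 == -2) continue;  // sampled jointly with its uAA partner
        if (j2 < 0) {
          // singleton equation: scalar normal conditional
          double rj = ra[j] * weA + rc[j] * weC;
          double d = 0.0, s = 0.0;
          for (int k = pp[j]; k < pp[j + 1]; ++k) {
            int i = pi[k];
            if (i == j) d = cv[k];
            else s += cv[k] * th[i];
          }
          if (d <= 0)
            stop("non-positive diagonal in MME at equation %d", j + 1);
          th[j] = (rj - s) / d + norm_rand() / std::sqrt(d);
        } else {
          // joint 2x2 conditional for the animal's (u_AA, u_AC) pair
          double r1 = ra[j] * weA + rc[j] * weC;
          double r2 = ra[j2] * weA + rc[j2] * weC;
          double d11 = 0.0, d12 = 0.0, d22 = 0.0, s1 = 0.0, s2 = 0.0;
          for (int k = pp[j]; k < pp[j + 1]; ++k) {
            int i = pi[k];
            if (i == j) d11 = cv[k];
            else if (i == j2) d12 = cv[k];
            else s1 += cv[k] * th[i];
          }
          for (int k = pp[j2]; k < pp[j2 + 1]; ++k) {
            int i = pi[k];
            if (i == j2) d22 = cv[k];
            else if (i == j) { /* symmetric d12, already taken */ }
            else s2 += cv[k] * th[i];
          }
          if (d11 <= 0 || d22 <= 0)
            stop("non-positive diagonal in MME at equation %d", j + 1);
          double b1 = r1 - s1, b2 = r2 - s2;
          // Cholesky of the 2x2 precision block; if it is numerically
          // semidefinite (near-singular G0 draw in the burn-in), fall
          // back to two scalar conditional updates (also valid Gibbs).
          double l11 = std::sqrt(d11);
          double l21 = d12 / l11;
          double t22 = d22 - l21 * l21;
          if (t22 > 1e-12 * d22) {
            double l22 = std::sqrt(t22);
            // mean: solve L (L' m) = b
            double c1 = b1 / l11;
            double c2 = (b2 - l21 * c1) / l22;
            double m2 = c2 / l22;
            double m1 = (c1 - l21 * m2) / l11;
            double z1 = norm_rand(), z2 = norm_rand();
            double x2 = z2 / l22;
            double x1 = (z1 - l21 * x2) / l11;
            th[j] = m1 + x1;
            th[j2] = m2 + x2;
          } else {
            th[j] = (b1 - d12 * th[j2]) / d11 +
              norm_rand() / std::sqrt(d11);
            th[j2] = (b2 - d12 * th[j]) / d22 +
              norm_rand() / std::sqrt(d22);
          }
        }
      }
    }

    // ---- genetic (co)variances -------------------------------------
    if (hasKA && idx_uAA.size() > 0) {
      for (int i = 0; i < idx_uAA.size(); ++i) uAA[i] = theta[idx_uAA[i] - 1];
    }
    if (hasKA && idx_uAC.size() > 0) {
      for (int i = 0; i < idx_uAC.size(); ++i) uAC[i] = theta[idx_uAC[i] - 1];
    }
    if (s_g0) {
      if (mode == 0) {
        double S11 = quad(KAp, KAi, KAx, uAA, uAA);
        double S12 = quad(KAp, KAi, KAx, uAA, uAC);
        double S22 = quad(KAp, KAi, KAx, uAC, uAC);
        draw_iw2(S11, S12, S22, nA - dfoff_w, vc.s2A, vc.sAAC, vc.s2AC);
      } else if (mode == 1) {
        double S11 = quad(KAp, KAi, KAx, uAA, uAA);
        vc.s2A = draw_scalar_var(S11, nA - dfoff_s);
      } else {
        double S22 = quad(KAp, KAi, KAx, uAC, uAC);
        vc.s2AC = draw_scalar_var(S22, nA - dfoff_s);
      }
    }
    if (s_bc && hasKB && nB > 0) {
      for (int i = 0; i < nB; ++i) uBC[i] = theta[idx_uBC[i] - 1];
      double S = quad(KBp, KBi, KBx, uBC, uBC);
      vc.s2BC = draw_scalar_var(S, nB - dfoff_s);
    }
    if (s_pA && idx_penA.size() > 0) {
      double S = 0.0;
      for (int i = 0; i < idx_penA.size(); ++i) {
        double t = theta[idx_penA[i] - 1];
        S += t * t;
      }
      vc.s2pA = draw_scalar_var(S, idx_penA.size() - dfoff_s);
    }
    if (s_pC && idx_penC.size() > 0) {
      double S = 0.0;
      for (int i = 0; i < idx_penC.size(); ++i) {
        double t = theta[idx_penC[i] - 1];
        S += t * t;
      }
      vc.s2pC = draw_scalar_var(S, idx_penC.size() - dfoff_s);
    }
    if (s_eA && nrecA > 0) {
      double S = rss(MAp, MAi, MAx, yA, theta, nrecA);
      vc.s2eA = draw_scalar_var(S, nrecA - dfoff_s);
    }
    if (s_eC && nrecC > 0) {
      double S = rss(MCp, MCi, MCx, yC, theta, nrecC);
      vc.s2eC = draw_scalar_var(S, nrecC - dfoff_s);
    }

    // ---- save -------------------------------------------------------
    if (it > burnin) {
      for (int i = 0; i < n; ++i) theta_mean[i] += theta[i];
      ++nmean;
      if ((it - burnin) % thin == 0) {
        draws(isave, 0) = vc.s2A;  draws(isave, 1) = vc.sAAC;
        draws(isave, 2) = vc.s2AC; draws(isave, 3) = vc.s2BC;
        draws(isave, 4) = vc.s2pA; draws(isave, 5) = vc.s2pC;
        draws(isave, 6) = vc.s2eA; draws(isave, 7) = vc.s2eC;
        stamps[isave] = it;
        ++isave;
      }
    }
  }
  if (nmean > 0) {
    for (int i = 0; i < n; ++i) theta_mean[i] /= nmean;
  }
  colnames(draws) = CharacterVector::create(
    "s2A", "sAAC", "s2AC", "s2BC", "s2pA", "s2pC", "s2eA", "s2eC");
  return List::create(_["draws"] = draws, _["iteration"] = stamps,
                      _["theta_mean"] = theta_mean);
}
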