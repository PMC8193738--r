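// Hyperelastic constitutive point evaluations: energy density W, second
// Piola-Kirchhoff stress S = 2 dW/dC, and the material tangent CC = 2 dS/dC
// (full 3x3x3x3, minor-symmetric). Isochoric split F_bar = J^(-1/3) F is
// applied to both deviatoric invariants and fibre pseudo-invariants.
//
// Material types:
//   0  St. Venant-Kirchhoff (linear elastic in a total-Lagrangian setting):
//      par = (E, nu)
//   1  Mooney-Rivlin + volumetric: par = (C10, C01, K)
//   2  Gasser-Ogden-Holzapfel, two discrete fibre families (kappa = 0),
//      tension-only fibres via Macaulay bracket: par = (C10, k1, k2, K),
//      fib = 3x2 matrix of unit reference fibre directions
//
// Volumetric forms: 0 -> U = K/2 (J-1)^2 ; 1 -> U = K/4 (J^2-1) - K/2 ln J

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int T4(int i, int j, int k, int l) {
  return ((i * 3 + j) * 3 + k) * 3 + l;
}

// Evaluate one material point. CC must have length 81.
void material_point(const mat& F, int type, const vec& par, const mat& fib,
                    int volform, double& W, mat& S, double* CC,
                    bool want_tangent) {
  const double J = det(F);
  if (J <= 0.0)
    Rcpp::stop("non-positive Jacobian det(F) = %f", J);
  const mat I3 = eye(3, 3);
  std::fill(CC, CC + 81, 0.0);

  if (type == 0) {  // St. Venant-Kirchhoff
    const double E = par[0], nu = par[1];
    const double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
    const double mu = E / (2.0 * (1.0 + nu));
    mat C = F.t() * F;
    mat Egl = 0.5 * (C - I3);
    double trE = trace(Egl);
    S = lam * trE * I3 + 2.0 * mu * Egl;
    W = 0.5 * lam * trE * trE + mu * accu(Egl % Egl);
    if (want_tangent) {
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          for (int k = 0; k < 3; ++k)
            for (int l = 0; l < 3; ++l)
              CC[T4(i, j, k, l)] =
                  lam * (i == j) * (k == l) +
                  mu * ((i == k) * (j == l) + (i == l) * (j == k));
    }
    return;
  }

  // isochoric hyperelastic families
  mat C = F.t() * F;
  mat Cinv = inv(C);
  const double J23 = std::pow(J, -2.0 / 3.0);
  mat Cbar = J23 * C;
  const double Ib1 = trace(Cbar);

  double K, Wbar;
  mat Stilde(3, 3, fill::zeros);
  double Ct[81];  // Ctilde = 4 d2Wbar/dCbar2
  std::fill(Ct, Ct + 81, 0.0);
  bool has_ct = false;

  if (type == 1) {  // Mooney-Rivlin
    const double C10 = par[0], C01 = par[1];
    K = par[2];
    const double Ib2 = 0.5 * (Ib1 * Ib1 - trace(Cbar * Cbar));
    Wbar = C10 * (Ib1 - 3.0) + C01 * (Ib2 - 3.0);
    Stilde = 2.0 * (C10 + C01 * Ib1) * I3 - 2.0 * C01 * Cbar;
    if (want_tangent && C01 != 0.0) {
      has_ct = true;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          for (int k = 0; k < 3; ++k)
            for (int l = 0; l < 3; ++l)
              Ct[T4(i, j, k, l)] =
                  4.0 * C01 *
                  ((i == j) * (k == l) -
                   0.5 * ((i == k) * (j == l) + (i == l) * (j == k)));
    }
  } else if (type == 2) {  // GOH
    const double C10 = par[0], k1 = par[1], k2 = par[2];
    K = par[3];
    Wbar = C10 * (Ib1 - 3.0);
    Stilde = 2.0 * C10 * I3;
    for (unsigned int f = 0; f < fib.n_cols; ++f) {
      vec a = fib.col(f);
      double I4 = as_scalar(a.t() * Cbar * a);
      double h = I4 - 1.0;
      if (h > 0.0) {  // Macaulay bracket: compressed fibres carry no load
        double ex = std::exp(k2 * h * h);
        double psi4 = k1 * h * ex;
        Wbar += k1 / (2.0 * k2) * (ex - 1.0);
        mat A = a * a.t();
        Stilde += 2.0 * psi4 * A;
        if (want_tangent) {
          has_ct = true;
          double psi44 = k1 * (1.0 + 2.0 * k2 * h * h) * ex;
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j)
              for (int k = 0; k < 3; ++k)
                for (int l = 0; l < 3; ++l)
                  Ct[T4(i, j, k, l)] += 4.0 * psi44 * A(i, j) * A(k, l);
        }
      }
    }
  } else {
    Rcpp::stop("unknown material type %d", type);
  }

  // volumetric part
  double U, Up, Upp;
  if (volform == 0) {
    U = 0.5 * K * (J - 1.0) * (J - 1.0);
    Up = K * (J - 1.0);
    Upp = K;
  } else {
    U = 0.25 * K * (J * J - 1.0) - 0.5 * K * std::log(J);
    Up = 0.5 * K * (J - 1.0 / J);
    Upp = 0.5 * K * (1.0 + 1.0 / (J * J));
  }

  mat Sbar = J23 * Stilde;
  const double trSbarC = accu(Sbar % C);
  mat Siso = Sbar - (trSbarC / 3.0) * Cinv;
  S = Siso + J * Up * Cinv;
  W = Wbar + U;

  if (!want_tangent) return;

  // CC_vol
  const double c1 = J * Up + J * J * Upp;
  const double c2 = 2.0 * J * Up;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l) {
          double ICinv =
              0.5 * (Cinv(i, k) * Cinv(j, l) + Cinv(i, l) * Cinv(j, k));
          CC[T4(i, j, k, l)] = c1 * Cinv(i, j) * Cinv(k, l) - c2 * ICinv;
        }

  // CC_iso = P : Cbar4 : P^T + (2/3) (Sbar:C) Ptilde
  //          - (2/3)(Cinv x Siso + Siso x Cinv)
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l) {
          double ICinv =
              0.5 * (Cinv(i, k) * Cinv(j, l) + Cinv(i, l) * Cinv(j, k));
          double Ptil = ICinv - Cinv(i, j) * Cinv(k, l) / 3.0;
          CC[T4(i, j, k, l)] +=
              (2.0 / 3.0) * trSbarC * Ptil -
              (2.0 / 3.0) * (Cinv(i, j) * Siso(k, l) + Siso(i, j) * Cinv(k, l));
        }

  if (has_ct) {
    // Cbar4 = J23^2 * Ct ; project: P_ijmn Cbar4_mnop P_klop
    const double J43 = J23 * J23;
    double E1[81];
    // P_ijmn = Isym_ijmn - (1/3) Cinv_ij C_mn
    // E1_ijop = sum_mn P_ijmn Cbar4_mnop
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int o = 0; o < 3; ++o)
          for (int p = 0; p < 3; ++p) {
            double s = 0.0;
            for (int m = 0; m < 3; ++m)
              for (int n = 0; n < 3; ++n) {
                double P = 0.5 * ((i == m) * (j == n) + (i == n) * (j == m)) -
                           Cinv(i, j) * C(m, n) / 3.0;
                s += P * J43 * Ct[T4(m, n, o, p)];
              }
            E1[T4(i, j, o, p)] = s;
          }
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l) {
            double s = 0.0;
            for (int o = 0; o < 3; ++o)
              for (int p = 0; p < 3; ++p) {
                double P = 0.5 * ((k == o) * (l == p) + (k == p) * (l == o)) -
                           Cinv(k, l) * C(o, p) / 3.0;
                s += E1[T4(i, j, o, p)] * P;
              }
            CC[T4(i, j, k, l)] += s;
          }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_material_eval(const arma::mat& F, int type, const arma::vec& par,
                             const arma::mat& fib, int volform) {
  double W;
  mat S(3, 3);
  double CC[81];
  material_point(F, type, par, fib, volform, W, S, CC, true);
  const double J = det(F);
  mat P = F * S;
  mat cauchy = P * F.t() / J;
  // A_{iI,jJ} = d P_iI / d F_jJ = delta_ij S_IJ + F_iM CC_{MIJQ} F_jQ
  // flattened column-major: row = i + 3 I, col = j + 3 J  (0-based)
  mat A(9, 9);
  for (int i = 0; i < 3; ++i)
    for (int I = 0; I < 3; ++I)
      for (int j = 0; j < 3; ++j)
        for (int J2 = 0; J2 < 3; ++J2) {
          double s = (i == j) ? S(I, J2) : 0.0;
          for (int M = 0; M < 3; ++M)
            for (int Q = 0; Q < 3; ++Q)
              s += F(i, M) * CC[T4(M, I, J2, Q)] * F(j, Q);
          A(i + 3 * I, j + 3 * J2) = s;
        }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("S") = S,
                            Rcpp::Named("P") = P,
                            Rcpp::Named("cauchy") = cauchy,
                            Rcpp::Named("A") = A);
}

// Total-Lagrangian assembly over a linear-tet mesh (one-point quadrature).
// nodes: N x 3 reference coordinates (mm); elems: E x 4, 0-based node ids;
// u: N x 3 nodal displacements; mtype: E; mpar: E x 4; mfib: E x 6 (two
// reference fibre directions per element, zero rows where unused).
// Returns internal force (3N), stiffness triplets (1-based dof = 3*node+comp),
// total strain energy and min det(F).
// [[Rcpp::export]]
Rcpp::List cpp_assemble(const arma::mat& nodes, const arma::imat& elems,
                        const arma::mat& u, const arma::ivec& mtype,
                        const arma::mat& mpar, const arma::mat& mfib,
                        int volform, bool want_stiffness) {
  const int ne = elems.n_rows;
  const int nn = nodes.n_rows;
  vec fint(3 * nn, fill::zeros);
  double energy = 0.0, min_detF = datum::inf;

  arma::uvec Ki, Kj;
  arma::vec Kx;
  if (want_stiffness) {
    Ki.set_size((size_t)ne * 144);
    Kj.set_size((size_t)ne * 144);
    Kx.set_size((size_t)ne * 144);
  }

  double CC[81];
  for (int e = 0; e < ne; ++e) {
    int n0 = elems(e, 0), n1 = elems(e, 1), n2 = elems(e, 2), n3 = elems(e, 3);
    mat Dm(3, 3);
    for (int c = 0; c < 3; ++c) {
      Dm(c, 0) = nodes(n1, c) - nodes(n0, c);
      Dm(c, 1) = nodes(n2, c) - nodes(n0, c);
      Dm(c, 2) = nodes(n3, c) - nodes(n0, c);
    }
    double V6 = det(Dm);
    if (V6 <= 0.0) Rcpp::stop("inverted reference element %d", e + 1);
    double V0 = V6 / 6.0;
    mat Dminv = inv(Dm);
    // shape gradients G (4 x 3): rows a, cols I; G_a = dN_a/dX
    mat G(4, 3);
    for (int I = 0; I < 3; ++I) {
      G(1, I) = Dminv(0, I);
      G(2, I) = Dminv(1, I);
      G(3, I) = Dminv(2, I);
      G(0, I) = -(G(1, I) + G(2, I) + G(3, I));
    }
    // F = I + sum_a u_a (x) G_a
    mat F = eye(3, 3);
    int en[4] = {n0, n1, n2, n3};
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        for (int I = 0; I < 3; ++I) F(i, I) += u(en[a], i) * G(a, I);
    double dF = det(F);
    if (dF < min_detF) min_detF = dF;
    if (dF <= 0.0) {
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("min_detF") = dF,
                                Rcpp::Named("element") = e + 1);
    }

    double W;
    mat S(3, 3);
    vec par = mpar.row(e).t();
    mat fib(3, 2, fill::zeros);
    if (mtype[e] == 2) {
      fib(0, 0) = mfib(e, 0); fib(1, 0) = mfib(e, 1); fib(2, 0) = mfib(e, 2);
      fib(0, 1) = mfib(e, 3); fib(1, 1) = mfib(e, 4); fib(2, 1) = mfib(e, 5);
    }
    material_point(F, mtype[e], par, fib, volform, W, S, CC, want_stiffness);
    energy += V0 * W;

    mat P = F * S;
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0.0;
        for (int I = 0; I < 3; ++I) s += P(i, I) * G(a, I);
        fint(3 * en[a] + i) += V0 * s;
      }

    if (want_stiffness) {
      // A_{iIjJ} = delta_ij S_IJ + F_iM CC_MIJQ F_jQ
      double A[81];
      for (int i = 0; i < 3; ++i)
        for (int I = 0; I < 3; ++I)
          for (int j = 0; j < 3; ++j)
            for (int J2 = 0; J2 < 3; ++J2) {
              double s = (i == j) ? S(I, J2) : 0.0;
              for (int M = 0; M < 3; ++M)
                for (int Q = 0; Q < 3; ++Q)
                  s += F(i, M) * CC[T4(M, I, J2, Q)] * F(j, Q);
              A[T4(i, I, j, J2)] = s;
            }
      size_t base = (size_t)e * 144;
      int idx = 0;
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 4; ++b)
            for (int j = 0; j < 3; ++j) {
              double s = 0.0;
              for (int I = 0; I < 3; ++I)
                for (int J2 = 0; J2 < 3; ++J2)
                  s += G(a, I) * A[T4(i, I, j, J2)] * G(b, J2);
              Ki[base + idx] = 3 * en[a] + i + 1;
              Kj[base + idx] = 3 * en[b] + j + 1;
              Kx[base + idx] = V0 * s;
              ++idx;
            }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("fint") = fint,
      Rcpp::Named("energy") = energy, Rcpp::Named("min_detF") = min_detF);
  if (want_stiffness) {
    out["Ki"] = Ki;
    out["Kj"] = Kj;
    out["Kx"] = Kx;
  }
  return out;
}
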