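#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shape-function gradients and volumes of linear tetrahedra.
// nodes: N x 3 (mm), elems: M x 4 (1-based node indices).
// Returns grads as M x 12 (node-major: columns 3a..3a+2 hold grad of node a)
// and signed volumes (mm^3); negative volume signals an inverted element.
// [[Rcpp::export]]
List tet_grads_cpp(NumericMatrix nodes, IntegerMatrix elems) {
  int m = elems.nrow();
  NumericMatrix grads(m, 12);
  NumericVector vols(m);
  for (int e = 0; e < m; ++e) {
    int n1 = elems(e, 0) - 1, n2 = elems(e, 1) - 1, n3 = elems(e, 2) - 1,
        n4 = elems(e, 3) - 1;
    double J[3][3];
    for (int c = 0; c < 3; ++c) {
      J[c][0] = nodes(n2, c) - nodes(n1, c);
      J[c][1] = nodes(n3, c) - nodes(n1, c);
      J[c][2] = nodes(n4, c) - nodes(n1, c);
    }
    double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
               - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
               + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
    vols[e] = det / 6.0;
    if (det == 0.0) continue;
    double inv[3][3];
    inv[0][0] = (J[1][1] * J[2][2] - J[1][2] * J[2][1]) / det;
    inv[0][1] = (J[0][2] * J[2][1] - J[0][1] * J[2][2]) / det;
    inv[0][2] = (J[0][1] * J[1][2] - J[0][2] * J[1][1]) / det;
    inv[1][0] = (J[1][2] * J[2][0] - J[1][0] * J[2][2]) / det;
    inv[1][1] = (J[0][0] * J[2][2] - J[0][2] * J[2][0]) / det;
    inv[1][2] = (J[0][2] * J[1][0] - J[0][0] * J[1][2]) / det;
    inv[2][0] = (J[1][0] * J[2][1] - J[1][1] * J[2][0]) / det;
    inv[2][1] = (J[0][1] * J[2][0] - J[0][0] * J[2][1]) / det;
    inv[2][2] = (J[0][0] * J[1][1] - J[0][1] * J[1][0]) / det;
    // grad N_{a+1} = row a of inv(J); grad N_1 = -sum of the others
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c)
        grads(e, 3 * (a + 1) + c) = inv[a][c];
    for (int c = 0; c < 3; ++c)
      grads(e, c) = -(grads(e, 3 + c) + grads(e, 6 + c) + grads(e, 9 + c));
  }
  return List::create(_["grads"] = grads, _["vols"] = vols);
}

static inline void bmat(const double *g, double B[6][12]) {
  // Voigt order [xx, yy, zz, xy, yz, zx] with engineering shear strains
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 12; ++j) B[i][j] = 0.0;
  for (int a = 0; a < 4; ++a) {
    double bx = g[3 * a], by = g[3 * a + 1], bz = g[3 * a + 2];
    int c = 3 * a;
    B[0][c] = bx;
    B[1][c + 1] = by;
    B[2][c + 2] = bz;
    B[3][c] = by; B[3][c + 1] = bx;
    B[4][c + 1] = bz; B[4][c + 2] = by;
    B[5][c] = bz; B[5][c + 2] = bx;
  }
}

// Isotropic elastic stiffness in Voigt form (engineering shears).
static void elastic_D(double E, double nu, double D[6][6]) {
  double G = E / (2.0 * (1.0 + nu));
  double K = E / (3.0 * (1.0 - 2.0 * nu));
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) D[i][j] = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      D[i][j] = K + 2.0 * G * ((i == j ? 1.0 : 0.0) - 1.0 / 3.0);
  for (int i = 3; i < 6; ++i) D[i][i] = G;
}

// Stress update with von Mises radial return (linear isotropic hardening H,
// H = 0 recovers perfect plasticity) plus the algorithmically consistent
// tangent.  State (eps_p with engineering shears, equivalent plastic strain)
// is evaluated from the committed values, not overwritten: callers commit
// the returned state only on converged increments.
// [[Rcpp::export]]
List state_update_cpp(NumericVector u, IntegerMatrix elems, NumericMatrix grads,
                      NumericVector vols, NumericVector E, NumericVector nu,
                      NumericVector sy, NumericVector H, NumericMatrix eps_p,
                      NumericVector eqpl) {
  int m = elems.nrow();
  int ndof = u.size();
  NumericVector fint(ndof);
  NumericMatrix eps_p_new(m, 6), sig_out(m, 6), Dtan(m, 36);
  NumericVector eqpl_new(m);
  for (int e = 0; e < m; ++e) {
    int nd[4] = {elems(e, 0) - 1, elems(e, 1) - 1, elems(e, 2) - 1,
                 elems(e, 3) - 1};
    double ue[12];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) ue[3 * a + c] = u[3 * nd[a] + c];
    const double *g = &grads(e, 0);
    double gloc[12];
    for (int j = 0; j < 12; ++j) gloc[j] = grads(e, j);
    // total strain (engineering shears)
    double eps[6] = {0, 0, 0, 0, 0, 0};
    for (int a = 0; a < 4; ++a) {
      double bx = gloc[3 * a], by = gloc[3 * a + 1], bz = gloc[3 * a + 2];
      double ux = ue[3 * a], uy = ue[3 * a + 1], uz = ue[3 * a + 2];
      eps[0] += bx * ux;
      eps[1] += by * uy;
      eps[2] += bz * uz;
      eps[3] += by * ux + bx * uy;
      eps[4] += bz * uy + by * uz;
      eps[5] += bz * ux + bx * uz;
    }
    double Ee = E[e], nue = nu[e], sye = sy[e], He = H[e];
    double G = Ee / (2.0 * (1.0 + nue));
    double K = Ee / (3.0 * (1.0 - 2.0 * nue));
    double eel[6];
    for (int i = 0; i < 6; ++i) eel[i] = eps[i] - eps_p(e, i);
    double tr = eel[0] + eel[1] + eel[2];
    double p = K * tr;
    // trial deviatoric stress
    double s[6];
    for (int i = 0; i < 3; ++i) s[i] = 2.0 * G * (eel[i] - tr / 3.0);
    for (int i = 3; i < 6; ++i) s[i] = G * eel[i];
    double q = std::sqrt(1.5 * (s[0] * s[0] + s[1] * s[1] + s[2] * s[2]) +
                         3.0 * (s[3] * s[3] + s[4] * s[4] + s[5] * s[5]));
    double sy_cur = sye + He * eqpl[e];
    double D[6][6];
    double sig[6];
    if (q <= sy_cur || q == 0.0) {
      elastic_D(Ee, nue, D);
      for (int i = 0; i < 6; ++i) {
        sig[i] = s[i];
        eps_p_new(e, i) = eps_p(e, i);
      }
      for (int i = 0; i < 3; ++i) sig[i] += p;
      eqpl_new[e] = eqpl[e];
    } else {
      double dgam = (q - sy_cur) / (3.0 * G + He);
      double sy_new = sy_cur + He * dgam;
      double beta = sy_new / q;
      for (int i = 0; i < 6; ++i) sig[i] = beta * s[i];
      for (int i = 0; i < 3; ++i) sig[i] += p;
      // flow direction from the trial stress; engineering shears carry x2
      for (int i = 0; i < 3; ++i)
        eps_p_new(e, i) = eps_p(e, i) + dgam * 1.5 * s[i] / q;
      for (int i = 3; i < 6; ++i)
        eps_p_new(e, i) = eps_p(e, i) + dgam * 3.0 * s[i] / q;
      eqpl_new[e] = eqpl[e] + dgam;
      // D = K 1x1 + beta*Cdev + (3G/q^2)(H/(3G+H) - beta) s x s
      double c = 3.0 * G / (q * q) * (He / (3.0 * G + He) - beta);
      for (int i = 0; i < 6; ++i)
        for (int j = 0; j < 6; ++j) D[i][j] = c * s[i] * s[j];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          D[i][j] += K + beta * 2.0 * G * ((i == j ? 1.0 : 0.0) - 1.0 / 3.0);
      for (int i = 3; i < 6; ++i) D[i][i] += beta * G;
    }
    double V = vols[e];
    // f_e = V * B^T sigma
    for (int a = 0; a < 4; ++a) {
      double bx = gloc[3 * a], by = gloc[3 * a + 1], bz = gloc[3 * a + 2];
      fint[3 * nd[a]]     += V * (bx * sig[0] + by * sig[3] + bz * sig[5]);
      fint[3 * nd[a] + 1] += V * (by * sig[1] + bx * sig[3] + bz * sig[4]);
      fint[3 * nd[a] + 2] += V * (bz * sig[2] + by * sig[4] + bx * sig[5]);
    }
    for (int i = 0; i < 6; ++i) {
      sig_out(e, i) = sig[i];
      for (int j = 0; j < 6; ++j) Dtan(e, 6 * i + j) = D[i][j];
    }
    (void)g;
  }
  return List::create(_["fint"] = fint, _["sigma"] = sig_out,
                      _["eps_p"] = eps_p_new, _["eqpl"] = eqpl_new,
                      _["D"] = Dtan);
}

// Elastic Voigt matrices for a set of elements, flattened row-major to M x 36.
// [[Rcpp::export]]
NumericMatrix elastic_D_cpp(NumericVector E, NumericVector nu) {
  int m = E.size();
  NumericMatrix out(m, 36);
  double D[6][6];
  for (int e = 0; e < m; ++e) {
    elastic_D(E[e], nu[e], D);
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) out(e, 6 * i + j) = D[i][j];
  }
  return out;
}

// Triplets of the assembled tangent K = sum_e V_e B_e^T D_e B_e.
// D given per element as M x 36 (row-major 6x6).  Indices are 1-based DOFs.
// [[Rcpp::export]]
List assemble_triplets_cpp(IntegerMatrix elems, NumericMatrix grads,
                           NumericVector vols, NumericMatrix Dmat) {
  int m = elems.nrow();
  R_xlen_t ntrip = (R_xlen_t)m * 144;
  IntegerVector I(ntrip), Jv(ntrip);
  NumericVector X(ntrip);
  double B[6][12], T[6][12], Ke[12][12];
  R_xlen_t pos = 0;
  for (int e = 0; e < m; ++e) {
    double gloc[12];
    for (int j = 0; j < 12; ++j) gloc[j] = grads(e, j);
    bmat(gloc, B);
    double D[6][6];
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 6; ++j) D[i][j] = Dmat(e, 6 * i + j);
    for (int i = 0; i < 6; ++i)
      for (int j = 0; j < 12; ++j) {
        double acc = 0;
        for (int k = 0; k < 6; ++k) acc += D[i][k] * B[k][j];
        T[i][j] = acc;
      }
    double V = vols[e];
    for (int i = 0; i < 12; ++i)
      for (int j = 0; j < 12; ++j) {
        double acc = 0;
        for (int k = 0; k < 6; ++k) acc += B[k][i] * T[k][j];
        Ke[i][j] = acc * V;
      }
    int dof[12];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) dof[3 * a + c] = 3 * (elems(e, a) - 1) + c + 1;
    for (int i = 0; i < 12; ++i)
      for (int j = 0; j < 12; ++j) {
        I[pos] = dof[i];
        Jv[pos] = dof[j];
        X[pos] = Ke[i][j];
        ++pos;
      }
  }
  return List::create(_["i"] = I, _["j"] = Jv, _["x"] = X);
}
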