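// Element assembly kernel for the plane-strain neo-Hookean solver.
//
// Energy split (selective reduced integration): the isochoric part
//   W_iso = C (I1 + 1 - 3) - 2 C ln J
// is integrated at the four full Gauss points (g = 0..3), the volumetric
// penalty
//   W_vol = (lambda/2) (ln J)^2
// at the element-center point (g = 4) only. A per-Gauss-point prestress
// history Fp multiplies the displacement gradient from the right
// (F = Fu * Fp), which implements the prestress-accumulation treatment of
// the imaged configuration.
//
// Layout conventions (match the R side):
//   dNx, dNy : E x 20, column g*4 + a = dN_a/dX at Gauss point g
//   wdet     : E x 5 integration weights (already scaled by ref. Jacobian)
//   Fp       : E x 20, columns g*4 + (0..3) = (F11, F12, F21, F22)
//   Kv       : E x 64, column c*8 + r = element stiffness entry (r, c),
//              local dofs ordered (node a, x/y): r = 2*a + i
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List assemble_internal_cpp(const NumericMatrix& dNx, const NumericMatrix& dNy,
                           const NumericMatrix& wdet, const NumericMatrix& Fp,
                           const NumericVector& u, const IntegerMatrix& elems,
                           const NumericVector& Cmod,
                           const NumericVector& lam,
                           int ndof, bool wantK) {
  const int E = elems.nrow();
  NumericVector f(ndof);
  NumericMatrix Kv(wantK ? E : 1, wantK ? 64 : 1);
  bool ok = true;

  for (int g = 0; g < 5 && ok; ++g) {
    const bool vol = (g == 4);
    const int off = g * 4;
    for (int e = 0; e < E; ++e) {
      double ux[4], uy[4], dnx[4], dny[4];
      int nd[4];
      for (int a = 0; a < 4; ++a) {
        nd[a] = elems(e, a) - 1;
        ux[a] = u[2 * nd[a]];
        uy[a] = u[2 * nd[a] + 1];
        dnx[a] = dNx(e, off + a);
        dny[a] = dNy(e, off + a);
      }
      double Fu11 = 1, Fu12 = 0, Fu21 = 0, Fu22 = 1;
      for (int a = 0; a < 4; ++a) {
        Fu11 += ux[a] * dnx[a];
        Fu12 += ux[a] * dny[a];
        Fu21 += uy[a] * dnx[a];
        Fu22 += uy[a] * dny[a];
      }
      const double Fp11 = Fp(e, off), Fp12 = Fp(e, off + 1);
      const double Fp21 = Fp(e, off + 2), Fp22 = Fp(e, off + 3);
      const double F11 = Fu11 * Fp11 + Fu12 * Fp21;
      const double F12 = Fu11 * Fp12 + Fu12 * Fp22;
      const double F21 = Fu21 * Fp11 + Fu22 * Fp21;
      const double F22 = Fu21 * Fp12 + Fu22 * Fp22;
      const double J = F11 * F22 - F12 * F21;
      if (!(J > 0.0) || !std::isfinite(J)) { ok = false; break; }
      const double iJ = 1.0 / J;
      // F^{-1}, rows J cols k
      const double Fi[2][2] = {{F22 * iJ, -F12 * iJ}, {-F21 * iJ, F11 * iJ}};
      const double C2 = 2.0 * Cmod[e];
      const double la = lam[e];
      const double lnJ = std::log(J);
      // first Piola-Kirchhoff part of this Gauss point, P[i][J]
      double P[2][2];
      if (!vol) {
        P[0][0] = C2 * F11 - C2 * Fi[0][0];
        P[0][1] = C2 * F12 - C2 * Fi[1][0];
        P[1][0] = C2 * F21 - C2 * Fi[0][1];
        P[1][1] = C2 * F22 - C2 * Fi[1][1];
      } else {
        const double s = la * lnJ;
        P[0][0] = s * Fi[0][0];
        P[0][1] = s * Fi[1][0];
        P[1][0] = s * Fi[0][1];
        P[1][1] = s * Fi[1][1];
      }
      // pull back through the history: Pe[i][K] = P[i][J] * Fp[K][J]
      const double Fpm[2][2] = {{Fp11, Fp12}, {Fp21, Fp22}};
      double Pe[2][2];
      for (int i = 0; i < 2; ++i)
        for (int K = 0; K < 2; ++K)
          Pe[i][K] = P[i][0] * Fpm[K][0] + P[i][1] * Fpm[K][1];
      const double w = wdet(e, g);
      for (int a = 0; a < 4; ++a) {
        f[2 * nd[a]]     += w * (Pe[0][0] * dnx[a] + Pe[0][1] * dny[a]);
        f[2 * nd[a] + 1] += w * (Pe[1][0] * dnx[a] + Pe[1][1] * dny[a]);
      }

      if (!wantK) continue;
      // material tangent A[i][J][k][L] = dP_iJ/dF_kL
      double A[2][2][2][2];
      for (int i = 0; i < 2; ++i)
        for (int Jj = 0; Jj < 2; ++Jj)
          for (int k = 0; k < 2; ++k)
            for (int L = 0; L < 2; ++L) {
              double v;
              if (!vol) {
                v = C2 * Fi[Jj][k] * Fi[L][i];
                if (i == k && Jj == L) v += C2;
              } else {
                v = la * (Fi[Jj][i] * Fi[L][k] - lnJ * Fi[Jj][k] * Fi[L][i]);
              }
              A[i][Jj][k][L] = v;
            }
      // chain through Fp: Ae[i][K][k][L] = Fp[K][J] Fp[L][N] A[i][J][k][N]
      double Ae[2][2][2][2];
      for (int i = 0; i < 2; ++i)
        for (int K = 0; K < 2; ++K)
          for (int k = 0; k < 2; ++k)
            for (int L = 0; L < 2; ++L) {
              double acc = 0;
              for (int Jj = 0; Jj < 2; ++Jj)
                for (int N = 0; N < 2; ++N)
                  acc += Fpm[K][Jj] * Fpm[L][N] * A[i][Jj][k][N];
              Ae[i][K][k][L] = acc;
            }
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          for (int i = 0; i < 2; ++i)
            for (int k = 0; k < 2; ++k) {
              double acc = 0;
              for (int K = 0; K < 2; ++K)
                for (int L = 0; L < 2; ++L)
                  acc += Ae[i][K][k][L] *
                    (K == 0 ? dnx[a] : dny[a]) *
                    (L == 0 ? dnx[b] : dny[b]);
              const int r = 2 * a + i, c = 2 * b + k;
              Kv(e, c * 8 + r) += w * acc;
            }
    }
  }
  return List::create(Named("f") = f, Named("Kv") = Kv, Named("ok") = ok);
}
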