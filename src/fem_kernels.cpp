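// Element-level kernels for 10-node tetrahedra (C3D10-style).
// Strains use Voigt order (e11, e22, e33, g12, g13, g23) with engineering
// shear; the strain-displacement operator returned here is the single source
// of truth: stiffness matrices are formed in R as B' W B so that assembly,
// internal-force evaluation and post-processing are exactly consistent.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Shape function derivatives wrt natural coords (xi, eta, zeta) at one point.
// Node order: corners 1..4 (L1..L4), midsides 5:(1,2) 6:(2,3) 7:(3,1)
// 8:(1,4) 9:(2,4) 10:(3,4) -- identical to the VTK quadratic-tetra order.
void tet10_dN(double xi, double eta, double zeta, arma::mat &G) {
  const double L1 = 1.0 - xi - eta - zeta, L2 = xi, L3 = eta, L4 = zeta;
  const double dL[4][3] = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  const double L[4] = {L1, L2, L3, L4};
  G.zeros(3, 10);
  for (int i = 0; i < 4; ++i)
    for (int k = 0; k < 3; ++k)
      G(k, i) = (4.0 * L[i] - 1.0) * dL[i][k];
  const int ed[6][2] = {{0, 1}, {1, 2}, {2, 0}, {0, 3}, {1, 3}, {2, 3}};
  for (int m = 0; m < 6; ++m) {
    int a = ed[m][0], b = ed[m][1];
    for (int k = 0; k < 3; ++k)
      G(k, 4 + m) = 4.0 * (L[a] * dL[b][k] + L[b] * dL[a][k]);
  }
}

void tet10_N(double xi, double eta, double zeta, arma::vec &N) {
  const double L1 = 1.0 - xi - eta - zeta, L2 = xi, L3 = eta, L4 = zeta;
  const double L[4] = {L1, L2, L3, L4};
  N.set_size(10);
  for (int i = 0; i < 4; ++i) N(i) = L[i] * (2.0 * L[i] - 1.0);
  const int ed[6][2] = {{0, 1}, {1, 2}, {2, 0}, {0, 3}, {1, 3}, {2, 3}};
  for (int m = 0; m < 6; ++m) N(4 + m) = 4.0 * L[ed[m][0]] * L[ed[m][1]];
}

// 4-point degree-2 rule (the standard C3D10 rule), barycentric (a,b,b,b).
struct Rule4 {
  double pts[4][3];
  double w;
  Rule4() {
    const double a = 0.5854101966249685, b = 0.1381966011250105;
    // natural coords (xi,eta,zeta) = (L2,L3,L4)
    double bc[4][4] = {{a, b, b, b}, {b, a, b, b}, {b, b, a, b}, {b, b, b, a}};
    for (int g = 0; g < 4; ++g) {
      pts[g][0] = bc[g][1];
      pts[g][1] = bc[g][2];
      pts[g][2] = bc[g][3];
    }
    w = 0.25 / 6.0; // weight x reference volume
  }
};

// Tensor-product Gauss rule on the collapsed cube (Duffy transform),
// n points per direction; exact for straight tet10 mass (n >= 4) and a
// close volume quadrature for mildly curved elements.
void duffy_rule(int n, std::vector<std::array<double, 3>> &pts,
                std::vector<double> &wts) {
  std::vector<double> x, w;
  if (n == 4) {
    x = {0.0694318442029737, 0.3300094782075719, 0.6699905217924281,
         0.9305681557970263};
    w = {0.1739274225687269, 0.3260725774312731, 0.3260725774312731,
         0.1739274225687269};
    // scaled to [0,1]: weights sum to 2 on [-1,1]; these are already /2
  } else {
    x = {0.0469100770306680, 0.2307653449471585, 0.5, 0.7692346550528415,
         0.9530899229693320};
    w = {0.1184634425280945, 0.2393143352496832, 0.2844444444444444,
         0.2393143352496832, 0.1184634425280945};
  }
  pts.clear();
  wts.clear();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      for (int k = 0; k < n; ++k) {
        double u = x[i], v = x[j], s = x[k];
        double xi = u, eta = v * (1.0 - u), zeta = s * (1.0 - u) * (1.0 - v);
        double jac = (1.0 - u) * (1.0 - u) * (1.0 - v);
        pts.push_back({xi, eta, zeta});
        wts.push_back(w[i] * w[j] * w[k] * jac);
      }
}

inline void fill_B(const arma::mat &dNdx, arma::mat &B) {
  B.zeros(6, 30);
  for (int i = 0; i < 10; ++i) {
    const double dx = dNdx(0, i), dy = dNdx(1, i), dz = dNdx(2, i);
    const int c = 3 * i;
    B(0, c) = dx;
    B(1, c + 1) = dy;
    B(2, c + 2) = dz;
    B(3, c) = dy;  B(3, c + 1) = dx;      // g12
    B(4, c) = dz;  B(4, c + 2) = dx;      // g13
    B(5, c + 1) = dz; B(5, c + 2) = dy;   // g23
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cs_tet10_strainop")]]
List cs_tet10_strainop(const arma::mat &coords, const arma::imat &conn,
                       bool bbar) {
  static Rule4 rule;
  const int nel = conn.n_rows;
  const int ngp = 4;
  const int nnz_el = 6 * ngp * 30;
  std::vector<int> I;
  std::vector<int> J;
  std::vector<double> X;
  I.reserve((size_t)nel * nnz_el);
  J.reserve((size_t)nel * nnz_el);
  X.reserve((size_t)nel * nnz_el);
  arma::vec wdet(nel * ngp);
  arma::vec vol(nel, arma::fill::zeros);
  arma::mat G(3, 10), dNdx(3, 10), B(6, 30);
  arma::cube Bg(6, 30, ngp);

  for (int e = 0; e < nel; ++e) {
    arma::mat X10(10, 3);
    for (int i = 0; i < 10; ++i) {
      int node = conn(e, i) - 1;
      X10.row(i) = coords.row(node);
    }
    arma::rowvec bvol(30, arma::fill::zeros);
    double ve = 0.0;
    for (int g = 0; g < ngp; ++g) {
      tet10_dN(rule.pts[g][0], rule.pts[g][1], rule.pts[g][2], G);
      arma::mat Jm = G * X10;
      double dj = arma::det(Jm);
      if (dj <= 0.0)
        stop("non-positive Jacobian in element %d (gauss point %d)", e + 1,
             g + 1);
      dNdx = arma::solve(Jm, G);
      fill_B(dNdx, B);
      Bg.slice(g) = B;
      double w = rule.w * dj;
      wdet(e * ngp + g) = w;
      ve += w;
      if (bbar) bvol += w * (B.row(0) + B.row(1) + B.row(2));
    }
    vol(e) = ve;
    if (bbar) bvol /= ve;
    for (int g = 0; g < ngp; ++g) {
      arma::mat Bu = Bg.slice(g);
      if (bbar) {
        arma::rowvec bv = Bu.row(0) + Bu.row(1) + Bu.row(2);
        arma::rowvec corr = (bvol - bv) / 3.0;
        for (int r = 0; r < 3; ++r) Bu.row(r) += corr;
      }
      const int row0 = (e * ngp + g) * 6;
      for (int r = 0; r < 6; ++r)
        for (int i = 0; i < 10; ++i) {
          int node = conn(e, i) - 1;
          for (int d = 0; d < 3; ++d) {
            double v = Bu(r, 3 * i + d);
            if (v != 0.0) {
              I.push_back(row0 + r + 1);
              J.push_back(3 * node + d + 1);
              X.push_back(v);
            }
          }
        }
    }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = X,
                      _["w"] = wdet, _["volume"] = vol,
                      _["nrow"] = nel * ngp * 6);
}

//' @noRd
// [[Rcpp::export(name = ".cs_tet10_mass")]]
List cs_tet10_mass(const arma::mat &coords, const arma::imat &conn,
                   const arma::vec &rho) {
  std::vector<std::array<double, 3>> pts;
  std::vector<double> wts;
  duffy_rule(4, pts, wts);
  const int nel = conn.n_rows;
  std::vector<int> I, J;
  std::vector<double> X;
  I.reserve((size_t)nel * 300);
  J.reserve((size_t)nel * 300);
  X.reserve((size_t)nel * 300);
  arma::mat G(3, 10);
  arma::vec N;
  for (int e = 0; e < nel; ++e) {
    arma::mat X10(10, 3);
    for (int i = 0; i < 10; ++i) X10.row(i) = coords.row(conn(e, i) - 1);
    arma::mat Me(10, 10, arma::fill::zeros);
    for (size_t g = 0; g < pts.size(); ++g) {
      tet10_dN(pts[g][0], pts[g][1], pts[g][2], G);
      double dj = arma::det(G * X10);
      tet10_N(pts[g][0], pts[g][1], pts[g][2], N);
      Me += (rho(e) * wts[g] * dj) * (N * N.t());
    }
    for (int i = 0; i < 10; ++i)
      for (int j = 0; j < 10; ++j) {
        double v = Me(i, j);
        int ni = conn(e, i) - 1, nj = conn(e, j) - 1;
        for (int d = 0; d < 3; ++d) {
          I.push_back(3 * ni + d + 1);
          J.push_back(3 * nj + d + 1);
          X.push_back(v);
        }
      }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = X);
}

//' @noRd
// [[Rcpp::export(name = ".cs_tet10_metrics")]]
List cs_tet10_metrics(const arma::mat &coords, const arma::imat &conn) {
  std::vector<std::array<double, 3>> pts;
  std::vector<double> wts;
  duffy_rule(5, pts, wts);
  const int nel = conn.n_rows;
  arma::vec vol(nel), jr(nel), jmin(nel);
  arma::mat G(3, 10);
  for (int e = 0; e < nel; ++e) {
    arma::mat X10(10, 3);
    for (int i = 0; i < 10; ++i) X10.row(i) = coords.row(conn(e, i) - 1);
    double v = 0.0, dmin = arma::datum::inf, dmax = -arma::datum::inf;
    for (size_t g = 0; g < pts.size(); ++g) {
      tet10_dN(pts[g][0], pts[g][1], pts[g][2], G);
      double dj = arma::det(G * X10);
      v += wts[g] * dj;
      dmin = std::min(dmin, dj);
      dmax = std::max(dmax, dj);
    }
    vol(e) = v;
    jmin(e) = dmin;
    jr(e) = (dmax > 0.0) ? dmin / dmax : -1.0;
  }
  return List::create(_["volume"] = vol, _["min_detj"] = jmin,
                      _["scaled_jacobian"] = jr);
}
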