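// Element kernels for linear-static tetrahedral finite elements:
// isotropic stiffness, centroid stress recovery and geometric (stress)
// stiffness for 4-node (linear) and 10-node (quadratic, straight-sided)
// tetrahedra. Straight-sided elements have an affine map, so the Jacobian
// is constant and a 4-point rule integrates the quadratic stiffness exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// barycentric gradients (rows: dL1..dL4) and 6*volume
double tet_geometry(const arma::mat33& J, arma::mat& gradL) {
  double detJ = arma::det(J);
  arma::mat33 Jinv = arma::inv(J);
  gradL.set_size(4, 3);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) gradL(r + 1, c) = Jinv(r, c);
  gradL.row(0) = -(gradL.row(1) + gradL.row(2) + gradL.row(3));
  return detJ;
}

arma::mat66 elastic_D(double E, double nu) {
  double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  double mu = E / (2 * (1 + nu));
  arma::mat66 D(arma::fill::zeros);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D(i, j) = lam;
    D(i, i) = lam + 2 * mu;
    D(i + 3, i + 3) = mu;
  }
  return D;
}

const int edge_def[6][2] = {{0, 1}, {1, 2}, {2, 0}, {0, 3}, {1, 3}, {2, 3}};

// shape-function gradients (k x 3) at barycentric point L
void shape_grads(int k, const arma::mat& gradL, const double* L, arma::mat& dN) {
  dN.set_size(k, 3);
  if (k == 4) {
    dN = gradL;
    return;
  }
  for (int a = 0; a < 4; ++a)
    dN.row(a) = (4.0 * L[a] - 1.0) * gradL.row(a);
  for (int e = 0; e < 6; ++e) {
    int a = edge_def[e][0], b = edge_def[e][1];
    dN.row(4 + e) = 4.0 * (L[a] * gradL.row(b) + L[b] * gradL.row(a));
  }
}

// strain-displacement matrix (6 x 3k) from shape gradients
void strain_B(const arma::mat& dN, arma::mat& B) {
  int k = dN.n_rows;
  B.zeros(6, 3 * k);
  for (int a = 0; a < k; ++a) {
    double gx = dN(a, 0), gy = dN(a, 1), gz = dN(a, 2);
    int c = 3 * a;
    B(0, c) = gx;
    B(1, c + 1) = gy;
    B(2, c + 2) = gz;
    B(3, c) = gy; B(3, c + 1) = gx;
    B(4, c + 1) = gz; B(4, c + 2) = gy;
    B(5, c) = gz; B(5, c + 2) = gx;
  }
}

struct GaussRule {
  int npt;
  double pts[4][4];
  double w;
};

GaussRule rule_for(int k) {
  GaussRule g;
  if (k == 4) {
    g.npt = 1; g.w = 1.0;
    g.pts[0][0] = g.pts[0][1] = g.pts[0][2] = g.pts[0][3] = 0.25;
  } else {
    const double a = 0.5854101966249685, b = 0.1381966011250105;
    g.npt = 4; g.w = 0.25;
    for (int i = 0; i < 4; ++i) {
      for (int j = 0; j < 4; ++j) g.pts[i][j] = b;
      g.pts[i][i] = a;
    }
  }
  return g;
}

arma::mat33 jacobian(const NumericMatrix& nodes, const IntegerMatrix& elems,
                     int e) {
  arma::mat33 J;
  int n0 = elems(e, 0) - 1;
  for (int c = 0; c < 3; ++c) {
    int nc = elems(e, c + 1) - 1;
    for (int d = 0; d < 3; ++d) J(d, c) = nodes(nc, d) - nodes(n0, d);
  }
  return J;
}

}  // namespace

// [[Rcpp::export]]
List fea_assemble_stiffness(NumericMatrix nodes, IntegerMatrix elems,
                            NumericVector E, NumericVector nu) {
  int m = elems.nrow(), k = elems.ncol();
  if (k != 4 && k != 10) stop("elements must have 4 or 10 nodes");
  GaussRule g = rule_for(k);
  int nd = 3 * k;
  int per = nd * (nd + 1) / 2;
  std::vector<int> ti; ti.reserve((size_t)m * per);
  std::vector<int> tj; tj.reserve((size_t)m * per);
  std::vector<double> tv; tv.reserve((size_t)m * per);
  NumericVector vols(m);
  arma::mat gradL, dN, B, Ke;
  for (int e = 0; e < m; ++e) {
    arma::mat33 J = jacobian(nodes, elems, e);
    double detJ = tet_geometry(J, gradL);
    if (detJ <= 0) stop("inverted element %d", e + 1);
    double V = detJ / 6.0;
    vols[e] = V;
    arma::mat66 D = elastic_D(E[e], nu[e]);
    Ke.zeros(nd, nd);
    for (int q = 0; q < g.npt; ++q) {
      shape_grads(k, gradL, g.pts[q], dN);
      strain_B(dN, B);
      Ke += (g.w * V) * (B.t() * D * B);
    }
    for (int a = 0; a < k; ++a) {
      for (int b = 0; b < k; ++b) {
        int ga = elems(e, a) - 1, gb = elems(e, b) - 1;
        for (int da = 0; da < 3; ++da) {
          for (int db = 0; db < 3; ++db) {
            int gi = 3 * ga + da, gj = 3 * gb + db;
            if (gi <= gj) {
              ti.push_back(gi + 1);
              tj.push_back(gj + 1);
              tv.push_back(Ke(3 * a + da, 3 * b + db));
            }
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["v"] = wrap(tv), _["volumes"] = vols);
}

// [[Rcpp::export]]
NumericMatrix fea_element_stress(NumericMatrix nodes, IntegerMatrix elems,
                                 NumericVector E, NumericVector nu,
                                 NumericVector u) {
  int m = elems.nrow(), k = elems.ncol();
  NumericMatrix out(m, 7);
  const double ctr[4] = {0.25, 0.25, 0.25, 0.25};
  arma::mat gradL, dN, B;
  arma::vec ue(3 * k);
  for (int e = 0; e < m; ++e) {
    arma::mat33 J = jacobian(nodes, elems, e);
    tet_geometry(J, gradL);
    for (int a = 0; a < k; ++a)
      for (int d = 0; d < 3; ++d) ue[3 * a + d] = u[3 * (elems(e, a) - 1) + d];
    shape_grads(k, gradL, ctr, dN);
    strain_B(dN, B);
    arma::vec sig = elastic_D(E[e], nu[e]) * (B * ue);
    for (int c = 0; c < 6; ++c) out(e, c) = sig[c];
    double vm = std::sqrt(0.5 * (std::pow(sig[0] - sig[1], 2) +
                                 std::pow(sig[1] - sig[2], 2) +
                                 std::pow(sig[2] - sig[0], 2)) +
                          3.0 * (sig[3] * sig[3] + sig[4] * sig[4] +
                                 sig[5] * sig[5]));
    out(e, 6) = vm;
  }
  colnames(out) = CharacterVector::create("sxx", "syy", "szz", "sxy", "syz",
                                          "sxz", "vm");
  return out;
}

// [[Rcpp::export]]
List fea_assemble_geometric(NumericMatrix nodes, IntegerMatrix elems,
                            NumericVector E, NumericVector nu,
                            NumericVector u) {
  int m = elems.nrow(), k = elems.ncol();
  GaussRule g = rule_for(k);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  size_t per = (size_t)m * k * (k + 1) / 2 * 3;
  ti.reserve(per); tj.reserve(per); tv.reserve(per);
  arma::mat gradL, dN, B, kg;
  arma::vec ue(3 * k);
  for (int e = 0; e < m; ++e) {
    arma::mat33 J = jacobian(nodes, elems, e);
    double detJ = tet_geometry(J, gradL);
    double V = detJ / 6.0;
    arma::mat66 D = elastic_D(E[e], nu[e]);
    for (int a = 0; a < k; ++a)
      for (int d = 0; d < 3; ++d) ue[3 * a + d] = u[3 * (elems(e, a) - 1) + d];
    kg.zeros(k, k);
    for (int q = 0; q < g.npt; ++q) {
      shape_grads(k, gradL, g.pts[q], dN);
      strain_B(dN, B);
      arma::vec sig = D * (B * ue);
      arma::mat33 S;
      S(0, 0) = sig[0]; S(1, 1) = sig[1]; S(2, 2) = sig[2];
      S(0, 1) = S(1, 0) = sig[3];
      S(1, 2) = S(2, 1) = sig[4];
      S(0, 2) = S(2, 0) = sig[5];
      kg += (g.w * V) * (dN * S * dN.t());
    }
    for (int a = 0; a < k; ++a) {
      for (int b = 0; b < k; ++b) {
        int ga = elems(e, a) - 1, gb = elems(e, b) - 1;
        for (int d = 0; d < 3; ++d) {
          int gi = 3 * ga + d, gj = 3 * gb + d;
          if (gi <= gj) {
            ti.push_back(gi + 1);
            tj.push_back(gj + 1);
            tv.push_back(kg(a, b));
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["v"] = wrap(tv));
}
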