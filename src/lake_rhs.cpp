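#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Compiled method-of-lines RHS for the 1D diffusion-reaction lake model,
// called natively by deSolve (func = "lake_derivs", dllname = "lakeredox").
// Parameters are staged from R via .lake_set_params() immediately before
// each integration; state is cell-major (y[j * n_sp + s]).
//
// Boundary codes: surf_type 1 = Dirichlet (surf_value, uM), bott_type 1 =
// influx (bott_value, uM m/day); anything else = zero flux. Rate constants
// are per year; model time is days. Kinetics see concentrations clipped at
// zero.

namespace {
struct LakeModel {
  int n_sp = 0, n = 0, n_rx = 0;
  double dz = 1.0, D0 = 0.0;
  std::vector<double> Din;
  std::vector<int> mobile, surf_type, bott_type;
  std::vector<double> surf_value, bott_value;
  std::vector<double> k, Kd, Ka, Ki;
  std::vector<int> first_order, donor, acceptor, inhibitor;
  std::vector<int> st_off, st_sp;
  std::vector<double> st_nu;
};
LakeModel M;

inline double clip0(double x) { return x > 0.0 ? x : 0.0; }
}  // namespace

// [[Rcpp::export(name = ".lake_set_params")]]
void lake_set_params(int n_sp, int n, double dz, double D0,
                     NumericVector Din, IntegerVector mobile,
                     IntegerVector surf_type, NumericVector surf_value,
                     IntegerVector bott_type, NumericVector bott_value,
                     NumericVector k, IntegerVector first_order,
                     IntegerVector donor, NumericVector K_donor,
                     IntegerVector acceptor, NumericVector K_acceptor,
                     IntegerVector inhibitor, NumericVector K_inhibit,
                     IntegerVector st_off, IntegerVector st_sp,
                     NumericVector st_nu) {
  M.n_sp = n_sp; M.n = n; M.dz = dz; M.D0 = D0;
  M.Din.assign(Din.begin(), Din.end());
  M.mobile.assign(mobile.begin(), mobile.end());
  M.surf_type.assign(surf_type.begin(), surf_type.end());
  M.surf_value.assign(surf_value.begin(), surf_value.end());
  M.bott_type.assign(bott_type.begin(), bott_type.end());
  M.bott_value.assign(bott_value.begin(), bott_value.end());
  M.k.assign(k.begin(), k.end());
  M.first_order.assign(first_order.begin(), first_order.end());
  M.donor.assign(donor.begin(), donor.end());
  M.Kd.assign(K_donor.begin(), K_donor.end());
  M.acceptor.assign(acceptor.begin(), acceptor.end());
  M.Ka.assign(K_acceptor.begin(), K_acceptor.end());
  M.inhibitor.assign(inhibitor.begin(), inhibitor.end());
  M.Ki.assign(K_inhibit.begin(), K_inhibit.end());
  M.st_off.assign(st_off.begin(), st_off.end());
  M.st_sp.assign(st_sp.begin(), st_sp.end());
  M.st_nu.assign(st_nu.begin(), st_nu.end());
  M.n_rx = k.size();
}

// deSolve resolves "lake_derivs" by dynamic symbol lookup, which the
// generated registration disables; re-enable it at load time.
// [[Rcpp::init]]
void lake_allow_native_lookup(DllInfo *dll) {
  R_useDynamicSymbols(dll, TRUE);
}

extern "C" void lake_derivs(int *neq, double *t, double *y, double *ydot,
                            double *yout, int *ip) {
  (void)t; (void)yout; (void)ip;
  const int n_sp = M.n_sp, n = M.n;
  const double dz = M.dz, dz2 = dz * dz;
  for (int i = 0; i < *neq; ++i) ydot[i] = 0.0;

  // transport
  for (int s = 0; s < n_sp; ++s) {
    if (!M.mobile[s]) continue;
    for (int j = 0; j < n - 1; ++j) {
      double flx = M.Din[j] * (y[(j + 1) * n_sp + s] - y[j * n_sp + s]) / dz2;
      ydot[j * n_sp + s] += flx;
      ydot[(j + 1) * n_sp + s] -= flx;
    }
    if (M.surf_type[s] == 1) {
      ydot[s] += M.D0 * (M.surf_value[s] - y[s]) * 2.0 / dz2;
    }
    if (M.bott_type[s] == 1) {
      ydot[(n - 1) * n_sp + s] += M.bott_value[s] / dz;
    }
  }

  // reactions
  for (int r = 0; r < M.n_rx; ++r) {
    if (M.k[r] == 0.0) continue;
    for (int j = 0; j < n; ++j) {
      double rate;
      if (M.first_order[r]) {
        rate = M.k[r] * clip0(y[j * n_sp + M.donor[r]]);
      } else {
        rate = M.k[r];
        if (M.donor[r] >= 0) {
          double cd = clip0(y[j * n_sp + M.donor[r]]);
          rate *= cd / (M.Kd[r] + cd);
        }
        if (M.acceptor[r] >= 0) {
          double ca = clip0(y[j * n_sp + M.acceptor[r]]);
          rate *= ca / (M.Ka[r] + ca);
        }
        if (M.inhibitor[r] >= 0) {
          double ci = clip0(y[j * n_sp + M.inhibitor[r]]);
          rate *= M.Ki[r] / (M.Ki[r] + ci);
        }
      }
      rate /= 365.0;
      for (int u = M.st_off[r]; u < M.st_off[r + 1]; ++u) {
        ydot[j * n_sp + M.st_sp[u]] += M.st_nu[u] * rate;
      }
    }
  }
}
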