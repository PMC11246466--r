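#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One iteration's chemistry pass on the aggregated directed neighbour-pair
// arrays: nsub explicit-Euler substeps in which the PIN repolarisation, auxin
// and CUC1 updates are all computed from the same pre-round state and applied
// together. pi/pj are 1-based cell indices per directed pair (i -> j).

// [[Rcpp::export(name = ".chem_kernel")]]
List chem_kernel(IntegerVector pi, IntegerVector pj, NumericVector L,
                 NumericVector pin0, NumericVector aux0, NumericVector cuc0,
                 NumericVector delta, NumericVector area,
                 double alpha, double cuc_thres, double prod_aux,
                 double dec_aux, double tran_aux, double prod_cuc,
                 double dec_cuc, double k_aux, double hill, double dt,
                 int nsub) {
  int np = pi.size();
  int C = aux0.size();
  std::vector<double> aux(aux0.begin(), aux0.end());
  std::vector<double> cuc(cuc0.begin(), cuc0.end());
  std::vector<double> pin(pin0.begin(), pin0.end());
  std::vector<double> newaux(C), newcuc(C), w(np), den(C), Ld(C, 0.0), net(C);
  std::vector<int> ii(np), jj(np);
  for (int e = 0; e < np; ++e) { ii[e] = pi[e] - 1; jj[e] = pj[e] - 1; }
  for (int e = 0; e < np; ++e) Ld[ii[e]] += L[e];

  for (int s = 0; s < nsub; ++s) {
    std::fill(den.begin(), den.end(), 0.0);
    std::fill(net.begin(), net.end(), 0.0);
    for (int e = 0; e < np; ++e) {
      double a = aux[jj[e]];
      w[e] = (cuc[ii[e]] >= cuc_thres ? a * a : a) * L[e];
      den[ii[e]] += w[e];
      double flow = aux[ii[e]] * pin[e];   // pre-round PIN
      net[jj[e]] += flow;
      net[ii[e]] -= flow;
    }
    for (int e = 0; e < np; ++e) {
      double target = den[ii[e]] > 0.0 ? w[e] / den[ii[e]] : L[e] / Ld[ii[e]];
      pin[e] = (1.0 - alpha) * pin[e] + alpha * target;
    }
    for (int i = 0; i < C; ++i) {
      double da = prod_aux * delta[i] - dec_aux * aux[i] +
        tran_aux * net[i] / area[i];
      newaux[i] = aux[i] + dt * da;
      if (!std::isfinite(newaux[i]))
        stop("non-finite auxin in cell %d", i + 1);
      if (newaux[i] < 0.0) newaux[i] = 0.0;
      double dc = prod_cuc / (1.0 + std::pow(aux[i] / k_aux, hill)) -
        dec_cuc * cuc[i];
      newcuc[i] = cuc[i] + dt * dc;
      if (!std::isfinite(newcuc[i]))
        stop("non-finite CUC1 in cell %d", i + 1);
      if (newcuc[i] < 0.0) newcuc[i] = 0.0;
    }
    aux.swap(newaux);
    cuc.swap(newcuc);
  }
  return List::create(_["pin"] = NumericVector(pin.begin(), pin.end()),
                      _["aux"] = NumericVector(aux.begin(), aux.end()),
                      _["cuc"] = NumericVector(cuc.begin(), cuc.end()));
}
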