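#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for the symmetric k-state Mk model, exploiting the
// two-value structure of the transition matrix:
//   P_same(t) = 1/k + ((k-1)/k) exp(-k t / (k-1))
//   P_diff(t) = (1/k) (1 - exp(-k t / (k-1)))
// so a child message is m_s = P_diff * S + (P_same - P_diff) * L_s with
// S = sum_s L_s, O(k) per node and site. Root frequencies are uniform.
//
// edge: (nedge x 2) 1-based node ids in postorder (tips 1..ntip, root
// ntip+1); states: (nsites x ntip) integers in 0..k-1. Returns per-site
// UNCORRECTED log-likelihoods plus the log-likelihood of an all-constant
// pattern at one state (identical for every state by symmetry).

// [[Rcpp::export]]
List mkv_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                    int ntip, IntegerMatrix states, int k) {
  const int nedge = edge.nrow();
  const int nsites = states.nrow();
  int nnode = ntip;
  for (int e = 0; e < nedge; ++e) {
    if (edge(e, 0) > nnode) nnode = edge(e, 0);
    if (edge(e, 1) > nnode) nnode = edge(e, 1);
  }
  // flat buffers: internal-node partials only (nodes ntip+1..nnode)
  const int nint = nnode - ntip;
  std::vector<double> part((size_t)nint * nsites * k);
  std::vector<double> scal((size_t)nint * nsites, 0.0);
  std::vector<double> cpart((size_t)nint * k);
  std::vector<double> cscal((size_t)nint, 0.0);
  std::vector<char> init(nint, 0);

  for (int e = 0; e < nedge; ++e) {
    const int parent = edge(e, 0) - ntip - 1; // internal index
    const int child = edge(e, 1);
    const double t = edge_length[e];
    const double ek = exp(-(double)k * t / (k - 1));
    const double psame = 1.0 / k + ((double)(k - 1) / k) * ek;
    const double pdiff = (1.0 - ek) / k;
    const double delta = psame - pdiff;
    double *pbase = &part[(size_t)parent * nsites * k];
    double *cbase = &cpart[(size_t)parent * k];
    if (!init[parent]) {
      std::fill(pbase, pbase + (size_t)nsites * k, 1.0);
      std::fill(cbase, cbase + k, 1.0);
      init[parent] = 1;
    }

    if (child <= ntip) {
      const int *obs = &states(0, child - 1);
      if (pdiff > 0) {
        const double ratio = psame / pdiff;
        for (int i = 0; i < nsites; ++i) {
          double *pp = pbase + (size_t)i * k;
          const int o = obs[i];
          for (int s = 0; s < k; ++s) pp[s] *= pdiff;
          pp[o] *= ratio;
        }
      } else { // zero-length branch: child state is certain
        for (int i = 0; i < nsites; ++i) {
          double *pp = pbase + (size_t)i * k;
          const int o = obs[i];
          for (int s = 0; s < k; ++s) if (s != o) pp[s] = 0.0;
        }
      }
      for (int s = 0; s < k; ++s) cbase[s] *= (s == 0) ? psame : pdiff;
    } else {
      const int ci = child - ntip - 1;
      double *cpbase = &part[(size_t)ci * nsites * k];
      double *ccbase = &cpart[(size_t)ci * k];
      for (int i = 0; i < nsites; ++i) {
        double *pc = cpbase + (size_t)i * k;
        double *pp = pbase + (size_t)i * k;
        double S = 0.0;
        for (int s = 0; s < k; ++s) S += pc[s];
        double mx = 0.0;
        for (int s = 0; s < k; ++s) {
          pp[s] *= pdiff * S + delta * pc[s];
          if (pp[s] > mx) mx = pp[s];
        }
        double sc = scal[(size_t)parent * nsites + i] +
          scal[(size_t)ci * nsites + i];
        if (mx > 0 && mx < 1e-200) {
          for (int s = 0; s < k; ++s) pp[s] /= mx;
          sc += log(mx);
        }
        scal[(size_t)parent * nsites + i] = sc;
      }
      double S = 0.0;
      for (int s = 0; s < k; ++s) S += ccbase[s];
      for (int s = 0; s < k; ++s)
        cbase[s] *= pdiff * S + delta * ccbase[s];
      cscal[parent] += cscal[ci];
    }
  }

  NumericVector site_ll(nsites);
  double *rbase = &part[0]; // root = ntip+1 -> internal index 0
  for (int i = 0; i < nsites; ++i) {
    double *pp = rbase + (size_t)i * k;
    double L = 0.0;
    for (int s = 0; s < k; ++s) L += pp[s];
    L /= k;
    site_ll[i] = (L > 0) ? log(L) + scal[i] : R_NegInf;
  }
  double Lc = 0.0;
  for (int s = 0; s < k; ++s) Lc += cpart[s];
  Lc /= k;
  double const_ll = (Lc > 0) ? log(Lc) + cscal[0] : R_NegInf;

  return List::create(_["site_loglik"] = site_ll,
                      _["const_loglik"] = const_ll);
}
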