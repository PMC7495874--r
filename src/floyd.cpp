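#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest paths by Floyd-Warshall on a dense weight matrix.
// Missing edges are encoded as R_PosInf; the diagonal must be 0.
// [[Rcpp::export(name = ".floyd_warshall")]]
NumericMatrix floyd_warshall(NumericMatrix W) {
  int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  NumericMatrix D(clone(W));
  for (int l = 0; l < n; ++l) {
    for (int i = 0; i < n; ++i) {
      double dil = D(i, l);
      if (dil == R_PosInf) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dil + D(l, j);
        if (alt < D(i, j)) D(i, j) = alt;
      }
    }
  }
  return D;
}
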