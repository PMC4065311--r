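#include <Rcpp.h>
using namespace Rcpp;

// Score of a gapless full-length placement of the peptide at every offset of
// the protein. Residues are 1-based indices into the substitution matrix.
// [[Rcpp::export]]
NumericVector offset_scores_cpp(IntegerVector pep, IntegerVector prot,
                                NumericMatrix smat) {
  const int L = pep.size(), P = prot.size();
  const int n = P - L + 1;
  if (n < 1) stop("protein shorter than peptide");
  NumericVector out(n);
  for (int o = 0; o < n; ++o) {
    double s = 0.0;
    for (int i = 0; i < L; ++i) {
      s += smat(pep[i] - 1, prot[o + i] - 1);
    }
    out[o] = s;
  }
  return out;
}
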