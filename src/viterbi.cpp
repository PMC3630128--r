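#include <Rcpp.h>
using namespace Rcpp;

// Global Viterbi over the match/insert/delete profile architecture in
// log2-odds space. Emission matrices already hold log-odds (last column =
// X, fixed to 0); tr holds log2 transition probabilities per node
// (columns mm, mi, md, im, ii, dm, dd). xi is the 1-based residue column
// index per sequence position. Returns the best-path score in bits and
// the number of states on the best path.
// [[Rcpp::export(name = ".viterbi_core")]]
List viterbi_core(NumericMatrix em_m, NumericMatrix em_i,
                  NumericMatrix tr, IntegerVector xi) {
  const int M = em_m.nrow();
  const int L = xi.size();
  const double NEG = R_NegInf;
  // column layout of tr
  const int MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6;

  NumericMatrix VM(M + 1, L + 1), VI(M + 1, L + 1), VD(M + 1, L + 1);
  IntegerMatrix PM(M + 1, L + 1), PI(M + 1, L + 1), PD(M + 1, L + 1);
  std::fill(VM.begin(), VM.end(), NEG);
  std::fill(VI.begin(), VI.end(), NEG);
  std::fill(VD.begin(), VD.end(), NEG);
  VM(0, 0) = 0.0;  // begin state at node 0, nothing consumed

  for (int k = 0; k <= M; ++k) {
    for (int i = 0; i <= L; ++i) {
      if (k > 0) {
        // D_k: from M_{k-1} or D_{k-1}, consuming nothing
        double c1 = VM(k - 1, i) + tr(k - 1, MD);
        double c3 = (k > 1) ? VD(k - 1, i) + tr(k - 1, DD) : NEG;
        if (c1 >= c3) { VD(k, i) = c1; PD(k, i) = 1; }
        else          { VD(k, i) = c3; PD(k, i) = 3; }
        if (i > 0) {
          // M_k: from node k-1 states at i-1, consuming x_i
          double a1 = VM(k - 1, i - 1) + tr(k - 1, MM);
          double a2 = VI(k - 1, i - 1) + tr(k - 1, IM);
          double a3 = (k > 1) ? VD(k - 1, i - 1) + tr(k - 1, DM) : NEG;
          double best = a1; int ptr = 1;
          if (a2 > best) { best = a2; ptr = 2; }
          if (a3 > best) { best = a3; ptr = 3; }
          VM(k, i) = best + em_m(k - 1, xi[i - 1] - 1);
          PM(k, i) = ptr;
        }
      }
      if (i > 0) {
        // I_k: from M_k or I_k at i-1, consuming x_i
        double b1 = VM(k, i - 1) + tr(k, MI);
        double b2 = VI(k, i - 1) + tr(k, II);
        if (b1 >= b2) { VI(k, i) = b1 + em_i(k, xi[i - 1] - 1); PI(k, i) = 1; }
        else          { VI(k, i) = b2 + em_i(k, xi[i - 1] - 1); PI(k, i) = 2; }
      }
    }
  }
  double e1 = VM(M, L) + tr(M, MM);
  double e2 = VI(M, L) + tr(M, IM);
  double e3 = (M > 0) ? VD(M, L) + tr(M, DM) : NEG;
  double score = e1; int state = 1;
  if (e2 > score) { score = e2; state = 2; }
  if (e3 > score) { score = e3; state = 3; }

  int path_length = NA_INTEGER;
  if (R_FINITE(score)) {
    int n = 0, k = M, i = L, st = state;
    while (!(st == 1 && k == 0 && i == 0)) {
      ++n;
      int prev;
      if (st == 1)      { prev = PM(k, i); --k; --i; }
      else if (st == 2) { prev = PI(k, i); --i; }
      else              { prev = PD(k, i); --k; }
      st = prev;
      if (n > 4 * (M + L + 2)) stop("viterbi traceback failed");
    }
    path_length = n;
  }
  return List::create(_["score"] = score, _["path_length"] = path_length);
}
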