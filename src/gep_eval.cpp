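#include <Rcpp.h>
#include <Rmath.h>
using namespace Rcpp;

// Symbol coding shared with the R side:
//   s > 0 : function id (1 +, 2 -, 3 *, 4 /, 5 pow, 6 sqrt, 7 sin, 8 tan,
//           9 ln, 10 pow10)
//   s == 0: random-numerical-constant placeholder "?"
//   s < 0 : terminal, descriptor column -s of the data matrix
//
// Arithmetic is deliberately unguarded IEEE ("protected math" in the GEP
// sense): invalid operations produce NaN/Inf which propagates; the fitness
// layer maps any non-finite chromosome output to fitness 0.  pow uses R_pow
// so that results agree exactly with R's `^`.

static const int FUN_ARITY[10] = {2, 2, 2, 2, 2, 1, 1, 1, 1, 1};

// Decode a Karva-notation gene: breadth-first (level-order) children
// assignment over the coding prefix.  Returns the coding length and fills
// left/right child indices (-1 = none) and the RNC order index per position.
static int karva_decode(const int* sym, int L, int* left, int* right,
                        int* rnc_order) {
  int m = 1, nrnc = 0;
  for (int i = 0; i < m && i < L; ++i) {
    int s = sym[i];
    int a = s > 0 ? FUN_ARITY[s - 1] : 0;
    left[i] = a >= 1 ? m : -1;
    right[i] = a == 2 ? m + 1 : -1;
    rnc_order[i] = s == 0 ? nrnc++ : -1;
    m += a;
  }
  return m;
}

// [[Rcpp::export]]
List cpp_decode_gene(IntegerVector sym) {
  int L = sym.size();
  std::vector<int> left(L), right(L), rnc(L);
  int m = karva_decode(INTEGER(sym), L, left.data(), right.data(), rnc.data());
  return List::create(_["length"] = m,
                      _["left"] = IntegerVector(left.begin(), left.begin() + m),
                      _["right"] = IntegerVector(right.begin(), right.begin() + m),
                      _["rnc_order"] = IntegerVector(rnc.begin(), rnc.begin() + m));
}

// Evaluate one gene over all rows of X.  dc holds 1-based indices into
// consts; "?" placeholders consume them in reading (level) order.
// [[Rcpp::export]]
NumericVector cpp_eval_gene(IntegerVector sym, IntegerVector dc,
                            NumericVector consts, NumericMatrix X) {
  int L = sym.size();
  std::vector<int> left(L), right(L), rnc(L);
  int m = karva_decode(INTEGER(sym), L, left.data(), right.data(), rnc.data());
  int n = X.nrow();
  std::vector<std::vector<double> > val((size_t) m, std::vector<double>(n));
  for (int i = m - 1; i >= 0; --i) {
    int s = sym[i];
    if (s == 0) {
      double c = consts[dc[rnc[i]] - 1];
      std::fill(val[i].begin(), val[i].end(), c);
    } else if (s < 0) {
      int col = -s - 1;
      for (int r = 0; r < n; ++r) val[i][r] = X(r, col);
    } else {
      const std::vector<double>& A = val[left[i]];
      const double* B = right[i] >= 0 ? val[right[i]].data() : (double*) 0;
      for (int r = 0; r < n; ++r) {
        double x = A[r], out;
        switch (s) {
        case 1: out = x + B[r]; break;
        case 2: out = x - B[r]; break;
        case 3: out = x * B[r]; break;
        case 4: out = x / B[r]; break;
        case 5: out = R_pow(x, B[r]); break;
        case 6: out = std::sqrt(x); break;
        case 7: out = std::sin(x); break;
        case 8: out = std::tan(x); break;
        case 9: out = std::log(x); break;
        default: out = R_pow(10.0, x); break;
        }
        val[i][r] = out;
      }
    }
  }
  return NumericVector(val[0].begin(), val[0].end());
}

// Sum of the gene values of a multigenic chromosome (addition linking).
// sym and dc are genes x position matrices, consts genes x n_constants.
// [[Rcpp::export]]
NumericVector cpp_eval_chromosome(IntegerMatrix sym, IntegerMatrix dc,
                                  NumericMatrix consts, NumericMatrix X) {
  int G = sym.nrow(), n = X.nrow();
  NumericVector out(n);
  for (int g = 0; g < G; ++g) {
    IntegerVector s = sym(g, _);
    IntegerVector d = dc(g, _);
    NumericVector c = consts.nrow() > 0 ? (NumericVector) consts(g, _)
                                        : NumericVector(0);
    NumericVector v = cpp_eval_gene(s, d, c, X);
    for (int r = 0; r < n; ++r) out[r] += v[r];
  }
  return out;
}
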