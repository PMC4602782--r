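#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labelling of a 3-D logical lattice by flood fill over
// linear indices. offs: m x 3 integer matrix of neighbour offsets.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector bin, IntegerVector dims,
                                   IntegerMatrix offs) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = bin.size();
  const int m = offs.nrow();
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  std::vector<int> oi(m), oj(m), ok(m);
  std::vector<R_xlen_t> loff(m);
  for (int o = 0; o < m; ++o) {
    oi[o] = offs(o, 0); oj[o] = offs(o, 1); ok[o] = offs(o, 2);
    loff[o] = (R_xlen_t)oi[o] + (R_xlen_t)n1 * (oj[o] + (R_xlen_t)n2 * ok[o]);
  }
  int lab = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!bin[s] || labels[s] != 0) continue;
    ++lab;
    labels[s] = lab;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int ci = (int)(cur % n1);
      int cj = (int)((cur / n1) % n2);
      int ck = (int)(cur / ((R_xlen_t)n1 * n2));
      for (int o = 0; o < m; ++o) {
        int ni = ci + oi[o];
        if (ni < 0 || ni >= n1) continue;
        int nj = cj + oj[o];
        if (nj < 0 || nj >= n2) continue;
        int nk = ck + ok[o];
        if (nk < 0 || nk >= n3) continue;
        R_xlen_t nb = cur + loff[o];
        if (bin[nb] && labels[nb] == 0) {
          labels[nb] = lab;
          stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}
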