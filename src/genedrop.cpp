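#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Transmit one gamete from the parental haplotype pair (rows h1, h2 of
// `haps`) under the Haldane model: crossover count per chromosome is
// Poisson(map length in Morgan), crossover positions uniform, no
// interference.  Uses R's RNG so results are reproducible under set.seed().
// `pos` holds within-chromosome positions in Morgan; chr_start/chr_end are
// 0-based [start, end) column ranges per chromosome.
static int make_gamete(const IntegerMatrix& haps, int h1, int h2,
                       const NumericVector& pos,
                       const NumericVector& chr_len,
                       const IntegerVector& chr_start,
                       const IntegerVector& chr_end,
                       IntegerMatrix& out, int orow) {
  int n_chr = chr_start.size();
  int n_xo_total = 0;
  for (int c = 0; c < n_chr; ++c) {
    int s = chr_start[c], e = chr_end[c];
    int cur = (unif_rand() < 0.5) ? h1 : h2;
    int nxo = (chr_len[c] > 0.0) ? (int) R::rpois(chr_len[c]) : 0;
    n_xo_total += nxo;
    if (nxo == 0) {
      for (int j = s; j < e; ++j) out(orow, j) = haps(cur, j);
      continue;
    }
    std::vector<double> xo((size_t) nxo);
    for (int k = 0; k < nxo; ++k) xo[(size_t) k] = unif_rand() * chr_len[c];
    std::sort(xo.begin(), xo.end());
    int k = 0;
    for (int j = s; j < e; ++j) {
      while (k < nxo && xo[(size_t) k] < pos[j]) {
        cur = (cur == h1) ? h2 : h1;
        ++k;
      }
      out(orow, j) = haps(cur, j);
    }
  }
  return n_xo_total;
}

// Random-mating forward simulation used to build LD-bearing founder
// haplotypes.  start_haps: 2*N0 x m binary matrix (one row per haplotype).
// Runs n_gen non-overlapping generations at size pop_size, except the last,
// which produces n_out individuals (the founders handed to the pedigree).
// [[Rcpp::export(name = ".evolve_founders_cpp")]]
IntegerMatrix evolve_founders_cpp(IntegerMatrix start_haps,
                                  NumericVector pos, NumericVector chr_len,
                                  IntegerVector chr_start, IntegerVector chr_end,
                                  int n_gen, int pop_size, int n_out) {
  int m = start_haps.ncol();
  IntegerMatrix cur = start_haps;
  for (int g = 0; g < n_gen; ++g) {
    int n_next = (g == n_gen - 1) ? n_out : pop_size;
    int n_par = cur.nrow() / 2;
    IntegerMatrix nxt(2 * n_next, m);
    for (int i = 0; i < n_next; ++i) {
      int p1 = (int) (unif_rand() * n_par);
      int p2 = (int) (unif_rand() * n_par);
      while (p2 == p1 && n_par > 1) p2 = (int) (unif_rand() * n_par);
      make_gamete(cur, 2 * p1, 2 * p1 + 1, pos, chr_len, chr_start, chr_end,
                  nxt, 2 * i);
      make_gamete(cur, 2 * p2, 2 * p2 + 1, pos, chr_len, chr_start, chr_end,
                  nxt, 2 * i + 1);
    }
    cur = nxt;
  }
  return cur;
}

// Gene drop down an ordered pedigree.  sire/dam are 0-based indices into the
// pedigree (-1 = unknown; founders have both unknown).  Haplotypes are kept
// in one 2n x m matrix: row 2i = paternal, row 2i+1 = maternal haplotype of
// individual i, so phase is retained for imprinting.
// [[Rcpp::export(name = ".gene_drop_cpp")]]
List gene_drop_cpp(IntegerVector sire, IntegerVector dam,
                   IntegerMatrix founder_haps,
                   NumericVector pos, NumericVector chr_len,
                   IntegerVector chr_start, IntegerVector chr_end) {
  int n = sire.size();
  int m = founder_haps.ncol();
  IntegerMatrix H(2 * n, m);
  int n_founder = 0;
  double n_xo = 0.0, n_meioses = 0.0;
  for (int i = 0; i < n; ++i) {
    bool founder = (sire[i] < 0 && dam[i] < 0);
    if (founder) {
      if (2 * n_founder + 1 >= founder_haps.nrow())
        stop("pedigree has more founders than supplied founder haplotypes");
      for (int j = 0; j < m; ++j) {
        H(2 * i, j)     = founder_haps(2 * n_founder, j);
        H(2 * i + 1, j) = founder_haps(2 * n_founder + 1, j);
      }
      ++n_founder;
    } else {
      if (sire[i] < 0 || dam[i] < 0)
        stop("individual %d has exactly one known parent; not supported", i + 1);
      if (sire[i] >= i || dam[i] >= i)
        stop("parents of individual %d must precede it in the pedigree", i + 1);
      n_xo += make_gamete(H, 2 * sire[i], 2 * sire[i] + 1, pos, chr_len,
                          chr_start, chr_end, H, 2 * i);
      n_xo += make_gamete(H, 2 * dam[i], 2 * dam[i] + 1, pos, chr_len,
                          chr_start, chr_end, H, 2 * i + 1);
      n_meioses += 2.0;
    }
  }
  IntegerMatrix pat(n, m), mat(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      pat(i, j) = H(2 * i, j);
      mat(i, j) = H(2 * i + 1, j);
    }
  return List::create(_["pat"] = pat, _["mat"] = mat,
                      _["n_crossovers"] = n_xo,
                      _["n_meioses"] = n_meioses);
}
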