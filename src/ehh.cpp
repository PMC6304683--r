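#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity machinery.
//
// Haplotype identity is tracked outward from a core SNP by partition
// refinement: all haplotypes start in one class (EHH(core) = 1) and each
// successive marker splits classes by its allele. EHH at marker m is
// sum_h C(n_h,2) / C(n,2) over the classes h after refining through m.

static inline double ehh_of(const std::vector<int> &lab,
                            const std::vector<int> &rows, int n_lab) {
  static std::vector<int> cnt;
  cnt.assign(n_lab, 0);
  for (int r : rows) ++cnt[lab[r]];
  double pairs = 0.0;
  for (int c : cnt) if (c > 1) pairs += 0.5 * c * (c - 1.0);
  const double n = (double)rows.size();
  return pairs / (0.5 * n * (n - 1.0));
}

// Refine labels by the allele column j of hap; returns new label count.
static int refine(const IntegerMatrix &hap, int j, std::vector<int> &lab,
                  int n_lab, std::vector<int> &remap) {
  remap.assign(2 * n_lab, -1);
  int nl = 0;
  const int n = lab.size();
  for (int i = 0; i < n; ++i) {
    const int key = 2 * lab[i] + (hap(i, j) != 0 ? 1 : 0);
    if (remap[key] < 0) remap[key] = nl++;
    lab[i] = remap[key];
  }
  return nl;
}

// EHH decay curve from a core marker in one direction (+1 toward larger
// positions, -1 toward smaller). Truncates at inter-marker gaps > max_gap.
// hap: haplotypes in rows, markers in columns (one chromosome, sorted pos).
// [[Rcpp::export(name = ".ehh_curve_cpp")]]
List ehh_curve_cpp(IntegerMatrix hap, NumericVector pos, int core,
                   int direction, double max_gap) {
  const int M = hap.ncol(), n = hap.nrow();
  if (core < 1 || core > M) stop("core index out of range");
  if (n < 2) stop("need at least 2 haplotypes");
  std::vector<int> lab(n, 0), remap;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  int n_lab = 1;
  std::vector<double> out_pos, out_ehh;
  out_pos.push_back(pos[core - 1]);
  out_ehh.push_back(1.0);
  double prev = pos[core - 1];
  for (int j = core - 1 + direction; j >= 0 && j < M; j += direction) {
    if (std::abs(pos[j] - prev) > max_gap) break;
    n_lab = refine(hap, j, lab, n_lab, remap);
    out_pos.push_back(pos[j]);
    out_ehh.push_back(ehh_of(lab, all, n_lab));
    prev = pos[j];
  }
  return List::create(_["pos"] = out_pos, _["ehh"] = out_ehh);
}

// Cross-population iHH at a set of cores. hapA / hapB share the marker
// columns. The integration boundary on each flank is where the EHH of the
// pooled sample drops below `cutoff` (selscan convention), at a gap larger
// than max_gap, or at the chromosome end; within that boundary each
// population's own EHH curve is integrated by trapezoids over bp.
// Returns cores x 2 matrix (iHH_A, iHH_B).
// [[Rcpp::export(name = ".xpehh_pair_cpp")]]
NumericMatrix xpehh_pair_cpp(IntegerMatrix hapA, IntegerMatrix hapB,
                             NumericVector pos, IntegerVector cores,
                             double cutoff, double max_gap) {
  const int M = hapA.ncol();
  if (hapB.ncol() != M) stop("panels must share the marker list");
  const int nA = hapA.nrow(), nB = hapB.nrow(), n = nA + nB;
  if (nA < 2 || nB < 2) stop("need at least 2 haplotypes per population");
  IntegerMatrix hap(n, M);
  for (int j = 0; j < M; ++j) {
    for (int i = 0; i < nA; ++i) hap(i, j) = hapA(i, j);
    for (int i = 0; i < nB; ++i) hap(nA + i, j) = hapB(i, j);
  }
  std::vector<int> rowsA(nA), rowsB(nB), rowsAll(n);
  for (int i = 0; i < nA; ++i) rowsA[i] = i;
  for (int i = 0; i < nB; ++i) rowsB[i] = nA + i;
  for (int i = 0; i < n; ++i) rowsAll[i] = i;

  NumericMatrix out(cores.size(), 2);
  std::vector<int> lab(n), remap;
  for (int ci = 0; ci < cores.size(); ++ci) {
    const int core = cores[ci] - 1;
    if (core < 0 || core >= M) stop("core index out of range");
    double ihhA = 0.0, ihhB = 0.0;
    for (int direction = -1; direction <= 1; direction += 2) {
      std::fill(lab.begin(), lab.end(), 0);
      int n_lab = 1;
      double eA = 1.0, eB = 1.0, eC = 1.0, prev = pos[core];
      for (int j = core + direction; j >= 0 && j < M; j += direction) {
        const double d = std::abs(pos[j] - prev);
        if (d > max_gap) break;
        n_lab = refine(hap, j, lab, n_lab, remap);
        const double nA2 = ehh_of(lab, rowsA, n_lab);
        const double nB2 = ehh_of(lab, rowsB, n_lab);
        const double nC2 = ehh_of(lab, rowsAll, n_lab);
        ihhA += d * 0.5 * (eA + nA2);
        ihhB += d * 0.5 * (eB + nB2);
        eA = nA2; eB = nB2; eC = nC2;
        prev = pos[j];
        if (eC < cutoff) break;
      }
    }
    out(ci, 0) = ihhA;
    out(ci, 1) = ihhB;
  }
  return out;
}
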