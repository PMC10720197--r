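#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Local (Plan7-style) Viterbi scan of a nucleotide profile HMM along one
// strand of one sequence, in log2-odds space. The alignment may begin at any
// match state (uniform entry, cost = begin_cost) and end at any match state.
// Insert emissions are scored against the background (log-odds 0).
//
// seq:  integer vector, 0..3 = A,C,G,T; negative = ambiguous (scores 0)
// msc:  4 x M matrix of match log2-odds emission scores
// tr:   M x 7 matrix of log2 transition scores, columns
//       0:MM 1:MI 2:MD 3:IM 4:II 5:DM 6:DD  (row j = transitions leaving
//       position j+1 toward position j+2; last row unused)
// Returns greedy non-overlapping hits with score >= score_min plus the
// global maximum cell score (used for E-value calibration).
// [[Rcpp::export]]
List viterbi_scan_cpp(IntegerVector seq, NumericMatrix msc, NumericMatrix tr,
                      double begin_cost, double score_min) {
  const int L = seq.size();
  const int M = msc.ncol();
  const double NEG = -1e30;

  // *_prev = row i-1, unsuffixed = row i (current).
  std::vector<double> vm_prev(M, NEG), vi_prev(M, NEG), vd_prev(M, NEG);
  std::vector<double> vm(M), vi(M), vd(M);
  std::vector<int> sm_prev(M, -1), si_prev(M, -1), sd_prev(M, -1);
  std::vector<int> sm(M), si(M), sd(M);

  // per end position: best score over match states and its start
  std::vector<double> best_score(L, NEG);
  std::vector<int> best_start(L, -1);
  double max_score = NEG;

  // raw column pointers (msc is 4 x M column-major; tr is M x 7)
  const double* mscp = msc.begin();
  const double* tMM = tr.begin();
  const double* tMI = tMM + M;
  const double* tMD = tMI + M;
  const double* tIM = tMD + M;
  const double* tII = tIM + M;
  const double* tDM = tII + M;
  const double* tDD = tDM + M;
  const int* sq = seq.begin();

  for (int i = 0; i < L; ++i) {
    const int x = sq[i];
    const double* ecol = (x >= 0) ? (mscp + 4 * 0) : 0; // per-j stride 4
    double* VM = vm.data();
    double* VI = vi.data();
    double* VD = vd.data();
    double* VMp = vm_prev.data();
    double* VIp = vi_prev.data();
    double* VDp = vd_prev.data();
    int* SM = sm.data();
    int* SI = si.data();
    int* SD = sd.data();
    int* SMp = sm_prev.data();
    int* SIp = si_prev.data();
    int* SDp = sd_prev.data();

    double bsc = NEG;
    int bst = -1;
    // register carry of prev-row values at j-1
    double vmp_l = NEG, vip_l = NEG, vdp_l = NEG;
    int smp_l = -1, sip_l = -1, sdp_l = -1;
    double vm_l = NEG, vd_l = NEG; // current row at j-1 (for D)
    int sm_l = -1, sd_l = -1;
    for (int j = 0; j < M; ++j) {
      const double e = (x >= 0) ? ecol[4 * j + x] : 0.0;
      const double vmp_j = VMp[j];
      const double vip_j = VIp[j];
      const double vdp_j = VDp[j];
      const int smp_j = SMp[j];
      const int sip_j = SIp[j];
      const int sdp_j = SDp[j];
      // M[i][j]
      double b = begin_cost;
      int st = i;
      if (j > 0) {
        const double a1 = vmp_l + tMM[j - 1];
        const double a2 = vip_l + tIM[j - 1];
        const double a3 = vdp_l + tDM[j - 1];
        if (a1 > b) { b = a1; st = smp_l; }
        if (a2 > b) { b = a2; st = sip_l; }
        if (a3 > b) { b = a3; st = sdp_l; }
      }
      const double vmj = e + b;
      VM[j] = vmj;
      SM[j] = st;
      // I[i][j]
      double bi = vmp_j + tMI[j];
      int sti = smp_j;
      const double bi2 = vip_j + tII[j];
      if (bi2 > bi) { bi = bi2; sti = sip_j; }
      VI[j] = bi;
      SI[j] = sti;
      // D[i][j] from current row j-1
      double vdj;
      int sdj;
      if (j > 0) {
        vdj = vm_l + tMD[j - 1];
        sdj = sm_l;
        const double bd2 = vd_l + tDD[j - 1];
        if (bd2 > vdj) { vdj = bd2; sdj = sd_l; }
      } else {
        vdj = NEG;
        sdj = -1;
      }
      VD[j] = vdj;
      SD[j] = sdj;
      if (vmj > bsc) { bsc = vmj; bst = st; }
      vmp_l = vmp_j; vip_l = vip_j; vdp_l = vdp_j;
      smp_l = smp_j; sip_l = sip_j; sdp_l = sdp_j;
      vm_l = vmj; sm_l = st; vd_l = vdj; sd_l = sdj;
    }
    best_score[i] = bsc;
    best_start[i] = bst;
    if (bsc > max_score) max_score = bsc;
    vm_prev.swap(vm);
    vi_prev.swap(vi);
    vd_prev.swap(vd);
    sm_prev.swap(sm);
    si_prev.swap(si);
    sd_prev.swap(sd);
  }

  // greedy non-overlapping extraction of candidate end positions
  std::vector<int> idx;
  for (int i = 0; i < L; ++i)
    if (best_score[i] >= score_min && best_start[i] >= 0) idx.push_back(i);
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (best_score[a] != best_score[b]) return best_score[a] > best_score[b];
    return a < b;
  });
  std::vector<std::pair<int, int> > taken; // [start, end)
  std::vector<int> hs, he;
  std::vector<double> hsc;
  for (size_t k = 0; k < idx.size(); ++k) {
    const int e = idx[k] + 1;
    const int s = best_start[idx[k]];
    bool ok = true;
    for (size_t q = 0; q < taken.size(); ++q)
      if (s < taken[q].second && taken[q].first < e) { ok = false; break; }
    if (ok) {
      taken.push_back(std::make_pair(s, e));
      hs.push_back(s);
      he.push_back(e);
      hsc.push_back(best_score[idx[k]]);
    }
  }
  return List::create(_["start"] = wrap(hs), _["end"] = wrap(he),
                      _["score"] = wrap(hsc), _["max_score"] = max_score);
}
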