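#include <Rcpp.h>
using namespace Rcpp;

// Ungapped sliding-window assignment of C->T collapsed reads against
// C->T converted references. Positions flagged in the CpG mask are
// excluded from the mismatch count (a methylated C read against a
// converted-T reference is biology, not sequencing error).
//
// Returns an n x 4 integer matrix per read:
//   col 0: best amplicon (1-based; 0 = unassigned)
//   col 1: best offset (0-based)
//   col 2: mismatch count at the best placement
//   col 3: tie flag (1 = two amplicons at equal best score)
// [[Rcpp::export(name = ".cpp_assign_reads")]]
IntegerMatrix cpp_assign_reads(CharacterVector reads,
                               CharacterVector refs,
                               List cpg_masks,
                               double max_mismatch_rate) {
  const int n = reads.size();
  const int na = refs.size();
  std::vector<std::string> ref_s(na);
  std::vector<std::vector<bool>> mask(na);
  for (int a = 0; a < na; ++a) {
    ref_s[a] = as<std::string>(refs[a]);
    LogicalVector m = cpg_masks[a];
    mask[a].assign(m.begin(), m.end());
    if ((int)mask[a].size() != (int)ref_s[a].size())
      stop("CpG mask length does not match reference length");
  }
  IntegerMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int lr = rd.size();
    int best_amp = -1, best_off = -1, best_mm = INT_MAX;
    bool tie = false;
    for (int a = 0; a < na; ++a) {
      const std::string &rf = ref_s[a];
      const int L = rf.size();
      if (lr > L) continue;
      int amp_best = INT_MAX, amp_off = -1;
      for (int off = 0; off + lr <= L; ++off) {
        int mm = 0;
        for (int j = 0; j < lr; ++j) {
          if (mask[a][off + j]) continue;
          if (rd[j] != rf[off + j] && ++mm >= amp_best) break;
        }
        if (mm < amp_best) { amp_best = mm; amp_off = off; }
      }
      if (amp_best < best_mm) {
        best_mm = amp_best; best_amp = a; best_off = amp_off; tie = false;
      } else if (amp_best == best_mm && amp_best != INT_MAX &&
                 a != best_amp) {
        tie = true;
      }
    }
    bool ok = best_amp >= 0 && !tie &&
      best_mm <= max_mismatch_rate * (double)lr;
    out(i, 0) = ok ? best_amp + 1 : 0;
    out(i, 1) = ok ? best_off : NA_INTEGER;
    out(i, 2) = best_amp >= 0 ? best_mm : NA_INTEGER;
    out(i, 3) = tie ? 1 : 0;
  }
  return out;
}
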