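#include <Rcpp.h>
using namespace Rcpp;

// Ungapped X-drop extension of exact word seeds on one frame pair.
// q, s: 0-based integer-encoded amino-acid sequences (indices into sm).
// sm: substitution matrix (square, same encoding).
// qpos, spos: 0-based seed start positions (parallel vectors), assumed
// sorted by (diagonal, qpos).
// Returns one row per surviving hit: qstart, qend, sstart, send (0-based
// half-open, aa coords), raw score, identities.
// [[Rcpp::export(name = ".cc_seed_extend")]]
DataFrame cc_seed_extend(IntegerVector q, IntegerVector s,
                         IntegerMatrix sm, IntegerVector qpos,
                         IntegerVector spos, int wordSize, int xdrop) {
  int nq = q.size(), ns = s.size(), nseed = qpos.size();
  std::vector<int> oqs, oqe, oss, ose, osc, oid;
  long lastDiag = 2147483647L;
  int lastReach = -1;  // q end (exclusive) of last hit on lastDiag
  for (int k = 0; k < nseed; ++k) {
    int qp = qpos[k], sp = spos[k];
    long diag = (long)qp - (long)sp;
    if (diag == lastDiag && qp < lastReach) continue;  // inside previous hit
    // score the seed word
    int score = 0;
    for (int i = 0; i < wordSize; ++i) score += sm(q[qp + i], s[sp + i]);
    int best = score, bestL = 0, bestR = wordSize;
    // extend right
    int cur = score;
    int i = qp + wordSize, j = sp + wordSize, r = wordSize;
    while (i < nq && j < ns) {
      cur += sm(q[i], s[j]);
      ++i; ++j; ++r;
      if (cur > best) { best = cur; bestR = r; }
      if (best - cur > xdrop) break;
    }
    // extend left
    cur = best;
    int l = 0;
    i = qp - 1; j = sp - 1;
    int curTail = 0;  // running score relative to best at bestR with left ext
    curTail = best;
    while (i >= 0 && j >= 0) {
      curTail += sm(q[i], s[j]);
      --i; --j; ++l;
      if (curTail > best) { best = curTail; bestL = l; }
      if (best - curTail > xdrop) break;
    }
    int qs0 = qp - bestL, qe0 = qp + bestR;
    int ss0 = sp - bestL, se0 = sp + bestR;
    int ident = 0;
    for (int a = 0; a < qe0 - qs0; ++a)
      if (q[qs0 + a] == s[ss0 + a]) ++ident;
    oqs.push_back(qs0); oqe.push_back(qe0);
    oss.push_back(ss0); ose.push_back(se0);
    osc.push_back(best); oid.push_back(ident);
    lastDiag = diag;
    lastReach = qe0;
  }
  return DataFrame::create(_["qstart"] = oqs, _["qend"] = oqe,
                           _["sstart"] = oss, _["send"] = ose,
                           _["score"] = osc, _["identities"] = oid);
}
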