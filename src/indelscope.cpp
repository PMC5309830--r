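#include <Rcpp.h>
#include <climits>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// Event kinds (kept in sync with .EVENT_KINDS on the R side):
// 1 = deletion, 2 = insertion, 3 = substitution
struct Ev {
  int kind;
  int start0;  // 0-based: del/sub = first affected ref base; ins = ref index
               // the inserted bases precede (junction between start0-1 and start0)
  int len;
  std::string alt;
};

// Semi-global affine-gap alignment of each query against one reference.
// Reference end gaps are free (the query is amplicon-contained); the full
// query must align. Gap of length L costs gapOpen + L * gapExtend.
// Traceback tie-break: M over D over I at equal score; endpoint tie-break:
// smallest reference end. Indels are left-shifted to the smallest reference
// coordinate and adjacent same-kind events coalesced.
// [[Rcpp::export]]
List cpp_align_reads(CharacterVector queries, std::string ref,
                     int match, int mismatch, int gapOpen, int gapExtend) {
  const int n = (int) ref.size();
  const int nq = queries.size();
  IntegerVector outScore(nq), outStart(nq), outEnd(nq);
  CharacterVector outCigar(nq);
  std::vector<int> evRead, evKind, evStart, evLen;
  std::vector<std::string> evAlt;

  // rolling score rows (the traceback only needs the packed byte pointers)
  std::vector<int> Mp, Ip, Dp, Mc, Ic, Dc;
  std::vector<unsigned char> pM, pI, pD;

  for (int r = 0; r < nq; ++r) {
    std::string q = as<std::string>(queries[r]);
    const int m = (int) q.size();
    if (m == 0) stop("empty query at index %d", r + 1);
    const size_t sz = (size_t)(m + 1) * (n + 1);
    if (pM.size() < sz) { pM.resize(sz); pI.resize(sz); pD.resize(sz); }
    if (Mp.size() < (size_t)(n + 1)) {
      Mp.resize(n + 1); Ip.resize(n + 1); Dp.resize(n + 1);
      Mc.resize(n + 1); Ic.resize(n + 1); Dc.resize(n + 1);
    }
    for (int j = 0; j <= n; ++j) { Mp[j] = 0; Ip[j] = NEG; Dp[j] = NEG; }

    for (int i = 1; i <= m; ++i) {
      const size_t row = (size_t)i * (n + 1);
      Mc[0] = NEG; Dc[0] = NEG;
      {
        int a = Mp[0] + gapOpen + gapExtend; unsigned char st = 0;
        int d = Dp[0] + gapOpen + gapExtend;
        int ii = Ip[0] + gapExtend;
        if (d > a) { a = d; st = 2; }
        if (ii > a) { a = ii; st = 1; }
        Ic[0] = a; pI[row] = st;
      }
      const char qc = q[i - 1];
      for (int j = 1; j <= n; ++j) {
        const size_t c = row + j;
        {
          int a = Mp[j - 1]; unsigned char st = 0;
          if (Dp[j - 1] > a) { a = Dp[j - 1]; st = 2; }
          if (Ip[j - 1] > a) { a = Ip[j - 1]; st = 1; }
          Mc[j] = a + ((qc == ref[j - 1]) ? match : mismatch);
          pM[c] = st;
        }
        {
          int a = Mp[j] + gapOpen + gapExtend; unsigned char st = 0;
          int d = Dp[j] + gapOpen + gapExtend;
          int ii = Ip[j] + gapExtend;
          if (d > a) { a = d; st = 2; }
          if (ii > a) { a = ii; st = 1; }
          Ic[j] = a; pI[c] = st;
        }
        {
          int a = Mc[j - 1] + gapOpen + gapExtend; unsigned char st = 0;
          int d = Dc[j - 1] + gapExtend;
          int ii = Ic[j - 1] + gapOpen + gapExtend;
          if (d > a) { a = d; st = 2; }
          if (ii > a) { a = ii; st = 1; }
          Dc[j] = a; pD[c] = st;
        }
      }
      Mp.swap(Mc); Ip.swap(Ic); Dp.swap(Dc);
    }

    // endpoint: free reference suffix, prefer M over D over I, smallest j
    int best = NEG - 1, endJ = 0, endState = 0;
    for (int j = 0; j <= n; ++j) {
      const int vM = Mp[j], vD = Dp[j], vI = Ip[j];
      if (vM > best) { best = vM; endJ = j; endState = 0; }
      if (vD > best) { best = vD; endJ = j; endState = 2; }
      if (vI > best) { best = vI; endJ = j; endState = 1; }
    }

    std::string opsRev;
    int i = m, j = endJ, st = endState;
    while (i > 0) {
      const size_t c = (size_t)i * (n + 1) + j;
      if (st == 0)      { opsRev.push_back('M'); st = pM[c]; --i; --j; }
      else if (st == 1) { opsRev.push_back('I'); st = pI[c]; --i; }
      else              { opsRev.push_back('D'); st = pD[c]; --j; }
    }
    const int refStart0 = j;
    std::reverse(opsRev.begin(), opsRev.end());

    // coalesce path columns into events + CIGAR (with =/X distinction)
    std::vector<Ev> evs;
    std::string cigar;
    int rp = refStart0, qp = 0;
    const int k2 = (int) opsRev.size();
    int t = 0;
    while (t < k2) {
      const char op = opsRev[t];
      if (op == 'M') {
        const bool mm = (q[qp] != ref[rp]);
        const int rp0 = rp; int L = 0; std::string alt;
        while (t < k2 && opsRev[t] == 'M' && ((q[qp] != ref[rp]) == mm)) {
          if (mm) alt.push_back(q[qp]);
          ++t; ++qp; ++rp; ++L;
        }
        cigar += std::to_string(L); cigar.push_back(mm ? 'X' : '=');
        if (mm) evs.push_back(Ev{3, rp0, L, alt});
      } else if (op == 'I') {
        int L = 0; std::string alt;
        while (t < k2 && opsRev[t] == 'I') { alt.push_back(q[qp]); ++t; ++qp; ++L; }
        cigar += std::to_string(L); cigar.push_back('I');
        evs.push_back(Ev{2, rp, L, alt});
      } else {
        const int rp0 = rp; int L = 0;
        while (t < k2 && opsRev[t] == 'D') { ++t; ++rp; ++L; }
        cigar += std::to_string(L); cigar.push_back('D');
        evs.push_back(Ev{1, rp0, L, ""});
      }
    }
    const int refEnd0 = rp;  // exclusive

    // left-normalize indels (VCF-style), bounded by the previous event
    for (size_t e = 0; e < evs.size(); ++e) {
      int low = refStart0;
      if (e > 0) {
        const Ev &p = evs[e - 1];
        low = (p.kind == 2) ? p.start0 : p.start0 + p.len;
      }
      Ev &ev = evs[e];
      if (ev.kind == 1) {
        while (ev.start0 > low && ref[ev.start0 - 1] == ref[ev.start0 + ev.len - 1])
          --ev.start0;
      } else if (ev.kind == 2) {
        while (ev.start0 > low && ref[ev.start0 - 1] == ev.alt[ev.len - 1]) {
          ev.alt = std::string(1, ref[ev.start0 - 1]) + ev.alt.substr(0, ev.len - 1);
          --ev.start0;
        }
      }
    }
    std::vector<Ev> evs2;
    for (size_t e = 0; e < evs.size(); ++e) {
      Ev &ev = evs[e];
      if (!evs2.empty()) {
        Ev &p = evs2.back();
        if (p.kind == 1 && ev.kind == 1 && ev.start0 == p.start0 + p.len) {
          p.len += ev.len; continue;
        }
        if (p.kind == 2 && ev.kind == 2 && ev.start0 == p.start0) {
          p.alt += ev.alt; p.len += ev.len; continue;
        }
      }
      evs2.push_back(ev);
    }

    outScore[r] = best;
    outStart[r] = refStart0 + 1;
    outEnd[r] = refEnd0;  // 1-based inclusive end == 0-based exclusive end
    outCigar[r] = cigar;
    for (size_t e = 0; e < evs2.size(); ++e) {
      evRead.push_back(r + 1);
      evKind.push_back(evs2[e].kind);
      evStart.push_back(evs2[e].start0 + 1);
      evLen.push_back(evs2[e].len);
      evAlt.push_back(evs2[e].alt);
    }
  }

  return List::create(
    _["score"] = outScore, _["refStart"] = outStart, _["refEnd"] = outEnd,
    _["cigar"] = outCigar,
    _["evRead"] = wrap(evRead), _["evKind"] = wrap(evKind),
    _["evStart"] = wrap(evStart), _["evLen"] = wrap(evLen),
    _["evAlt"] = wrap(evAlt));
}

static char complement(char b) {
  switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// Exhaustive-offset merging of a forward/reverse read pair. All relative
// placements of the reverse-complemented mate with overlap >= minOverlap are
// scored; the placement minimising the mismatch fraction wins (ties: longer
// overlap, then smaller offset). Disagreeing overlap bases take the
// higher-quality call (r1 on quality ties); agreeing bases take the max
// quality.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector s1v, CharacterVector q1v,
                     CharacterVector s2v, CharacterVector q2v,
                     int minOverlap, double maxMismatchFrac) {
  const int np = s1v.size();
  LogicalVector merged(np);
  CharacterVector mseq(np), mqual(np);
  IntegerVector ovLen(np), nMis(np), offset(np);

  for (int r = 0; r < np; ++r) {
    std::string s1 = as<std::string>(s1v[r]);
    std::string q1 = as<std::string>(q1v[r]);
    std::string s2 = as<std::string>(s2v[r]);
    std::string q2 = as<std::string>(q2v[r]);
    const int L1 = (int) s1.size(), L2 = (int) s2.size();
    merged[r] = false; ovLen[r] = 0; nMis[r] = 0; offset[r] = NA_INTEGER;
    mseq[r] = NA_STRING; mqual[r] = NA_STRING;
    if (L1 < 1 || L2 < 1 || L1 + L2 < 2 * 1) continue;

    std::string s2r(L2, 'N'), q2r(L2, '!');
    for (int k = 0; k < L2; ++k) {
      s2r[k] = complement(s2[L2 - 1 - k]);
      q2r[k] = q2[L2 - 1 - k];
    }

    int bestMm = 0, bestOv = -1, bestO = 0;
    for (int o = -(L2 - minOverlap); o <= L1 - minOverlap; ++o) {
      const int a = std::max(0, o), b = std::min(L1, o + L2);
      const int ov = b - a;
      if (ov < minOverlap) continue;
      int mm = 0;
      for (int k = a; k < b; ++k) if (s1[k] != s2r[k - o]) ++mm;
      bool better;
      if (bestOv < 0) better = true;
      else {
        const long long lhs = (long long) mm * bestOv;
        const long long rhs = (long long) bestMm * ov;
        better = (lhs < rhs) || (lhs == rhs && ov > bestOv);
      }
      if (better) { bestMm = mm; bestOv = ov; bestO = o; }
    }
    if (bestOv < minOverlap) continue;
    if ((double) bestMm / (double) bestOv > maxMismatchFrac) {
      ovLen[r] = bestOv; nMis[r] = bestMm; offset[r] = bestO;
      continue;
    }

    const int o = bestO;
    const int lo = std::min(0, o), hi = std::max(L1, o + L2);
    std::string ms; ms.reserve(hi - lo);
    std::string mq; mq.reserve(hi - lo);
    for (int t = lo; t < hi; ++t) {
      const bool in1 = (t >= 0 && t < L1);
      const bool in2 = (t >= o && t < o + L2);
      if (in1 && in2) {
        const char b1 = s1[t], b2 = s2r[t - o];
        const char c1 = q1[t], c2 = q2r[t - o];
        if (b1 == b2) { ms.push_back(b1); mq.push_back(std::max(c1, c2)); }
        else if (c2 > c1) { ms.push_back(b2); mq.push_back(c2); }
        else { ms.push_back(b1); mq.push_back(c1); }
      } else if (in1) { ms.push_back(s1[t]); mq.push_back(q1[t]); }
      else { ms.push_back(s2r[t - o]); mq.push_back(q2r[t - o]); }
    }
    merged[r] = true; ovLen[r] = bestOv; nMis[r] = bestMm; offset[r] = bestO;
    mseq[r] = ms; mqual[r] = mq;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq, _["qual"] = mqual,
                      _["overlap"] = ovLen, _["mismatches"] = nMis,
                      _["offset"] = offset);
}

// 3' adapter removal (best match = most matching bases among candidates with
// <= 10% mismatches and >= 3 nt overlap) followed by running-sum 3' quality
// trimming at qualCutoff. Returns the retained prefix length per read.
// [[Rcpp::export]]
IntegerVector cpp_trim_lengths(CharacterVector seqs, CharacterVector quals,
                               std::string adapter, int qualCutoff) {
  const int nr = seqs.size();
  const int alen = (int) adapter.size();
  IntegerVector keep(nr);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::string q = as<std::string>(quals[r]);
    int len = (int) s.size();

    if (alen > 0) {
      int bestScore = -1, bestPos = -1;
      for (int p = 0; p < len; ++p) {
        const int ov = std::min(alen, len - p);
        if (ov < 3) break;
        int mm = 0;
        for (int k = 0; k < ov; ++k) if (s[p + k] != adapter[k]) ++mm;
        if (mm * 10 <= ov) {  // <= 10% mismatches
          const int score = ov - mm;
          if (score > bestScore) { bestScore = score; bestPos = p; }
        }
      }
      if (bestPos >= 0) len = bestPos;
    }

    // running-sum quality trim: cut at the leftmost minimum of the
    // 3'-anchored partial sums of (q - cutoff), if negative
    long long cs = 0, minCs = 0;
    int cut = len;  // number of leading bases kept
    for (int k = len - 1; k >= 0; --k) {
      cs += (int)(q[k] - 33) - qualCutoff;
      if (cs <= minCs) { minCs = cs; if (cs < 0) cut = k; }
    }
    keep[r] = cut;
  }
  return keep;
}
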