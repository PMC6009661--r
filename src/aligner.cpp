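#include <Rcpp.h>
#include <cstring>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

// Banded overlap (free end-gap) alignment with affine gaps, Gotoh recursion.
// Conventions:
//   - op codes: 0 = match, 1 = mismatch, 2 = insertion (read-consuming),
//     3 = deletion (ref-consuming).
//   - a gap of length k costs gap_open + k * gap_ext (BWA-style).
//   - leading/trailing gaps on either sequence are free; read overhang beyond
//     the reference is emitted as unpenalised insertion ops so that the op
//     list consumes the full read.
// The band restricts the diagonal j - i to
//   [min(0, n - m) - band, max(0, n - m) + band]; band < 0 disables banding.

static const int NEG = -(1 << 28);

struct AlnResult {
  int score;
  int ref_start, ref_end;
  std::vector<unsigned char> ops;
  bool ok;
};

static AlnResult align_overlap(const std::string &ref, const std::string &read,
                               int match, int mismatch, int gap_open,
                               int gap_ext, int band) {
  const int m = (int)ref.size(), n = (int)read.size();
  AlnResult res;
  res.ok = false;
  if (m == 0 || n == 0) {
    res.score = 0;
    res.ref_start = 0;
    res.ref_end = 0;
    if (n > 0) res.ops.assign(n, 2);
    res.ok = true;
    return res;
  }
  int dmin, dmax;
  if (band < 0) {
    dmin = -m;
    dmax = n;
  } else {
    dmin = std::min(0, n - m) - band;
    dmax = std::max(0, n - m) + band;
  }
  if (dmin < -m) dmin = -m;
  if (dmax > n) dmax = n;
  const int W = dmax - dmin + 1;
  const int go = gap_open + gap_ext;

  std::vector<int> H((size_t)(m + 1) * W, NEG), E((size_t)(m + 1) * W, NEG),
      F((size_t)(m + 1) * W, NEG);
  // traceback byte: bits 0-1 H source (0 diag, 1 E, 2 F), bit 2 E opened,
  // bit 3 F opened
  std::vector<unsigned char> TB((size_t)(m + 1) * W, 0);

  auto idx = [&](int i, int j) { return (size_t)i * W + (j - i - dmin); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= n && j - i >= dmin && j - i <= dmax;
  };
  auto getH = [&](int i, int j) -> int {
    if (i == 0) return (j >= 0 && j <= dmax) ? 0 : NEG;
    if (j == 0) return (i <= -dmin) ? 0 : NEG;
    if (!inband(i, j)) return NEG;
    return H[idx(i, j)];
  };
  auto getE = [&](int i, int j) -> int {
    if (i == 0 || j <= 0 || !inband(i, j)) return NEG;
    return E[idx(i, j)];
  };
  auto getF = [&](int i, int j) -> int {
    if (i <= 0 || j == 0 || !inband(i, j)) return NEG;
    return F[idx(i, j)];
  };

  // seed the free boundaries inside the band storage so the hot loop can use
  // constant-offset neighbour access:
  //   idx(i, j-1) = k - 1; idx(i-1, j) = k - W + 1; idx(i-1, j-1) = k - W
  {
    int jhi0 = std::min(n, dmax);
    for (int j = 0; j <= jhi0; ++j)
      if (j - dmin >= 0 && j - dmin < W) H[idx(0, j)] = 0;  // H(0, j) = 0
    for (int i = 1; i <= std::min(m, -dmin); ++i) H[idx(i, 0)] = 0;
  }
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(1, i + dmin), jhi = std::min(n, i + dmax);
    if (jlo > jhi) continue;
    const char ri = ref[i - 1];
    int *Hp = &H[0], *Ep = &E[0], *Fp = &F[0];
    unsigned char *Tp = &TB[0];
    size_t k = idx(i, jlo);
    for (int j = jlo; j <= jhi; ++j, ++k) {
      unsigned char tb = 0;
      const bool leftOk = (j - 1 >= i + dmin);  // (i, j-1) in band (or j-1==0)
      const int hl = leftOk ? Hp[k - 1] : NEG;
      const int el = leftOk ? Ep[k - 1] : NEG;
      const int eOpen = hl - go, eExt = el - gap_ext;
      int e = eOpen >= eExt ? (tb |= 4, eOpen) : eExt;
      Ep[k] = e;
      const bool upOk = (j <= (i - 1) + dmax);  // (i-1, j) in band
      const int hu = upOk ? Hp[k - W + 1] : NEG;
      const int fu = upOk ? Fp[k - W + 1] : NEG;
      const int fOpen = hu - go, fExt = fu - gap_ext;
      int f = fOpen >= fExt ? (tb |= 8, fOpen) : fExt;
      Fp[k] = f;
      const int s = (ri == read[j - 1]) ? match : mismatch;
      int h = Hp[k - W] + s;
      unsigned char src = 0;
      if (e > h) { h = e; src = 1; }
      if (f > h) { h = f; src = 2; }
      Hp[k] = h;
      Tp[k] = tb | src;
    }
  }

  // End anywhere on the last row (read exhausted later = overhang) or last
  // column (ref exhausted). Ties prefer larger i + j, then larger i.
  int best = NEG, bi = -1, bj = -1;
  for (int j = std::max(0, m + dmin); j <= std::min(n, m + dmax); ++j) {
    int v = getH(m, j);
    if (v > best || (v == best && (m + j > bi + bj || (m + j == bi + bj && m > bi)))) {
      best = v;
      bi = m;
      bj = j;
    }
  }
  for (int i = std::max(0, n - dmax); i <= std::min(m, n - dmin); ++i) {
    int v = getH(i, n);
    if (v > best || (v == best && (i + n > bi + bj || (i + n == bi + bj && i > bi)))) {
      best = v;
      bi = i;
      bj = n;
    }
  }
  if (bi < 0) return res;  // band too narrow, no valid endpoint

  std::vector<unsigned char> rops;
  rops.reserve(m + n);
  for (int j = bj; j < n; ++j) rops.push_back(2);  // trailing read overhang
  std::reverse(rops.begin(), rops.end());
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (getH(i, j) == 0 && i == 0) break;
      unsigned char tb = inband(i, j) ? TB[idx(i, j)] : 0;
      int src = tb & 3;
      if (src == 0) {
        // guard: boundary-start diag (score came from H(i-1,j-1) boundary)
        rops.push_back(ref[i - 1] == read[j - 1] ? 0 : 1);
        --i;
        --j;
      } else if (src == 1) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      unsigned char tb = TB[idx(i, j)];
      rops.push_back(2);
      --j;
      if (tb & 4) state = 0;
    } else {
      unsigned char tb = TB[idx(i, j)];
      rops.push_back(3);
      --i;
      if (tb & 8) state = 0;
    }
  }
  int ref_start = i;
  for (int jj = j; jj > 0; --jj) rops.push_back(2);  // leading read overhang
  std::reverse(rops.begin(), rops.end());
  res.score = best;
  res.ref_start = ref_start;
  res.ref_end = bi;
  res.ops = rops;
  res.ok = true;
  return res;
}

// [[Rcpp::export(name = ".align_overlap_cpp")]]
List align_overlap_cpp(std::string ref, std::string read, int match,
                       int mismatch, int gap_open, int gap_ext, int band) {
  AlnResult r = align_overlap(ref, read, match, mismatch, gap_open, gap_ext,
                              band);
  if (!r.ok) return List::create(Named("ok") = false);
  IntegerVector ops(r.ops.size());
  for (size_t k = 0; k < r.ops.size(); ++k) ops[k] = r.ops[k];
  return List::create(Named("ok") = true, Named("score") = r.score,
                      Named("ref_start") = r.ref_start,
                      Named("ref_end") = r.ref_end, Named("ops") = ops);
}

// canonicalise indel placement: shift each indel run to its leftmost
// equivalent position (preceding column is a match and the trailing indel
// base equals the preceding reference base). Mirrors the R-level
// normalisation used on read-to-reference alignments.
static void left_align_ops(std::vector<unsigned char> &ops,
                           const std::string &ref, const std::string &read,
                           int ref_start) {
  const int n = (int)ops.size();
  bool moved = true;
  while (moved) {
    moved = false;
    // per-op 1-based coordinates
    std::vector<int> refIdx(n), readIdx(n);
    int ri = ref_start, rj = 0;
    for (int k = 0; k < n; ++k) {
      if (ops[k] != 2) ++ri;
      if (ops[k] != 3) ++rj;
      refIdx[k] = ri;
      readIdx[k] = rj;
    }
    int k = 0;
    while (k < n) {
      unsigned char v = ops[k];
      if (v != 2 && v != 3) { ++k; continue; }
      int s = k, e = k;
      while (e + 1 < n && ops[e + 1] == v) ++e;
      int snext = e + 1;
      while (s > 0 && ops[s - 1] == 0) {
        bool okShift;
        if (v == 3) {
          int a = refIdx[s], b = refIdx[e];
          okShift = (a >= 2) && ref[a - 2] == ref[b - 1];
        } else {
          int jb = readIdx[e], pa = refIdx[s - 1];
          okShift = (pa >= 1) && read[jb - 1] == ref[pa - 1];
        }
        if (!okShift) break;
        ops[s - 1] = v;
        ops[e] = 0;
        --s; --e;
        moved = true;
        // recompute coordinates locally
        ri = (s >= 1) ? refIdx[s - 1] : ref_start;
        rj = (s >= 1) ? readIdx[s - 1] : 0;
        for (int t = s; t < n; ++t) {
          if (ops[t] != 2) ++ri;
          if (ops[t] != 3) ++rj;
          refIdx[t] = ri;
          readIdx[t] = rj;
        }
      }
      k = snext;
    }
  }
  // re-derive match/mismatch codes
  int ri = ref_start, rj = 0;
  for (int k = 0; k < n; ++k) {
    if (ops[k] == 0 || ops[k] == 1) {
      ops[k] = (ref[ri] == read[rj]) ? 0 : 1;
      ++ri; ++rj;
    } else if (ops[k] == 3) ++ri;
    else ++rj;
  }
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return 0;
  }
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline int phred_from_fraction(double f) {
  double e = 1.0 - f;
  double floor_e = std::pow(10.0, -9.3);
  if (e < floor_e) e = floor_e;
  int q = (int)std::lround(-10.0 * std::log10(e));
  if (q > 93) q = 93;
  if (q < 0) q = 0;
  return q;
}

// one round of column-wise majority voting of the subreads against a draft
static void consensus_round(const std::vector<std::string> &reads,
                            const std::string &draft, int match, int mismatch,
                            int gap_open, int gap_ext, int band,
                            std::string &seq, std::vector<int> &qual) {
  const int L = (int)draft.size();
  std::vector<int> counts((size_t)L * 5, 0);
  std::vector<int> coverDiff(L + 2, 0);  // junction coverage (diff array)
  std::map<std::pair<int, std::string>, int> insCount;
  std::vector<int> insAny(L + 1, 0);  // reads with any insertion at junction

  for (size_t s = 0; s < reads.size(); ++s) {
    const std::string &rd = reads[s];
    AlnResult a = align_overlap(draft, rd, match, mismatch, gap_open, gap_ext,
                                band);
    if (!a.ok) continue;
    left_align_ops(a.ops, draft, rd, a.ref_start);
    int i = a.ref_start, j = 0;
    std::string pending;
    auto flush = [&](int at) {
      if (!pending.empty()) {
        if (at >= a.ref_start && at <= a.ref_end) {
          insCount[std::make_pair(at, pending)] += 1;
          insAny[at] += 1;
        }
        pending.clear();
      }
    };
    for (size_t k = 0; k < a.ops.size(); ++k) {
      unsigned char op = a.ops[k];
      if (op == 0 || op == 1) {
        flush(i);
        counts[(size_t)i * 5 + base_code(rd[j])] += 1;
        ++i;
        ++j;
      } else if (op == 3) {
        flush(i);
        counts[(size_t)i * 5 + 4] += 1;
        ++i;
      } else {
        pending.push_back(rd[j]);
        ++j;
      }
    }
    flush(i);  // trailing insertion / read overhang at the end junction
    // junction coverage: [ref_start, ref_end] inclusive
    coverDiff[a.ref_start] += 1;
    coverDiff[a.ref_end + 1] -= 1;
  }

  std::vector<int> junCover(L + 1, 0);
  int run = 0;
  for (int j = 0; j <= L; ++j) {
    run += coverDiff[j];
    junCover[j] = run;
  }

  // trim draft overhang: terminal columns covered by fewer than half of the
  // reads are unsupported end noise of the draft, not consensus sequence
  const int N = (int)reads.size();
  int firstCol = 0, lastCol = L - 1;
  auto colCovered = [&](int i) {
    const int *ct = &counts[(size_t)i * 5];
    return ct[0] + ct[1] + ct[2] + ct[3] + ct[4];
  };
  while (firstCol < L && colCovered(firstCol) * 2 < N) ++firstCol;
  while (lastCol >= 0 && colCovered(lastCol) * 2 < N) --lastCol;

  seq.clear();
  qual.clear();
  seq.reserve(L + 8);
  for (int i = firstCol; i <= lastCol + 1 && i <= L; ++i) {
    // majority insertion before column i (ties inclusive; the plurality
    // string among the insertion-bearing reads is emitted)
    if (i >= firstCol && i <= lastCol + 1 && junCover[i] > 0 &&
        insAny[i] >= 2 && insAny[i] * 10 >= 3 * junCover[i]) {
      int bestC = 0;
      std::string bestS;
      for (auto it = insCount.lower_bound(std::make_pair(i, std::string()));
           it != insCount.end() && it->first.first == i; ++it) {
        if (it->second > bestC ||
            (it->second == bestC && it->first.second < bestS)) {
          bestC = it->second;
          bestS = it->first.second;
        }
      }
      if (bestC > 0) {
        int q = phred_from_fraction((double)bestC / junCover[i]);
        for (size_t b = 0; b < bestS.size(); ++b) {
          seq.push_back(bestS[b]);
          qual.push_back(q);
        }
      }
    }
    if (i > lastCol || i == L) break;
    const int *ct = &counts[(size_t)i * 5];
    int covered = ct[0] + ct[1] + ct[2] + ct[3] + ct[4];
    if (covered == 0) {  // uncovered draft column: keep draft base, qual 0
      seq.push_back(draft[i]);
      qual.push_back(0);
      continue;
    }
    int win = 0, winC = ct[0];
    for (int b = 1; b < 4; ++b)
      if (ct[b] > winC) {
        win = b;
        winC = ct[b];
      }
    if (ct[4] > winC) {
      win = 4;
      winC = ct[4];
    }
    if (win == 4) continue;  // majority deletion: drop column
    seq.push_back(BASES[win]);
    qual.push_back(phred_from_fraction((double)winC / covered));
  }
}

// Majority-vote consensus over subreads aligned pairwise to a draft. The
// initial draft is the lexicographically smallest among the longest
// subreads (so the result is invariant to subread order); voting is then
// repeated with the emerging consensus as the new draft until it is stable
// (at most three rounds), which resolves indel-placement ambiguity left by
// a noisy initial draft. Column winner: highest count, ties prefer a base
// over a gap, then A < C < G < T. Per-base quality is the Phred-scaled
// column agreement min(93, round(-10 log10(max(1 - f, 10^-9.3)))).
// [[Rcpp::export(name = ".build_consensus_cpp")]]
List build_consensus_cpp(CharacterVector subreads, int match, int mismatch,
                         int gap_open, int gap_ext, int band) {
  const int N = subreads.size();
  if (N == 0) stop("no subreads");
  std::vector<std::string> reads(N);
  for (int s = 0; s < N; ++s) reads[s] = as<std::string>(subreads[s]);
  int di = 0;
  for (int s = 1; s < N; ++s) {
    if (reads[s].size() > reads[di].size() ||
        (reads[s].size() == reads[di].size() && reads[s] < reads[di]))
      di = s;
  }
  std::string draft = reads[di];
  std::string seq;
  std::vector<int> qual;
  for (int round = 0; round < 4; ++round) {
    consensus_round(reads, draft, match, mismatch, gap_open, gap_ext, band,
                    seq, qual);
    if (seq == draft) break;
    draft = seq;
  }
  return List::create(Named("seq") = seq, Named("qual") = wrap(qual));
}
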