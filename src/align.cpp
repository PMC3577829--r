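// Alignment kernels shared by the mapper, assembler polish, damage and
// comparison modules.  All coordinates are 0-based half-open; strings are
// over {A,C,G,T,N}.  Cost model (read placement): 2 per mismatch, 3 per
// inserted base (extra read base), 3 per deleted base (skipped target
// base); N never matches.

#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline char complement_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = complement_base(s[i]);
  return out;
}

static inline int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// ---------------------------------------------------------------------------
// Fitting ("semiglobal") alignment: the read is aligned end to end, the
// target window has free leading and trailing gaps.  Minimises
//   mmc * mismatches + ic * inserted_bases + dc * deleted_bases.
// Traceback preference on ties: diagonal, then insertion, then deletion,
// and the smallest end column, so results are deterministic.
// ---------------------------------------------------------------------------

struct FitRes {
  bool ok;
  int cost, ws, we;           // window start / end (half-open) of the placement
  int nmatch, nmis, nins, ndel;
  std::string cigar;          // runs of M / I / D over the read placement
};

static FitRes fit_core(const std::string& rd, const std::string& win,
                       int mmc, int ic, int dc, int band, int diag0) {
  const int n = (int) rd.size();
  const int m = (int) win.size();
  const int INF = INT_MAX / 4;
  FitRes res; res.ok = false;
  res.cost = INF; res.ws = res.we = 0;
  res.nmatch = res.nmis = res.nins = res.ndel = 0;
  if (n == 0 || m == 0) return res;

  std::vector<int> D((size_t)(n + 1) * (m + 1), INF);
  // 0 = diagonal, 1 = up (insertion), 2 = left (deletion), 3 = free start
  std::vector<signed char> TB((size_t)(n + 1) * (m + 1), -1);

  auto lo = [&](int i) { return band < 0 ? 0 : std::max(0, i + diag0 - band); };
  auto hi = [&](int i) { return band < 0 ? m : std::min(m, i + diag0 + band); };

  for (int j = lo(0); j <= hi(0); ++j) {
    D[(size_t)j] = 0;
    TB[(size_t)j] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    const int jl = lo(i), jh = hi(i);
    for (int j = jl; j <= jh; ++j) {
      const size_t idx = (size_t)i * (m + 1) + j;
      int best = INF; signed char tb = -1;
      if (j >= 1) {
        const size_t d = (size_t)(i - 1) * (m + 1) + (j - 1);
        if (D[d] < INF) {
          const char a = rd[i - 1], b = win[j - 1];
          const int c = D[d] + ((a == b && a != 'N') ? 0 : mmc);
          if (c < best) { best = c; tb = 0; }
        }
      }
      {
        const size_t u = (size_t)(i - 1) * (m + 1) + j;
        if (D[u] < INF) {
          const int c = D[u] + ic;
          if (c < best) { best = c; tb = 1; }
        }
      }
      if (j >= 1) {
        const size_t l = idx - 1;
        if (D[l] < INF) {
          const int c = D[l] + dc;
          if (c < best) { best = c; tb = 2; }
        }
      }
      D[idx] = best; TB[idx] = tb;
    }
  }

  int bj = -1, bc = INF;
  for (int j = lo(n); j <= hi(n); ++j) {
    const size_t idx = (size_t)n * (m + 1) + j;
    if (D[idx] < bc) { bc = D[idx]; bj = j; }
  }
  if (bj < 0 || bc >= INF) return res;

  // traceback
  std::string ops;
  int i = n, j = bj;
  while (true) {
    const size_t idx = (size_t)i * (m + 1) + j;
    const signed char tb = TB[idx];
    if (tb == 3 || tb < 0) break;
    if (tb == 0) {
      ops.push_back('M');
      const char a = rd[i - 1], b = win[j - 1];
      if (a == b && a != 'N') res.nmatch++; else res.nmis++;
      --i; --j;
    } else if (tb == 1) {
      ops.push_back('I'); res.nins++; --i;
    } else {
      ops.push_back('D'); res.ndel++; --j;
    }
  }
  if (i != 0) return res;  // band did not admit a full path
  std::reverse(ops.begin(), ops.end());

  // run-length encode
  std::string cig;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  res.ok = true;
  res.cost = bc;
  res.ws = j;
  res.we = bj;
  res.cigar = cig;
  return res;
}

// [[Rcpp::export(name = ".fit_align_cpp")]]
List fit_align_cpp(std::string read, std::string window,
                   int mismatch_cost, int insertion_cost, int deletion_cost,
                   int band, int diag0) {
  FitRes r = fit_core(read, window, mismatch_cost, insertion_cost,
                      deletion_cost, band, diag0);
  return List::create(
    _["ok"] = r.ok, _["cost"] = r.cost,
    _["win_start"] = r.ws, _["win_end"] = r.we,
    _["matches"] = r.nmatch, _["mismatches"] = r.nmis,
    _["insertions"] = r.nins, _["deletions"] = r.ndel,
    _["cigar"] = r.cigar);
}

// ---------------------------------------------------------------------------
// Seeded read mapping: exact k-mer seeds over the forward strand of every
// target, probes spread along the read on both strands, banded fitting
// extension, deterministic tie-breaks.
// ---------------------------------------------------------------------------

static bool encode_kmer(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    const int b = base_index(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t) b;
  }
  out = v;
  return true;
}

struct Candidate { int tgt; int start; char strand; int votes; };

struct Placement {
  bool ok = false;
  int tgt = -1, tstart = 0, cost = 0, nmatch = -1, nmis = 0, nins = 0, ndel = 0;
  char strand = '+';
  int clip_front = 0, clip_back = 0;
  std::string cigar, oriented;
};

// ranking: more matches first, then lower cost, then target, start, strand '+'
static bool better(const Placement& a, const Placement& b) {
  if (!b.ok) return a.ok;
  if (!a.ok) return false;
  if (a.nmatch != b.nmatch) return a.nmatch > b.nmatch;
  if (a.cost != b.cost) return a.cost < b.cost;
  if (a.tgt != b.tgt) return a.tgt < b.tgt;
  if (a.tstart != b.tstart) return a.tstart < b.tstart;
  return a.strand == '+' && b.strand == '-';
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, CharacterVector targets,
                   int k, int mismatch_cost, int insertion_cost,
                   int deletion_cost, int band, int max_candidates) {
  const int nt = targets.size();
  std::vector<std::string> tg(nt);
  for (int t = 0; t < nt; ++t) tg[t] = as<std::string>(targets[t]);

  // index every position of every target (forward strand)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > index;
  size_t total = 0;
  for (int t = 0; t < nt; ++t)
    if ((int) tg[t].size() >= k) total += tg[t].size() - k + 1;
  index.reserve(total * 2);
  for (int t = 0; t < nt; ++t) {
    const std::string& s = tg[t];
    for (int p = 0; p + k <= (int) s.size(); ++p) {
      uint64_t key;
      if (encode_kmer(s, p, k, key))
        index[key].push_back(std::make_pair(t, p));
    }
  }

  const int nr = reads.size();
  IntegerVector out_tgt(nr), out_start(nr), out_cost(nr),
    out_match(nr), out_mis(nr), out_ins(nr), out_del(nr),
    out_clipf(nr), out_clipb(nr);
  CharacterVector out_strand(nr), out_cigar(nr), out_oriented(nr);
  LogicalVector out_found(nr);

  const int pad = 12;

  for (int r = 0; r < nr; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const int L0 = (int) fwd.size();
    Placement best;

    if (L0 >= k) {
      const std::string rev = revcomp_str(fwd);
      // probe offsets: disjoint k-windows along the read
      std::vector<int> offs;
      for (int o = 0; o + k <= L0; o += k) offs.push_back(o);
      if (!offs.empty() && offs.back() != L0 - k) offs.push_back(L0 - k);

      std::vector<Candidate> cands;
      for (int si = 0; si < 2; ++si) {
        const std::string& rs = (si == 0) ? fwd : rev;
        const char strand = (si == 0) ? '+' : '-';
        for (size_t oi = 0; oi < offs.size(); ++oi) {
          uint64_t key;
          if (!encode_kmer(rs, offs[oi], k, key)) continue;
          std::unordered_map<uint64_t,
            std::vector<std::pair<int,int> > >::const_iterator it =
              index.find(key);
          if (it == index.end()) continue;
          if (it->second.size() > 64) continue;  // over-represented seed
          for (size_t h = 0; h < it->second.size(); ++h) {
            const int t = it->second[h].first;
            const int s = it->second[h].second - offs[oi];
            bool merged = false;
            for (size_t c = 0; c < cands.size(); ++c) {
              if (cands[c].tgt == t && cands[c].strand == strand &&
                  std::abs(cands[c].start - s) <= band) {
                cands[c].votes++;
                merged = true;
                break;
              }
            }
            if (!merged) {
              Candidate cd; cd.tgt = t; cd.start = s;
              cd.strand = strand; cd.votes = 1;
              cands.push_back(cd);
            }
          }
        }
      }
      std::stable_sort(cands.begin(), cands.end(),
        [](const Candidate& a, const Candidate& b) {
          if (a.votes != b.votes) return a.votes > b.votes;
          if (a.tgt != b.tgt) return a.tgt < b.tgt;
          if (a.start != b.start) return a.start < b.start;
          return a.strand == '+' && b.strand == '-';
        });
      if ((int) cands.size() > max_candidates) cands.resize(max_candidates);

      for (size_t c = 0; c < cands.size(); ++c) {
        const int t = cands[c].tgt;
        const std::string& ts = tg[t];
        const int mt = (int) ts.size();
        const std::string& rs = (cands[c].strand == '+') ? fwd : rev;
        int s = cands[c].start;
        int clip_front = 0, clip_back = 0;
        if (s < 0) { clip_front = -s; s = 0; }
        int sub_len = L0 - clip_front;
        if (s + sub_len > mt) { clip_back = s + sub_len - mt; sub_len -= clip_back; }
        if (sub_len < k) continue;
        const std::string sub = rs.substr(clip_front, sub_len);
        const int ws0 = std::max(0, s - pad);
        const int we0 = std::min(mt, s + sub_len + pad);
        const std::string win = ts.substr(ws0, we0 - ws0);
        FitRes f = fit_core(sub, win, mismatch_cost, insertion_cost,
                            deletion_cost, band, s - ws0);
        if (!f.ok) continue;
        Placement p;
        p.ok = true; p.tgt = t; p.tstart = ws0 + f.ws;
        p.cost = f.cost; p.nmatch = f.nmatch; p.nmis = f.nmis;
        p.nins = f.nins; p.ndel = f.ndel;
        p.strand = cands[c].strand;
        p.clip_front = clip_front; p.clip_back = clip_back;
        p.cigar = f.cigar; p.oriented = sub;
        if (better(p, best)) best = p;
      }
    }

    out_found[r] = best.ok;
    out_tgt[r] = best.ok ? best.tgt + 1 : NA_INTEGER;
    out_start[r] = best.ok ? best.tstart : NA_INTEGER;
    out_cost[r] = best.ok ? best.cost : NA_INTEGER;
    out_match[r] = best.ok ? best.nmatch : NA_INTEGER;
    out_mis[r] = best.ok ? best.nmis : NA_INTEGER;
    out_ins[r] = best.ok ? best.nins : NA_INTEGER;
    out_del[r] = best.ok ? best.ndel : NA_INTEGER;
    out_clipf[r] = best.ok ? best.clip_front : NA_INTEGER;
    out_clipb[r] = best.ok ? best.clip_back : NA_INTEGER;
    out_strand[r] = best.ok ? std::string(1, best.strand) : "";
    out_cigar[r] = best.ok ? best.cigar : "";
    out_oriented[r] = best.ok ? best.oriented : "";
  }

  return List::create(
    _["found"] = out_found, _["target"] = out_tgt, _["tstart"] = out_start,
    _["cost"] = out_cost, _["matches"] = out_match,
    _["mismatches"] = out_mis, _["insertions"] = out_ins,
    _["deletions"] = out_del, _["clip_front"] = out_clipf,
    _["clip_back"] = out_clipb, _["strand"] = out_strand,
    _["cigar"] = out_cigar, _["oriented"] = out_oriented);
}

// ---------------------------------------------------------------------------
// Pileup / mismatch-spectrum accumulation over accepted placements.
// `consensus` may be an extended copy of a circular sequence; positions are
// wrapped modulo `real_len`.  Columns where either base is N contribute
// neither counts nor opportunities.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".accumulate_cpp")]]
List accumulate_cpp(std::string consensus, IntegerVector tstart,
                    CharacterVector cigar, CharacterVector oriented,
                    int real_len) {
  IntegerMatrix pileup(4, real_len);
  IntegerMatrix mm(4, 4);
  IntegerVector opp(4);
  double aligned = 0.0, mismatches = 0.0;
  const int n = tstart.size();
  const int clen = (int) consensus.size();

  for (int a = 0; a < n; ++a) {
    if (tstart[a] == NA_INTEGER) continue;
    const std::string cg = as<std::string>(cigar[a]);
    const std::string rs = as<std::string>(oriented[a]);
    int toff = tstart[a], roff = 0;
    size_t p = 0;
    while (p < cg.size()) {
      int len = 0;
      while (p < cg.size() && cg[p] >= '0' && cg[p] <= '9') {
        len = len * 10 + (cg[p] - '0');
        ++p;
      }
      const char op = cg[p++];
      if (op == 'M') {
        for (int i = 0; i < len; ++i) {
          if (toff >= clen || roff >= (int) rs.size()) break;
          const char cb = consensus[toff], rb = rs[roff];
          const int ci = base_index(cb), ri = base_index(rb);
          const int pw = toff % real_len;
          if (ri >= 0) pileup(ri, pw)++;
          if (ci >= 0 && ri >= 0) {
            opp[ci]++;
            aligned += 1.0;
            if (ci != ri) { mm(ci, ri)++; mismatches += 1.0; }
          }
          ++toff; ++roff;
        }
      } else if (op == 'I') {
        roff += len;
      } else if (op == 'D') {
        toff += len;
      }
    }
  }

  return List::create(
    _["pileup"] = pileup, _["mismatch"] = mm, _["opportunities"] = opp,
    _["aligned_bases"] = aligned, _["mismatch_bases"] = mismatches);
}

// ---------------------------------------------------------------------------
// Banded global alignment (linear gap) for whole-mitogenome comparison.
// Score = match * matches + mismatch * mismatches + gap * gap_chars,
// maximised.  Traceback ties prefer diagonal, then gap in A, then gap in B.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".global_align_cpp")]]
List global_align_cpp(std::string a, std::string b,
                      int match, int mismatch, int gap, int band) {
  const int la = (int) a.size(), lb = (int) b.size();
  const long NEG = LONG_MIN / 4;
  const int lo_off = std::min(0, lb - la) - band;
  const int hi_off = std::max(0, lb - la) + band;
  const int W = hi_off - lo_off + 1;

  std::vector<long> prev((size_t) W, NEG), cur((size_t) W, NEG);
  std::vector<signed char> TB((size_t)(la + 1) * W, -1);
  // TB codes: 0 diag, 1 left (gap in A: consume b), 2 up (gap in B: consume a)

  auto col = [&](int i, int off) { return (size_t) i * W + (off - lo_off); };

  // row 0
  for (int j = 0; j <= lb; ++j) {
    const int off = j - 0;
    if (off < lo_off || off > hi_off) continue;
    prev[off - lo_off] = (long) gap * j;
    TB[col(0, off)] = (j == 0) ? -1 : 1;
  }
  for (int i = 1; i <= la; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int jl = std::max(0, i + lo_off);
    const int jh = std::min(lb, i + hi_off);
    for (int j = jl; j <= jh; ++j) {
      const int off = j - i;
      long best = NEG; signed char tb = -1;
      if (j >= 1) {  // diagonal: prev row, offset stays
        const int poff = off;  // (j-1)-(i-1)
        if (poff >= lo_off && poff <= hi_off && prev[poff - lo_off] > NEG) {
          const char x = a[i - 1], y = b[j - 1];
          const long sc = prev[poff - lo_off] +
            ((x == y && x != 'N') ? match : mismatch);
          if (sc > best) { best = sc; tb = 0; }
        }
      }
      if (j >= 1) {  // gap in A (left)
        const int poff = off - 1;  // (j-1)-i
        if (poff >= lo_off && poff <= hi_off && cur[poff - lo_off] > NEG) {
          const long sc = cur[poff - lo_off] + gap;
          if (sc > best) { best = sc; tb = 1; }
        }
      }
      {  // gap in B (up)
        const int poff = off + 1;  // j-(i-1)
        if (poff >= lo_off && poff <= hi_off && prev[poff - lo_off] > NEG) {
          const long sc = prev[poff - lo_off] + gap;
          if (sc > best) { best = sc; tb = 2; }
        }
      }
      cur[off - lo_off] = best;
      TB[col(i, off)] = tb;
    }
    std::swap(prev, cur);
  }

  const int off_end = lb - la;
  if (off_end < lo_off || off_end > hi_off || prev[off_end - lo_off] <= NEG)
    stop("alignment band too narrow for these sequences");
  const long score = prev[off_end - lo_off];

  // traceback
  std::string aa, bb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    const signed char tb = TB[col(i, j - i)];
    if (tb == 0) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (tb == 1) {
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    } else if (tb == 2) {
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      stop("internal error: broken traceback");
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(_["score"] = (double) score,
                      _["a"] = aa, _["b"] = bb);
}

// ---------------------------------------------------------------------------
// Booth's algorithm: index of the lexicographically minimal rotation.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".min_rotation_cpp")]]
int min_rotation_cpp(std::string s) {
  const int n = (int) s.size();
  if (n == 0) return 0;
  std::string t = s + s;
  std::vector<int> f(2 * n, -1);
  int kmin = 0;
  for (int j = 1; j < 2 * n; ++j) {
    const char sj = t[j];
    int i = f[j - kmin - 1];
    while (i != -1 && sj != t[kmin + i + 1]) {
      if (sj < t[kmin + i + 1]) kmin = j - i - 1;
      i = f[i];
    }
    if (sj != t[kmin + i + 1]) {
      if (sj < t[kmin + i + 1]) kmin = j;
      f[j - kmin] = -1;
    } else {
      f[j - kmin] = i + 1;
    }
  }
  return kmin;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
std::string revcomp_cpp(std::string s) { return revcomp_str(s); }
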