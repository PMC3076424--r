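// Compiled core: canonical k-mer de Bruijn graph (build / simplify / extract),
// banded seed-and-extend read alignment, and small sequence utilities.
//
// k-mers are stored canonically (lexicographic min of k-mer and reverse
// complement); k must be odd so no k-mer is its own reverse complement.
// All iteration that has side effects runs over sorted keys so results are
// reproducible across platforms and hash implementations.

#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'a': return 't';
  case 'c': return 'g';
  case 'g': return 'c';
  case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline std::string canon(const std::string& s) {
  std::string r = revcomp(s);
  return s <= r ? s : r;
}

static inline bool acgt_only(const std::string& s) {
  for (char c : s)
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  return true;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(x[i]));
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-mer graph
// ---------------------------------------------------------------------------

typedef std::unordered_map<std::string, double> KmerMap;

static void add_seq_kmers(KmerMap& cnt, const std::string& s, int k,
                          double weight) {
  if ((int)s.size() < k) return;
  for (int i = 0; i + k <= (int)s.size(); ++i) {
    std::string km = s.substr(i, k);
    if (!acgt_only(km)) continue;  // k-mers containing N are skipped
    cnt[canon(km)] += weight;
  }
}

struct DBG {
  int k;
  KmerMap cnt;

  bool has(const std::string& km) const { return cnt.count(canon(km)) > 0; }
  double cov(const std::string& km) const {
    KmerMap::const_iterator it = cnt.find(canon(km));
    return it == cnt.end() ? 0.0 : it->second;
  }
  std::vector<std::string> fwd(const std::string& km) const {
    std::vector<std::string> out;
    std::string suf = km.substr(1);
    const char bases[4] = {'A', 'C', 'G', 'T'};
    for (int i = 0; i < 4; ++i) {
      std::string nk = suf + bases[i];
      if (has(nk)) out.push_back(nk);
    }
    return out;
  }
  std::vector<std::string> bwd(const std::string& km) const {
    std::vector<std::string> out;
    std::string pre = km.substr(0, k - 1);
    const char bases[4] = {'A', 'C', 'G', 'T'};
    for (int i = 0; i < 4; ++i) {
      std::string nk = bases[i] + pre;
      if (has(nk)) out.push_back(nk);
    }
    return out;
  }
  std::vector<std::string> sorted_keys() const {
    std::vector<std::string> keys;
    keys.reserve(cnt.size());
    for (KmerMap::const_iterator it = cnt.begin(); it != cnt.end(); ++it)
      keys.push_back(it->first);
    std::sort(keys.begin(), keys.end());
    return keys;
  }
};

struct Unitig {
  std::vector<std::string> nodes;  // oriented k-mers along the path
  std::string seq;
  double mean_cov;
  int left_deg;   // number of extensions beyond the first node
  int right_deg;  // number of extensions beyond the last node
};

// Maximal unbranched paths over the canonical graph.
static std::vector<Unitig> build_unitigs(const DBG& g) {
  std::vector<Unitig> out;
  std::unordered_set<std::string> visited;
  std::vector<std::string> keys = g.sorted_keys();

  for (size_t ki = 0; ki < keys.size(); ++ki) {
    const std::string& seed = keys[ki];
    if (visited.count(seed)) continue;

    std::vector<std::string> path;
    path.push_back(seed);
    std::unordered_set<std::string> inpath;
    inpath.insert(seed);

    // extend right
    std::string cur = seed;
    while (true) {
      std::vector<std::string> f = g.fwd(cur);
      if (f.size() != 1) break;
      std::string nxt = f[0];
      std::string cn = canon(nxt);
      if (inpath.count(cn)) break;           // cycle guard
      if (g.bwd(nxt).size() != 1) break;     // next node is a junction
      path.push_back(nxt);
      inpath.insert(cn);
      cur = nxt;
    }
    // extend left
    cur = seed;
    while (true) {
      std::vector<std::string> b = g.bwd(cur);
      if (b.size() != 1) break;
      std::string prv = b[0];
      std::string cn = canon(prv);
      if (inpath.count(cn)) break;
      if (g.fwd(prv).size() != 1) break;
      path.insert(path.begin(), prv);
      inpath.insert(cn);
      cur = prv;
    }

    Unitig u;
    u.nodes = path;
    u.seq = path[0];
    double covsum = g.cov(path[0]);
    for (size_t i = 1; i < path.size(); ++i) {
      u.seq += path[i][g.k - 1];
      covsum += g.cov(path[i]);
    }
    u.mean_cov = covsum / path.size();
    u.left_deg = (int)g.bwd(path.front()).size();
    u.right_deg = (int)g.fwd(path.back()).size();
    out.push_back(u);
    for (size_t i = 0; i < path.size(); ++i) visited.insert(canon(path[i]));
  }
  return out;
}

// Remove k-mers whose multiplicity is below cutoff. Returns true on change.
static bool prune_coverage(DBG& g, double cov_cutoff) {
  if (cov_cutoff <= 1) return false;
  std::vector<std::string> doomed;
  for (KmerMap::const_iterator it = g.cnt.begin(); it != g.cnt.end(); ++it)
    if (it->second < cov_cutoff) doomed.push_back(it->first);
  for (size_t i = 0; i < doomed.size(); ++i) g.cnt.erase(doomed[i]);
  return !doomed.empty();
}

// Clip dead-end unitigs shorter than tip_max that hang off a junction.
// Isolated unitigs (dead ends on both sides) are kept: they are contigs.
static bool clip_tips(DBG& g, int tip_max) {
  std::vector<Unitig> unis = build_unitigs(g);
  std::unordered_set<std::string> doomed;
  for (size_t i = 0; i < unis.size(); ++i) {
    const Unitig& u = unis[i];
    if ((int)u.seq.size() >= tip_max) continue;
    bool dead_right = (u.right_deg == 0);
    bool dead_left = (u.left_deg == 0);
    if (dead_left == dead_right) continue;  // isolated or internal
    // the attached side must offer an alternative branch
    std::vector<std::string> anchors = dead_right
        ? g.bwd(u.nodes.front()) : g.fwd(u.nodes.back());
    bool has_alt = false;
    for (size_t a = 0; a < anchors.size(); ++a) {
      size_t deg = dead_right ? g.fwd(anchors[a]).size()
                              : g.bwd(anchors[a]).size();
      if (deg >= 2) { has_alt = true; break; }
    }
    if (anchors.size() >= 2) has_alt = true;
    if (!has_alt) continue;
    for (size_t n = 0; n < u.nodes.size(); ++n)
      doomed.insert(canon(u.nodes[n]));
  }
  for (std::unordered_set<std::string>::const_iterator it = doomed.begin();
       it != doomed.end(); ++it)
    g.cnt.erase(*it);
  return !doomed.empty();
}

// Plain edit distance for short bubble arms.
static int edit_distance(const std::string& a, const std::string& b) {
  size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Walk an unbranched arm from `start` until a reconvergence node (in-degree
// >= 2) is met; returns internal nodes, sets `endpoint` (oriented) or "".
static std::vector<std::string> walk_arm(const DBG& g, const std::string& start,
                                         int limit, std::string& endpoint) {
  std::vector<std::string> internal_nodes;
  std::string cur = start;
  endpoint.clear();
  for (int steps = 0; steps < limit; ++steps) {
    if (g.bwd(cur).size() >= 2) { endpoint = cur; return internal_nodes; }
    internal_nodes.push_back(cur);
    std::vector<std::string> f = g.fwd(cur);
    if (f.size() != 1) return internal_nodes;  // dead end or junction: no bubble
    cur = f[0];
  }
  return internal_nodes;  // too long: endpoint stays empty
}

// Merge simple two-arm bubbles: keep the higher-coverage arm when the two
// spelled sequences are at least `identity` similar.
static bool pop_bubbles(DBG& g, double identity, int arm_limit) {
  std::vector<std::string> keys = g.sorted_keys();
  for (size_t ki = 0; ki < keys.size(); ++ki) {
    std::string orients[2];
    orients[0] = keys[ki];
    orients[1] = revcomp(keys[ki]);
    for (int oi = 0; oi < 2; ++oi) {
      const std::string& p = orients[oi];
      if (!g.has(p)) continue;
      std::vector<std::string> f = g.fwd(p);
      if (f.size() != 2) continue;
      std::string end_a, end_b;
      std::vector<std::string> arm_a = walk_arm(g, f[0], arm_limit, end_a);
      std::vector<std::string> arm_b = walk_arm(g, f[1], arm_limit, end_b);
      if (end_a.empty() || end_b.empty() || end_a != end_b) continue;
      if (arm_a.empty() && arm_b.empty()) continue;

      std::string seq_a = p, seq_b = p;
      double cov_a = 0, cov_b = 0;
      for (size_t i = 0; i < arm_a.size(); ++i) {
        seq_a += arm_a[i][g.k - 1];
        cov_a += g.cov(arm_a[i]);
      }
      for (size_t i = 0; i < arm_b.size(); ++i) {
        seq_b += arm_b[i][g.k - 1];
        cov_b += g.cov(arm_b[i]);
      }
      seq_a += end_a[g.k - 1];
      seq_b += end_b[g.k - 1];
      cov_a = arm_a.empty() ? 0 : cov_a / arm_a.size();
      cov_b = arm_b.empty() ? 0 : cov_b / arm_b.size();

      int d = edit_distance(seq_a, seq_b);
      double ident = 1.0 - (double)d / std::max(seq_a.size(), seq_b.size());
      if (ident < identity) continue;

      // keep the higher-coverage arm; ties keep the lexicographically
      // smaller spelled sequence for determinism
      bool drop_a;
      if (cov_a != cov_b) drop_a = cov_a < cov_b;
      else drop_a = !(seq_a <= seq_b);
      const std::vector<std::string>& doomed = drop_a ? arm_a : arm_b;
      if (doomed.empty()) continue;
      for (size_t i = 0; i < doomed.size(); ++i) g.cnt.erase(canon(doomed[i]));
      return true;  // graph changed: caller restarts the scan
    }
  }
  return false;
}

static DBG dbg_from_vectors(CharacterVector kmers, NumericVector counts,
                            int k) {
  DBG g;
  g.k = k;
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    g.cnt[as<std::string>(kmers[i])] = counts[i];
  return g;
}

static List dbg_to_list(const DBG& g) {
  std::vector<std::string> keys = g.sorted_keys();
  CharacterVector km(keys.size());
  NumericVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = keys[i];
    ct[i] = g.cnt.find(keys[i])->second;
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// [[Rcpp::export]]
List dbg_count_kmers(CharacterVector seqs, int k, NumericVector weights) {
  if (k % 2 == 0) stop("k must be odd");
  DBG g;
  g.k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    double w = weights.size() == 1 ? weights[0] : weights[i];
    add_seq_kmers(g.cnt, as<std::string>(seqs[i]), k, w);
  }
  return dbg_to_list(g);
}

// [[Rcpp::export]]
List dbg_simplify_cpp(CharacterVector kmers, NumericVector counts, int k,
                      int tip_max, double bubble_identity, double cov_cutoff,
                      int max_rounds) {
  DBG g = dbg_from_vectors(kmers, counts, k);
  prune_coverage(g, cov_cutoff);
  int arm_limit = std::max(4 * k, 100);
  for (int round = 0; round < max_rounds; ++round) {
    bool changed = clip_tips(g, tip_max);
    while (pop_bubbles(g, bubble_identity, arm_limit)) changed = true;
    if (!changed) break;
  }
  return dbg_to_list(g);
}

// [[Rcpp::export]]
List dbg_extract_cpp(CharacterVector kmers, NumericVector counts, int k,
                     int min_len) {
  DBG g = dbg_from_vectors(kmers, counts, k);
  std::vector<Unitig> unis = build_unitigs(g);
  std::vector<std::pair<std::string, double> > keep;
  for (size_t i = 0; i < unis.size(); ++i) {
    if ((int)unis[i].seq.size() < min_len) continue;
    std::string s = unis[i].seq;
    std::string r = revcomp(s);
    keep.push_back(std::make_pair(s <= r ? s : r, unis[i].mean_cov));
  }
  std::sort(keep.begin(), keep.end(),
            [](const std::pair<std::string, double>& a,
               const std::pair<std::string, double>& b) {
              if (a.first.size() != b.first.size())
                return a.first.size() > b.first.size();
              return a.first < b.first;
            });
  CharacterVector seq(keep.size());
  IntegerVector len(keep.size());
  NumericVector cov(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) {
    seq[i] = keep[i].first;
    len[i] = (int)keep[i].first.size();
    cov[i] = keep[i].second;
  }
  return List::create(_["sequence"] = seq, _["length"] = len,
                      _["coverage"] = cov);
}

// ---------------------------------------------------------------------------
// Seed-and-extend banded alignment of reads against one contig
// ---------------------------------------------------------------------------

struct AlnResult {
  bool ok;
  int start;      // 0-based ref offset of first aligned ref base
  char strand;
  int score;
  std::string cigar;
  // per aligned read base (M ops): ref pos (0-based), base, qual
  std::vector<int> m_refpos;
  std::string m_bases;
  std::vector<int> m_quals;
  std::vector<int> ins_refpos;  // ref base preceding the insertion (0-based)
  std::vector<std::string> ins_seq;
  std::vector<int> ins_qual;
  std::vector<int> del_refpos;  // first deleted ref base (0-based)
  std::vector<int> del_len;
};

// Glocal affine DP: read fully aligned, free leading/trailing ref.
// Returns best score; fills traceback ops ('M','I','D'), I = ins in read.
static int glocal_align(const std::string& read, const std::string& ref,
                        int match, int mismatch, int gap_open, int gap_ext,
                        std::vector<char>& ops, int& ref_start) {
  int n = (int)read.size(), m = (int)ref.size();
  const int NEG = -1000000;
  // states: 0 = M, 1 = gap in ref (ins in read), 2 = gap in read (del)
  std::vector<int> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<signed char> tbM((n + 1) * (m + 1), -1),
      tbX((n + 1) * (m + 1), -1), tbY((n + 1) * (m + 1), -1);
#define IDX(i, j) ((i) * (m + 1) + (j))
  for (int j = 0; j <= m; ++j) M[IDX(0, j)] = 0;  // free ref prefix
  for (int i = 1; i <= n; ++i) {
    // gap in ref at read start
    X[IDX(i, 0)] = gap_open + gap_ext * (i - 1);
    tbX[IDX(i, 0)] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      int sub = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      int bm = M[IDX(i - 1, j - 1)], bx = X[IDX(i - 1, j - 1)],
          by = Y[IDX(i - 1, j - 1)];
      int best = bm; signed char tb = 0;
      if (bx > best) { best = bx; tb = 1; }
      if (by > best) { best = by; tb = 2; }
      M[IDX(i, j)] = best + sub;
      tbM[IDX(i, j)] = tb;
      // X: gap in ref (consume read base i)
      int xo = M[IDX(i - 1, j)] + gap_open, xe = X[IDX(i - 1, j)] + gap_ext;
      if (xo >= xe) { X[IDX(i, j)] = xo; tbX[IDX(i, j)] = 0; }
      else { X[IDX(i, j)] = xe; tbX[IDX(i, j)] = 1; }
      // Y: gap in read (consume ref base j)
      int yo = M[IDX(i, j - 1)] + gap_open, ye = Y[IDX(i, j - 1)] + gap_ext;
      if (yo >= ye) { Y[IDX(i, j)] = yo; tbY[IDX(i, j)] = 0; }
      else { Y[IDX(i, j)] = ye; tbY[IDX(i, j)] = 2; }
    }
  }
  int best = NEG, bj = 0, bstate = 0;
  for (int j = 0; j <= m; ++j) {
    if (M[IDX(n, j)] > best) { best = M[IDX(n, j)]; bj = j; bstate = 0; }
    if (X[IDX(n, j)] > best) { best = X[IDX(n, j)]; bj = j; bstate = 1; }
  }
  // traceback
  ops.clear();
  int i = n, j = bj, state = bstate;
  while (i > 0) {
    if (state == 0) {
      ops.push_back('M');
      state = tbM[IDX(i, j)];
      --i; --j;
    } else if (state == 1) {
      ops.push_back('I');
      state = tbX[IDX(i, j)];
      --i;
    } else {
      ops.push_back('D');
      state = tbY[IDX(i, j)];
      --j;
    }
  }
  ref_start = j;
  std::reverse(ops.begin(), ops.end());
#undef IDX
  return best;
}

static void collect_seed_starts(const std::string& ref, const std::string& rd,
                                int seed_len, std::vector<int>& starts) {
  int n = (int)rd.size();
  if (n < seed_len) return;
  int offs[3] = {0, (n - seed_len) / 2, n - seed_len};
  std::unordered_set<int> seen;
  for (int oi = 0; oi < 3; ++oi) {
    int off = offs[oi];
    if (oi > 0 && off == offs[oi - 1]) continue;
    std::string seed = rd.substr(off, seed_len);
    size_t pos = ref.find(seed);
    int hits = 0;
    while (pos != std::string::npos && hits < 20) {
      int st = (int)pos - off;
      if (!seen.count(st)) { seen.insert(st); starts.push_back(st); }
      ++hits;
      pos = ref.find(seed, pos + 1);
    }
  }
  std::sort(starts.begin(), starts.end());
}

static AlnResult align_one(const std::string& contig, const std::string& read,
                           const std::vector<int>& qual, int seed_len, int band,
                           int match, int mismatch, int gap_open, int gap_ext,
                           double min_score_frac) {
  AlnResult res;
  res.ok = false;
  int n = (int)read.size();
  int best_score = -1000000;

  for (int si = 0; si < 2; ++si) {
    char strand = (si == 0) ? '+' : '-';
    std::string rd = (si == 0) ? read : revcomp(read);
    std::vector<int> starts;
    collect_seed_starts(contig, rd, seed_len, starts);
    for (size_t ci = 0; ci < starts.size(); ++ci) {
      int wstart = std::max(0, starts[ci] - band);
      int wend = std::min((int)contig.size(), starts[ci] + n + band);
      if (wend - wstart < seed_len) continue;
      std::string window = contig.substr(wstart, wend - wstart);
      std::vector<char> ops;
      int ref_off;
      int sc = glocal_align(rd, window, match, mismatch, gap_open, gap_ext,
                            ops, ref_off);
      if (sc <= best_score) continue;
      best_score = sc;

      // rebuild coordinates
      res.ok = true;
      res.strand = strand;
      res.score = sc;
      res.start = wstart + ref_off;
      res.m_refpos.clear(); res.m_bases.clear(); res.m_quals.clear();
      res.ins_refpos.clear(); res.ins_seq.clear(); res.ins_qual.clear();
      res.del_refpos.clear(); res.del_len.clear();
      std::string cig;
      int run = 0; char runop = 0;
      int ri = 0, rj = wstart + ref_off;
      std::string cur_ins; int cur_ins_q = 1000; int pend_del = 0;
      for (size_t oi2 = 0; oi2 < ops.size(); ++oi2) {
        char op = ops[oi2];
        if (op != runop) {
          if (run) cig += std::to_string(run) + runop;
          run = 0; runop = op;
        }
        ++run;
        // qual index maps back to original read orientation
        int qidx = (strand == '+') ? ri : (n - 1 - ri);
        if (op == 'M') {
          if (!cur_ins.empty()) {
            res.ins_refpos.push_back(rj - 1);
            res.ins_seq.push_back(cur_ins);
            res.ins_qual.push_back(cur_ins_q);
            cur_ins.clear(); cur_ins_q = 1000;
          }
          if (pend_del) {
            res.del_refpos.push_back(rj - pend_del);
            res.del_len.push_back(pend_del);
            pend_del = 0;
          }
          res.m_refpos.push_back(rj);
          res.m_bases += rd[ri];
          res.m_quals.push_back(qual.empty() ? 40 : qual[qidx]);
          ++ri; ++rj;
        } else if (op == 'I') {
          cur_ins += rd[ri];
          int q = qual.empty() ? 40 : qual[qidx];
          if (q < cur_ins_q) cur_ins_q = q;
          ++ri;
        } else {
          ++pend_del;
          ++rj;
        }
      }
      if (run) cig += std::to_string(run) + runop;
      if (!cur_ins.empty()) {
        res.ins_refpos.push_back(rj - 1);
        res.ins_seq.push_back(cur_ins);
        res.ins_qual.push_back(cur_ins_q);
      }
      if (pend_del) {
        res.del_refpos.push_back(rj - pend_del);
        res.del_len.push_back(pend_del);
      }
      res.cigar = cig;
    }
  }
  if (res.ok && res.score < min_score_frac * n) res.ok = false;
  return res;
}

// [[Rcpp::export]]
List align_reads_cpp(std::string contig, CharacterVector reads, List quals,
                     int seed_len, int band, int match, int mismatch,
                     int gap_open, int gap_ext, double min_score_frac) {
  R_xlen_t nr = reads.size();
  List out(nr);
  for (R_xlen_t i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::vector<int> q;
    if (quals.size() > i && !Rf_isNull(quals[i]))
      q = as<std::vector<int> >(quals[i]);
    AlnResult a = align_one(contig, rd, q, seed_len, band, match, mismatch,
                            gap_open, gap_ext, min_score_frac);
    if (!a.ok) { out[i] = R_NilValue; continue; }
    out[i] = List::create(
        _["start"] = a.start + 1,  // 1-based
        _["strand"] = std::string(1, a.strand),
        _["score"] = a.score,
        _["cigar"] = a.cigar,
        _["ref_pos"] = wrap(a.m_refpos),   // 0-based; R side shifts
        _["base"] = a.m_bases,
        _["qual"] = wrap(a.m_quals),
        _["ins_ref_pos"] = wrap(a.ins_refpos),
        _["ins_seq"] = wrap(a.ins_seq),
        _["ins_qual"] = wrap(a.ins_qual),
        _["del_ref_pos"] = wrap(a.del_refpos),
        _["del_len"] = wrap(a.del_len));
  }
  return out;
}

// Hamming-distance-1 neighbours present in a reference set; used for
// repetitive-tag derivative removal and bi-allelic tag pairing.
// [[Rcpp::export]]
List hamming1_hits(CharacterVector query, CharacterVector reference) {
  std::unordered_set<std::string> ref;
  for (R_xlen_t i = 0; i < reference.size(); ++i)
    ref.insert(as<std::string>(reference[i]));
  const char bases[4] = {'A', 'C', 'G', 'T'};
  List out(query.size());
  for (R_xlen_t i = 0; i < query.size(); ++i) {
    std::string q = as<std::string>(query[i]);
    std::vector<std::string> hits;
    for (size_t p = 0; p < q.size(); ++p) {
      char orig = q[p];
      for (int b = 0; b < 4; ++b) {
        if (bases[b] == orig) continue;
        q[p] = bases[b];
        if (ref.count(q)) hits.push_back(q);
        q[p] = orig;
      }
    }
    out[i] = wrap(hits);
  }
  return out;
}
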