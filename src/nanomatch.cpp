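#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 4-bit IUPAC encoding: A=1, C=2, G=4, T=8; degenerate codes are unions.
static inline int base_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return 15;
    default:  return 0;
  }
}

static inline bool is_concrete(int m) {
  return m == 1 || m == 2 || m == 4 || m == 8;
}

// A target position matches a primer position when the (concrete) target
// base belongs to the primer code's set; ambiguous/unknown target bases
// always count as mismatches.
static int mismatches_at(const std::string& target, const std::string& pattern,
                         int start, int budget) {
  int mm = 0;
  const int p = (int) pattern.size();
  for (int j = 0; j < p; ++j) {
    int tm = base_mask(target[start + j]);
    int pm = base_mask(pattern[j]);
    if (!is_concrete(tm) || !(tm & pm)) {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_iupac_scan")]]
IntegerVector cpp_iupac_scan(std::string target, std::string pattern) {
  const int n = (int) target.size(), p = (int) pattern.size();
  if (p == 0 || n < p) return IntegerVector(0);
  IntegerVector out(n - p + 1);
  for (int s = 0; s <= n - p; ++s)
    out[s] = mismatches_at(target, pattern, s, p);
  return out;
}

// Best hit (fewest mismatches, tie -> smallest position) of one IUPAC
// pattern in each target, within a fixed mismatch budget.
// [[Rcpp::export(name = ".cpp_scan_best")]]
List cpp_scan_best(CharacterVector targets, std::string pattern, int max_mm) {
  const int n = targets.size(), p = (int) pattern.size();
  IntegerVector pos(n, NA_INTEGER), mm(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (targets[i] == NA_STRING) continue;
    std::string t = as<std::string>(targets[i]);
    const int L = (int) t.size();
    if (L < p) continue;
    int best_mm = max_mm + 1, best_pos = -1;
    for (int s = 0; s <= L - p; ++s) {
      int m = mismatches_at(t, pattern, s, best_mm - 1);
      if (m < best_mm) { best_mm = m; best_pos = s; if (m == 0) break; }
    }
    if (best_pos >= 0 && best_mm <= max_mm) {
      pos[i] = best_pos + 1;  // 1-based
      mm[i] = best_mm;
    }
  }
  return List::create(_["pos"] = pos, _["mismatches"] = mm);
}

static inline char comp_char(char c) {
  int m = base_mask(c);
  // reverse the 4-bit mask: A<->T, C<->G
  int r = ((m & 1) ? 8 : 0) | ((m & 2) ? 4 : 0) | ((m & 4) ? 2 : 0) | ((m & 8) ? 1 : 0);
  static const char* lut = "NACMGRSVTWYHKDBN";  // index by mask
  return r ? lut[r] : 'N';
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j)
      r[j] = comp_char(s[s.size() - 1 - j]);
    out[i] = r;
  }
  return out;
}

// Merge read pairs by ungapped overlap. s2rc/q2rc are the reverse
// complement of read 2 and its reversed quality string. Picks the longest
// overlap whose mismatch fraction is within budget; conflicts resolved by
// the higher Phred base, quality ties keep the read-1 base.
// [[Rcpp::export(name = ".cpp_merge_pairs")]]
List cpp_merge_pairs(CharacterVector s1v, CharacterVector q1v,
                     CharacterVector s2rcv, CharacterVector q2rcv,
                     int min_overlap, double max_frac) {
  const int n = s1v.size();
  CharacterVector merged(n, NA_STRING);
  IntegerVector overlap(n, NA_INTEGER), conflicts(n, NA_INTEGER);
  CharacterVector status(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(s1v[i]);
    std::string b = as<std::string>(s2rcv[i]);
    std::string qa = as<std::string>(q1v[i]);
    std::string qb = as<std::string>(q2rcv[i]);
    const int la = (int) a.size(), lb = (int) b.size();
    const int ov_max = std::min(la, lb);
    if (min_overlap < 1 || ov_max < min_overlap) {
      status[i] = "no_overlap";
      continue;
    }
    int chosen = -1, chosen_mm = 0;
    for (int ov = ov_max; ov >= min_overlap; --ov) {
      const int budget = (int) std::floor(max_frac * ov + 1e-9);
      int mm = 0; bool ok = true;
      for (int j = 0; j < ov; ++j) {
        if (a[la - ov + j] != b[j]) {
          if (++mm > budget) { ok = false; break; }
        }
      }
      if (ok) { chosen = ov; chosen_mm = mm; break; }
    }
    if (chosen < 0) { status[i] = "no_overlap"; continue; }
    std::string m = a.substr(0, la - chosen);
    for (int j = 0; j < chosen; ++j) {
      char ba = a[la - chosen + j], bb = b[j];
      if (ba == bb) { m.push_back(ba); continue; }
      char pa = qa[la - chosen + j], pb = qb[j];
      m.push_back(pb > pa ? bb : ba);
    }
    m += b.substr(chosen);
    merged[i] = m;
    overlap[i] = chosen;
    conflicts[i] = chosen_mm;
    status[i] = "ok";
  }
  return List::create(_["seq"] = merged, _["overlap_len"] = overlap,
                      _["conflict_count"] = conflicts, _["status"] = status);
}

// [[Rcpp::export(name = ".cpp_fnv1a64")]]
CharacterVector cpp_fnv1a64(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    uint64_t h = 1469598103934665603ULL;
    for (size_t j = 0; j < s.size(); ++j) {
      h ^= (uint64_t)(unsigned char) s[j];
      h *= 1099511628211ULL;
    }
    char buf[17];
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long) h);
    out[i] = buf;
  }
  return out;
}

// Per-sequence covered-residue counts per region, from peptide match spans.
// regions: n_seq x (2*n_region) matrix of 1-based closed [start, end]
// columns (NA = unresolved region). Spans: parallel vectors (1-based seq
// index, start, end). Returns an n_seq x n_region count matrix.
// [[Rcpp::export(name = ".cpp_region_cover")]]
IntegerMatrix cpp_region_cover(IntegerVector seq_idx, IntegerVector start,
                               IntegerVector end, IntegerMatrix regions,
                               IntegerVector seq_len) {
  const int n_seq = regions.nrow();
  const int n_reg = regions.ncol() / 2;
  IntegerMatrix out(n_seq, n_reg);
  const int n_span = seq_idx.size();
  // order spans by sequence
  std::vector<int> ord(n_span);
  for (int i = 0; i < n_span; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return seq_idx[a] < seq_idx[b];
  });
  int k = 0;
  std::vector<char> cov;
  while (k < n_span) {
    const int s = seq_idx[ord[k]];
    const int L = seq_len[s - 1];
    cov.assign(L + 1, 0);
    while (k < n_span && seq_idx[ord[k]] == s) {
      int a = std::max(1, (int) start[ord[k]]);
      int b = std::min(L, (int) end[ord[k]]);
      for (int j = a; j <= b; ++j) cov[j] = 1;
      ++k;
    }
    for (int r = 0; r < n_reg; ++r) {
      int rs = regions(s - 1, 2 * r), re = regions(s - 1, 2 * r + 1);
      if (rs == NA_INTEGER || re == NA_INTEGER) { out(s - 1, r) = NA_INTEGER; continue; }
      int c = 0;
      for (int j = std::max(1, rs); j <= std::min(L, re); ++j) c += cov[j];
      out(s - 1, r) = c;
    }
  }
  // rows with no spans: 0 for resolved regions, NA for unresolved
  for (int i = 0; i < n_seq; ++i) {
    bool any = false;
    for (int r = 0; r < n_reg; ++r) if (out(i, r) != 0) { any = true; break; }
    if (!any) {
      for (int r = 0; r < n_reg; ++r)
        if (regions(i, 2 * r) == NA_INTEGER) out(i, r) = NA_INTEGER;
    }
  }
  return out;
}

// Hamming distance of each string in `a` against `b` (NA if lengths differ).
// [[Rcpp::export(name = ".cpp_hamming")]]
IntegerVector cpp_hamming(CharacterVector a, std::string b) {
  const int n = a.size();
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(a[i]);
    if (s.size() != b.size()) continue;
    int d = 0;
    for (size_t j = 0; j < s.size(); ++j) if (s[j] != b[j]) ++d;
    out[i] = d;
  }
  return out;
}
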