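#include <Rcpp.h>
using namespace Rcpp;

static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (std::size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// Merge one pair given the already reverse-complemented mate.
// Returns merged sequence or "" on failure. The best overlap maximises the
// number of matching bases subject to mismatches <= max_mm_frac * overlap;
// ties go to the larger overlap. At disagreeing positions the base with the
// higher quality wins (ties to the forward read).
static std::string merge_one(const std::string &f, const std::string &fq,
                             const std::string &rc, const std::string &rcq,
                             int min_overlap, double max_mm_frac) {
  const int lf = (int)f.size(), lr = (int)rc.size();
  const int omax = std::min(lf, lr);
  int best_o = -1, best_matches = -1;
  for (int o = min_overlap; o <= omax; ++o) {
    const int max_mm = (int)std::floor(max_mm_frac * o);
    int mm = 0;
    const int off = lf - o;
    bool ok = true;
    for (int i = 0; i < o; ++i) {
      if (f[off + i] != rc[i] && ++mm > max_mm) { ok = false; break; }
    }
    if (ok) {
      const int matches = o - mm;
      if (matches > best_matches || (matches == best_matches && o > best_o)) {
        best_matches = matches;
        best_o = o;
      }
    }
  }
  if (best_o < 0) return std::string();
  const int o = best_o, off = lf - o;
  std::string out;
  out.reserve(lf + lr - o);
  out.append(f, 0, off);
  for (int i = 0; i < o; ++i) {
    if (f[off + i] == rc[i] || fq[off + i] >= rcq[i]) out.push_back(f[off + i]);
    else out.push_back(rc[i]);
  }
  out.append(rc, o, lr - o);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_merge_pairs(CharacterVector fwd, CharacterVector fwd_qual,
                                CharacterVector rev, CharacterVector rev_qual,
                                int min_overlap, double max_mm_frac) {
  const R_xlen_t n = fwd.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string f = as<std::string>(fwd[i]);
    std::string r = as<std::string>(rev[i]);
    std::string fq = as<std::string>(fwd_qual[i]);
    std::string rq = as<std::string>(rev_qual[i]);
    std::string rc = revcomp(r);
    std::string rcq(rq.rbegin(), rq.rend());
    std::string m = merge_one(f, fq, rc, rcq, min_overlap, max_mm_frac);
    if (m.empty()) out[i] = NA_STRING; else out[i] = m;
  }
  return out;
}

// Apply n_err[i] substitution errors to seqs[i] at uniform positions, using
// R's RNG so results follow set.seed(). Error bases drawn uniformly from the
// three alternatives.
// [[Rcpp::export]]
CharacterVector cpp_mutate_seqs(CharacterVector seqs, IntegerVector n_err) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const R_xlen_t n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    const int k = n_err[i];
    if (k <= 0) { out[i] = seqs[i]; continue; }
    std::string s = as<std::string>(seqs[i]);
    const int len = (int)s.size();
    for (int j = 0; j < k; ++j) {
      const int pos = (int)(unif_rand() * len);
      char cur = s[pos < len ? pos : len - 1];
      char sub = cur;
      while (sub == cur) sub = bases[(int)(unif_rand() * 4) & 3];
      s[pos < len ? pos : len - 1] = sub;
    }
    out[i] = s;
  }
  return out;
}
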