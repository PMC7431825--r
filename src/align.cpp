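#include <Rcpp.h>
using namespace Rcpp;

// Bisulfite-aware base scoring: a read T opposite a reference C counts as a
// match (unmethylated cytosines read as T after conversion); the reverse
// direction (read C vs reference T) does not.
static inline double base_score(char r, char f, double match, double mismatch) {
  if (r == f) return match;
  if (f == 'C' && r == 'T') return match;
  return mismatch;
}

// Global (Needleman-Wunsch) alignment with linear gap penalty and
// deterministic tie-breaking: diagonal, then up (gap in reference / consume
// read base), then left (gap in read / consume reference base).
// Returns the optimal score and, for each reference position, the 1-based
// read position aligned to it (NA where the reference base is gapped).
static double nw_core(const std::string& read, const std::string& ref,
                      double match, double mismatch, double gap,
                      std::vector<int>& ref2read) {
  const int n = (int)read.size();   // rows: read
  const int m = (int)ref.size();    // cols: reference
  std::vector<double> S((n + 1) * (m + 1));
  std::vector<unsigned char> tb((n + 1) * (m + 1)); // 0 diag, 1 up, 2 left
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  S[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) { S[idx(i, 0)] = i * gap; tb[idx(i, 0)] = 1; }
  for (int j = 1; j <= m; ++j) { S[idx(0, j)] = j * gap; tb[idx(0, j)] = 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S[idx(i - 1, j - 1)] +
        base_score(read[i - 1], ref[j - 1], match, mismatch);
      double u = S[idx(i - 1, j)] + gap;
      double l = S[idx(i, j - 1)] + gap;
      double best = d; unsigned char t = 0;
      if (u > best) { best = u; t = 1; }
      if (l > best) { best = l; t = 2; }
      S[idx(i, j)] = best; tb[idx(i, j)] = t;
    }
  }

  ref2read.assign(m, NA_INTEGER);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[idx(i, j)];
    if (i > 0 && j > 0 && t == 0) { ref2read[j - 1] = i; --i; --j; }
    else if (i > 0 && (t == 1 || j == 0)) { --i; }
    else { --j; }
  }
  return S[idx(n, m)];
}

// [[Rcpp::export]]
List nw_align_cpp(std::string read, std::string ref,
                  double match = 1.0, double mismatch = -1.0,
                  double gap = -2.0) {
  std::vector<int> map;
  double score = nw_core(read, ref, match, mismatch, gap, map);
  IntegerVector ref2read(map.begin(), map.end());
  return List::create(_["score"] = score, _["ref_to_read"] = ref2read);
}

// Ungapped bisulfite-aware score of an equal-length read against the
// reference (identity mapping).
static double ungapped_score(const std::string& read, const std::string& ref,
                             double match, double mismatch) {
  double s = 0.0;
  for (size_t k = 0; k < ref.size(); ++k)
    s += base_score(read[k], ref[k], match, mismatch);
  return s;
}

// Batch per-read methylation calling against one amplicon reference.
//
// For each read: align (identity fast path for equal-length, high-identity
// reads; full NW otherwise), then call each reference CpG cytosine
// (C=methylated, T=unmethylated, gap/other=missing), tally conversion at
// non-CpG reference cytosines (T converted, C unconverted, gap/other
// excluded), and read the allele base at the variant position.
//
// cpg_pos, noncpg_c_pos, variant_pos are 1-based reference coordinates.
// calls matrix coding: 1 methylated, 0 unmethylated, NA missing.
// [[Rcpp::export]]
List call_reads_cpp(CharacterVector reads, std::string ref,
                    IntegerVector cpg_pos, IntegerVector noncpg_c_pos,
                    int variant_pos,
                    double match = 1.0, double mismatch = -1.0,
                    double gap = -2.0,
                    double score_floor = NA_REAL,
                    double fastpath_identity = 0.9) {
  const int nr = reads.size();
  const int nc = cpg_pos.size();
  const int nq = noncpg_c_pos.size();
  const int m = (int)ref.size();
  if (ISNA(score_floor)) score_floor = 0.5 * m * match;
  const double fast_min = fastpath_identity * m * match;

  IntegerMatrix calls(nr, nc);
  CharacterVector allele(nr);
  IntegerVector n_sites(nr), n_conv(nr);
  NumericVector score(nr);
  LogicalVector aligned(nr);

  std::vector<int> map(m);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    double sc;
    bool identity = false;
    if ((int)rd.size() == m) {
      sc = ungapped_score(rd, ref, match, mismatch);
      identity = (sc >= fast_min);
    }
    if (!identity) {
      sc = nw_core(rd, ref, match, mismatch, gap, map);
    } else {
      for (int j = 0; j < m; ++j) map[j] = j + 1;
    }
    score[r] = sc;
    if (sc < score_floor) {
      aligned[r] = false;
      for (int k = 0; k < nc; ++k) calls(r, k) = NA_INTEGER;
      allele[r] = "undetermined";
      n_sites[r] = 0; n_conv[r] = 0;
      continue;
    }
    aligned[r] = true;

    for (int k = 0; k < nc; ++k) {
      int rp = map[cpg_pos[k] - 1];
      if (rp == NA_INTEGER) { calls(r, k) = NA_INTEGER; continue; }
      char b = rd[rp - 1];
      if (b == 'C') calls(r, k) = 1;
      else if (b == 'T') calls(r, k) = 0;
      else calls(r, k) = NA_INTEGER;
    }

    int ns = 0, cv = 0;
    for (int k = 0; k < nq; ++k) {
      int rp = map[noncpg_c_pos[k] - 1];
      if (rp == NA_INTEGER) continue;
      char b = rd[rp - 1];
      if (b == 'T') { ++ns; ++cv; }
      else if (b == 'C') { ++ns; }
      // gap / other base excluded from the denominator
    }
    n_sites[r] = ns; n_conv[r] = cv;

    int vp = map[variant_pos - 1];
    if (vp == NA_INTEGER) allele[r] = "undetermined";
    else {
      char b = rd[vp - 1];
      if (b == 'A') allele[r] = "A";
      else if (b == 'G') allele[r] = "G";
      else allele[r] = "undetermined";
    }
  }

  return List::create(
    _["calls"] = calls, _["allele"] = allele,
    _["n_noncpg_c_sites"] = n_sites, _["n_converted"] = n_conv,
    _["score"] = score, _["aligned"] = aligned);
}
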