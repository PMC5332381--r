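// Affine-gap pairwise protein alignment (Gotoh three-state DP).
//
// Gap accounting follows the EMBOSS convention: a gap of length L costs
// gap_open + (L - 1) * gap_extend.  Traceback ties are broken in the fixed
// order match/mismatch > gap-in-a > gap-in-b so alignments are deterministic.

#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Build a 256-entry lookup from residue char to row index of the scoring matrix.
static std::vector<int> char_lookup(const CharacterVector& letters) {
  std::vector<int> lut(256, -1);
  for (int i = 0; i < letters.size(); ++i) {
    std::string s = as<std::string>(letters[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
  return lut;
}

static std::vector<int> encode(const std::string& s, const std::vector<int>& lut) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[(unsigned char)s[i]];
    if (code < 0) stop("residue '%s' not present in the scoring matrix", std::string(1, s[i]).c_str());
    v[i] = code;
  }
  return v;
}

// State codes for traceback: 0 = M (aligned pair), 1 = GA (gap in a), 2 = GB (gap in b).
// [[Rcpp::export(name = ".cpp_align_global")]]
List cpp_align_global(std::string a, std::string b, NumericMatrix sub,
                      CharacterVector letters, double gap_open, double gap_extend) {
  std::vector<int> lut = char_lookup(letters);
  std::vector<int> ea = encode(a, lut), eb = encode(b, lut);
  int n = ea.size(), m = eb.size();

  NumericMatrix M(n + 1, m + 1), GA(n + 1, m + 1), GB(n + 1, m + 1);
  IntegerMatrix PM(n + 1, m + 1), PA(n + 1, m + 1), PB(n + 1, m + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(GA.begin(), GA.end(), NEG_INF);
  std::fill(GB.begin(), GB.end(), NEG_INF);
  M(0, 0) = 0.0;
  for (int j = 1; j <= m; ++j) { GA(0, j) = -(gap_open + (j - 1) * gap_extend); PA(0, j) = 1; }
  for (int i = 1; i <= n; ++i) { GB(i, 0) = -(gap_open + (i - 1) * gap_extend); PB(i, 0) = 2; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(ea[i - 1], eb[j - 1]);
      // M: preference M > GA > GB on ties
      double best = M(i - 1, j - 1); int prev = 0;
      if (GA(i - 1, j - 1) > best) { best = GA(i - 1, j - 1); prev = 1; }
      if (GB(i - 1, j - 1) > best) { best = GB(i - 1, j - 1); prev = 2; }
      M(i, j) = best + s; PM(i, j) = prev;
      // GA: consume b_j against a gap in a
      double open_m = M(i, j - 1) - gap_open;
      double ext    = GA(i, j - 1) - gap_extend;
      double open_b = GB(i, j - 1) - gap_open;
      best = open_m; prev = 0;
      if (ext > best) { best = ext; prev = 1; }
      if (open_b > best) { best = open_b; prev = 2; }
      GA(i, j) = best; PA(i, j) = prev;
      // GB: consume a_i against a gap in b
      open_m = M(i - 1, j) - gap_open;
      double open_a = GA(i - 1, j) - gap_open;
      ext = GB(i - 1, j) - gap_extend;
      best = open_m; prev = 0;
      if (open_a > best) { best = open_a; prev = 1; }
      if (ext > best) { best = ext; prev = 2; }
      GB(i, j) = best; PB(i, j) = prev;
    }
  }

  double score = M(n, m); int state = 0;
  if (GA(n, m) > score) { score = GA(n, m); state = 1; }
  if (GB(n, m) > score) { score = GB(n, m); state = 2; }

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = PM(i, j);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = PA(i, j);
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    } else {
      int prev = PB(i, j);
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["aligned_a"] = ra, _["aligned_b"] = rb);
}

// [[Rcpp::export(name = ".cpp_align_local")]]
List cpp_align_local(std::string a, std::string b, NumericMatrix sub,
                     CharacterVector letters, double gap_open, double gap_extend) {
  std::vector<int> lut = char_lookup(letters);
  std::vector<int> ea = encode(a, lut), eb = encode(b, lut);
  int n = ea.size(), m = eb.size();

  NumericMatrix M(n + 1, m + 1), GA(n + 1, m + 1), GB(n + 1, m + 1);
  IntegerMatrix PM(n + 1, m + 1), PA(n + 1, m + 1), PB(n + 1, m + 1);
  std::fill(GA.begin(), GA.end(), NEG_INF);
  std::fill(GB.begin(), GB.end(), NEG_INF);
  // M(i,0), M(0,j) stay 0: a local alignment may start anywhere.
  double best_score = 0.0; int bi = 0, bj = 0, bstate = 0; bool found = false;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(ea[i - 1], eb[j - 1]);
      // fresh start (state 3) wins ties at zero so the traceback never walks
      // through boundary cells
      double best = 0.0; int prev = 3;
      if (M(i - 1, j - 1) > best) { best = M(i - 1, j - 1); prev = 0; }
      if (GA(i - 1, j - 1) > best) { best = GA(i - 1, j - 1); prev = 1; }
      if (GB(i - 1, j - 1) > best) { best = GB(i - 1, j - 1); prev = 2; }
      M(i, j) = best + s; PM(i, j) = prev;

      double open_m = M(i, j - 1) - gap_open;
      double ext    = GA(i, j - 1) - gap_extend;
      double open_b = GB(i, j - 1) - gap_open;
      best = open_m; prev = 0;
      if (ext > best) { best = ext; prev = 1; }
      if (open_b > best) { best = open_b; prev = 2; }
      GA(i, j) = best; PA(i, j) = prev;

      open_m = M(i - 1, j) - gap_open;
      double open_a = GA(i - 1, j) - gap_open;
      ext = GB(i - 1, j) - gap_extend;
      best = open_m; prev = 0;
      if (open_a > best) { best = open_a; prev = 1; }
      if (ext > best) { best = ext; prev = 2; }
      GB(i, j) = best; PB(i, j) = prev;

      if (M(i, j) > best_score) { best_score = M(i, j); bi = i; bj = j; bstate = 0; found = true; }
    }
  }

  std::string ra, rb;
  if (found && best_score > 0.0) {
    int i = bi, j = bj, state = bstate;
    while (true) {
      if (state == 0) {
        int prev = PM(i, j);
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
        --i; --j;
        if (prev == 3) break;
        state = prev;
        if (i == 0 && j == 0) break;
      } else if (state == 1) {
        int prev = PA(i, j);
        ra.push_back('-'); rb.push_back(b[j - 1]);
        --j; state = prev;
      } else {
        int prev = PB(i, j);
        ra.push_back(a[i - 1]); rb.push_back('-');
        --i; state = prev;
      }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
  } else {
    best_score = 0.0;
  }
  return List::create(_["score"] = best_score, _["aligned_a"] = ra, _["aligned_b"] = rb);
}

// Score-only local Gotoh against a precomputed target profile:
// prof[r * m + j] = sub(r, target[j]).  O(m) memory, raw-pointer inner loop.
static double local_score_profile(const std::vector<int>& eq,
                                  const std::vector<double>& prof, int m,
                                  double gap_open, double gap_extend,
                                  std::vector<double>& M, std::vector<double>& GA,
                                  std::vector<double>& GB) {
  int n = eq.size();
  std::fill(M.begin(), M.begin() + m + 1, 0.0);
  std::fill(GA.begin(), GA.begin() + m + 1, NEG_INF);
  std::fill(GB.begin(), GB.begin() + m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    const double* srow = &prof[(size_t)eq[i - 1] * m];
    double diagM = M[0], diagGA = GA[0], diagGB = GB[0];
    double leftM = 0.0, leftGA = NEG_INF, leftGB = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double upM = M[j], upGA = GA[j], upGB = GB[j];
      double s = srow[j - 1];
      double d = diagM;
      if (diagGA > d) d = diagGA;
      if (diagGB > d) d = diagGB;
      if (d < 0.0) d = 0.0;
      double mv = d + s;
      double ga = leftM - gap_open;
      double t = leftGA - gap_extend; if (t > ga) ga = t;
      t = leftGB - gap_open; if (t > ga) ga = t;
      double gb = upM - gap_open;
      t = upGA - gap_open; if (t > gb) gb = t;
      t = upGB - gap_extend; if (t > gb) gb = t;
      M[j] = mv; GA[j] = ga; GB[j] = gb;
      leftM = mv; leftGA = ga; leftGB = gb;
      if (mv > best) best = mv;
      diagM = upM; diagGA = upGA; diagGB = upGB;
    }
  }
  return best;
}

static std::vector<double> build_profile(const std::vector<int>& eb, int nletters,
                                         const NumericMatrix& sub) {
  int m = eb.size();
  std::vector<double> prof((size_t)nletters * m);
  for (int r = 0; r < nletters; ++r)
    for (int j = 0; j < m; ++j)
      prof[(size_t)r * m + j] = sub(r, eb[j]);
  return prof;
}

// Score-only local alignment of one query against many targets.
// [[Rcpp::export(name = ".cpp_local_scores")]]
NumericVector cpp_local_scores(std::string query, CharacterVector targets, NumericMatrix sub,
                               CharacterVector letters, double gap_open, double gap_extend) {
  std::vector<int> lut = char_lookup(letters);
  std::vector<int> eq = encode(query, lut);
  int nletters = letters.size();
  NumericVector out(targets.size());
  size_t maxm = 0;
  std::vector<std::vector<int> > enc(targets.size());
  for (int t = 0; t < targets.size(); ++t) {
    enc[t] = encode(as<std::string>(targets[t]), lut);
    if (enc[t].size() > maxm) maxm = enc[t].size();
  }
  std::vector<double> M(maxm + 1), GA(maxm + 1), GB(maxm + 1);
  for (int t = 0; t < targets.size(); ++t) {
    std::vector<double> prof = build_profile(enc[t], nletters, sub);
    out[t] = local_score_profile(eq, prof, enc[t].size(), gap_open, gap_extend,
                                 M, GA, GB);
  }
  return out;
}

// All-vs-all local scores (symmetric); returns full matrix.
// [[Rcpp::export(name = ".cpp_local_score_matrix")]]
NumericMatrix cpp_local_score_matrix(CharacterVector seqs, NumericMatrix sub,
                                     CharacterVector letters, double gap_open, double gap_extend) {
  int N = seqs.size();
  std::vector<int> lut = char_lookup(letters);
  int nletters = letters.size();
  std::vector<std::vector<int> > enc(N);
  size_t maxm = 0;
  for (int i = 0; i < N; ++i) {
    enc[i] = encode(as<std::string>(seqs[i]), lut);
    if (enc[i].size() > maxm) maxm = enc[i].size();
  }
  std::vector<double> M(maxm + 1), GA(maxm + 1), GB(maxm + 1);
  NumericMatrix out(N, N);
  for (int ti = 0; ti < N; ++ti) {
    std::vector<double> prof = build_profile(enc[ti], nletters, sub);
    int m = enc[ti].size();
    for (int qi = 0; qi <= ti; ++qi) {
      double best = local_score_profile(enc[qi], prof, m, gap_open, gap_extend,
                                        M, GA, GB);
      out(qi, ti) = best;
      out(ti, qi) = best;
    }
  }
  return out;
}
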