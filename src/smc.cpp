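// Sequential Monte Carlo core for two-block motif discovery.
//
// One call advances the particle population by a single sequence: for each
// particle, candidate placements (absent, or (offset, strand) over both
// strands) are weighted by
//   presence prior x Dirichlet-multinomial predictive of the aligned
//   window relative to background x exp(-lambda_sym * D_min)
// where D_min is the minimum symmetrized cross-entropy (bits) between the
// half-site blocks of the tentatively updated posterior-mean PWM, over the
// palindromic / direct-repeat / inverted-repeat transforms.  One placement
// is sampled per particle; particle weights are multiplied by the
// candidate normalizer; systematic resampling triggers when the effective
// sample size falls below resample_frac * n.
//
// Performance layout: per particle, log tables of the predictive
// numerators and, for the symmetry prior, per-(block pair, added-base
// combination) contribution tables, so that each of the ~2L candidates
// costs O(w) table lookups and a single exp().
//
// RNG: self-contained splitmix64 so runs are reproducible independently
// of the C++ standard library.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

const double LN2 = 0.6931471805599453;

// pair structure of the half-site blocks: block1 = [0,c), block2 = [w-c,w)
// sym 0 = palindromic (partner w-1-j, complemented bases)
// sym 1 = direct repeat (partner w-c+j, identity)
// sym 2 = inverted repeat (partner w-1-j, identity)
inline int partner_col(int sym, int j, int w, int c) {
  return sym == 1 ? w - c + j : w - 1 - j;
}
inline int transform_base(int sym, int b) { return sym == 0 ? 3 - b : b; }

}  // namespace

// [[Rcpp::export]]
List smc_step_cpp(NumericMatrix counts, NumericVector weights,
                  IntegerMatrix placements, IntegerVector seq_codes,
                  int w, double alpha, double presence, double lambda_sym,
                  NumericVector background, int step_seed,
                  double resample_frac) {
  const int n = counts.nrow();
  const int t_prev = placements.ncol();
  const int L = seq_codes.size();
  const int K = L - w + 1;          // offsets per strand (may be <= 0)
  const int c = w / 2;
  const bool use_sym = lambda_sym > 0.0 && c >= 1;
  // lambda folded with the 1/(c ln 2) bits normalization of D
  const double lam = use_sym ? lambda_sym / (c * LN2) : 0.0;

  // candidate windows in motif orientation, precomputed once
  // cand 0 = absent; cand 1..2K = placement code o*2+s
  const int n_place = K > 0 ? 2 * K : 0;
  std::vector<int> cand_bases;          // n_place * w, 0-based base
  std::vector<bool> cand_ok(n_place, true);
  std::vector<double> cand_logbg(n_place, 0.0);
  if (K > 0) {
    cand_bases.assign(static_cast<size_t>(n_place) * w, 0);
    double logbg[4];
    for (int b = 0; b < 4; ++b) logbg[b] = std::log(background[b]);
    for (int o = 0; o < K; ++o) {
      for (int s = 0; s < 2; ++s) {
        const int ci = 2 * o + s;
        double lb = 0.0;
        bool ok = true;
        for (int j = 0; j < w; ++j) {
          const int base = s == 0 ? seq_codes[o + j] : seq_codes[o + w - 1 - j];
          if (base == 0) { ok = false; break; }
          const int b0 = s == 0 ? base - 1 : 4 - base;  // '-': complement
          cand_bases[static_cast<size_t>(ci) * w + j] = b0;
          lb += logbg[b0];
        }
        cand_ok[ci] = ok;
        cand_logbg[ci] = lb;
      }
    }
  }

  NumericMatrix new_counts = clone(counts);
  IntegerMatrix new_placements(n, t_prev + 1);
  for (int p = 0; p < n; ++p)
    for (int t = 0; t < t_prev; ++t) new_placements(p, t) = placements(p, t);

  NumericVector zvec(n);
  Rng rng(static_cast<uint64_t>(static_cast<uint32_t>(step_seed)) *
              2654435761ULL + 1ULL);

  std::vector<double> cw(n_place + 1);
  // per-particle tables
  std::vector<double> num(4 * w), den(w), l0(4 * w), l1(4 * w),
      ld0(w), ld1(w);
  // pair tables: [sym][pair j][a1][a2] -> symmetrized-KL contribution
  std::vector<double> pair_tab(use_sym ? 3 * c * 16 : 0);

  const double place_prior =
      n_place > 0 ? presence / static_cast<double>(n_place) : 0.0;

  for (int p = 0; p < n; ++p) {
    double sum_lden = 0.0;
    for (int j = 0; j < w; ++j) {
      double nj = 0.0;
      for (int b = 0; b < 4; ++b) {
        const double v = new_counts(p, 4 * j + b) + alpha;
        num[4 * j + b] = v;
        l0[4 * j + b] = std::log(v);
        l1[4 * j + b] = std::log(v + 1.0);
        nj += v;
      }
      den[j] = nj;
      ld0[j] = std::log(nj);
      ld1[j] = std::log(nj + 1.0);
      sum_lden += ld0[j];
    }

    double d_abs = 0.0;  // unnormalized D_min of the current PWM
    if (use_sym) {
      // contribution tables for tentatively updated columns
      for (int sym = 0; sym < 3; ++sym) {
        for (int j = 0; j < c; ++j) {
          const int j2 = partner_col(sym, j, w, c);
          for (int a1 = 0; a1 < 4; ++a1) {
            for (int a2 = 0; a2 < 4; ++a2) {
              double d = 0.0;
              for (int b = 0; b < 4; ++b) {
                const int tb = transform_base(sym, b);
                const double pn = num[4 * j + b] + (b == a1 ? 1.0 : 0.0);
                const double qn = num[4 * j2 + tb] + (tb == a2 ? 1.0 : 0.0);
                const double pv = pn / (den[j] + 1.0);
                const double qv = qn / (den[j2] + 1.0);
                const double lp =
                    (b == a1 ? l1[4 * j + b] : l0[4 * j + b]) - ld1[j];
                const double lq =
                    (tb == a2 ? l1[4 * j2 + tb] : l0[4 * j2 + tb]) - ld1[j2];
                d += 0.5 * (pv - qv) * (lp - lq);
              }
              pair_tab[((sym * c + j) * 4 + a1) * 4 + a2] = d;
            }
          }
        }
      }
      // D_min of the current (absent-candidate) PWM
      double dsym[3] = {0.0, 0.0, 0.0};
      for (int sym = 0; sym < 3; ++sym) {
        for (int j = 0; j < c; ++j) {
          const int j2 = partner_col(sym, j, w, c);
          for (int b = 0; b < 4; ++b) {
            const int tb = transform_base(sym, b);
            const double pv = num[4 * j + b] / den[j];
            const double qv = num[4 * j2 + tb] / den[j2];
            const double lp = l0[4 * j + b] - ld0[j];
            const double lq = l0[4 * j2 + tb] - ld0[j2];
            dsym[sym] += 0.5 * (pv - qv) * (lp - lq);
          }
        }
      }
      d_abs = std::min(dsym[0], std::min(dsym[1], dsym[2]));
    }

    cw[0] = (1.0 - presence) * (use_sym ? std::exp(-lam * d_abs) : 1.0);
    double z = cw[0];
    for (int ci = 0; ci < n_place; ++ci) {
      if (!cand_ok[ci]) { cw[ci + 1] = 0.0; continue; }
      const int* bases = &cand_bases[static_cast<size_t>(ci) * w];
      double logpred = -sum_lden - cand_logbg[ci];
      for (int j = 0; j < w; ++j) logpred += l0[4 * j + bases[j]];
      double dmin = 0.0;
      if (use_sym) {
        double d0 = 0.0, d1 = 0.0, d2 = 0.0;
        for (int j = 0; j < c; ++j) {
          const int a1 = bases[j];
          d0 += pair_tab[((0 * c + j) * 4 + a1) * 4 + bases[w - 1 - j]];
          d1 += pair_tab[((1 * c + j) * 4 + a1) * 4 + bases[w - c + j]];
          d2 += pair_tab[((2 * c + j) * 4 + a1) * 4 + bases[w - 1 - j]];
        }
        dmin = std::min(d0, std::min(d1, d2));
      }
      const double wgt = place_prior * std::exp(logpred - lam * dmin);
      cw[ci + 1] = wgt;
      z += wgt;
    }
    zvec[p] = z;

    // sample one candidate by inverse CDF
    int pick = 0;
    if (z > 0.0) {
      const double u = rng.unif() * z;
      double acc = 0.0;
      pick = n_place;  // fp-safe fallback
      for (int ci = 0; ci <= n_place; ++ci) {
        acc += cw[ci];
        if (u <= acc) { pick = ci; break; }
      }
      while (pick > 0 && cw[pick] == 0.0) --pick;
    }
    new_placements(p, t_prev) = pick - 1;
    if (pick > 0) {
      const int* bases = &cand_bases[static_cast<size_t>(pick - 1) * w];
      for (int j = 0; j < w; ++j) new_counts(p, 4 * j + bases[j]) += 1.0;
    }
  }

  // weight update: w_new propto w_old * Z_p
  double log_z_step;
  {
    double s = 0.0;
    for (int p = 0; p < n; ++p) s += weights[p] * zvec[p];
    log_z_step = std::log(s);
  }
  NumericVector new_w(n);
  double tot = 0.0;
  for (int p = 0; p < n; ++p) {
    new_w[p] = weights[p] * zvec[p];
    tot += new_w[p];
  }
  if (tot <= 0.0) {
    for (int p = 0; p < n; ++p) new_w[p] = 1.0 / n;
  } else {
    for (int p = 0; p < n; ++p) new_w[p] /= tot;
  }

  double ess = 0.0;
  for (int p = 0; p < n; ++p) ess += new_w[p] * new_w[p];
  ess = 1.0 / ess;

  bool resampled = false;
  if (ess < resample_frac * n) {
    resampled = true;
    std::vector<int> idx(n);
    const double u0 = rng.unif() / n;
    double acc = new_w[0];
    int j = 0;
    for (int i = 0; i < n; ++i) {
      const double u = u0 + static_cast<double>(i) / n;
      while (acc < u && j < n - 1) acc += new_w[++j];
      idx[i] = j;
    }
    NumericMatrix rc(n, new_counts.ncol());
    IntegerMatrix rp(n, t_prev + 1);
    for (int i = 0; i < n; ++i) {
      for (int col = 0; col < new_counts.ncol(); ++col)
        rc(i, col) = new_counts(idx[i], col);
      for (int t = 0; t <= t_prev; ++t) rp(i, t) = new_placements(idx[i], t);
    }
    new_counts = rc;
    new_placements = rp;
    for (int p = 0; p < n; ++p) new_w[p] = 1.0 / n;
  }

  return List::create(_["counts"] = new_counts,
                      _["weights"] = new_w,
                      _["placements"] = new_placements,
                      _["log_z"] = log_z_step,
                      _["ess"] = ess,
                      _["resampled"] = resampled);
}

// Log-likelihood-ratio scores (log2) of every window of a coded sequence
// against a PWM; windows containing N (code 0) get NA.
// theta_flat is length 4w, position-major.
// [[Rcpp::export]]
NumericVector scan_scores_cpp(IntegerVector seq_codes,
                              NumericVector theta_flat,
                              NumericVector background, int w,
                              bool reverse_strand) {
  const int L = seq_codes.size();
  const int K = L - w + 1;
  if (K <= 0) return NumericVector(0);
  std::vector<double> lw(4 * w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b)
      lw[4 * j + b] =
          std::log2(theta_flat[4 * j + b]) - std::log2(background[b]);
  NumericVector out(K);
  for (int o = 0; o < K; ++o) {
    double s = 0.0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      const int base =
          reverse_strand ? seq_codes[o + w - 1 - j] : seq_codes[o + j];
      if (base == 0) { ok = false; break; }
      const int b0 = reverse_strand ? 4 - base : base - 1;
      s += lw[4 * j + b0];
    }
    out[o] = ok ? s : NA_REAL;
  }
  return out;
}
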