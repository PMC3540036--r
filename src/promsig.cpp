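// Core lattice computations for promoter recognition signature models.
//
// All sequence likelihoods are handled as odds against the iid GC background,
// with periodic rescaling by 1e-300 (counted) so that strongly matching
// promoters with many sites cannot overflow a double.  The recursion collapses
// the per-position state lattice (b0/b1/bx + matrix blocks) into two running
// quantities per position:
//   A[i]: odds mass of paths over bases 1..i that have emitted no site yet
//         (state b0), relative to pure background;
//   B[i]: odds mass of paths that have completed >= 1 site (state b1 or a
//         just-finished matrix block).
// Site blocks enter as precomputed emission odds (product over the block of
// matrix/background ratios), so a single likelihood evaluation is O(L) after
// an O(L*w) per-dataset precomputation.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>

using namespace Rcpp;

static const double SCALE_DOWN = 1e-300;
static const double LOG_SCALE = 690.77552789821368; // -log(1e-300)
static const double RESCALE_AT = 1e280;

// position-dependent site initiation rates; j is the 0-based start of a
// candidate site of width w in a promoter of length L (TSS at the right end),
// so the site's TSS-proximal end lies p = L - j - w bases upstream of the TSS.
static void fill_q(int L, int w, double mu, double omega, double tau,
                   double lambda, double eta,
                   std::vector<double> &qf, std::vector<double> &qr) {
  qf.assign(L, 0.0);
  qr.assign(L, 0.0);
  for (int j = 0; j + w <= L; ++j) {
    double p = (double)(L - j - w);
    double g1 = 1.0 / (1.0 + std::exp(-eta * (p - (mu - omega))));
    double g2 = 1.0 / (1.0 + std::exp(-eta * ((mu + omega) - p)));
    double g = lambda * g1 * g2;
    qf[j] = g * tau;
    qr[j] = g * (1.0 - tau);
  }
}

// Monosite variant: exactly one site is placed at a position/strand drawn
// from the plateau-shaped categorical distribution q / sum(q) (the rate
// scale lambda cancels, leaving rho, tau, mu, omega as the variant's
// parameters).  Returns the log emission odds of the single-site branch.
static double mono_logB(const double *ef, const double *er, int L, int w,
                        const std::vector<double> &qf,
                        const std::vector<double> &qr) {
  double Q = 0.0, num = 0.0;
  for (int j = 0; j + w <= L; ++j) {
    if (ef[j] < 0.0) continue;
    Q += qf[j] + qr[j];
    num += qf[j] * ef[j] + qr[j] * er[j];
  }
  return (Q > 0.0 && num > 0.0) ? std::log(num / Q) : R_NegInf;
}

// forward pass in odds space (multisite); ef/er have length L with -1
// marking starts at which initiation is forbidden (site would overlap
// N/masked fill or run off the 3' end).  Returns log of the accept-state
// odds mass B(L); optionally keeps the full A/B/scale arrays for posterior
// computation.
static double forward_logB(const double *ef, const double *er, int L, int w,
                           const std::vector<double> &qf,
                           const std::vector<double> &qr, bool monosite,
                           std::vector<double> *Aout, std::vector<double> *Bout,
                           std::vector<int> *scout) {
  if (monosite && !Aout) return mono_logB(ef, er, L, w, qf, qr);
  std::vector<double> A(L + 1), B(L + 1);
  std::vector<int> sc(L + 1, 0);
  A[0] = 1.0;
  B[0] = 0.0;
  for (int i = 1; i <= L; ++i) {
    int j = i - 1; // candidate site start at this base
    double qt = (j + w <= L && ef[j] >= 0.0) ? (qf[j] + qr[j]) : 0.0;
    double a = A[i - 1] * (1.0 - qt);
    double b = monosite ? B[i - 1] : B[i - 1] * (1.0 - qt);
    int s = i - w; // start of a site whose last base is i-1
    if (s >= 0 && ef[s] >= 0.0) {
      double inflow = monosite ? A[s] : (A[s] + B[s]);
      double contrib = inflow * (qf[s] * ef[s] + qr[s] * er[s]);
      int d = sc[i - 1] - sc[s];
      while (d-- > 0) contrib *= SCALE_DOWN;
      b += contrib;
    }
    sc[i] = sc[i - 1];
    if (a > RESCALE_AT || b > RESCALE_AT) {
      a *= SCALE_DOWN;
      b *= SCALE_DOWN;
      sc[i]++;
    }
    A[i] = a;
    B[i] = b;
  }
  double logB = (B[L] <= 0.0) ? R_NegInf : std::log(B[L]) + sc[L] * LOG_SCALE;
  if (Aout) {
    *Aout = A;
    *Bout = B;
    *scout = sc;
  }
  return logB;
}

// backward pass: D1[i] = odds mass of emitting bases i..L-1 and accepting,
// given >= 1 site already emitted; D0[i] likewise given no site yet.
static void backward_D(const double *ef, const double *er, int L, int w,
                       const std::vector<double> &qf,
                       const std::vector<double> &qr, bool monosite,
                       std::vector<double> &D1, std::vector<double> &D0,
                       std::vector<int> &scD) {
  D1.assign(L + 1, 0.0);
  D0.assign(L + 1, 0.0);
  scD.assign(L + 1, 0);
  D1[L] = 1.0;
  D0[L] = 0.0;
  for (int i = L - 1; i >= 0; --i) {
    bool ok = (i + w <= L && ef[i] >= 0.0);
    double qt = ok ? (qf[i] + qr[i]) : 0.0;
    double site = 0.0;
    if (ok) {
      double adj = 1.0;
      int d = scD[i + 1] - scD[i + w];
      while (d-- > 0) adj *= SCALE_DOWN;
      site = (qf[i] * ef[i] + qr[i] * er[i]) * D1[i + w] * adj;
    }
    double d1 = monosite ? D1[i + 1] : (1.0 - qt) * D1[i + 1] + site;
    double d0 = (1.0 - qt) * D0[i + 1] + site;
    scD[i] = scD[i + 1];
    if (d1 > RESCALE_AT || d0 > RESCALE_AT) {
      d1 *= SCALE_DOWN;
      d0 *= SCALE_DOWN;
      scD[i]++;
    }
    D1[i] = d1;
    D0[i] = d0;
  }
}

// Per-start emission odds against background for both orientations.
// seq: 1..4 codes (A,C,G,T), 0 for N; mask marks padded fill positions.
// [[Rcpp::export]]
List cpp_site_odds(IntegerVector seq, LogicalVector mask, NumericMatrix probs,
                   NumericVector bg) {
  int L = seq.size(), w = probs.nrow();
  NumericVector ef(L), er(L);
  for (int j = 0; j < L; ++j) {
    if (j + w > L) {
      ef[j] = -1.0;
      er[j] = -1.0;
      continue;
    }
    bool ok = true;
    double of = 1.0, orv = 1.0;
    for (int t = 0; t < w; ++t) {
      int b = seq[j + t];
      if (b == 0 || mask[j + t]) {
        ok = false;
        break;
      }
      double denom = bg[b - 1];
      of *= probs(t, b - 1) / denom;
      // reverse orientation: block position t carries matrix row w-1-t
      // read on the complementary base (A<->T, C<->G i.e. code 5-b)
      orv *= probs(w - 1 - t, 4 - b) / denom;
    }
    ef[j] = ok ? of : -1.0;
    er[j] = ok ? orv : -1.0;
  }
  return List::create(_["ef"] = ef, _["er"] = er);
}

struct QCache {
  std::map<int, std::pair<std::vector<double>, std::vector<double> > > m;
  int w;
  double mu, omega, tau, lambda, eta;
  QCache(int w_, double mu_, double om_, double ta_, double la_, double et_)
      : w(w_), mu(mu_), omega(om_), tau(ta_), lambda(la_), eta(et_) {}
  const std::pair<std::vector<double>, std::vector<double> > &get(int L) {
    std::map<int, std::pair<std::vector<double>, std::vector<double> > >::iterator
        it = m.find(L);
    if (it == m.end()) {
      std::pair<std::vector<double>, std::vector<double> > qq;
      fill_q(L, w, mu, omega, tau, lambda, eta, qq.first, qq.second);
      it = m.insert(std::make_pair(L, qq)).first;
    }
    return it->second;
  }
};

// [[Rcpp::export]]
NumericVector cpp_batch_logB(List odds, int w, bool monosite, double mu,
                             double omega, double tau, double lambda,
                             double eta) {
  int n = odds.size();
  NumericVector out(n);
  QCache qc(w, mu, omega, tau, lambda, eta);
  for (int k = 0; k < n; ++k) {
    List o = odds[k];
    NumericVector ef = o["ef"], er = o["er"];
    int L = ef.size();
    const std::pair<std::vector<double>, std::vector<double> > &qq = qc.get(L);
    out[k] = forward_logB(ef.begin(), er.begin(), L, w, qq.first, qq.second,
                          monosite, 0, 0, 0);
  }
  return out;
}

static double log_denom(double rho, double logB) {
  // log(rho * exp(logB) + (1 - rho))
  if (rho <= 0.0) return 0.0;
  if (rho >= 1.0) return logB;
  double a = std::log(rho) + logB, b = std::log1p(-rho);
  if (a == R_NegInf) return b;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// E-step summaries for one sequence given precomputed odds.
static void seq_posteriors(const double *ef, const double *er, int L, int w,
                           const std::vector<double> &qf,
                           const std::vector<double> &qr, bool monosite,
                           double rho, double &logB, double &e_r,
                           double &fwd_mass, double &rev_mass,
                           NumericMatrix *track) {
  if (monosite) {
    double Q = 0.0, num = 0.0;
    for (int j = 0; j + w <= L; ++j) {
      if (ef[j] < 0.0) continue;
      Q += qf[j] + qr[j];
      num += qf[j] * ef[j] + qr[j] * er[j];
    }
    logB = (Q > 0.0 && num > 0.0) ? std::log(num / Q) : R_NegInf;
    double ld = log_denom(rho, logB);
    e_r = (rho <= 0.0 || logB == R_NegInf)
              ? (rho >= 1.0 ? NA_REAL : 0.0)
              : std::exp(std::log(rho) + logB - ld);
    if (rho >= 1.0 && logB > R_NegInf) e_r = 1.0;
    fwd_mass = 0.0;
    rev_mass = 0.0;
    bool dead = (rho <= 0.0 || logB == R_NegInf);
    double lrho = dead ? 0.0 : std::log(rho);
    for (int j = 0; j + w <= L; ++j) {
      double pf = 0.0, pr = 0.0;
      if (!dead && ef[j] >= 0.0) {
        if (qf[j] * ef[j] > 0.0)
          pf = std::exp(lrho + std::log(qf[j] * ef[j] / Q) - ld);
        if (qr[j] * er[j] > 0.0)
          pr = std::exp(lrho + std::log(qr[j] * er[j] / Q) - ld);
      }
      fwd_mass += pf;
      rev_mass += pr;
      if (track) {
        (*track)(0, j) = pf;
        (*track)(1, j) = pr;
      }
    }
    if (track) {
      for (int j = (L - w + 1 > 0 ? L - w + 1 : 0); j < L; ++j) {
        (*track)(0, j) = 0.0;
        (*track)(1, j) = 0.0;
      }
    }
    return;
  }
  std::vector<double> A, B, D1, D0;
  std::vector<int> sc, scD;
  logB = forward_logB(ef, er, L, w, qf, qr, monosite, &A, &B, &sc);
  double ld = log_denom(rho, logB);
  e_r = (rho <= 0.0 || logB == R_NegInf)
            ? (rho >= 1.0 ? NA_REAL : 0.0)
            : std::exp(std::log(rho) + logB - ld);
  if (rho >= 1.0 && logB > R_NegInf) e_r = 1.0;
  fwd_mass = 0.0;
  rev_mass = 0.0;
  if (rho <= 0.0 || logB == R_NegInf) {
    if (track)
      for (int j = 0; j < L; ++j) {
        (*track)(0, j) = 0.0;
        (*track)(1, j) = 0.0;
      }
    return;
  }
  backward_D(ef, er, L, w, qf, qr, monosite, D1, D0, scD);
  double lrho = std::log(rho);
  for (int j = 0; j + w <= L; ++j) {
    double pf = 0.0, pr = 0.0;
    if (ef[j] >= 0.0) {
      double inflow = monosite ? A[j] : (A[j] + B[j]);
      if (inflow > 0.0 && D1[j + w] > 0.0) {
        double lbase = lrho + std::log(inflow) + sc[j] * LOG_SCALE +
                       std::log(D1[j + w]) + scD[j + w] * LOG_SCALE - ld;
        if (qf[j] * ef[j] > 0.0)
          pf = std::exp(lbase + std::log(qf[j] * ef[j]));
        if (qr[j] * er[j] > 0.0)
          pr = std::exp(lbase + std::log(qr[j] * er[j]));
      }
    }
    fwd_mass += pf;
    rev_mass += pr;
    if (track) {
      (*track)(0, j) = pf;
      (*track)(1, j) = pr;
    }
  }
}

// [[Rcpp::export]]
List cpp_batch_estep(List odds, int w, bool monosite, double rho, double mu,
                     double omega, double tau, double lambda, double eta) {
  int n = odds.size();
  NumericVector logB(n), e_r(n), fwd(n), rev(n);
  QCache qc(w, mu, omega, tau, lambda, eta);
  for (int k = 0; k < n; ++k) {
    List o = odds[k];
    NumericVector ef = o["ef"], er = o["er"];
    int L = ef.size();
    const std::pair<std::vector<double>, std::vector<double> > &qq = qc.get(L);
    double lb, erk, fm, rm;
    seq_posteriors(ef.begin(), er.begin(), L, w, qq.first, qq.second, monosite,
                   rho, lb, erk, fm, rm, 0);
    logB[k] = lb;
    e_r[k] = erk;
    fwd[k] = fm;
    rev[k] = rm;
  }
  return List::create(_["logB"] = logB, _["e_r"] = e_r, _["fwd_mass"] = fwd,
                      _["rev_mass"] = rev);
}

// [[Rcpp::export]]
List cpp_posterior_track(NumericVector ef, NumericVector er, int w,
                         bool monosite, double rho, double mu, double omega,
                         double tau, double lambda, double eta) {
  int L = ef.size();
  std::vector<double> qf, qr;
  fill_q(L, w, mu, omega, tau, lambda, eta, qf, qr);
  NumericMatrix track(2, L);
  double logB, e_r, fm, rm;
  seq_posteriors(ef.begin(), er.begin(), L, w, qf, qr, monosite, rho, logB, e_r,
                 fm, rm, &track);
  return List::create(_["logB"] = logB, _["e_r"] = e_r, _["fwd_mass"] = fm,
                      _["rev_mass"] = rm, _["site_start"] = track);
}

// log P(C = 1 | R = 1): forward pass with unit emission odds over the
// positions where initiation is allowed.
// [[Rcpp::export]]
double cpp_log_accept(LogicalVector allow, int w, bool monosite, double mu,
                      double omega, double tau, double lambda, double eta) {
  int L = allow.size();
  std::vector<double> qf, qr;
  fill_q(L, w, mu, omega, tau, lambda, eta, qf, qr);
  std::vector<double> ef(L), er(L);
  for (int j = 0; j < L; ++j) {
    ef[j] = allow[j] ? 1.0 : -1.0;
    er[j] = allow[j] ? 1.0 : -1.0;
  }
  return forward_logB(&ef[0], &er[0], L, w, qf, qr, monosite, 0, 0, 0);
}

// Generative sampler; rejection-resamples whole draws until the consistency
// constraint is met (R = 1 paths must contain at least one complete site).
// Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List cpp_sample(int L, NumericMatrix probs, NumericVector bg, bool monosite,
                double rho, double mu, double omega, double tau, double lambda,
                double eta, int max_tries) {
  int w = probs.nrow();
  std::vector<double> qf, qr;
  fill_q(L, w, mu, omega, tau, lambda, eta, qf, qr);
  double cbg[4];
  cbg[0] = bg[0];
  for (int b = 1; b < 4; ++b) cbg[b] = cbg[b - 1] + bg[b];
  IntegerVector seq(L);
  std::vector<int> starts, strands;
  int r = 0, tries = 0;
  bool ok = false;
  double Q = 0.0;
  if (monosite) {
    for (int j = 0; j + w <= L; ++j) Q += qf[j] + qr[j];
  }
  // R is drawn once; an R = 1 promoter's lattice walk is resampled until
  // it contains at least one complete site (the consistency constraint)
  r = (unif_rand() < rho) ? 1 : 0;
  while (tries < max_tries && !ok) {
    ++tries;
    starts.clear();
    strands.clear();
    if (monosite && r == 1) {
      if (Q <= 0.0) continue; // cannot satisfy consistency
      // place the single site by the normalized plateau distribution
      double u = unif_rand() * Q, c = 0.0;
      int site_j = -1, site_f = 1;
      for (int j = 0; j + w <= L && site_j < 0; ++j) {
        c += qf[j];
        if (u < c) {
          site_j = j;
          site_f = 1;
          break;
        }
        c += qr[j];
        if (u < c) {
          site_j = j;
          site_f = 0;
          break;
        }
      }
      if (site_j < 0) site_j = L - w;
      starts.push_back(site_j);
      strands.push_back(site_f ? 1 : -1);
      for (int i = 0; i < L; ++i) {
        if (i >= site_j && i < site_j + w) {
          int t = i - site_j;
          double v = unif_rand(), cc = 0.0;
          int row = site_f ? t : (w - 1 - t);
          int emitted = 3;
          for (int b = 0; b < 4; ++b) {
            cc += probs(row, b);
            if (v < cc) {
              emitted = b;
              break;
            }
          }
          seq[i] = site_f ? (emitted + 1) : (4 - emitted);
        } else {
          double v = unif_rand();
          int b = 3;
          for (int k = 0; k < 4; ++k)
            if (v < cbg[k]) {
              b = k;
              break;
            }
          seq[i] = b + 1;
        }
      }
      ok = true;
      break;
    }
    int i = 0;
    while (i < L) {
      bool can = (r == 1) && (i + w <= L);
      double u = unif_rand();
      if (can && u < qf[i] + qr[i]) {
        int fwdsite = (u < qf[i]) ? 1 : 0;
        starts.push_back(i);
        strands.push_back(fwdsite ? 1 : -1);
        for (int t = 0; t < w; ++t) {
          double v = unif_rand(), c = 0.0;
          int row = fwdsite ? t : (w - 1 - t);
          int emitted = 3;
          for (int b = 0; b < 4; ++b) {
            c += probs(row, b);
            if (v < c) {
              emitted = b;
              break;
            }
          }
          // reverse orientation emits the complement on the stored strand
          seq[i + t] = fwdsite ? (emitted + 1) : (4 - emitted);
        }
        i += w;
      } else {
        double v = unif_rand();
        int b = 3;
        for (int k = 0; k < 4; ++k)
          if (v < cbg[k]) {
            b = k;
            break;
          }
        seq[i] = b + 1;
        ++i;
      }
    }
    ok = (r == 0) || !starts.empty();
  }
  return List::create(_["seq"] = seq, _["starts"] = wrap(starts),
                      _["strands"] = wrap(strands), _["r"] = r,
                      _["ok"] = ok, _["tries"] = tries);
}

// Exact KL divergence between the model's conditional promoter distribution
// (given C = 1) and the iid background, by enumerating all 4^L sequences.
// [[Rcpp::export]]
List cpp_exact_kl(int L, NumericMatrix probs, NumericVector bg, bool monosite,
                  double rho, double mu, double omega, double tau,
                  double lambda, double eta) {
  int w = probs.nrow();
  std::vector<double> qf, qr;
  fill_q(L, w, mu, omega, tau, lambda, eta, qf, qr);
  std::vector<double> allow_f(L, 1.0), allow_r(L, 1.0);
  for (int j = 0; j < L; ++j)
    if (j + w > L) {
      allow_f[j] = -1.0;
      allow_r[j] = -1.0;
    }
  // log P(>=1 complete site | R = 1); the model's normalized sequence
  // distribution is the mixture rho * P(N | R=1, C=1) + (1-rho) * bg
  double logA = forward_logB(&allow_f[0], &allow_r[0], L, w, qf, qr,
                             monosite, 0, 0, 0);
  std::vector<int> seq(L, 0);
  std::vector<double> ef(L), er(L);
  double kl = 0.0, tot = 0.0;
  long long nseq = 1;
  for (int i = 0; i < L; ++i) nseq *= 4;
  for (long long g = 0; g < nseq; ++g) {
    long long x = g;
    double lbg = 0.0;
    for (int i = 0; i < L; ++i) {
      seq[i] = (int)(x & 3);
      x >>= 2;
      lbg += std::log(bg[seq[i]]);
    }
    for (int j = 0; j < L; ++j) {
      if (j + w > L) {
        ef[j] = -1.0;
        er[j] = -1.0;
        continue;
      }
      double of = 1.0, orv = 1.0;
      for (int t = 0; t < w; ++t) {
        int b = seq[j + t];
        of *= probs(t, b) / bg[b];
        orv *= probs(w - 1 - t, 3 - b) / bg[b];
      }
      ef[j] = of;
      er[j] = orv;
    }
    double logB = forward_logB(&ef[0], &er[0], L, w, qf, qr, monosite, 0, 0, 0);
    double lp;
    if (rho <= 0.0 || logB == R_NegInf) {
      lp = (rho >= 1.0) ? R_NegInf : std::log1p(-rho) + lbg;
    } else if (rho >= 1.0) {
      lp = logB - logA + lbg;
    } else {
      double a = std::log(rho) + logB - logA, b = std::log1p(-rho);
      double m = a > b ? a : b;
      lp = m + std::log(std::exp(a - m) + std::exp(b - m)) + lbg;
    }
    double p = std::exp(lp);
    tot += p;
    if (p > 0.0) kl += p * (lp - lbg);
  }
  return List::create(_["kl"] = kl, _["total_p"] = tot,
                      _["log_accept"] = logA);
}

// does the window starting at t score >= thresh on either strand?
// Windows containing N are never counted as sites.
static bool window_is_site(const int *s, int L, int t, int w,
                           const NumericMatrix &lo, const NumericMatrix &lorc,
                           double thresh) {
  if (t < 0 || t + w > L) return false;
  double sf = 0.0, sr = 0.0;
  for (int k = 0; k < w; ++k) {
    int b = s[t + k];
    if (b == 0) return false;
    sf += lo(k, b - 1);
    sr += lorc(k, b - 1);
  }
  return sf >= thresh || sr >= thresh;
}

// Iterative segment-swap scrambler.  Each iteration picks a random segment
// whose two boundaries are not crossed by any scoring site, then an
// equal-length partner segment under the same condition, and swaps them.
// A per-position site flag is kept current after every swap (equivalent to
// rescanning), so the border check always reflects earlier swaps.  Base
// multiset and per-sequence lengths are conserved exactly.  Uses R's RNG.
// [[Rcpp::export]]
List cpp_scramble(List seqs, NumericMatrix lo, NumericMatrix lorc,
                  double thresh, int min_len, int max_len, double iters,
                  int max_attempts) {
  int n = seqs.size(), w = lo.nrow();
  std::vector<IntegerVector> S(n);
  std::vector<int> lens(n);
  std::vector<std::vector<char> > flag(n); // window at t is a site
  for (int i = 0; i < n; ++i) {
    S[i] = clone(as<IntegerVector>(seqs[i]));
    lens[i] = S[i].size();
    flag[i].assign(lens[i], 0);
    for (int t = 0; t + w <= lens[i]; ++t) {
      flag[i][t] = window_is_site(S[i].begin(), lens[i], t, w, lo, lorc,
                                  thresh);
    }
  }
  // a boundary between x-1 and x is blocked if any site window crosses it
  // (window starts x-w+1 .. x-1); sequence ends are never blocked
  struct Blocked {
    static bool check(const std::vector<char> &f, int L, int x, int w) {
      if (x <= 0 || x >= L) return false;
      int t0 = x - w + 1 < 0 ? 0 : x - w + 1;
      for (int t = t0; t <= x - 1; ++t) {
        if (f[t]) return true;
      }
      return false;
    }
  };
  double swaps = 0.0, skipped = 0.0;
  for (double it = 0.0; it < iters; ++it) {
    int len = min_len + (int)(unif_rand() * (max_len - min_len + 1));
    if (len > max_len) len = max_len;
    int s1 = -1, a1 = -1;
    for (int att = 0; att < max_attempts; ++att) {
      int si = (int)(unif_rand() * n);
      if (si >= n) si = n - 1;
      if (lens[si] < len) continue;
      int a = (int)(unif_rand() * (lens[si] - len + 1));
      if (Blocked::check(flag[si], lens[si], a, w)) continue;
      if (Blocked::check(flag[si], lens[si], a + len, w)) continue;
      s1 = si;
      a1 = a;
      break;
    }
    if (s1 < 0) {
      skipped += 1.0;
      continue;
    }
    int s2 = -1, a2 = -1;
    for (int att = 0; att < max_attempts; ++att) {
      int si = (int)(unif_rand() * n);
      if (si >= n) si = n - 1;
      if (lens[si] < len) continue;
      int a = (int)(unif_rand() * (lens[si] - len + 1));
      if (si == s1 && a < a1 + len && a1 < a + len) continue; // overlap
      if (Blocked::check(flag[si], lens[si], a, w)) continue;
      if (Blocked::check(flag[si], lens[si], a + len, w)) continue;
      s2 = si;
      a2 = a;
      break;
    }
    if (s2 < 0) {
      skipped += 1.0;
      continue;
    }
    for (int k = 0; k < len; ++k) {
      int tmp = S[s1][a1 + k];
      S[s1][a1 + k] = S[s2][a2 + k];
      S[s2][a2 + k] = tmp;
    }
    // refresh flags over every window touching the altered ranges
    int segs[2] = {s1, s2};
    int starts[2] = {a1, a2};
    for (int u = 0; u < 2; ++u) {
      int si = segs[u];
      int t0 = starts[u] - w + 1 < 0 ? 0 : starts[u] - w + 1;
      int t1 = starts[u] + len - 1;
      if (t1 + w > lens[si]) t1 = lens[si] - w;
      for (int t = t0; t <= t1; ++t) {
        flag[si][t] = window_is_site(S[si].begin(), lens[si], t, w, lo, lorc,
                                     thresh);
      }
    }
    swaps += 1.0;
  }
  List out(n);
  for (int i = 0; i < n; ++i) out[i] = S[i];
  return List::create(_["seqs"] = out, _["swaps"] = swaps,
                      _["skipped"] = skipped);
}
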