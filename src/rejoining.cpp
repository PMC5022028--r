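#include <Rcpp.h>
using namespace Rcpp;

// Uniform point in the unit sphere via rejection from the enclosing cube.
static inline void runif_sphere(double &x, double &y, double &z) {
  double r2;
  do {
    x = 2.0 * unif_rand() - 1.0;
    y = 2.0 * unif_rand() - 1.0;
    z = 2.0 * unif_rand() - 1.0;
    r2 = x * x + y * y + z * z;
  } while (r2 > 1.0);
}

// Sequential competitive rejoining of DSB free ends in the unit sphere.
//
// Each break contributes two co-located free ends; the pairing weight between
// ends separated by d is the Gaussian kernel exp(-d^2 / (2 sigma^2)). Ends are
// drawn uniformly at random; the drawn end picks its partner among the
// remaining free ends with probability proportional to the kernel, until all
// ends are joined. A break is scored as misrepaired when its two ends did not
// rejoin with each other. Misrepair events are classified intra- vs
// inter-chromosome by labels assigned from the nearest of n_chrom uniformly
// placed territory centres, and the break-to-break separations of intra events
// can be recorded.
//
// [[Rcpp::export]]
List rejoin_pairing_cpp(int n0, double sigma, int n_chrom, int replicates,
                        bool keep_separations = false) {
  if (n0 < 1 || replicates < 1 || n_chrom < 1)
    stop("n0, n_chrom and replicates must be positive");
  if (sigma <= 0.0) stop("sigma must be positive");
  NumericVector mis_frac(replicates), intra_frac(replicates);
  std::vector<double> seps;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);

  std::vector<double> px(n0), py(n0), pz(n0);
  std::vector<double> cx(n_chrom), cy(n_chrom), cz(n_chrom);
  std::vector<int> lab(n0);
  std::vector<double> W((size_t)n0 * n0);
  std::vector<int> alive(2 * n0), match(2 * n0);
  std::vector<double> wts(2 * n0);

  for (int rep = 0; rep < replicates; ++rep) {
    for (int i = 0; i < n0; ++i) runif_sphere(px[i], py[i], pz[i]);
    for (int c = 0; c < n_chrom; ++c) runif_sphere(cx[c], cy[c], cz[c]);
    for (int i = 0; i < n0; ++i) {
      double best = R_PosInf; int bi = 0;
      for (int c = 0; c < n_chrom; ++c) {
        double dx = px[i] - cx[c], dy = py[i] - cy[c], dz = pz[i] - cz[c];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) { best = d2; bi = c; }
      }
      lab[i] = bi;
    }
    // break-pair kernel weights; diagonal = correct-partner weight (d = 0)
    for (int i = 0; i < n0; ++i) {
      W[(size_t)i * n0 + i] = 1.0;
      for (int j = i + 1; j < n0; ++j) {
        double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
        double w = std::exp(-(dx * dx + dy * dy + dz * dz) * inv2s2);
        W[(size_t)i * n0 + j] = w;
        W[(size_t)j * n0 + i] = w;
      }
    }
    int nAlive = 2 * n0;
    for (int e = 0; e < nAlive; ++e) alive[e] = e;
    std::fill(match.begin(), match.end(), -1);
    while (nAlive > 0) {
      int idx = (int)(unif_rand() * nAlive);
      if (idx >= nAlive) idx = nAlive - 1;
      int e = alive[idx];
      int be = e >> 1;
      double tot = 0.0;
      for (int k = 0; k < nAlive; ++k) {
        int f = alive[k];
        double w = (f == e) ? 0.0 : W[(size_t)be * n0 + (f >> 1)];
        wts[k] = w;
        tot += w;
      }
      int kSel = -1;
      if (tot > 0.0) {
        double u = unif_rand() * tot;
        double acc = 0.0;
        for (int k = 0; k < nAlive; ++k) {
          acc += wts[k];
          if (u <= acc && wts[k] > 0.0) { kSel = k; break; }
        }
        if (kSel < 0) { // guard against rounding at u ~ tot
          for (int k = nAlive - 1; k >= 0; --k)
            if (wts[k] > 0.0) { kSel = k; break; }
        }
      }
      if (kSel < 0) {
        // every candidate weight underflowed; partner choice is then uniform
        int off = 1 + (int)(unif_rand() * (nAlive - 1));
        if (off > nAlive - 1) off = nAlive - 1;
        kSel = (idx + off) % nAlive;
      }
      int f = alive[kSel];
      match[e] = f; match[f] = e;
      int i1 = idx, i2 = kSel;
      if (i1 < i2) std::swap(i1, i2);
      alive[i1] = alive[--nAlive];
      alive[i2] = alive[--nAlive];
    }
    int nMis = 0, nIntra = 0, nEvents = 0;
    for (int i = 0; i < n0; ++i)
      if (match[2 * i] != 2 * i + 1) ++nMis;
    for (int e = 0; e < 2 * n0; ++e) {
      int f = match[e];
      if (f > e) {
        int a = e >> 1, b = f >> 1;
        if (a != b) {
          ++nEvents;
          if (lab[a] == lab[b]) {
            ++nIntra;
            if (keep_separations) {
              double dx = px[a] - px[b], dy = py[a] - py[b], dz = pz[a] - pz[b];
              seps.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
            }
          }
        }
      }
    }
    mis_frac[rep] = (double)nMis / n0;
    intra_frac[rep] = nEvents > 0 ? (double)nIntra / nEvents : NA_REAL;
  }
  return List::create(_["mis_frac"] = mis_frac,
                      _["intra_frac"] = intra_frac,
                      _["separations"] = wrap(seps));
}

// Mean-field misrejoining ensemble for a single randomly placed DSB.
//
// One test break sits at a uniform point of the unit sphere and competes
// against 2 * n_other free ends placed independently and uniformly; per
// configuration the misrepair probability is W / (1 + W), where W is the sum
// of Gaussian kernel weights to the wrong ends and the co-located correct
// partner has weight 1. This is the ensemble whose mean defines the analytic
// misrejoining propensity, and whose skew across configurations the omega
// correction absorbs.
//
// [[Rcpp::export]]
List eta_ensemble_cpp(int n_other, double sigma, int replicates) {
  if (n_other < 0 || replicates < 1) stop("invalid counts");
  if (sigma <= 0.0) stop("sigma must be positive");
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double sum = 0.0, sum2 = 0.0;
  for (int rep = 0; rep < replicates; ++rep) {
    double x0, y0, z0;
    runif_sphere(x0, y0, z0);
    double W = 0.0;
    for (int i = 0; i < 2 * n_other; ++i) {
      double x, y, z;
      runif_sphere(x, y, z);
      double dx = x - x0, dy = y - y0, dz = z - z0;
      W += std::exp(-(dx * dx + dy * dy + dz * dz) * inv2s2);
    }
    double p = W / (1.0 + W);
    sum += p; sum2 += p * p;
  }
  double m = sum / replicates;
  double v = replicates > 1 ? (sum2 / replicates - m * m) / (replicates - 1) : NA_REAL;
  return List::create(_["m"] = m,
                      _["se"] = std::sqrt(v > 0 ? v : 0.0));
}
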