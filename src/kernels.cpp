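#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Minimum-image displacement for a rectangular box. box may have length 0
// (vacuum), in which case the displacement is returned unchanged.
static inline void min_image(double *d, const double *box, bool periodic) {
  if (!periodic) return;
  for (int k = 0; k < 3; ++k) d[k] -= box[k] * std::nearbyint(d[k] / box[k]);
}

// Charge-group based pair list: a pair of groups enters when the minimum-image
// distance of their geometric centers is within the cutoff; the list is then
// expanded to atom pairs, dropping topological exclusions. Pairs inside one
// group are always kept (their center distance is zero). Indices are 1-based
// on both sides of the interface.
// [[Rcpp::export]]
List cpp_build_pairlist(NumericMatrix pos, IntegerVector group_id,
                        NumericVector box, double cutoff, List exclusions) {
  const int n = pos.nrow();
  const bool periodic = box.size() == 3;
  double bx[3] = {0, 0, 0};
  if (periodic) { bx[0] = box[0]; bx[1] = box[1]; bx[2] = box[2]; }

  int ngroup = 0;
  for (int i = 0; i < n; ++i) ngroup = std::max(ngroup, group_id[i]);

  std::vector<double> cx(ngroup, 0.0), cy(ngroup, 0.0), cz(ngroup, 0.0);
  std::vector<int> cnt(ngroup, 0);
  std::vector<std::vector<int> > members(ngroup);
  for (int i = 0; i < n; ++i) {
    int g = group_id[i] - 1;
    cx[g] += pos(i, 0); cy[g] += pos(i, 1); cz[g] += pos(i, 2);
    cnt[g]++; members[g].push_back(i);
  }
  for (int g = 0; g < ngroup; ++g) {
    if (cnt[g] == 0) continue;
    cx[g] /= cnt[g]; cy[g] /= cnt[g]; cz[g] /= cnt[g];
  }

  // sorted exclusion lists for O(log k) membership tests
  std::vector<std::vector<int> > excl(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector e = exclusions[i];
    excl[i].assign(e.begin(), e.end());
    std::sort(excl[i].begin(), excl[i].end());
  }

  const double cut2 = cutoff * cutoff;
  std::vector<int> pi, pj;
  pi.reserve(16 * n); pj.reserve(16 * n);

  for (int g = 0; g < ngroup; ++g) {
    if (cnt[g] == 0) continue;
    for (int h = g; h < ngroup; ++h) {
      if (cnt[h] == 0) continue;
      if (h > g) {
        double d[3] = {cx[g] - cx[h], cy[g] - cy[h], cz[g] - cz[h]};
        min_image(d, bx, periodic);
        if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] > cut2) continue;
      }
      const std::vector<int> &ga = members[g], &ha = members[h];
      for (size_t a = 0; a < ga.size(); ++a) {
        size_t b0 = (h == g) ? a + 1 : 0;
        for (size_t b = b0; b < ha.size(); ++b) {
          int i = ga[a], j = ha[b];
          int lo = std::min(i, j), hi = std::max(i, j);
          if (std::binary_search(excl[lo].begin(), excl[lo].end(), hi + 1))
            continue;
          pi.push_back(lo + 1); pj.push_back(hi + 1);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj));
}

// Lennard-Jones plus reaction-field Coulomb over a prepared pair list.
// Per-pair C6, C12 (kJ mol^-1 nm^6 / nm^12) and qq = k_Coulomb * q_i * q_j
// are supplied by the caller so that embedding rules can zero out classes of
// interactions without touching the kernel. Energies, forces, and the scalar
// pair virial sum(f_ij . r_ij) are returned.
// [[Rcpp::export]]
List cpp_lj_rf(NumericMatrix pos, IntegerVector pi, IntegerVector pj,
               NumericVector c6, NumericVector c12, NumericVector qq,
               NumericVector box, double crf, double rc, double r_overlap) {
  const int np = pi.size();
  const bool periodic = box.size() == 3;
  double bx[3] = {0, 0, 0};
  if (periodic) { bx[0] = box[0]; bx[1] = box[1]; bx[2] = box[2]; }

  NumericMatrix forces(pos.nrow(), 3);
  double elj = 0.0, ecoul = 0.0, virial = 0.0;
  const double rc3 = rc * rc * rc;
  const double crf_half = (1.0 + 0.5 * crf) / rc;

  for (int p = 0; p < np; ++p) {
    const int i = pi[p] - 1, j = pj[p] - 1;
    double d[3] = {pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                   pos(i, 2) - pos(j, 2)};
    min_image(d, bx, periodic);
    const double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    const double r = std::sqrt(r2);
    if (r < r_overlap)
      stop("atom overlap: pair (%d, %d) at distance %f nm", i + 1, j + 1, r);
    const double ir2 = 1.0 / r2;
    const double ir6 = ir2 * ir2 * ir2;

    // LJ
    const double vlj = c12[p] * ir6 * ir6 - c6[p] * ir6;
    const double flj = (12.0 * c12[p] * ir6 * ir6 - 6.0 * c6[p] * ir6) * ir2;
    // reaction-field Coulomb
    const double vc = qq[p] * (1.0 / r + 0.5 * crf * r2 / rc3 - crf_half);
    const double fc = qq[p] * (ir2 / r - crf / rc3);

    elj += vlj; ecoul += vc;
    const double fscal = flj + fc;
    for (int k = 0; k < 3; ++k) {
      const double fk = fscal * d[k];
      forces(i, k) += fk; forces(j, k) -= fk;
    }
    virial += fscal * r2;
  }
  return List::create(_["elj"] = elj, _["ecoul"] = ecoul,
                      _["forces"] = forces, _["virial"] = virial);
}

// Distance-dependent and constant reaction-field terms for excluded
// (intramolecular) pairs: V = qq * (crf r^2 / (2 rc^3) - (1 + crf/2)/rc).
// [[Rcpp::export]]
List cpp_rf_excluded(NumericMatrix pos, IntegerVector pi, IntegerVector pj,
                     NumericVector qq, NumericVector box, double crf,
                     double rc) {
  const int np = pi.size();
  const bool periodic = box.size() == 3;
  double bx[3] = {0, 0, 0};
  if (periodic) { bx[0] = box[0]; bx[1] = box[1]; bx[2] = box[2]; }

  NumericMatrix forces(pos.nrow(), 3);
  double energy = 0.0, virial = 0.0;
  const double rc3 = rc * rc * rc;
  const double crf_half = (1.0 + 0.5 * crf) / rc;

  for (int p = 0; p < np; ++p) {
    const int i = pi[p] - 1, j = pj[p] - 1;
    double d[3] = {pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                   pos(i, 2) - pos(j, 2)};
    min_image(d, bx, periodic);
    const double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    energy += qq[p] * (0.5 * crf * r2 / rc3 - crf_half);
    const double fscal = -qq[p] * crf / rc3;
    for (int k = 0; k < 3; ++k) {
      const double fk = fscal * d[k];
      forces(i, k) += fk; forces(j, k) -= fk;
    }
    virial += fscal * r2;
  }
  return List::create(_["energy"] = energy, _["forces"] = forces,
                      _["virial"] = virial);
}

// SHAKE: iteratively restore holonomic distance constraints on trial
// positions, using constraint directions from the reference positions.
// Returns corrected positions, the number of iterations, and the accumulated
// sum(gamma * |r_ref|^2) from which the constraint virial follows as
// -sum/dt^2.
// [[Rcpp::export]]
List cpp_shake(NumericMatrix ref, NumericMatrix trial, IntegerVector ci,
               IntegerVector cj, NumericVector d0, NumericVector invmass,
               double tol, int maxit) {
  const int nc = ci.size();
  NumericMatrix out = clone(trial);
  double gsum = 0.0;
  int iter = 0;
  bool done = false;

  while (!done && iter < maxit) {
    done = true;
    ++iter;
    for (int c = 0; c < nc; ++c) {
      const int i = ci[c] - 1, j = cj[c] - 1;
      double d[3] = {out(i, 0) - out(j, 0), out(i, 1) - out(j, 1),
                     out(i, 2) - out(j, 2)};
      const double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      const double d02 = d0[c] * d0[c];
      const double diff = r2 - d02;
      if (std::fabs(diff) > tol * d02) {
        done = false;
        double rr[3] = {ref(i, 0) - ref(j, 0), ref(i, 1) - ref(j, 1),
                        ref(i, 2) - ref(j, 2)};
        const double dot = d[0] * rr[0] + d[1] * rr[1] + d[2] * rr[2];
        if (std::fabs(dot) < 1e-12)
          stop("SHAKE: constraint %d (atoms %d-%d) perpendicular to reference",
               c + 1, i + 1, j + 1);
        const double g = diff / (2.0 * (invmass[i] + invmass[j]) * dot);
        for (int k = 0; k < 3; ++k) {
          out(i, k) -= g * invmass[i] * rr[k];
          out(j, k) += g * invmass[j] * rr[k];
        }
        gsum += g * (rr[0] * rr[0] + rr[1] * rr[1] + rr[2] * rr[2]);
      }
    }
  }
  if (!done)
    stop("SHAKE did not converge in %d iterations (first atoms %d-%d)", maxit,
         ci[0], cj[0]);
  return List::create(_["positions"] = out, _["iterations"] = iter,
                      _["gsum"] = gsum);
}

// Interaction energy between a tagged atom selection and the rest of the
// system under the same LJ + reaction-field force field (pairs crossing the
// selection boundary only).
// [[Rcpp::export]]
List cpp_cross_energy(NumericMatrix pos, IntegerVector pi, IntegerVector pj,
                      LogicalVector in_sel, NumericVector c6, NumericVector c12,
                      NumericVector qq, NumericVector box, double crf,
                      double rc) {
  const int np = pi.size();
  const bool periodic = box.size() == 3;
  double bx[3] = {0, 0, 0};
  if (periodic) { bx[0] = box[0]; bx[1] = box[1]; bx[2] = box[2]; }
  double elj = 0.0, ecoul = 0.0;
  const double rc3 = rc * rc * rc;
  const double crf_half = (1.0 + 0.5 * crf) / rc;
  for (int p = 0; p < np; ++p) {
    const int i = pi[p] - 1, j = pj[p] - 1;
    if (in_sel[i] == in_sel[j]) continue;
    double d[3] = {pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                   pos(i, 2) - pos(j, 2)};
    min_image(d, bx, periodic);
    const double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    const double r = std::sqrt(r2);
    const double ir6 = 1.0 / (r2 * r2 * r2);
    elj += c12[p] * ir6 * ir6 - c6[p] * ir6;
    ecoul += qq[p] * (1.0 / r + 0.5 * crf * r2 / rc3 - crf_half);
  }
  return List::create(_["elj"] = elj, _["ecoul"] = ecoul);
}

// Accumulate per-term force contributions onto atoms: rows of `mat` are
// added into `forces` at (1-based) indices `idx`, which may repeat.
// [[Rcpp::export]]
NumericMatrix cpp_accumulate(NumericMatrix forces, IntegerVector idx,
                             NumericMatrix mat) {
  NumericMatrix out = clone(forces);
  for (int r = 0; r < idx.size(); ++r) {
    const int i = idx[r] - 1;
    out(i, 0) += mat(r, 0);
    out(i, 1) += mat(r, 1);
    out(i, 2) += mat(r, 2);
  }
  return out;
}

// Minimum-image distance histogram between two selections, for radial
// distribution functions. Returns bin counts of ordered pairs (a in A, b in
// B, a != b), bins of width dr on [0, rmax).
// [[Rcpp::export]]
IntegerVector cpp_dist_hist(NumericMatrix pos, IntegerVector sel_a,
                            IntegerVector sel_b, NumericVector box, double dr,
                            double rmax) {
  const bool periodic = box.size() == 3;
  double bx[3] = {0, 0, 0};
  if (periodic) { bx[0] = box[0]; bx[1] = box[1]; bx[2] = box[2]; }
  const int nbin = (int)std::ceil(rmax / dr);
  IntegerVector hist(nbin);
  for (int a = 0; a < sel_a.size(); ++a) {
    const int i = sel_a[a] - 1;
    for (int b = 0; b < sel_b.size(); ++b) {
      const int j = sel_b[b] - 1;
      if (i == j) continue;
      double d[3] = {pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                     pos(i, 2) - pos(j, 2)};
      min_image(d, bx, periodic);
      const double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (r < rmax) hist[(int)(r / dr)]++;
    }
  }
  return hist;
}
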