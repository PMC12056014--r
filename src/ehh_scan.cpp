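#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Haplotype-homozygosity machinery shared by the iHS and xpEHH scans.
// A haplotype group state is a vector of group ids, refined one site at a
// time; homozygosity is sum C(k_g,2) / C(n,2) over group multiplicities.

namespace {

struct GroupState {
  std::vector<int> gid;
  std::vector<int> remap, cnt, used;  // scratch; group ids stay < n so keys < 2n
  explicit GroupState(int n) : gid(n, 0), remap(2 * n, -1), cnt(n, 0) {
    used.reserve(n);
  }

  // refine by the alleles of `cols` at row `site`, return homozygosity
  double split(const IntegerMatrix& mat, int site, const std::vector<int>& cols) {
    const int n = (int)gid.size();
    int next = 0;
    used.clear();
    for (int i = 0; i < n; ++i) {
      const int key = 2 * gid[i] + mat(site, cols[i]);
      if (remap[key] < 0) {
        remap[key] = next;
        cnt[next] = 0;
        used.push_back(key);
        ++next;
      }
      gid[i] = remap[key];
      ++cnt[gid[i]];
    }
    for (int key : used) remap[key] = -1;
    double s = 0.0;
    for (int g = 0; g < next; ++g) s += 0.5 * (double)cnt[g] * (cnt[g] - 1.0);
    return s / (0.5 * (double)n * (n - 1.0));
  }
};

// walk status: 0 = EHH fell below cutoff (success), 1 = chromosome end,
// 2 = max extension exceeded, 3 = inter-SNP gap exceeded
struct WalkOut {
  double area;
  int status;
};

// One-directional EHH decay for a fixed carrier set (all identical at the
// core by construction), integrating trapezoids until EHH < cutoff.  The
// final trapezoid into the first below-cutoff point is included.
WalkOut walk_one(const IntegerMatrix& mat, const NumericVector& pos, int core,
                 const std::vector<int>& cols, double cutoff, double max_ext,
                 double max_gap, int dir) {
  const int nsite = mat.nrow();
  GroupState gs((int)cols.size());
  double area = 0.0, prev_ehh = 1.0, prev_dist = 0.0;
  int prev_site = core;
  for (int j = core + dir; j >= 0 && j < nsite; j += dir) {
    const double gap = std::fabs(pos[j] - pos[prev_site]);
    if (gap > max_gap) return {area, 3};
    const double dist = std::fabs(pos[j] - pos[core]);
    if (dist > max_ext) return {area, 2};
    const double ehh = gs.split(mat, j, cols);
    area += 0.5 * (prev_ehh + ehh) * (dist - prev_dist);
    if (ehh < cutoff) return {area, 0};
    prev_ehh = ehh;
    prev_dist = dist;
    prev_site = j;
  }
  return {area, 1};
}

int status_to_code(int s1, int s2) {
  // map worst walk status to a track NA-reason code
  int s = std::max(s1, s2);
  if (s == 1) return 2;  // chrom_end
  if (s == 2) return 3;  // max_extension
  if (s == 3) return 4;  // gap
  return 0;
}

}  // namespace

// [[Rcpp::export]]
List cpp_ihs_scan(IntegerMatrix mat, NumericVector pos, double cutoff,
                  double max_ext, double max_gap) {
  const int nsite = mat.nrow(), nhap = mat.ncol();
  NumericVector ihh_a(nsite, NA_REAL), ihh_d(nsite, NA_REAL);
  IntegerVector code(nsite, 0);
  for (int s = 0; s < nsite; ++s) {
    std::vector<int> anc, der;
    anc.reserve(nhap);
    der.reserve(nhap);
    for (int h = 0; h < nhap; ++h) {
      if (mat(s, h) == 1)
        der.push_back(h);
      else
        anc.push_back(h);
    }
    if (anc.size() < 2 || der.size() < 2) {
      code[s] = 1;  // few_carriers
      continue;
    }
    WalkOut al = walk_one(mat, pos, s, anc, cutoff, max_ext, max_gap, -1);
    WalkOut ar = walk_one(mat, pos, s, anc, cutoff, max_ext, max_gap, +1);
    WalkOut dl = walk_one(mat, pos, s, der, cutoff, max_ext, max_gap, -1);
    WalkOut dr = walk_one(mat, pos, s, der, cutoff, max_ext, max_gap, +1);
    if (al.status != 0 || ar.status != 0 || dl.status != 0 || dr.status != 0) {
      int worst = std::max(std::max(al.status, ar.status), std::max(dl.status, dr.status));
      code[s] = status_to_code(worst, worst);
      continue;
    }
    double ia = al.area + ar.area, id = dl.area + dr.area;
    if (ia <= 0.0 || id <= 0.0) {
      code[s] = 5;  // zero_ihh
      continue;
    }
    ihh_a[s] = ia;
    ihh_d[s] = id;
  }
  return List::create(_["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d, _["code"] = code);
}

namespace {

// One-directional pooled-boundary walk for xpEHH: pop A, pop B and the
// pooled sample are refined together; accumulation stops where the POOLED
// EHH first drops below cutoff, and both population integrals include the
// trapezoid into that point.  Grouping starts from the core-site alleles,
// so the pooled curve starts at the core-site homozygosity.
struct XpOut {
  double area_a, area_b;
  int status;
};

XpOut walk_xp(const IntegerMatrix& mat, const NumericVector& pos, int core,
              const std::vector<int>& colsA, const std::vector<int>& colsB,
              double cutoff, double max_ext, double max_gap, int dir) {
  const int nsite = mat.nrow();
  std::vector<int> colsP(colsA);
  colsP.insert(colsP.end(), colsB.begin(), colsB.end());
  GroupState ga((int)colsA.size()), gb((int)colsB.size()), gp((int)colsP.size());
  // initialise with the core site itself
  double ehh_a = ga.split(mat, core, colsA);
  double ehh_b = gb.split(mat, core, colsB);
  double ehh_p = gp.split(mat, core, colsP);
  double area_a = 0.0, area_b = 0.0, prev_dist = 0.0;
  if (ehh_p < cutoff) return {0.0, 0.0, 0};
  int prev_site = core;
  for (int j = core + dir; j >= 0 && j < nsite; j += dir) {
    const double gap = std::fabs(pos[j] - pos[prev_site]);
    if (gap > max_gap) return {area_a, area_b, 3};
    const double dist = std::fabs(pos[j] - pos[core]);
    if (dist > max_ext) return {area_a, area_b, 2};
    const double na = ga.split(mat, j, colsA);
    const double nb = gb.split(mat, j, colsB);
    const double np = gp.split(mat, j, colsP);
    area_a += 0.5 * (ehh_a + na) * (dist - prev_dist);
    area_b += 0.5 * (ehh_b + nb) * (dist - prev_dist);
    if (np < cutoff) return {area_a, area_b, 0};
    ehh_a = na;
    ehh_b = nb;
    ehh_p = np;
    prev_dist = dist;
    prev_site = j;
  }
  return {area_a, area_b, 1};
}

}  // namespace

// [[Rcpp::export]]
List cpp_xpehh_scan(IntegerMatrix mat, NumericVector pos, IntegerVector colsA,
                    IntegerVector colsB, double cutoff, double max_ext,
                    double max_gap) {
  const int nsite = mat.nrow();
  std::vector<int> ca(colsA.begin(), colsA.end()), cb(colsB.begin(), colsB.end());
  NumericVector ihh_a(nsite, NA_REAL), ihh_b(nsite, NA_REAL);
  IntegerVector code(nsite, 0);
  for (int s = 0; s < nsite; ++s) {
    XpOut l = walk_xp(mat, pos, s, ca, cb, cutoff, max_ext, max_gap, -1);
    XpOut r = walk_xp(mat, pos, s, ca, cb, cutoff, max_ext, max_gap, +1);
    if (l.status != 0 || r.status != 0) {
      int worst = std::max(l.status, r.status);
      code[s] = status_to_code(worst, worst);
      continue;
    }
    double ia = l.area_a + r.area_a, ib = l.area_b + r.area_b;
    if (ia <= 0.0 || ib <= 0.0) {
      code[s] = 5;
      continue;
    }
    ihh_a[s] = ia;
    ihh_b[s] = ib;
  }
  return List::create(_["ihh_a"] = ihh_a, _["ihh_b"] = ihh_b, _["code"] = code);
}

// EHH decay curve for a fixed carrier set from one core, both directions
// reported as distance/EHH point lists (distance 0 has EHH 1 by
// construction).  Used for plotting and for cross-checking the scans.
// [[Rcpp::export]]
List cpp_ehh_curve(IntegerMatrix mat, NumericVector pos, int core0,
                   IntegerVector carriers0, double cutoff, double max_ext,
                   double max_gap, int dir) {
  const int nsite = mat.nrow();
  std::vector<int> cols(carriers0.begin(), carriers0.end());
  GroupState gs((int)cols.size());
  std::vector<double> dists{0.0}, ehhs{1.0};
  int status = 1, prev_site = core0;
  for (int j = core0 + dir; j >= 0 && j < nsite; j += dir) {
    const double gap = std::fabs(pos[j] - pos[prev_site]);
    if (gap > max_gap) {
      status = 3;
      break;
    }
    const double dist = std::fabs(pos[j] - pos[core0]);
    if (dist > max_ext) {
      status = 2;
      break;
    }
    const double ehh = gs.split(mat, j, cols);
    dists.push_back(dist);
    ehhs.push_back(ehh);
    if (ehh < cutoff) {
      status = 0;
      break;
    }
    prev_site = j;
  }
  return List::create(_["distance"] = wrap(dists), _["ehh"] = wrap(ehhs),
                      _["status"] = status);
}
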