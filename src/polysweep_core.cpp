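#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Meiosis of one chromosome: recombinant gamete from two parental strands.
// Crossover count ~ Poisson(lambda), cut points uniform on the L-1 inter-locus
// boundaries, random start phase, no interference. Mutation is binomial
// thinning: the number of flips is Binomial(L, mu), positions distinct.
// All randomness goes through R's RNG so set.seed() controls everything.
static void meiosis(const int* h0, const int* h1, int L,
                    double lambda, double mu, int* out) {
  int nxo = (int) R::rpois(lambda);
  int strand = (unif_rand() < 0.5) ? 0 : 1;
  if (nxo <= 0 || L < 2) {
    const int* src = strand ? h1 : h0;
    std::copy(src, src + L, out);
  } else {
    std::vector<int> cuts(nxo);
    for (int i = 0; i < nxo; ++i)
      cuts[i] = 1 + (int) std::floor(unif_rand() * (L - 1));
    std::sort(cuts.begin(), cuts.end());
    int pos = 0;
    for (int i = 0; i <= nxo; ++i) {
      int end = (i == nxo) ? L : cuts[i];
      if (end > pos) {
        const int* src = strand ? h1 : h0;
        std::copy(src + pos, src + end, out + pos);
        pos = end;
      }
      strand = 1 - strand;
    }
  }
  if (mu > 0) {
    int m = (int) R::rbinom((double) L, mu);
    if (m > 0) {
      std::vector<int> hit;
      hit.reserve(m);
      while ((int) hit.size() < m) {
        int p = (int) std::floor(unif_rand() * L);
        if (p >= L) p = L - 1;
        if (std::find(hit.begin(), hit.end(), p) == hit.end())
          hit.push_back(p);
      }
      for (int p : hit) out[p] = 1 - out[p];
    }
  }
}

// One round of reproduction. mats: one L x (2*n_parents) integer matrix per
// chromosome (columns 2i, 2i+1 are the two haplotypes of parent i; the
// parent pool may concatenate two populations for migrant matings).
// par1/par2: 0-based parent index per offspring for gamete 1 and gamete 2.
// Returns L x (2*n_off) matrices in the same layout.
// [[Rcpp::export]]
List cpp_make_offspring(List mats, IntegerVector par1, IntegerVector par2,
                        double lambda, double mu) {
  int n_off = par1.size();
  int n_chr = mats.size();
  List out(n_chr);
  for (int c = 0; c < n_chr; ++c) {
    IntegerMatrix M = mats[c];
    int L = M.nrow();
    IntegerMatrix O(L, 2 * n_off);
    for (int i = 0; i < n_off; ++i) {
      int pa = par1[i], pb = par2[i];
      meiosis(&M(0, 2 * pa), &M(0, 2 * pa + 1), L, lambda, mu, &O(0, 2 * i));
      meiosis(&M(0, 2 * pb), &M(0, 2 * pb + 1), L, lambda, mu, &O(0, 2 * i + 1));
    }
    out[c] = O;
  }
  out.attr("names") = mats.attr("names");
  return out;
}

// Haplotype-homozygosity pair counts around a core site, for the group
// refinement underlying EHH (Voight et al. style) and nSL. haps is an
// n x L matrix (rows = haplotypes, columns = sites). carriers are 0-based
// row indices sharing one core allele. Returns, for each direction, the
// number of carrier pairs identical on the closed interval from the core out
// to each successive site (element 1 = the core site itself). NA alleles
// break identity (each NA haplotype becomes its own group).
static std::vector<double> refine_counts(const IntegerMatrix& haps,
                                         const std::vector<int>& rows,
                                         int core0, int step) {
  int nc = rows.size();
  int L = haps.ncol();
  std::vector<double> out;
  std::vector<int> group(nc, 0);
  int ngroups = 1;  // retained for clarity of the group-code domain
  (void) ngroups;
  int s = core0;
  long long na_code = 0;
  while (s >= 0 && s < L) {
    std::unordered_map<long long, int> remap;
    std::vector<int> newgroup(nc);
    int ng = 0;
    for (int i = 0; i < nc; ++i) {
      int a = haps(rows[i], s);
      long long code;
      if (a == NA_INTEGER) {
        code = 2LL * (long long) nc + (++na_code);  // unique singleton
      } else {
        code = (long long) group[i] * 2LL + a;
      }
      auto it = remap.find(code);
      if (it == remap.end()) {
        remap[code] = ng;
        newgroup[i] = ng++;
      } else {
        newgroup[i] = it->second;
      }
    }
    group.swap(newgroup);
    ngroups = ng;
    std::vector<int> sz(ng, 0);
    for (int i = 0; i < nc; ++i) sz[group[i]]++;
    double hh = 0;
    for (int g = 0; g < ng; ++g) hh += 0.5 * (double) sz[g] * (sz[g] - 1);
    out.push_back(hh);
    if (hh == 0) break;  // all singletons: identity cannot recover
    s += step;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_hh_counts(IntegerMatrix haps, int core0, IntegerVector carriers0) {
  std::vector<int> rows(carriers0.begin(), carriers0.end());
  std::vector<double> right = refine_counts(haps, rows, core0, +1);
  std::vector<double> left = refine_counts(haps, rows, core0, -1);
  return List::create(_["right"] = NumericVector(right.begin(), right.end()),
                      _["left"] = NumericVector(left.begin(), left.end()));
}

// Combined iHS/nSL kernel. For every core site above the frequency floor,
// the group-refinement walk is done once per allele class and direction,
// accumulating simultaneously (a) the trapezoid integral of EHH over cM up
// to the truncation cutoff (iHS; NA when a gap exceeds max_gap_cm or the
// chromosome edge is reached with EHH still above the cutoff) and (b) the
// summed pair-identity counts over all sites (nSL).
// Group relabeling uses flat arrays, not hashing: codes are old_group * 2 +
// allele; NA alleles become fresh singleton groups.
struct WalkResult {
  double ihh;     // trapezoid integral, NA_REAL on edge/gap failure
  double slsum;   // sum of HH counts over sites walked (incl. core)
};

static WalkResult walk_side(const int* col_ptr, const IntegerMatrix& haps,
                            const std::vector<int>& rows, int core0, int step,
                            const NumericVector& pos, double np,
                            double cutoff, double max_gap) {
  (void) col_ptr;
  int nc = rows.size();
  int L = haps.ncol();
  std::vector<int> group(nc, 0);
  std::vector<int> remap;
  int ng = 1;
  WalkResult res;
  res.slsum = 0.0;
  res.ihh = NA_REAL;
  double ihh_acc = 0.0;
  bool ihh_open = true;   // still integrating
  bool ihh_fail = false;  // gap failure
  double prev_ehh = 1.0;
  double prev_pos = pos[core0];
  int s = core0;
  while (s >= 0 && s < L) {
    // refine groups by the allele at site s
    remap.assign(2 * ng, -1);
    int ng_new = 0;
    const int* col = &haps(0, s);
    for (int i = 0; i < nc; ++i) {
      int a = col[rows[i]];
      if (a == NA_INTEGER) {
        group[i] = ng_new++;            // fresh singleton
        if ((int) remap.size() < 2 * ng_new) remap.resize(2 * ng_new, -1);
        continue;
      }
      int code = group[i] * 2 + a;
      if (remap[code] < 0) remap[code] = ng_new++;
      group[i] = remap[code];
    }
    ng = ng_new > 0 ? ng_new : 1;
    // pair counts
    std::vector<int> sz(ng, 0);
    for (int i = 0; i < nc; ++i) sz[group[i]]++;
    double hh = 0.0;
    for (int g = 0; g < ng; ++g) hh += 0.5 * (double) sz[g] * (sz[g] - 1);
    res.slsum += hh;
    double e = hh / np;
    if (s != core0 && ihh_open && !ihh_fail) {
      double gap = std::abs(pos[s] - prev_pos);
      if (gap > max_gap) {
        ihh_fail = true;
      } else {
        ihh_acc += 0.5 * (e + prev_ehh) * gap;
        if (e < cutoff) {
          res.ihh = ihh_acc;
          ihh_open = false;
        }
      }
    } else if (s == core0 && e < cutoff) {
      // no extension needed: EHH already below cutoff at distance zero
      res.ihh = 0.0;
      ihh_open = false;
    }
    prev_ehh = e;
    prev_pos = pos[s];
    if (hh == 0.0) {
      // all singletons: nothing further can contribute to either statistic
      if (ihh_open && !ihh_fail) { res.ihh = ihh_acc; ihh_open = false; }
      break;
    }
    s += step;
  }
  if (ihh_fail || ihh_open) {
    // gap failure, or ran off the chromosome with EHH >= cutoff
    if (ihh_fail || prev_ehh >= cutoff) res.ihh = NA_REAL;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_haplo_scan(IntegerMatrix haps, NumericVector pos_cm,
                    double maf_floor, double cutoff, double max_gap) {
  int n = haps.nrow(), L = haps.ncol();
  NumericVector ihh0(L, NA_REAL), ihh1(L, NA_REAL);
  NumericVector sl0(L, NA_REAL), sl1(L, NA_REAL);
  NumericVector freq1(L, NA_REAL);
  IntegerVector nn(L, 0);
  std::vector<int> rows0, rows1;
  for (int j = 0; j < L; ++j) {
    rows0.clear();
    rows1.clear();
    for (int r = 0; r < n; ++r) {
      int a = haps(r, j);
      if (a == 0) rows0.push_back(r);
      else if (a == 1) rows1.push_back(r);
    }
    int m = rows0.size() + rows1.size();
    nn[j] = m;
    if (m == 0) continue;
    double f1 = (double) rows1.size() / m;
    freq1[j] = f1;
    double maf = std::min(f1, 1.0 - f1);
    if (maf < maf_floor) continue;
    for (int al = 0; al <= 1; ++al) {
      const std::vector<int>& rows = al ? rows1 : rows0;
      if ((int) rows.size() < 2) continue;
      double np = 0.5 * (double) rows.size() * (rows.size() - 1);
      WalkResult right = walk_side(nullptr, haps, rows, j, +1, pos_cm, np,
                                   cutoff, max_gap);
      WalkResult left = walk_side(nullptr, haps, rows, j, -1, pos_cm, np,
                                  cutoff, max_gap);
      double ihh = (ISNA(right.ihh) || ISNA(left.ihh))
        ? NA_REAL : right.ihh + left.ihh;
      double sl = (right.slsum + left.slsum - np) / np;  // core counted once
      if (al) { ihh1[j] = ihh; sl1[j] = sl; }
      else { ihh0[j] = ihh; sl0[j] = sl; }
    }
  }
  return List::create(_["ihh0"] = ihh0, _["ihh1"] = ihh1,
                      _["sl0"] = sl0, _["sl1"] = sl1,
                      _["freq1"] = freq1, _["n"] = nn);
}

// Hill-Robertson r^2 between two 0/1 haplotype vectors with pairwise-complete
// filtering. Returns NA when either locus is monomorphic after filtering.
static double r2_one(const int* x, const int* y, int n) {
  int m = 0, sx = 0, sy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_INTEGER || y[i] == NA_INTEGER) continue;
    ++m;
    sx += x[i];
    sy += y[i];
    sxy += x[i] * y[i];
  }
  if (m < 2) return NA_REAL;
  double pa = (double) sx / m, pb = (double) sy / m;
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return NA_REAL;
  double D = (double) sxy / m - pa * pb;
  return D * D / (pa * (1 - pa) * pb * (1 - pb));
}

// r^2 for an explicit list of locus pairs. haps: n x L (rows = haplotypes);
// i, j: 0-based column indices.
// [[Rcpp::export]]
NumericVector cpp_r2_pairs(IntegerMatrix haps, IntegerVector i, IntegerVector j) {
  int n = haps.nrow();
  int np = i.size();
  NumericVector out(np);
  // column extraction: copy columns once into a transposed buffer is wasteful
  // for scattered pairs; extract per pair instead (n is small).
  std::vector<int> xi(n), xj(n);
  for (int k = 0; k < np; ++k) {
    int ci = i[k], cj = j[k];
    for (int r = 0; r < n; ++r) {
      xi[r] = haps(r, ci);
      xj[r] = haps(r, cj);
    }
    out[k] = r2_one(xi.data(), xj.data(), n);
  }
  return out;
}

// Full r^2 matrix between the columns of X and the columns of Y
// (same haplotype rows).
// [[Rcpp::export]]
NumericMatrix cpp_r2_cross(IntegerMatrix X, IntegerMatrix Y) {
  int n = X.nrow(), p = X.ncol(), q = Y.ncol();
  NumericMatrix out(p, q);
  std::vector<int> xi(n), yj(n);
  for (int a = 0; a < p; ++a) {
    for (int r = 0; r < n; ++r) xi[r] = X(r, a);
    for (int b = 0; b < q; ++b) {
      for (int r = 0; r < n; ++r) yj[r] = Y(r, b);
      out(a, b) = r2_one(xi.data(), yj.data(), n);
    }
  }
  return out;
}
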