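#include <Rcpp.h>
using namespace Rcpp;

// Correspondence of edge pixels by projection onto the facing edge's
// polyline.  Pixel i of A corresponds to a pixel of B iff the foot of its
// projection onto B's chain is interior (a pixel "overhanging" beyond the
// ends of the facing edge has no correspondent), the distance is <= tau,
// and the displacement crosses the cut: |cos(angle(displacement, edge
// normal))| >= min_cos.  Displacements shorter than 3 px are exempt from
// the cone test -- at abutting edges their direction is contour-jitter
// noise.  Partners are claimed injectively in chain order so the matching
// cannot collapse many-to-one.  (nx, ny) is the unit normal of A's edge
// in the common frame; min_cos <= 0 disables the cone test.  Returns
// 1-based match indices into B (0 = unmatched).
// [[Rcpp::export]]
IntegerVector cpp_proj_match(NumericVector ax, NumericVector ay,
                             NumericVector bx, NumericVector by,
                             double tau, double nx = 0, double ny = 0,
                             double min_cos = -1) {
  const int na = ax.size(), nb = bx.size();
  IntegerVector match(na, 0);
  if (nb == 0) return match;
  const bool cone = min_cos > 0;
  const double tau2 = tau * tau;
  std::vector<char> used(nb, 0);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf, bt = 0, btraw = 0;
    int bj = -1;
    if (nb == 1) {
      const double dx = ax[i] - bx[0], dy = ay[i] - by[0];
      best = dx * dx + dy * dy; bj = 0; bt = 0;
    } else {
      for (int j = 0; j + 1 < nb; ++j) {
        const double ex = bx[j + 1] - bx[j], ey = by[j + 1] - by[j];
        const double len2 = ex * ex + ey * ey;
        double traw = 0, t = 0;
        if (len2 > 0) {
          traw = ((ax[i] - bx[j]) * ex + (ay[i] - by[j]) * ey) / len2;
          t = traw < 0 ? 0 : (traw > 1 ? 1 : traw);
        }
        const double fx = bx[j] + t * ex, fy = by[j] + t * ey;
        const double dx = ax[i] - fx, dy = ay[i] - fy;
        const double d2 = dx * dx + dy * dy;
        if (d2 < best) { best = d2; bj = j; bt = t; btraw = traw; }
      }
    }
    if (best > tau2) continue;
    // overhang: the projection falls past a terminal endpoint of the
    // chain by more than half a pixel of chain order
    if (nb > 1 && ((bj == 0 && btraw < -0.5) ||
                   (bj == nb - 2 && btraw > 1.5)))
      continue;
    if (cone && best > 9.0) {
      const double ex = (nb > 1) ? bx[bj + 1] - bx[bj] : 0;
      const double ey = (nb > 1) ? by[bj + 1] - by[bj] : 0;
      const double dx = ax[i] - (bx[bj] + bt * ex);
      const double dy = ay[i] - (by[bj] + bt * ey);
      const double dot = dx * nx + dy * ny;
      if (dot * dot < min_cos * min_cos * best) continue;
    }
    int partner = (nb == 1) ? 0 : (bt >= 0.5 ? bj + 1 : bj);
    if (used[partner]) {
      // look for a free partner within 2 px of chain order, so slight
      // spacing mismatches between the chains do not shed matches
      int found = -1;
      for (int off = 1; off <= 2 && found < 0; ++off) {
        if (partner + off < nb && !used[partner + off]) found = partner + off;
        else if (partner - off >= 0 && !used[partner - off])
          found = partner - off;
      }
      if (found < 0) continue;
      partner = found;
    }
    used[partner] = 1;
    match[i] = partner + 1;
  }
  return match;
}

// Pair dissimilarity for one adjacency: projection correspondence on the
// transformed edge coordinates, then D = (sum L1(Va_i, Vb_j) + m * phi)
// / (n + m), where n counts corresponding pairs and m counts
// non-corresponding edge pixels of both edges.  Va/Vb hold one histogram
// (or single intensity) per column.  extra_m counts edge pixels already
// discarded (empty patches); they are maximally dissimilar by convention.
// [[Rcpp::export]]
List cpp_pair_dissim(NumericVector ax, NumericVector ay,
                     NumericVector bx, NumericVector by,
                     NumericMatrix Va, NumericMatrix Vb,
                     double tau, double phi, int extra_m,
                     double nx = 0, double ny = 0, double min_cos = -1) {
  IntegerVector match = cpp_proj_match(ax, ay, bx, by, tau, nx, ny, min_cos);
  const int na = ax.size(), nb = bx.size(), nbin = Va.nrow();
  int n = 0;
  double sumd = 0.0;
  for (int i = 0; i < na; ++i) {
    if (match[i] == 0) continue;
    const int j = match[i] - 1;
    double d = 0.0;
    for (int k = 0; k < nbin; ++k) d += std::abs(Va(k, i) - Vb(k, j));
    sumd += d;
    ++n;
  }
  const int m = (na - n) + (nb - n) + extra_m;
  double dpair = (n + m > 0) ? (sumd + m * phi) / double(n + m) : phi;
  return List::create(_["n"] = n, _["m"] = m, _["sum_matched"] = sumd,
                      _["d_pair"] = dpair);
}

// Normalized intensity histograms of square patches centred on edge pixels.
// img/mask are Y x X matrices (rows = y).  Window is p x p (p odd) clipped
// at the image border; only tissue pixels contribute.  Columns with no
// tissue pixel in the window are flagged empty and left all-zero.
// [[Rcpp::export]]
List cpp_patch_hist(NumericMatrix img, IntegerMatrix mask,
                    IntegerVector cx, IntegerVector cy, int p, int b) {
  const int Y = img.nrow(), X = img.ncol(), L = cx.size(), r = (p - 1) / 2;
  NumericMatrix V(b, L);
  LogicalVector empty(L);
  for (int k = 0; k < L; ++k) {
    const int x0 = std::max(0, cx[k] - 1 - r), x1 = std::min(X - 1, cx[k] - 1 + r);
    const int y0 = std::max(0, cy[k] - 1 - r), y1 = std::min(Y - 1, cy[k] - 1 + r);
    int cnt = 0;
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y) {
        if (!mask(y, x)) continue;
        int bin = int(img(y, x) * b);       // uniform bin edges on [0, 1]
        if (bin >= b) bin = b - 1;
        if (bin < 0) bin = 0;
        V(bin, k) += 1.0;
        ++cnt;
      }
    if (cnt == 0) empty[k] = true;
    else for (int i = 0; i < b; ++i) V(i, k) /= cnt;
  }
  return List::create(_["V"] = V, _["empty"] = empty);
}

// Symmetric Hausdorff distance between two point chains:
// max(sup_a inf_b d, sup_b inf_a d).
// [[Rcpp::export]]
double cpp_hausdorff(NumericVector ax, NumericVector ay,
                     NumericVector bx, NumericVector by) {
  const int na = ax.size(), nb = bx.size();
  double h = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    if (best > h) h = best;
  }
  for (int j = 0; j < nb; ++j) {
    double best = R_PosInf;
    for (int i = 0; i < na; ++i) {
      const double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    if (best > h) h = best;
  }
  return std::sqrt(h);
}
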