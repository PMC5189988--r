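#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent accessible surface area.
// xyz: n x 3, radii: n (vdW), probe radius in Angstrom, n_points per sphere
// (quasi-uniform Fibonacci spiral). Returns per-atom SASA in Angstrom^2.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  int n = xyz.nrow();
  // Fibonacci sphere unit points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    px[k] = r * std::cos(th); py[k] = r * std::sin(th); pz[k] = z;
  }
  NumericVector out(n);
  std::vector<int> neigh;
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    neigh.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = xyz(j,0)-xyz(i,0), dy = xyz(j,1)-xyz(i,1), dz = xyz(j,2)-xyz(i,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      double rr = ri + rj;
      if (d2 < rr * rr) neigh.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xyz(i,0) + ri * px[k];
      double qy = xyz(i,1) + ri * py[k];
      double qz = xyz(i,2) + ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < neigh.size(); ++m) {
        int j = neigh[m];
        double rj = radii[j] + probe;
        double dx = qx - xyz(j,0), dy = qy - xyz(j,1), dz = qz - xyz(j,2);
        double d2 = dx*dx + dy*dy + dz*dz, r2 = rj * rj;
        // boundary points (coincident spheres) are owned by the
        // lower-index atom so shared surface is counted exactly once
        if (d2 < r2 * (1.0 - 1e-9) ||
            (d2 <= r2 * (1.0 + 1e-9) && j < i)) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * ((double)acc / n_points);
  }
  return out;
}

// Debye-formula scattering curve: I(q) = sum_ij f_i f_j sinc(q r_ij).
// [[Rcpp::export(name = ".debye_cpp")]]
NumericVector debye_cpp(NumericMatrix xyz, NumericVector f, NumericVector q) {
  int n = xyz.nrow(), nq = q.size();
  NumericVector I(nq);
  double f2 = 0.0;
  for (int i = 0; i < n; ++i) f2 += f[i] * f[i];
  for (int k = 0; k < nq; ++k) I[k] = f2;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i,0)-xyz(j,0), dy = xyz(i,1)-xyz(j,1), dz = xyz(i,2)-xyz(j,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double ff = 2.0 * f[i] * f[j];
      for (int k = 0; k < nq; ++k) {
        double x = q[k] * r;
        I[k] += ff * (x < 1e-9 ? 1.0 : std::sin(x) / x);
      }
    }
  }
  return I;
}

// Weighted pairwise-distance histogram (P(r)).  Returns counts per bin of
// width `bw` (bin b covers [b*bw, (b+1)*bw)) and the exact maximum distance.
// [[Rcpp::export(name = ".pair_hist_cpp")]]
List pair_hist_cpp(NumericMatrix xyz, NumericVector w, double bw) {
  int n = xyz.nrow();
  double dmax = 0.0;
  std::vector<double> counts;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i,0)-xyz(j,0), dy = xyz(i,1)-xyz(j,1), dz = xyz(i,2)-xyz(j,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r > dmax) dmax = r;
      size_t b = (size_t)(r / bw);
      if (counts.size() <= b) counts.resize(b + 1, 0.0);
      counts[b] += w[i] * w[j];
    }
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["dmax"] = dmax);
}

// Sliding-window running cross-correlation statistics for all residue pairs.
// X, Y, Z are F x R coordinate matrices of the (fitted) representative atoms.
// For each pair the correlation C_ij = <dri.drj>/sqrt(<|dri|^2><|drj|^2>) is
// computed inside every length-W window with window-local means; returns the
// per-pair mean and standard deviation over window positions.
// [[Rcpp::export(name = ".rcc_stats_cpp")]]
List rcc_stats_cpp(NumericMatrix X, NumericMatrix Y, NumericMatrix Z, int W) {
  int F = X.nrow(), R = X.ncol();
  if (W > F) stop("window larger than trajectory");
  int nw = F - W + 1;
  std::vector<double> S(R * R, 0.0);          // sum over window of dot(ri, rj)
  std::vector<double> mx(R), my(R), mz(R);    // window sums per coordinate
  NumericMatrix mean_rcc(R, R), sd_rcc(R, R);
  std::vector<double> acc(R * R, 0.0), acc2(R * R, 0.0);
  auto add_frame = [&](int t, double sgn) {
    for (int i = 0; i < R; ++i) {
      double xi = X(t,i), yi = Y(t,i), zi = Z(t,i);
      mx[i] += sgn * xi; my[i] += sgn * yi; mz[i] += sgn * zi;
      double* Si = &S[(size_t)i * R];
      for (int j = i; j < R; ++j)
        Si[j] += sgn * (xi * X(t,j) + yi * Y(t,j) + zi * Z(t,j));
    }
  };
  for (int t = 0; t < W; ++t) add_frame(t, 1.0);
  for (int w = 0; ; ++w) {
    // correlations for current window [w, w+W-1]
    for (int i = 0; i < R; ++i) {
      double vi = S[(size_t)i * R + i] / W -
        (mx[i]*mx[i] + my[i]*my[i] + mz[i]*mz[i]) / ((double)W * W);
      for (int j = i; j < R; ++j) {
        double vj = S[(size_t)j * R + j] / W -
          (mx[j]*mx[j] + my[j]*my[j] + mz[j]*mz[j]) / ((double)W * W);
        double cij = S[(size_t)i * R + j] / W -
          (mx[i]*mx[j] + my[i]*my[j] + mz[i]*mz[j]) / ((double)W * W);
        double c = (vi > 1e-300 && vj > 1e-300) ? cij / std::sqrt(vi * vj) : 0.0;
        acc[(size_t)i * R + j] += c;
        acc2[(size_t)i * R + j] += c * c;
      }
    }
    if (w == nw - 1) break;
    add_frame(w, -1.0);
    add_frame(w + W, 1.0);
  }
  for (int i = 0; i < R; ++i)
    for (int j = i; j < R; ++j) {
      double m = acc[(size_t)i * R + j] / nw;
      double v = acc2[(size_t)i * R + j] / nw - m * m;
      double s = std::sqrt(std::max(v, 0.0));
      mean_rcc(i,j) = mean_rcc(j,i) = m;
      sd_rcc(i,j) = sd_rcc(j,i) = (i == j ? 0.0 : s);
    }
  return List::create(_["mean"] = mean_rcc, _["sigma"] = sd_rcc);
}

// Fraction of frames in which the minimal heavy-atom distance between two
// residues is <= dcut.  resAtoms: list of 1-based atom index vectors per
// residue; pairs: P x 2 matrix of 1-based residue indices into resAtoms.
// X, Y, Z: F x A coordinate matrices.
// [[Rcpp::export(name = ".contact_fraction_cpp")]]
NumericVector contact_fraction_cpp(NumericMatrix X, NumericMatrix Y,
                                   NumericMatrix Z, List resAtoms,
                                   IntegerMatrix pairs, double dcut) {
  int F = X.nrow(), P = pairs.nrow();
  double d2cut = dcut * dcut;
  NumericVector frac(P);
  for (int p = 0; p < P; ++p) {
    IntegerVector ai = resAtoms[pairs(p,0) - 1];
    IntegerVector aj = resAtoms[pairs(p,1) - 1];
    int hits = 0;
    for (int t = 0; t < F; ++t) {
      bool contact = false;
      for (int u = 0; u < ai.size() && !contact; ++u) {
        int a = ai[u] - 1;
        for (int v = 0; v < aj.size(); ++v) {
          int b = aj[v] - 1;
          double dx = X(t,a)-X(t,b), dy = Y(t,a)-Y(t,b), dz = Z(t,a)-Z(t,b);
          if (dx*dx + dy*dy + dz*dz <= d2cut) { contact = true; break; }
        }
      }
      if (contact) ++hits;
    }
    frac[p] = (double)hits / F;
  }
  return frac;
}

// Standard deviation over frames of every pairwise distance between the R
// representative atoms.  X, Y, Z: F x R.
// [[Rcpp::export(name = ".distance_sd_cpp")]]
NumericMatrix distance_sd_cpp(NumericMatrix X, NumericMatrix Y, NumericMatrix Z) {
  int F = X.nrow(), R = X.ncol();
  NumericMatrix out(R, R);
  for (int i = 0; i < R; ++i)
    for (int j = i + 1; j < R; ++j) {
      // two-pass variance: immune to cancellation for rigid geometries
      double s = 0.0;
      std::vector<double> dist(F);
      for (int t = 0; t < F; ++t) {
        double dx = X(t,i)-X(t,j), dy = Y(t,i)-Y(t,j), dz = Z(t,i)-Z(t,j);
        dist[t] = std::sqrt(dx*dx + dy*dy + dz*dz);
        s += dist[t];
      }
      double m = s / F, v = 0.0;
      for (int t = 0; t < F; ++t) v += (dist[t] - m) * (dist[t] - m);
      out(i,j) = out(j,i) = std::sqrt(v / F);
    }
  return out;
}
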