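#include <Rcpp.h>
#include <array>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Axis-wise running sums: the O(N) primitive behind box filtering.
// Windows are truncated at the borders; the caller divides by true counts.
// ---------------------------------------------------------------------------

static void box_sum_axis(std::vector<double> &a, int d0, int d1, int d2,
                         int axis, int r) {
  int n = (axis == 0) ? d0 : (axis == 1) ? d1 : d2;
  if (n == 1 || r <= 0) return;
  long stride = (axis == 0) ? 1L : (axis == 1) ? (long)d0 : (long)d0 * d1;
  std::vector<double> pre(n + 1), line(n);
  long nlines0, nlines1;
  if (axis == 0)      { nlines0 = d1; nlines1 = d2; }
  else if (axis == 1) { nlines0 = d0; nlines1 = d2; }
  else                { nlines0 = d0; nlines1 = d1; }
  for (long j = 0; j < nlines1; ++j) {
    for (long i = 0; i < nlines0; ++i) {
      long base;
      if (axis == 0)      base = i * (long)d0 + j * (long)d0 * d1; // i over d1, j over d2
      else if (axis == 1) base = i + j * (long)d0 * d1;
      else                base = i + j * (long)d0;
      pre[0] = 0.0;
      for (int k = 0; k < n; ++k) {
        line[k] = a[base + (long)k * stride];
        pre[k + 1] = pre[k] + line[k];
      }
      for (int k = 0; k < n; ++k) {
        int lo = k - r; if (lo < 0) lo = 0;
        int hi = k + r; if (hi > n - 1) hi = n - 1;
        a[base + (long)k * stride] = pre[hi + 1] - pre[lo];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_box_sum(NumericVector arr, IntegerVector dims, int r) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  std::vector<double> a(arr.begin(), arr.end());
  box_sum_axis(a, d0, d1, d2, 0, r);
  box_sum_axis(a, d0, d1, d2, 1, r);
  box_sum_axis(a, d0, d1, d2, 2, r);
  NumericVector out(a.begin(), a.end());
  return out;
}

// ---------------------------------------------------------------------------
// Separable 1-D convolution along all three axes with edge replication.
// kernel must have odd length and sum to 1 for a mean-preserving smoother.
// ---------------------------------------------------------------------------

static void conv_axis(std::vector<double> &a, int d0, int d1, int d2,
                      int axis, const std::vector<double> &k) {
  int n = (axis == 0) ? d0 : (axis == 1) ? d1 : d2;
  int r = ((int)k.size() - 1) / 2;
  long stride = (axis == 0) ? 1L : (axis == 1) ? (long)d0 : (long)d0 * d1;
  std::vector<double> line(n), out(n);
  long nlines0, nlines1;
  if (axis == 0)      { nlines0 = d1; nlines1 = d2; }
  else if (axis == 1) { nlines0 = d0; nlines1 = d2; }
  else                { nlines0 = d0; nlines1 = d1; }
  for (long j = 0; j < nlines1; ++j) {
    for (long i = 0; i < nlines0; ++i) {
      long base;
      if (axis == 0)      base = i * (long)d0 + j * (long)d0 * d1;
      else if (axis == 1) base = i + j * (long)d0 * d1;
      else                base = i + j * (long)d0;
      for (int t = 0; t < n; ++t) line[t] = a[base + (long)t * stride];
      for (int t = 0; t < n; ++t) {
        double s = 0.0;
        for (int q = -r; q <= r; ++q) {
          int idx = t + q;
          if (idx < 0) idx = 0;
          if (idx > n - 1) idx = n - 1;
          s += k[q + r] * line[idx];
        }
        out[t] = s;
      }
      for (int t = 0; t < n; ++t) a[base + (long)t * stride] = out[t];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sep_convolve(NumericVector arr, IntegerVector dims,
                               NumericVector kernel) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  std::vector<double> a(arr.begin(), arr.end());
  std::vector<double> k(kernel.begin(), kernel.end());
  conv_axis(a, d0, d1, d2, 0, k);
  conv_axis(a, d0, d1, d2, 1, k);
  conv_axis(a, d0, d1, d2, 2, k);
  return NumericVector(a.begin(), a.end());
}

// ---------------------------------------------------------------------------
// Trilinear sampling at arbitrary continuous 0-based voxel coordinates,
// with edge clamping for out-of-bounds positions.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericVector xs, NumericVector ys,
                            NumericVector zs) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  R_xlen_t n = xs.size();
  NumericVector out(n);
  const double *v = vol.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = xs[p], y = ys[p], z = zs[p];
    if (x < 0) x = 0; if (x > d0 - 1) x = d0 - 1;
    if (y < 0) y = 0; if (y > d1 - 1) y = d1 - 1;
    if (z < 0) z = 0; if (z > d2 - 1) z = d2 - 1;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > d0 - 2) i0 = d0 - 2; if (i0 < 0) i0 = 0;
    if (j0 > d1 - 2) j0 = d1 - 2; if (j0 < 0) j0 = 0;
    if (k0 > d2 - 2) k0 = d2 - 2; if (k0 < 0) k0 = 0;
    int i1 = i0 + 1 < d0 ? i0 + 1 : i0;
    int j1 = j0 + 1 < d1 ? j0 + 1 : j0;
    int k1 = k0 + 1 < d2 ? k0 + 1 : k0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    long s1 = d0, s2 = (long)d0 * d1;
    double c000 = v[i0 + j0 * s1 + k0 * s2], c100 = v[i1 + j0 * s1 + k0 * s2];
    double c010 = v[i0 + j1 * s1 + k0 * s2], c110 = v[i1 + j1 * s1 + k0 * s2];
    double c001 = v[i0 + j0 * s1 + k1 * s2], c101 = v[i1 + j0 * s1 + k1 * s2];
    double c011 = v[i0 + j1 * s1 + k1 * s2], c111 = v[i1 + j1 * s1 + k1 * s2];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// SLIC assignment/update iterations. Intensities are expected on the scale
// matching the compactness weight m (the R wrapper uses 0..255). Centers are
// 0-based voxel coordinates. Search window is +/- S around each center.
// Returns 1-based labels; unassigned voxels fall back to the spatially
// nearest center.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_slic(NumericVector intensity, IntegerVector dims,
              NumericMatrix centers0, double S, double m, int i_max) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  long N = (long)d0 * d1 * d2;
  int K = centers0.nrow();
  const double *I = intensity.begin();
  std::vector<double> cx(K), cy(K), cz(K), cI(K);
  for (int k = 0; k < K; ++k) {
    cx[k] = centers0(k, 0); cy[k] = centers0(k, 1);
    cz[k] = centers0(k, 2); cI[k] = centers0(k, 3);
  }
  std::vector<int> label(N, 0), prev(N, -1);
  std::vector<double> dist(N);
  int win = (int)std::ceil(S);
  double invS2 = 1.0 / (S * S), invm2 = 1.0 / (m * m);
  int iter_used = 0;
  bool converged = false;
  double last_move = R_PosInf;
  for (int it = 0; it < i_max; ++it) {
    iter_used = it + 1;
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(label.begin(), label.end(), 0);
    for (int k = 0; k < K; ++k) {
      int x0 = (int)std::floor(cx[k] - win), x1 = (int)std::ceil(cx[k] + win);
      int y0 = (int)std::floor(cy[k] - win), y1 = (int)std::ceil(cy[k] + win);
      int z0 = (int)std::floor(cz[k] - win), z1 = (int)std::ceil(cz[k] + win);
      if (x0 < 0) x0 = 0; if (x1 > d0 - 1) x1 = d0 - 1;
      if (y0 < 0) y0 = 0; if (y1 > d1 - 1) y1 = d1 - 1;
      if (z0 < 0) z0 = 0; if (z1 > d2 - 1) z1 = d2 - 1;
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y) {
          long base = (long)y * d0 + (long)z * d0 * d1;
          for (int x = x0; x <= x1; ++x) {
            long idx = base + x;
            double dxs = (x - cx[k]) * (x - cx[k]) + (y - cy[k]) * (y - cy[k]) +
                         (z - cz[k]) * (z - cz[k]);
            double dI = I[idx] - cI[k];
            double D2 = dxs * invS2 + dI * dI * invm2;
            if (D2 < dist[idx]) { dist[idx] = D2; label[idx] = k + 1; }
          }
        }
    }
    // fallback for voxels outside every search window
    for (long idx = 0; idx < N; ++idx) {
      if (label[idx] == 0) {
        int x = (int)(idx % d0), y = (int)((idx / d0) % d1), z = (int)(idx / ((long)d0 * d1));
        double best = R_PosInf; int bk = 1;
        for (int k = 0; k < K; ++k) {
          double dxs = (x - cx[k]) * (x - cx[k]) + (y - cy[k]) * (y - cy[k]) +
                       (z - cz[k]) * (z - cz[k]);
          if (dxs < best) { best = dxs; bk = k + 1; }
        }
        label[idx] = bk;
      }
    }
    if (label == prev) { converged = true; break; }
    prev = label;
    // recompute centers; empty clusters keep their previous position
    std::vector<double> sx(K, 0), sy(K, 0), sz(K, 0), sI(K, 0);
    std::vector<long> cnt(K, 0);
    for (long idx = 0; idx < N; ++idx) {
      int k = label[idx] - 1;
      int x = (int)(idx % d0), y = (int)((idx / d0) % d1), z = (int)(idx / ((long)d0 * d1));
      sx[k] += x; sy[k] += y; sz[k] += z; sI[k] += I[idx]; cnt[k]++;
    }
    last_move = 0.0;
    for (int k = 0; k < K; ++k) {
      if (cnt[k] > 0) {
        double nx = sx[k] / cnt[k], ny = sy[k] / cnt[k], nz = sz[k] / cnt[k];
        double mv = std::sqrt((nx - cx[k]) * (nx - cx[k]) +
                              (ny - cy[k]) * (ny - cy[k]) +
                              (nz - cz[k]) * (nz - cz[k]));
        if (mv > last_move) last_move = mv;
        cx[k] = nx; cy[k] = ny; cz[k] = nz; cI[k] = sI[k] / cnt[k];
      }
    }
  }
  if (converged) last_move = 0.0;
  IntegerVector lab(label.begin(), label.end());
  NumericMatrix cen(K, 4);
  for (int k = 0; k < K; ++k) {
    cen(k, 0) = cx[k]; cen(k, 1) = cy[k]; cen(k, 2) = cz[k]; cen(k, 3) = cI[k];
  }
  return List::create(_["labels"] = lab, _["centers"] = cen,
                      _["iterations"] = iter_used, _["converged"] = converged,
                      _["center_move"] = last_move);
}

// ---------------------------------------------------------------------------
// Connectivity enforcement: each label must form one 26-connected component.
// The largest component of each label keeps it; smaller fragments below
// min_size are merged (union-find) into the neighbouring component with the
// largest face contact; large detached fragments receive fresh labels.
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int> &par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// [[Rcpp::export]]
IntegerVector cpp_enforce_connectivity(IntegerVector labels, IntegerVector dims,
                                       int min_size) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  long N = (long)d0 * d1 * d2;
  std::vector<int> comp(N, -1);
  std::vector<long> comp_size, comp_first;
  std::vector<int> comp_label;
  int ncomp = 0;
  std::vector<long> stack;
  // 26-neighbourhood offsets
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx || dy || dz) nb.push_back({dx, dy, dz});
  for (long s = 0; s < N; ++s) {
    if (comp[s] >= 0) continue;
    int lab = labels[s];
    int c = ncomp++;
    comp_label.push_back(lab);
    comp_first.push_back(s);
    long size = 0;
    stack.clear(); stack.push_back(s); comp[s] = c;
    while (!stack.empty()) {
      long cur = stack.back(); stack.pop_back();
      ++size;
      int x = (int)(cur % d0), y = (int)((cur / d0) % d1), z = (int)(cur / ((long)d0 * d1));
      for (auto &o : nb) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= d0 || yy < 0 || yy >= d1 || zz < 0 || zz >= d2) continue;
        long q = xx + (long)yy * d0 + (long)zz * d0 * d1;
        if (comp[q] < 0 && labels[q] == lab) { comp[q] = c; stack.push_back(q); }
      }
    }
    comp_size.push_back(size);
  }
  // face-contact counts between distinct components
  std::vector<std::unordered_map<int, long>> contact(ncomp);
  for (long s = 0; s < N; ++s) {
    int x = (int)(s % d0), y = (int)((s / d0) % d1), z = (int)(s / ((long)d0 * d1));
    int c = comp[s];
    if (x + 1 < d0) { int q = comp[s + 1]; if (q != c) { contact[c][q]++; contact[q][c]++; } }
    if (y + 1 < d1) { int q = comp[s + d0]; if (q != c) { contact[c][q]++; contact[q][c]++; } }
    if (z + 1 < d2) { int q = comp[s + (long)d0 * d1]; if (q != c) { contact[c][q]++; contact[q][c]++; } }
  }
  // anchor = largest component of each original label (ties: earliest)
  std::unordered_map<int, int> anchor;
  for (int c = 0; c < ncomp; ++c) {
    auto it = anchor.find(comp_label[c]);
    if (it == anchor.end() || comp_size[c] > comp_size[it->second]) anchor[comp_label[c]] = c;
  }
  std::vector<int> par(ncomp);
  for (int c = 0; c < ncomp; ++c) par[c] = c;
  // merge small orphans into their dominant neighbour (process small first)
  std::vector<int> order(ncomp);
  for (int c = 0; c < ncomp; ++c) order[c] = c;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return comp_size[a] < comp_size[b];
  });
  for (int oi = 0; oi < ncomp; ++oi) {
    int c = order[oi];
    if (anchor[comp_label[c]] == c) continue;
    if (comp_size[c] >= min_size) continue;
    long best = -1; int bq = -1; long bsize = -1;
    for (auto &kv : contact[c]) {
      int q = uf_find(par, kv.first);
      if (q == uf_find(par, c)) continue;
      if (kv.second > best || (kv.second == best && comp_size[q] > bsize)) {
        best = kv.second; bq = q; bsize = comp_size[q];
      }
    }
    if (bq >= 0) par[uf_find(par, c)] = bq;
  }
  // assign output labels: anchored roots keep their label, other roots get
  // fresh labels beyond the current maximum, in first-voxel order
  int max_lab = 0;
  for (long s = 0; s < N; ++s) if (labels[s] > max_lab) max_lab = labels[s];
  std::vector<int> out_lab(ncomp, 0);
  std::vector<int> roots;
  for (int c = 0; c < ncomp; ++c) if (uf_find(par, c) == c) roots.push_back(c);
  std::sort(roots.begin(), roots.end(), [&](int a, int b) {
    return comp_first[a] < comp_first[b];
  });
  int next_lab = max_lab + 1;
  for (int r : roots) {
    if (anchor[comp_label[r]] == r) out_lab[r] = comp_label[r];
    else out_lab[r] = next_lab++;
  }
  IntegerVector out(N);
  for (long s = 0; s < N; ++s) out[s] = out_lab[uf_find(par, comp[s])];
  return out;
}

// ---------------------------------------------------------------------------
// Batched inversion of small symmetric positive-definite systems (one M x M
// matrix per voxel), used for multichannel guided filtering. A has one row
// per voxel holding the matrix column-major; returns inverses in the same
// layout. Plain Gauss-Jordan with partial pivoting: M is tiny (<= ~8).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_invert_batch(NumericMatrix A, int M) {
  R_xlen_t n = A.nrow();
  NumericMatrix out(n, M * M);
  std::vector<double> W(M * 2 * M);
  for (R_xlen_t row = 0; row < n; ++row) {
    // augmented [A | I]
    for (int j = 0; j < M; ++j)
      for (int i = 0; i < M; ++i) {
        W[i * 2 * M + j] = A(row, j * M + i); // W is row-major M x 2M
        W[i * 2 * M + M + j] = (i == j) ? 1.0 : 0.0;
      }
    for (int col = 0; col < M; ++col) {
      int piv = col;
      double best = std::fabs(W[col * 2 * M + col]);
      for (int i = col + 1; i < M; ++i) {
        double v = std::fabs(W[i * 2 * M + col]);
        if (v > best) { best = v; piv = i; }
      }
      if (best == 0.0) stop("singular system in multichannel guided filter");
      if (piv != col)
        for (int j = 0; j < 2 * M; ++j) std::swap(W[col * 2 * M + j], W[piv * 2 * M + j]);
      double d = W[col * 2 * M + col];
      for (int j = 0; j < 2 * M; ++j) W[col * 2 * M + j] /= d;
      for (int i = 0; i < M; ++i) {
        if (i == col) continue;
        double f = W[i * 2 * M + col];
        if (f != 0.0)
          for (int j = 0; j < 2 * M; ++j) W[i * 2 * M + j] -= f * W[col * 2 * M + j];
      }
    }
    for (int j = 0; j < M; ++j)
      for (int i = 0; i < M; ++i)
        out(row, j * M + i) = W[i * 2 * M + M + j];
  }
  return out;
}
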