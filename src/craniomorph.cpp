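// Low-level numerical kernels: trilinear resampling, separable Gaussian
// convolution, block-matching node optimisation (Nelder-Mead over local
// translations), displacement-field inversion, Jacobian determinants and
// cluster labelling. All lattices are column-major (R order); voxel indices
// are 0-based here and converted at the R boundary.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline double trilerp(const double *v, int nx, int ny, int nz,
                             double x, double y, double z, bool &inside) {
  // zero outside the grid
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) {
    inside = false;
    return 0.0;
  }
  inside = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int zi = z0 + dz;
    if (zi < 0 || zi >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy < 2; ++dy) {
      int yi = y0 + dy;
      if (yi < 0 || yi >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx < 2; ++dx) {
        int xi = x0 + dx;
        if (xi < 0 || xi >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
      }
    }
  }
  return acc;
}

// clamped (edge-replicating) trilinear sample, used for displacement fields
static inline double trilerp_clamp(const double *v, int nx, int ny, int nz,
                                   double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  bool ins;
  return trilerp(v, nx, ny, nz, x, y, z, ins);
}

static inline void apply4(const double *m, double x, double y, double z,
                          double &ox, double &oy, double &oz) {
  // m is a 4x4 column-major homogeneous matrix
  ox = m[0] * x + m[4] * y + m[8] * z + m[12];
  oy = m[1] * x + m[5] * y + m[9] * z + m[13];
  oz = m[2] * x + m[6] * y + m[10] * z + m[14];
}

// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector sdim,
                                  NumericMatrix vox_map, IntegerVector tdim) {
  // vox_map: 0-based target voxel -> 0-based source voxel
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((size_t)tx * ty * tz);
  const double *s = src.begin();
  const double *m = vox_map.begin();
  size_t idx = 0;
  for (int k = 0; k < tz; ++k)
    for (int j = 0; j < ty; ++j)
      for (int i = 0; i < tx; ++i, ++idx) {
        double xs, ys, zs; bool ins;
        apply4(m, i, j, k, xs, ys, zs);
        out[idx] = trilerp(s, nx, ny, nz, xs, ys, zs, ins);
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_eval_volume_at(NumericVector data, IntegerVector dim,
                                 NumericMatrix vox) {
  // trilinear samples at 0-based voxel coordinates; zero outside
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = vox.nrow();
  NumericVector out(n);
  const double *v = data.begin();
  for (int p = 0; p < n; ++p) {
    bool ins;
    out[p] = trilerp(v, nx, ny, nz, vox(p, 0), vox(p, 1), vox(p, 2), ins);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_eval_field(NumericVector disp, IntegerVector fdim,
                             NumericMatrix w2v, NumericMatrix pts) {
  // disp: [nx,ny,nz,3] world-mm displacement; pts: n x 3 world points.
  // Returns n x 4: (ux, uy, uz, inside-flag). Evaluation clamps to the edge
  // of the lattice; the flag records whether the point was inside.
  int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  size_t nvox = (size_t)nx * ny * nz;
  int n = pts.nrow();
  NumericMatrix out(n, 4);
  const double *d = disp.begin();
  const double *m = w2v.begin();
  for (int p = 0; p < n; ++p) {
    double vx, vy, vz;
    apply4(m, pts(p, 0), pts(p, 1), pts(p, 2), vx, vy, vz);
    bool ins = !(vx < -0.5 || vy < -0.5 || vz < -0.5 ||
                 vx > nx - 0.5 || vy > ny - 0.5 || vz > nz - 0.5);
    for (int c = 0; c < 3; ++c)
      out(p, c) = trilerp_clamp(d + c * nvox, nx, ny, nz, vx, vy, vz);
    out(p, 3) = ins ? 1.0 : 0.0;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resample_field(NumericVector src, IntegerVector sdim,
                                 NumericMatrix src_w2v,
                                 IntegerVector tdim, NumericMatrix t_v2w,
                                 NumericVector disp, IntegerVector fdim,
                                 NumericMatrix f_w2v) {
  // pull-back resampling through a displacement field:
  //   out(v) = src( world(v) + u(world(v)) )
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  size_t fvox = (size_t)fx * fy * fz;
  NumericVector out((size_t)tx * ty * tz);
  const double *s = src.begin(), *d = disp.begin();
  const double *mv = t_v2w.begin(), *mf = f_w2v.begin(), *ms = src_w2v.begin();
  size_t idx = 0;
  for (int k = 0; k < tz; ++k)
    for (int j = 0; j < ty; ++j)
      for (int i = 0; i < tx; ++i, ++idx) {
        double wx, wy, wz;
        apply4(mv, i, j, k, wx, wy, wz);
        double vx, vy, vz;
        apply4(mf, wx, wy, wz, vx, vy, vz);
        double ux = trilerp_clamp(d, fx, fy, fz, vx, vy, vz);
        double uy = trilerp_clamp(d + fvox, fx, fy, fz, vx, vy, vz);
        double uz = trilerp_clamp(d + 2 * fvox, fx, fy, fz, vx, vy, vz);
        double sx, sy, sz; bool ins;
        apply4(ms, wx + ux, wy + uy, wz + uz, sx, sy, sz);
        out[idx] = trilerp(s, nx, ny, nz, sx, sy, sz, ins);
      }
  return out;
}

static void conv1(std::vector<double> &buf, const std::vector<double> &ker,
                  std::vector<double> &tmp) {
  int n = (int)buf.size();
  int r = ((int)ker.size() - 1) / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = -r; t <= r; ++t) {
      int j = i + t;
      if (j >= 0 && j < n) acc += buf[j] * ker[t + r];
    }
    tmp[i] = acc;
  }
  buf.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector data, IntegerVector dim,
                                NumericVector sigma_vox) {
  // separable convolution, zero-padded, kernel truncated at 4 sigma and
  // normalised so interior-supported signals conserve their total intensity
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(data);
  double *v = out.begin();
  for (int ax = 0; ax < 3; ++ax) {
    double sg = sigma_vox[ax];
    if (sg <= 1e-8) continue;
    int r = std::max(1, (int)std::ceil(4.0 * sg));
    std::vector<double> ker(2 * r + 1);
    double ssum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (sg * sg));
      ssum += ker[t + r];
    }
    for (auto &k : ker) k /= ssum;
    int n = ax == 0 ? nx : (ax == 1 ? ny : nz);
    std::vector<double> buf(n), tmp(n);
    if (ax == 0) {
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          size_t base = (size_t)nx * (j + (size_t)ny * k);
          for (int i = 0; i < n; ++i) buf[i] = v[base + i];
          conv1(buf, ker, tmp);
          for (int i = 0; i < n; ++i) v[base + i] = buf[i];
        }
    } else if (ax == 1) {
      for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
          for (int j = 0; j < n; ++j) buf[j] = v[i + (size_t)nx * (j + (size_t)ny * k)];
          conv1(buf, ker, tmp);
          for (int j = 0; j < n; ++j) v[i + (size_t)nx * (j + (size_t)ny * k)] = buf[j];
        }
    } else {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          for (int k = 0; k < n; ++k) buf[k] = v[i + (size_t)nx * (j + (size_t)ny * k)];
          conv1(buf, ker, tmp);
          for (int k = 0; k < n; ++k) v[i + (size_t)nx * (j + (size_t)ny * k)] = buf[k];
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
double cpp_ncc_affine(NumericVector src, IntegerVector sdim,
                      NumericVector tgt, IntegerVector tdim,
                      NumericMatrix vox_map, IntegerVector mask) {
  // normalised cross-correlation between the target and the source pulled
  // back through vox_map (0-based target voxel -> source voxel); out-of-FOV
  // source samples count as 0, matching the resampler
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  const double *s = src.begin(), *t = tgt.begin();
  const double *m = vox_map.begin();
  bool use_mask = mask.size() == (int)((size_t)tx * ty * tz);
  double st = 0, ss = 0, stt = 0, sss = 0, sts = 0;
  size_t n = 0, idx = 0;
  for (int k = 0; k < tz; ++k)
    for (int j = 0; j < ty; ++j)
      for (int i = 0; i < tx; ++i, ++idx) {
        if (use_mask && mask[idx] == 0) continue;
        double xs, ys, zs; bool ins;
        apply4(m, i, j, k, xs, ys, zs);
        double sv = trilerp(s, nx, ny, nz, xs, ys, zs, ins);
        double tv = t[idx];
        st += tv; ss += sv; stt += tv * tv; sss += sv * sv; sts += tv * sv;
        ++n;
      }
  if (n < 2) return 0.0;
  double covts = sts - st * ss / n;
  double vart = stt - st * st / n;
  double vars = sss - ss * ss / n;
  if (vart <= 0 || vars <= 0) return 0.0;
  return covts / std::sqrt(vart * vars);
}

// ---- local block matching ------------------------------------------------

struct LocalObj {
  const double *src; int snx, sny, snz;
  const double *sw2v; // source world->voxel 4x4
  const std::vector<double> *tvals; // target window values
  const std::vector<double> *wpts;  // window world points (3*n)
  double px, py, pz;                // node world position (unused; wpts absolute)
  double search2;                   // squared search radius
  double tmean, tsd;
};

static double local_negncc(const LocalObj &o, const double *delta) {
  double d2 = delta[0] * delta[0] + delta[1] * delta[1] + delta[2] * delta[2];
  if (d2 > o.search2) return 1e3 + d2; // soft barrier outside search sphere
  int n = (int)o.tvals->size();
  double ss = 0, sss = 0, sts = 0;
  const std::vector<double> &tp = *o.wpts;
  const std::vector<double> &tv = *o.tvals;
  for (int q = 0; q < n; ++q) {
    double wx = tp[3 * q] + delta[0];
    double wy = tp[3 * q + 1] + delta[1];
    double wz = tp[3 * q + 2] + delta[2];
    double vx, vy, vz;
    apply4(o.sw2v, wx, wy, wz, vx, vy, vz);
    bool ins;
    double sv = trilerp(o.src, o.snx, o.sny, o.snz, vx, vy, vz, ins);
    ss += sv; sss += sv * sv; sts += tv[q] * sv;
  }
  double vars = sss - ss * ss / n;
  if (vars <= 1e-12) return 0.0;
  double covts = sts - o.tmean * n * ss / n; // sum(t*s) - mean(t)*sum(s)
  return -covts / std::sqrt(vars * o.tsd * o.tsd * n);
}

// minimal Nelder-Mead in 3D; starts at zero displacement so flat similarity
// keeps the node where it is (minimal-deformation tie-break)
static void nelder_mead3(const LocalObj &o, double edge, int max_eval,
                         double *best) {
  const int d = 3;
  double simplex[4][3];
  double fv[4];
  for (int i = 0; i < 4; ++i)
    for (int c = 0; c < d; ++c) simplex[i][c] = 0.0;
  for (int i = 1; i < 4; ++i) simplex[i][i - 1] = edge;
  int evals = 0;
  for (int i = 0; i < 4; ++i) { fv[i] = local_negncc(o, simplex[i]); ++evals; }
  while (evals < max_eval) {
    // order
    int lo = 0, hi = 0, nh = 0;
    for (int i = 1; i < 4; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    nh = lo;
    for (int i = 0; i < 4; ++i)
      if (i != hi && fv[i] > fv[nh]) nh = i;
    if (fv[hi] - fv[lo] < 1e-8) break;
    double cen[3] = {0, 0, 0};
    for (int i = 0; i < 4; ++i)
      if (i != hi)
        for (int c = 0; c < d; ++c) cen[c] += simplex[i][c] / 3.0;
    double refl[3], exp_[3], con[3];
    for (int c = 0; c < d; ++c) refl[c] = cen[c] + (cen[c] - simplex[hi][c]);
    double fr = local_negncc(o, refl); ++evals;
    if (fr < fv[lo]) {
      for (int c = 0; c < d; ++c) exp_[c] = cen[c] + 2.0 * (cen[c] - simplex[hi][c]);
      double fe = local_negncc(o, exp_); ++evals;
      if (fe < fr) { for (int c = 0; c < d; ++c) simplex[hi][c] = exp_[c]; fv[hi] = fe; }
      else { for (int c = 0; c < d; ++c) simplex[hi][c] = refl[c]; fv[hi] = fr; }
    } else if (fr < fv[nh]) {
      for (int c = 0; c < d; ++c) simplex[hi][c] = refl[c]; fv[hi] = fr;
    } else {
      for (int c = 0; c < d; ++c) con[c] = cen[c] + 0.5 * (simplex[hi][c] - cen[c]);
      double fc = local_negncc(o, con); ++evals;
      if (fc < fv[hi]) { for (int c = 0; c < d; ++c) simplex[hi][c] = con[c]; fv[hi] = fc; }
      else { // shrink toward best
        for (int i = 0; i < 4; ++i) {
          if (i == lo) continue;
          for (int c = 0; c < d; ++c)
            simplex[i][c] = simplex[lo][c] + 0.5 * (simplex[i][c] - simplex[lo][c]);
          fv[i] = local_negncc(o, simplex[i]); ++evals;
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 4; ++i) if (fv[i] < fv[lo]) lo = i;
  // keep zero displacement unless the move actually improved similarity
  double f0[3] = {0, 0, 0};
  if (fv[lo] >= local_negncc(o, f0) - 1e-10) {
    best[0] = best[1] = best[2] = 0.0;
  } else {
    for (int c = 0; c < d; ++c) best[c] = simplex[lo][c];
  }
}

// [[Rcpp::export]]
List cpp_node_updates(NumericVector src, IntegerVector sdim, NumericMatrix src_w2v,
                      NumericVector tgt, IntegerVector tdim, NumericMatrix tgt_w2v,
                      NumericMatrix node_world, NumericMatrix node_disp,
                      NumericMatrix offsets, double search_radius,
                      double simplex_edge, int max_eval, double min_tsd) {
  // One block-matching sweep. node_world: m x 3 node positions in target
  // world space; node_disp: m x 3 current displacements (target -> source).
  // offsets: q x 3 world-mm sampling offsets of the spherical window.
  // Returns the per-node data-driven displacement proposal and an
  // activity flag (0 = degenerate target window, proposal invalid).
  int m = node_world.nrow(), q = offsets.nrow();
  int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  NumericMatrix prop(m, 3);
  IntegerVector active(m);
  const double *t = tgt.begin();
  const double *mt = tgt_w2v.begin();
  std::vector<double> tvals(q), wpts(3 * q);
  LocalObj o;
  o.src = src.begin(); o.snx = sdim[0]; o.sny = sdim[1]; o.snz = sdim[2];
  o.sw2v = src_w2v.begin();
  o.search2 = search_radius * search_radius;
  for (int nd = 0; nd < m; ++nd) {
    double px = node_world(nd, 0), py = node_world(nd, 1), pz = node_world(nd, 2);
    double tsum = 0, tss = 0;
    for (int k = 0; k < q; ++k) {
      double wx = px + offsets(k, 0), wy = py + offsets(k, 1), wz = pz + offsets(k, 2);
      double vx, vy, vz; bool ins;
      apply4(mt, wx, wy, wz, vx, vy, vz);
      double tv = trilerp(t, tnx, tny, tnz, vx, vy, vz, ins);
      tvals[k] = tv; tsum += tv; tss += tv * tv;
      // source is probed at the *displaced* window: absolute points carry
      // the current node displacement so delta is the incremental move
      wpts[3 * k] = wx + node_disp(nd, 0);
      wpts[3 * k + 1] = wy + node_disp(nd, 1);
      wpts[3 * k + 2] = wz + node_disp(nd, 2);
    }
    double tmean = tsum / q;
    double tvar = tss / q - tmean * tmean;
    if (tvar < min_tsd * min_tsd) { active[nd] = 0; continue; }
    active[nd] = 1;
    for (int k = 0; k < q; ++k) tvals[k] -= tmean;
    o.tvals = &tvals; o.wpts = &wpts;
    o.tmean = 0.0;
    o.tsd = std::sqrt(tvar);
    double best[3];
    nelder_mead3(o, simplex_edge, max_eval, best);
    prop(nd, 0) = node_disp(nd, 0) + best[0];
    prop(nd, 1) = node_disp(nd, 1) + best[1];
    prop(nd, 2) = node_disp(nd, 2) + best[2];
  }
  return List::create(_["proposal"] = prop, _["active"] = active);
}

// [[Rcpp::export]]
List cpp_invert_field(NumericVector disp, IntegerVector fdim,
                      NumericMatrix v2w, NumericMatrix w2v,
                      double tol, int max_iter) {
  // fixed-point inversion: v_{k+1}(y) = -u(y + v_k(y))
  int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector inv(3 * nvox);
  const double *d = disp.begin();
  const double *mv = v2w.begin(), *mw = w2v.begin();
  int nonconv = 0;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double yx, yy, yz;
        apply4(mv, i, j, k, yx, yy, yz);
        double vx = 0, vy = 0, vz = 0;
        bool ok = false;
        for (int it = 0; it < max_iter; ++it) {
          double gx, gy, gz;
          apply4(mw, yx + vx, yy + vy, yz + vz, gx, gy, gz);
          double ux = trilerp_clamp(d, nx, ny, nz, gx, gy, gz);
          double uy = trilerp_clamp(d + nvox, nx, ny, nz, gx, gy, gz);
          double uz = trilerp_clamp(d + 2 * nvox, nx, ny, nz, gx, gy, gz);
          double nvx = -ux, nvy = -uy, nvz = -uz;
          double ch = std::sqrt((nvx - vx) * (nvx - vx) + (nvy - vy) * (nvy - vy) +
                                (nvz - vz) * (nvz - vz));
          vx = nvx; vy = nvy; vz = nvz;
          if (ch < tol) { ok = true; break; }
        }
        if (!ok) ++nonconv;
        inv[idx] = vx; inv[idx + nvox] = vy; inv[idx + 2 * nvox] = vz;
      }
  return List::create(_["disp"] = inv, _["nonconv"] = nonconv);
}

// [[Rcpp::export]]
NumericVector cpp_jacobian(NumericVector disp, IntegerVector dim,
                           NumericMatrix v2w3inv) {
  // det(I + du/dx_world); du/dvoxel by central differences (one-sided at
  // borders), converted with the inverse of the voxel->world 3x3 block
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  const double *d = disp.begin();
  const double *A = v2w3inv.begin(); // 3x3 column-major: dvox/dworld
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double G[9]; // du_c/dvox_a, column-major c + 3*a
        for (int a = 0; a < 3; ++a) {
          int ip = i, im = i, jp = j, jm = j, kp = k, km = k;
          double h = 2.0;
          if (a == 0) { ip = i + 1; im = i - 1; if (ip >= nx) { ip = nx - 1; h = 1; } if (im < 0) { im = 0; h = 1; } }
          if (a == 1) { jp = j + 1; jm = j - 1; if (jp >= ny) { jp = ny - 1; h = 1; } if (jm < 0) { jm = 0; h = 1; } }
          if (a == 2) { kp = k + 1; km = k - 1; if (kp >= nz) { kp = nz - 1; h = 1; } if (km < 0) { km = 0; h = 1; } }
          size_t idp = ip + (size_t)nx * (jp + (size_t)ny * kp);
          size_t idm = im + (size_t)nx * (jm + (size_t)ny * km);
          for (int c = 0; c < 3; ++c)
            G[c + 3 * a] = (d[idp + c * nvox] - d[idm + c * nvox]) / h;
        }
        // J = I + G * A  (A = dvox/dworld)
        double J[9];
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c) {
            double acc = (r == c) ? 1.0 : 0.0;
            for (int q = 0; q < 3; ++q) acc += G[r + 3 * q] * A[q + 3 * c];
            J[r + 3 * c] = acc;
          }
        out[idx] = J[0] * (J[4] * J[8] - J[7] * J[5]) -
                   J[3] * (J[1] * J[8] - J[7] * J[2]) +
                   J[6] * (J[1] * J[5] - J[4] * J[2]);
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label_clusters(IntegerVector mask, IntegerVector dim) {
  // 18-connectivity connected components (faces + edges, no corners)
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab(nvox);
  int next = 0;
  std::vector<int> neigh;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz_ = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz_ == 0 || nz_ > 2) continue; // 18-connectivity
        neigh.push_back(dx); neigh.push_back(dy); neigh.push_back(dz);
      }
  std::queue<size_t> q;
  for (size_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front(); q.pop();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((size_t)nx * ny);
      for (size_t t = 0; t < neigh.size(); t += 3) {
        int ii = ci + neigh[t], jj = cj + neigh[t + 1], kk = ck + neigh[t + 2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t nid = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[nid] && !lab[nid]) { lab[nid] = next; q.push(nid); }
      }
    }
  }
  return lab;
}
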