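// Compute kernels for the 3D segmentation engine.
//
// Array convention: feature tensors are R arrays with dim (Z, Y, X, C),
// column-major, so the depth axis is the fastest-varying index.  All
// convolutions use 3x3x3 kernels with SAME zero padding; stride is 1
// (within-stage convolutions) or 2 (down/upsampling).  Weight tensors have
// dim (3, 3, 3, Cin, Cout).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline int idx4(int z, int y, int x, int c, int Z, int Y, int X) {
  return z + Z * (y + Y * (x + (long)X * c));
}

// Forward 3D convolution: x (Z,Y,X,Cin) -> out (Zo,Yo,Xo,Cout),
// Zo = ceil(Z / stride) etc. (SAME padding).
//
// The stride-1 path accumulates one output row (fixed yo, xo, co) at a time
// so the 3x3xCin input rows it reads stay in L1; the stride-2 path keeps the
// simpler tap-by-tap form since the downsampled tensors are small.
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, NumericVector b, int stride) {
  const int Z = xdim[0], Y = xdim[1], X = xdim[2], Cin = xdim[3];
  const int Cout = b.size();
  const int Zo = (Z + stride - 1) / stride;
  const int Yo = (Y + stride - 1) / stride;
  const int Xo = (X + stride - 1) / stride;
  NumericVector out(Zo * (long)Yo * Xo * Cout);
  const double* xp = x.begin();
  double* op = out.begin();

  if (stride == 1) {
    std::vector<double> buf(Z);
    for (int xo = 0; xo < X; ++xo) {
      for (int yo = 0; yo < Y; ++yo) {
        for (int co = 0; co < Cout; ++co) {
          for (int z = 0; z < Z; ++z) buf[z] = b[co];
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xc = xp + (long)Z * Y * X * ci;
            for (int kx = 0; kx < 3; ++kx) {
              const int xi = xo + kx - 1;
              if (xi < 0 || xi >= X) continue;
              for (int ky = 0; ky < 3; ++ky) {
                const int yi = yo + ky - 1;
                if (yi < 0 || yi >= Y) continue;
                const double* xrow = xc + (long)Z * (yi + (long)Y * xi);
                const double* wk = &w[3 * (ky + 3 * (kx + 3 * (ci + Cin * co)))];
                // kz = 0, 1, 2 <=> dz = -1, 0, +1
                const double w0 = wk[0], w1 = wk[1], w2 = wk[2];
                for (int z = 1; z < Z; ++z) buf[z] += w0 * xrow[z - 1];
                for (int z = 0; z < Z; ++z) buf[z] += w1 * xrow[z];
                for (int z = 0; z < Z - 1; ++z) buf[z] += w2 * xrow[z + 1];
              }
            }
          }
          double* orow = op + (long)Z * (yo + (long)Y * (xo + (long)X * co));
          for (int z = 0; z < Z; ++z) orow[z] = buf[z];
        }
      }
    }
    out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, Cout);
    return out;
  }

  for (int co = 0; co < Cout; ++co) {
    const double bc = b[co];
    double* oc = op + (long)Zo * Yo * Xo * co;
    for (long i = 0; i < (long)Zo * Yo * Xo; ++i) oc[i] = bc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (long)Z * Y * X * ci;
      for (int kx = 0; kx < 3; ++kx) {
        for (int ky = 0; ky < 3; ++ky) {
          for (int kz = 0; kz < 3; ++kz) {
            const double wv = w[kz + 3 * (ky + 3 * (kx + 3 * (ci + Cin * co)))];
            if (wv == 0.0) continue;
            const int dz = kz - 1, dy = ky - 1, dx = kx - 1;
            for (int xo = 0; xo < Xo; ++xo) {
              const int xi = stride * xo + dx;
              if (xi < 0 || xi >= X) continue;
              for (int yo = 0; yo < Yo; ++yo) {
                const int yi = stride * yo + dy;
                if (yi < 0 || yi >= Y) continue;
                double* orow = oc + (long)Zo * (yo + (long)Yo * xo);
                const double* xrow = xc + (long)Z * (yi + (long)Y * xi);
                // zo range such that zi = stride*zo + dz lies in [0, Z)
                int zo0 = 0;
                while (stride * zo0 + dz < 0) ++zo0;
                int zo1 = Zo;
                while (zo1 > zo0 && stride * (zo1 - 1) + dz >= Z) --zo1;
                if (stride == 1) {
                  for (int zo = zo0; zo < zo1; ++zo)
                    orow[zo] += wv * xrow[zo + dz];
                } else {
                  for (int zo = zo0; zo < zo1; ++zo)
                    orow[zo] += wv * xrow[stride * zo + dz];
                }
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Zo, Yo, Xo, Cout);
  return out;
}

// Gradient of the convolution w.r.t. its input: scatter gout back through w.
// xdim is the shape of the ORIGINAL input (Z,Y,X,Cin).
// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_dx(NumericVector gout, IntegerVector gdim,
                                NumericVector w, IntegerVector xdim,
                                int stride) {
  const int Zo = gdim[0], Yo = gdim[1], Xo = gdim[2], Cout = gdim[3];
  const int Z = xdim[0], Y = xdim[1], X = xdim[2], Cin = xdim[3];
  NumericVector dx(Z * (long)Y * X * Cin);
  const double* gp = gout.begin();
  double* dp = dx.begin();

  if (stride == 1) {
    // gather form: dx[zi] = sum w[k] * g[zi - dz] (the flipped-kernel
    // correlation), accumulated one input row at a time
    std::vector<double> buf(Z);
    for (int xi = 0; xi < X; ++xi) {
      for (int yi = 0; yi < Y; ++yi) {
        for (int ci = 0; ci < Cin; ++ci) {
          std::fill(buf.begin(), buf.end(), 0.0);
          for (int co = 0; co < Cout; ++co) {
            const double* gc = gp + (long)Zo * Yo * Xo * co;
            for (int kx = 0; kx < 3; ++kx) {
              const int xo = xi - (kx - 1);
              if (xo < 0 || xo >= Xo) continue;
              for (int ky = 0; ky < 3; ++ky) {
                const int yo = yi - (ky - 1);
                if (yo < 0 || yo >= Yo) continue;
                const double* grow = gc + (long)Zo * (yo + (long)Yo * xo);
                const double* wk = &w[3 * (ky + 3 * (kx + 3 * (ci + Cin * co)))];
                const double w0 = wk[0], w1 = wk[1], w2 = wk[2];
                // dz = -1: zi = zo - 1 -> buf[z] += w0 * grow[z + 1]
                for (int z = 0; z < Z - 1; ++z) buf[z] += w0 * grow[z + 1];
                for (int z = 0; z < Z; ++z) buf[z] += w1 * grow[z];
                for (int z = 1; z < Z; ++z) buf[z] += w2 * grow[z - 1];
              }
            }
          }
          double* drow = dp + (long)Z * (yi + (long)Y * (xi + (long)X * ci));
          for (int z = 0; z < Z; ++z) drow[z] = buf[z];
        }
      }
    }
    dx.attr("dim") = xdim;
    return dx;
  }

  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + (long)Zo * Yo * Xo * co;
    for (int ci = 0; ci < Cin; ++ci) {
      double* dc = dp + (long)Z * Y * X * ci;
      for (int kx = 0; kx < 3; ++kx) {
        for (int ky = 0; ky < 3; ++ky) {
          for (int kz = 0; kz < 3; ++kz) {
            const double wv = w[kz + 3 * (ky + 3 * (kx + 3 * (ci + Cin * co)))];
            if (wv == 0.0) continue;
            const int dz = kz - 1, dy = ky - 1, dxk = kx - 1;
            for (int xo = 0; xo < Xo; ++xo) {
              const int xi = stride * xo + dxk;
              if (xi < 0 || xi >= X) continue;
              for (int yo = 0; yo < Yo; ++yo) {
                const int yi = stride * yo + dy;
                if (yi < 0 || yi >= Y) continue;
                const double* grow = gc + (long)Zo * (yo + (long)Yo * xo);
                double* drow = dc + (long)Z * (yi + (long)Y * xi);
                int zo0 = 0;
                while (stride * zo0 + dz < 0) ++zo0;
                int zo1 = Zo;
                while (zo1 > zo0 && stride * (zo1 - 1) + dz >= Z) --zo1;
                for (int zo = zo0; zo < zo1; ++zo)
                  drow[stride * zo + dz] += wv * grow[zo];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// Gradients w.r.t. weights and bias.  Returns list(dw, db).
// [[Rcpp::export]]
List cpp_conv3d_bwd_dw(NumericVector x, IntegerVector xdim,
                       NumericVector gout, IntegerVector gdim, int stride) {
  const int Z = xdim[0], Y = xdim[1], X = xdim[2], Cin = xdim[3];
  const int Zo = gdim[0], Yo = gdim[1], Xo = gdim[2], Cout = gdim[3];
  NumericVector dw(27L * Cin * Cout);
  NumericVector db(Cout);
  const double* xp = x.begin();
  const double* gp = gout.begin();

  if (stride == 1) {
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gp + (long)Zo * Yo * Xo * co;
      double acc_b = 0.0;
      for (long i = 0; i < (long)Zo * Yo * Xo; ++i) acc_b += gc[i];
      db[co] = acc_b;
    }
    for (int xo = 0; xo < Xo; ++xo) {
      for (int yo = 0; yo < Yo; ++yo) {
        for (int co = 0; co < Cout; ++co) {
          const double* grow = gp + (long)Zo * (yo + (long)Yo *
                               (xo + (long)Xo * co));
          for (int ci = 0; ci < Cin; ++ci) {
            const double* xc = xp + (long)Z * Y * X * ci;
            for (int kx = 0; kx < 3; ++kx) {
              const int xi = xo + kx - 1;
              if (xi < 0 || xi >= X) continue;
              for (int ky = 0; ky < 3; ++ky) {
                const int yi = yo + ky - 1;
                if (yi < 0 || yi >= Y) continue;
                const double* xrow = xc + (long)Z * (yi + (long)Y * xi);
                double a0 = 0.0, a1 = 0.0, a2 = 0.0;
                for (int z = 1; z < Z; ++z) a0 += grow[z] * xrow[z - 1];
                for (int z = 0; z < Z; ++z) a1 += grow[z] * xrow[z];
                for (int z = 0; z < Z - 1; ++z) a2 += grow[z] * xrow[z + 1];
                double* wk = &dw[3 * (ky + 3 * (kx + 3 * (ci + Cin * co)))];
                wk[0] += a0; wk[1] += a1; wk[2] += a2;
              }
            }
          }
        }
      }
    }
    dw.attr("dim") = IntegerVector::create(3, 3, 3, Cin, Cout);
    return List::create(_["dw"] = dw, _["db"] = db);
  }

  for (int co = 0; co < Cout; ++co) {
    const double* gc = gp + (long)Zo * Yo * Xo * co;
    double acc_b = 0.0;
    for (long i = 0; i < (long)Zo * Yo * Xo; ++i) acc_b += gc[i];
    db[co] = acc_b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (long)Z * Y * X * ci;
      for (int kx = 0; kx < 3; ++kx) {
        for (int ky = 0; ky < 3; ++ky) {
          for (int kz = 0; kz < 3; ++kz) {
            const int dz = kz - 1, dy = ky - 1, dxk = kx - 1;
            double acc = 0.0;
            for (int xo = 0; xo < Xo; ++xo) {
              const int xi = stride * xo + dxk;
              if (xi < 0 || xi >= X) continue;
              for (int yo = 0; yo < Yo; ++yo) {
                const int yi = stride * yo + dy;
                if (yi < 0 || yi >= Y) continue;
                const double* grow = gc + (long)Zo * (yo + (long)Yo * xo);
                const double* xrow = xc + (long)Z * (yi + (long)Y * xi);
                int zo0 = 0;
                while (stride * zo0 + dz < 0) ++zo0;
                int zo1 = Zo;
                while (zo1 > zo0 && stride * (zo1 - 1) + dz >= Z) --zo1;
                for (int zo = zo0; zo < zo1; ++zo)
                  acc += grow[zo] * xrow[stride * zo + dz];
              }
            }
            dw[kz + 3 * (ky + 3 * (kx + 3 * (ci + Cin * co)))] = acc;
          }
        }
      }
    }
  }
  dw.attr("dim") = IntegerVector::create(3, 3, 3, Cin, Cout);
  return List::create(_["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (lower-envelope-of-parabolas method),
// separable over axes, supporting anisotropic voxel spacing.  Returns, for
// every voxel, the Euclidean distance (voxel-center to voxel-center, in the
// units of `spacing`) to the nearest voxel where seed != 0.  If no seed
// exists, all distances are +Inf.

// "No seed" is encoded as a huge finite squared distance rather than Inf so
// the parabola intersections stay well defined; anything that large on output
// is mapped back to Inf.  Grid squared distances are < 1e8, so 1e20 always
// loses against a genuine seed.
static const double DT_HUGE = 1e20;

static void dt1d(const std::vector<double>& f, const std::vector<double>& pos,
                 std::vector<double>& d, int n) {
  // f: squared distances at sample positions pos (increasing); d: output.
  std::vector<int> v(n);
  std::vector<double> zi(n + 1);
  int k = 0;
  v[0] = 0;
  zi[0] = -std::numeric_limits<double>::infinity();
  zi[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + pos[q] * pos[q]) - (f[p] + pos[p] * pos[p])) /
          (2.0 * pos[q] - 2.0 * pos[p]);
      if (s <= zi[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zi[k] = s;
    zi[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zi[k + 1] < pos[q]) ++k;
    const int p = v[k];
    const double diff = pos[q] - pos[p];
    d[q] = diff * diff + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(NumericVector seed, IntegerVector dim,
                      NumericVector spacing) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  std::vector<double> D((long)Z * Y * X);
  for (long i = 0; i < (long)Z * Y * X; ++i)
    D[i] = (seed[i] != 0.0) ? 0.0 : DT_HUGE;

  const int nmax = std::max(Z, std::max(Y, X));
  std::vector<double> f(nmax), pos(nmax), d(nmax);

  // pass along Z
  for (int i = 0; i < Z; ++i) pos[i] = i * spacing[0];
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y) {
      double* col = &D[(long)Z * (y + (long)Y * x)];
      for (int z = 0; z < Z; ++z) f[z] = col[z];
      dt1d(f, pos, d, Z);
      for (int z = 0; z < Z; ++z) col[z] = d[z];
    }
  // pass along Y
  for (int i = 0; i < Y; ++i) pos[i] = i * spacing[1];
  for (int x = 0; x < X; ++x)
    for (int z = 0; z < Z; ++z) {
      for (int y = 0; y < Y; ++y) f[y] = D[z + (long)Z * (y + (long)Y * x)];
      dt1d(f, pos, d, Y);
      for (int y = 0; y < Y; ++y) D[z + (long)Z * (y + (long)Y * x)] = d[y];
    }
  // pass along X
  for (int i = 0; i < X; ++i) pos[i] = i * spacing[2];
  for (int y = 0; y < Y; ++y)
    for (int z = 0; z < Z; ++z) {
      for (int x = 0; x < X; ++x) f[x] = D[z + (long)Z * (y + (long)Y * x)];
      dt1d(f, pos, d, X);
      for (int x = 0; x < X; ++x) D[z + (long)Z * (y + (long)Y * x)] = d[x];
    }

  NumericVector out((long)Z * Y * X);
  for (long i = 0; i < (long)Z * Y * X; ++i)
    out[i] = (D[i] >= 1e18) ? R_PosInf : std::sqrt(D[i]);
  out.attr("dim") = IntegerVector::create(Z, Y, X);
  return out;
}

// ---------------------------------------------------------------------------
// Directed nearest-neighbour distances between point sets (rows are points,
// 3 columns, already spacing-scaled).  Brute force; surface sets at the
// problem sizes used here are small.
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double a0 = A(i, 0), a1 = A(i, 1), a2 = A(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      const double d0 = a0 - B(j, 0), d1 = a1 - B(j, 1), d2 = a2 - B(j, 2);
      const double dd = d0 * d0 + d1 * d1 + d2 * d2;
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rasterize capsules (sphere-swept segments) into a (Z,Y,X) volume.  Each
// row of `segs` is (z0,y0,x0, z1,y1,x1, radius) in mm; voxel centre of index
// (z,y,x) is (z*sz, y*sy, x*sx).  Voxels within `radius` of a segment are
// set to max(current, value[seg]).  A sphere is the degenerate capsule
// p0 == p1.  Operates on a single copy of `vol`.
// [[Rcpp::export]]
NumericVector cpp_paint_capsules(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericMatrix segs,
                                 NumericVector value) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  NumericVector out = clone(vol);
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];

  for (int s = 0; s < segs.nrow(); ++s) {
    const double p0z = segs(s, 0), p0y = segs(s, 1), p0x = segs(s, 2);
    const double p1z = segs(s, 3), p1y = segs(s, 4), p1x = segs(s, 5);
    const double radius = segs(s, 6);
    const double val = value[s];
    const int z0 = std::max(0, (int)std::floor((std::min(p0z, p1z) - radius) / sz));
    const int z1 = std::min(Z - 1, (int)std::ceil((std::max(p0z, p1z) + radius) / sz));
    const int y0 = std::max(0, (int)std::floor((std::min(p0y, p1y) - radius) / sy));
    const int y1 = std::min(Y - 1, (int)std::ceil((std::max(p0y, p1y) + radius) / sy));
    const int x0 = std::max(0, (int)std::floor((std::min(p0x, p1x) - radius) / sx));
    const int x1 = std::min(X - 1, (int)std::ceil((std::max(p0x, p1x) + radius) / sx));

    const double vz = p1z - p0z, vy = p1y - p0y, vx = p1x - p0x;
    const double vv = vz * vz + vy * vy + vx * vx;
    const double r2 = radius * radius;

    for (int x = x0; x <= x1; ++x) {
      const double px = x * sx - p0x;
      for (int y = y0; y <= y1; ++y) {
        const double py = y * sy - p0y;
        for (int z = z0; z <= z1; ++z) {
          const double pz = z * sz - p0z;
          double t = 0.0;
          if (vv > 0.0) {
            t = (pz * vz + py * vy + px * vx) / vv;
            if (t < 0.0) t = 0.0;
            if (t > 1.0) t = 1.0;
          }
          const double dz = pz - t * vz, dy = py - t * vy, dx = px - t * vx;
          if (dz * dz + dy * dy + dx * dx <= r2) {
            const long i = z + (long)Z * (y + (long)Y * x);
            if (out[i] < val) out[i] = val;
          }
        }
      }
    }
  }
  return out;
}
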