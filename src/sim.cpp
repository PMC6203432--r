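// Core simulation engine: bounded random-walk path generation and the
// coupled border/grid/place spiking network.
//
// Design notes:
//  * Grid sheets are square tori with side a power of two, so toroidal
//    wrapping is a bitmask.  Each unit inhibits a disc of radius 12 centred
//    2 units away along its preferred direction.  Rather than recomputing
//    the inhibitory drive as a full convolution each timestep, we maintain
//    the convolved field F = disc (*) shifted(a) incrementally: activations
//    decay by a fixed factor (1 - dt/c) and grow only by alpha per spike,
//    so F obeys the same linear recursion and spikes are "stamped" into it.
//  * All randomness comes from R's RNG (RNGScope), so set.seed() on the R
//    side makes whole simulations bit-reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- geometry

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// proper segment intersection test (shared endpoints count as crossing,
// which is what we want for wall collision)
static bool seg_intersect(double p0x, double p0y, double p1x, double p1y,
                          double q0x, double q0y, double q1x, double q1y) {
  double d1 = cross2(q1x - q0x, q1y - q0y, p0x - q0x, p0y - q0y);
  double d2 = cross2(q1x - q0x, q1y - q0y, p1x - q0x, p1y - q0y);
  double d3 = cross2(p1x - p0x, p1y - p0y, q0x - p0x, q0y - p0y);
  double d4 = cross2(p1x - p0x, p1y - p0y, q1x - p0x, q1y - p0y);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  // collinear / touching cases: treat any touch as a crossing
  const double eps = 1e-12;
  auto on_seg = [eps](double ax, double ay, double bx, double by,
                      double px, double py) {
    if (std::fabs(cross2(bx - ax, by - ay, px - ax, py - ay)) > 1e-9)
      return false;
    return px >= std::min(ax, bx) - eps && px <= std::max(ax, bx) + eps &&
           py >= std::min(ay, by) - eps && py <= std::max(ay, by) + eps;
  };
  if (on_seg(q0x, q0y, q1x, q1y, p0x, p0y)) return true;
  if (on_seg(q0x, q0y, q1x, q1y, p1x, p1y)) return true;
  if (on_seg(p0x, p0y, p1x, p1y, q0x, q0y)) return true;
  if (on_seg(p0x, p0y, p1x, p1y, q1x, q1y)) return true;
  return false;
}

static bool point_in_poly(const NumericMatrix& poly, double x, double y) {
  int n = poly.nrow(), j = n - 1;
  bool inside = false;
  for (int i = 0; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1), xj = poly(j, 0), yj = poly(j, 1);
    if (((yi > y) != (yj > y)) &&
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export(name = ".rw_path_cpp")]]
List rw_path_cpp(NumericMatrix poly, NumericMatrix inner_walls,
                 double start_x, double start_y, int n_steps,
                 double dt_ms, double sigma_speed_cmms,
                 double sigma_heading_deg, double vmax_cmms,
                 int max_retry) {
  RNGScope scope;
  int n = n_steps + 1;
  NumericMatrix pos(n, 2);
  NumericVector speed(n), heading(n);
  double x = start_x, y = start_y;
  double v = 0.0;                              // cm per ms
  double h = R::unif_rand() * 360.0;           // degrees, ccw from east
  const double d2r = M_PI / 180.0;
  int nwall = inner_walls.nrow();
  pos(0, 0) = x; pos(0, 1) = y; speed[0] = 0.0; heading[0] = h;

  auto legal = [&](double nx, double ny) {
    if (!point_in_poly(poly, nx, ny)) return false;
    for (int w = 0; w < nwall; ++w)
      if (seg_intersect(x, y, nx, ny, inner_walls(w, 0), inner_walls(w, 1),
                        inner_walls(w, 2), inner_walls(w, 3)))
        return false;
    return true;
  };

  for (int i = 1; i < n; ++i) {
    v += R::norm_rand() * sigma_speed_cmms;
    if (v < 0) v = 0; else if (v > vmax_cmms) v = vmax_cmms;
    double d = v * dt_ms;
    double hbase = h;
    double htry = hbase + R::norm_rand() * sigma_heading_deg;
    double nx = x + d * std::cos(htry * d2r);
    double ny = y + d * std::sin(htry * d2r);
    if (d > 0 && !legal(nx, ny)) {
      bool ok = false;
      for (int r = 0; r < max_retry; ++r) {
        htry = hbase + R::norm_rand() * sigma_heading_deg;
        nx = x + d * std::cos(htry * d2r);
        ny = y + d * std::sin(htry * d2r);
        if (legal(nx, ny)) { ok = true; break; }
      }
      if (!ok) {                              // reflect, else stand still
        htry = hbase + 180.0;
        nx = x + d * std::cos(htry * d2r);
        ny = y + d * std::sin(htry * d2r);
        if (!legal(nx, ny)) { nx = x; ny = y; v = 0.0; htry = hbase; }
      }
    }
    x = nx; y = ny;
    h = std::fmod(htry, 360.0); if (h < 0) h += 360.0;
    pos(i, 0) = x; pos(i, 1) = y;
    speed[i] = v * 1000.0;                    // report cm/s
    heading[i] = h;
  }
  return List::create(_["pos"] = pos, _["speed_cms"] = speed,
                      _["heading_deg"] = heading);
}

// ------------------------------------------------------------ grid engine

struct Disc {
  std::vector<int> dr, dc;
  explicit Disc(int radius) {
    for (int a = -radius; a <= radius; ++a)
      for (int b = -radius; b <= radius; ++b)
        if (a * a + b * b <= radius * radius) { dr.push_back(a); dc.push_back(b); }
  }
};

// preferred-direction layout inside each 2x2 tile, rows = y (north up):
//   (odd row, even col) -> N   (odd row, odd col) -> E
//   (even row, even col) -> W  (even row, odd col) -> S
// dir codes: 0 = E, 1 = N, 2 = W, 3 = S
static inline int unit_dir(int r, int c) {
  if (r & 1) return (c & 1) ? 0 : 1;
  return (c & 1) ? 3 : 2;
}

// [[Rcpp::export(name = ".unit_dirs_cpp")]]
IntegerVector unit_dirs_cpp(int nside) {
  IntegerVector out(nside * nside);
  for (int r = 0; r < nside; ++r)
    for (int c = 0; c < nside; ++c)
      out[r * nside + c] = unit_dir(r, c);
  return out;
}

// number of lattice points in the inhibition disc (out-degree of a unit)
// [[Rcpp::export(name = ".disc_size_cpp")]]
int disc_size_cpp(int radius) { return (int)Disc(radius).dr.size(); }

// Rebuild the shifted-disc convolved activation field from scratch.
static void build_field(const std::vector<double>& a, int nside, int shift,
                        const Disc& disc, std::vector<double>& F) {
  int mask = nside - 1;
  std::fill(F.begin(), F.end(), 0.0);
  int ndisc = (int)disc.dr.size();
  static const int sdx[4] = {1, 0, -1, 0};   // E N W S
  static const int sdy[4] = {0, 1, 0, -1};
  for (int r = 0; r < nside; ++r)
    for (int c = 0; c < nside; ++c) {
      double av = a[r * nside + c];
      if (av <= 1e-12) continue;
      int dir = unit_dir(r, c);
      int cr = r + shift * sdy[dir], cc = c + shift * sdx[dir];
      for (int k = 0; k < ndisc; ++k) {
        int rr = (cr + disc.dr[k]) & mask, c2 = (cc + disc.dc[k]) & mask;
        F[rr * nside + c2] += av;
      }
    }
}

// The full coupled network run.  `cfg` fields:
//   dt, kappa, alpha, decay (1 - dt/c), gamma
//   beta_border, beta_grid, beta_place
//   inhib_radius, inhib_shift, inhib_w, border_amp
//   lambda, xi_bg, xi_gp, place_inhib_w
//   learn (bool), rate_based (bool), snapshot (bool)
// modules: list of lists with nside, gain, a (init), w_bg (N x 32 or NULL)
// border_csr: list(ptr = int[n_steps+1], idx = int[] 0-based unit ids)
// place: list(aff = 500 x n_place int matrix of 0-based global grid ids,
//             w_gp = 500 x n_place, a = init activations) or NULL
// rec_grid: 0-based global grid unit ids to record (may be empty)
// pix: 0-based pixel index per step (or -1), used for snapshots and
//      rate-based count accumulation; npix: number of pixels
// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(NumericMatrix disp, IntegerVector pix, int npix,
                  List modules, List border_csr, Nullable<List> place_,
                  IntegerVector rec_grid, List cfg) {
  RNGScope scope;
  const int n_steps = disp.nrow();
  const double dt = as<double>(cfg["dt"]);
  const double kappa = as<double>(cfg["kappa"]);
  const double alpha = as<double>(cfg["alpha"]);
  const double decay = as<double>(cfg["decay"]);
  const double gamma = as<double>(cfg["gamma"]);
  const double beta_b = as<double>(cfg["beta_border"]);
  const double beta_g = as<double>(cfg["beta_grid"]);
  const double beta_p = as<double>(cfg["beta_place"]);
  const int    irad = as<int>(cfg["inhib_radius"]);
  const int    ishift = as<int>(cfg["inhib_shift"]);
  const double inhib_w = as<double>(cfg["inhib_w"]);
  const double border_amp = as<double>(cfg["border_amp"]);
  const double lambda = as<double>(cfg["lambda"]);
  const double xi_bg = as<double>(cfg["xi_bg"]);
  const double xi_gp = as<double>(cfg["xi_gp"]);
  const double p_inh = as<double>(cfg["place_inhib_w"]);
  const bool learn = as<bool>(cfg["learn"]);
  const bool rate_based = as<bool>(cfg["rate_based"]);
  const bool snapshot = as<bool>(cfg["snapshot"]);
  // record expected spike counts (probabilities) for recorded units even
  // under Bernoulli dynamics: denoises rate maps without changing the
  // network's stochastic evolution
  const bool rec_exp = cfg.containsElementNamed("record_expected") ?
    as<bool>(cfg["record_expected"]) : false;
  const double kdt = kappa * dt;

  Disc disc(irad);
  const int ndisc = (int)disc.dr.size();
  static const int sdx[4] = {1, 0, -1, 0};
  static const int sdy[4] = {0, 1, 0, -1};

  // ---- modules
  const int n_mod = modules.size();
  std::vector<int> nside(n_mod), nunit(n_mod), moff(n_mod + 1, 0);
  std::vector<double> gain(n_mod);
  std::vector<std::vector<double> > A(n_mod), F(n_mod), S(n_mod), P(n_mod);
  std::vector<NumericMatrix> Wbg(n_mod);
  std::vector<bool> has_wbg(n_mod, false);
  std::vector<std::vector<int> > dirs(n_mod);
  for (int m = 0; m < n_mod; ++m) {
    List mod = modules[m];
    nside[m] = as<int>(mod["nside"]);
    if (nside[m] & (nside[m] - 1))
      stop("sheet side must be a power of two");
    nunit[m] = nside[m] * nside[m];
    moff[m + 1] = moff[m] + nunit[m];
    gain[m] = as<double>(mod["gain"]);
    NumericVector a0 = mod["a"];
    if ((int)a0.size() != nunit[m]) stop("bad init activation length");
    A[m].assign(a0.begin(), a0.end());
    F[m].assign(nunit[m], 0.0);
    S[m].assign(nunit[m], 0.0);
    P[m].assign(nunit[m], 0.0);
    build_field(A[m], nside[m], ishift, disc, F[m]);
    dirs[m].resize(nunit[m]);
    for (int r = 0; r < nside[m]; ++r)
      for (int c = 0; c < nside[m]; ++c)
        dirs[m][r * nside[m] + c] = unit_dir(r, c);
    if (mod.containsElementNamed("w_bg") && !Rf_isNull(mod["w_bg"])) {
      Wbg[m] = as<NumericMatrix>(mod["w_bg"]);  // N x 32, modified in place copy
      Wbg[m] = clone(Wbg[m]);
      has_wbg[m] = true;
      if (Wbg[m].nrow() != nunit[m] || Wbg[m].ncol() != 32)
        stop("w_bg must be N x 32");
    }
  }
  const int n_grid_total = moff[n_mod];

  // ---- border layer
  IntegerVector bptr = border_csr["ptr"], bidx = border_csr["idx"];
  if ((int)bptr.size() != n_steps + 1) stop("border ptr length mismatch");
  std::vector<double> a_b(32, 0.0), s_b(32, 0.0), b_in(32, 0.0);

  // ---- place layer
  bool has_place = place_.isNotNull();
  IntegerMatrix aff; NumericMatrix Wgp;
  std::vector<double> a_p, s_p;
  int n_place = 0, n_aff = 0;
  if (has_place) {
    List place(place_);
    aff = as<IntegerMatrix>(place["aff"]);
    Wgp = clone(as<NumericMatrix>(place["w_gp"]));
    n_aff = aff.nrow(); n_place = aff.ncol();
    NumericVector ap0 = place["a"];
    a_p.assign(ap0.begin(), ap0.end());
    s_p.assign(n_place, 0.0);
  }

  // ---- recording
  const int n_rec = rec_grid.size();
  std::vector<int> rec_mod(n_rec), rec_loc(n_rec);
  for (int k = 0; k < n_rec; ++k) {
    int g = rec_grid[k];
    if (g < 0 || g >= n_grid_total) stop("recorded grid id out of range");
    int m = 0; while (g >= moff[m + 1]) ++m;
    rec_mod[k] = m; rec_loc[k] = g - moff[m];
  }
  std::vector<int> spk_unit, spk_step;       // grid spikes (spiking mode)
  std::vector<int> pspk_unit, pspk_step;     // place spikes
  std::vector<int> bspk_unit, bspk_step;     // border spikes
  NumericMatrix rec_counts, place_counts;    // expected-count accumulators
  if (rate_based || rec_exp) {
    rec_counts = NumericMatrix(n_rec, npix);
    if (has_place) place_counts = NumericMatrix(n_place, npix);
  }

  // ---- snapshots: one activation column per visited pixel, last visit wins
  std::vector<NumericMatrix> snap(n_mod);
  LogicalVector snap_seen(npix, false);
  if (snapshot)
    for (int m = 0; m < n_mod; ++m) snap[m] = NumericMatrix(nunit[m], npix);

  std::vector<double> bsum(0);
  std::vector<double> aff_sum(n_place, 0.0);

  for (int t = 0; t < n_steps; ++t) {
    const double dx = disp(t, 0), dy = disp(t, 1);

    // 1. border drive for this step
    double A_b = 0.0;
    for (int j = 0; j < 32; ++j) b_in[j] = 0.0;
    for (int k = bptr[t]; k < bptr[t + 1]; ++k) b_in[bidx[k]] = border_amp;

    // 2. border spiking + integration
    for (int j = 0; j < 32; ++j) {
      double p = kdt * (b_in[j] - beta_b);
      if (p < 0) p = 0; else if (p > 1) p = 1;
      double s;
      if (rate_based) s = p;
      else {
        s = (p > 0 && (p >= 1 || p > unif_rand())) ? 1.0 : 0.0;
        if (s > 0) { bspk_unit.push_back(j); bspk_step.push_back(t); }
      }
      s_b[j] = s;
      a_b[j] = a_b[j] * decay + alpha * s;
      A_b += a_b[j];
    }
    const bool border_on = A_b > 1e-10;

    // 3. grid modules
    for (int m = 0; m < n_mod; ++m) {
      const int ns = nside[m], N = nunit[m], mask = ns - 1;
      const double g = gain[m];
      // velocity input per preferred direction (E N W S)
      double vdir[4] = {gamma + g * dx, gamma + g * dy,
                        gamma - g * dx, gamma - g * dy};
      std::vector<double>& a = A[m];
      std::vector<double>& Fm = F[m];
      std::vector<double>& s = S[m];
      std::vector<double>& pm = P[m];
      const std::vector<int>& dr = dirs[m];
      double* wbg = has_wbg[m] ? REAL(Wbg[m]) : nullptr;

      for (int j = 0; j < N; ++j) {
        double b = vdir[dr[j]] + inhib_w * Fm[j];
        if (border_on && wbg) {
          double acc = 0.0;
          for (int i = 0; i < 32; ++i) {
            double ab = a_b[i];
            if (ab > 1e-12) acc += ab * wbg[j + (size_t)i * N];
          }
          b += acc;
        }
        double p = kdt * (b - beta_g);
        if (p < 0) p = 0; else if (p > 1) p = 1;
        pm[j] = p;
        if (rate_based) s[j] = p;
        else s[j] = (p > 0 && (p >= 1 || p > unif_rand())) ? 1.0 : 0.0;
      }
      // integrate activations and the convolved field together
      for (int j = 0; j < N; ++j) a[j] = a[j] * decay + alpha * s[j];
      for (int j = 0; j < N; ++j) Fm[j] *= decay;
      for (int j = 0; j < N; ++j) {
        double sv = s[j];
        if (sv <= 1e-12) continue;
        int r = j >> __builtin_ctz(ns), c = j & mask;   // j = r*ns + c
        int d4 = dr[j];
        int cr = r + ishift * sdy[d4], cc = c + ishift * sdx[d4];
        double add = alpha * sv;
        for (int k2 = 0; k2 < ndisc; ++k2) {
          int rr = (cr + disc.dr[k2]) & mask, c2 = (cc + disc.dc[k2]) & mask;
          Fm[rr * ns + c2] += add;
        }
      }
      // Hebbian border->grid (competitive rule, see hebbian_update in R)
      if (learn && border_on && wbg) {
        for (int i = 0; i < 32; ++i) {
          double abi = a_b[i];
          double* col = wbg + (size_t)i * N;
          for (int j = 0; j < N; ++j) {
            double aj = a[j];
            if (aj <= 1e-6) continue;
            double w = col[j];
            w += lambda * aj * (xi_bg * abi - w * A_b);
            col[j] = w < 0 ? 0 : w;
          }
        }
      }
    }

    // 4. place layer
    if (has_place) {
      double Ap_tot = 0.0;
      for (int j = 0; j < n_place; ++j) Ap_tot += a_p[j];
      for (int j = 0; j < n_place; ++j) {
        double acc = 0.0, asum = 0.0;
        for (int k = 0; k < n_aff; ++k) {
          int g = aff(k, j);
          int m = 0; while (g >= moff[m + 1]) ++m;
          double ag = A[m][g - moff[m]];
          acc += ag * Wgp(k, j);
          asum += ag;
        }
        aff_sum[j] = asum;
        double b = acc + p_inh * Ap_tot;
        double p = kdt * (b - beta_p);
        if (p < 0) p = 0; else if (p > 1) p = 1;
        if (rate_based) s_p[j] = p;
        else {
          s_p[j] = (p > 0 && (p >= 1 || p > unif_rand())) ? 1.0 : 0.0;
          if (s_p[j] > 0) { pspk_unit.push_back(j); pspk_step.push_back(t); }
        }
      }
      for (int j = 0; j < n_place; ++j) {
        a_p[j] = a_p[j] * decay + alpha * s_p[j];
        if (learn && a_p[j] > 1e-6) {
          double aj = a_p[j], As = aff_sum[j];
          if (As > 1e-10) {
            for (int k = 0; k < n_aff; ++k) {
              int g = aff(k, j);
              int m = 0; while (g >= moff[m + 1]) ++m;
              double ai = A[m][g - moff[m]];
              double w = Wgp(k, j);
              w += lambda * aj * (xi_gp * ai - w * As);
              Wgp(k, j) = w < 0 ? 0 : w;
            }
          }
        }
      }
    }

    // 5. recording and snapshots
    int px = pix[t];
    if (rate_based || rec_exp) {
      if (px >= 0) {
        for (int k = 0; k < n_rec; ++k)
          rec_counts(k, px) += P[rec_mod[k]][rec_loc[k]];
        if (has_place)
          for (int j = 0; j < n_place; ++j) place_counts(j, px) += s_p[j];
      }
    }
    if (!rate_based) {
      for (int k = 0; k < n_rec; ++k)
        if (S[rec_mod[k]][rec_loc[k]] > 0) {
          spk_unit.push_back(k); spk_step.push_back(t);
        }
    }
    if (snapshot && px >= 0) {
      snap_seen[px] = true;
      for (int m = 0; m < n_mod; ++m) {
        double* col = REAL(snap[m]) + (size_t)px * nunit[m];
        std::copy(A[m].begin(), A[m].end(), col);
      }
    }
  }

  // ---- pack results
  List mods_out(n_mod);
  for (int m = 0; m < n_mod; ++m) {
    mods_out[m] = List::create(
      _["a"] = NumericVector(A[m].begin(), A[m].end()),
      _["w_bg"] = has_wbg[m] ? (SEXP)Wbg[m] : R_NilValue);
  }
  List out = List::create(
    _["modules"] = mods_out,
    _["a_border"] = NumericVector(a_b.begin(), a_b.end()),
    _["border_spikes"] = List::create(
        _["unit"] = IntegerVector(bspk_unit.begin(), bspk_unit.end()),
        _["step"] = IntegerVector(bspk_step.begin(), bspk_step.end())),
    _["grid_spikes"] = List::create(
        _["slot"] = IntegerVector(spk_unit.begin(), spk_unit.end()),
        _["step"] = IntegerVector(spk_step.begin(), spk_step.end())),
    _["place_spikes"] = List::create(
        _["unit"] = IntegerVector(pspk_unit.begin(), pspk_unit.end()),
        _["step"] = IntegerVector(pspk_step.begin(), pspk_step.end())));
  if (rate_based || rec_exp) {
    out["rec_counts"] = rec_counts;
    if (has_place) out["place_counts"] = place_counts;
  }
  if (has_place) {
    out["a_place"] = NumericVector(a_p.begin(), a_p.end());
    out["w_gp"] = Wgp;
  }
  if (snapshot) {
    List sn(n_mod);
    for (int m = 0; m < n_mod; ++m) sn[m] = snap[m];
    out["snapshots"] = sn;
    out["snapshot_seen"] = snap_seen;
  }
  return out;
}
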