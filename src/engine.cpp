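#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cell fate codes shared with the R side
// 0 viable, 1 doomed (scheduled death), 2 senescent, 3 giant

// Neighbourhood shells: order k is Manhattan radius k (Von Neumann) or
// Chebyshev radius k (Moore). kind: 0 = Von Neumann, 1 = Moore.
static void shell_offsets(int kind, int k,
                          std::vector<int> &dx, std::vector<int> &dy) {
  dx.clear(); dy.clear();
  for (int a = -k; a <= k; ++a) {
    for (int b = -k; b <= k; ++b) {
      if (a == 0 && b == 0) continue;
      int cheb = std::max(std::abs(a), std::abs(b));
      int manh = std::abs(a) + std::abs(b);
      if ((kind == 1 && cheb == k) || (kind == 0 && manh == k)) {
        dx.push_back(a); dy.push_back(b);
      }
    }
  }
}

struct Engine {
  int n;                       // lattice side
  const int *mask;             // 1 = in well
  std::vector<int> occ;        // 0 empty, else cell index + 1
  // per-cell state (parallel vectors)
  std::vector<int> px, py, fate, ntog, gsize;
  std::vector<double> clock_, dur, dtime;
  std::vector<char> quiesc, alive;
  double mean_dur, sd_frac, p_mcat, p_sen;
  long created, removed;

  int at(int x, int y) const { return occ[(size_t)(x - 1) + (size_t)n * (y - 1)]; }
  void set(int x, int y, int v) { occ[(size_t)(x - 1) + (size_t)n * (y - 1)] = v; }
  bool inwell(int x, int y) const {
    return x >= 1 && x <= n && y >= 1 && y <= n &&
           mask[(size_t)(x - 1) + (size_t)n * (y - 1)];
  }

  double draw_duration() {
    // normal, truncated at +/- 3 sd (and > 0)
    double sd = sd_frac * mean_dur;
    if (sd <= 0.0) return mean_dur;
    for (;;) {
      double d = R::rnorm(mean_dur, sd);
      if (std::fabs(d - mean_dur) <= 3.0 * sd && d > 0.0) return d;
    }
  }

  // free voxels in the lowest non-empty shell up to `order`; returns shell
  // order or 0 if none; candidates in fx/fy
  int lowest_free_shell(int x, int y, int kind, int order,
                        std::vector<int> &fx, std::vector<int> &fy) {
    std::vector<int> dx, dy;
    for (int k = 1; k <= order; ++k) {
      shell_offsets(kind, k, dx, dy);
      fx.clear(); fy.clear();
      for (size_t j = 0; j < dx.size(); ++j) {
        int xx = x + dx[j], yy = y + dy[j];
        if (inwell(xx, yy) && at(xx, yy) == 0) { fx.push_back(xx); fy.push_back(yy); }
      }
      if (!fx.empty()) return k;
    }
    return 0;
  }

  int spawn(int x, int y, double clk, double duration, int f, double dth,
            int tog) {
    px.push_back(x); py.push_back(y);
    clock_.push_back(clk); dur.push_back(duration);
    fate.push_back(f); dtime.push_back(dth);
    ntog.push_back(tog); gsize.push_back(0);
    quiesc.push_back(0); alive.push_back(1);
    int idx = (int)px.size() - 1;
    set(x, y, idx + 1);
    ++created;
    return idx;
  }

  // attempt a division of cell i (already fated to divide normally);
  // returns true on success, false -> caller sends cell to G0
  bool try_divide(int i) {
    int kind = ntog[i];
    ntog[i] ^= 1;                       // alternate Moore / Von Neumann
    std::vector<int> fx, fy;
    if (!lowest_free_shell(px[i], py[i], kind, 3, fx, fy)) return false;
    int j = (int)std::floor(unif_rand() * fx.size());
    if (j >= (int)fx.size()) j = (int)fx.size() - 1;
    double ddur = draw_duration();
    int f = fate[i] == 1 ? 1 : 0;       // doomed daughters inherit death time
    double dth = fate[i] == 1 ? dtime[i] : R_PosInf;
    spawn(fx[j], fy[j], 0.0, ddur, f, dth, ntog[i]);
    clock_[i] = 0.0;                     // parent restarts in G1
    quiesc[i] = 0;
    return true;
  }

  void kill(int i) {
    set(px[i], py[i], 0);
    alive[i] = 0;
    ++removed;
  }
};

// [[Rcpp::export]]
List engine_run(IntegerVector occ, IntegerVector mask, int n,
                IntegerVector pos_x, IntegerVector pos_y,
                NumericVector clock_, NumericVector dur,
                IntegerVector fate, NumericVector death_time,
                IntegerVector ntoggle, IntegerVector giant_size,
                LogicalVector quiescent,
                double t0, double t_end, double dt, double lag_until,
                double mean_duration, double sd_fraction,
                double p_mcat, double p_sen,
                NumericVector cum_fractions,  // cumulative (G1, G1+S, G1+S+G2)
                NumericVector record_times,
                long created0, long removed0) {
  Engine e;
  e.n = n;
  e.mask = INTEGER(mask);
  e.occ.assign(occ.begin(), occ.end());
  int m = pos_x.size();
  e.px.assign(pos_x.begin(), pos_x.end());
  e.py.assign(pos_y.begin(), pos_y.end());
  e.clock_.assign(clock_.begin(), clock_.end());
  e.dur.assign(dur.begin(), dur.end());
  e.fate.assign(fate.begin(), fate.end());
  e.dtime.assign(death_time.begin(), death_time.end());
  e.ntog.assign(ntoggle.begin(), ntoggle.end());
  e.gsize.assign(giant_size.begin(), giant_size.end());
  e.quiesc.resize(m); e.alive.assign(m, 1);
  for (int i = 0; i < m; ++i) e.quiesc[i] = quiescent[i] ? 1 : 0;
  e.mean_dur = mean_duration; e.sd_frac = sd_fraction;
  e.p_mcat = p_mcat; e.p_sen = p_sen;
  e.created = created0; e.removed = removed0;

  int nrec = record_times.size();
  // columns: time, G1, S, G2, M, G0, doomed, senescent, giant, total
  NumericMatrix curve(nrec, 10);
  int next_rec = 0;
  double f1 = cum_fractions[0], f2 = cum_fractions[1], f3 = cum_fractions[2];

  std::vector<int> perm;

  auto record_at = [&](double now) {
    while (next_rec < nrec && record_times[next_rec] <= now + 1e-9) {
      double cnt[9] = {0};
      for (size_t i = 0; i < e.alive.size(); ++i) {
        if (!e.alive[i]) continue;
        int f = e.fate[i];
        if (f == 2) { cnt[6]++; }
        else if (f == 3) { cnt[7]++; }
        else if (f == 1) { cnt[5]++; }
        else if (e.quiesc[i]) { cnt[4]++; }
        else {
          double frac = e.dur[i] > 0 ? e.clock_[i] / e.dur[i] : 0.0;
          if (frac >= 1.0) frac = 1.0 - 1e-12;
          int ph = frac < f1 ? 0 : (frac < f2 ? 1 : (frac < f3 ? 2 : 3));
          cnt[ph]++;
        }
        cnt[8]++;
      }
      curve(next_rec, 0) = record_times[next_rec];
      for (int c = 0; c < 9; ++c) curve(next_rec, c + 1) = cnt[c];
      ++next_rec;
    }
  };

  record_at(t0);
  double now = t0;
  while (now < t_end - 1e-9) {
    double step = std::min(dt, t_end - now);
    // seeded random permutation of the cells existing at step start
    perm.clear();
    for (size_t i = 0; i < e.alive.size(); ++i)
      if (e.alive[i]) perm.push_back((int)i);
    for (int i = (int)perm.size() - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }

    for (size_t pi = 0; pi < perm.size(); ++pi) {
      int i = perm[pi];
      if (!e.alive[i]) continue;
      int f = e.fate[i];
      // scheduled deaths (doomed or giant) fire once their time has come
      if ((f == 1 || f == 3) && e.dtime[i] <= now + 1e-9) { e.kill(i); continue; }
      if (f == 2) continue;                       // senescent: inert
      if (now < lag_until - 1e-9) continue;       // attachment lag: clock frozen
      if (f == 3) {                               // giant: cycles, never divides
        e.clock_[i] += step;
        if (e.clock_[i] >= e.dur[i]) { e.gsize[i]++; e.clock_[i] = 0.0; }
        continue;
      }
      if (e.quiesc[i]) {
        // quiescent cells re-check for space each step and divide on success
        if (e.try_divide(i)) e.quiesc[i] = 0;
        continue;
      }
      e.clock_[i] += step;
      if (e.clock_[i] < e.dur[i]) continue;
      // cycle complete: doomed cells may enter mitotic catastrophe at M exit
      if (f == 1 && e.p_mcat > 0 && unif_rand() < e.p_mcat) {
        if (unif_rand() < e.p_sen) {
          e.fate[i] = 2; e.dtime[i] = R_PosInf;   // senescent: viable, arrested
        } else {
          e.fate[i] = 3; e.gsize[i] = 1;          // giant: keeps its death time
        }
        e.clock_[i] = 0.0;
        continue;
      }
      if (!e.try_divide(i)) {
        e.quiesc[i] = 1;                          // contact inhibition -> G0
        e.clock_[i] = e.dur[i];
      }
    }
    now += step;
    record_at(now);
  }

  // compact live cells and renumber the occupancy grid
  int alive_n = 0;
  for (size_t i = 0; i < e.alive.size(); ++i) if (e.alive[i]) ++alive_n;
  IntegerVector rx(alive_n), ry(alive_n), rf(alive_n), rt(alive_n),
      rg(alive_n);
  NumericVector rc(alive_n), rd(alive_n), rdt(alive_n);
  LogicalVector rq(alive_n);
  IntegerVector rocc((R_xlen_t)n * n);
  int k = 0;
  for (size_t i = 0; i < e.alive.size(); ++i) {
    if (!e.alive[i]) continue;
    rx[k] = e.px[i]; ry[k] = e.py[i];
    rc[k] = e.clock_[i]; rd[k] = e.dur[i];
    rf[k] = e.fate[i]; rdt[k] = e.dtime[i];
    rt[k] = e.ntog[i]; rg[k] = e.gsize[i];
    rq[k] = e.quiesc[i] != 0;
    rocc[(R_xlen_t)(e.px[i] - 1) + (R_xlen_t)n * (e.py[i] - 1)] = k + 1;
    ++k;
  }

  return List::create(
      _["pos_x"] = rx, _["pos_y"] = ry, _["clock"] = rc, _["duration"] = rd,
      _["fate"] = rf, _["death_time"] = rdt, _["ntoggle"] = rt,
      _["giant_size"] = rg, _["quiescent"] = rq, _["occ"] = rocc,
      _["curve"] = curve, _["created"] = (double)e.created,
      _["removed"] = (double)e.removed);
}

// Exposed for cross-checking the R-level neighbourhood enumeration against
// the engine's: returns free in-well voxels grouped by shell order.
// [[Rcpp::export]]
List cpp_free_spaces(IntegerVector occ, IntegerVector mask, int n,
                     int x, int y, int kind, int order) {
  std::vector<int> fx, fy, fo;
  std::vector<int> dx, dy;
  for (int k = 1; k <= order; ++k) {
    shell_offsets(kind, k, dx, dy);
    for (size_t j = 0; j < dx.size(); ++j) {
      int xx = x + dx[j], yy = y + dy[j];
      if (xx < 1 || xx > n || yy < 1 || yy > n) continue;
      size_t lin = (size_t)(xx - 1) + (size_t)n * (yy - 1);
      if (mask[lin] && occ[lin] == 0) {
        fx.push_back(xx); fy.push_back(yy); fo.push_back(k);
      }
    }
  }
  return List::create(_["x"] = wrap(fx), _["y"] = wrap(fy),
                      _["order"] = wrap(fo));
}
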