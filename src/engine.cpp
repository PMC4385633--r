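// Core per-tick world engine: movement, uniform-grid collision detection,
// behavioural rule resolution, membrane actions, timed catalysis, influx.
// All randomness is drawn from R's RNG so that set.seed() on the R side
// makes whole runs bit-reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double TWOPI = 6.283185307179586476925286766559;

struct Grid {
  int ncx, ncy;
  double cw, ch, W, H;
  std::vector<int> head, nxt;

  void init(double W_, double H_, double max_radius, int capacity) {
    W = W_; H = H_;
    double cell = 2.0 * max_radius;
    if (cell <= 0) cell = std::max(W, H);
    ncx = std::max(1, (int)std::floor(W / cell));
    ncy = std::max(1, (int)std::floor(H / cell));
    // keep the cell-list table bounded even for very small particles
    const int maxc = 1024;
    if (ncx > maxc) ncx = maxc;
    if (ncy > maxc) ncy = maxc;
    cw = W / ncx; ch = H / ncy;
    head.assign((size_t)ncx * ncy, -1);
    nxt.assign(capacity, -1);
  }
  inline int cellx(double x) const {
    int c = (int)std::floor(x / cw);
    if (c < 0) c = 0; if (c >= ncx) c = ncx - 1;
    return c;
  }
  inline int celly(double y) const {
    int c = (int)std::floor(y / ch);
    if (c < 0) c = 0; if (c >= ncy) c = ncy - 1;
    return c;
  }
  inline void insert(int i, double x, double y) {
    if ((int)nxt.size() <= i) nxt.resize(i + 256, -1);
    int c = celly(y) * ncx + cellx(x);
    nxt[i] = head[c];
    head[c] = i;
  }
  void clear() { std::fill(head.begin(), head.end(), -1); }
};

struct World {
  // species tables
  int S;
  std::vector<double> sp_radius, sp_step;
  std::vector<int> sp_mobile, sp_memact, sp_reconv; // memact: 0 reflect 1 reconvert 2 excrete
  // binding rules
  int NB;
  std::vector<int> bmap;               // S*S -> binding rule index or -1 (enzyme x cofactor)
  std::vector<int> bind_holo;
  // reaction rules
  int NR;
  std::vector<int> rmap;               // S*S -> reaction rule index or -1 (catalyst x substrate)
  std::vector<double> rx_p;
  std::vector<int> rx_tau, prod_start, prod_len, prod_sp;
  // arena
  double W_, H_, jitter;
  // agents
  std::vector<double> x, y, th;
  std::vector<int> sp, busy, pend, alive, id, lock;
  int next_id;
  // counters
  std::vector<int> n_bind, n_rx, n_ex;
  int step;
  long long n_influx;

  Grid grid;
  double max_radius;

  int n() const { return (int)x.size(); }

  void add_agent(int species, double px, double py, double heading) {
    x.push_back(px); y.push_back(py); th.push_back(heading);
    sp.push_back(species); busy.push_back(0); pend.push_back(0);
    alive.push_back(1); id.push_back(next_id++); lock.push_back(-1);
  }
};

inline double runif01() { return unif_rand(); }

inline double rand_heading() { return runif01() * TWOPI; }

inline double wrap_angle(double a) {
  a -= TWOPI * std::floor(a / TWOPI);
  if (a >= TWOPI) a = 0;
  return a;
}

// specular reflection of direction `a` about unit normal (nx, ny),
// applied only when approaching (dir . n < 0); jitter added regardless
inline double bounce(double a, double nx, double ny, double jitter) {
  double dx = std::cos(a), dy = std::sin(a);
  double dot = dx * nx + dy * ny;
  if (dot < 0) {
    dx -= 2.0 * dot * nx;
    dy -= 2.0 * dot * ny;
    a = std::atan2(dy, dx);
  }
  if (jitter > 0) a += jitter * (2.0 * runif01() - 1.0);
  return wrap_angle(a);
}

void shuffle(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(runif01() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// place one agent uniformly at random, rejecting positions that overlap
// agents already in the grid; after `tries` failures the last candidate is
// kept (crowded-arena fallback)
void place_random(World& w, int species, int tries) {
  double r = w.sp_radius[species];
  double px = 0, py = 0;
  bool ok = false;
  for (int t = 0; t < tries && !ok; ++t) {
    px = r + runif01() * (w.W_ - 2 * r);
    py = r + runif01() * (w.H_ - 2 * r);
    ok = true;
    int cx = w.grid.cellx(px), cy = w.grid.celly(py);
    for (int ddy = -1; ddy <= 1 && ok; ++ddy) {
      int yy = cy + ddy; if (yy < 0 || yy >= w.grid.ncy) continue;
      for (int ddx = -1; ddx <= 1 && ok; ++ddx) {
        int xx = cx + ddx; if (xx < 0 || xx >= w.grid.ncx) continue;
        for (int j = w.grid.head[yy * w.grid.ncx + xx]; j != -1; j = w.grid.nxt[j]) {
          if (!w.alive[j]) continue;
          double dx = px - w.x[j], dy = py - w.y[j];
          double rr = r + w.sp_radius[w.sp[j]];
          if (dx * dx + dy * dy < rr * rr) { ok = false; break; }
        }
      }
    }
  }
  w.add_agent(species, px, py, rand_heading());
  w.grid.insert(w.n() - 1, px, py);
}

void unpack(const List& world, World& w) {
  List spl = world["species"];
  w.sp_radius = as<std::vector<double> >(spl["radius"]);
  w.sp_step   = as<std::vector<double> >(spl["step_length"]);
  w.sp_mobile = as<std::vector<int> >(spl["mobile"]);
  w.sp_memact = as<std::vector<int> >(spl["membrane_action"]);
  w.sp_reconv = as<std::vector<int> >(spl["reconvert_to"]);
  w.S = (int)w.sp_radius.size();
  w.max_radius = 0;
  for (int s = 0; s < w.S; ++s) w.max_radius = std::max(w.max_radius, w.sp_radius[s]);

  IntegerMatrix bm = world["binding"];
  w.NB = bm.nrow();
  w.bmap.assign((size_t)w.S * w.S, -1);
  w.bind_holo.assign(w.NB, 0);
  for (int b = 0; b < w.NB; ++b) {
    int e = bm(b, 0) - 1, c = bm(b, 1) - 1;
    w.bmap[(size_t)e * w.S + c] = b;
    w.bind_holo[b] = bm(b, 2) - 1;
  }

  List rl = world["reactions"];
  std::vector<int> rcat = as<std::vector<int> >(rl["catalyst"]);
  std::vector<int> rsub = as<std::vector<int> >(rl["substrate"]);
  w.rx_p   = as<std::vector<double> >(rl["p_react"]);
  w.rx_tau = as<std::vector<int> >(rl["tau"]);
  w.prod_start = as<std::vector<int> >(rl["prod_start"]);
  w.prod_len   = as<std::vector<int> >(rl["prod_len"]);
  w.prod_sp    = as<std::vector<int> >(rl["prod_sp"]);
  w.NR = (int)w.rx_p.size();
  w.rmap.assign((size_t)w.S * w.S, -1);
  for (int r = 0; r < w.NR; ++r)
    w.rmap[(size_t)(rcat[r] - 1) * w.S + (rsub[r] - 1)] = r;

  List ar = world["arena"];
  w.W_ = as<double>(ar["width"]);
  w.H_ = as<double>(ar["height"]);
  w.jitter = as<double>(ar["jitter"]);

  List ag = world["agents"];
  w.x  = as<std::vector<double> >(ag["x"]);
  w.y  = as<std::vector<double> >(ag["y"]);
  w.th = as<std::vector<double> >(ag["heading"]);
  w.sp = as<std::vector<int> >(ag["species"]);
  for (size_t i = 0; i < w.sp.size(); ++i) w.sp[i] -= 1;
  w.busy = as<std::vector<int> >(ag["busy_until"]);
  w.pend = as<std::vector<int> >(ag["pending_rule"]);
  w.alive.assign(w.x.size(), 1);
  w.id   = as<std::vector<int> >(ag["agent_id"]);
  w.lock.assign(w.x.size(), -1);

  w.n_bind = as<std::vector<int> >(world["bind_count"]);
  w.n_rx   = as<std::vector<int> >(world["reaction_count"]);
  w.n_ex   = as<std::vector<int> >(world["excreted_count"]);
  w.step     = as<int>(world["step"]);
  w.next_id  = as<int>(world["next_id"]);
  w.n_influx = as<int>(world["influx_so_far"]);
}

void reorient_pair(World& w, int a, int b) {
  double dx = w.x[a] - w.x[b], dy = w.y[a] - w.y[b];
  double d = std::sqrt(dx * dx + dy * dy);
  double nx, ny;
  if (d < 1e-300) { double ang = rand_heading(); nx = std::cos(ang); ny = std::sin(ang); }
  else { nx = dx / d; ny = dy / d; }
  bool ma = w.sp_mobile[w.sp[a]] != 0, mb = w.sp_mobile[w.sp[b]] != 0;
  if (ma) w.th[a] = bounce(w.th[a], nx, ny, w.jitter);
  if (mb) w.th[b] = bounce(w.th[b], -nx, -ny, w.jitter);
  // push apart along the contact normal to exact tangency
  double ra = w.sp_radius[w.sp[a]], rb = w.sp_radius[w.sp[b]];
  double overlap = (ra + rb) - d;
  if (overlap > 0) {
    double eps = 1e-9 * (ra + rb);
    double push = overlap + eps;
    if (ma && mb) {
      w.x[a] += nx * push * 0.5; w.y[a] += ny * push * 0.5;
      w.x[b] -= nx * push * 0.5; w.y[b] -= ny * push * 0.5;
    } else if (ma) { w.x[a] += nx * push; w.y[a] += ny * push; }
    else if (mb)   { w.x[b] -= nx * push; w.y[b] -= ny * push; }
    if (ma) {
      w.x[a] = std::min(std::max(w.x[a], ra), w.W_ - ra);
      w.y[a] = std::min(std::max(w.y[a], ra), w.H_ - ra);
    }
    if (mb) {
      w.x[b] = std::min(std::max(w.x[b], rb), w.W_ - rb);
      w.y[b] = std::min(std::max(w.y[b], rb), w.H_ - rb);
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_run")]]
List cpp_run(List world, IntegerMatrix influx, int nsteps, bool record) {
  World w;
  unpack(world, w);

  int ncol = 1 + w.S + w.NB + w.NR + w.S;
  NumericMatrix series(record ? nsteps : 0, record ? ncol : 0);
  std::vector<int> counts(w.S, 0);
  std::vector<std::pair<int,int> > pairs;
  std::vector<int> order, pairidx;
  int infl_ptr = 0;
  // influx events are sorted by absolute step on the R side
  while (infl_ptr < influx.nrow() && influx(infl_ptr, 0) <= w.step) ++infl_ptr;

  for (int k = 0; k < nsteps; ++k) {
    int t = w.step + 1;

    // (1) influx: spawn scheduled agents at random non-overlapping positions
    if (infl_ptr < influx.nrow() && influx(infl_ptr, 0) == t) {
      w.grid.init(w.W_, w.H_, w.max_radius, w.n() + 64);
      for (int i = 0; i < w.n(); ++i)
        if (w.alive[i]) w.grid.insert(i, w.x[i], w.y[i]);
      while (infl_ptr < influx.nrow() && influx(infl_ptr, 0) == t) {
        int species = influx(infl_ptr, 1) - 1;
        int cnt = influx(infl_ptr, 2);
        for (int m = 0; m < cnt; ++m) { place_random(w, species, 100); w.n_influx++; }
        ++infl_ptr;
      }
    }

    // (2) move mobile agents in seeded-shuffled order; membrane actions on
    //     boundary crossing (busy complexes always reflect)
    order.clear();
    for (int i = 0; i < w.n(); ++i)
      if (w.alive[i] && w.sp_mobile[w.sp[i]]) order.push_back(i);
    shuffle(order);
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int i = order[oi];
      int s = w.sp[i];
      double step_len = w.sp_step[s];
      if (step_len <= 0) continue;
      double r = w.sp_radius[s];
      double nx = w.x[i] + step_len * std::cos(w.th[i]);
      double ny = w.y[i] + step_len * std::sin(w.th[i]);
      bool crossed = (nx < r || nx > w.W_ - r || ny < r || ny > w.H_ - r);
      if (!crossed) { w.x[i] = nx; w.y[i] = ny; continue; }
      int act = (w.busy[i] > 0) ? 0 : w.sp_memact[s];
      if (act == 2) {                      // excrete: leave the cell
        w.alive[i] = 0;
        w.n_ex[s] += 1;
        continue;
      }
      if (act == 1) {                      // reconvert in place, then reflect
        int s2 = w.sp_reconv[s] - 1;
        if (s2 >= 0) { w.sp[i] = s2; s = s2; r = w.sp_radius[s]; }
        nx = w.x[i]; ny = w.y[i];          // species swap happens where it stood
      }
      // specular wall reflection
      double a = w.th[i];
      if (nx < r || nx > w.W_ - r) a = std::atan2(std::sin(a), -std::cos(a));
      if (ny < r || ny > w.H_ - r) a = std::atan2(-std::sin(a), std::cos(a));
      if (w.jitter > 0) a += w.jitter * (2.0 * runif01() - 1.0);
      w.th[i] = wrap_angle(a);
      w.x[i] = std::min(std::max(nx, r), w.W_ - r);
      w.y[i] = std::min(std::max(ny, r), w.H_ - r);
    }

    // (3) collision detection on post-move positions (uniform grid);
    //     busy complexes ignore collisions, immobile pairs are inert
    w.grid.init(w.W_, w.H_, w.max_radius, w.n());
    for (int i = 0; i < w.n(); ++i)
      if (w.alive[i]) w.grid.insert(i, w.x[i], w.y[i]);
    pairs.clear();
    // only mobile agents drive the scan; mobile-mobile pairs are taken once
    // (j > i) and mobile-obstacle pairs always from the mobile side, so
    // immobile pairs are never visited
    for (int i = 0; i < w.n(); ++i) {
      if (!w.alive[i] || w.busy[i] > 0 || !w.sp_mobile[w.sp[i]]) continue;
      double xi = w.x[i], yi = w.y[i], ri = w.sp_radius[w.sp[i]];
      int cx = w.grid.cellx(xi), cy = w.grid.celly(yi);
      for (int ddy = -1; ddy <= 1; ++ddy) {
        int yy = cy + ddy; if (yy < 0 || yy >= w.grid.ncy) continue;
        for (int ddx = -1; ddx <= 1; ++ddx) {
          int xx = cx + ddx; if (xx < 0 || xx >= w.grid.ncx) continue;
          for (int j = w.grid.head[yy * w.grid.ncx + xx]; j != -1; j = w.grid.nxt[j]) {
            if (j == i || !w.alive[j] || w.busy[j] > 0) continue;
            bool mj = w.sp_mobile[w.sp[j]] != 0;
            if (mj && j < i) continue;
            double dx = xi - w.x[j], dy = yi - w.y[j];
            double rr = ri + w.sp_radius[w.sp[j]];
            if (dx * dx + dy * dy < rr * rr)
              pairs.push_back(std::make_pair(i, j));
          }
        }
      }
    }

    // (4) resolve colliding pairs in seeded-shuffled order; each agent takes
    //     part in at most one rule-triggering event per tick
    pairidx.resize(pairs.size());
    for (size_t p = 0; p < pairs.size(); ++p) pairidx[p] = (int)p;
    shuffle(pairidx);
    for (size_t pi = 0; pi < pairidx.size(); ++pi) {
      int a = pairs[pairidx[pi]].first, b = pairs[pairidx[pi]].second;
      if (!w.alive[a] || !w.alive[b]) continue;
      if (w.lock[a] == t || w.lock[b] == t) continue;
      if (w.busy[a] > 0 || w.busy[b] > 0) continue;
      int sa = w.sp[a], sb = w.sp[b];
      // cofactor binding
      int brule = w.bmap[(size_t)sa * w.S + sb];
      int enz = a, cof = b;
      if (brule < 0) { brule = w.bmap[(size_t)sb * w.S + sa]; enz = b; cof = a; }
      if (brule >= 0) {
        w.sp[enz] = w.bind_holo[brule];   // holoenzyme keeps enzyme position/heading
        w.alive[cof] = 0;
        w.n_bind[brule] += 1;
        w.lock[enz] = t; w.lock[cof] = t;
        continue;
      }
      // enzymatic catalysis
      int rrule = w.rmap[(size_t)sa * w.S + sb];
      int cat = a, sub = b;
      if (rrule < 0) { rrule = w.rmap[(size_t)sb * w.S + sa]; cat = b; sub = a; }
      if (rrule >= 0) {
        if (runif01() < w.rx_p[rrule]) {
          w.alive[sub] = 0;
          w.busy[cat] = t + w.rx_tau[rrule];
          w.pend[cat] = rrule + 1;
          w.lock[cat] = t; w.lock[sub] = t;
          continue;
        }
      }
      // no rule fired: reorient both and separate
      reorient_pair(w, a, b);
    }

    // (6) complete reactions whose busy interval ends this tick
    int n_before = w.n();
    for (int i = 0; i < n_before; ++i) {
      if (!w.alive[i] || w.pend[i] == 0 || w.busy[i] != t) continue;
      int r = w.pend[i] - 1;
      w.alive[i] = 0;
      w.n_rx[r] += 1;
      for (int m = 0; m < w.prod_len[r]; ++m) {
        int psp = w.prod_sp[w.prod_start[r] + m] - 1;
        w.add_agent(psp, w.x[i], w.y[i], rand_heading());
      }
    }

    w.step = t;

    // (7) record per-tick counts and cumulative event counters
    if (record) {
      std::fill(counts.begin(), counts.end(), 0);
      for (int i = 0; i < w.n(); ++i) if (w.alive[i]) counts[w.sp[i]] += 1;
      int c = 0;
      series(k, c++) = t;
      for (int s = 0; s < w.S; ++s) series(k, c++) = counts[s];
      for (int b = 0; b < w.NB; ++b) series(k, c++) = w.n_bind[b];
      for (int r = 0; r < w.NR; ++r) series(k, c++) = w.n_rx[r];
      for (int s = 0; s < w.S; ++s) series(k, c++) = w.n_ex[s];
    }
  }

  // compact: return live agents only
  int nl = 0;
  for (int i = 0; i < w.n(); ++i) if (w.alive[i]) ++nl;
  NumericVector ox(nl), oy(nl), oth(nl);
  IntegerVector osp(nl), obusy(nl), opend(nl), oid(nl);
  for (int i = 0, j = 0; i < w.n(); ++i) {
    if (!w.alive[i]) continue;
    ox[j] = w.x[i]; oy[j] = w.y[i]; oth[j] = w.th[i];
    osp[j] = w.sp[i] + 1; obusy[j] = w.busy[i]; opend[j] = w.pend[i];
    oid[j] = w.id[i];
    ++j;
  }
  return List::create(
    _["agents"] = List::create(
      _["agent_id"] = oid, _["x"] = ox, _["y"] = oy, _["heading"] = oth,
      _["species"] = osp, _["busy_until"] = obusy, _["pending_rule"] = opend),
    _["bind_count"] = IntegerVector(w.n_bind.begin(), w.n_bind.end()),
    _["reaction_count"] = IntegerVector(w.n_rx.begin(), w.n_rx.end()),
    _["excreted_count"] = IntegerVector(w.n_ex.begin(), w.n_ex.end()),
    _["step"] = w.step,
    _["next_id"] = w.next_id,
    _["influx_so_far"] = (int)w.n_influx,
    _["series"] = series);
}

// Rejection-sampled initial placement. `species` is the (1-based) species of
// each agent to place, in placement order; returns n x 2 positions.
// [[Rcpp::export(name = ".cpp_place")]]
NumericMatrix cpp_place(IntegerVector species, NumericVector radius_by_species,
                        double W, double H, int tries) {
  int n = species.size();
  World w;
  w.sp_radius = as<std::vector<double> >(radius_by_species);
  w.S = (int)w.sp_radius.size();
  w.sp_mobile.assign(w.S, 1);
  w.W_ = W; w.H_ = H; w.next_id = 1;
  w.max_radius = 0;
  for (int s = 0; s < w.S; ++s) w.max_radius = std::max(w.max_radius, w.sp_radius[s]);
  w.grid.init(W, H, w.max_radius, n);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    place_random(w, species[i] - 1, tries);
    out(i, 0) = w.x[i];
    out(i, 1) = w.y[i];
  }
  return out;
}

// Grid-accelerated circle-circle collision detection; returns the unordered
// pairs (i < j, 1-based) with centre distance strictly below the combined
// radius, ordered by (i, j).
// [[Rcpp::export(name = ".cpp_detect_grid")]]
IntegerMatrix cpp_detect_grid(NumericVector x, NumericVector y, NumericVector r,
                              double W, double H) {
  int n = x.size();
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, (double)r[i]);
  Grid g;
  g.init(W, H, rmax, n);
  for (int i = 0; i < n; ++i) g.insert(i, x[i], y[i]);
  std::vector<std::pair<int,int> > pairs;
  for (int i = 0; i < n; ++i) {
    int cx = g.cellx(x[i]), cy = g.celly(y[i]);
    for (int ddy = -1; ddy <= 1; ++ddy) {
      int yy = cy + ddy; if (yy < 0 || yy >= g.ncy) continue;
      for (int ddx = -1; ddx <= 1; ++ddx) {
        int xx = cx + ddx; if (xx < 0 || xx >= g.ncx) continue;
        for (int j = g.head[yy * g.ncx + xx]; j != -1; j = g.nxt[j]) {
          if (j <= i) continue;
          double dx = x[i] - x[j], dy = y[i] - y[j];
          double rr = r[i] + r[j];
          if (dx * dx + dy * dy < rr * rr)
            pairs.push_back(std::make_pair(i, j));
        }
      }
    }
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); ++p) {
    out((int)p, 0) = pairs[p].first + 1;
    out((int)p, 1) = pairs[p].second + 1;
  }
  return out;
}
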