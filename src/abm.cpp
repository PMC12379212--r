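// Agent-based simulation core: yearly-step spatial dynamics with movement,
// horizontal learning, mating/reproduction with recombination, and age- plus
// density-dependent mortality. All randomness goes through R's RNG so runs
// are reproducible with set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int N_LOCI = 247;    // marker loci per haplotype, 1 per Mb
static const int N_MARK = 494;    // diploid marker count
static const double MORGANS = 2.47;  // 247 Mb at 1 cM/Mb

// ---------------------------------------------------------------------------
// Landscape

struct Mask {
  const int* hab;        // column-major logical matrix, row 1 = top of map
  const int* route;      // overlay id per cell (0 = none), may be null
  const double* rsx;     // on-route sigma_x per cell, may be null
  const double* rsy;
  const double* habfrac; // habitable fraction of competition disk, may be null
  int nr, nc;
  double cell, W, H;

  bool inside(double x, double y) const {
    return x >= 0 && x <= W && y >= 0 && y <= H;
  }
  int cell_of(double x, double y) const {  // column-major linear index
    int col = std::min(std::max((int)std::floor(x / cell), 0), nc - 1);
    int row = std::min(std::max((int)std::floor((H - y) / cell), 0), nr - 1);
    return row + col * nr;
  }
  bool habitable(double x, double y) const {
    return inside(x, y) && hab[cell_of(x, y)] != 0;
  }
  int route_at(double x, double y) const {
    return route ? route[cell_of(x, y)] : 0;
  }
};

// ---------------------------------------------------------------------------
// Uniform spatial hash over the bounding box

struct Grid {
  double cs;
  int ngx, ngy;
  std::vector<int> start, items;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             double W, double H, double cell_size) {
    cs = cell_size;
    ngx = std::max(1, (int)std::ceil(W / cs));
    ngy = std::max(1, (int)std::ceil(H / cs));
    int n = (int)x.size();
    std::vector<int> cnt(ngx * ngy + 1, 0);
    std::vector<int> cid(n);
    for (int i = 0; i < n; i++) {
      int gx = std::min(std::max((int)(x[i] / cs), 0), ngx - 1);
      int gy = std::min(std::max((int)(y[i] / cs), 0), ngy - 1);
      cid[i] = gx * ngy + gy;
      cnt[cid[i] + 1]++;
    }
    for (size_t k = 1; k < cnt.size(); k++) cnt[k] += cnt[k - 1];
    start = cnt;
    items.assign(n, 0);
    std::vector<int> fill = start;
    for (int i = 0; i < n; i++) items[fill[cid[i]]++] = i;
  }

  // visit all individuals in cells overlapping the disk around (px, py)
  template <class F>
  void visit(double px, double py, double r, F f) const {
    int gx0 = std::max(0, (int)((px - r) / cs));
    int gx1 = std::min(ngx - 1, (int)((px + r) / cs));
    int gy0 = std::max(0, (int)((py - r) / cs));
    int gy1 = std::min(ngy - 1, (int)((py + r) / cs));
    for (int gx = gx0; gx <= gx1; gx++)
      for (int gy = gy0; gy <= gy1; gy++) {
        int c = gx * ngy + gy;
        for (int k = start[c]; k < start[c + 1]; k++) f(items[k]);
      }
  }
};

// ---------------------------------------------------------------------------
// Population state (structure of arrays; genomes as packed 0/1 bytes)

struct Pop {
  std::vector<double> x, y;
  std::vector<int> age;
  std::vector<uint8_t> cult;   // 0 = hunter-gatherer, 1 = farmer
  std::vector<uint8_t> gen;    // N_MARK * n, column per individual
  int n() const { return (int)x.size(); }
};

struct Params {
  double f;             // yearly learning rate
  double m;             // within-group mating probability
  double lambda;        // Poisson offspring rate per successful mating
  int maturity;         // mature iff age >= maturity
  double comp_radius, mate_radius, learn_radius;
  double expectedF, expectedHG;  // expected neighbours at (downscaled) K
  std::vector<double> hazard;    // yearly hazard by age; beyond end -> 1
  double sx, sy;        // base step sigmas
  bool offspring_random_culture;  // farmer-HG offspring: random parent's culture
  int max_attempts;
};

static double hazard_at(const Params& P, int age) {
  if (age < 0) return 0.0;
  if (age >= (int)P.hazard.size()) return 1.0;
  return P.hazard[age];
}

// ---------------------------------------------------------------------------
// Movement: Gaussian displacement with rejection against the mask; on-route
// individuals keep or leave the corridor with equal probability.

static void move_one(const Mask& M, const Params& P, double& px, double& py) {
  int rid = M.route_at(px, py);
  double sx = P.sx, sy = P.sy;
  bool constrain = false, want_on = false;
  if (rid > 0) {
    bool stay = unif_rand() < 0.5;
    constrain = true;
    want_on = stay;
    if (stay) {
      int c = M.cell_of(px, py);
      sx = M.rsx[c];
      sy = M.rsy[c];
    }
  }
  if (sx == 0 && sy == 0) return;
  for (int a = 0; a < P.max_attempts; a++) {
    double nx = px + norm_rand() * sx;
    double ny = py + norm_rand() * sy;
    if (!M.habitable(nx, ny)) continue;
    if (constrain) {
      bool on = M.route_at(nx, ny) == rid;
      if (on != want_on) continue;
    }
    px = nx;
    py = ny;
    return;
  }
}

static void move_step(Pop& pop, const Mask& M, const Params& P) {
  for (int i = 0; i < pop.n(); i++) move_one(M, P, pop.x[i], pop.y[i]);
}

// ---------------------------------------------------------------------------
// Learning: each HG converts with probability f * local farmer proportion
// (neighbours within learn_radius, focal excluded). Synchronous update.

static void learning_probs(const Pop& pop, const Grid& G, const Params& P,
                           std::vector<double>& prob) {
  int n = pop.n();
  prob.assign(n, 0.0);
  double r2 = P.learn_radius * P.learn_radius;
  for (int i = 0; i < n; i++) {
    if (pop.cult[i] != 0) continue;
    int all = 0, farmers = 0;
    G.visit(pop.x[i], pop.y[i], P.learn_radius, [&](int j) {
      if (j == i) return;
      double dx = pop.x[j] - pop.x[i], dy = pop.y[j] - pop.y[i];
      if (dx * dx + dy * dy <= r2) {
        all++;
        if (pop.cult[j]) farmers++;
      }
    });
    if (all > 0) prob[i] = P.f * (double)farmers / (double)all;
  }
}

static int learning_step(Pop& pop, const Grid& G, const Params& P) {
  std::vector<double> prob;
  learning_probs(pop, G, P, prob);
  int conv = 0;
  for (int i = 0; i < pop.n(); i++) {
    if (prob[i] > 0 && unif_rand() < prob[i]) {
      pop.cult[i] = 1;
      conv++;
    }
  }
  return conv;
}

// ---------------------------------------------------------------------------
// Meiosis: gamete built by walking the 247 Mb map with Poisson crossovers
// (1 cM/Mb, expected 2.47 per meiosis); starting haplotype uniform.

static void meiosis(const uint8_t* parent, uint8_t* gamete) {
  int k = (int)R::rpois(MORGANS);
  double xov[32];
  if (k > 32) k = 32;
  for (int c = 0; c < k; c++) xov[c] = unif_rand() * N_LOCI;
  std::sort(xov, xov + k);
  int hap = unif_rand() < 0.5 ? 0 : 1;
  int c = 0;
  for (int j = 0; j < N_LOCI; j++) {
    double posn = j + 0.5;   // marker midpoints, 1 per Mb
    while (c < k && xov[c] < posn) {
      hap ^= 1;
      c++;
    }
    gamete[j] = parent[hap * N_LOCI + j];
  }
}

// ---------------------------------------------------------------------------
// Reproduction: every mature individual seeks a mate within mate_radius
// (same-culture with probability m, any culture otherwise); on success draws
// Poisson(lambda) offspring placed at the chooser's position.

struct Newborns {
  std::vector<double> x, y;
  std::vector<uint8_t> cult;
  std::vector<uint8_t> gen;
};

static void reproduction_step(const Pop& pop, const Grid& G, const Params& P,
                              Newborns& nb) {
  int n = pop.n();
  double r2 = P.mate_radius * P.mate_radius;
  std::vector<int> cand;
  for (int i = 0; i < n; i++) {
    if (pop.age[i] < P.maturity) continue;
    bool restrict = unif_rand() < P.m;
    cand.clear();
    G.visit(pop.x[i], pop.y[i], P.mate_radius, [&](int j) {
      if (j == i || pop.age[j] < P.maturity) return;
      if (restrict && pop.cult[j] != pop.cult[i]) return;
      double dx = pop.x[j] - pop.x[i], dy = pop.y[j] - pop.y[i];
      if (dx * dx + dy * dy <= r2) cand.push_back(j);
    });
    if (cand.empty()) continue;
    int mate = cand[std::min((int)(unif_rand() * cand.size()),
                             (int)cand.size() - 1)];
    int noff = (int)R::rpois(P.lambda);
    for (int o = 0; o < noff; o++) {
      nb.x.push_back(pop.x[i]);
      nb.y.push_back(pop.y[i]);
      uint8_t culture;
      if (pop.cult[i] == pop.cult[mate]) culture = pop.cult[i];
      else if (P.offspring_random_culture)
        culture = unif_rand() < 0.5 ? pop.cult[i] : pop.cult[mate];
      else culture = 1;  // mixed matings produce farmers
      nb.cult.push_back(culture);
      size_t at = nb.gen.size();
      nb.gen.resize(at + N_MARK);
      meiosis(&pop.gen[(size_t)i * N_MARK], &nb.gen[at]);
      meiosis(&pop.gen[(size_t)mate * N_MARK], &nb.gen[at + N_LOCI]);
    }
  }
}

static void append_newborns(Pop& pop, const Newborns& nb) {
  int k = (int)nb.x.size();
  for (int i = 0; i < k; i++) {
    pop.x.push_back(nb.x[i]);
    pop.y.push_back(nb.y[i]);
    pop.age.push_back(0);
    pop.cult.push_back(nb.cult[i]);
  }
  pop.gen.insert(pop.gen.end(), nb.gen.begin(), nb.gen.end());
}

// ---------------------------------------------------------------------------
// Mortality: experienced hazard = equilibrium hazard x local pressure, where
// pressure = neighbours within comp_radius / expected at the focal group's
// (downscaled) K, optionally corrected for the habitable fraction of the
// competition disk. Survivors age one year.

static void mortality_probs(const Pop& pop, const Grid& G, const Mask& M,
                            const Params& P, std::vector<double>& prob) {
  int n = pop.n();
  prob.assign(n, 0.0);
  double r2 = P.comp_radius * P.comp_radius;
  for (int i = 0; i < n; i++) {
    int cnt = 0;
    G.visit(pop.x[i], pop.y[i], P.comp_radius, [&](int j) {
      if (j == i) return;
      double dx = pop.x[j] - pop.x[i], dy = pop.y[j] - pop.y[i];
      if (dx * dx + dy * dy <= r2) cnt++;
    });
    double expected = pop.cult[i] ? P.expectedF : P.expectedHG;
    if (M.habfrac) {
      double hf = M.habfrac[M.cell_of(pop.x[i], pop.y[i])];
      if (hf > 0) expected *= hf;
    }
    double pressure = (double)cnt / expected;
    prob[i] = std::min(1.0, hazard_at(P, pop.age[i]) * pressure);
  }
}

static void mortality_step(Pop& pop, const Grid& G, const Mask& M,
                           const Params& P) {
  std::vector<double> prob;
  mortality_probs(pop, G, M, P, prob);
  int n = pop.n(), keep = 0;
  for (int i = 0; i < n; i++) {
    if (unif_rand() < prob[i]) continue;
    if (keep != i) {
      pop.x[keep] = pop.x[i];
      pop.y[keep] = pop.y[i];
      pop.age[keep] = pop.age[i];
      pop.cult[keep] = pop.cult[i];
      std::copy(&pop.gen[(size_t)i * N_MARK],
                &pop.gen[(size_t)i * N_MARK + N_MARK],
                &pop.gen[(size_t)keep * N_MARK]);
    }
    pop.age[keep] += 1;
    keep++;
  }
  pop.x.resize(keep);
  pop.y.resize(keep);
  pop.age.resize(keep);
  pop.cult.resize(keep);
  pop.gen.resize((size_t)keep * N_MARK);
}

// ---------------------------------------------------------------------------
// Front extent: farmer proportion in n_bins X-bins; the extent is the centre
// of the farthest bin of the contiguous >=50% block starting at the origin.

static double front_extent_cpp(const Pop& pop, double W, int n_bins) {
  std::vector<int> tot(n_bins, 0), farm(n_bins, 0);
  double bw = W / n_bins;
  for (int i = 0; i < pop.n(); i++) {
    int b = std::min(std::max((int)(pop.x[i] / bw), 0), n_bins - 1);
    tot[b]++;
    if (pop.cult[i]) farm[b]++;
  }
  double extent = 0.0;
  for (int b = 0; b < n_bins; b++) {
    if (tot[b] > 0 && farm[b] * 2 >= tot[b]) extent = (b + 0.5) * bw;
    else break;
  }
  return extent;
}

// ---------------------------------------------------------------------------
// Conversions between R objects and internal state

static Pop pop_from_r(const NumericVector& x, const NumericVector& y,
                      const IntegerVector& age, const IntegerVector& cult,
                      const RawMatrix& gen) {
  Pop p;
  int n = x.size();
  if (gen.nrow() != N_MARK || gen.ncol() != n)
    stop("genome matrix must be 494 x n");
  p.x.assign(x.begin(), x.end());
  p.y.assign(y.begin(), y.end());
  p.age.assign(age.begin(), age.end());
  p.cult.resize(n);
  for (int i = 0; i < n; i++) p.cult[i] = (uint8_t)cult[i];
  p.gen.assign(gen.begin(), gen.end());
  return p;
}

static List pop_to_r(const Pop& p) {
  int n = p.n();
  RawMatrix gen(N_MARK, n);
  std::copy(p.gen.begin(), p.gen.end(), gen.begin());
  IntegerVector cult(n);
  NumericVector anc(n);
  for (int i = 0; i < n; i++) {
    cult[i] = p.cult[i];
    int s = 0;
    for (int j = 0; j < N_MARK; j++) s += p.gen[(size_t)i * N_MARK + j];
    anc[i] = (double)s / N_MARK;
  }
  return List::create(_["x"] = NumericVector(p.x.begin(), p.x.end()),
                      _["y"] = NumericVector(p.y.begin(), p.y.end()),
                      _["age"] = IntegerVector(p.age.begin(), p.age.end()),
                      _["culture"] = cult, _["genome"] = gen,
                      _["ancestry"] = anc);
}

static Mask mask_from_r(const List& mask) {
  // the caller's `mask` list protects the matrices we take pointers into
  Mask M;
  IntegerMatrix hab = mask["grid_int"];
  M.hab = INTEGER(hab);
  M.nr = hab.nrow();
  M.nc = hab.ncol();
  M.cell = as<double>(mask["cell_size"]);
  M.W = as<double>(mask["width_km"]);
  M.H = as<double>(mask["height_km"]);
  M.route = nullptr;
  M.rsx = M.rsy = M.habfrac = nullptr;
  return M;
}

static Params params_from_r(const List& par) {
  Params P;
  P.f = as<double>(par["f"]);
  P.m = as<double>(par["m"]);
  P.lambda = as<double>(par["fertility"]);
  P.maturity = as<int>(par["maturity_age"]);
  P.comp_radius = as<double>(par["comp_radius"]);
  P.mate_radius = as<double>(par["mate_radius"]);
  P.learn_radius = as<double>(par["learn_radius"]);
  P.expectedF = as<double>(par["expectedF"]);
  P.expectedHG = as<double>(par["expectedHG"]);
  P.hazard = as<std::vector<double>>(par["hazard"]);
  NumericVector sg = par["sigma"];
  P.sx = sg[0];
  P.sy = sg[1];
  P.offspring_random_culture = as<bool>(par["offspring_random_culture"]);
  P.max_attempts = as<int>(par["max_attempts"]);
  return P;
}

// ---------------------------------------------------------------------------
// Exported step kernels (used by the R-level operations and unit tests)

// [[Rcpp::export]]
NumericMatrix cpp_move(NumericVector x, NumericVector y, List mask, List par) {
  Mask M = mask_from_r(mask);
  if (mask.containsElementNamed("route_int") &&
      !Rf_isNull(mask["route_int"])) {
    IntegerMatrix ri = mask["route_int"];
    NumericMatrix sx = mask["route_sx"], sy = mask["route_sy"];
    M.route = INTEGER(ri);
    M.rsx = REAL(sx);
    M.rsy = REAL(sy);
    Params P = params_from_r(par);
    NumericMatrix out(x.size(), 2);
    for (int i = 0; i < x.size(); i++) {
      double px = x[i], py = y[i];
      move_one(M, P, px, py);
      out(i, 0) = px;
      out(i, 1) = py;
    }
    return out;
  }
  Params P = params_from_r(par);
  NumericMatrix out(x.size(), 2);
  for (int i = 0; i < x.size(); i++) {
    double px = x[i], py = y[i];
    move_one(M, P, px, py);
    out(i, 0) = px;
    out(i, 1) = py;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbour_counts(NumericVector x, NumericVector y,
                                   IntegerVector culture, double radius,
                                   double W, double H) {
  Pop pop;
  pop.x.assign(x.begin(), x.end());
  pop.y.assign(y.begin(), y.end());
  int n = x.size();
  pop.cult.resize(n);
  for (int i = 0; i < n; i++) pop.cult[i] = (uint8_t)culture[i];
  Grid G;
  G.build(pop.x, pop.y, W, H, radius);
  IntegerMatrix out(n, 2);  // all, farmers (self excluded)
  double r2 = radius * radius;
  for (int i = 0; i < n; i++) {
    int all = 0, farm = 0;
    G.visit(pop.x[i], pop.y[i], radius, [&](int j) {
      if (j == i) return;
      double dx = pop.x[j] - pop.x[i], dy = pop.y[j] - pop.y[i];
      if (dx * dx + dy * dy <= r2) {
        all++;
        if (pop.cult[j]) farm++;
      }
    });
    out(i, 0) = all;
    out(i, 1) = farm;
  }
  return out;
}

// [[Rcpp::export]]
RawVector cpp_meiosis(RawVector parent) {
  if (parent.size() != N_MARK) stop("parent genome must have 494 entries");
  RawVector gamete(N_LOCI);
  meiosis(RAW(parent), RAW(gamete));
  return gamete;
}

// [[Rcpp::export]]
NumericVector cpp_learning_probs(NumericVector x, NumericVector y,
                                 IntegerVector culture, double W, double H,
                                 List par) {
  Pop pop;
  pop.x.assign(x.begin(), x.end());
  pop.y.assign(y.begin(), y.end());
  pop.cult.resize(x.size());
  for (int i = 0; i < x.size(); i++) pop.cult[i] = (uint8_t)culture[i];
  Params P = params_from_r(par);
  Grid G;
  G.build(pop.x, pop.y, W, H, std::max(P.learn_radius, 1.0));
  std::vector<double> prob;
  learning_probs(pop, G, P, prob);
  return NumericVector(prob.begin(), prob.end());
}

// [[Rcpp::export]]
List cpp_reproduction(NumericVector x, NumericVector y, IntegerVector age,
                      IntegerVector culture, RawMatrix genome, double W,
                      double H, List par) {
  Pop pop = pop_from_r(x, y, age, culture, genome);
  Params P = params_from_r(par);
  Grid G;
  G.build(pop.x, pop.y, W, H, std::max(P.mate_radius, 1.0));
  Newborns nb;
  reproduction_step(pop, G, P, nb);
  Pop off;
  off.x = nb.x;
  off.y = nb.y;
  off.cult = nb.cult;
  off.age.assign(nb.x.size(), 0);
  off.gen = nb.gen;
  return pop_to_r(off);
}

// [[Rcpp::export]]
NumericVector cpp_mortality_probs(NumericVector x, NumericVector y,
                                  IntegerVector age, IntegerVector culture,
                                  List mask, List par) {
  Mask M = mask_from_r(mask);
  if (mask.containsElementNamed("habfrac") && !Rf_isNull(mask["habfrac"])) {
    NumericMatrix hf = mask["habfrac"];
    M.habfrac = REAL(hf);
  }
  Pop pop;
  pop.x.assign(x.begin(), x.end());
  pop.y.assign(y.begin(), y.end());
  pop.age.assign(age.begin(), age.end());
  pop.cult.resize(x.size());
  for (int i = 0; i < x.size(); i++) pop.cult[i] = (uint8_t)culture[i];
  Params P = params_from_r(par);
  Grid G;
  G.build(pop.x, pop.y, M.W, M.H, P.comp_radius);
  std::vector<double> prob;
  mortality_probs(pop, G, M, P, prob);
  return NumericVector(prob.begin(), prob.end());
}

// [[Rcpp::export]]
double cpp_front_extent(NumericVector x, IntegerVector culture, double W,
                        int n_bins) {
  Pop pop;
  pop.x.assign(x.begin(), x.end());
  pop.cult.resize(x.size());
  for (int i = 0; i < x.size(); i++) pop.cult[i] = (uint8_t)culture[i];
  return front_extent_cpp(pop, W, n_bins);
}

// ---------------------------------------------------------------------------
// Full yearly loop. Event order: permutation of 1=move, 2=learn,
// 3=reproduce, 4=mortality. Terminates early when no HGs remain (after
// `settle_years` additional years so the landscape fills in).

// [[Rcpp::export]]
List cpp_run_abm(NumericVector x, NumericVector y, IntegerVector age,
                 IntegerVector culture, RawMatrix genome, List mask, List par,
                 int years, IntegerVector order, int front_bins,
                 int settle_years) {
  Mask M = mask_from_r(mask);
  IntegerMatrix ri;
  NumericMatrix rsx, rsy, hf;
  if (mask.containsElementNamed("route_int") &&
      !Rf_isNull(mask["route_int"])) {
    ri = as<IntegerMatrix>(mask["route_int"]);
    rsx = as<NumericMatrix>(mask["route_sx"]);
    rsy = as<NumericMatrix>(mask["route_sy"]);
    M.route = INTEGER(ri);
    M.rsx = REAL(rsx);
    M.rsy = REAL(rsy);
  }
  if (mask.containsElementNamed("habfrac") && !Rf_isNull(mask["habfrac"])) {
    hf = as<NumericMatrix>(mask["habfrac"]);
    M.habfrac = REAL(hf);
  }
  Pop pop = pop_from_r(x, y, age, culture, genome);
  Params P = params_from_r(par);

  std::vector<double> extents;
  extents.reserve(years);
  int completion_year = NA_INTEGER;
  bool extinct = false;
  int yr = 0, settle_left = -1;

  for (yr = 1; yr <= years; yr++) {
    Grid Gsmall, Gcomp;
    for (int k = 0; k < order.size(); k++) {
      switch (order[k]) {
      case 1:
        move_step(pop, M, P);
        break;
      case 2:
        if (P.f > 0) {
          Gsmall.build(pop.x, pop.y, M.W, M.H, std::max(P.learn_radius, 1.0));
          learning_step(pop, Gsmall, P);
        }
        break;
      case 3: {
        Grid Gm;
        Gm.build(pop.x, pop.y, M.W, M.H, std::max(P.mate_radius, 1.0));
        Newborns nb;
        reproduction_step(pop, Gm, P, nb);
        append_newborns(pop, nb);
        break;
      }
      case 4:
        Gcomp.build(pop.x, pop.y, M.W, M.H, P.comp_radius);
        mortality_step(pop, Gcomp, M, P);
        break;
      }
    }
    if (pop.n() == 0) {
      extinct = true;
      break;
    }
    extents.push_back(front_extent_cpp(pop, M.W, front_bins));
    int hg = 0;
    for (int i = 0; i < pop.n(); i++) hg += pop.cult[i] == 0;
    if (hg == 0 && completion_year == NA_INTEGER) {
      completion_year = yr;
      settle_left = settle_years;
    }
    if (settle_left >= 0 && settle_left-- == 0) break;
    if (yr % 50 == 0) Rcpp::checkUserInterrupt();
  }

  List snap = pop_to_r(pop);
  snap["years_run"] = std::min(yr, years);
  snap["completion_year"] = completion_year;
  snap["extinct"] = extinct;
  snap["front_extents"] = NumericVector(extents.begin(), extents.end());
  return snap;
}
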