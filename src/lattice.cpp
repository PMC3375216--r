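#include <Rcpp.h>
using namespace Rcpp;

// Occupancy states of a grid spot.
static const int EMPTY = 0, SUSC = 1, INF = 2;

// Moore neighborhood offsets (8 nearest neighbors).
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline int draw_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Asynchronous stochastic update of the virus/cell lattice.
//
// Each time step performs N^2 sequential random spot draws (uniform with
// replacement) on a single evolving grid. For an occupied spot the action
// (division for uninfected, transmission for infected) is attempted first
// with probability weight/Lambda; if no action occurred the cell dies with
// probability weight/Lambda. Lambda = max(1, R, D, B, A) maps weights that
// exceed one onto probabilities while preserving all rate ratios.
// Offspring/virus go to a uniformly chosen Moore neighbor; the event silently
// fails if the destination is off-grid (hard walls), occupied (division) or
// not susceptible (transmission). scheme = 0 selects the alternative
// single-draw convention with disjoint death-then-action windows and
// Lambda = max(1, R + D, A + B) (used for internal comparisons only).
//
// [[Rcpp::export]]
List lattice_run_cpp(IntegerMatrix grid0, double R, double D, double B,
                     double A, int max_steps, int record_every,
                     bool keep_snapshots, int scheme = 1) {
  RNGScope rngScope;
  const int N = grid0.nrow();
  if (grid0.ncol() != N) stop("grid must be square");
  const int NN = N * N;

  IntegerMatrix g = clone(grid0);

  double lambda;
  if (scheme == 0)
    lambda = std::max(1.0, std::max(R + D, A + B));
  else
    lambda = std::max(std::max(1.0, R), std::max(std::max(D, B), A));
  const double pR = R / lambda, pD = D / lambda;
  const double pB = B / lambda, pA = A / lambda;

  int nS = 0, nI = 0;
  bool boundary = false;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      int st = g(i, j);
      if (st == SUSC) ++nS;
      else if (st == INF) ++nI;
      if (st != EMPTY && (i == 0 || j == 0 || i == N - 1 || j == N - 1))
        boundary = true;
    }

  std::vector<int> rec_t, rec_S, rec_I, rec_bnd;
  rec_t.reserve(max_steps + 1); rec_S.reserve(max_steps + 1);
  rec_I.reserve(max_steps + 1); rec_bnd.reserve(max_steps + 1);
  rec_t.push_back(0); rec_S.push_back(nS); rec_I.push_back(nI);
  rec_bnd.push_back(boundary ? 1 : 0);

  List snaps; std::vector<int> snap_t;
  if (keep_snapshots) { snaps.push_back(clone(g)); snap_t.push_back(0); }

  std::string termination = "MAX_STEPS";
  int t = 0;
  int max_I = nI;
  // infection-free runs (pure growth experiments) are not terminated by
  // the virus-extinction rule
  const bool hadI = nI > 0;

  if (nS == 0 && nI == 0) termination = "CELLS_EXTINCT";

  while (t < max_steps && (nI > 0 || !hadI) && (nS + nI > 0)) {
    for (int s = 0; s < NN; ++s) {
      int idx = draw_int(NN);
      int i = idx % N, j = idx / N;
      int st = g(i, j);
      if (st == EMPTY) continue;

      bool acted = false, dies = false;
      if (scheme == 0) {
        // disjoint windows: death first, then action
        double u = unif_rand();
        double pdie = (st == SUSC) ? pD : pA;
        double pact = (st == SUSC) ? pR : pB;
        if (u < pdie) dies = true;
        else if (u < pdie + pact) acted = true;
      } else {
        // action first; death only when no action occurred
        double pact = (st == SUSC) ? pR : pB;
        if (unif_rand() < pact) acted = true;
        else if (unif_rand() < ((st == SUSC) ? pD : pA)) dies = true;
      }

      if (acted) {
        int d = draw_int(8);
        int ni = i + DR[d], nj = j + DC[d];
        if (ni >= 0 && ni < N && nj >= 0 && nj < N) {
          if (st == SUSC && g(ni, nj) == EMPTY) {
            g(ni, nj) = SUSC; ++nS;
            if (ni == 0 || nj == 0 || ni == N - 1 || nj == N - 1)
              boundary = true;
          } else if (st == INF && g(ni, nj) == SUSC) {
            g(ni, nj) = INF; --nS; ++nI;
            if (nI > max_I) max_I = nI;
          }
        }
      } else if (dies) {
        g(i, j) = EMPTY;
        if (st == SUSC) --nS; else --nI;
      }
    }
    ++t;
    rec_t.push_back(t); rec_S.push_back(nS); rec_I.push_back(nI);
    rec_bnd.push_back(boundary ? 1 : 0);
    if (keep_snapshots && (t % record_every == 0)) {
      snaps.push_back(clone(g)); snap_t.push_back(t);
    }
    if (nS + nI == 0) {
      termination = "CELLS_EXTINCT";
      break;
    }
    if (hadI && nI == 0) {
      termination = "VIRUS_EXTINCT";
      break;
    }
  }
  if (keep_snapshots && (snap_t.empty() || snap_t.back() != t)) {
    snaps.push_back(clone(g)); snap_t.push_back(t);
  }

  return List::create(
      _["t"] = wrap(rec_t), _["n_S"] = wrap(rec_S), _["n_I"] = wrap(rec_I),
      _["boundary_contacted"] = wrap(rec_bnd), _["grid"] = g,
      _["snapshots"] = snaps, _["snap_t"] = wrap(snap_t),
      _["termination"] = termination, _["max_I"] = max_I,
      _["boundary"] = boundary);
}
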