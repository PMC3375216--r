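#include <Rcpp.h>
using namespace Rcpp;

// Exact continuous-time (Gillespie direct method) simulation of the 1D
// stochastic metapopulation: n patches with local logistic birth of
// susceptibles, frequency-scaled infection beta*S*I/k, linear deaths, and
// nearest-neighbor migration at rate m/2 per side (hard walls: the off-chain
// channels are absent, so end patches emigrate at half the interior rate).
//
// Per-patch total rates are maintained incrementally (the touched patch is
// recomputed after every event); every `check_every` events the global total
// is recomputed from scratch and the worst discrepancy is reported, guarding
// the bookkeeping.

struct PatchRates {
  double birth, inf, sdeath, ideath, smigL, smigR, imigL, imigR;
  double total() const {
    return birth + inf + sdeath + ideath + smigL + smigR + imigL + imigR;
  }
};

static inline PatchRates patch_rates(int i, int n, double S, double I,
                                     double r, double beta, double a, double d,
                                     double k, double mS, double mI) {
  PatchRates p;
  double crowd = 1.0 - (S + I) / k;
  p.birth = r * S * (crowd > 0 ? crowd : 0.0);
  p.inf = beta * S * I / k;
  p.sdeath = d * S;
  p.ideath = a * I;
  p.smigL = (i > 0) ? 0.5 * mS * S : 0.0;
  p.smigR = (i < n - 1) ? 0.5 * mS * S : 0.0;
  p.imigL = (i > 0) ? 0.5 * mI * I : 0.0;
  p.imigR = (i < n - 1) ? 0.5 * mI * I : 0.0;
  return p;
}

// [[Rcpp::export]]
List metapop_run_cpp(IntegerVector S0, IntegerVector I0, double r, double beta,
                     double a, double d, double k, double mS, double mI,
                     double t_max, NumericVector record_times,
                     NumericVector profile_times, int check_every = 1000) {
  RNGScope rngScope;
  const int n = S0.size();
  if (I0.size() != n) stop("S and I must have equal length");

  std::vector<double> S(n), I(n);
  for (int i = 0; i < n; ++i) { S[i] = S0[i]; I[i] = I0[i]; }

  std::vector<double> prate(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    prate[i] = patch_rates(i, n, S[i], I[i], r, beta, a, d, k, mS, mI).total();
    total += prate[i];
  }

  double totS = 0, totI = 0;
  for (int i = 0; i < n; ++i) { totS += S[i]; totI += I[i]; }
  // boundary contact tracks the target-cell wave: stray infected migrants
  // carry no offspring potential of their own
  bool boundary = (S[0] > 0) || (S[n - 1] > 0);
  double max_totI = totI;
  // infection-free runs (pure growth/migration experiments) are not
  // terminated by the virus-extinction rule
  const bool hadI = totI > 0;

  const int nrec = record_times.size();
  NumericVector rec_S(nrec), rec_I(nrec);
  const int nprof = profile_times.size();
  NumericMatrix prof_S(nprof, n), prof_I(nprof, n);
  int irec = 0, iprof = 0;
  double t = 0.0;
  double max_discrepancy = 0.0;
  long long nev = 0;
  std::string termination = "T_MAX";

  auto flush_records = [&](double upto) {
    while (irec < nrec && record_times[irec] <= upto) {
      rec_S[irec] = totS; rec_I[irec] = totI; ++irec;
    }
    while (iprof < nprof && profile_times[iprof] <= upto) {
      for (int i = 0; i < n; ++i) {
        prof_S(iprof, i) = S[i]; prof_I(iprof, i) = I[i];
      }
      ++iprof;
    }
  };

  while (t < t_max) {
    if (total <= 0) {
      termination = (totI == 0 && totS == 0) ? "CELLS_EXTINCT"
                    : (totI == 0 ? "VIRUS_EXTINCT" : "FROZEN");
      break;
    }
    double dt = exp_rand() / total;
    double t_next = t + dt;
    flush_records(std::min(t_next, t_max));
    if (t_next >= t_max) { t = t_max; break; }
    t = t_next;

    // pick the patch, then the channel within it
    double u = unif_rand() * total;
    int i = 0;
    for (; i < n - 1; ++i) {
      if (u < prate[i]) break;
      u -= prate[i];
    }
    PatchRates pr = patch_rates(i, n, S[i], I[i], r, beta, a, d, k, mS, mI);
    int touched2 = -1;
    if (u < pr.birth) { S[i] += 1; totS += 1; }
    else if ((u -= pr.birth) < pr.inf) { S[i] -= 1; I[i] += 1; totI += 1; totS -= 1; }
    else if ((u -= pr.inf) < pr.sdeath) { S[i] -= 1; totS -= 1; }
    else if ((u -= pr.sdeath) < pr.ideath) { I[i] -= 1; totI -= 1; }
    else if ((u -= pr.ideath) < pr.smigL) { S[i] -= 1; S[i - 1] += 1; touched2 = i - 1; }
    else if ((u -= pr.smigL) < pr.smigR) { S[i] -= 1; S[i + 1] += 1; touched2 = i + 1; }
    else if ((u -= pr.smigR) < pr.imigL) { I[i] -= 1; I[i - 1] += 1; touched2 = i - 1; }
    else { I[i] -= 1; I[i + 1] += 1; touched2 = i + 1; }

    if (totI > max_totI) max_totI = totI;
    if (touched2 == 0 || touched2 == n - 1 || i == 0 || i == n - 1)
      if (S[0] > 0 || S[n - 1] > 0) boundary = true;

    double old = prate[i];
    prate[i] = patch_rates(i, n, S[i], I[i], r, beta, a, d, k, mS, mI).total();
    total += prate[i] - old;
    if (touched2 >= 0) {
      old = prate[touched2];
      prate[touched2] = patch_rates(touched2, n, S[touched2], I[touched2], r,
                                    beta, a, d, k, mS, mI).total();
      total += prate[touched2] - old;
    }

    ++nev;
    if (nev % check_every == 0) {
      double fresh = 0.0;
      for (int j = 0; j < n; ++j)
        fresh += patch_rates(j, n, S[j], I[j], r, beta, a, d, k, mS, mI).total();
      double disc = std::fabs(fresh - total);
      if (disc > max_discrepancy) max_discrepancy = disc;
      total = fresh;
    }

    if (hadI && totI == 0) {
      termination = (totS == 0) ? "CELLS_EXTINCT" : "VIRUS_EXTINCT";
      break;
    }
  }
  flush_records(t_max);
  // pad any unreached record/profile points with the final (absorbed) state
  while (irec < nrec) { rec_S[irec] = totS; rec_I[irec] = totI; ++irec; }
  while (iprof < nprof) {
    for (int i = 0; i < n; ++i) {
      prof_S(iprof, i) = S[i]; prof_I(iprof, i) = I[i];
    }
    ++iprof;
  }

  NumericVector Sf(n), If(n);
  for (int i = 0; i < n; ++i) { Sf[i] = S[i]; If[i] = I[i]; }
  return List::create(
      _["t_end"] = t, _["sum_S"] = rec_S, _["sum_I"] = rec_I,
      _["record_times"] = record_times, _["profile_S"] = prof_S,
      _["profile_I"] = prof_I, _["profile_times"] = profile_times,
      _["S"] = Sf, _["I"] = If, _["termination"] = termination,
      _["max_sum_I"] = max_totI, _["boundary_contacted"] = boundary,
      _["n_events"] = (double)nev, _["rate_discrepancy"] = max_discrepancy);
}
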