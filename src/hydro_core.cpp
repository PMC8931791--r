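// Daily two-layer soil-water dynamics for a period of days with fixed
// vegetation cover. This is the performance core behind runScenario(); the
// exported R function stepDay() implements the identical process order
// (precipitation -> infiltration -> runoff routing -> percolation ->
// diffusion -> evaporation -> transpiration) and a testthat block asserts
// equivalence of the two paths.
//
// Transpiration is factorized over "uptake groups": types sharing the same
// wilting point and root profile. Within a day, every type in a group sees
// the same water-limitation term g(theta) and rationing factor f, so the
// per-type transpiration over a period of constant cover is
//   T_t = cover_t * uptake_t * sum_days(PET * rootFrac_l * g * f)
// which the R side reconstructs from the returned per-group sums.

#include <Rcpp.h>
using namespace Rcpp;

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Hargreaves-type potential evapotranspiration (mm/day); fixed seasonal
// radiation proxy for a southern-hemisphere site (maximum at the December
// solstice) with a constant diurnal-range term folded in.
static inline double petDailyC(double temp, int doy) {
  double ra = (14.0 + 3.5 * std::cos(2.0 * M_PI * (doy - 355.0) / 365.0)) *
              2.8284271247461903; // sqrt(8)
  double pet = 0.0023 * ra * (temp + 17.8);
  return pet > 0.0 ? pet : 0.0;
}

// [[Rcpp::export(name = ".hydroPeriodCpp")]]
List hydroPeriodCpp(NumericVector thetaU0, NumericVector thetaL0,
                    NumericVector surface0, NumericMatrix coverUptake,
                    IntegerVector groupOf, NumericVector groupWp,
                    NumericVector groupRfU, NumericVector groupRfL,
                    NumericVector precip, NumericVector temp,
                    IntegerVector doy, LogicalVector inSeason,
                    IntegerVector receiver, NumericVector soil,
                    NumericVector constants, NumericVector totCover) {
  const int ncell = thetaU0.size();
  const int ntype = coverUptake.ncol();
  const int ndays = precip.size();
  const int G = groupWp.size();

  const double du = soil["depthUpper"], dl = soil["depthLower"];
  const double por = soil["porosity"];
  const double fcU = soil["fcUpper"], fcL = soil["fcLower"];
  const double res = soil["residualWater"];
  const double ksat = soil["satConductivity"];
  const double econst = soil["evaporationConstant"];
  const double dcoef = soil["diffusionCoeff"];
  const double c0 = constants["infiltrationBare"];
  const double rough = constants["roughness"];
  const double shade = constants["shading"];
  const double gStress = constants["stressThreshold"];

  NumericVector thetaU = clone(thetaU0), thetaL = clone(thetaL0),
                surface = clone(surface0);

  // per-cell totals and per-group cover*uptake aggregates (cover is fixed
  // within the period; coverUptake holds cover_t * uptake_t)
  // cu is cell-major (cell i, group g at i*G+g) for cache locality
  std::vector<double> totcov(ncell, 0.0), cu(ncell * G, 0.0);
  for (int i = 0; i < ncell; ++i) totcov[i] = std::min(totCover[i], 1.0);
  for (int t = 0; t < ntype; ++t) {
    const int g = groupOf[t];
    for (int i = 0; i < ncell; ++i) cu[i * G + g] += coverUptake(i, t);
  }

  // inverse slopes of the water-limitation ramp per group and layer
  std::vector<double> invU(G), invL(G);
  double wpMin = 1.0;
  for (int g = 0; g < G; ++g) {
    invU[g] = fcU > groupWp[g] ? 1.0 / (fcU - groupWp[g]) : 0.0;
    invL[g] = fcL > groupWp[g] ? 1.0 / (fcL - groupWp[g]) : 0.0;
    if (groupWp[g] < wpMin) wpMin = groupWp[g];
  }

  NumericMatrix groupS(ncell, 2 * G);     // sum of PET*g*f per group/layer
  IntegerMatrix stressG(ncell, G);        // growing-season stress days
  NumericVector evapSum(ncell), transpUpperSum(ncell), transpSum(ncell);
  NumericVector thetaUDaily(ndays), thetaLDaily(ndays);
  NumericVector thetaUCellSum(ncell);
  double percTotal = 0.0, deepTotal = 0.0, diffTotal = 0.0,
         infilTotal = 0.0;
  std::vector<double> transfer(ncell), gvalU(G), gvalL(G);

  for (int d = 0; d < ndays; ++d) {
    const double pet = petDailyC(temp[d], doy[d]);
    const double p = precip[d];
    const bool seasonDay = inSeason[d];

    for (int i = 0; i < ncell; ++i) {
      surface[i] += p;
      double ksatEff = ksat * (c0 + (1.0 - c0) * totcov[i]);
      double cap = (por - thetaU[i]) * du;
      double infil = std::min(surface[i], std::min(cap, ksatEff));
      if (infil < 0.0) infil = 0.0;
      surface[i] -= infil;
      thetaU[i] += infil / du;
      infilTotal += infil;
    }

    bool anyFlow = false;
    for (int i = 0; i < ncell; ++i) {
      if (receiver[i] >= 0 && surface[i] > 0.0) {
        transfer[i] = surface[i] * (1.0 - rough * totcov[i]);
        anyFlow = true;
      } else {
        transfer[i] = 0.0;
      }
    }
    if (anyFlow) {
      for (int i = 0; i < ncell; ++i) {
        if (transfer[i] > 0.0) {
          surface[i] -= transfer[i];
          surface[receiver[i]] += transfer[i];
        }
      }
    }

    double thetaUSum = 0.0, thetaLSum = 0.0;
    for (int i = 0; i < ncell; ++i) {
      double excess = (thetaU[i] - fcU) * du;
      if (excess > 0.0) {
        double perc = std::min(excess, ksat);
        perc = std::min(perc, (por - thetaL[i]) * dl);
        if (perc > 0.0) {
          thetaU[i] -= perc / du;
          thetaL[i] += perc / dl;
          percTotal += perc;
        }
      }
      double dexc = (thetaL[i] - fcL) * dl;
      if (dexc > 0.0) {
        double deep = std::min(dexc, ksat);
        thetaL[i] -= deep / dl;
        deepTotal += deep;
      }
      if (dcoef > 0.0 && thetaU[i] > thetaL[i]) {
        double dif = std::min(dcoef, (thetaU[i] - res) * du);
        dif = std::min(dif, (por - thetaL[i]) * dl);
        if (dif > 0.0) {
          thetaU[i] -= dif / du;
          thetaL[i] += dif / dl;
          diffTotal += dif;
        }
      }
      double wet = clip01((thetaU[i] - res) / (fcU - res));
      double ev = pet * econst * wet * (1.0 - shade * totcov[i]);
      double evMax = (thetaU[i] - res) * du;
      if (ev > evMax) ev = evMax;
      if (ev < 0.0) ev = 0.0;
      thetaU[i] -= ev / du;
      evapSum[i] += ev;

      // transpiration, upper then lower layer, factorized by group
      for (int layer = 0; layer < 2; ++layer) {
        const double th = layer == 0 ? thetaU[i] : thetaL[i];
        if (th <= wpMin) continue;  // drier than every wilting point
        const double dd = layer == 0 ? du : dl;
        double demand = 0.0, minwp = 1.0;
        std::vector<double> &gval = layer == 0 ? gvalU : gvalL;
        const double *inv = layer == 0 ? invU.data() : invL.data();
        const double *rfv = layer == 0 ? &groupRfU[0] : &groupRfL[0];
        for (int g = 0; g < G; ++g) {
          const double w = cu[i * G + g] * rfv[g];
          if (w <= 0.0) { gval[g] = 0.0; continue; }
          const double gv = clip01((th - groupWp[g]) * inv[g]);
          if (gv > 0.0) {
            demand += pet * gv * w;
            if (groupWp[g] < minwp) minwp = groupWp[g];
          }
          gval[g] = gv;
        }
        if (demand > 0.0) {
          double avail = (th - minwp) * dd;
          if (avail < 0.0) avail = 0.0;
          double f = demand > avail ? avail / demand : 1.0;
          for (int g = 0; g < G; ++g) {
            if (gval[g] > 0.0 && cu[i * G + g] * rfv[g] > 0.0)
              groupS(i, layer * G + g) += pet * gval[g] * f;
          }
          const double taken = demand * f;
          if (layer == 0) {
            thetaU[i] -= taken / dd;
            transpUpperSum[i] += taken;
          } else {
            thetaL[i] -= taken / dd;
          }
          transpSum[i] += taken;
        }
      }

      // a stress day: uptake ability in the type's principal rooting
      // layer below the threshold
      if (seasonDay) {
        for (int g = 0; g < G; ++g) {
          const double th = groupRfL[g] > groupRfU[g] ? thetaL[i]
                                                      : thetaU[i];
          const double inv = groupRfL[g] > groupRfU[g] ? invL[g] : invU[g];
          if (clip01((th - groupWp[g]) * inv) < gStress)
            stressG(i, g) += 1;
        }
      }
      thetaUSum += thetaU[i];
      thetaLSum += thetaL[i];
      thetaUCellSum[i] += thetaU[i];
    }
    thetaUDaily[d] = thetaUSum / ncell;
    thetaLDaily[d] = thetaLSum / ncell;
  }

  return List::create(
    _["thetaU"] = thetaU, _["thetaL"] = thetaL, _["surface"] = surface,
    _["groupS"] = groupS, _["stressG"] = stressG,
    _["evapSum"] = evapSum, _["transpUpperSum"] = transpUpperSum,
    _["transpSum"] = transpSum, _["thetaUDaily"] = thetaUDaily,
    _["thetaLDaily"] = thetaLDaily, _["thetaUCellSum"] = thetaUCellSum,
    _["percolation"] = percTotal, _["deepDrainage"] = deepTotal,
    _["diffusion"] = diffTotal, _["infiltration"] = infilTotal);
}

// Weighted neighbourhood aggregation for seed dispersal: for every type
// column, the per-target-cell weighted mean of source-cell values over the
// given offsets, with per-cell weight renormalization at closed
// boundaries (a uniform field is a fixed point).
// [[Rcpp::export(name = ".kernelMeanCpp")]]
NumericMatrix kernelMeanCpp(NumericMatrix values, int nr, int nc,
                            IntegerMatrix offsets, NumericVector weights) {
  const int ncell = values.nrow();
  const int K = values.ncol();
  const int M = offsets.nrow();
  NumericMatrix acc(ncell, K);
  std::vector<double> wacc(ncell, 0.0);
  for (int m = 0; m < M; ++m) {
    const int di = offsets(m, 0), dj = offsets(m, 1);
    const double w = weights[m];
    for (int j = 0; j < nc; ++j) {
      const int sj = j + dj;
      if (sj < 0 || sj >= nc) continue;
      const int i0 = std::max(0, -di), i1 = std::min(nr, nr - di);
      for (int i = i0; i < i1; ++i) {
        const int tgt = j * nr + i;
        const int src = sj * nr + (i + di);
        wacc[tgt] += w;
        for (int k = 0; k < K; ++k) acc(tgt, k) += w * values(src, k);
      }
    }
  }
  for (int t = 0; t < ncell; ++t) {
    if (wacc[t] > 0.0)
      for (int k = 0; k < K; ++k) acc(t, k) /= wacc[t];
  }
  return acc;
}

// Biweekly growth increments with the shared per-meta growth cap and the
// free-space budget; mirrors the R rules in stepBiweek().
// [[Rcpp::export(name = ".growStepCpp")]]
NumericMatrix growStepCpp(NumericMatrix cover, NumericMatrix transp,
                          IntegerVector metaOf, NumericVector tVeg,
                          NumericVector maxGrow, LogicalVector dynamic,
                          double wue) {
  const int ncell = cover.nrow(), ntype = cover.ncol();
  int nmeta = 0;
  for (int t = 0; t < ntype; ++t) nmeta = std::max(nmeta, metaOf[t] + 1);
  NumericMatrix out = clone(cover);
  std::vector<double> inc(ntype), metaSum(nmeta), metaCap(nmeta, 0.0);
  for (int t = 0; t < ntype; ++t) metaCap[metaOf[t]] = maxGrow[t];
  for (int i = 0; i < ncell; ++i) {
    double fs = 1.0;
    for (int t = 0; t < ntype; ++t) fs -= cover(i, t);
    if (fs < 0.0) fs = 0.0;
    if (fs == 0.0) continue;
    double tot = 0.0;
    std::fill(metaSum.begin(), metaSum.end(), 0.0);
    for (int t = 0; t < ntype; ++t) {
      double v = 0.0;
      if (dynamic[t] && cover(i, t) > 0.0) {
        v = tVeg[t] * wue * transp(i, t) * fs;
        if (v > maxGrow[t]) v = maxGrow[t];
        if (v > fs) v = fs;
      }
      inc[t] = v;
      metaSum[metaOf[t]] += v;
    }
    // shared per-meta cap
    for (int t = 0; t < ntype; ++t) {
      const int m = metaOf[t];
      if (metaSum[m] > metaCap[m] && metaSum[m] > 0.0)
        inc[t] *= metaCap[m] / metaSum[m];
    }
    for (int t = 0; t < ntype; ++t) tot += inc[t];
    // proportional scaling into the remaining free space
    double f = (tot > fs && tot > 0.0) ? fs / tot : 1.0;
    for (int t = 0; t < ntype; ++t) out(i, t) += inc[t] * f;
  }
  return out;
}

// Establishment increments with moisture gate, per-type establishment
// probability and stochastic rounding; uses the R RNG stream.
// [[Rcpp::export(name = ".establishCpp")]]
NumericMatrix establishCpp(NumericMatrix cover, NumericMatrix seedBank,
                           NumericVector thetaUMean, NumericVector wp,
                           NumericVector pEst, LogicalVector dynamic,
                           double estMargin, double quantum) {
  const int ncell = cover.nrow(), ntype = cover.ncol();
  NumericMatrix out = clone(cover);
  std::vector<double> inc(ntype);
  std::vector<bool> anyBank(ntype, false);
  for (int t = 0; t < ntype; ++t) {
    if (!dynamic[t]) continue;
    for (int i = 0; i < ncell; ++i)
      if (seedBank(i, t) > 0.0) { anyBank[t] = true; break; }
  }
  RNGScope scope;
  for (int i = 0; i < ncell; ++i) {
    double fs = 1.0;
    for (int t = 0; t < ntype; ++t) fs -= cover(i, t);
    if (fs <= 0.0) continue;
    double tot = 0.0;
    for (int t = 0; t < ntype; ++t) {
      double v = 0.0;
      if (anyBank[t] && thetaUMean[i] > wp[t] + estMargin &&
          seedBank(i, t) > 0.0) {
        const double mu = pEst[t] * seedBank(i, t) * fs;
        const double n = mu / quantum;
        const double fl = std::floor(n);
        v = quantum * (fl + (unif_rand() < n - fl ? 1.0 : 0.0));
      }
      inc[t] = v;
      tot += v;
    }
    double f = (tot > fs && tot > 0.0) ? fs / tot : 1.0;
    for (int t = 0; t < ntype; ++t) out(i, t) += inc[t] * f;
  }
  return out;
}
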