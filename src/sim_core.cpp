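// Daily inner loop of the stand simulator. One call advances the stand
// through one simulation year (365 days) of: infiltration and drainage,
// soil evaporation, per-individual root-weighted water status and percent
// loss of conductance, phenology triggers, light competition (height-ranked
// Beer-Lambert), supply-limited carbon gain with a CO2 factor, allocation,
// turnover, and stress/mortality accounting. Water and carbon are conserved
// to floating-point accuracy; the per-day residuals are returned so the R
// side can audit conservation.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// trait matrix columns
enum { T_AROOT = 0, T_ASTEM, T_ALEAF, T_ASTORE, T_P50, T_EVER, T_LIGHT, T_RDEPTH };
// derived matrix columns
enum { D_SLA = 0, D_LONG, D_KMAX };
// state matrix columns
enum { S_LEAF = 0, S_STEM, S_ROOT, S_STORE, S_REPRO, S_LEAVES, S_PLC,
       S_CONSEC, S_ALIVE, S_STRESS, S_CAUSE, S_REFRACT, S_NCOLS };

// [[Rcpp::export]]
List sim_year_cpp(NumericMatrix state_in, NumericMatrix traits,
                  NumericMatrix derived, NumericMatrix rootfrac,
                  NumericVector soil_water_in, NumericVector soil_cap,
                  NumericVector soil_wilt,
                  NumericVector precip, NumericVector tmean,
                  NumericVector light, double co2, List params) {
  NumericMatrix state = clone(state_in);
  NumericVector w = clone(soil_water_in);
  const int n = state.nrow();
  const int L = w.size();
  const int ndays = precip.size();

  const double es_max = params["es_max"];
  const double psi_dry = params["psi_dry"];
  const double psi_exp = params["psi_exp"];
  const double e0 = params["e0"];
  const double dd0 = params["dd0"];
  const double amax = params["amax"];
  const double kbeer = params["kbeer"];
  const double rmaint = params["rmaint"];
  const double rstem = params["rstem"];
  const double root_turn = params["root_turn"];
  const double stem_turn = params["stem_turn"];
  const double plc_slope = params["plc_slope"];
  const double plc_kill = params["plc_kill"];
  const int d_kill = params["d_kill"];
  const double plc_crit = params["plc_crit"];
  const double store_crit = params["store_crit"];
  const double flush_hi = params["flush_hi"];
  const double flush_lo = params["flush_lo"];
  const double flush_frac = params["flush_frac"];
  const double flush_overhead = params["flush_overhead"];
  const double h1 = params["h1"];
  const double hexp = params["hexp"];
  const double hhalf = params["hhalf"];
  const double crown_area = params["crown_area"];
  const double depth_cost = params["depth_cost"];
  const double co2_half = params["co2_half"];
  const double light_thresh = params["light_thresh"];
  const double refract_days = params["refract_days"];
  const double dormancy_frac = params["dormancy_frac"];
  const double closure_exp = params["closure_exp"];
  const double uptake_wet_pref = params["uptake_wet_pref"];
  const double uptake_rate = params["uptake_rate"];
  std::vector<double> thick(L);
  {
    NumericVector th = params["layer_thickness_mm"];
    for (int l = 0; l < L; ++l) thick[l] = th[l] / 1000.0; // back to metres
  }
  const bool pref1 = std::abs(uptake_wet_pref - 1.0) < 1e-12;
  const bool psi2 = std::abs(psi_exp - 2.0) < 1e-12;
  const bool clos1 = std::abs(closure_exp - 1.0) < 1e-12;
  auto upw = [&](double r) { return pref1 ? r : std::pow(r, uptake_wet_pref); };
  auto clw = [&](double open) { return clos1 ? open : std::pow(open, closure_exp); };
  const double area_m2 = params["area_m2"];

  const double co2f = (co2 / (co2 + co2_half)) / (380.0 / (380.0 + co2_half));

  NumericVector transp_day(ndays), evap_day(ndays), drain_day(ndays);
  double water_resid_max = 0.0, carbon_resid_max = 0.0;
  double gpp_year = 0.0;

  std::vector<double> rel(L), psi_l(L), avail(L), desired_l(L), scale_l(L);
  std::vector<double> la(n), lightcomp(n), demand(n), supply(n), height(n);
  std::vector<double> uw(n); // rootzone weighted relative water
  std::vector<double> usum(n);
  std::vector<int> ord(n);
  std::vector<double> pheno_litter(n), pheno_resp(n), pools_start(n);

  for (int d = 0; d < ndays; ++d) {
    const double soil_before = std::accumulate(w.begin(), w.end(), 0.0);

    // (1) infiltration top-down with drainage above field capacity
    double drain = 0.0;
    double influx = precip[d];
    for (int l = 0; l < L; ++l) {
      w[l] += influx;
      influx = 0.0;
      if (w[l] > soil_cap[l]) {
        influx = w[l] - soil_cap[l];
        w[l] = soil_cap[l];
      }
    }
    drain = influx;

    // soil evaporation from the top layer
    double rel0 = (w[0] - soil_wilt[0]) / (soil_cap[0] - soil_wilt[0]);
    rel0 = std::max(0.0, std::min(1.0, rel0));
    double evap = std::min(es_max * rel0, std::max(0.0, w[0] - soil_wilt[0]));
    w[0] -= evap;

    // (2) layer water status
    for (int l = 0; l < L; ++l) {
      double r = (w[l] - soil_wilt[l]) / (soil_cap[l] - soil_wilt[l]);
      rel[l] = std::max(0.0, std::min(1.0, r));
      double dry = 1.0 - rel[l];
      psi_l[l] = psi_dry * (psi2 ? dry * dry : std::pow(dry, psi_exp));
      // supply is limited both by storage and by an unsaturated-conductivity
      // rate cap, so overlapping root profiles compete even over wet soil
      const double rate_cap = uptake_rate * thick[l] * rel[l];
      avail[l] = std::min(std::max(0.0, w[l] - soil_wilt[l]), rate_cap);
      desired_l[l] = 0.0;
    }

    // per-individual water status, phenology, geometry
    const bool light_on = light[d] >= light_thresh;
    for (int i = 0; i < n; ++i) {
      pheno_litter[i] = 0.0;
      pheno_resp[i] = 0.0;
      if (state(i, S_ALIVE) < 0.5) { la[i] = 0; demand[i] = 0; continue; }
      pools_start[i] = state(i, S_LEAF) + state(i, S_STEM) +
        state(i, S_ROOT) + state(i, S_STORE);
      double wz = 0.0, psz_dry = 0.0, psz_wet = 0.0, us = 0.0, uq = 0.0;
      for (int l = 0; l < L; ++l) {
        const double f = rootfrac(i, l);
        wz += f * rel[l];
        psz_dry += f * psi_l[l];
        psz_wet += f * rel[l] * psi_l[l];
        us += f * rel[l];
        // extraction weight: mostly profile-driven, with only a mild
        // preference for wetter layers, so deep-rooted trees do not chase
        // the same wet mid-profile layers every neighbour needs
        uq += f * upw(rel[l]);
      }
      uw[i] = wz;
      usum[i] = uq;
      // uptake-weighted root-zone water potential: wet layers dominate the
      // plant's effective supply potential; a fully dry root zone falls back
      // to the unweighted mean
      const double psz = (us > 1e-9) ? psz_wet / us : psz_dry;

      // (3) phenology with hysteresis
      const bool ever = traits(i, T_EVER) > 0.5;
      const bool ltrig = traits(i, T_LIGHT) > 0.5;
      bool leaves = state(i, S_LEAVES) > 0.5;
      bool flushed = false;
      if (ever) {
        if (!leaves) { leaves = true; flushed = true; }
      } else if (ltrig) {
        if (!leaves && light_on) { leaves = true; flushed = true; }
        if (leaves && !light_on) leaves = false;
      } else {
        // water trigger: flush on recharge (after a refractory period so a
        // single dry spell is not paid for twice); shed on a dry root zone
        // or at incipient cavitation (past the plant's own P50)
        if (state(i, S_REFRACT) > 0) state(i, S_REFRACT) -= 1.0;
        if (!leaves && wz >= flush_hi && state(i, S_REFRACT) <= 0) {
          leaves = true; flushed = true;
        }
        if (leaves && (wz <= flush_lo || state(i, S_PLC) >= 0.5)) {
          leaves = false;
          state(i, S_REFRACT) = refract_days;
        }
      }
      if (!leaves && state(i, S_LEAVES) > 0.5) {
        // abscission: the whole leaf pool becomes litter
        pheno_litter[i] += state(i, S_LEAF);
        state(i, S_LEAF) = 0.0;
      }
      if (flushed && state(i, S_STORE) > 1e-8) {
        // rebuild leaves from storage; construction overhead is respired
        double c = flush_frac * state(i, S_STORE);
        state(i, S_STORE) -= c;
        state(i, S_LEAF) += c * (1.0 - flush_overhead);
        pheno_resp[i] += c * flush_overhead;
      }
      state(i, S_LEAVES) = leaves ? 1.0 : 0.0;

      // leaf area from the leaf pool, capped by a crown allometry on stem
      // mass (sapwood support limit)
      la[i] = leaves ? derived(i, D_SLA) * state(i, S_LEAF) : 0.0;
      const double la_cap = crown_area * std::pow(std::max(state(i, S_STEM), 1e-6), 0.75);
      if (la[i] > la_cap) la[i] = la_cap;
      height[i] = h1 * std::pow(std::max(state(i, S_STEM), 1e-6), hexp);

      // (4) plant water potential with transpiration-induced drawdown
      const double plc_prev = state(i, S_PLC);
      double drawdown = 0.0;
      if (leaves && la[i] > 0) {
        // taller trees carry a longer hydraulic path: size-dependent risk
        const double hfac = std::min(1.75, 0.5 + height[i] / 40.0);
        drawdown = dd0 * (1.0 - plc_prev) * hfac / derived(i, D_KMAX);
      }
      const double psi = psz - drawdown;
      const double p50 = traits(i, T_P50);
      const double plc = 1.0 / (1.0 + std::exp(plc_slope * (psi - p50)));
      state(i, S_PLC) = plc;

      // stand-level demand in mm: e0 (L m-2 leaf day-1) x leaf area, spread
      // over the stand area (1 mm over 1 ha = 1e4 L)
      demand[i] = (la[i] / area_m2) * e0 / co2f;
      // desired extraction, weighted by root fraction x availability; the
      // quadratic closure term represents stomatal downregulation on top of
      // lost xylem conductance, so stressed trees stop draining shared soil
      double want = demand[i] * clw(1.0 - plc);
      if (want > 0 && usum[i] > 1e-12) {
        for (int l = 0; l < L; ++l) {
          desired_l[l] += want * rootfrac(i, l) * upw(rel[l]) / usum[i];
        }
      }
    }

    // (5) layer-capped extraction
    for (int l = 0; l < L; ++l) {
      scale_l[l] = (desired_l[l] > avail[l] && desired_l[l] > 0)
        ? avail[l] / desired_l[l] : 1.0;
    }
    double transp = 0.0;
    for (int i = 0; i < n; ++i) {
      supply[i] = 0.0;
      if (state(i, S_ALIVE) < 0.5) continue;
      double want = demand[i] * clw(1.0 - state(i, S_PLC));
      if (want <= 0 || usum[i] <= 1e-12) continue;
      for (int l = 0; l < L; ++l) {
        double take = want * rootfrac(i, l) * upw(rel[l]) / usum[i] * scale_l[l];
        w[l] -= take;
        supply[i] += take;
      }
      transp += supply[i];
    }

    // light competition: taller individuals shade shorter ones
    int nalive = 0;
    for (int i = 0; i < n; ++i) if (state(i, S_ALIVE) > 0.5) ord[nalive++] = i;
    std::sort(ord.begin(), ord.begin() + nalive,
              [&](int a, int b) { return height[a] > height[b]; });
    double lai_above = 0.0;
    for (int k = 0; k < nalive; ++k) {
      const int i = ord[k];
      lightcomp[i] = std::exp(-kbeer * lai_above);
      lai_above += la[i] / area_m2;
    }

    // (6) carbon gain, respiration, turnover, allocation
    for (int k = 0; k < nalive; ++k) {
      const int i = ord[k];
      double gain = 0.0;
      if (la[i] > 0 && demand[i] > 0) {
        const double fsup = std::min(1.0, supply[i] / demand[i]);
        const double htfac = 1.0 / (1.0 + height[i] / hhalf);
        gain = amax * la[i] * lightcomp[i] * light[d] * fsup * co2f * htfac;
      }
      gpp_year += gain;

      // leafless plants drop to a dormant metabolism
      const double root_cost = 1.0 + depth_cost * traits(i, T_RDEPTH);
      const double dorm = (state(i, S_LEAVES) > 0.5) ? 1.0 : dormancy_frac;
      double resp = dorm * (rmaint * (state(i, S_LEAF) + root_cost * state(i, S_ROOT)) +
        rstem * state(i, S_STEM));
      double litter = 0.0;
      if (state(i, S_LEAVES) > 0.5 && state(i, S_LEAF) > 0) {
        double lt = state(i, S_LEAF) / derived(i, D_LONG);
        state(i, S_LEAF) -= lt;
        litter += lt;
      }
      double rt = state(i, S_ROOT) * root_turn;
      state(i, S_ROOT) -= rt;
      litter += rt;
      // woody turnover (branch shedding, heart rot): biomass declines when
      // growth stalls
      double wt = state(i, S_STEM) * stem_turn;
      state(i, S_STEM) -= wt;
      litter += wt;

      double net = gain - resp;
      if (net >= 0) {
        const double aleaf = traits(i, T_ALEAF);
        if (state(i, S_LEAVES) > 0.5) {
          state(i, S_LEAF) += aleaf * net;
        } else {
          state(i, S_STORE) += aleaf * net; // divert leaf share while leafless
        }
        state(i, S_ROOT) += traits(i, T_AROOT) * net;
        state(i, S_STEM) += traits(i, T_ASTEM) * net;
        state(i, S_STORE) += traits(i, T_ASTORE) * net;
      } else {
        double deficit = -net;
        double use = std::min(deficit, state(i, S_STORE));
        state(i, S_STORE) -= use;
        deficit -= use;
        if (deficit > 0) { // consume tissue (counted as respiration)
          double fromleaf = std::min(deficit, state(i, S_LEAF));
          state(i, S_LEAF) -= fromleaf; deficit -= fromleaf;
          double fromroot = std::min(deficit, state(i, S_ROOT));
          state(i, S_ROOT) -= fromroot; deficit -= fromroot;
          double fromstem = std::min(deficit, state(i, S_STEM));
          state(i, S_STEM) -= fromstem; deficit -= fromstem;
          resp -= deficit; // unpayable remainder: no pool left to respire
        }
      }

      // audit over the whole day: gain = delta pools + respiration + litter
      // (the reproduction pool only changes at the annual step)
      resp += pheno_resp[i];
      litter += pheno_litter[i];
      const double pools_after = state(i, S_LEAF) + state(i, S_STEM) +
        state(i, S_ROOT) + state(i, S_STORE);
      const double resid = gain - resp - litter - (pools_after - pools_start[i]);
      if (std::abs(resid) > carbon_resid_max) carbon_resid_max = std::abs(resid);

      // (7) stress accounting and in-year hydraulic mortality
      // hydraulic failure accrues only while the plant carries leaves and
      // transpires; a leafless (avoiding) plant risks starvation instead
      const double plc = state(i, S_PLC);
      if (plc > plc_kill && state(i, S_LEAVES) > 0.5) {
        state(i, S_CONSEC) += 1.0;
      } else if (plc <= plc_kill) {
        state(i, S_CONSEC) = 0.0;
      }
      if (plc > plc_crit || state(i, S_STORE) < store_crit) {
        state(i, S_STRESS) += 1.0;
      }
      const bool no_tissue = (state(i, S_LEAF) + state(i, S_ROOT) +
                              state(i, S_STEM) + state(i, S_STORE)) < 1e-7;
      if (state(i, S_CONSEC) >= d_kill) {
        state(i, S_ALIVE) = 0.0;
        state(i, S_CAUSE) = 1.0; // hydraulic failure
      } else if (no_tissue) {
        state(i, S_ALIVE) = 0.0;
        state(i, S_CAUSE) = 2.0; // carbon starvation
      }

      if (!R_finite(state(i, S_LEAF)) || !R_finite(state(i, S_STORE)) ||
          !R_finite(state(i, S_STEM)) || !R_finite(state(i, S_ROOT))) {
        stop("non-finite carbon pool for individual %d on day %d", i + 1, d + 1);
      }
    }

    const double soil_after = std::accumulate(w.begin(), w.end(), 0.0);
    const double wres = precip[d] - (soil_after - soil_before) - transp - evap - drain;
    if (std::abs(wres) > water_resid_max) water_resid_max = std::abs(wres);

    transp_day[d] = transp;
    evap_day[d] = evap;
    drain_day[d] = drain;
  }

  return List::create(
    _["state"] = state,
    _["soil_water"] = w,
    _["transp_day"] = transp_day,
    _["evap_day"] = evap_day,
    _["drain_day"] = drain_day,
    _["water_resid_max"] = water_resid_max,
    _["carbon_resid_max"] = carbon_resid_max,
    _["gpp"] = gpp_year
  );
}
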