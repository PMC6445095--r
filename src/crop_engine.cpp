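// Daily-timestep winter wheat engine: phenology (thermal time, vernalisation,
// daylength-responsive final leaf number), cohort-based canopy with
// stay-green senescence, Beer-law light interception, RUE-based growth with
// temperature and water-stress limitation, a cascading 5-cm soil water
// balance with Priestley-Taylor evaporative demand, stem-reserve
// translocation and thermal-time-limited grain filling.
#include <Rcpp.h>
using namespace Rcpp;

static const int MAX_COHORTS = 26;

struct Consts {
  double t_base, rue, k, par_frac;
  double tt_emergence;
  double base_fln, max_fln, daylength_cap, vern_tmin, vern_tmax,
         vern_ramp, vern_days, vern_extra_leaves;
  double anthesis_phyllochrons;
  double shoot_density, leaf_rank_floor, leaf_green_tt, leaf_decline_tt,
         sg_reference;
  double root_growth_cm_day; int init_root_layers;
  double pt_alpha, rn_a, rn_b, psychrometric, latent_heat;
  double soil_evap_frac, soil_evap_avail_frac;
  double root_frac_preanthesis, reserve_frac, reserve_translocation_rate,
         sink_ratio, sink_bref, sink_gamma;
  double heat_threshold, heat_slope, drought_wsf_threshold, drought_slope;
  double flower_window_before_tt, flower_window_after_tt;
  double lai_exhaust, stress_day_wsf;
};

static Consts read_consts(const List& cl) {
  Consts c;
  c.t_base = cl["t_base"]; c.rue = cl["rue"]; c.k = cl["k"];
  c.par_frac = cl["par_frac"]; c.tt_emergence = cl["tt_emergence"];
  c.base_fln = cl["base_fln"]; c.max_fln = cl["max_fln"];
  c.daylength_cap = cl["daylength_cap"];
  c.vern_tmin = cl["vern_tmin"]; c.vern_tmax = cl["vern_tmax"];
  c.vern_ramp = cl["vern_ramp"];
  c.vern_days = cl["vern_days"];
  c.vern_extra_leaves = cl["vern_extra_leaves"];
  c.anthesis_phyllochrons = cl["anthesis_phyllochrons"];
  c.shoot_density = cl["shoot_density"];
  c.leaf_rank_floor = cl["leaf_rank_floor"];
  c.leaf_green_tt = cl["leaf_green_tt"];
  c.leaf_decline_tt = cl["leaf_decline_tt"];
  c.sg_reference = cl["sg_reference"];
  c.root_growth_cm_day = cl["root_growth_cm_day"];
  c.init_root_layers = as<int>(cl["init_root_layers"]);
  c.pt_alpha = cl["pt_alpha"]; c.rn_a = cl["rn_a"]; c.rn_b = cl["rn_b"];
  c.psychrometric = cl["psychrometric"]; c.latent_heat = cl["latent_heat"];
  c.soil_evap_frac = cl["soil_evap_frac"];
  c.soil_evap_avail_frac = cl["soil_evap_avail_frac"];
  c.root_frac_preanthesis = cl["root_frac_preanthesis"];
  c.reserve_frac = cl["reserve_frac"];
  c.reserve_translocation_rate = cl["reserve_translocation_rate"];
  c.sink_ratio = cl["sink_ratio"];
  c.sink_bref = cl["sink_bref"];
  c.sink_gamma = cl["sink_gamma"];
  c.heat_threshold = cl["heat_threshold"]; c.heat_slope = cl["heat_slope"];
  c.drought_wsf_threshold = cl["drought_wsf_threshold"];
  c.drought_slope = cl["drought_slope"];
  c.flower_window_before_tt = cl["flower_window_before_tt"];
  c.flower_window_after_tt = cl["flower_window_after_tt"];
  c.lai_exhaust = cl["lai_exhaust"];
  c.stress_day_wsf = cl["stress_day_wsf"];
  return c;
}

static inline double thermal_time_day(double tmin, double tmax, double t_base) {
  double tt = 0.5 * (tmin + tmax) - t_base;
  return tt > 0 ? tt : 0;
}

static inline double temp_factor_day(double tmean) {
  if (tmean <= 0) return 0;
  if (tmean < 10) return tmean / 10.0;
  if (tmean <= 20) return 1.0;
  if (tmean < 37) return (37.0 - tmean) / 17.0;
  return 0;
}

static inline double priestley_taylor(double tmean, double rad, const Consts& c) {
  double es = 0.6108 * std::exp(17.27 * tmean / (tmean + 237.3));
  double slope = 4098.0 * es / std::pow(tmean + 237.3, 2);
  double rn = c.rn_a * rad - c.rn_b;
  if (rn < 0) rn = 0;
  return c.pt_alpha * slope / (slope + c.psychrometric) * rn / c.latent_heat;
}

// One day of the soil water cascade. `water` is modified in place.
// Returns (transpiration, soil_evap, drainage, irrigation).
static void soil_day(std::vector<double>& water, const std::vector<double>& awc,
                     const std::vector<double>& lambda,
                     double precip, double transp_demand, double evap_demand,
                     double ru, int n_rooted, bool irrigate,
                     double evap_avail_frac,
                     double& transp, double& soil_evap, double& drainage,
                     double& irrigation) {
  int n = water.size();
  irrigation = 0;
  if (irrigate) {
    for (int i = 0; i < n; ++i) {
      irrigation += awc[i] - water[i];
      water[i] = awc[i];
    }
  }
  // infiltration cascade
  double inflow = precip;
  for (int i = 0; i < n && inflow > 0; ++i) {
    double room = awc[i] - water[i];
    double add = inflow < room ? inflow : room;
    water[i] += add;
    inflow -= add;
  }
  drainage = inflow;
  // soil evaporation from the top two layers
  double avail_e = 0;
  int ne = n < 2 ? n : 2;
  for (int i = 0; i < ne; ++i) avail_e += water[i];
  soil_evap = std::min(evap_demand, evap_avail_frac * avail_e);
  double rem = soil_evap;
  for (int i = 0; i < ne && rem > 0; ++i) {
    double take = rem < water[i] ? rem : water[i];
    water[i] -= take; rem -= take;
  }
  // root extraction: daily extractable fraction of layer i is
  // lambda_i * ru / 3, i.e. the lambda profile applies as-is at the
  // reference cultivar's uptake rate (ru = 3%)
  if (n_rooted > n) n_rooted = n;
  double supply = 0;
  std::vector<double> cap(n_rooted);
  for (int i = 0; i < n_rooted; ++i) {
    cap[i] = lambda[i] * (ru / 3.0) * water[i];
    supply += cap[i];
  }
  transp = std::min(transp_demand, supply);
  if (supply > 0 && transp > 0) {
    double frac = transp / supply;
    for (int i = 0; i < n_rooted; ++i) water[i] -= cap[i] * frac;
  }
}

// [[Rcpp::export]]
List soil_water_step_cpp(NumericVector water, NumericVector awc,
                         NumericVector lambda, double precip,
                         double transp_demand, double evap_demand,
                         double ru, int n_rooted, bool irrigate) {
  if (precip < 0 || transp_demand < 0 || evap_demand < 0)
    stop("negative water inputs are not allowed");
  std::vector<double> w(water.begin(), water.end()),
      a(awc.begin(), awc.end()), l(lambda.begin(), lambda.end());
  double tr, ev, dr, ir;
  soil_day(w, a, l, precip, transp_demand, evap_demand, ru, n_rooted,
           irrigate, 0.3, tr, ev, dr, ir);
  return List::create(_["water"] = NumericVector(w.begin(), w.end()),
                      _["transpiration"] = tr, _["soil_evap"] = ev,
                      _["drainage"] = dr, _["irrigation"] = ir);
}

struct SeasonOut {
  bool complete;
  double grain, b_ag, anthesis_doy, maturity_doy, anthesis_das, maturity_das,
      grainfill_days, grainfill_tt, cum_int_rad, cum_incident_rad, max_lai,
      stress_days, fln, reserves_left, grain_mult;
};

// weather: columns doy, tmin, tmax, precip, rad; rows from sowing day.
static SeasonOut run_season(const NumericMatrix& weather, int start,
                            const NumericVector& daylen,
                            double ph, double pp, double gf, double amax,
                            double sg, double ru, double wss,
                            const Consts& c,
                            const std::vector<double>& soil_awc,
                            const std::vector<double>& soil_lambda,
                            bool water_limited, double lue,
                            bool flowering_stress,
                            NumericMatrix* daily) {
  const int n = weather.nrow() - start;
  const int nlay = soil_awc.size();
  std::vector<double> water(soil_awc);  // profile full at sowing

  SeasonOut out; out.complete = false;
  out.grain = 0; out.b_ag = 0; out.cum_int_rad = 0; out.cum_incident_rad = 0;
  out.max_lai = 0; out.stress_days = 0; out.fln = NA_REAL;
  out.anthesis_doy = NA_REAL; out.maturity_doy = NA_REAL;
  out.anthesis_das = NA_REAL; out.maturity_das = NA_REAL;
  out.grainfill_days = NA_REAL; out.grainfill_tt = 0;
  out.reserves_left = 0; out.grain_mult = 1;

  // phenology state
  int phase = 0;  // 0 sown, 1 vegetative, 2 flag-leaf latched, 3 grainfill, 4 mature
  double tt_sow = 0, cum_tt = 0, vern = 0, leaf_number = 0;
  double fln = NA_REAL, tt_latch = NA_REAL, tt_anth = NA_REAL, tt_post = 0;
  bool latched = false;

  // canopy cohorts
  int n_cohorts = 0;
  double app_tt[MAX_COHORTS], area_max[MAX_COHORTS], sen_clock[MAX_COHORTS];
  double lai = 0;
  const double green_dur = c.leaf_green_tt;
  const double decline_dur = c.leaf_decline_tt;
  // stay-green slows the post-anthesis senescence clock relative to the
  // reference cultivar's stay-green level
  const double sg_rate = (1.0 + c.sg_reference) / (1.0 + sg);

  double reserves = 0, reserves0 = 0, grain_mult = 1, b_anth = 0;

  for (int d = 0; d < n; ++d) {
    const int r = start + d;
    double doy = weather(r, 0), tmin = weather(r, 1), tmax = weather(r, 2),
           precip = weather(r, 3), rad = weather(r, 4);
    if (tmax < tmin) stop("tmax < tmin in weather input (row %d)", d + 1);
    double tmean = 0.5 * (tmin + tmax);
    double tt_day = thermal_time_day(tmin, tmax, c.t_base);

    // evaporative demand from yesterday's canopy
    double f_int = 1.0 - std::exp(-c.k * lai);
    double pet = priestley_taylor(tmean, rad, c);
    double demand_t = pet * f_int;
    double demand_e = c.soil_evap_frac * pet * (1.0 - f_int);

    int n_rooted = c.init_root_layers +
        (int)std::floor(c.root_growth_cm_day * d / 5.0);
    if (n_rooted > nlay) n_rooted = nlay;

    double transp, soil_evap, drainage, irrigation;
    soil_day(water, soil_awc, soil_lambda, precip, demand_t, demand_e, ru,
             n_rooted, !water_limited, c.soil_evap_avail_frac, transp,
             soil_evap, drainage, irrigation);
    double wsf = 1.0;
    if (water_limited && demand_t > 1e-12) {
      wsf = transp / demand_t;
      if (wsf > 1) wsf = 1;
    }

    // ---- phenology ----
    if (phase == 0) {
      tt_sow += tt_day;
      if (tt_sow >= c.tt_emergence) phase = 1;
    } else {
      cum_tt += tt_day;
      if (vern < 1 && tmean >= c.vern_tmin) {
        double credit = 0;
        if (tmean <= c.vern_tmax) credit = 1;
        else if (tmean < c.vern_tmax + c.vern_ramp)
          credit = (c.vern_tmax + c.vern_ramp - tmean) / c.vern_ramp;
        vern += credit / c.vern_days;
        if (vern > 1) vern = 1;
      }
      if (phase >= 1 && phase <= 2) {
        leaf_number += tt_day / ph;
        if (latched && leaf_number > fln) leaf_number = fln;
      }
      if (!latched && phase == 1) {
        double shortfall = c.daylength_cap - daylen[r];
        if (shortfall < 0) shortfall = 0;
        double fln_prov = c.base_fln + pp * shortfall +
            c.vern_extra_leaves * (1.0 - vern);
        if (fln_prov < c.base_fln) fln_prov = c.base_fln;
        if (fln_prov > c.max_fln) fln_prov = c.max_fln;
        if (leaf_number >= fln_prov) {
          latched = true;
          fln = fln_prov;
          out.fln = fln;
          tt_latch = cum_tt;
          tt_anth = tt_latch + c.anthesis_phyllochrons * ph;
          leaf_number = fln;
          phase = 2;
        } else {
          // new leaf cohorts appear as the Haun stage crosses integers
          while (n_cohorts < MAX_COHORTS - 1 && leaf_number >= n_cohorts &&
                 n_cohorts < (int)std::ceil(fln_prov)) {
            app_tt[n_cohorts] = cum_tt;
            double rank_frac = (n_cohorts + 1.0) / fln_prov;
            if (rank_frac > 1) rank_frac = 1;
            if (rank_frac < c.leaf_rank_floor) rank_frac = c.leaf_rank_floor;
            area_max[n_cohorts] = amax * c.shoot_density * rank_frac;
            sen_clock[n_cohorts] = 0;
            ++n_cohorts;
          }
        }
      }
      if (phase == 2 && cum_tt >= tt_anth) {
        phase = 3;
        out.anthesis_doy = doy;
        out.anthesis_das = d;
        b_anth = out.b_ag;
        reserves = c.reserve_frac * out.b_ag;
        reserves0 = reserves;
      }
    }

    // ---- canopy senescence / expansion ----
    if (phase >= 1) {
      double f_sen = 1.0 + (wss - 1.0) * (1.0 - wsf);
      if (phase >= 3) f_sen *= sg_rate;
      lai = 0;
      for (int i = 0; i < n_cohorts; ++i) {
        double since_app = cum_tt - app_tt[i];
        double fexp = since_app / ph;
        if (fexp > 1) {
          fexp = 1;
          sen_clock[i] += tt_day * f_sen;
        }
        double fgreen = 1.0;
        if (sen_clock[i] > green_dur) {
          fgreen = 1.0 - (sen_clock[i] - green_dur) / decline_dur;
          if (fgreen < 0) fgreen = 0;
        }
        lai += area_max[i] * fexp * fgreen;
      }
      if (lai > out.max_lai) out.max_lai = lai;
      if (water_limited && wsf < c.stress_day_wsf) out.stress_days += 1;
    }

    // ---- growth and grain filling ----
    double db = 0, dgrain = 0, transloc = 0;
    if (phase >= 1 && phase <= 3) {
      double tf = temp_factor_day(tmean);
      double assim = c.par_frac * rad * f_int * c.rue * lue * tf * wsf;
      if (phase < 3) {
        db = assim * (1.0 - c.root_frac_preanthesis);
        out.b_ag += db;
      } else {
        db = assim;  // post-anthesis: all new biomass above ground
        out.b_ag += db;
      }
      // flowering-stress multiplier on grain set (heat / severe drought
      // around anthesis); disabled by flag or outside the window
      if (flowering_stress && latched &&
          cum_tt >= tt_anth - c.flower_window_before_tt &&
          cum_tt <= tt_anth + c.flower_window_after_tt) {
        if (tmax > c.heat_threshold) {
          double f = 1.0 - c.heat_slope * (tmax - c.heat_threshold);
          grain_mult *= f > 0 ? f : 0;
        }
        if (water_limited && wsf < c.drought_wsf_threshold) {
          double f = 1.0 - c.drought_slope * (c.drought_wsf_threshold - wsf);
          grain_mult *= f > 0 ? f : 0;
        }
      }
      if (phase == 3) {
        transloc = c.reserve_translocation_rate * reserves0;
        if (transloc > reserves) transloc = reserves;
        reserves -= transloc;
        dgrain = (db + transloc) * grain_mult;
        // sink limit: grain number and potential kernel weight are set by
        // crop size at anthesis, scaling sub-linearly with crop biomass
        double sink = c.sink_ratio * c.sink_bref *
            std::pow(b_anth / c.sink_bref, c.sink_gamma);
        if (out.grain + dgrain > sink) dgrain = std::max(0.0, sink - out.grain);
        out.grain += dgrain;
        double tt_inc = tt_day;
        if (tt_post + tt_inc > gf) tt_inc = gf - tt_post;
        tt_post += tt_inc;
        out.grainfill_tt = tt_post;
        bool tt_done = tt_post >= gf - 1e-9;
        bool canopy_done = lai < c.lai_exhaust;
        if (tt_done || canopy_done) {
          phase = 4;
          out.maturity_doy = doy;
          out.maturity_das = d;
          out.grainfill_days = out.maturity_das - out.anthesis_das;
        }
      }
    }

    out.cum_int_rad += rad * f_int;
    out.cum_incident_rad += rad;

    if (daily) {
      NumericMatrix& dm = *daily;
      dm(d, 0) = d; dm(d, 1) = doy; dm(d, 2) = tt_day; dm(d, 3) = phase;
      dm(d, 4) = lai; dm(d, 5) = db; dm(d, 6) = out.b_ag; dm(d, 7) = dgrain;
      dm(d, 8) = out.grain; dm(d, 9) = reserves; dm(d, 10) = precip;
      dm(d, 11) = irrigation; dm(d, 12) = transp; dm(d, 13) = soil_evap;
      dm(d, 14) = drainage;
      double storage = 0; for (int i = 0; i < nlay; ++i) storage += water[i];
      dm(d, 15) = storage; dm(d, 16) = wsf; dm(d, 17) = leaf_number;
      dm(d, 18) = vern; dm(d, 19) = rad * f_int;
    }

    if (phase == 4) {
      out.complete = true;
      out.reserves_left = reserves;
      out.grain_mult = grain_mult;
      if (daily) {
        // truncate marker: R side trims rows after maturity
      }
      return out;
    }
  }
  return out;  // weather exhausted before maturity
}

static std::vector<double> nv2v(const NumericVector& x) {
  return std::vector<double>(x.begin(), x.end());
}

// [[Rcpp::export]]
List simulate_season_cpp(NumericMatrix weather, NumericVector daylen,
                         List traits, List consts, List soil,
                         bool water_limited, double lue,
                         bool flowering_stress, bool return_daily) {
  Consts c = read_consts(consts);
  std::vector<double> awc = nv2v(soil["awc_per_layer"]);
  std::vector<double> lambda = nv2v(soil["lambda"]);
  NumericMatrix daily;
  if (return_daily) daily = NumericMatrix(weather.nrow(), 20);
  SeasonOut o = run_season(
      weather, 0, daylen, traits["ph"], traits["pp"], traits["gf"],
      traits["amax"], traits["sg"], traits["ru"], traits["wss"], c, awc,
      lambda, water_limited, lue, flowering_stress,
      return_daily ? &daily : nullptr);
  List res = List::create(
      _["complete"] = o.complete, _["grain_yield"] = o.grain * 0.01,
      _["total_biomass"] = o.b_ag * 0.01,
      _["hi"] = o.b_ag > 0 ? o.grain / o.b_ag : 0.0,
      _["anthesis_doy"] = o.anthesis_doy, _["maturity_doy"] = o.maturity_doy,
      _["anthesis_das"] = o.anthesis_das, _["maturity_das"] = o.maturity_das,
      _["grainfill_days"] = o.grainfill_days,
      _["grainfill_tt"] = o.grainfill_tt,
      _["cum_intercepted_radiation"] = o.cum_int_rad,
      _["cum_incident_radiation"] = o.cum_incident_rad,
      _["max_lai"] = o.max_lai, _["water_stress_days"] = o.stress_days,
      _["final_leaf_number"] = o.fln, _["grain_mult"] = o.grain_mult);
  if (return_daily) res["daily"] = daily;
  return res;
}

// Run one season per sowing index (0-based rows into `weather`).
// Returns a matrix: one row per season with the headline outputs.
// [[Rcpp::export]]
NumericMatrix simulate_years_cpp(NumericMatrix weather, NumericVector daylen,
                                 IntegerVector sow_rows, List traits,
                                 List consts, List soil, bool water_limited,
                                 double lue, bool flowering_stress) {
  Consts c = read_consts(consts);
  std::vector<double> awc = nv2v(soil["awc_per_layer"]);
  std::vector<double> lambda = nv2v(soil["lambda"]);
  double ph = traits["ph"], pp = traits["pp"], gf = traits["gf"],
         amax = traits["amax"], sg = traits["sg"], ru = traits["ru"],
         wss = traits["wss"];
  int ns = sow_rows.size();
  NumericMatrix res(ns, 11);
  colnames(res) = CharacterVector::create(
      "grain_yield", "total_biomass", "hi", "anthesis_doy", "maturity_doy",
      "anthesis_das", "maturity_das", "grainfill_days",
      "cum_intercepted_radiation", "max_lai", "water_stress_days");
  for (int s = 0; s < ns; ++s) {
    int start = sow_rows[s];
    if (weather.nrow() - start < 1)
      stop("sowing index beyond weather series (season %d)", s + 1);
    SeasonOut o = run_season(weather, start, daylen, ph, pp, gf, amax, sg,
                             ru, wss, c, awc, lambda, water_limited, lue,
                             flowering_stress, nullptr);
    if (!o.complete)
      stop("season incomplete: weather exhausted before maturity (season %d)",
           s + 1);
    res(s, 0) = o.grain * 0.01; res(s, 1) = o.b_ag * 0.01;
    res(s, 2) = o.b_ag > 0 ? o.grain / o.b_ag : 0.0;
    res(s, 3) = o.anthesis_doy; res(s, 4) = o.maturity_doy;
    res(s, 5) = o.anthesis_das; res(s, 6) = o.maturity_das;
    res(s, 7) = o.grainfill_days; res(s, 8) = o.cum_int_rad;
    res(s, 9) = o.max_lai; res(s, 10) = o.stress_days;
  }
  return res;
}
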