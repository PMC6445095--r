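#' Fixed physiological constants of the simulator
#'
#' All non-cultivar model constants live here, in one block, and can be
#' overridden individually. Units and roles:
#' \describe{
#'   \item{t_base}{Base temperature for thermal time, degC (0).}
#'   \item{rue}{Radiation use efficiency, g DM per MJ intercepted PAR.}
#'   \item{k}{Canopy extinction coefficient for Beer-law interception.}
#'   \item{par_frac}{PAR fraction of global radiation (0.5).}
#'   \item{tt_emergence}{Thermal time sowing to emergence, degC day.}
#'   \item{base_fln, max_fln}{Base and absolute maximum final leaf number.}
#'   \item{daylength_cap}{Daylength (h) at/above which the daylength
#'     response adds no leaves.}
#'   \item{vern_tmin, vern_tmax, vern_ramp, vern_days}{Vernalisation:
#'     full credit between `vern_tmin` and `vern_tmax` (degC), declining
#'     linearly to zero over the next `vern_ramp` degC; `vern_days`
#'     effective days are required.}
#'   \item{vern_extra_leaves}{Leaves added per unit unfulfilled
#'     vernalisation at flag-leaf commitment.}
#'   \item{anthesis_phyllochrons}{Phyllochrons from flag-leaf tip
#'     appearance to anthesis (tip to ligule, ligule + 2).}
#'   \item{shoot_density, leaf_rank_floor}{Green-area scaling
#'     (shoot-density equivalent, shoots m^-2): a cohort's LAI contribution
#'     is `amax * shoot_density * max(leaf_rank_floor, rank/FLN)`; the
#'     floor stands in for tiller leaf area accompanying early mainstem
#'     leaves.}
#'   \item{leaf_green_tt, leaf_decline_tt, sg_reference}{Thermal duration
#'     (degC day) of a cohort's fully green phase and of its linear
#'     decline. After anthesis the senescence clock runs at
#'     `(1 + sg_reference) / (1 + sg)` of the thermal rate, so cultivars
#'     with stay-green above the reference hold green area longer during
#'     grain fill.}
#'   \item{root_growth_cm_day, init_root_layers}{Root front descent and
#'     initial rooted 5-cm layers.}
#'   \item{pt_alpha, rn_a, rn_b, psychrometric, latent_heat}{Priestley-
#'     Taylor coefficient, net-radiation approximation `rn_a*Rs - rn_b`
#'     (MJ m^-2), psychrometric constant (kPa/degC) and latent heat of
#'     vaporisation (MJ/kg).}
#'   \item{soil_evap_frac, soil_evap_avail_frac}{Soil-evaporation demand as
#'     a fraction of non-intercepted PET, and the per-day evaporable
#'     fraction of top-two-layer water.}
#'   \item{root_frac_preanthesis}{Fraction of pre-anthesis assimilate
#'     partitioned below ground.}
#'   \item{reserve_frac, reserve_translocation_rate}{Stem-reserve pool as a
#'     fraction of above-ground biomass at anthesis, and its maximum daily
#'     translocation (fraction of the initial pool).}
#'   \item{sink_ratio, sink_bref, sink_gamma}{Grain sink capacity:
#'     `sink_ratio * sink_bref * (b_anth/sink_bref)^sink_gamma` g m^-2,
#'     where `b_anth` is above-ground biomass at anthesis. Grain number
#'     and potential kernel weight are set by crop size at flowering and
#'     scale sub-linearly with it (`sink_gamma` < 1); `sink_bref` (g m^-2)
#'     is the reference crop size at which `sink_ratio` applies directly.}
#'   \item{heat_threshold, heat_slope, drought_wsf_threshold,
#'     drought_slope}{Flowering-window heat/drought grain-set response.}
#'   \item{flower_window_before_tt, flower_window_after_tt}{Thermal window
#'     around anthesis for flowering stress, degC day.}
#'   \item{lai_exhaust}{LAI below which green area counts as exhausted.}
#'   \item{stress_day_wsf}{Water-stress-day bookkeeping threshold.}
#' }
#'
#' The values of `rue`, `shoot_density`, `leaf_green_tt`, `leaf_decline_tt`
#' and `daylength_cap` were fixed by calibrating the reference cultivar's
#' 100-year potential-mode yield and grain-fill duration to the published
#' site means, and are not re-tuned per site or per cultivar.
#'
#' @param ... Named overrides of individual constants.
#' @return A named list of constants.
#' @export
crop_constants <- function(...) {
  defaults <- list(
    t_base = 0, rue = 3.5, k = 0.55, par_frac = 0.5,
    tt_emergence = 150,
    base_fln = 11, max_fln = 24, daylength_cap = 15,
    vern_tmin = -1, vern_tmax = 8, vern_ramp = 5, vern_days = 95,
    vern_extra_leaves = 8,
    anthesis_phyllochrons = 2,
    shoot_density = 220, leaf_rank_floor = 0.5,
    leaf_green_tt = 630, leaf_decline_tt = 210, sg_reference = 0.5,
    root_growth_cm_day = 1.2, init_root_layers = 2L,
    pt_alpha = 1.26, rn_a = 0.75, rn_b = 2.0,
    psychrometric = 0.066, latent_heat = 2.45,
    soil_evap_frac = 0.5, soil_evap_avail_frac = 0.3,
    root_frac_preanthesis = 0.10,
    reserve_frac = 0.18, reserve_translocation_rate = 0.025,
    sink_ratio = 0.74, sink_bref = 2000, sink_gamma = 0.6,
    heat_threshold = 32, heat_slope = 0.04,
    drought_wsf_threshold = 0.3, drought_slope = 0.1,
    flower_window_before_tt = 200, flower_window_after_tt = 100,
    lai_exhaust = 0.05, stress_day_wsf = 0.95
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown crop constant(s): %s", paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, over)
}

#' Management settings for a simulation
#'
#' @param country `"UK"` or `"NZ"`; sets the default sowing date
#'   (20 October, doy 293, in the UK; 20 April, doy 110, in NZ).
#' @param mode `"water_limited"` (rainfed) or `"potential"` (irrigated: the
#'   profile is refilled daily, so water stress never develops).
#' @param sowing_doy Day of year of sowing; defaults by country.
#' @param lue_multiplier Light-use-efficiency multiplier: 1.00 for the
#'   reference cultivar, 1.10 for ideotype design.
#' @param flowering_stress Enable heat/drought grain-set effects around
#'   flowering.
#' @return An object of class `management`.
#' @export
management <- function(country = c("UK", "NZ"),
                       mode = c("water_limited", "potential"),
                       sowing_doy = NULL,
                       lue_multiplier = 1.00,
                       flowering_stress = TRUE) {
  country <- match.arg(country)
  mode <- match.arg(mode)
  if (is.null(sowing_doy)) sowing_doy <- if (country == "UK") 293L else 110L
  if (sowing_doy < 1 || sowing_doy > 365) stop("sowing_doy must be in 1..365")
  if (!lue_multiplier %in% c(1.00, 1.10))
    warning("lue_multiplier is normally 1.00 (reference) or 1.10 (ideotype)")
  structure(list(country = country, mode = mode,
                 sowing_doy = as.integer(sowing_doy),
                 lue_multiplier = lue_multiplier,
                 flowering_stress = isTRUE(flowering_stress)),
            class = "management")
}

#' Daily thermal time
#'
#' `max(0, (tmin + tmax)/2 - t_base)`, the thermal-time driver of all
#' developmental clocks.
#'
#' @param tmin,tmax Daily minimum/maximum temperature, degC.
#' @param t_base Base temperature, degC.
#' @return Thermal time, degC day. Vectorised.
#' @export
thermal_time <- function(tmin, tmax, t_base = 0) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  pmax(0, (tmin + tmax) / 2 - t_base)
}

#' Temperature limitation factor on growth
#'
#' Piecewise linear: 0 at or below 0 degC, rising to 1 at 10, flat to 20,
#' declining to 0 at 37 degC.
#'
#' @param tmean Daily mean temperature, degC.
#' @return Factor in `[0, 1]`. Vectorised.
#' @export
temp_factor <- function(tmean) {
  ifelse(tmean <= 0, 0,
  ifelse(tmean < 10, tmean / 10,
  ifelse(tmean <= 20, 1,
  ifelse(tmean < 37, (37 - tmean) / 17, 0))))
}

#' Intercepted photosynthetically active radiation
#'
#' Beer's law on the PAR fraction of global radiation:
#' `par_frac * radiation * (1 - exp(-k * lai))`.
#'
#' @param lai Green leaf area index, m^2 m^-2 (>= 0).
#' @param radiation Global radiation, MJ m^-2 day^-1.
#' @param k Extinction coefficient.
#' @param par_frac PAR fraction of global radiation.
#' @return Intercepted PAR, MJ m^-2 day^-1. Vectorised.
#' @export
intercepted_par <- function(lai, radiation, k = 0.45, par_frac = 0.5) {
  if (any(lai < 0)) stop("lai must be >= 0")
  par_frac * radiation * (1 - exp(-k * lai))
}

#' Daily biomass increment
#'
#' `intercepted_par * rue * lue_multiplier * temp_factor * water_stress`.
#'
#' @param ipar Intercepted PAR, MJ m^-2 day^-1.
#' @param rue Radiation use efficiency, g DM MJ^-1 PAR.
#' @param lue_multiplier Light-use-efficiency uplift (1.00 or 1.10).
#' @param temp_factor,water_stress_factor Limitation factors in `[0, 1]`.
#' @return Biomass increment, g m^-2 day^-1.
#' @export
daily_growth <- function(ipar, rue, lue_multiplier = 1,
                         temp_factor = 1, water_stress_factor = 1) {
  if (any(temp_factor < 0 | temp_factor > 1) ||
      any(water_stress_factor < 0 | water_stress_factor > 1))
    stop("limitation factors must be in [0, 1]")
  ipar * rue * lue_multiplier * temp_factor * water_stress_factor
}

#' Water stress factor
#'
#' The ratio of actual to potential transpiration, clamped to `[0, 1]`;
#' 1 when there is no demand or under potential (irrigated) management.
#'
#' @param actual Actual transpiration, mm day^-1.
#' @param demand Potential transpiration demand, mm day^-1 (>= 0).
#' @param mode `"water_limited"` or `"potential"`.
#' @return Factor in `[0, 1]`.
#' @export
water_stress_factor <- function(actual, demand,
                                mode = c("water_limited", "potential")) {
  mode <- match.arg(mode)
  if (any(demand < 0)) stop("demand must be >= 0")
  if (mode == "potential") return(rep(1, length(actual)))
  ifelse(demand == 0, 1, pmin(1, pmax(0, actual / demand)))
}

#' One day of vernalisation progress
#'
#' Progress accrues at `credit/vern_days`, where the daily credit is 1 for
#' mean temperatures inside the effective window and declines linearly to 0
#' over `vern_ramp` degC above it; progress saturates at 1.
#'
#' @param progress Current progress in `[0, 1]`.
#' @param tmin,tmax Daily temperatures, degC.
#' @param constants See [crop_constants()].
#' @return Updated progress.
#' @export
vernalisation_step <- function(progress, tmin, tmax,
                               constants = crop_constants()) {
  tmean <- (tmin + tmax) / 2
  credit <- ifelse(
    tmean < constants$vern_tmin, 0,
    ifelse(tmean <= constants$vern_tmax, 1,
           pmax(0, (constants$vern_tmax + constants$vern_ramp - tmean) /
                  constants$vern_ramp)))
  pmin(1, progress + credit / constants$vern_days)
}

#' Final leaf number
#'
#' `base_fln + pp * max(0, daylength_cap - daylength) + vern_extra_leaves *
#' (1 - vern_progress)`, clamped to `[base_fln, max_fln]`. Monotone
#' non-increasing in daylength.
#'
#' @param pp Daylength response, leaves per hour of shortfall.
#' @param vern_progress Vernalisation progress in `[0, 1]`.
#' @param dl Daylength, hours.
#' @param constants See [crop_constants()].
#' @return Final leaf number (mainstem leaves).
#' @export
final_leaf_number <- function(pp, vern_progress, dl,
                              constants = crop_constants()) {
  fln <- constants$base_fln +
    pp * pmax(0, constants$daylength_cap - dl) +
    constants$vern_extra_leaves * (1 - vern_progress)
  pmin(constants$max_fln, pmax(constants$base_fln, fln))
}

#' Daily leaf appearance increment
#'
#' @param delta_tt Daily thermal time, degC day.
#' @param ph Phyllochron, degC day per leaf.
#' @return Haun-stage increment, leaves.
#' @export
leaf_appearance_step <- function(delta_tt, ph) {
  if (any(ph <= 0)) stop("ph must be > 0")
  delta_tt / ph
}

#' Flowering-window grain-set multiplier for one day
#'
#' Heat above `heat_threshold` and severe drought (water stress factor
#' below `drought_wsf_threshold`) multiply grain set down; under no stress
#' the multiplier is 1. Matches the engine's in-window daily update.
#'
#' @param tmax Daily maximum temperature, degC.
#' @param wsf Water stress factor in `[0, 1]`.
#' @param constants See [crop_constants()].
#' @return Multiplier in `[0, 1]`.
#' @export
flowering_stress_effects <- function(tmax, wsf = 1,
                                     constants = crop_constants()) {
  m <- rep(1, length(tmax))
  hot <- tmax > constants$heat_threshold
  m[hot] <- pmax(0, 1 - constants$heat_slope *
                   (tmax[hot] - constants$heat_threshold))
  dry <- wsf < constants$drought_wsf_threshold
  if (length(wsf) == 1) wsf <- rep(wsf, length(tmax))
  m[dry] <- m[dry] * pmax(0, 1 - constants$drought_slope *
                            (constants$drought_wsf_threshold - wsf[dry]))
  m
}

#' One day of the soil water cascade
#'
#' Infiltration fills 5-cm layers top-down (overflow past the bottom layer
#' is drainage); soil evaporation draws on the top two layers; root
#' extraction from layer i is capped at `lambda_i * (ru/3) * available_i`
#' (the efficiency profile applies as-is at the reference uptake rate),
#' summed over rooted layers up to the transpiration demand. With
#' `irrigate = TRUE` the profile is refilled first and the water added is
#' reported as irrigation. The balance
#' `precip + irrigation = delta_storage + drainage + transpiration + soil_evap`
#' closes exactly.
#'
#' @param soil A [soil_profile()].
#' @param precip Rain (plus any applied irrigation water), mm.
#' @param transp_demand Potential transpiration, mm.
#' @param evap_demand Potential soil evaporation, mm.
#' @param ru Root water-uptake rate (cultivar trait), %.
#' @param n_rooted Number of rooted layers (defaults to all).
#' @param irrigate Refill the profile before the water balance.
#' @return A list: updated `soil`, `transpiration`, `soil_evap`,
#'   `drainage`, `irrigation` (all mm).
#' @export
soil_water_step <- function(soil, precip, transp_demand, evap_demand = 0,
                            ru = 3, n_rooted = soil$n_layers,
                            irrigate = FALSE) {
  stopifnot(inherits(soil, "soil_profile"))
  res <- soil_water_step_cpp(soil$water_content, soil$awc_per_layer,
                             soil$lambda, precip, transp_demand, evap_demand,
                             ru, as.integer(n_rooted), isTRUE(irrigate))
  soil$water_content <- res$water
  list(soil = soil, transpiration = res$transpiration,
       soil_evap = res$soil_evap, drainage = res$drainage,
       irrigation = res$irrigation)
}

# Internal: weather series -> engine inputs
weather_matrix <- function(weather) {
  d <- weather$days
  as.matrix(d[, c("doy", "tmin", "tmax", "precip", "radiation")])
}

engine_traits <- function(cultivar) {
  cultivar[c("ph", "pp", "gf", "amax", "sg", "ru", "wss")]
}

#' Simulate one wheat season
#'
#' Runs the daily engine from the first occurrence of the management sowing
#' date in the weather series (or from `sow_index`) until maturity.
#'
#' @param cultivar A [cultivar_params()].
#' @param weather A `weather_series` covering sowing through maturity
#'   (at least ~400 days is safe).
#' @param soil A [soil_profile()]; defaults to the site country's profile.
#' @param mgmt A [management()]; defaults to the site country's settings.
#' @param constants See [crop_constants()].
#' @param sow_index Optional explicit row of `weather$days` to sow on.
#' @param return_daily If `TRUE`, attach a per-day state/flux trace.
#' @return A `season_result` list: `grain_yield` and `total_biomass`
#'   (t ha^-1, dry matter), `hi`, `anthesis_doy`, `maturity_doy`,
#'   `anthesis_das`/`maturity_das` (days after sowing), `grainfill_days`,
#'   `grainfill_tt`, `cum_intercepted_radiation` (MJ m^-2 global),
#'   `max_lai`, `water_stress_days`, `final_leaf_number`; plus `daily` if
#'   requested.
#' @export
simulate_season <- function(cultivar, weather, soil = NULL, mgmt = NULL,
                            constants = crop_constants(), sow_index = NULL,
                            return_daily = FALSE) {
  stopifnot(inherits(cultivar, "cultivar_params"),
            inherits(weather, "weather_series"))
  country <- weather$site$country
  if (is.null(mgmt)) mgmt <- management(country)
  if (is.null(soil)) soil <- default_soil(country)
  d <- weather$days
  if (is.null(sow_index)) {
    sow_index <- which(d$doy == mgmt$sowing_doy)[1]
    if (is.na(sow_index)) stop("sowing date not present in weather series")
  }
  rows <- sow_index:nrow(d)
  wm <- weather_matrix(weather)[rows, , drop = FALSE]
  dl <- daylength(weather$site$latitude, d$doy[rows])
  res <- simulate_season_cpp(wm, dl, engine_traits(cultivar), constants,
                             soil[c("awc_per_layer", "lambda")],
                             mgmt$mode == "water_limited",
                             mgmt$lue_multiplier, mgmt$flowering_stress,
                             isTRUE(return_daily))
  if (!isTRUE(res$complete))
    stop("season incomplete: weather exhausted before maturity")
  if (return_daily) {
    dm <- res$daily[seq_len(res$maturity_das + 1), , drop = FALSE]
    colnames(dm) <- c("das", "doy", "tt", "phase", "lai", "d_biomass",
                      "biomass", "d_grain", "grain", "reserves", "precip",
                      "irrigation", "transpiration", "soil_evap", "drainage",
                      "soil_storage", "wsf", "leaf_number", "vern", "int_rad")
    res$daily <- as.data.frame(dm)
  }
  structure(res, class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf(paste0("<season_result> yield %.2f t/ha | biomass %.2f t/ha | ",
                     "HI %.3f\n  anthesis doy %d, maturity doy %d, ",
                     "grain fill %d days\n"),
              x$grain_yield, x$total_biomass, x$hi,
              as.integer(x$anthesis_doy), as.integer(x$maturity_doy),
              as.integer(x$grainfill_days)))
  invisible(x)
}

#' Simulate every season in a multi-year weather series
#'
#' One season is sown at each occurrence of the sowing date that is
#' followed by at least a full year of weather; with `n` generated years
#' this yields `n - 1` seasons (generate `n + 1` years for `n` seasons).
#'
#' @inheritParams simulate_season
#' @return A `yield_series`: data.frame `seasons` (one row per season),
#'   `mean_yield`, `cv_yield` (sample sd / mean), `mean_hi`, `n_seasons`.
#' @export
simulate_years <- function(cultivar, weather, soil = NULL, mgmt = NULL,
                           constants = crop_constants()) {
  stopifnot(inherits(cultivar, "cultivar_params"),
            inherits(weather, "weather_series"))
  country <- weather$site$country
  if (is.null(mgmt)) mgmt <- management(country)
  if (is.null(soil)) soil <- default_soil(country)
  d <- weather$days
  sow <- which(d$doy == mgmt$sowing_doy)
  sow <- sow[nrow(d) - sow + 1 >= 365]
  if (length(sow) < 1) stop("weather series too short for any full season")
  dl <- daylength(weather$site$latitude, d$doy)
  m <- simulate_years_cpp(weather_matrix(weather), dl, sow - 1L,
                          engine_traits(cultivar), constants,
                          soil[c("awc_per_layer", "lambda")],
                          mgmt$mode == "water_limited",
                          mgmt$lue_multiplier, mgmt$flowering_stress)
  seasons <- as.data.frame(m)
  seasons$season <- seq_len(nrow(seasons))
  my <- mean(seasons$grain_yield)
  structure(list(
    seasons = seasons,
    mean_yield = my,
    cv_yield = if (nrow(seasons) > 1) stats::sd(seasons$grain_yield) / my else 0,
    mean_hi = mean(seasons$hi),
    n_seasons = nrow(seasons),
    cultivar = cultivar$name, site = weather$site$site_id, mode = mgmt$mode
  ), class = "yield_series")
}

#' @export
print.yield_series <- function(x, ...) {
  cat(sprintf(paste0("<yield_series> %s at %s (%s): %d seasons\n  mean yield ",
                     "%.2f t/ha | CV %.1f%% | mean HI %.3f\n"),
              x$cultivar, x$site, x$mode, x$n_seasons,
              x$mean_yield, 100 * x$cv_yield, x$mean_hi))
  invisible(x)
}

#' Export season results
#'
#' @param x A `yield_series`.
#' @param path Output path; format from extension (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_yield_series <- function(x, path) {
  stopifnot(inherits(x, "yield_series"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(x$seasons, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
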