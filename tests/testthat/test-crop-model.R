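# Crop simulator: process functions, conservation laws, phenology and
# whole-season behaviour.

test_that("thermal time is the clamped daily mean above base", {
  expect_equal(thermal_time(10, 20, 0), 15)
  expect_equal(thermal_time(-5, 1, 0), 0)
  expect_equal(thermal_time(5, 15, 4), 6)
  expect_error(thermal_time(10, 5), "tmax")
})

test_that("engine thermal-time accumulation matches a day-loop oracle", {
  w <- generate_weather("RR", 2, seed = 31)
  s <- simulate_season(claire(), w, mgmt = management("UK", "potential"),
                       return_daily = TRUE)
  d <- w$days[s$daily$das + which(w$days$doy == 293)[1], ]
  oracle <- 0
  for (i in seq_len(nrow(d)))  # brute-force accumulation
    oracle <- oracle + max(0, (d$tmin[i] + d$tmax[i]) / 2)
  expect_equal(sum(s$daily$tt), oracle, tolerance = 1e-9)
})

test_that("vernalisation accrues only in the effective window", {
  cst <- crop_constants()
  p <- 0
  for (i in seq_len(ceiling(cst$vern_days)))  # full-credit 5 degC days
    p <- vernalisation_step(p, 3, 7, cst)
  expect_equal(p, 1)
  expect_equal(vernalisation_step(0.4, 26, 34), 0.4) # 30 degC: no progress
  # partial credit on the warm ramp
  mid <- cst$vern_tmax + cst$vern_ramp / 2
  expect_equal(vernalisation_step(0, mid - 4, mid + 4, cst),
               0.5 / cst$vern_days)
  # mixed series equals a brute-force daily accumulation oracle
  set.seed(1)
  tmin <- runif(120, -4, 12); tmax <- tmin + 8
  p <- 0
  for (i in 1:120) p <- vernalisation_step(p, tmin[i], tmax[i], cst)
  tm <- (tmin + tmax) / 2
  credit <- ifelse(tm < cst$vern_tmin, 0,
            ifelse(tm <= cst$vern_tmax, 1,
                   pmax(0, (cst$vern_tmax + cst$vern_ramp - tm) /
                          cst$vern_ramp)))
  expect_equal(p, min(1, sum(credit) / cst$vern_days))
})

test_that("final leaf number responds to daylength and vernalisation", {
  cst <- crop_constants()
  expect_equal(final_leaf_number(0.5, 1, cst$daylength_cap), cst$base_fln)
  expect_equal(final_leaf_number(0, 1, 8), final_leaf_number(0, 1, 16))
  d <- seq(6, 18, by = 0.5)
  fln <- final_leaf_number(0.565, 1, d)
  expect_true(all(diff(fln) <= 0))
  # unfulfilled vernalisation adds leaves
  expect_gt(final_leaf_number(0.5, 0.4, 12), final_leaf_number(0.5, 1, 12))
  expect_lte(final_leaf_number(0.9, 0, 1), cst$max_fln)
})

test_that("leaf appearance is thermal time over the phyllochron", {
  expect_equal(leaf_appearance_step(110, 110), 1)
  expect_equal(leaf_appearance_step(110, 55), 2 * leaf_appearance_step(110, 110))
  expect_error(leaf_appearance_step(10, 0), "ph")
})

test_that("Beer-law interception behaves at the limits and at k=0.45", {
  expect_equal(intercepted_par(0, 20), 0)
  expect_equal(intercepted_par(50, 20, k = 0.45), 10, tolerance = 1e-6)
  expect_equal(intercepted_par(6, 20, k = 0.45), 9.327945, tolerance = 1e-6)
  expect_error(intercepted_par(-1, 20), "lai")
})

test_that("growth and stress factors behave per definition", {
  expect_equal(daily_growth(10, 3, 1, 1, 0), 0)
  expect_equal(daily_growth(10, 3, 1.1, 0.5, 0.5), 10 * 3 * 1.1 * 0.25)
  expect_error(daily_growth(10, 3, 1, 1.2, 1), "factors")
  expect_equal(water_stress_factor(3, 0), 1)
  expect_equal(water_stress_factor(0, 5, "potential"), 1)
  expect_equal(water_stress_factor(5, 5), 1)
  expect_equal(water_stress_factor(0, 5), 0)
  expect_equal(temp_factor(c(-2, 0, 5, 15, 37, 40)), c(0, 0, 0.5, 1, 0, 0))
})

test_that("flowering-stress multiplier is 1 without stress and <1 with heat", {
  expect_equal(flowering_stress_effects(25, 1), 1)
  expect_lt(flowering_stress_effects(38, 1), 1)
  expect_lt(flowering_stress_effects(25, 0.1), 1)
})

test_that("above-ground mass balance closes over a season", {
  w <- generate_weather("RR", 2, seed = 8)
  for (mode in c("potential", "water_limited")) {
    s <- simulate_season(claire(), w, mgmt = management("UK", mode),
                         return_daily = TRUE)
    expect_equal(sum(s$daily$d_biomass), 100 * s$total_biomass,
                 tolerance = 1e-6)
    expect_equal(sum(s$daily$d_grain), 100 * s$grain_yield, tolerance = 1e-6)
    expect_lte(s$grain_yield, s$total_biomass)
    expect_equal(s$hi, s$grain_yield / s$total_biomass, tolerance = 1e-9)
    expect_lte(s$cum_intercepted_radiation, s$cum_incident_radiation)
  }
})

test_that("reference-cultivar anthesis at Rothamsted falls in mid June", {
  ys <- simulate_reference("RR", "potential", seed = 12, n_years = 15)
  expect_gt(mean(ys$seasons$anthesis_doy), 145)  # late May
  expect_lt(mean(ys$seasons$anthesis_doy), 170)  # late June
})

test_that("season water balance closes to 1e-6 mm", {
  w <- generate_weather("LI", 2, seed = 8)
  for (mode in c("potential", "water_limited")) {
    s <- simulate_season(claire(), w, mgmt = management("NZ", mode),
                         return_daily = TRUE)
    d <- s$daily
    soil0 <- sum(default_soil("NZ")$water_content)
    resid <- sum(d$precip) + sum(d$irrigation) -
      (utils::tail(d$soil_storage, 1) - soil0) -
      sum(d$transpiration) - sum(d$soil_evap) - sum(d$drainage)
    expect_lt(abs(resid), 1e-6)
  }
})

test_that("phenology is ordered and grain-fill thermal time is exact", {
  w <- generate_weather("RR", 2, seed = 13)
  s <- simulate_season(claire(), w, mgmt = management("UK", "potential"),
                       return_daily = TRUE)
  d <- s$daily
  expect_true(all(diff(d$phase) >= 0))           # monotone forward
  emergence <- min(d$das[d$phase >= 1])
  expect_gt(emergence, 0)
  expect_lt(emergence, s$anthesis_das)
  expect_lt(s$anthesis_das, s$maturity_das)
  expect_lte(s$grainfill_tt, claire()$gf + 1e-9)
  # with generous stay-green the canopy outlasts G_f: thermal time == G_f
  cv <- cultivar_params(110, 0.565, 650, 0.007, 1.5, 3, 1.27)
  s2 <- simulate_season(cv, w, mgmt = management("UK", "potential"))
  expect_equal(s2$grainfill_tt, 650)
})

test_that("potential mode yields at least the water-limited yield", {
  w <- generate_weather("LI", 2, seed = 77)
  set.seed(99)
  for (i in 1:5) {
    cv <- random_cultivar()
    yp <- simulate_season(cv, w, mgmt = management("NZ", "potential"))$grain_yield
    yw <- simulate_season(cv, w, mgmt = management("NZ", "water_limited"))$grain_yield
    expect_gte(yp, yw - 1e-9)
  }
})

test_that("the LUE uplift raises season biomass by at most its own factor", {
  w <- generate_weather("RR", 2, seed = 4)
  b1 <- simulate_season(claire(), w,
                        mgmt = management("UK", "water_limited"))$total_biomass
  b2 <- simulate_season(claire(), w,
                        mgmt = management("UK", "water_limited",
                                          lue_multiplier = 1.10))$total_biomass
  expect_gt(b2 / b1, 1.00)
  expect_lte(b2 / b1, 1.10 + 1e-9)
})

test_that("G_f and stay-green act monotonically under potential mode", {
  w <- generate_weather("RR", 2, seed = 15)
  mg <- management("UK", "potential")
  mk <- function(gf, sg) cultivar_params(110, 0.565, gf, 0.007, sg, 3, 1.27)
  y <- vapply(c(500, 700, 900), function(gf)
    simulate_season(mk(gf, 1.5), w, mgmt = mg)$grain_yield, 0)
  expect_true(all(diff(y) >= -1e-9))
  # larger stay-green: strictly longer post-anthesis green-area duration and
  # no less post-anthesis intercepted radiation
  post_green <- function(sg) {
    s <- simulate_season(mk(650, sg), w, mgmt = mg, return_daily = TRUE)
    d <- s$daily
    list(days = sum(d$das >= s$anthesis_das & d$lai > 0.05),
         rad = sum(d$int_rad[d$das >= s$anthesis_das]))
  }
  lo <- post_green(0.5); hi <- post_green(1.13)
  expect_gt(hi$days, lo$days)
  expect_gte(hi$rad, lo$rad)
})

test_that("degenerate weather and exhausted series are handled", {
  wz <- constant_weather(700, tmin = 8, tmax = 16, precip = 2, radiation = 0)
  s <- simulate_season(claire(), wz, mgmt = management("UK", "potential"))
  expect_lt(s$grain_yield, 1e-6)
  wshort <- constant_weather(120)
  expect_error(simulate_season(claire(), wshort,
                               mgmt = management("UK", "potential")),
               "season incomplete")
})

test_that("seasons are deterministic for fixed inputs", {
  w <- generate_weather("RR", 2, seed = 6)
  s1 <- simulate_season(claire(), w, mgmt = management("UK", "water_limited"))
  s2 <- simulate_season(claire(), w, mgmt = management("UK", "water_limited"))
  expect_identical(s1[names(s1) != "daily"], s2[names(s2) != "daily"])
})

test_that("flowering stress is negligible under baseline climate but real under heat", {
  w <- generate_weather("RR", 21, seed = 44)
  mg_on <- management("UK", "water_limited")
  mg_off <- management("UK", "water_limited", flowering_stress = FALSE)
  y_on <- simulate_years(claire(), w, mgmt = mg_on)$mean_yield
  y_off <- simulate_years(claire(), w, mgmt = mg_off)$mean_yield
  expect_lt(abs(y_on / y_off - 1), 0.01)
  # synthetic heat wave through the flowering window
  w2 <- generate_weather("RR", 2, seed = 44)
  s <- simulate_season(claire(), w2, mgmt = mg_off)
  idx <- which(w2$days$doy == 293)[1] + s$anthesis_das + (-12:5)
  w2$days$tmax[idx] <- 38
  w2$days$tmin[idx] <- pmax(w2$days$tmin[idx], 24)
  y_hot_on <- simulate_season(claire(), w2, mgmt = mg_on)$grain_yield
  y_hot_off <- simulate_season(claire(), w2, mgmt = mg_off)$grain_yield
  expect_lt(y_hot_on, y_hot_off)
})

test_that("simulate_years aggregates seasons correctly", {
  w <- constant_weather(365 * 4)
  ys <- simulate_years(claire(), w, mgmt = management("UK", "potential"))
  expect_equal(ys$cv_yield, 0, tolerance = 1e-9)   # identical weather
  expect_equal(ys$mean_yield, mean(ys$seasons$grain_yield))
  w2 <- generate_weather("RR", 3, seed = 2)
  ys2 <- simulate_years(claire(), w2, mgmt = management("UK", "potential"))
  expect_equal(ys2$n_seasons, 2L)  # 3 years -> 2 complete UK seasons
  expect_equal(ys2$cv_yield,
               stats::sd(ys2$seasons$grain_yield) / mean(ys2$seasons$grain_yield))
})

test_that("cultivar and soil files read and write consistently", {
  path <- withr::local_tempfile(fileext = ".cfg")
  write_cultivar(claire(), path)
  cl <- read_cultivar(path)
  expect_equal(cl[c("ph", "pp", "gf", "amax", "sg", "ru", "wss")],
               claire()[c("ph", "pp", "gf", "amax", "sg", "ru", "wss")])
  shipped <- read_cultivar(system.file("extdata", "claire.cfg",
                                       package = "wheatgap"))
  expect_equal(shipped$ph, 110); expect_equal(shipped$pp, 0.565)
  expect_equal(shipped$gf, 650); expect_equal(shipped$wss, 1.27)
  expect_error(read_cultivar(withr::local_tempfile()), "not found")
  soil <- read_soil(system.file("extdata", "lincoln_270.cfg",
                                package = "wheatgap"))
  expect_equal(soil$total_awc, 270)
  expect_equal(sum(soil$awc_per_layer), 270)
  spath <- withr::local_tempfile(fileext = ".cfg")
  write_soil(soil, spath)
  expect_equal(read_soil(spath), soil)
})
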