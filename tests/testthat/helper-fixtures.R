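# Shared test fixtures, built in code.

# A weather_series with fully controlled daily values. Days start at
# `start_doy` and wrap over 365-day years; the site defaults to Rothamsted
# so that UK management (sowing doy 293) applies.
constant_weather <- function(n_days, tmin = 8, tmax = 16, precip = 2,
                             radiation = 12, start_doy = 290,
                             site = builtin_sites()[["RR"]]) {
  doy <- ((start_doy - 1 + seq_len(n_days) - 1) %% 365) + 1
  days <- data.frame(
    day_index = seq_len(n_days),
    year = cumsum(c(TRUE, diff(doy) < 0)),
    doy = doy,
    tmin = rep_len(tmin, n_days), tmax = rep_len(tmax, n_days),
    precip = rep_len(precip, n_days), radiation = rep_len(radiation, n_days)
  )
  structure(list(site = site, n_years = ceiling(n_days / 365),
                 seed = 0L, days = days),
            class = "weather_series")
}

# A random cultivar drawn within the optimization trait bounds.
random_cultivar <- function() {
  b <- trait_bounds("water_limited")
  v <- vapply(b, function(x) stats::runif(1, x[1], x[2]), 0)
  cultivar_params(v[["ph"]], v[["pp"]], v[["gf"]], v[["amax"]],
                  v[["sg"]], v[["ru"]], v[["wss"]], name = "random")
}

# Concave quadratic fitness with a known in-bounds argmax, for optimizer
# verification. Returns list(fitness, argmax).
quadratic_fitness <- function(bounds, frac = 0.35) {
  target <- vapply(bounds, function(b) b[1] + frac * (b[2] - b[1]), 0)
  rng <- vapply(bounds, diff, 0)
  list(
    fitness = function(tr) 20 - 10 * sum(((tr - target) / rng)^2),
    argmax = target
  )
}
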