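# Seed handling: run `expr` under a local RNG stream, restoring any existing
# .Random.seed afterwards so package functions never disturb the caller's RNG.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483629)
}

#' Generate a synthetic daily weather series for a site
#'
#' A seeded, reduced stochastic weather generator whose long-run statistics
#' reproduce a site's climate normals. Mean temperature follows an annual
#' sinusoid (phase set by hemisphere: warmest near mid-July in the north,
#' mid-January in the south) plus a small semi-annual harmonic, with AR(1)
#' Gaussian residuals; tmin/tmax are the daily mean minus/plus half the
#' diurnal range. Precipitation occurrence is a two-state Markov chain
#' (unconditional wet-day probability and wet-day persistence) with
#' exponentially distributed wet-day amounts scaled so the expected annual
#' total equals the site target. Radiation follows an annual sinusoid
#' peaking at the summer solstice, damped 25% on wet days, rescaled to preserve the target mean, and capped
#' below the extraterrestrial bound. Years are 365 days (no leap days).
#' All outputs are rounded to 2 decimals, the precision of the weather file
#' format, so write/read round trips are exact.
#'
#' @param site A [site_climate()] object or a built-in site code
#'   (`"ED","LE","RR","GO","LI","PU"`).
#' @param n_years Number of 365-day years to generate (>= 1).
#' @param seed Integer seed; identical inputs give identical series.
#' @return A `weather_series`: list with `site`, `n_years`, `seed` and
#'   `days`, a data.frame with columns `day_index`, `year`, `doy`, `tmin`,
#'   `tmax`, `precip`, `radiation`.
#' @examples
#' w <- generate_weather("RR", 2, seed = 1)
#' summarize_climate(w)
#' @export
generate_weather <- function(site, n_years, seed) {
  if (is.character(site)) {
    sites <- builtin_sites()
    if (!site %in% names(sites))
      stop(sprintf("unknown site '%s'; built-in sites: %s",
                   site, paste(names(sites), collapse = ", ")))
    site <- sites[[site]]
  }
  if (!inherits(site, "site_climate")) stop("site must be a site_climate or site code")
  if (!is.numeric(n_years) || length(n_years) != 1L || is.na(n_years) ||
      n_years < 1 || n_years != round(n_years))
    stop("n_years must be a positive integer")
  n_years <- as.integer(n_years)

  n <- n_years * 365L
  doy <- rep.int(1:365, n_years)
  year <- rep(seq_len(n_years), each = 365L)
  peak <- if (site$latitude >= 0) 200 else 17    # warmest day of year
  rad_peak <- if (site$latitude >= 0) 172 else 355  # solstice
  ang <- 2 * pi * (doy - peak) / 365
  rad_ang <- 2 * pi * (doy - rad_peak) / 365

  with_local_seed(seed, {
    # temperature: annual + semi-annual harmonics + AR(1) residual
    tbar <- site$mean_temp +
      site$seasonal_temp_amplitude * cos(ang) +
      site$semiannual_temp_amplitude * cos(2 * ang)
    rho <- site$temp_residual_ar1
    z <- stats::rnorm(n, sd = site$temp_residual_sd * sqrt(1 - rho^2))
    resid <- as.numeric(stats::filter(z, rho, method = "recursive"))
    tmean <- tbar + resid
    tmin <- tmean - site$diurnal_range / 2
    tmax <- tmean + site$diurnal_range / 2

    # precipitation: two-state Markov occurrence, exponential amounts
    pw <- site$wet_day_prob
    p11 <- site$precip_autocorr
    p01 <- pw * (1 - p11) / (1 - pw)
    u <- stats::runif(n)
    wet <- logical(n)
    wet[1] <- u[1] < pw
    for (i in 2:n) wet[i] <- u[i] < if (wet[i - 1]) p11 else p01
    mu <- site$annual_precip / (365 * pw)
    precip <- numeric(n)
    precip[wet] <- stats::rexp(sum(wet), rate = 1 / mu)

    # radiation: annual cycle, wet-day damping, rescale, physical cap
    rad <- site$mean_radiation * (1 + site$radiation_amplitude_frac * cos(rad_ang))
    rad <- pmax(rad, 0.05 * site$mean_radiation)
    rad[wet] <- rad[wet] * 0.75
    rad <- rad * site$mean_radiation / mean(rad)
    rad <- pmin(rad, 0.95 * extraterrestrial_radiation(site$latitude, doy))

    days <- data.frame(
      day_index = seq_len(n), year = year, doy = doy,
      tmin = round(tmin, 2), tmax = round(tmax, 2),
      precip = round(precip, 2), radiation = round(rad, 2)
    )
    structure(list(site = site, n_years = n_years, seed = as.integer(seed),
                   days = days),
              class = "weather_series")
  })
}

#' @export
print.weather_series <- function(x, ...) {
  s <- summarize_climate(x)
  cat(sprintf("<weather_series> %s: %d years (%d days), seed %d\n",
              x$site$site_id, x$n_years, nrow(x$days), x$seed))
  cat(sprintf("  realised: %.2f degC | %.0f mm/yr | %.2f MJ/m2/day\n",
              s$mean_temp, s$annual_precip, s$mean_radiation))
  invisible(x)
}

#' Write a weather series to a plain-text file
#'
#' Self-documenting columnar text format: `#`-prefixed header lines carrying
#' site metadata, then one TAB-separated row per day with columns
#' `DOY TMIN_C TMAX_C RAIN_MM SRAD_MJ` at 2 decimal places.
#'
#' @param series A `weather_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(series, path) {
  stopifnot(inherits(series, "weather_series"))
  d <- series$days
  s <- series$site
  num_fields <- setdiff(names(s), c("site_id", "country"))
  hdr <- c(
    sprintf("# site_id: %s", s$site_id),
    sprintf("# country: %s", s$country),
    sprintf("# %s: %.17g", num_fields, vapply(s[num_fields], as.numeric, 0)),
    sprintf("# n_years: %d", series$n_years),
    sprintf("# seed: %d", series$seed),
    "# columns: DOY\tTMIN_C\tTMAX_C\tRAIN_MM\tSRAD_MJ"
  )
  rows <- sprintf("%d\t%.2f\t%.2f\t%.2f\t%.2f",
                  d$doy, d$tmin, d$tmax, d$precip, d$radiation)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a weather series written by [write_weather()]
#'
#' Validates the header and every data row; malformed rows, negative
#' precipitation, `tmax < tmin` or non-monotone day sequences are rejected
#' with the offending line number.
#'
#' @param path File path.
#' @return A `weather_series`. Site metadata from the header is attached;
#'   generator-only site parameters take defaults.
#' @export
read_weather <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  nhdr <- match(FALSE, is_hdr) - 1L
  if (is.na(nhdr)) nhdr <- length(lines)
  hdr <- lines[seq_len(nhdr)]
  get_hdr <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m) != 1L) stop(sprintf("malformed header: missing '%s'", key))
    trimws(sub(sprintf("^# %s:", key), "", m))
  }
  site_id <- get_hdr("site_id"); country <- get_hdr("country")
  num_fields <- c("latitude", "longitude", "mean_temp", "annual_precip",
                  "mean_radiation", "seasonal_temp_amplitude",
                  "semiannual_temp_amplitude", "radiation_amplitude_frac",
                  "wet_day_prob", "precip_autocorr", "temp_residual_sd",
                  "temp_residual_ar1", "diurnal_range")
  vals <- lapply(num_fields, function(k) as.numeric(get_hdr(k)))
  names(vals) <- num_fields
  n_years <- as.integer(get_hdr("n_years")); seed <- as.integer(get_hdr("seed"))
  if (anyNA(unlist(vals)) || is.na(n_years))
    stop("malformed header: non-numeric site field or n_years")

  body <- lines[-seq_len(nhdr)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 5L)
  if (length(bad))
    stop(sprintf("malformed row at line %d: expected 5 tab-separated fields",
                 nhdr + bad[1]))
  m <- matrix(as.numeric(unlist(fields)), ncol = 5, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("non-numeric value at line %d", nhdr + bad))
  }
  doy <- m[, 1]
  if (any(m[, 4] < 0)) {
    bad <- which(m[, 4] < 0)[1]
    stop(sprintf("negative precipitation at line %d", nhdr + bad))
  }
  if (any(m[, 3] < m[, 2])) {
    bad <- which(m[, 3] < m[, 2])[1]
    stop(sprintf("tmax < tmin at line %d", nhdr + bad))
  }
  if (any(m[, 5] < 0)) {
    bad <- which(m[, 5] < 0)[1]
    stop(sprintf("negative radiation at line %d", nhdr + bad))
  }
  jump <- diff(doy)
  bad <- which(!(jump == 1 | jump < 0))  # within-year increment or year wrap
  if (length(bad))
    stop(sprintf("non-monotone day sequence at line %d", nhdr + bad[1] + 1L))
  site <- do.call(site_climate, c(list(site_id = site_id, country = country), vals))
  days <- data.frame(
    day_index = seq_len(nrow(m)),
    year = cumsum(c(TRUE, jump < 0)),
    doy = as.integer(doy),
    tmin = m[, 2], tmax = m[, 3], precip = m[, 4], radiation = m[, 5]
  )
  structure(list(site = site, n_years = n_years, seed = seed, days = days),
            class = "weather_series")
}
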