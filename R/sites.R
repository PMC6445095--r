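#' Construct a site climate description
#'
#' A `site_climate` object holds the location and the long-run climate
#' statistics that the stochastic weather generator is parameterised on:
#' annual mean temperature, annual precipitation total, mean daily global
#' radiation, plus the generator-only parameters (seasonal amplitudes,
#' wet-day occurrence/persistence, residual variability, diurnal range).
#'
#' @param site_id Short site code (e.g. `"RR"`).
#' @param country `"UK"` or `"NZ"`.
#' @param latitude,longitude Decimal degrees; southern latitudes negative.
#' @param mean_temp Annual mean air temperature, degrees C.
#' @param annual_precip Annual precipitation, mm yr^-1.
#' @param mean_radiation Mean daily global radiation, MJ m^-2 day^-1.
#' @param seasonal_temp_amplitude Half peak-to-trough of the annual
#'   temperature cycle, degrees C.
#' @param semiannual_temp_amplitude Second-harmonic amplitude, degrees C.
#'   Positive values warm both solstices and cool the equinoxes relative to
#'   a pure sinusoid, reproducing the broad summer plateau of maritime
#'   temperate climates while leaving the annual mean unchanged.
#' @param radiation_amplitude_frac Relative amplitude of the annual
#'   radiation cycle (fraction of the mean).
#' @param wet_day_prob Unconditional probability that a day is wet.
#' @param precip_autocorr Wet-day persistence P(wet | wet yesterday).
#' @param temp_residual_sd Standard deviation of the AR(1) daily temperature
#'   residual, degrees C.
#' @param temp_residual_ar1 Lag-1 autocorrelation of temperature residuals.
#' @param diurnal_range Daily tmax - tmin, degrees C.
#' @return An object of class `site_climate`.
#' @export
site_climate <- function(site_id, country, latitude, longitude,
                         mean_temp, annual_precip, mean_radiation,
                         seasonal_temp_amplitude = if (latitude >= 0) 6.5 else 5.0,
                         semiannual_temp_amplitude = 0.8,
                         radiation_amplitude_frac = 0.8,
                         wet_day_prob = 0.45,
                         precip_autocorr = 0.65,
                         temp_residual_sd = 2.5,
                         temp_residual_ar1 = 0.7,
                         diurnal_range = 8) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  country <- match.arg(country, c("UK", "NZ"))
  if (latitude < -90 || latitude > 90) stop("latitude must be in [-90, 90]")
  if (country == "NZ" && latitude >= 0) stop("NZ sites must have latitude < 0")
  if (country == "UK" && latitude <= 0) stop("UK sites must have latitude > 0")
  if (mean_radiation <= 0) stop("mean_radiation must be > 0")
  if (annual_precip < 0) stop("annual_precip must be >= 0")
  if (wet_day_prob <= 0 || wet_day_prob >= 1) stop("wet_day_prob must be in (0,1)")
  if (precip_autocorr <= 0 || precip_autocorr >= 1) stop("precip_autocorr must be in (0,1)")
  structure(list(
    site_id = site_id, country = country,
    latitude = latitude, longitude = longitude,
    mean_temp = mean_temp, annual_precip = annual_precip,
    mean_radiation = mean_radiation,
    seasonal_temp_amplitude = seasonal_temp_amplitude,
    semiannual_temp_amplitude = semiannual_temp_amplitude,
    radiation_amplitude_frac = radiation_amplitude_frac,
    wet_day_prob = wet_day_prob, precip_autocorr = precip_autocorr,
    temp_residual_sd = temp_residual_sd,
    temp_residual_ar1 = temp_residual_ar1,
    diurnal_range = diurnal_range
  ), class = "site_climate")
}

#' @export
print.site_climate <- function(x, ...) {
  cat(sprintf("<site_climate> %s (%s)  lat %.2f lon %.2f\n",
              x$site_id, x$country, x$latitude, x$longitude))
  cat(sprintf("  mean temp %.1f degC | precip %.0f mm/yr | radiation %.1f MJ/m2/day\n",
              x$mean_temp, x$annual_precip, x$mean_radiation))
  invisible(x)
}

#' Built-in study sites
#'
#' The six wheat-growing study sites: Edinburgh (ED), Leeds (LE) and
#' Rothamsted (RR) in the UK; Gore (GO), Lincoln (LI) and Pukekohe (PU) in
#' New Zealand, with their 1981--2010 climate normals (annual mean air
#' temperature, annual precipitation, mean daily global radiation).
#' Generator-only parameters take the documented defaults of
#' [site_climate()].
#'
#' @return A named list of six `site_climate` objects.
#' @examples
#' builtin_sites()[["RR"]]
#' @export
builtin_sites <- function() {
  sites <- list(
    site_climate("ED", "UK",  55.94,  -3.31,  8.6,  717,  8.7),
    site_climate("LE", "UK",  54.30,  -1.53,  9.5,  626,  8.6),
    site_climate("RR", "UK",  51.80,  -0.35,  9.8,  700,  9.8),
    site_climate("GO", "NZ", -46.12, 168.89,  9.8,  976, 12.4),
    site_climate("LI", "NZ", -43.70, 172.00, 11.6,  596, 13.6),
    site_climate("PU", "NZ", -37.21, 174.86, 14.5, 1296, 14.0)
  )
  names(sites) <- vapply(sites, `[[`, "", "site_id")
  sites
}

#' Summarise climate of sites or of a generated weather series
#'
#' For a list of [site_climate()] objects, returns the unweighted means of
#' the target statistics across sites. For a `weather_series`, returns the
#' realised long-run statistics of the generated daily record (mean of
#' (tmin+tmax)/2, mean annual precipitation total, mean daily radiation).
#'
#' @param x A `weather_series`, a `site_climate`, or a list of `site_climate`.
#' @return A list with `mean_temp` (degC), `annual_precip` (mm yr^-1) and
#'   `mean_radiation` (MJ m^-2 day^-1).
#' @export
summarize_climate <- function(x) {
  if (inherits(x, "weather_series")) {
    d <- x$days
    if (nrow(d) == 0L) stop("empty weather series")
    return(list(
      mean_temp = mean((d$tmin + d$tmax) / 2),
      annual_precip = sum(d$precip) / x$n_years,
      mean_radiation = mean(d$radiation)
    ))
  }
  if (inherits(x, "site_climate")) x <- list(x)
  if (!is.list(x) || length(x) == 0L ||
      !all(vapply(x, inherits, TRUE, "site_climate")))
    stop("input must be a weather_series or a non-empty list of site_climate")
  list(
    mean_temp = mean(vapply(x, `[[`, 0, "mean_temp")),
    annual_precip = mean(vapply(x, `[[`, 0, "annual_precip")),
    mean_radiation = mean(vapply(x, `[[`, 0, "mean_radiation"))
  )
}

#' Country climate contrasts between the NZ and UK site sets
#'
#' Computes the NZ-vs-UK contrasts of the site climate normals: temperature
#' difference, precipitation and radiation ratios, and the photothermal
#' quotient (radiation/temperature) ratio. The PTQ contrast is reported both
#' as the ratio of country means and as the ratio of country-mean site-level
#' PTQs, since the two averaging orders differ.
#'
#' @param sites A list of the six built-in `site_climate` objects (default).
#' @return A list of contrasts; percentage fields are in percent.
#' @export
climate_contrasts <- function(sites = builtin_sites()) {
  cn <- vapply(sites, `[[`, "", "country")
  uk <- summarize_climate(unname(sites[cn == "UK"]))
  nz <- summarize_climate(unname(sites[cn == "NZ"]))
  ptq_site <- function(s) s$mean_radiation / s$mean_temp
  list(
    uk = uk, nz = nz,
    delta_temp = nz$mean_temp - uk$mean_temp,
    precip_ratio_pct = 100 * (nz$annual_precip / uk$annual_precip - 1),
    radiation_ratio_pct = 100 * (nz$mean_radiation / uk$mean_radiation - 1),
    ptq_ratio_of_means_pct = 100 *
      ((nz$mean_radiation / nz$mean_temp) / (uk$mean_radiation / uk$mean_temp) - 1),
    ptq_mean_of_site_ratios_pct = 100 *
      (mean(vapply(unname(sites[cn == "NZ"]), ptq_site, 0)) /
         mean(vapply(unname(sites[cn == "UK"]), ptq_site, 0)) - 1)
  )
}
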