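#' Daily extraterrestrial radiation
#'
#' Computes the daily total solar radiation at the top of the atmosphere for
#' a latitude and day of year, following the standard FAO-56 closed form
#' (inverse relative Earth--Sun distance, solar declination, sunset hour
#' angle). Used as a physical upper bound for generated surface radiation.
#'
#' @param latitude Latitude in decimal degrees (south negative).
#' @param doy Day of year, 1--366. Vectorised over `latitude` and `doy`.
#' @return Extraterrestrial radiation in MJ m^-2 day^-1.
#' @examples
#' extraterrestrial_radiation(51.8, 172)
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  stopifnot(all(latitude >= -90), all(latitude <= 90),
            all(doy >= 1), all(doy <= 366))
  gsc <- 0.0820 # solar constant, MJ m^-2 min^-1
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(dec))))
  24 * 60 / pi * gsc * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

#' Astronomical daylength
#'
#' Daylength in hours from the standard solar-declination formula. The
#' default sun angle of -0.833 degrees accounts for atmospheric refraction
#' and the solar disc; set `sun_angle = -6` for civil twilight.
#'
#' @param latitude Latitude in decimal degrees (south negative).
#' @param doy Day of year, 1--366.
#' @param sun_angle Solar elevation angle (degrees) defining sunrise/sunset.
#' @return Daylength in hours, in `[0, 24]`.
#' @examples
#' daylength(51.8, 172)
#' @export
daylength <- function(latitude, doy, sun_angle = -0.833) {
  stopifnot(all(latitude >= -90), all(latitude <= 90),
            all(doy >= 1), all(doy <= 366))
  phi <- latitude * pi / 180
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  cosws <- (sin(sun_angle * pi / 180) - sin(phi) * sin(dec)) /
    (cos(phi) * cos(dec))
  24 / pi * acos(pmin(1, pmax(-1, cosws)))
}
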