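#' Construct a soil water profile
#'
#' The soil is a cascade of 5-cm layers, each holding `total_awc / n_layers`
#' mm of plant-available water. Infiltration fills layers from the top;
#' overflow below the bottom layer is drainage. The water-extraction
#' efficiency profile `lambda` declines linearly with depth; the daily
#' extractable fraction of a layer's available water is `lambda * ru / 3`,
#' where `ru` is the cultivar's root water-uptake rate (%, trait range
#' 1--5): the lambda profile applies as-is at the reference cultivar's
#' rate (ru = 3), so its top layer yields 10% of available water per day.
#'
#' @param total_awc Total plant-available water capacity, mm.
#' @param n_layers Number of 5-cm layers (default 30, i.e. 150 cm).
#' @param lambda_top,lambda_bottom Extraction-efficiency profile endpoints.
#' @param name Profile name.
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(total_awc, n_layers = 30L,
                         lambda_top = 0.10, lambda_bottom = 0.04,
                         name = "custom") {
  if (!is.numeric(total_awc) || total_awc <= 0) stop("total_awc must be > 0")
  if (n_layers < 1) stop("n_layers must be >= 1")
  n_layers <- as.integer(n_layers)
  awc <- rep(total_awc / n_layers, n_layers)
  lambda <- if (n_layers == 1L) lambda_top else
    seq(lambda_top, lambda_bottom, length.out = n_layers)
  structure(list(
    name = name, layer_thickness_cm = 5, n_layers = n_layers,
    awc_per_layer = awc, total_awc = total_awc, lambda = lambda,
    water_content = awc  # initialised full
  ), class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf("<soil_profile> %s: %d x 5 cm layers, AWC %.0f mm (%.0f mm stored)\n",
              x$name, x$n_layers, x$total_awc, sum(x$water_content)))
  invisible(x)
}

#' Built-in soil profiles
#'
#' `rothamsted_210()` (210 mm AWC, used for all UK sites) and
#' `lincoln_270()` (270 mm AWC, used for all NZ sites).
#'
#' @return A `soil_profile`.
#' @export
rothamsted_210 <- function() soil_profile(210, name = "Rothamsted")

#' @rdname rothamsted_210
#' @export
lincoln_270 <- function() soil_profile(270, name = "Lincoln")

#' Default soil for a country
#' @param country `"UK"` or `"NZ"`.
#' @return A `soil_profile`.
#' @export
default_soil <- function(country) {
  switch(match.arg(country, c("UK", "NZ")),
         UK = rothamsted_210(), NZ = lincoln_270())
}

#' Read / write soil profile files
#'
#' `key = value` text with `name`, `total_awc`, `n_layers` and the lambda
#' endpoints. Packaged files: `rothamsted_210.cfg`, `lincoln_270.cfg`.
#'
#' @param path File path.
#' @return `read_soil()` returns a `soil_profile`.
#' @export
read_soil <- function(path) {
  if (!file.exists(path)) stop(sprintf("soil file not found: %s", path))
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop(sprintf("malformed line in %s", path))
  x <- as.list(trimws(vapply(kv, `[[`, "", 2)))
  names(x) <- trimws(vapply(kv, `[[`, "", 1))
  soil_profile(total_awc = as.numeric(x$total_awc),
               n_layers = as.integer(x$n_layers),
               lambda_top = as.numeric(x$lambda_top),
               lambda_bottom = as.numeric(x$lambda_bottom),
               name = x$name)
}

#' @rdname read_soil
#' @param soil A `soil_profile` to write.
#' @export
write_soil <- function(soil, path) {
  stopifnot(inherits(soil, "soil_profile"))
  writeLines(c(
    sprintf("name = %s", soil$name),
    sprintf("total_awc = %.17g", soil$total_awc),
    sprintf("n_layers = %d", soil$n_layers),
    sprintf("lambda_top = %.17g", soil$lambda[1]),
    sprintf("lambda_bottom = %.17g", soil$lambda[soil$n_layers])
  ), path)
  invisible(path)
}
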