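#' Optimizable trait bounds
#'
#' The ranges of genetic variation used when designing ideotypes:
#' phyllochron `ph` (degC day), daylength response `pp` (leaf h^-1),
#' grain-fill duration `gf` (degC day), potential flag-leaf area `amax`
#' (m^2 leaf m^-2 soil), stay-green factor `sg` (-), root water-uptake rate
#' `ru` (% day^-1) and maximum water-stress acceleration of senescence
#' `wss` (-).
#'
#' @param mode `"water_limited"` includes all seven traits; `"potential"`
#'   excludes `wss`, which has no effect without water stress.
#' @return A named list of `c(lower, upper)` pairs.
#' @export
trait_bounds <- function(mode = c("water_limited", "potential")) {
  mode <- match.arg(mode)
  b <- list(
    ph   = c(80, 140),
    pp   = c(0.065, 0.900),
    gf   = c(500, 900),
    amax = c(0.005, 0.010),
    sg   = c(0.00, 1.50),
    ru   = c(1.0, 5.0),
    wss  = c(1.0, 1.7)
  )
  if (mode == "potential") b$wss <- NULL
  b
}

#' Construct a cultivar parameter set
#'
#' The seven optimizable traits of the simulator. Fixed physiological
#' constants (base temperature, RUE, extinction coefficient, leaf-number
#' limits, vernalisation parameters, reserve pool, ...) live in
#' [crop_constants()] and are shared across cultivars.
#'
#' @param ph Phyllochron, degC day per leaf.
#' @param pp Daylength response, additional leaves per hour of daylength
#'   shortfall below the saturating daylength.
#' @param gf Grain-fill duration, degC day of post-anthesis thermal time.
#' @param amax Potential area of the flag leaf, m^2 leaf m^-2 soil.
#' @param sg Stay-green factor (>= 0); leaf green duration in thermal time
#'   is multiplied by `1 + sg`.
#' @param ru Root water-uptake rate, percent of extractable layer water per
#'   day at unit extraction efficiency.
#' @param wss Maximum acceleration of leaf senescence under full water
#'   stress (multiplier on the senescence thermal-time clock).
#' @param name Optional cultivar name.
#' @param check_bounds If `TRUE`, require traits within [trait_bounds()].
#' @return An object of class `cultivar_params`.
#' @export
cultivar_params <- function(ph, pp, gf, amax, sg, ru, wss,
                            name = "custom", check_bounds = FALSE) {
  x <- list(ph = ph, pp = pp, gf = gf, amax = amax, sg = sg, ru = ru, wss = wss)
  if (any(vapply(x, function(v) !is.numeric(v) || length(v) != 1L || is.na(v), TRUE)))
    stop("all seven traits must be single numeric values")
  pos <- c("ph", "pp", "gf", "amax", "ru", "wss")
  if (any(unlist(x[pos]) <= 0)) stop("traits must be positive (sg may be 0)")
  if (x$sg < 0) stop("sg must be >= 0")
  if (check_bounds) {
    b <- trait_bounds("water_limited")
    for (k in names(b))
      if (x[[k]] < b[[k]][1] || x[[k]] > b[[k]][2])
        stop(sprintf("trait '%s' = %g outside bounds [%g, %g]",
                     k, x[[k]], b[[k]][1], b[[k]][2]))
  }
  structure(c(x, list(name = name)), class = "cultivar_params")
}

#' @export
print.cultivar_params <- function(x, ...) {
  cat(sprintf(
    "<cultivar_params> %s: ph=%.1f pp=%.3f gf=%.1f amax=%.4f sg=%.2f ru=%.2f wss=%.2f\n",
    x$name, x$ph, x$pp, x$gf, x$amax, x$sg, x$ru, x$wss))
  invisible(x)
}

#' The reference winter wheat cultivar Claire
#'
#' The locally adapted cultivar used as the yield-gap baseline and as the
#' seeded parent of the ideotype optimizer.
#'
#' @return A `cultivar_params` object.
#' @export
claire <- function() {
  cultivar_params(ph = 110.0, pp = 0.565, gf = 650.0, amax = 0.007,
                  sg = 0.5, ru = 3.0, wss = 1.27, name = "Claire")
}

#' Read / write cultivar parameter files
#'
#' Plain-text `key = value` format with one trait per line; `name` optional.
#' The packaged file `claire.cfg` reproduces the reference cultivar.
#'
#' @param path File path.
#' @return `read_cultivar()` returns a `cultivar_params`.
#' @export
read_cultivar <- function(path) {
  if (!file.exists(path)) stop(sprintf("cultivar file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop(sprintf("malformed line in %s", path))
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  x <- as.list(vals)
  names(x) <- keys
  need <- c("ph", "pp", "gf", "amax", "sg", "ru", "wss")
  miss <- setdiff(need, keys)
  if (length(miss))
    stop(sprintf("cultivar file %s missing traits: %s", path,
                 paste(miss, collapse = ", ")))
  args <- lapply(x[need], as.numeric)
  args$name <- if ("name" %in% keys) x[["name"]] else basename(path)
  do.call(cultivar_params, args)
}

#' @rdname read_cultivar
#' @param cultivar A `cultivar_params` to write.
#' @export
write_cultivar <- function(cultivar, path) {
  stopifnot(inherits(cultivar, "cultivar_params"))
  keys <- c("ph", "pp", "gf", "amax", "sg", "ru", "wss")
  writeLines(c(sprintf("name = %s", cultivar$name),
               sprintf("%s = %.17g", keys,
                       vapply(cultivar[keys], as.numeric, 0))), path)
  invisible(path)
}
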