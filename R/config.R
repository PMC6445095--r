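#' Default analysis configuration
#'
#' The zero-override configuration encodes the study settings: 8 parents,
#' 16 offspring, 100 evaluation years, CV threshold 0.10, HI threshold
#' 0.64, 10% LUE uplift for ideotype design, sowing 20 October (UK) /
#' 20 April (NZ), 210 mm (UK) / 270 mm (NZ) soils, and the reference
#' cultivar's trait values. Any entry can be overridden in a YAML file
#' read by [load_config()].
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    easa = list(
      n_parents = 8L, n_offspring = 16L, n_years = 100L,
      cv_threshold = 0.10, hi_threshold = 0.64,
      max_generations = 200L, stall_generations = 15L,
      lue_multiplier = 1.10
    ),
    management = list(sowing_doy_uk = 293L, sowing_doy_nz = 110L),
    soils = list(UK = "rothamsted_210", NZ = "lincoln_270"),
    reference_cultivar = list(ph = 110.0, pp = 0.565, gf = 650.0,
                              amax = 0.007, sg = 0.5, ru = 3.0, wss = 1.27),
    trait_bounds = trait_bounds("water_limited"),
    crop_constants = list()
  )
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, applies [default_config()] for any missing
#' entries, and validates: unknown keys, ill-ordered trait bounds and
#' out-of-range thresholds are rejected with the offending key path.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config file must contain a YAML mapping")
    check_keys <- function(user, ref, prefix) {
      unknown <- setdiff(names(user), names(ref))
      if (length(unknown))
        stop(sprintf("unknown config key: %s%s", prefix, unknown[1]))
      for (k in names(user))
        if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(user[[k]]))
          check_keys(user[[k]], ref[[k]], paste0(prefix, k, "/"))
    }
    # crop_constants is validated by crop_constants() itself
    ref <- cfg; ref$crop_constants <- NULL
    usr <- user; usr$crop_constants <- NULL
    check_keys(usr, ref, "")
    cfg <- utils::modifyList(cfg, user)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  e <- cfg$easa
  if (e$cv_threshold <= 0 || e$cv_threshold >= 1)
    stop("easa/cv_threshold must be in (0, 1)")
  if (e$hi_threshold <= 0 || e$hi_threshold >= 1)
    stop("easa/hi_threshold must be in (0, 1)")
  if (e$n_offspring < 1) stop("easa/n_offspring must be >= 1")
  if (e$n_parents < 1) stop("easa/n_parents must be >= 1")
  for (k in names(cfg$trait_bounds)) {
    b <- cfg$trait_bounds[[k]]
    if (length(b) != 2 || b[1] >= b[2])
      stop(sprintf("trait_bounds/%s must be an increasing pair", k))
  }
  do.call(crop_constants, cfg$crop_constants)  # rejects unknown constants
  invisible(cfg)
}

#' Write a configuration to YAML
#'
#' `load_config(save_config(cfg, path))` reproduces the effective
#' configuration.
#'
#' @param cfg A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Run manifest: configuration echo, seeds and digests sufficient to replay.
make_manifest <- function(config, stages = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  digest <- unname(tools::md5sum(tmp)); unlink(tmp)
  list(
    package = "wheatgap",
    version = as.character(utils::packageVersion("wheatgap")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = config,
    config_md5 = digest,
    stages = stages
  )
}

#' Re-run an analysis from a manifest
#'
#' A manifest stores the full configuration and master seed, so replaying
#' it reproduces the analysis tables bit-identically.
#'
#' @param manifest A manifest list or path to a `manifest.json`.
#' @param ... Passed to [run_full_analysis()].
#' @return A `yieldgap_analysis`.
#' @export
replay_manifest <- function(manifest, ...) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), manifest$config)
  validate_config(cfg)
  run_full_analysis(cfg, ...)
}
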