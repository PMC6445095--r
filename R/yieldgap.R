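#' Simulate the reference cultivar at a site
#'
#' The management-optimal yield of the locally adapted reference cultivar
#' (Y_M): no light-use-efficiency uplift, the requested water mode, and the
#' country's soil, sowing date and default management.
#'
#' @param site A `site_climate` or built-in site code.
#' @param mode `"water_limited"` or `"potential"`.
#' @param seed Integer seed for weather generation.
#' @param n_years Number of seasons (one extra weather year is generated).
#' @param cultivar Reference cultivar (default [claire()]).
#' @param weather Optional pre-generated `weather_series`.
#' @param constants See [crop_constants()].
#' @return A `yield_series` (see [simulate_years()]).
#' @export
simulate_reference <- function(site, mode = c("water_limited", "potential"),
                               seed = 1, n_years = 100, cultivar = claire(),
                               weather = NULL,
                               constants = crop_constants()) {
  mode <- match.arg(mode)
  if (is.character(site)) {
    sites <- builtin_sites()
    if (!site %in% names(sites)) stop(sprintf("unknown site '%s'", site))
    site <- sites[[site]]
  }
  if (is.null(weather))
    weather <- generate_weather(site, n_years + 1L, derive_seed(seed, 1L))
  mgmt <- management(site$country, mode, lue_multiplier = 1.00)
  simulate_years(cultivar, weather, default_soil(site$country), mgmt,
                 constants)
}

#' Yield gap between genetic yield potential and the reference cultivar
#'
#' `y_g = y_gp - y_m` and `y_g_pct = 100 * y_g / y_gp`, where `y_gp` is the
#' mean yield of the locally optimized ideotype and `y_m` the mean
#' management-optimal yield of the reference cultivar.
#'
#' @param y_gp Ideotype (genetic) yield potential, t ha^-1 (> 0).
#' @param y_m Reference cultivar yield, t ha^-1.
#' @return A list with `y_g` (t ha^-1) and `y_g_pct` (% of potential).
#' @export
yield_gap <- function(y_gp, y_m) {
  if (any(y_gp <= 0)) stop("y_gp must be > 0")
  list(y_g = y_gp - y_m, y_g_pct = 100 * (y_gp - y_m) / y_gp)
}

#' Gap expressed as a percentage of the yield potential
#'
#' Convenience for recomputing printed gap percentages from printed gap and
#' potential values (the alternative order of operations: round per site,
#' then average, then divide).
#'
#' @param y_g Yield gap, t ha^-1.
#' @param y_gp Yield potential, t ha^-1 (> 0).
#' @return Percentage of potential.
#' @export
gap_percent <- function(y_g, y_gp) {
  if (any(y_gp <= 0)) stop("y_gp must be > 0")
  100 * y_g / y_gp
}

#' Aggregate site yield-gap reports to country level
#'
#' Unweighted arithmetic means of `y_m`, `y_gp` and `y_g` over sites of one
#' country and mode, plus the sample variance of the site means.
#'
#' @param reports A data.frame of site reports (rows) with columns
#'   `site_id`, `country`, `mode`, `y_m`, `y_gp`, `y_g`.
#' @return A one-row data.frame with country means, `y_g_pct` computed from
#'   the country means, and between-site variances.
#' @export
country_aggregate <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 2)
  if (length(unique(reports$country)) != 1)
    stop("reports must all be from one country")
  if (length(unique(reports$mode)) != 1)
    stop("reports must all be from one mode")
  data.frame(
    country = reports$country[1], mode = reports$mode[1],
    n_sites = nrow(reports),
    y_m = mean(reports$y_m), y_gp = mean(reports$y_gp),
    y_g = mean(reports$y_g),
    y_g_pct = 100 * mean(reports$y_g) / mean(reports$y_gp),
    y_g_pct_site_mean = mean(100 * reports$y_g / reports$y_gp),
    var_y_gp = stats::var(reports$y_gp),
    var_y_g = stats::var(reports$y_g)
  )
}

#' Run the full yield-gap analysis
#'
#' For every site and both water modes: simulate the reference cultivar
#' (Y_M, no LUE uplift), design an ideotype with EASA (Y_GP, 10% LUE
#' uplift), and compute the yield gap. Returns per-site reports, country
#' aggregates, the optimized trait table and a run manifest sufficient to
#' replay the analysis. All candidates at a site share one weather
#' realisation; the reference cultivar is evaluated on the same series.
#'
#' @param config A configuration list from [default_config()] /
#'   [load_config()]; `config$seed`, `config$easa$n_years`,
#'   `config$easa$max_generations` etc. control run size.
#' @param sites Site codes to run (default all six).
#' @param modes Water modes to run (default both).
#' @param cache_dir Optional directory; finished site/mode stages are
#'   stored there and reused on rerun (resume support).
#' @param verbose Print stage progress.
#' @return A list of class `yieldgap_analysis`: `reports` (12-row
#'   data.frame), `country` (4-row data.frame), `traits` (optimized trait
#'   table), `manifest`.
#' @export
run_full_analysis <- function(config = default_config(),
                              sites = names(builtin_sites()),
                              modes = c("water_limited", "potential"),
                              cache_dir = NULL, verbose = FALSE) {
  all_sites <- builtin_sites()
  stopifnot(all(sites %in% names(all_sites)))
  reports <- list(); traits <- list(); stages <- list()
  for (sid in sites) {
    site <- all_sites[[sid]]
    for (mode in modes) {
      stage_id <- sprintf("%s_%s", sid, mode)
      cache_file <- if (!is.null(cache_dir))
        file.path(cache_dir, paste0(stage_id, ".rds")) else NULL
      stage <- NULL
      if (!is.null(cache_file) && file.exists(cache_file))
        stage <- readRDS(cache_file)
      if (is.null(stage)) {
        stage <- tryCatch(
          run_site_stage(site, mode, config, verbose = verbose),
          error = function(e) list(status = "failed",
                                   error = conditionMessage(e)))
        if (!is.null(cache_file) && identical(stage$status, "ok")) {
          dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
          saveRDS(stage, cache_file)
        }
      }
      stages[[stage_id]] <- stage[c("status", "error")]
      if (identical(stage$status, "ok")) {
        reports[[stage_id]] <- stage$report
        traits[[stage_id]] <- stage$trait_row
      }
      if (verbose && identical(stage$status, "ok"))
        message(sprintf("%s: y_m %.2f, y_gp %.2f, gap %.2f (%.0f%%)",
                        stage_id, stage$report$y_m, stage$report$y_gp,
                        stage$report$y_g, stage$report$y_g_pct))
    }
  }
  reports <- do.call(rbind, reports)
  rownames(reports) <- NULL
  country <- do.call(rbind, lapply(
    split(reports, list(reports$country, reports$mode), drop = TRUE),
    country_aggregate))
  rownames(country) <- NULL
  traits <- do.call(rbind, traits)
  rownames(traits) <- NULL
  manifest <- make_manifest(config, stages)
  structure(list(reports = reports, country = country, traits = traits,
                 manifest = manifest),
            class = "yieldgap_analysis")
}

# One site x mode stage: reference run + ideotype design + gap
run_site_stage <- function(site, mode, config, verbose = FALSE) {
  ec <- easa_config(
    mode = mode,
    n_parents = config$easa$n_parents,
    n_offspring = config$easa$n_offspring,
    n_years = config$easa$n_years,
    cv_threshold = config$easa$cv_threshold,
    hi_threshold = config$easa$hi_threshold,
    max_generations = config$easa$max_generations,
    stall_generations = config$easa$stall_generations,
    lue_multiplier = config$easa$lue_multiplier,
    seed = derive_seed(config$seed, site_mode_index(site$site_id, mode))
  )
  constants <- do.call(crop_constants, config$crop_constants)
  weather <- generate_weather(site, ec$n_years + 1L, derive_seed(ec$seed, 1L))
  ref <- simulate_reference(site, mode, cultivar = claire(),
                            weather = weather, constants = constants)
  opt <- run_easa(site, mode, config = ec, weather = weather,
                  constants = constants, verbose = verbose)
  gap <- yield_gap(opt$best_fitness$mean_yield, ref$mean_yield)
  report <- data.frame(
    site_id = site$site_id, country = site$country, mode = mode,
    y_m = ref$mean_yield, y_gp = opt$best_fitness$mean_yield,
    y_g = gap$y_g, y_g_pct = gap$y_g_pct,
    ref_cv = ref$cv_yield, ideotype_cv = opt$best_fitness$cv_yield,
    ideotype_hi = opt$best_fitness$mean_hi, seed = ec$seed
  )
  tr <- as.list(opt$ideotype[c("ph", "pp", "gf", "amax", "sg", "ru", "wss")])
  if (mode == "potential") tr$wss <- NA_real_  # inert without water stress
  trait_row <- data.frame(site_id = site$site_id, country = site$country,
                          mode = mode, as.data.frame(tr))
  list(status = "ok", error = NA_character_, report = report,
       trait_row = trait_row, ideotype = opt$ideotype)
}

site_mode_index <- function(site_id, mode) {
  si <- match(site_id, names(builtin_sites()))
  si * 2L + (mode == "potential")
}

#' @export
print.yieldgap_analysis <- function(x, ...) {
  cat("<yieldgap_analysis>\n")
  r <- x$reports
  cat(format_report_table(x), sep = "\n")
  invisible(x)
}

#' Format the site x mode yield summary table
#'
#' Yields and gaps to 1 decimal, gap percentages to integer, matching the
#' reporting convention of the analysis.
#'
#' @param analysis A `yieldgap_analysis`.
#' @return Character vector of table lines.
#' @export
format_report_table <- function(analysis) {
  r <- analysis$reports
  lines <- sprintf("%-4s %-3s %-14s  Y_M %5.1f  Y_GP %5.1f  Y_G %4.1f (%2.0f%%)",
                   r$site_id, r$country, r$mode, r$y_m, r$y_gp, r$y_g, r$y_g_pct)
  c <- analysis$country
  c(lines, "-- country means --",
    sprintf("%-8s %-14s  Y_M %5.1f  Y_GP %5.1f  Y_G %4.1f (%2.0f%%)",
            c$country, c$mode, c$y_m, c$y_gp, c$y_g, c$y_g_pct))
}

#' Write analysis tables
#'
#' @param analysis A `yieldgap_analysis`.
#' @param dir Output directory (created if missing).
#' @param format `"tsv"`, `"json"` or `"md"`.
#' @return The directory, invisibly.
#' @export
write_analysis <- function(analysis, dir, format = c("tsv", "json", "md")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "tsv") {
    utils::write.table(analysis$reports, file.path(dir, "site_reports.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(analysis$country, file.path(dir, "country_means.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(analysis$traits, file.path(dir, "ideotype_traits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(
      list(reports = analysis$reports, country = analysis$country,
           traits = analysis$traits),
      file.path(dir, "analysis.json"), auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(c("# Yield-gap analysis", "",
                 "```", format_report_table(analysis), "```"),
               file.path(dir, "analysis.md"))
  }
  jsonlite::write_json(analysis$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
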