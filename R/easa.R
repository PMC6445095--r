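#' Configuration for the evolutionary search algorithm with self-adaptation
#'
#' EASA runs independent elitist (1+lambda) evolution-strategy lineages,
#' one per parent, with log-normal self-adaptation of per-trait mutation
#' scales. Candidates whose 100-year yield CV exceeds `cv_threshold` or
#' whose mean harvest index exceeds `hi_threshold` are removed from
#' selection (thresholds inclusive: CV <= 0.10 and HI <= 0.64 are kept).
#'
#' @param mode `"water_limited"` (7-trait genome) or `"potential"`
#'   (6 traits; the water-stress senescence trait is inert without stress).
#' @param n_parents Number of independent lineages (default 8).
#' @param n_offspring Offspring per parent per generation (default 16).
#' @param n_years Evaluation horizon in seasons (default 100).
#' @param cv_threshold,hi_threshold Feasibility limits on yield CV and mean
#'   harvest index.
#' @param max_generations,stall_generations,rel_tol Stopping rule: quit a
#'   lineage after `stall_generations` without relative improvement above
#'   `rel_tol`, or at `max_generations`.
#' @param include_reference_parent Seed lineage 1 with the reference
#'   cultivar (clipped into bounds if needed).
#' @param lue_multiplier Light-use-efficiency uplift applied to candidate
#'   evaluations (1.10 for ideotype design).
#' @param seed Integer seed for the whole run.
#' @param bounds Per-trait bounds; defaults to [trait_bounds()] for `mode`.
#' @return A list of class `easa_config`.
#' @export
easa_config <- function(mode = c("water_limited", "potential"),
                        n_parents = 8, n_offspring = 16, n_years = 100,
                        cv_threshold = 0.10, hi_threshold = 0.64,
                        max_generations = 200, stall_generations = 15,
                        rel_tol = 1e-3, include_reference_parent = TRUE,
                        lue_multiplier = 1.10, seed = 1,
                        bounds = NULL) {
  mode <- match.arg(mode)
  if (is.null(bounds)) bounds <- trait_bounds(mode)
  stopifnot(n_parents >= 1, n_offspring >= 1, n_years >= 2,
            max_generations >= 1, stall_generations >= 1)
  if (cv_threshold <= 0 || cv_threshold >= 1)
    stop("cv_threshold must be in (0, 1)")
  if (hi_threshold <= 0 || hi_threshold >= 1)
    stop("hi_threshold must be in (0, 1)")
  if (!all(vapply(bounds, function(b) length(b) == 2 && b[1] < b[2], TRUE)))
    stop("each bound must be an increasing (lower, upper) pair")
  structure(list(mode = mode, n_parents = as.integer(n_parents),
                 n_offspring = as.integer(n_offspring),
                 n_years = as.integer(n_years),
                 cv_threshold = cv_threshold, hi_threshold = hi_threshold,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 rel_tol = rel_tol,
                 include_reference_parent = isTRUE(include_reference_parent),
                 lue_multiplier = lue_multiplier, seed = as.integer(seed),
                 bounds = bounds),
            class = "easa_config")
}

new_genome <- function(traits, step_sizes, lineage_id, generation) {
  list(traits = traits, step_sizes = step_sizes,
       lineage_id = lineage_id, generation = generation)
}

clip_to_bounds <- function(x, bounds) {
  for (k in names(bounds)) x[k] <- min(bounds[[k]][2], max(bounds[[k]][1], x[k]))
  x
}

#' Initial parent genomes
#'
#' Parent 1 carries the reference cultivar's traits (clipped into bounds
#' with a message if outside); the remaining parents are drawn uniformly
#' within the trait bounds. Mutation scales start at 10% of each trait's
#' range. Draws use the current RNG state; seed via [run_easa()] or
#' `set.seed()` for reproducibility.
#'
#' @param config An [easa_config()].
#' @param reference A [cultivar_params()]; required when
#'   `include_reference_parent` is set.
#' @return A list of `config$n_parents` genomes.
#' @export
init_parents <- function(config, reference = claire()) {
  bounds <- config$bounds
  keys <- names(bounds)
  lb <- vapply(bounds, `[`, 0, 1)
  ub <- vapply(bounds, `[`, 0, 2)
  step0 <- 0.1 * (ub - lb)
  parents <- vector("list", config$n_parents)
  start <- 1L
  if (config$include_reference_parent) {
    if (is.null(reference)) stop("reference cultivar required")
    tr <- unlist(reference[keys])
    clipped <- clip_to_bounds(tr, bounds)
    if (any(clipped != tr))
      message("reference traits clipped into optimization bounds")
    parents[[1]] <- new_genome(clipped, step0, 1L, 0L)
    start <- 2L
  }
  for (i in seq(from = start, length.out = config$n_parents - start + 1L)) {
    tr <- lb + stats::runif(length(keys)) * (ub - lb)
    names(tr) <- keys
    parents[[i]] <- new_genome(tr, step0, as.integer(i), 0L)
  }
  parents
}

#' Mutate a parent genome
#'
#' Standard evolution-strategy log-normal self-adaptation: each offspring
#' first rescales the per-trait mutation scales by
#' `exp(tau_g * N_global + tau_c * N_i)` with `tau_g = 1/sqrt(2 n)` and
#' `tau_c = 1/sqrt(2 sqrt(n))` for `n` traits, then perturbs each trait by
#' a normal draw of that scale, then clips to bounds.
#'
#' @param parent A genome from [init_parents()].
#' @param config An [easa_config()].
#' @param generation Generation counter stored on the offspring.
#' @return A list of `config$n_offspring` genomes.
#' @export
mutate_genome <- function(parent, config, generation = parent$generation + 1L) {
  bounds <- config$bounds
  n <- length(parent$traits)
  tau_g <- 1 / sqrt(2 * n)
  tau_c <- 1 / sqrt(2 * sqrt(n))
  lb <- vapply(bounds, `[`, 0, 1)
  ub <- vapply(bounds, `[`, 0, 2)
  rng <- ub - lb
  lapply(seq_len(config$n_offspring), function(j) {
    g <- stats::rnorm(1)
    steps <- parent$step_sizes * exp(tau_g * g + tau_c * stats::rnorm(n))
    steps <- pmin(rng, pmax(1e-9 * rng, steps))
    tr <- parent$traits + steps * stats::rnorm(n)
    tr <- pmin(ub, pmax(lb, tr))
    names(tr) <- names(parent$traits)
    new_genome(tr, steps, parent$lineage_id, as.integer(generation))
  })
}

# Normalise a fitness result to a record list
as_fitness_record <- function(x, config) {
  if (is.numeric(x) && length(x) == 1)
    x <- list(mean_yield = x, cv_yield = 0, mean_hi = 0.5, n_years = config$n_years)
  if (is.null(x$error)) x$error <- NA_character_
  x$feasible <- is.na(x$error) &&
    x$cv_yield <= config$cv_threshold && x$mean_hi <= config$hi_threshold
  x
}

#' Evaluate a candidate genome with the crop simulator
#'
#' Runs [simulate_years()] on the candidate's traits (with the configured
#' light-use-efficiency uplift) and applies the CV and harvest-index
#' feasibility filters. A simulation failure yields an infeasible record
#' carrying the error message.
#'
#' @param genome A genome (or a named trait vector).
#' @param weather A `weather_series` shared across candidates of a run.
#' @param soil A [soil_profile()].
#' @param mgmt A [management()]; its `lue_multiplier` is used as-is.
#' @param config An [easa_config()].
#' @param constants See [crop_constants()].
#' @return A fitness record: `mean_yield`, `cv_yield`, `mean_hi`,
#'   `n_years`, `feasible`, `error`.
#' @export
evaluate_candidate <- function(genome, weather, soil, mgmt, config,
                               constants = crop_constants()) {
  traits <- if (is.list(genome) && !is.null(genome$traits)) genome$traits else genome
  full <- as.list(traits)
  if (is.null(full$wss)) full$wss <- 1.0  # inert without water stress
  cv <- cultivar_params(full$ph, full$pp, full$gf, full$amax, full$sg,
                        full$ru, full$wss, name = "candidate")
  rec <- tryCatch({
    ys <- simulate_years(cv, weather, soil, mgmt, constants)
    list(mean_yield = ys$mean_yield, cv_yield = ys$cv_yield,
         mean_hi = ys$mean_hi, n_years = ys$n_seasons)
  }, error = function(e) {
    list(mean_yield = -Inf, cv_yield = Inf, mean_hi = Inf, n_years = 0,
         error = conditionMessage(e))
  })
  as_fitness_record(rec, config)
}

#' Select the next parent from a parent and its offspring
#'
#' Elitist argmax of mean yield over the feasible members of
#' `{parent} U offspring`; the parent is retained when every offspring is
#' infeasible or worse. Ties break deterministically toward the earliest
#' candidate (parent first, then offspring in creation order).
#'
#' @param parent,parent_rec The current parent genome and fitness record.
#' @param offspring,offspring_recs Offspring genomes and fitness records.
#' @return A list: `genome`, `record`, `improved` (strictly better than the
#'   parent), `any_feasible`.
#' @export
select_next_parent <- function(parent, parent_rec, offspring, offspring_recs) {
  genomes <- c(list(parent), offspring)
  recs <- c(list(parent_rec), offspring_recs)
  feas <- vapply(recs, function(r) isTRUE(r$feasible), TRUE)
  if (!any(feas))
    return(list(genome = parent, record = parent_rec, improved = FALSE,
                any_feasible = FALSE))
  yields <- vapply(recs, function(r) r$mean_yield, 0)
  yields[!feas] <- -Inf
  best <- which.max(yields)  # first maximum: deterministic tie-break
  list(genome = genomes[[best]], record = recs[[best]],
       improved = feas[best] &&
         (!isTRUE(parent_rec$feasible) || yields[best] > parent_rec$mean_yield),
       any_feasible = TRUE)
}

# Fast candidate-fitness closure: engine inputs are prepared once and every
# candidate reuses them (and the same weather realisation).
make_sim_fitness <- function(weather, soil, mgmt, config,
                             constants = crop_constants()) {
  wm <- weather_matrix(weather)
  d <- weather$days
  dl <- daylength(weather$site$latitude, d$doy)
  sow <- which(d$doy == mgmt$sowing_doy)
  sow <- sow[nrow(d) - sow + 1 >= 365]
  if (length(sow) < 1) stop("weather series too short for any full season")
  soil_l <- soil[c("awc_per_layer", "lambda")]
  wl <- mgmt$mode == "water_limited"
  function(traits) {
    full <- as.list(traits)
    if (is.null(full$wss)) full$wss <- 1.0
    tryCatch({
      m <- simulate_years_cpp(wm, dl, sow - 1L, full, constants, soil_l, wl,
                              mgmt$lue_multiplier, mgmt$flowering_stress)
      y <- m[, "grain_yield"]
      list(mean_yield = mean(y),
           cv_yield = if (length(y) > 1) stats::sd(y) / mean(y) else 0,
           mean_hi = mean(m[, "hi"]), n_years = length(y))
    }, error = function(e) {
      list(mean_yield = -Inf, cv_yield = Inf, mean_hi = Inf, n_years = 0,
           error = conditionMessage(e))
    })
  }
}

# Core multi-start loop over an arbitrary fitness function.
# fitness(traits) must return a fitness record list or a single number.
easa_optimize <- function(fitness, config, reference = claire(),
                          verbose = FALSE) {
  memo <- new.env(parent = emptyenv())
  eval_memo <- function(traits) {
    key <- paste(signif(traits, 12), collapse = "|")
    if (exists(key, envir = memo, inherits = FALSE))
      return(get(key, envir = memo))
    rec <- as_fitness_record(fitness(traits), config)
    assign(key, rec, envir = memo)
    rec
  }
  parents <- init_parents(config, reference)
  traces <- vector("list", length(parents))
  best_overall <- NULL; best_rec <- NULL
  n_evals <- 0L
  for (li in seq_along(parents)) {
    parent <- parents[[li]]
    parent_rec <- eval_memo(parent$traits); n_evals <- n_evals + 1L
    lineage_best <- if (isTRUE(parent_rec$feasible)) parent_rec$mean_yield else -Inf
    stall <- 0L
    trace <- data.frame(generation = 0L,
                        best_yield = ifelse(is.finite(lineage_best),
                                            lineage_best, NA_real_))
    gen <- 0L
    while (gen < config$max_generations && stall < config$stall_generations) {
      gen <- gen + 1L
      offspring <- mutate_genome(parent, config, gen)
      recs <- lapply(offspring, function(o) eval_memo(o$traits))
      n_evals <- n_evals + config$n_offspring
      sel <- select_next_parent(parent, parent_rec, offspring, recs)
      new_best <- if (isTRUE(sel$record$feasible)) sel$record$mean_yield else lineage_best
      rel_gain <- if (is.finite(lineage_best) && lineage_best > 0)
        (new_best - lineage_best) / lineage_best else
          ifelse(is.finite(new_best) && !is.finite(lineage_best), Inf, 0)
      if (isTRUE(rel_gain > config$rel_tol)) stall <- 0L else stall <- stall + 1L
      if (is.finite(new_best)) lineage_best <- max(lineage_best, new_best)
      parent <- sel$genome; parent_rec <- sel$record
      trace <- rbind(trace, data.frame(
        generation = gen,
        best_yield = ifelse(is.finite(lineage_best), lineage_best, NA_real_)))
      if (verbose)
        message(sprintf("lineage %d gen %d best %.3f stall %d",
                        li, gen, lineage_best, stall))
    }
    traces[[li]] <- trace
    if (isTRUE(parent_rec$feasible) &&
        (is.null(best_rec) || parent_rec$mean_yield > best_rec$mean_yield)) {
      best_overall <- parent; best_rec <- parent_rec
    }
  }
  if (is.null(best_overall))
    stop("EASA found no feasible candidate in any lineage")
  structure(list(best_genome = best_overall, best_fitness = best_rec,
                 traces = traces, n_evaluations = n_evals,
                 config = config), class = "easa_result")
}

#' Design an ideotype for a site with EASA
#'
#' Generates (or accepts) a shared weather series for the site, then runs
#' the multi-start elitist evolution strategy, evaluating every candidate
#' on the same weather realisation (common random numbers) with the
#' configured light-use-efficiency uplift. The best feasible candidate
#' across all lineages is returned as the site ideotype.
#'
#' @param site A `site_climate` or built-in site code.
#' @param mode `"water_limited"` or `"potential"`.
#' @param config An [easa_config()]; its `mode` is overridden by `mode`.
#' @param weather Optional pre-generated `weather_series`; by default
#'   `config$n_years + 1` years are generated from a seed derived from
#'   `config$seed` (one extra year so every sowing completes).
#' @param soil,constants Simulator settings; soil defaults by country.
#' @param reference Reference cultivar seeded as parent 1.
#' @param fitness Optional fitness-function override (traits -> record or
#'   number); used for algorithm verification against analytic surfaces.
#' @param verbose Print per-generation progress.
#' @return An `easa_result` with `best_genome`, `best_fitness`, per-lineage
#'   `traces`, `n_evaluations`, `config`, and (for simulator runs)
#'   `ideotype`, a [cultivar_params()].
#' @export
run_easa <- function(site, mode = c("water_limited", "potential"),
                     config = NULL, weather = NULL, soil = NULL,
                     constants = crop_constants(), reference = claire(),
                     fitness = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- easa_config(mode = mode)
  if (config$mode != mode)
    config <- utils::modifyList(config, list(mode = mode,
                                             bounds = trait_bounds(mode)))
  with_local_seed(config$seed, {
    if (is.null(fitness)) {
      if (is.character(site)) site <- builtin_sites()[[site]]
      stopifnot(inherits(site, "site_climate"))
      if (is.null(weather))
        weather <- generate_weather(site, config$n_years + 1L,
                                    derive_seed(config$seed, 1L))
      if (is.null(soil)) soil <- default_soil(site$country)
      mgmt <- management(site$country, mode,
                         lue_multiplier = config$lue_multiplier)
      fitness <- make_sim_fitness(weather, soil, mgmt, config, constants)
    }
    res <- easa_optimize(fitness, config, reference, verbose)
    tr <- as.list(res$best_genome$traits)
    if (is.null(tr$wss)) tr$wss <- 1.0
    res$ideotype <- cultivar_params(tr$ph, tr$pp, tr$gf, tr$amax, tr$sg,
                                    tr$ru, tr$wss,
                                    name = sprintf("ideotype_%s", mode))
    res
  })
}

#' @export
print.easa_result <- function(x, ...) {
  cat(sprintf("<easa_result> best mean yield %.2f t/ha (CV %.1f%%, HI %.3f) after %d evaluations\n",
              x$best_fitness$mean_yield, 100 * x$best_fitness$cv_yield,
              x$best_fitness$mean_hi, x$n_evaluations))
  invisible(x)
}
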