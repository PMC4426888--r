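#' Configuration of a simulation experiment
#'
#' @param scenario A scenario name (`"BTS"`, `"AMIS"`), file path, or a
#'   `scenario_params` object.
#' @param intervention An [intervention_spec()].
#' @param start_year,end_year Simulated period (default 2005-2030).
#' @param replicates Number of Monte-Carlo replicates (default 50).
#' @param seed Master seed; replicate `r` uses the RNG stream derived from
#'   `(seed, r)` and the region is generated from `seed`.
#' @param region A [region_config()], or a pre-generated `region` to reuse
#'   across configurations (common random numbers across experiment arms).
#' @param out_dir Optional output directory for CSV/YAML artefacts.
#' @param log_events Also collect the agent-level event log (cease, retire,
#'   expand, transfer, abandon, adopt) and write it to `events.csv`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = "BTS",
                       intervention = intervention_spec(),
                       start_year = 2005L, end_year = 2030L,
                       replicates = 50L, seed = 1L,
                       region = region_config(),
                       out_dir = NULL, log_events = FALSE) {
  if (end_year <= start_year) stopf("end_year must be after start_year")
  if (replicates < 1L) stopf("replicates must be >= 1")
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  if (!inherits(intervention, "intervention_spec"))
    intervention <- do.call(intervention_spec, intervention)
  structure(list(scenario = scenario, intervention = intervention,
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), region = region,
                 out_dir = out_dir, log_events = isTRUE(log_events)),
            class = "run_config")
}

# one replicate trajectory; full validation at the first step and on the
# final state, cheap checks in between (the per-step validation invariant is
# exercised in the test suite on small regions)
run_replicate <- function(region, config, replicate, collect_events = FALSE) {
  sc <- config$scenario
  iv <- config$intervention
  years <- config$end_year - config$start_year
  rows <- vector("list", years + 1L)
  base0 <- region
  rows[[1L]] <- cbind(compute_indicators(region, base0),
                      extra_indicators(region, NULL))
  events <- list()
  for (t in seq_len(years)) {
    ctx <- decision_context(sc, iv, run_seed = config$seed,
                            replicate = replicate, validate = (t == 1L))
    region <- step_year(region, ctx)
    rows[[t + 1L]] <- cbind(compute_indicators(region, base0),
                            extra_indicators(region, region$counters))
    if (collect_events) events[[t]] <- region$events
  }
  v <- validate_region(region)
  if (nrow(v))
    stopf("replicate %d produced an invalid region (%s: %s); state dumped to tempdir",
          replicate, v$check[1], {
            write_region(region, file.path(tempdir(), sprintf("invalid_rep%d", replicate)))
            v$message[1]
          })
  out <- rbindlist(rows)
  out[, replicate := replicate]
  if (collect_events) attr(out, "events") <- rbindlist(events)
  out
}

extra_indicators <- function(region, counters) {
  f <- region$farmers[region$farmers$active]
  pilot_ids <- region$parcels$id[region$parcels$z_pilot]
  data.table(
    n_multifunctional = sum(f$type == "diversified_multifunctional"),
    n_expansionist = sum(f$type == "expansionist"),
    n_expansionist_pilot = sum(f$type == "expansionist" &
                                 f$farmstead_id %in% pilot_ids),
    n_residents = nrow(region$residents),
    tourism_demand = region$tourism_demand,
    element_total_m = sum(region$parcels$element_m),
    purchases_estate = counters$purchases_estate %||% 0L,
    qualifying_estate = counters$qualifying_estate %||% 0L,
    purchases_nature = counters$purchases_nature %||% 0L,
    abandoned_ha = counters$abandoned %||% 0L,
    adopted = counters$adopted %||% 0L,
    cessations = counters$cessations %||% 0L)
}

#' Run a seeded multi-replicate simulation experiment
#'
#' Generates (or reuses) the region, runs every replicate on its own RNG
#' stream derived from `(seed, replicate)`, and summarises the indicator
#' series over replicates with mean, sd and percentile intervals. Reruns
#' with the same configuration reproduce every number; summaries are
#' invariant to replicate execution order.
#'
#' @param config A [run_config()].
#' @return List of class `experiment_result`: `series` (one row per
#'   replicate-year), `summary` (mean/sd/2.5/97.5 percentiles per
#'   indicator-year), `baseline` (year-0 indicators), `provenance` (config
#'   and scenario hashes, seed, package version). Written to
#'   `config$out_dir` as CSVs when set.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  region <- if (inherits(config$region, "region")) config$region else
    generate_region(config$region, seed = config$seed)
  if (region$year != config$start_year)
    stopf("region is at year %d but the experiment starts in %d",
          region$year, config$start_year)
  region <- ensure_knn(region)
  if (config$intervention$cooperation$enabled)
    region <- freeze_asset_threshold(region, config$intervention)
  reps <- lapply(seq_len(config$replicates), function(r)
    run_replicate(region, config, r,
                  collect_events = config$log_events %||% FALSE))
  series <- rbindlist(reps)
  events <- if (isTRUE(config$log_events))
    rbindlist(lapply(seq_along(reps), function(r) {
      ev <- attr(reps[[r]], "events")
      if (nrow(ev)) ev[, replicate := r]
      ev
    }), fill = TRUE)
  idcols <- setdiff(names(series), c("year", "replicate"))
  num <- copy(series)[, (idcols) := lapply(.SD, as.numeric), .SDcols = idcols]
  long <- data.table::melt(num, id.vars = c("replicate", "year"),
                           measure.vars = idcols, variable.name = "variable")
  summary <- long[, .(mean = mean(value), sd = sd(value),
                      q2.5 = unname(quantile(value, 0.025, na.rm = TRUE)),
                      q97.5 = unname(quantile(value, 0.975, na.rm = TRUE))),
                  by = .(year, variable)]
  prov <- list(seed = config$seed, replicates = config$replicates,
               scenario = config$scenario$name,
               scenario_hash = object_hash(unclass(config$scenario)),
               config_hash = object_hash(list(
                 region = unclass(config$region), start = config$start_year,
                 end = config$end_year,
                 intervention = unclass(config$intervention))),
               package_version = as.character(utils::packageVersion("coulisse")))
  out <- structure(list(series = series, summary = summary,
                        baseline = series[year == config$start_year & replicate == 1L],
                        provenance = prov, config = config),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(series, file.path(config$out_dir, "series.csv"))
    fwrite(summary, file.path(config$out_dir, "summary.csv"))
    if (isTRUE(config$log_events))
      fwrite(events, file.path(config$out_dir, "events.csv"))
    yaml::write_yaml(prov, file.path(config$out_dir, "provenance.yaml"))
  }
  out
}

# stable content hash without extra dependencies: md5 of a canonical
# serialisation written to a scratch file
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(x, file = f, control = c("digits17", "niceNames"))
  unname(tools::md5sum(f))
}

#' @export
print.experiment_result <- function(x, ...) {
  fin <- x$summary[year == max(year) & variable %in%
                     c("total_farmers", "pct_multifunctional",
                       "element_pct_change", "semi_natural", "total_agri")]
  cat(sprintf("<experiment_result> %s, %d replicates, %d-%d\n",
              x$provenance$scenario, x$provenance$replicates,
              min(x$series$year), max(x$series$year)))
  for (i in seq_len(nrow(fin)))
    cat(sprintf("  final %-20s mean %10.1f (sd %.1f)\n",
                as.character(fin$variable[i]), fin$mean[i], fin$sd[i]))
  invisible(x)
}

# --- sensitivity analysis ----------------------------------------------------

#' Specify a sensitivity analysis
#'
#' @param parameters Character vector of scenario parameter paths, e.g.
#'   `"cessation.scenario_mult"` or `"expansion.participation.expansionist"`.
#' @param magnitude Relative perturbation (e.g. 0.1 = +-10%).
#' @param replicates Replicates per setting (default 50).
#' @param output Indicator whose final-year mean is tracked.
#' @return List of class `sensitivity_spec`.
#' @export
sensitivity_spec <- function(parameters, magnitude = 0.1, replicates = 50L,
                             output = "total_farmers") {
  if (magnitude <= 0) stopf("perturbation magnitude must be > 0")
  structure(list(parameters = parameters, magnitude = magnitude,
                 replicates = as.integer(replicates), output = output),
            class = "sensitivity_spec")
}

scenario_param_get <- function(sc, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- sc
  for (p in parts) {
    if (is.list(node)) {
      if (!p %in% names(node)) return(NULL)
      node <- node[[p]]
    } else {
      if (!p %in% names(node)) return(NULL)
      node <- node[[p]]
    }
  }
  if (!is.numeric(node)) return(NULL)
  node
}

scenario_param_set <- function(sc, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- paste0("sc[['", paste(parts, collapse = "']][['"), "']]")
  eval(parse(text = paste0(ref, " <- value")))
  sc
}

#' Perturb key parameters and measure the response
#'
#' For every named parameter, runs the base configuration with the parameter
#' scaled by `(1 +- magnitude)` (probabilities clamped at 1) and reports the
#' final-year mean and sd of the tracked output plus the elasticity
#' (% output change / % parameter change). Unknown parameter names are
#' rejected before any simulation.
#'
#' @param spec A [sensitivity_spec()].
#' @param base A [run_config()] providing scenario, region and seed.
#' @return data.table: parameter, direction, perturbed value, output mean,
#'   output sd, elasticity.
#' @export
sensitivity_analysis <- function(spec, base) {
  if (!inherits(spec, "sensitivity_spec")) spec <- do.call(sensitivity_spec, spec)
  if (!inherits(base, "run_config")) base <- do.call(run_config, base)
  for (pp in spec$parameters)
    if (is.null(scenario_param_get(base$scenario, pp)))
      stopf("unknown scenario parameter `%s`", pp)
  region <- if (inherits(base$region, "region")) base$region else
    generate_region(base$region, seed = base$seed)
  base$region <- region
  base$replicates <- spec$replicates
  base_res <- run_experiment(base)
  out_of <- function(res) {
    s <- res$summary[year == max(year) & variable == spec$output]
    c(mean = s$mean, sd = s$sd)
  }
  b <- out_of(base_res)
  rows <- list()
  for (pp in spec$parameters) {
    v0 <- scenario_param_get(base$scenario, pp)
    for (dir in c(1, -1)) {
      v1 <- v0 * (1 + dir * spec$magnitude)
      cfg <- base
      perturbed <- scenario_param_set(unclass(base$scenario), pp, v1)
      if (grepl("^elements\\.base\\.", pp)) {
        # keep absorbs the change so the action triple still sums to 1
        cl <- strsplit(pp, ".", fixed = TRUE)[[1]][3]
        tri <- perturbed$elements$base[[cl]]
        tri[["keep"]] <- 1 - tri[["cut"]] - tri[["plant"]]
        perturbed$elements$base[[cl]] <- tri
      }
      cfg$scenario <- tryCatch(
        validate_scenario(perturbed),
        error = function(e) validate_scenario(
          scenario_param_set(unclass(base$scenario), pp, pmin(v1, 1))))
      res <- run_experiment(cfg)
      o <- out_of(res)
      d_out <- (o[["mean"]] - b[["mean"]]) / b[["mean"]]
      rows[[length(rows) + 1L]] <- data.table(
        parameter = pp, direction = if (dir > 0) "up" else "down",
        perturbation = dir * spec$magnitude,
        output = spec$output, mean = o[["mean"]], sd = o[["sd"]],
        base_mean = b[["mean"]],
        elasticity = d_out / (dir * spec$magnitude))
    }
  }
  rbindlist(rows)
}
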