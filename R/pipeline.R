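# End-to-end pipeline: simulate or ingest -> biomass indices -> stability
# partitions (species and harvest layers on the same survey-month grid) ->
# annual indicators -> piecewise SEMs -> interannual trends -> manifest.
#
# Every artifact is a plain CSV/JSON file in the run directory, and a rerun
# with the same (config, seed) is byte-identical.

default_sem_specs <- function(has_shr) {
  eco <- if (has_shr) {
    list(edges = c("shr -> cpe_harvest", "shr -> sae_harvest",
                   "cpe_species -> cpe_harvest",
                   "sae_species -> sae_harvest"))
  } else {
    list(edges = c("sae_species -> cpe_species",
                   "sae_species -> cpe_harvest",
                   "cpe_species -> cpe_harvest",
                   "sae_species -> effort_index",
                   "effort_index -> s_bar_harvest"))
  }
  econ <- list(edges = c("s_portfolio_s -> s_portfolio_l",
                         "s_portfolio_l -> value_stability",
                         "s_portfolio_l -> portfolio_yield",
                         "portfolio_yield -> portfolio_value",
                         "value_stability -> portfolio_value"))
  list(ecological = eco, economic = econ)
}

partitions_wide <- function(parts) {
  out <- NULL
  for (layer in unique(parts$layer)) {
    sub <- parts[parts$layer == layer,
                 c("region", "year", "S_agg", "S_bar", "phi", "SAE", "CPE")]
    names(sub)[3:7] <- paste0(c("s_agg_", "s_bar_", "phi_", "sae_", "cpe_"),
                              layer)
    out <- if (is.null(out)) sub else merge(out, sub,
                                            by = c("region", "year"),
                                            all = TRUE)
  }
  out
}

#' Merge stability partitions and annual indicators into one table
#'
#' @param parts output of [partition_by_year()] (both layers row-bound).
#' @param indicators output of [annual_indicators()].
#' @return data frame keyed by (region, year) with wide per-layer columns
#'   `s_agg_<layer>`, `s_bar_<layer>`, `phi_<layer>`, `sae_<layer>`,
#'   `cpe_<layer>` plus all indicator columns.
#' @export
analysis_table <- function(parts, indicators) {
  merge(partitions_wide(parts), indicators, by = c("region", "year"),
        all = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a scenario (when `config$scenario` names a preset)
#' or read long records from `config$records`; (2) estimate design-based
#' biomass indices from simulated hauls (simulated runs) or take
#' `biomass_kg` records as supplied; (3) partition stability for the
#' species layer (biomass) and harvest layer (landings) on the same
#' survey-month grid; (4) compute annual indicators; (5) fit the declared
#' (or default) piecewise SEMs; (6) fit interannual trends; (7) write a
#' manifest with the config hash and seed for exact rerun.
#'
#' @param config configuration list or path to a YAML file.  Recognised
#'   fields: `scenario` (preset name), `records` (CSV path of long
#'   records), `region`, `calendar` (YAML path), `sems` (named list with
#'   `edges`/`error`/`transform`), `trend_series` (columns of the analysis
#'   table), `trend_ar_order`.
#' @param seed integer seed for all randomness.
#' @param out_dir run directory (created if missing).
#' @return (invisibly) list with the analysis table, SEM fits, trend
#'   table and manifest.
#' @export
run_pipeline <- function(config, seed, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    fs_log(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  calendar <- if (!is.null(config$calendar)) read_calendar(config$calendar)
              else default_calendar()
  surv <- calendar$survey_months

  # (1) simulate or ingest
  sim <- NULL
  records <- stage("simulate", {
    if (!is.null(config$scenario)) {
      sim <- simulate_scenario(config$scenario, seed)
      calendar <- sim$config$calendar
      surv <- calendar$survey_months
      note("simulated scenario '", config$scenario, "' with seed ", seed)
      write_long(sim$records, file.path(out_dir, "records.csv"))
      sim$records
    } else if (!is.null(config$records)) {
      read_long(config$records)
    } else {
      stop_validation("config must give either 'scenario' or 'records'")
    }
  })
  region <- config$region %||% unique(records$region)[1L]

  # (2) biomass indices
  stage("index", {
    if (!is.null(sim)) {
      write.csv(sim$indices, file.path(out_dir, "biomass_indices.csv"),
                row.names = FALSE)
      note("wrote design-based biomass indices (",
           nrow(sim$indices), " rows)")
    } else {
      note("using supplied biomass_kg records as indices")
    }
  })

  # portfolio species: top 90% of cumulative multi-year yield, fixed per
  # region and applied to every downstream layer
  species <- stage("species_selection", {
    h <- records[records$quantity_kind == "harvest_kg" &
                   records$region == region, , drop = FALSE]
    totals <- tapply(h$value, h$species, sum)
    sel <- select_top_species(setNames(as.numeric(totals), names(totals)))
    note("portfolio species: ", paste(sort(sel), collapse = ", "))
    sort(sel)
  })

  # (3) stability partitions, both layers on the survey-month grid
  parts <- stage("partition", {
    rbind(
      partition_by_year(records, "biomass_kg", "species", months = surv,
                        species = intersect(species,
                                            records$species[records$quantity_kind == "biomass_kg"])),
      partition_by_year(records, "harvest_kg", "harvest", months = surv,
                        species = species)
    )
  })
  write.csv(parts, file.path(out_dir, "partitions.csv"), row.names = FALSE)

  # (4) annual indicators
  indicators <- stage("indicators",
                      annual_indicators(records, region, calendar,
                                        species = species))
  write.csv(indicators, file.path(out_dir, "indicators.csv"),
            row.names = FALSE)
  tab <- analysis_table(parts, indicators)
  write.csv(tab, file.path(out_dir, "analysis_table.csv"), row.names = FALSE)

  # (5) piecewise SEMs
  sems <- stage("sem", {
    specs <- config$sems
    if (is.null(specs)) {
      specs <- default_sem_specs(has_shr = any(is.finite(tab$shr)))
    }
    fits <- list()
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      pm <- path_model(unlist(sp$edges),
                       error = if (length(sp$error)) unlist(sp$error),
                       transform = if (length(sp$transform)) unlist(sp$transform))
      fit <- fit_psem(pm, tab)
      fits[[nm]] <- fit
      jsonlite::write_json(
        list(paths = fit$paths, claims = fit$claims,
             fisher_c = fit$C, df = fit$df, p = fit$p,
             dropped_years = fit$dropped_years),
        file.path(out_dir, paste0("sem_", nm, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
      note("SEM '", nm, "': C = ", signif(fit$C, 6L), ", df = ", fit$df,
           ", p = ", signif(fit$p, 6L))
    }
    fits
  })
  all_paths <- do.call(rbind, lapply(names(sems), function(nm) {
    cbind(data.frame(sem = nm, stringsAsFactors = FALSE), sems[[nm]]$paths)
  }))
  write.csv(all_paths, file.path(out_dir, "sem_paths.csv"), row.names = FALSE)

  # (6) interannual trends
  trend_tab <- stage("trends", {
    series <- config$trend_series %||%
      c("sae_species", "cpe_species", "sae_harvest", "cpe_harvest",
        "s_portfolio_l", "effort_index")
    series <- intersect(series, names(tab))
    ar_ord <- config$trend_ar_order %||% 1L
    rows <- lapply(series, function(s) {
      tryCatch({
        tf <- fit_trend(tab$year, tab[[s]], form = "linear",
                        ar_order = ar_ord)
        sl <- tf$coefficients[tf$coefficients$term == "t1", ]
        data.frame(series = s, slope = sl$estimate, se = sl$se, p = sl$p,
                   ar_order = ar_ord, included = tf$included,
                   note = "", stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(series = s, slope = NA_real_, se = NA_real_, p = NA_real_,
                   ar_order = ar_ord, included = NA,
                   note = conditionMessage(e), stringsAsFactors = FALSE)
      })
    })
    do.call(rbind, rows)
  })
  write.csv(trend_tab, file.path(out_dir, "trends.csv"), row.names = FALSE)

  # (7) manifest
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package = "finstab",
    version = as.character(utils::packageVersion("finstab")),
    seed = as.integer(seed),
    config_md5 = unname(tools::md5sum(cfg_path)),
    region = region,
    outputs = sort(setdiff(list.files(out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(table = tab, sems = sems, trends = trend_tab,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
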