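#' Pipeline run configuration
#'
#' Bundles every knob of the synthetic study emulation and analysis into one
#' list. All randomness flows from `seed`, split into named per-stage streams,
#' so a rerun with an identical config is bit-identical.
#'
#' @param seed root integer seed.
#' @param populations population config data.frame
#'   (default [default_population_configs()]).
#' @param scenarios scenario offsets (default [default_scenarios()]).
#' @param n_cells occurrence cells in the climate grid.
#' @param n_days field-campaign days.
#' @param n_spots spot records per individual.
#' @param cold_fraction fraction of early-morning sub-set-point spot records.
#' @param skip_tb_populations populations with operative loggers but no
#'   captured animals (default `"VA"`, emulating the study site without
#'   body-temperature records).
#' @param n_boot bootstrap resamples for index CIs.
#' @param n_perm permutations for the K test.
#' @param budget_params an [ectotherm_params()] object.
#' @param outdir optional output directory; when set, all tables and reports
#'   are written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            populations = default_population_configs(),
                            scenarios = default_scenarios(),
                            n_cells = 102, n_days = 14, n_spots = 5,
                            cold_fraction = 0.05,
                            skip_tb_populations = "VA",
                            n_boot = 10000, n_perm = 999,
                            budget_params = ectotherm_params(),
                            outdir = NULL) {
  validate_population_configs(populations)
  validate_scenarios(scenarios)
  structure(
    list(seed = seed, populations = populations, scenarios = scenarios,
         n_cells = n_cells, n_days = n_days, n_spots = n_spots,
         cold_fraction = cold_fraction,
         skip_tb_populations = skip_tb_populations,
         n_boot = n_boot, n_perm = n_perm, budget_params = budget_params,
         outdir = outdir),
    class = "pipeline_config"
  )
}

# Map each climate cell to the population whose configured latitude is nearest,
# so the per-population upper set-point bound applies to that population's cells.
cell_tset_upper <- function(climate, configs, pop_tset) {
  cells <- unique(climate[, c("cell_id", "latitude")])
  idx <- vapply(cells$latitude, function(la) {
    which.min(abs(configs$latitude - la))
  }, integer(1))
  upper <- pop_tset$t_set_upper[match(configs$name[idx], pop_tset$population)]
  data.frame(cell_id = cells$cell_id, t_set_upper = upper,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the five input tables, estimates individual and
#' population set-point ranges, builds the thermoregulation index report,
#' computes the annual restriction-time budget under every scenario, tests
#' for phylogenetic signal in population Tp, and runs the comparative
#' statistics. With `config$outdir` set, all tables and reports are written
#' to disk along with a run log.
#'
#' @param config a [pipeline_config()].
#' @param tables optional named list of pre-loaded input tables (`roster`,
#'   `trials`, `spots`, `otm`, `climate`, `tree`); any supplied table
#'   replaces its synthetic counterpart, so real field data can be dropped in
#'   with the same schemas.
#' @return list of class `vipertherm_run` with elements `tables`,
#'   `estimates`, `indices`, `budget`, `signal`, `stats`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), tables = list()) {
  if (!inherits(config, "pipeline_config")) {
    vt_stop("invalid_config", "`config` must come from pipeline_config()")
  }
  seed <- config$seed
  cfg <- config$populations

  roster <- tables$roster
  if (is.null(roster)) roster <- generate_roster(cfg, seed = seed)
  trials <- tables$trials
  if (is.null(trials)) {
    trials <- generate_gradient_trials(roster, seed = seed)
  }
  if (is.null(tables$spots) != is.null(tables$otm)) {
    vt_stop("missing_input",
            "field-campaign stage needs both `spots` and `otm` (or neither)")
  }
  if (is.null(tables$otm)) {
    field <- generate_field_campaign(
      roster, n_days = config$n_days, seed = seed,
      n_spots = config$n_spots, cold_fraction = config$cold_fraction,
      skip_tb_populations = config$skip_tb_populations
    )
    spots <- field$spots
    otm <- field$otm
  } else {
    spots <- tables$spots
    otm <- tables$otm
  }
  climate <- tables$climate
  if (is.null(climate)) {
    climate <- generate_climate_grid(n_cells = config$n_cells,
                                     scenarios = config$scenarios,
                                     seed = seed)
  }
  tree <- tables$tree
  if (is.null(tree)) tree <- generate_phylogeny(cfg$name)

  estimates <- estimate_tset_table(trials)
  pop_tset <- estimates[estimates$level == "population", , drop = FALSE]

  indices <- build_index_report(spots, otm, estimates,
                                n_boot = config$n_boot, seed = seed)

  upper_by_cell <- cell_tset_upper(climate, cfg, pop_tset)
  budget <- scenario_change_summary(climate, upper_by_cell,
                                    params = config$budget_params)
  cur <- budget$per_cell[budget$per_cell$scenario_id == "current", ]
  budget$latitude_trend <- latitude_trend(cur$h_r, cur$latitude)
  fut <- setdiff(unique(budget$per_cell$scenario_id), "current")
  if (length(fut) >= 2) {
    s1 <- budget$per_cell[budget$per_cell$scenario_id == fut[1], "h_r"]
    s2 <- budget$per_cell[budget$per_cell$scenario_id == fut[2], "h_r"]
    budget$scenario_test <- compare_scenarios(s2, s1)
  }

  trait <- stats::setNames(pop_tset$t_p, pop_tset$population)
  signal <- phylo_signal(trait[tree$tip.label], tree,
                         n_perm = config$n_perm, seed = seed)

  pstats <- population_statistics(estimates, roster)

  run <- structure(
    list(tables = list(roster = roster, trials = trials, spots = spots,
                       otm = otm, climate = climate, tree = tree),
         estimates = estimates, indices = indices, budget = budget,
         signal = signal, stats = pstats, config = config),
    class = "vipertherm_run"
  )
  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_synth_tables(run$tables, outdir)
  vt_write_csv(run$estimates, file.path(outdir, "tset_estimates.csv"))
  vt_write_csv(as.data.frame(run$indices),
               file.path(outdir, "index_report.csv"))
  vt_write_csv(run$budget$per_cell, file.path(outdir, "hr_per_cell.csv"))
  vt_write_csv(run$budget$per_scenario, file.path(outdir, "hr_summary.csv"))
  sig <- unclass(run$signal)
  jsonlite::write_json(sig, file.path(outdir, "signal.json"),
                       auto_unbox = TRUE, digits = NA)
  st <- run$stats
  st$pairwise_tp <- as.data.frame(st$pairwise_tp)
  jsonlite::write_json(lapply(unclass(st), unclass),
                       file.path(outdir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_lines <- c(
    paste0("vipertherm ", as.character(utils::packageVersion("vipertherm"))),
    paste0("R ", R.version.string),
    paste0("seed: ", run$config$seed),
    paste0("populations: ", paste(run$config$populations$name,
                                  collapse = ", ")),
    paste0("n_cells: ", run$config$n_cells),
    paste0("n_boot: ", run$config$n_boot),
    paste0("n_perm: ", run$config$n_perm)
  )
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.vipertherm_run <- function(x, ...) {
  cat("vipertherm pipeline run (seed", x$config$seed, ")\n\n")
  print(x$indices)
  cat("\n")
  print(x$budget)
  cat("\n")
  print(x$signal)
  cat("\n")
  print(x$stats)
  invisible(x)
}

#' Validate input tables against the pipeline schemas
#'
#' Checks schema (required columns), unit ranges, timestamp monotonicity and
#' cadence constancy of operative series, and returns a machine-readable
#' report with row-level diagnostics.
#'
#' @param paths named character vector or list of CSV paths; recognised names
#'   are `roster`, `trials`, `spots`, `otm`, `climate`.
#' @return data.frame with columns `table`, `check`, `pass`, `detail`.
#' @export
validate_tables <- function(paths) {
  schemas <- list(
    roster = c("individual_id", "population", "sex", "svl_mm", "gravid",
               "true_tp"),
    trials = c("individual_id", "population", "timestamp", "temp_c"),
    spots = c("individual_id", "population", "datetime", "t_b",
              "microhabitat"),
    otm = c("population", "microhabitat", "datetime", "t_e"),
    climate = c("cell_id", "latitude", "scenario_id", "gcm_id", month_cols)
  )
  out <- list()
  add <- function(tbl, check, pass, detail = "") {
    out[[length(out) + 1L]] <<- data.frame(table = tbl, check = check,
                                           pass = pass, detail = detail,
                                           stringsAsFactors = FALSE)
  }
  for (nm in names(paths)) {
    path <- paths[[nm]]
    if (!file.exists(path)) {
      vt_stop("io", paste0("cannot read file: ", path))
    }
    x <- vt_read_csv(path, datetime_cols = c("timestamp", "datetime"))
    sch <- schemas[[nm]]
    if (is.null(sch)) next
    miss <- setdiff(sch, names(x))
    add(nm, "schema", length(miss) == 0L,
        if (length(miss)) paste("missing:", paste(miss, collapse = ", "))
        else "")
    if (length(miss)) next
    if (nm == "trials") {
      bad <- which(x$temp_c < 0 | x$temp_c > 50)
      add(nm, "temp_range", length(bad) == 0L,
          if (length(bad)) paste("rows:", paste(utils::head(bad, 5),
                                                collapse = ",")) else "")
    }
    if (nm == "spots") {
      bad <- which(x$t_b <= 0 | x$t_b >= 50)
      add(nm, "t_b_range", length(bad) == 0L,
          if (length(bad)) paste("rows:", paste(utils::head(bad, 5),
                                                collapse = ",")) else "")
      add(nm, "microhabitat_labels",
          all(x$microhabitat %in% c("sun", "shade")), "")
    }
    if (nm == "otm") {
      add(nm, "microhabitat_labels",
          all(x$microhabitat %in% c("sun", "shade")), "")
      for (key in split(seq_len(nrow(x)),
                        paste(x$population, x$microhabitat))) {
        dt <- diff(as.numeric(x$datetime[key]))
        lab <- paste(x$population[key[1]], x$microhabitat[key[1]])
        if (any(dt <= 0)) {
          add(nm, paste0("monotone_timestamps[", lab, "]"), FALSE,
              paste("row:", key[which(dt <= 0)[1] + 1L]))
        } else {
          add(nm, paste0("monotone_timestamps[", lab, "]"), TRUE, "")
          add(nm, paste0("constant_cadence[", lab, "]"),
              length(unique(dt)) == 1L,
              if (length(unique(dt)) > 1L)
                paste("row:", key[which(dt != dt[1])[1] + 1L]) else "")
        }
      }
    }
    if (nm == "climate") {
      m <- as.matrix(x[month_cols])
      add(nm, "temp_range", all(m > -40 & m < 50), "")
      add(nm, "has_current", "current" %in% x$scenario_id, "")
    }
  }
  do.call(rbind, out)
}
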