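#' Default population configurations
#'
#' Five configurations emulating an alpine viper study spanning the species'
#' latitudinal range (populations TO, KU, TY, LA, VA from north to south).
#' Individual counts and mean snout-vent lengths follow the study design the
#' generator emulates; `base_tp` encodes an overall mean preferred temperature
#' of 28.77 degC and a cross-population latitude slope of 1.557 degC/degree
#' exactly, so downstream regressions have a known target.
#'
#' @param tp_sd_between SD (degC) of individual preferred temperature around
#'   the population mean.
#' @param tp_sd_within SD (degC) of gradient-trial readings around an
#'   individual's preferred temperature.
#' @param n_otm_days days of operative-temperature logging per population.
#' @return data.frame with one row per population; columns `name`, `latitude`,
#'   `base_tp`, `svl_mean`, `svl_sd`, `tp_sd_between`, `tp_sd_within`,
#'   `n_individuals`, `n_otm_days`.
#' @export
default_population_configs <- function(tp_sd_between = 1.5, tp_sd_within = 2,
                                       n_otm_days = 14) {
  lat <- c(TO = 40.71, KU = 40.47, TY = 39.98, LA = 39.66, VA = 38.66)
  data.frame(
    name = names(lat),
    latitude = unname(lat),
    base_tp = 28.77 + 1.557 * (unname(lat) - mean(lat)),
    svl_mean = c(293.2, 234.3, 257.7, 317.7, 262.6),
    svl_sd = 35,
    tp_sd_between = tp_sd_between,
    tp_sd_within = tp_sd_within,
    n_individuals = c(19L, 5L, 31L, 3L, 15L),
    n_otm_days = n_otm_days,
    stringsAsFactors = FALSE
  )
}

validate_population_configs <- function(configs) {
  need <- c("name", "latitude", "base_tp", "tp_sd_between", "tp_sd_within",
            "n_individuals")
  if (!is.data.frame(configs) || nrow(configs) == 0L) {
    vt_stop("invalid_config", "`configs` must be a non-empty data.frame")
  }
  miss <- setdiff(need, names(configs))
  if (length(miss)) {
    vt_stop("invalid_config",
            paste0("configs missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(configs$name)) {
    vt_stop("invalid_config", "population names must be unique")
  }
  if (any(configs$latitude < 35 | configs$latitude > 45)) {
    vt_stop("invalid_config", "latitude must lie in [35, 45]")
  }
  if (any(configs$base_tp <= 15 | configs$base_tp >= 45)) {
    vt_stop("invalid_config", "base_tp must lie in (15, 45) degC")
  }
  if (any(configs$tp_sd_between <= 0) || any(configs$tp_sd_within <= 0)) {
    vt_stop("invalid_config", "temperature SDs must be > 0")
  }
  if (any(configs$n_individuals < 1)) {
    vt_stop("invalid_config", "n_individuals must be >= 1")
  }
  if (is.null(configs$svl_mean)) configs$svl_mean <- 270
  if (is.null(configs$svl_sd)) configs$svl_sd <- 35
  if (is.null(configs$n_otm_days)) configs$n_otm_days <- 14
  invisible(configs)
}

#' Generate an individual roster
#'
#' Draws individuals per population with sex, snout-vent length, gravidity and
#' a latent preferred temperature `true_tp`. Female `true_tp` rises with SVL at
#' `slope_svl` degC/mm around the configured population SVL mean; male
#' `true_tp` is independent of SVL. Latent half-maximum set-point bounds
#' implied by the within-individual SD (`tp +- sqrt(2 log 2) * sd`) are carried
#' along so field-campaign generation can honour them.
#'
#' @param configs population configuration data.frame
#'   (see [default_population_configs()]).
#' @param seed integer seed; identical seeds give identical rosters.
#' @param slope_svl degC per mm of female SVL added to `true_tp` (default 0.02).
#' @param p_female probability an individual is female.
#' @param p_gravid probability a female is gravid.
#' @return data.frame with one row per individual.
#' @export
generate_roster <- function(configs, seed, slope_svl = 0.02,
                            p_female = 0.5, p_gravid = 0.4) {
  configs <- validate_population_configs(configs)
  with_stage_seed(seed, "roster", {
    rows <- lapply(seq_len(nrow(configs)), function(i) {
      cf <- configs[i, ]
      n <- cf$n_individuals
      sex <- ifelse(runif(n) < p_female, "female", "male")
      svl <- rnorm_trunc(n, cf$svl_mean, cf$svl_sd, 120, 500)
      gravid <- sex == "female" & runif(n) < p_gravid
      tp <- cf$base_tp +
        ifelse(sex == "female", slope_svl * (svl - cf$svl_mean), 0) +
        rnorm(n, 0, cf$tp_sd_between)
      tp <- pmin(pmax(tp, 15.5), 44.5)
      data.frame(
        individual_id = sprintf("%s_%02d", cf$name, seq_len(n)),
        population = cf$name,
        sex = sex,
        svl_mm = svl,
        gravid = gravid,
        true_tp = tp,
        latitude = cf$latitude,
        tp_sd_within = cf$tp_sd_within,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Generate thermal-gradient trial readings
#'
#' One cloacal-temperature reading per clock hour per individual, drawn from a
#' normal distribution centred on the individual's latent preferred
#' temperature and truncated to (15, 45) degC, emulating a 6:00-18:00 gradient
#' trial with hourly measurements.
#'
#' @param roster output of [generate_roster()].
#' @param hours integer clock hours of the readings (default 6:18, 13 readings).
#' @param seed integer seed.
#' @return data.frame with columns `individual_id`, `population`, `timestamp`,
#'   `temp_c`.
#' @export
generate_gradient_trials <- function(roster, hours = 6:18, seed) {
  if (length(hours) == 0L) vt_stop("invalid_config", "`hours` must be non-empty")
  if (any(hours < 0 | hours > 23)) {
    vt_stop("invalid_config", "`hours` must be clock hours in 0-23")
  }
  with_stage_seed(seed, "gradient_trials", {
    n_h <- length(hours)
    rows <- lapply(seq_len(nrow(roster)), function(i) {
      ind <- roster[i, ]
      data.frame(
        individual_id = ind$individual_id,
        population = ind$population,
        timestamp = vt_datetime(1L, hours * 3600),
        temp_c = rnorm_trunc(n_h, ind$true_tp, ind$tp_sd_within, 15, 45),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

# Latent half-maximum set-point bounds of a Normal(tp, sd) gradient distribution.
latent_tset <- function(true_tp, tp_sd_within) {
  hw <- sqrt(2 * log(2)) * tp_sd_within
  list(lower = true_tp - hw, upper = true_tp + hw)
}

#' Generate a field campaign: spot body temperatures and OTM logger series
#'
#' Produces two operative-temperature series per population (sun and shade) at
#' a 5-minute cadence, built as diurnal sinusoids peaking at 14:00 (sun
#' amplitude exceeding shade amplitude) with AR(1) noise, and "grab and jab"
#' spot records with body temperatures near each individual's latent set-point
#' range. A configurable fraction of records are early-morning "cold"
#' observations below the latent lower set-point bound, mimicking animals at
#' the start of morning basking.
#'
#' @param roster output of [generate_roster()].
#' @param n_days days of logging and sampling (default 14).
#' @param seed integer seed.
#' @param n_spots spot records per individual.
#' @param cold_fraction fraction of spot records forced below the individual's
#'   latent lower set-point bound (default 0.05).
#' @param sun_mean,sun_amplitude,shade_mean,shade_amplitude degC parameters of
#'   the diurnal sinusoids.
#' @param ar_phi,ar_sd AR(1) coefficient and innovation SD of the logger noise.
#' @param skip_tb_populations populations sampled for operative temperature
#'   only (no body-temperature records), as for a site where no animals could
#'   be captured.
#' @return list with elements `spots` and `otm` (data.frames).
#' @export
generate_field_campaign <- function(roster, n_days = 14, seed, n_spots = 5,
                                    cold_fraction = 0.05,
                                    sun_mean = 21, sun_amplitude = 13,
                                    shade_mean = 18, shade_amplitude = 7,
                                    ar_phi = 0.8, ar_sd = 0.8,
                                    skip_tb_populations = character()) {
  if (n_days < 1) vt_stop("invalid_config", "`n_days` must be >= 1")
  if (sun_amplitude <= shade_amplitude) {
    vt_stop("invalid_config", "sun amplitude must exceed shade amplitude")
  }
  if (cold_fraction < 0 || cold_fraction > 1) {
    vt_stop("invalid_config", "`cold_fraction` must be in [0, 1]")
  }
  with_stage_seed(seed, "field_campaign", {
    pops <- unique(roster$population)
    n_steps <- n_days * 288L
    secs <- (seq_len(n_steps) - 1L) * 300
    hours <- (secs %% 86400) / 3600

    otm <- do.call(rbind, lapply(pops, function(p) {
      make_series <- function(micro, m, a, sd_i) {
        eps <- stats::filter(rnorm(n_steps, 0, sd_i), ar_phi,
                             method = "recursive")
        data.frame(
          population = p,
          microhabitat = micro,
          datetime = vt_datetime(1L, secs),
          t_e = m + a * sin(2 * pi * (hours - 8) / 24) + as.numeric(eps),
          stringsAsFactors = FALSE
        )
      }
      rbind(make_series("sun", sun_mean, sun_amplitude, ar_sd),
            make_series("shade", shade_mean, shade_amplitude, ar_sd / 2))
    }))

    sampled <- roster[!(roster$population %in% skip_tb_populations), ,
                      drop = FALSE]
    spots <- NULL
    if (nrow(sampled) > 0L) {
      spots <- do.call(rbind, lapply(seq_len(nrow(sampled)), function(i) {
        ind <- sampled[i, ]
        ts <- latent_tset(ind$true_tp, ind$tp_sd_within)
        cold <- runif(n_spots) < cold_fraction
        t_b <- numeric(n_spots)
        n_cold <- sum(cold)
        # warm records sit inside the latent set-point range
        t_b[!cold] <- rnorm_trunc(n_spots - n_cold, ind$true_tp,
                                  0.5 * ind$tp_sd_within, ts$lower, ts$upper)
        # cold records: early-morning animals still below the range
        t_b[cold] <- ts$lower - runif(n_cold, 0.5, 8)
        day <- sample.int(n_days, n_spots, replace = TRUE)
        hr <- ifelse(cold, runif(n_spots, 6, 9), runif(n_spots, 6, 20))
        data.frame(
          individual_id = ind$individual_id,
          population = ind$population,
          datetime = vt_datetime(day, round(hr * 3600 / 60) * 60),
          t_b = t_b,
          microhabitat = sample(c("sun", "shade"), n_spots, replace = TRUE,
                                prob = c(0.6, 0.4)),
          latitude = ind$latitude,
          svl_mm = ind$svl_mm,
          sex = ind$sex,
          gravid = ind$gravid,
          stringsAsFactors = FALSE
        )
      }))
      spots <- spots[order(spots$population, spots$datetime), ]
      rownames(spots) <- NULL
    }
    list(spots = spots, otm = otm)
  })
}

#' Default climate-change scenario offsets
#'
#' One `current` scenario (zero offsets) plus three global climate models
#' crossed with an optimistic (SSP1-2.6) and a pessimistic (SSP5-8.5) pathway.
#' Offsets are degC added to the twelve monthly means for 2081-2100-style
#' warming, slightly stronger in summer.
#'
#' @return data.frame with columns `scenario_id`, `gcm_id`, `m01`..`m12`.
#' @export
default_scenarios <- function() {
  summer_shape <- 0.3 * cos(2 * pi * (1:12 - 7) / 12)
  mk <- function(scn, gcm, base) {
    out <- data.frame(scenario_id = scn, gcm_id = gcm,
                      stringsAsFactors = FALSE)
    off <- if (base == 0) rep(0, 12) else base + summer_shape
    out[paste0("m", sprintf("%02d", 1:12))] <- as.list(off)
    out
  }
  rbind(
    mk("current", "none", 0),
    mk("SSP1-2.6", "HadGEM3", 2.1), mk("SSP1-2.6", "IPSL", 1.8),
    mk("SSP1-2.6", "MIROC6", 2.4),
    mk("SSP5-8.5", "HadGEM3", 5.2), mk("SSP5-8.5", "IPSL", 4.7),
    mk("SSP5-8.5", "MIROC6", 5.6)
  )
}

month_cols <- paste0("m", sprintf("%02d", 1:12))

validate_scenarios <- function(scenarios) {
  need <- c("scenario_id", "gcm_id", month_cols)
  miss <- setdiff(need, names(scenarios))
  if (length(miss)) {
    vt_stop("invalid_config",
            paste0("scenarios missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!"current" %in% scenarios$scenario_id) {
    vt_stop("invalid_config", "scenario list must include `current`")
  }
  cur <- scenarios[scenarios$scenario_id == "current", month_cols]
  if (any(as.matrix(cur) != 0)) {
    vt_stop("invalid_config", "`current` scenario must have all offsets = 0")
  }
  invisible(scenarios)
}

#' Generate a grid of occurrence-cell monthly climates
#'
#' Each cell gets twelve monthly mean air temperatures built from a sinusoidal
#' seasonal cycle peaking in July, a negative latitude trend, and cell-level
#' noise; scenario offsets are then added per scenario x GCM. The default cell
#' count emulates a 102-cell occurrence set.
#'
#' @param n_cells number of occurrence cells (default 102).
#' @param lat_range numeric length-2, latitude range of the cells.
#' @param scenarios scenario data.frame (see [default_scenarios()]); must
#'   include the `current` scenario.
#' @param seed integer seed.
#' @param annual_mean degC mean at the midpoint latitude.
#' @param seasonal_amplitude degC half-range of the seasonal cycle.
#' @param lat_slope degC lost per degree of latitude northward.
#' @return data.frame with columns `cell_id`, `latitude`, `scenario_id`,
#'   `gcm_id`, `m01`..`m12`.
#' @export
generate_climate_grid <- function(n_cells = 102, lat_range = c(38.5, 41),
                                  scenarios = default_scenarios(), seed,
                                  annual_mean = 9, seasonal_amplitude = 9,
                                  lat_slope = 1.8) {
  if (n_cells < 1) vt_stop("invalid_config", "`n_cells` must be >= 1")
  validate_scenarios(scenarios)
  with_stage_seed(seed, "climate_grid", {
    lat <- runif(n_cells, lat_range[1], lat_range[2])
    cell_noise <- rnorm(n_cells, 0, 1)
    season <- seasonal_amplitude * cos(2 * pi * (1:12 - 7) / 12)
    base <- t(vapply(seq_len(n_cells), function(i) {
      annual_mean - lat_slope * (lat[i] - mean(lat_range)) + cell_noise[i] +
        season + rnorm(12, 0, 0.5)
    }, numeric(12)))
    rows <- lapply(seq_len(nrow(scenarios)), function(s) {
      off <- as.numeric(scenarios[s, month_cols])
      out <- data.frame(
        cell_id = sprintf("cell_%03d", seq_len(n_cells)),
        latitude = lat,
        scenario_id = scenarios$scenario_id[s],
        gcm_id = scenarios$gcm_id[s],
        stringsAsFactors = FALSE
      )
      out[month_cols] <- sweep(base, 2, off, `+`)
      out
    })
    do.call(rbind, rows)
  })
}

#' Generate a population-level phylogeny
#'
#' Builds a newick topology for the study populations. By default the
#' designated southern population (the last label) is sister to a ladder of
#' the remaining populations, mirroring a two-lineage (southern vs northern)
#' structure. Branch lengths are not assigned; see [grafen_lengths()].
#'
#' @param populations character vector of unique tip labels (>= 2).
#' @param outgroup label placed sister to all others (default: last label).
#' @param newick optional newick string overriding the default topology.
#' @return an [ape::phylo] object.
#' @export
generate_phylogeny <- function(populations, outgroup = NULL, newick = NULL) {
  if (length(populations) < 2L) {
    vt_stop("invalid_config", "need at least 2 populations")
  }
  if (anyDuplicated(populations)) {
    vt_stop("invalid_config", "population labels must be unique")
  }
  if (!is.null(newick)) return(ape::read.tree(text = newick))
  if (is.null(outgroup)) outgroup <- populations[length(populations)]
  if (!outgroup %in% populations) {
    vt_stop("invalid_config", "outgroup must be one of the populations")
  }
  rest <- setdiff(populations, outgroup)
  clade <- rest[1]
  if (length(rest) > 1L) {
    for (lab in rest[-1]) clade <- sprintf("(%s,%s)", clade, lab)
  }
  ape::read.tree(text = sprintf("(%s,%s);", outgroup, clade))
}

#' Write the synthetic tables of one study emulation to disk
#'
#' @param tables named list as produced by the generator stages of
#'   [run_pipeline()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_synth_tables <- function(tables, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    roster = file.path(outdir, "roster.csv"),
    trials = file.path(outdir, "gradient_trials.csv"),
    spots = file.path(outdir, "spot_records.csv"),
    otm = file.path(outdir, "otm_series.csv"),
    climate = file.path(outdir, "climate_cells.csv"),
    tree = file.path(outdir, "population_tree.nwk")
  )
  vt_write_csv(tables$roster, paths["roster"])
  vt_write_csv(tables$trials, paths["trials"])
  if (!is.null(tables$spots)) vt_write_csv(tables$spots, paths["spots"])
  vt_write_csv(tables$otm, paths["otm"])
  vt_write_csv(tables$climate, paths["climate"])
  ape::write.tree(tables$tree, file = paths["tree"])
  invisible(paths)
}
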