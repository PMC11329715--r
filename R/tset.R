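#' Temperature grid of the density procedure
#'
#' 15 to 45 degC inclusive in 0.05 degC steps (601 points).
#' @return numeric vector of length 601.
#' @export
tset_grid <- function() seq(15, 45, by = 0.05)

#' Normalized kernel density of a gradient-trial series
#'
#' Fits a Gaussian kernel density (Silverman-type rule-of-thumb bandwidth
#' \code{0.9 min(SD, IQR/1.34) n^(-1/5)}, the R default) to the readings,
#' evaluates it on the fixed 15-45 degC grid at 0.05 degC steps, and rescales
#' so the maximum is exactly 1. Readings outside the grid are clipped to its
#' ends with a warning.
#'
#' @param temps numeric vector of gradient readings (degC), >= 5 values with
#'   non-zero variance.
#' @return object of class `density_curve`: list with `grid` (601 points) and
#'   `prob` (in [0, 1], max exactly 1).
#' @export
normalized_density <- function(temps) {
  temps <- temps[!is.na(temps)]
  if (length(temps) < 5L) {
    vt_stop("insufficient_data",
            "need at least 5 gradient readings for a density estimate")
  }
  if (stats::sd(temps) == 0) {
    vt_stop("degenerate_input",
            "gradient readings have zero variance; density is degenerate")
  }
  if (any(temps < 15 | temps > 45)) {
    warning("readings outside [15, 45] degC clipped to the grid",
            call. = FALSE)
    temps <- pmin(pmax(temps, 15), 45)
    if (stats::sd(temps) == 0) {
      vt_stop("degenerate_input", "readings degenerate after clipping")
    }
  }
  grid <- tset_grid()
  d <- stats::density(temps, bw = stats::bw.nrd0(temps), kernel = "gaussian",
                      from = 15, to = 45, n = 2048)
  prob <- stats::approx(d$x, d$y, xout = grid, rule = 2)$y
  prob <- prob / max(prob)
  structure(list(grid = grid, prob = prob), class = "density_curve")
}

#' Read Tp and the set-point range off a normalized density curve
#'
#' Tp is the grid temperature at the curve maximum (lowest temperature on
#' ties); the set-point bounds are the smallest and largest grid temperatures
#' where the normalized density reaches 0.5 (the half-maximum crossings). An
#' interquartile alternative (central 50% of the reading distribution) is
#' available via `method = "iqr"`, which requires the raw readings.
#'
#' @param curve a `density_curve` from [normalized_density()].
#' @param method `"halfmax"` (default) or `"iqr"`.
#' @param temps raw readings, required for `method = "iqr"`.
#' @param level `"individual"` or `"population"` label carried in the result.
#' @param n_obs number of readings behind the curve (metadata).
#' @return object of class `tset_estimate`: list with `t_p`, `t_set_lower`,
#'   `t_set_upper`, `level`, `n_obs`, `method`, and `clipped` (TRUE when a
#'   bound sits on the grid edge).
#' @export
extract_tset <- function(curve, method = c("halfmax", "iqr"), temps = NULL,
                         level = "individual", n_obs = NA_integer_) {
  method <- match.arg(method)
  if (!inherits(curve, "density_curve")) {
    vt_stop("invalid_config", "`curve` must be a density_curve")
  }
  prob <- curve$prob
  grid <- curve$grid
  if (max(prob) < 0.5) {
    vt_stop("malformed_curve", "normalized density never reaches 0.5")
  }
  t_p <- grid[which.max(prob)]
  if (method == "halfmax") {
    at_half <- which(prob >= 0.5)
    lower <- grid[min(at_half)]
    upper <- grid[max(at_half)]
  } else {
    if (is.null(temps)) {
      vt_stop("invalid_config", "`temps` required for the IQR method")
    }
    q <- stats::quantile(temps, c(0.25, 0.75), names = FALSE, type = 7)
    lower <- q[1]
    upper <- q[2]
  }
  clipped <- lower <= grid[1] || upper >= grid[length(grid)]
  if (clipped) {
    warning("set-point bound clipped at the 15/45 degC grid edge",
            call. = FALSE)
  }
  structure(
    list(t_p = t_p, t_set_lower = lower, t_set_upper = upper,
         level = level, n_obs = n_obs, method = method, clipped = clipped),
    class = "tset_estimate"
  )
}

#' @export
print.tset_estimate <- function(x, ...) {
  cat(sprintf("Set-point estimate (%s, %s): Tp = %.2f degC, Tset = %.2f-%.2f degC (n = %s)\n",
              x$level, x$method, x$t_p, x$t_set_lower, x$t_set_upper,
              ifelse(is.na(x$n_obs), "?", x$n_obs)))
  invisible(x)
}

# One individual's estimate from its readings.
individual_tset <- function(temps, method = "halfmax") {
  est <- extract_tset(normalized_density(temps), method = method,
                      temps = temps, level = "individual",
                      n_obs = length(temps))
  est
}

#' Pooled population-level set-point estimate
#'
#' Pools all gradient readings of one population into a single series and
#' applies the density/half-maximum procedure to the pooled distribution.
#'
#' @param trials data.frame of gradient trials for one population (columns
#'   `individual_id`, `temp_c`).
#' @param method passed to [extract_tset()].
#' @return a `tset_estimate` with `level = "population"`.
#' @export
population_tset <- function(trials, method = "halfmax") {
  if (nrow(trials) == 0L) {
    vt_stop("insufficient_data", "no gradient readings for this population")
  }
  temps <- trials$temp_c
  est <- extract_tset(normalized_density(temps), method = method,
                      temps = temps, level = "population",
                      n_obs = length(temps))
  est
}

#' Estimate Tp and Tset for every individual and population
#'
#' @param trials gradient-trial data.frame (columns `individual_id`,
#'   `population`, `temp_c`).
#' @param method `"halfmax"` or `"iqr"`.
#' @return data.frame with one row per individual plus one per population
#'   (`level` column distinguishes them), columns `id`, `population`, `level`,
#'   `t_p`, `t_set_lower`, `t_set_upper`, `n_obs`, `clipped`.
#' @export
estimate_tset_table <- function(trials, method = "halfmax") {
  need <- c("individual_id", "population", "temp_c")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    vt_stop("invalid_config",
            paste0("trials missing columns: ", paste(miss, collapse = ", ")))
  }
  row_of <- function(est, id, pop) {
    data.frame(id = id, population = pop, level = est$level,
               t_p = est$t_p, t_set_lower = est$t_set_lower,
               t_set_upper = est$t_set_upper, n_obs = est$n_obs,
               clipped = est$clipped, stringsAsFactors = FALSE)
  }
  ind_rows <- lapply(split(trials, trials$individual_id), function(tr) {
    row_of(individual_tset(tr$temp_c, method), tr$individual_id[1],
           tr$population[1])
  })
  pop_rows <- lapply(split(trials, trials$population), function(tr) {
    row_of(population_tset(tr, method), tr$population[1], tr$population[1])
  })
  out <- do.call(rbind, c(ind_rows, pop_rows))
  rownames(out) <- NULL
  out
}
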