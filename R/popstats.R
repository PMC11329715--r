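#' Ordinary least-squares fit of y on x
#'
#' Simple linear regression via `stats::lm`, returning the slope with its
#' standard error and two-sided t-test.
#'
#' @param x predictor vector (must vary).
#' @param y response vector.
#' @return list of class `fit_result`: `slope`, `intercept`, `slope_se`,
#'   `t_stat`, `p_value`, `n`.
#' @export
ols_fit <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) vt_stop("insufficient_data", "need at least 3 points")
  if (stats::sd(x) == 0) {
    vt_stop("degenerate_design", "`x` has no variance")
  }
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["x", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 slope_se = unname(cf["x", "Std. Error"]),
                 t_stat = unname(cf["x", "t value"]),
                 p_value = unname(cf["x", "Pr(>|t|)"]),
                 n = length(x)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope b = %.4g (SE %.3g), t = %.3g, P = %.4g\n",
              x$n, x$slope, x$slope_se, x$t_stat, x$p_value))
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' W is in the count-of-wins orientation (number of (a, b) pairs with
#' a > b, ties counting half). The null distribution is enumerated exactly
#' when `length(a) * length(b) <= 400` and the pooled data are tie-free;
#' otherwise a normal approximation with continuity and tie correction is
#' used.
#'
#' @param a,b numeric samples (both non-empty).
#' @return list with `W`, `p_value`, `exact` (logical).
#' @export
wilcoxon_ranksum <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    vt_stop("insufficient_data", "both samples must be non-empty")
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) * length(b) <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(W = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Pairwise comparisons of a response across groups
#'
#' Fits a one-factor linear model and tests every pairwise group contrast
#' with pooled-variance t statistics. P-values are adjusted by Holm's method
#' (default) or by the single-step multivariate-t method (via multcomp when
#' available, Bonferroni otherwise).
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, total n > number of groups).
#' @param adjustment `"holm"` (default) or `"single-step"`.
#' @return data.frame of class `pairwise_table`: `pair`, `estimate`, `t_stat`,
#'   `p_raw`, `p_adjusted`, plus attribute `adjustment`.
#' @export
pairwise_population_comparison <- function(values, groups,
                                           adjustment = c("holm",
                                                          "single-step")) {
  adjustment <- match.arg(adjustment)
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.character(groups[keep])
  g <- sort(unique(groups))
  if (length(g) < 2L) vt_stop("invalid_config", "need at least 2 groups")
  n <- length(values)
  k <- length(g)
  if (n <= k) {
    vt_stop("insufficient_data",
            "no residual degrees of freedom for pooled variance")
  }
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  df <- n - k
  ss_res <- sum((values - means[groups])^2)
  s2 <- ss_res / df
  pairs <- utils::combn(g, 2)
  est <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(s2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  t_stat <- est / se
  p_raw <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  if (adjustment == "holm") {
    p_adj <- stats::p.adjust(p_raw, "holm")
  } else if (requireNamespace("multcomp", quietly = TRUE)) {
    dat <- data.frame(y = values, grp = factor(groups, levels = g))
    gl <- multcomp::glht(stats::lm(y ~ grp, data = dat),
                         linfct = multcomp::mcp(grp = "Tukey"))
    p_adj <- as.numeric(summary(gl)$test$pvalues)
  } else {
    p_adj <- stats::p.adjust(p_raw, "bonferroni")
  }
  out <- data.frame(pair = paste(pairs[2, ], "-", pairs[1, ]),
                    estimate = as.numeric(est), t_stat = as.numeric(t_stat),
                    p_raw = as.numeric(p_raw),
                    p_adjusted = pmax(as.numeric(p_adj), as.numeric(p_raw)),
                    stringsAsFactors = FALSE)
  attr(out, "adjustment") <- adjustment
  class(out) <- c("pairwise_table", "data.frame")
  out
}

#' The study's comparative statistics on a set of individual estimates
#'
#' Reproduces the battery of population-level tests: effect of SVL on Tp in
#' females and males separately (OLS), sex effect (Wilcoxon + LM), gravidity
#' effect within females (Wilcoxon + LM), latitude effects on Tp and both
#' set-point bounds (OLS), and multiplicity-adjusted pairwise population
#' comparisons of Tp. Factor coding for the LMs uses the first level
#' alphabetically as reference (female for sex, FALSE for gravid).
#'
#' @param estimates individual-level rows of [estimate_tset_table()].
#' @param roster the roster with `individual_id`, `sex`, `svl_mm`, `gravid`,
#'   `latitude`.
#' @param adjustment passed to [pairwise_population_comparison()].
#' @return list of class `popstats_report`.
#' @export
population_statistics <- function(estimates, roster,
                                  adjustment = "holm") {
  ind <- estimates[estimates$level == "individual", , drop = FALSE]
  d <- merge(ind, roster, by.x = "id", by.y = "individual_id",
             suffixes = c("", ".roster"))
  fem <- d[d$sex == "female", ]
  mal <- d[d$sex == "male", ]
  sex_num <- as.numeric(factor(d$sex, levels = c("female", "male"))) - 1
  grav_num <- as.numeric(fem$gravid)
  res <- list(
    svl_female = if (nrow(fem) >= 3) ols_fit(fem$svl_mm, fem$t_p),
    svl_male = if (nrow(mal) >= 3) ols_fit(mal$svl_mm, mal$t_p),
    sex_wilcoxon = if (nrow(fem) && nrow(mal))
      wilcoxon_ranksum(fem$t_p, mal$t_p),
    sex_lm = if (length(unique(sex_num)) == 2) ols_fit(sex_num, d$t_p),
    gravid_wilcoxon = if (length(unique(fem$gravid)) == 2)
      wilcoxon_ranksum(fem$t_p[fem$gravid], fem$t_p[!fem$gravid]),
    gravid_lm = if (length(unique(grav_num)) == 2)
      ols_fit(grav_num, fem$t_p),
    latitude_tp = ols_fit(d$latitude, d$t_p),
    latitude_tset_lower = ols_fit(d$latitude, d$t_set_lower),
    latitude_tset_upper = ols_fit(d$latitude, d$t_set_upper),
    pairwise_tp = pairwise_population_comparison(d$t_p, d$population,
                                                 adjustment = adjustment),
    n_individuals = nrow(d)
  )
  class(res) <- "popstats_report"
  res
}

#' @export
print.popstats_report <- function(x, ...) {
  cat(sprintf("Population statistics on %d individuals\n", x$n_individuals))
  show <- function(label, f) {
    if (!is.null(f)) cat(sprintf("  %-22s b = %8.4f  P = %.4f\n",
                                 label, f$slope, f$p_value))
  }
  show("SVL -> Tp (females):", x$svl_female)
  show("SVL -> Tp (males):", x$svl_male)
  if (!is.null(x$sex_wilcoxon)) {
    cat(sprintf("  %-22s W = %8.1f  P = %.4f\n", "sex (Wilcoxon):",
                x$sex_wilcoxon$W, x$sex_wilcoxon$p_value))
  }
  show("sex (LM):", x$sex_lm)
  show("latitude -> Tp:", x$latitude_tp)
  show("latitude -> Tset low:", x$latitude_tset_lower)
  show("latitude -> Tset up:", x$latitude_tset_upper)
  cat("  pairwise Tp contrasts:\n")
  print(as.data.frame(x$pairwise_tp), row.names = FALSE)
  invisible(x)
}
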