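#' @keywords internal
"_PACKAGE"

# Classed errors so callers can distinguish config problems from data problems.
vt_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("vipertherm_", class), "vipertherm_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

# All randomness flows from one root seed split into named per-stage streams.
# The derived seed stays below 2^31 - 1 so set.seed() always accepts it.
stage_seed <- function(seed, stage) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    vt_stop("invalid_config", "`seed` must be a single number")
  }
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stage_seed(seed, stage))
  expr
}

# Normal draws truncated to (lo, hi) by inverse-CDF; degenerate sd returns the mean.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (any(sd < 0)) vt_stop("invalid_config", "sd must be >= 0")
  if (all(sd == 0)) return(pmin(pmax(rep_len(mean, n), lo), hi))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

# Timestamps are timezone-naive local clock time; internally kept as POSIXct in UTC.
vt_datetime <- function(day, seconds_of_day, origin = "2017-08-01") {
  as.POSIXct(origin, tz = "UTC") + (day - 1) * 86400 + seconds_of_day
}

hour_of_day <- function(datetime) {
  as.numeric(format(datetime, "%H", tz = "UTC")) +
    as.numeric(format(datetime, "%M", tz = "UTC")) / 60 +
    as.numeric(format(datetime, "%S", tz = "UTC")) / 3600
}

# RFC 4180-style CSV writers with fixed schemas.
vt_write_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (nm in names(x)) {
    if (inherits(x[[nm]], "POSIXct")) {
      x[[nm]] <- format(x[[nm]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
    }
  }
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

vt_read_csv <- function(path, datetime_cols = character()) {
  if (!file.exists(path)) vt_stop("io", paste0("cannot read file: ", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(datetime_cols, names(x))) {
    x[[nm]] <- as.POSIXct(x[[nm]], tz = "UTC")
  }
  x
}
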