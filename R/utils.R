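# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic code in the package routes
# through this so that a single integer reproduces any result.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed, kept below 2^31.
deriveSeeds <- function(seed, n, stream = 0L) {
  (as.numeric(seed) * 48271 + stream * 1299721 + seq_len(n) * 7919) %% 2147483629
}

# Median absolute... no: *mean* absolute deviation about the median, the
# session-level typing-variability statistic.
meanAbsDeviation <- function(x, center = stats::median(x)) {
  mean(abs(x - center))
}

# 95th percentile with linear interpolation between order statistics
# (quantile type 7), fixed so downstream outputs are stable.
percentile95 <- function(x) {
  unname(stats::quantile(x, probs = 0.95, type = 7, names = FALSE))
}

# Coerce a date-ish column (Date, IDate, character) to Date.
asDate <- function(x) {
  if (inherits(x, "Date")) return(as.Date(x))
  as.Date(as.character(x))
}

# Coerce timestamps to numeric seconds. Accepts numeric (already seconds),
# POSIXct, or ISO-8601 strings with fractional seconds.
asSeconds <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (inherits(x, "POSIXct")) return(as.numeric(x))
  if (is.character(x)) {
    out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    bad <- is.na(out) & !is.na(x)
    if (any(bad)) {
      out[bad] <- as.POSIXct(x[bad], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
    }
    if (anyNA(out[!is.na(x)])) {
      stop("timestamp strings must be ISO-8601 (YYYY-MM-DDTHH:MM:SS.sss)")
    }
    return(as.numeric(out))
  }
  stop("unsupported timestamp type: ", paste(class(x), collapse = "/"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnotScalarNumeric <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}
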