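#' @keywords internal
"_PACKAGE"

# Sensor kinds handled by the ingest layer.
SENSORS <- c("call", "battery", "screen")

# Feature statistic suffixes, in the canonical reporting order.
FEATURE_STATS <- c("Use", "Freq", "Mean", "SD", "Ent")

#' Canonical names of the 15 passive features
#'
#' Three sensors (battery, call, screen) crossed with five statistics:
#' `Use` (hours of event time per observed hour), `Freq` (events per hour),
#' `Mean` and `SD` (event duration moments, in hours) and `Ent` (hour-of-day
#' occurrence entropy, nats).
#'
#' @return Character vector of length 15, e.g. `"battery_Use"`, `"call_Ent"`.
#' @export
feature_names <- function() {
  as.vector(t(outer(c("battery", "call", "screen"), FEATURE_STATS, paste, sep = "_")))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic child seed derived from a master seed and a few small integer
# tags, kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, ...) {
  tags <- c(...)
  s <- as.double(master) %% 2147483647
  for (t in tags) s <- (s * 69069 + as.double(t) * 104729 + 12345) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Lognormal parameters (meanlog, sdlog) giving a target arithmetic mean and SD.
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
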