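# Builders for small in-memory fixtures used across the suite.

t0 <- function(tz = "UTC") as.POSIXct("2020-01-06 00:00:00", tz = tz)

# Stream from hour offsets (relative to t0) and durations in seconds.
make_stream <- function(hours, durations_s, sensor = "screen",
                        span_hours = NULL, pid = "P01", tz = "UTC") {
  start <- t0(tz) + hours * 3600
  span <- if (is.null(span_hours)) NULL else t0(tz) + span_hours * 3600
  event_stream(pid, sensor, start, durations_s, span = span, tz = tz)
}

day_window <- function(from_h = 0, to_h = 24) {
  time_window(t0() + from_h * 3600, t0() + to_h * 3600)
}

# Independent proximal-gradient (ISTA) Lasso solver used as an oracle for
# the coordinate-descent implementation: minimises
# (1/2n)||y - b0 - X b||^2 + penalty * ||b||_1.
ista_lasso <- function(X, y, penalty, iters = 50000) {
  X <- as.matrix(X)
  n <- nrow(X)
  b0 <- mean(y)
  b <- rep(0, ncol(X))
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  for (i in seq_len(iters)) {
    r <- y - b0 - X %*% b
    g <- -crossprod(X, r) / n
    b_new <- b - g / L
    b_new <- sign(b_new) * pmax(abs(b_new) - penalty / L, 0)
    b0 <- mean(y - X %*% b_new)
    if (max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
    b <- b_new
  }
  as.vector(b)
}

# KKT subgradient verification for a Lasso active set at a given solution.
kkt_violations <- function(X, y, beta, b0, penalty, tol = 1e-6) {
  n <- nrow(X)
  g <- crossprod(X, y - b0 - X %*% beta) / n
  active <- beta != 0
  sum(abs(g[active] - penalty * sign(beta[active])) > tol) +
    sum(abs(g[!active]) > penalty + tol)
}
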