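test_that("usage per hour matches the worked examples and clips at edges", {
  # one 6-minute unlock in a 1-hour window
  s <- make_stream(0.5, 360, span_hours = c(0, 24))
  expect_equal(use_per_hour(s, day_window(0, 1)), 0.1)
  # no events
  empty <- make_stream(numeric(), numeric(), span_hours = c(0, 24))
  expect_equal(use_per_hour(empty, day_window()), 0)
  # an event straddling the window edge contributes only its inside portion
  s2 <- make_stream(23.5, 3600, span_hours = c(0, 48))
  expect_equal(use_per_hour(s2, day_window(0, 24)), 0.5 / 24)
  expect_error(time_window(t0(), t0()), "end > start")
})

test_that("usage agrees with a brute-force minute-grid oracle", {
  set.seed(31)
  s <- make_stream(sort(runif(60, 0, 24)), rlnorm(60, 5, 1),
                   span_hours = c(0, 48))
  w <- day_window(2, 26)
  # oracle: per-minute overlap sum on a discrete grid
  mins <- seq(2 * 3600, 26 * 3600 - 60, by = 60)
  ev_s <- as.double(s$events$start) - as.double(t0())
  ev_e <- ev_s + s$events$duration
  occ <- 0
  for (m in mins) {
    occ <- occ + sum(pmax(0, pmin(ev_e, m + 60) - pmax(ev_s, m)))
  }
  expect_equal(use_per_hour(s, w), (occ / 3600) / 24, tolerance = 1 / 60)
})

test_that("frequency per hour counts starts inside the half-open window", {
  s <- make_stream(seq(0, 23.5, by = 0.5), rep(30, 48), span_hours = c(0, 24))
  expect_equal(freq_per_hour(s, day_window(0, 24)), 2)
  empty <- make_stream(numeric(), numeric(), span_hours = c(0, 24))
  expect_equal(freq_per_hour(empty, day_window()), 0)
  # start exactly at the window end is excluded
  s2 <- make_stream(c(0, 24), c(10, 10), span_hours = c(0, 48))
  expect_equal(freq_per_hour(s2, day_window(0, 24)) * 24, 1)
})

test_that("duration moments use hours, handle 0/1 events, match the two-pass formula", {
  s <- make_stream(1, 360, span_hours = c(0, 24))
  m <- duration_moments(s, day_window())
  expect_equal(unname(m), c(0.1, 0))
  # 0.1 h mean reads as 6 minutes
  expect_equal(m[["mean"]] * 60, 6)

  empty <- make_stream(numeric(), numeric(), span_hours = c(0, 24))
  expect_true(all(is.na(duration_moments(empty, day_window()))))

  set.seed(5)
  d <- rlnorm(40, 6, 1.3)
  s2 <- make_stream(runif(40, 0, 24), d, span_hours = c(0, 24))
  m2 <- duration_moments(s2, day_window())
  dh <- d / 3600
  expect_equal(m2[["mean"]], sum(dh) / 40, tolerance = 1e-12)
  expect_equal(m2[["sd"]], sqrt(sum((dh - mean(dh))^2) / 39), tolerance = 1e-12)
})

test_that("occurrence entropy hits its closed forms", {
  # all events within one clock hour -> 0
  s <- make_stream(14 + runif(50), rep(30, 50), span_hours = c(0, 24))
  expect_equal(occurrence_entropy(s, day_window()), 0)
  # equal counts in all 24 bins -> log(24)
  hrs <- rep(0:23, each = 5) + 0.5
  s2 <- make_stream(hrs, rep(30, 120), span_hours = c(0, 24))
  expect_equal(occurrence_entropy(s2, day_window()), log(24))
  # base option
  expect_equal(occurrence_entropy(s2, day_window(), base = 2), log2(24))
  # no events -> missing
  empty <- make_stream(numeric(), numeric(), span_hours = c(0, 24))
  expect_true(is.na(occurrence_entropy(empty, day_window())))
})

test_that("entropy of multinomial-sampled streams matches the generating distribution", {
  set.seed(99)
  p <- c(rep(0.08, 5), rep(0.04, 10), rep(0.02, 9))
  p <- p / sum(p)
  H_true <- -sum(p * log(p))
  counts <- as.vector(rmultinom(1, 1000, p))
  hrs <- rep(0:23, counts) + runif(1000)
  s <- make_stream(hrs, rep(10, 1000), span_hours = c(0, 24))
  expect_equal(occurrence_entropy(s, day_window()), H_true, tolerance = 0.05)
})

test_that("entropy ignores durations and event order; scaling laws hold", {
  set.seed(13)
  hrs <- runif(80, 0, 24)
  d <- rlnorm(80, 5, 1)
  s <- make_stream(hrs, d, span_hours = c(0, 24))
  s_scaled <- make_stream(hrs, d * 3, span_hours = c(0, 24))
  s_perm <- make_stream(hrs[sample(80)], d[sample(80)], span_hours = c(0, 24))
  w <- day_window()
  expect_equal(occurrence_entropy(s, w), occurrence_entropy(s_scaled, w))
  expect_equal(occurrence_entropy(s, w),
               occurrence_entropy(make_stream(hrs, rep(1, 80),
                                              span_hours = c(0, 24)), w))
  expect_equal(freq_per_hour(s, w), freq_per_hour(s_scaled, w))
  # durations scaled by c scale use/mean/sd by c (no edge clipping here)
  expect_equal(use_per_hour(s_scaled, w), 3 * use_per_hour(s, w))
  m1 <- duration_moments(s, w); m3 <- duration_moments(s_scaled, w)
  expect_equal(unname(m3), unname(m1) * 3)
  # permutation leaves every statistic unchanged
  expect_equal(occurrence_entropy(s_perm, w), occurrence_entropy(s, w))
})

test_that("use and freq are additive over a partition of the window", {
  set.seed(21)
  s <- make_stream(sort(runif(100, 0, 48)), runif(100, 10, 1800),
                   span_hours = c(0, 48))
  whole <- day_window(0, 48)
  parts <- list(day_window(0, 12), day_window(12, 31), day_window(31, 48))
  lens <- c(12, 19, 17)
  f_whole <- freq_per_hour(s, whole)
  f_parts <- vapply(parts, function(w) freq_per_hour(s, w), 1)
  expect_equal(sum(f_parts * lens) / 48, f_whole)
  u_whole <- use_per_hour(s, whole)
  u_parts <- vapply(parts, function(w) use_per_hour(s, w), 1)
  expect_equal(sum(u_parts * lens) / 48, u_whole, tolerance = 1e-12)
})

test_that("extract_features agrees slot-wise with its component operations", {
  set.seed(3)
  streams <- list(
    battery = make_stream(runif(30, 0, 24), rlnorm(30, 7, 1), "battery",
                          span_hours = c(0, 24)),
    call = make_stream(runif(20, 0, 24), rlnorm(20, 4, 1), "call",
                       span_hours = c(0, 24)),
    screen = make_stream(runif(60, 0, 24), rlnorm(60, 5, 1), "screen",
                         span_hours = c(0, 24))
  )
  w <- day_window()
  fv <- extract_features(streams, w)
  expect_named(fv, feature_names())
  for (sensor in c("battery", "call", "screen")) {
    st <- streams[[sensor]]
    expect_equal(fv[[paste0(sensor, "_Use")]], use_per_hour(st, w))
    expect_equal(fv[[paste0(sensor, "_Freq")]], freq_per_hour(st, w))
    m <- duration_moments(st, w)
    expect_equal(fv[[paste0(sensor, "_Mean")]], m[["mean"]])
    expect_equal(fv[[paste0(sensor, "_SD")]], m[["sd"]])
    expect_equal(fv[[paste0(sensor, "_Ent")]], occurrence_entropy(st, w))
  }
})

test_that("event-free windows give zero use/freq and missing moments/entropy", {
  streams <- list(
    battery = make_stream(numeric(), numeric(), "battery", span_hours = c(0, 24)),
    call = make_stream(numeric(), numeric(), "call", span_hours = c(0, 24)),
    screen = make_stream(numeric(), numeric(), "screen", span_hours = c(0, 24))
  )
  fv <- extract_features(streams, day_window())
  expect_equal(unname(fv[c("battery_Use", "battery_Freq")]), c(0, 0))
  expect_true(all(is.na(fv[c("battery_Mean", "battery_SD", "battery_Ent")])))
})

test_that("a missing sensor warns and leaves its five slots missing", {
  streams <- list(
    screen = make_stream(runif(10, 0, 24), rep(60, 10), "screen",
                         span_hours = c(0, 24))
  )
  expect_warning(fv <- extract_features(streams, day_window()), "battery")
  expect_true(all(is.na(fv[paste0("call_", c("Use", "Freq", "Mean", "SD", "Ent"))])))
  expect_false(anyNA(fv[paste0("screen_", c("Use", "Freq", "Mean", "SD", "Ent"))]))
})

test_that("daily windows are the 24 h preceding each morning assessment", {
  t_am <- t0() + c(4, 5) * 86400 + 8 * 3600
  ws <- daily_windows(t_am)
  expect_length(ws, 2)
  expect_equal(as.double(ws[[1]][1]), as.double(t_am[1]) - 86400)
  expect_equal(as.double(ws[[1]][2]), as.double(t_am[1]))
  # consecutive 24h-apart mornings tile without overlap
  expect_equal(as.double(ws[[1]][2]), as.double(ws[[2]][1]))
  expect_error(daily_windows(rep(t_am[1], 2)), "duplicate")
  # irregular mornings less than 24 h apart produce overlapping windows
  irr <- t0() + c(30, 50) * 3600
  wi <- daily_windows(irr)
  expect_true(as.double(wi[[2]][1]) < as.double(wi[[1]][2]))
})

test_that("battery filtering changes mean/use exactly by the removed events' share", {
  set.seed(17)
  d <- c(runif(30, 0.5, 9.5), rlnorm(70, 7, 1) + 10)
  s <- make_stream(runif(100, 0, 24), d, "battery", span_hours = c(0, 24))
  w <- day_window()
  filtered <- filter_battery(s)$stream
  removed_h <- sum(s$events$duration[s$events$duration < 10]) / 3600
  expect_equal(use_per_hour(s, w) - use_per_hour(filtered, w),
               removed_h / 24, tolerance = 1e-6)
  m_all <- duration_moments(s, w)[["mean"]]
  m_f <- duration_moments(filtered, w)[["mean"]]
  expect_equal(m_all * 100 - m_f * 70, removed_h, tolerance = 1e-6)
})
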