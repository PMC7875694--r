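test_that("trait moments match the clipped-normal closed form at large n", {
  cfg <- cohort_config(n_participants = 10000, seed = 901)
  tr <- generate_traits(cfg)
  # closed-form mean/sd of a normal clipped (winsorised) to [1, 4]
  clip_moments <- function(mu, s) {
    a <- (1 - mu) / s; b <- (4 - mu) / s
    m <- 1 * pnorm(a) + 4 * (1 - pnorm(b)) +
      (mu * (pnorm(b) - pnorm(a)) - s * (dnorm(b) - dnorm(a)))
    ex2 <- 1 * pnorm(a) + 16 * (1 - pnorm(b)) +
      ((mu^2 + s^2) * (pnorm(b) - pnorm(a)) -
         s * ((4 + mu) * dnorm(b) - (1 + mu) * dnorm(a)))
    c(mean = m, sd = sqrt(ex2 - m^2))
  }
  for (trait in c("upps_sensation", "upps_perseverance", "bis_motor")) {
    i <- match(trait, impulsense:::TRAIT_MOMENTS$trait)
    mom <- clip_moments(impulsense:::TRAIT_MOMENTS$mean[i],
                        impulsense:::TRAIT_MOMENTS$sd[i])
    se_mean <- mom["sd"] / sqrt(10000)
    expect_lt(abs(mean(tr[[trait]]) - mom["mean"]), 3 * se_mean)
    expect_lt(abs(sd(tr[[trait]]) - mom["sd"]), 3 * se_mean)
  }
  # reference sensation-seeking descriptives are reproduced to ~0.03
  expect_equal(mean(tr$upps_sensation), 2.66, tolerance = 0.03)
  expect_equal(sd(tr$upps_sensation), 0.64, tolerance = 0.03)
})

test_that("zero trait SDs produce an identical cohort", {
  mom <- impulsense:::TRAIT_MOMENTS
  mom$sd <- 0
  cfg <- cohort_config(n_participants = 6, seed = 2, trait_moments = mom)
  tr <- generate_traits(cfg)
  expect_equal(unname(apply(tr[, mom$trait], 2, sd)), rep(0, 7))
  expect_equal(unname(unlist(tr[1, mom$trait])), mom$mean)
})

test_that("generated streams satisfy the stream invariants and round-trip", {
  cfg <- cohort_config(n_participants = 4, n_days = 5, seed = 41)
  tr <- generate_traits(cfg)
  st <- generate_streams(tr, cfg)
  expect_named(st, tr$participant_id)
  for (pid in names(st)) {
    for (sensor in c("call", "battery", "screen")) {
      s <- st[[pid]][[sensor]]
      expect_true(validate_event_stream(s))
    }
  }
  s <- st$P02$screen
  path <- tempfile(fileext = ".csv")
  write_event_log(s, path)
  s2 <- read_event_log(path, "screen", span = s$span)
  expect_equal(as.double(s2$events$start), as.double(s$events$start),
               tolerance = 1e-3)
  expect_equal(s2$events$duration, s$events$duration, tolerance = 1e-5)
})

test_that("the hourly-profile solver hits any attainable entropy target", {
  template <- impulsense:::circadian_template(15, 6)
  lo <- impulsense:::shannon(template)
  for (H in seq(lo + 0.05, log(24) - 0.01, length.out = 8)) {
    w <- impulsense:::profile_from_entropy(H, template)
    expect_equal(impulsense:::shannon(w), H, tolerance = 1e-8)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  # mixture entropy is monotone in the mixing weight
  ms <- seq(0, 1, by = 0.1)
  hs <- vapply(ms, function(m) {
    impulsense:::shannon((1 - m) / 24 + m * template)
  }, 1)
  expect_true(all(diff(hs) < 0))
})

test_that("high entropy targets drive generated streams toward uniform occupancy", {
  tg <- SENSOR_TARGETS_uniform <- impulsense:::SENSOR_TARGETS
  cfg <- cohort_config(n_participants = 6, n_days = 21, seed = 77,
                       trait_links = impulsense:::DEFAULT_TRAIT_LINKS[0, ])
  cfg$sensor_targets$screen$ent <- c(log(24), 1e-4)
  tr <- generate_traits(cfg)
  st <- generate_streams(tr, cfg)
  ents <- vapply(st, function(ss) {
    occurrence_entropy(ss$screen, time_window(ss$screen$span[1],
                                              ss$screen$span[2]))
  }, 1)
  expect_true(all(ents > 3.1))
})

test_that("cohort feature means sit within 2 SE of their calibration targets", {
  # battery usage is heavy-tailed across participants, so the moment check
  # pools several cohorts; the better-behaved anchors use a single cohort
  means <- sapply(1:12, function(i) {
    cfg <- cohort_config(seed = 310 + i)
    tr <- generate_traits(cfg)
    st <- generate_streams(tr, cfg)
    cl <- lapply(st, function(ss) lapply(ss, function(s) clean_stream(s)$stream))
    tf <- trait_features(cl)
    c(bU = mean(tf$battery_Use), cF = mean(tf$call_Freq),
      sE = mean(tf$screen_Ent), sF = mean(tf$screen_Freq),
      sE_se = sd(tf$screen_Ent) / sqrt(nrow(tf)),
      sF_se = sd(tf$screen_Freq) / sqrt(nrow(tf)))
  })
  expect_lt(abs(mean(means["bU", ]) - 0.30),
            2 * sd(means["bU", ]) / sqrt(12) + 0.015)
  expect_lt(abs(mean(means["cF", ]) - 0.38),
            2 * sd(means["cF", ]) / sqrt(12) + 0.015)
  expect_lt(abs(means["sE", 1] - 2.89), 2 * means["sE_se", 1] + 0.03)
  expect_lt(abs(means["sF", 1] - 1.97), 2 * means["sF_se", 1] + 0.05)
})

test_that("filter contamination defaults reproduce the reported removal fractions", {
  cfg <- cohort_config(seed = 21)
  b <- suppressWarnings(generate_bundle(cfg))
  expect_lt(abs(b$filter_fractions$battery - 0.165), 0.025)
  expect_lt(abs(b$filter_fractions$screen - 0.004), 0.003)
})

test_that("planted trait links are recovered as correlations near their targets", {
  rs <- vapply(1:8, function(i) {
    cfg <- cohort_config(seed = 1200 + i)
    tr <- generate_traits(cfg)
    st <- generate_streams(tr, cfg)
    cl <- lapply(st, function(ss) lapply(ss, function(s) clean_stream(s)$stream))
    tf <- trait_features(cl)
    c(cor(tf$battery_Ent, tr$upps_sensation),
      cor(tf$battery_Freq, tr$upps_sensation),
      cor(tf$call_Ent, tr$upps_sensation))
  }, numeric(3))
  # battery-entropy link planted at r = 0.48; pooled mean within sampling error
  expect_equal(mean(rs[1, ]), 0.48, tolerance = 2 * 0.18 / sqrt(8))
  expect_gt(mean(rs[2, ]), 0.5)
  expect_lt(mean(rs[3, ]), -0.4)
})

test_that("zero links and zero within-person noise give participant-constant outcomes", {
  cfg <- cohort_config(n_participants = 5, n_days = 6, seed = 9,
                       ema_missing_rate = 0)
  cfg$daily_outcomes$r <- 0
  cfg$daily_outcomes$icc <- 1
  b <- suppressWarnings(generate_bundle(cfg))
  for (oc in c("am_distracted", "prev_stressed", "pam_positive")) {
    spread <- tapply(b$daily[[oc]], b$daily$participant_id, function(v) {
      diff(range(v))
    })
    expect_true(all(abs(as.numeric(spread)) < 1e-12))
  }
})

test_that("daily outcome descriptives match their calibration (present bias ~0.34)", {
  b <- suppressWarnings(generate_bundle(cohort_config(seed = 628)))
  pb <- tapply(b$daily$dd_present_bias, b$daily$participant_id, mean)
  se <- sd(pb) / sqrt(length(pb))
  expect_lt(abs(mean(pb) - 0.34), 2 * se + 0.02)
  expect_equal(sd(b$daily$dd_present_bias), 0.18, tolerance = 0.08)
})

test_that("bundles are bit-reproducible and participant-stable under cohort growth", {
  cfg <- cohort_config(n_participants = 5, n_days = 4, seed = 55)
  b1 <- suppressWarnings(generate_bundle(cfg))
  b2 <- suppressWarnings(generate_bundle(cfg))
  expect_identical(b1$traits, b2$traits)
  expect_identical(b1$daily, b2$daily)
  expect_identical(b1$streams_raw$P03$battery$events,
                   b2$streams_raw$P03$battery$events)

  # adding a participant never perturbs existing traits or streams
  cfg6 <- cohort_config(n_participants = 6, n_days = 4, seed = 55)
  tr5 <- generate_traits(cfg); tr6 <- generate_traits(cfg6)
  expect_equal(tr6[1:5, ], tr5, ignore_attr = TRUE)
  st5 <- generate_streams(tr5, cfg); st6 <- generate_streams(tr6, cfg6)
  for (pid in names(st5)) {
    expect_identical(st6[[pid]]$screen$events, st5[[pid]]$screen$events)
    expect_identical(st6[[pid]]$call$events, st5[[pid]]$call$events)
  }
})

test_that("written bundles are byte-identical across runs and readable back", {
  cfg <- cohort_config(n_participants = 3, n_days = 3, seed = 17)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  b <- suppressWarnings(generate_bundle(cfg))
  write_bundle(b, d1)
  write_bundle(suppressWarnings(generate_bundle(cfg)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  s <- read_event_log(file.path(d1, "P01_battery.csv"), "battery")
  expect_gt(nrow(s$events), 0)
})

test_that("the full pipeline runs end-to-end on a small default-style cohort", {
  cfg <- cohort_config(n_participants = 8, n_days = 8, seed = 404)
  out <- suppressWarnings(run_pipeline(cfg, out_dir = file.path(tempdir(), "rep")))
  expect_length(out$trait_report, 9)
  expect_gt(length(out$state_report), 15)
  expect_true(file.exists(file.path(tempdir(), "rep", "trait_report.json")))
  expect_true(file.exists(file.path(tempdir(), "rep", "manifest.json")))
  rep2 <- jsonlite::read_json(file.path(tempdir(), "rep", "state_report.json"))
  expect_true(all(c("r", "within_group_correlation") %in%
                    names(rep2$dd_present_bias)))
})
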