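# --- Calibration constants -------------------------------------------------
#
# The generator is calibrated to reference cohort descriptives: per-sensor
# feature means/SDs (usage, frequency, duration mean/SD, occurrence entropy),
# trait score moments, and daily-outcome moments. Cross-participant frequency
# and mean duration are lognormal; their log-scale correlation is set so that
# the expected usage (freq x mean duration, with covariance) hits the usage
# target even though freq and duration targets alone would overshoot it --
# frequent users have shorter events.

SENSOR_TARGETS <- list(
  battery = list(use = 0.30, freq = c(0.20, 0.15), dur = c(1.50, 0.99),
                 within_sd = 2.09, ent = c(2.65, 0.24)),
  call    = list(use = 0.02, freq = c(0.38, 0.28), dur = c(0.0526, 0.035),
                 within_sd = 0.132, ent = c(2.52, 0.25)),
  screen  = list(use = 0.17, freq = c(1.97, 1.22), dur = c(0.11, 0.05),
                 within_sd = 0.17, ent = c(2.89, 0.10))
)

# Trait subscale moments (mean item scores on the 1-4 instrument range).
TRAIT_MOMENTS <- data.frame(
  trait = c("bis_motor", "bis_nonplanning", "bis_attention",
            "upps_urgency", "upps_perseverance", "upps_premeditation",
            "upps_sensation"),
  mean = c(1.74, 1.84, 1.66, 2.07, 1.57, 1.73, 2.66),
  sd   = c(0.45, 0.54, 0.49, 0.66, 0.42, 0.35, 0.64)
)

# Planted trait -> feature links. `channel` is the generative channel the
# standardized trait score shifts: "logf" (event rate), "logm" (duration
# scale), or "ent" (occurrence-entropy target). `r` is the approximate
# marginal correlation the link induces on the matching feature.
DEFAULT_TRAIT_LINKS <- data.frame(
  trait   = c("upps_sensation", "upps_sensation", "upps_sensation",
              "upps_sensation", "upps_sensation", "upps_sensation",
              "bis_nonplanning", "upps_perseverance",
              "bis_motor", "upps_urgency"),
  sensor  = c("battery", "battery", "screen", "screen", "battery", "call",
              "screen", "screen", "screen", "call"),
  channel = c("logf", "logm", "logf", "logm", "ent", "ent",
              "logm", "logm", "ent", "ent"),
  r       = c(0.84, -0.25, 0.46, -0.08, 0.48, -0.75,
              0.20, 0.15, 0.39, -0.39)
)

# Daily EMA/affect outcomes: reference mean/SD, the share of variance carried
# by the prior-24-hour features (as a correlation), the residual intraclass
# correlation, and which standardized daily features carry the link.
DAILY_OUTCOME_SPEC <- local({
  f <- function(...) I(list(c(...)))
  rbind(
    data.frame(outcome = "am_distracted", mean = 3.23, sd = 2.45, r = 0.276,
               icc = 0.388, features = f("screen_Freq", "screen_Use", "call_Freq"), sign = 1),
    data.frame(outcome = "pm_distracted", mean = 3.71, sd = 2.74, r = 0.194,
               icc = 0.388, features = f("screen_Freq", "screen_Use", "call_Freq"), sign = 1),
    data.frame(outcome = "am_impulsive", mean = 3.86, sd = 2.75, r = 0,
               icc = 0.743, features = f("screen_Freq"), sign = 1),
    data.frame(outcome = "pm_impulsive", mean = 4.47, sd = 2.93, r = 0,
               icc = 0.753, features = f("screen_Freq"), sign = 1),
    data.frame(outcome = "am_thrill", mean = 3.63, sd = 2.20, r = 0.245,
               icc = 0.633, features = f("screen_Freq", "battery_Ent"), sign = 1),
    data.frame(outcome = "pm_thrill", mean = 3.63, sd = 3.68, r = 0.361,
               icc = 0.631, features = f("screen_Freq", "battery_Ent"), sign = 1),
    data.frame(outcome = "am_bored", mean = 3.24, sd = 2.11, r = 0.273,
               icc = 0.329, features = f("screen_Use", "screen_Mean"), sign = 1),
    data.frame(outcome = "pm_bored", mean = 3.23, sd = 2.33, r = 0.061,
               icc = 0.481, features = f("screen_Use", "screen_Mean"), sign = 1),
    data.frame(outcome = "am_aimless", mean = 2.74, sd = 2.04, r = 0.360,
               icc = 0.185, features = f("screen_SD", "screen_Ent"), sign = 1),
    data.frame(outcome = "pm_aimless", mean = 3.08, sd = 2.19, r = 0.217,
               icc = 0.285, features = f("screen_SD", "screen_Ent"), sign = 1),
    data.frame(outcome = "prev_negative", mean = 2.59, sd = 2.11, r = 0.316,
               icc = 0.157, features = f("call_Ent", "call_Freq"), sign = -1),
    data.frame(outcome = "prev_impulsive", mean = 3.95, sd = 2.92, r = 0,
               icc = 0.794, features = f("screen_Freq"), sign = 1),
    data.frame(outcome = "prev_unproductive", mean = 2.47, sd = 1.99, r = 0.271,
               icc = 0.161, features = f("screen_Use", "screen_Freq"), sign = 1),
    data.frame(outcome = "prev_stressed", mean = 4.64, sd = 2.84, r = 0.377,
               icc = 0.134, features = f("battery_Freq", "screen_Freq"), sign = 1),
    data.frame(outcome = "prev_unhealthy", mean = 3.92, sd = 2.50, r = 0.248,
               icc = 0.242, features = f("screen_Use", "battery_Use"), sign = 1),
    data.frame(outcome = "pam_positive", mean = 9.25, sd = 3.50, r = 0.143,
               icc = 0.112, features = f("call_Freq", "call_Ent"), sign = 1),
    data.frame(outcome = "pam_negative", mean = 5.79, sd = 3.66, r = 0.171,
               icc = 0.114, features = f("screen_Freq", "battery_Ent"), sign = 1)
  )
})

# Active-task agent-parameter links: feature-carried share (r, on the
# parameter scale, before task noise) and between-person share (icc).
TASK_LINK_SPEC <- list(
  dd  = list(r = 0.85, icc = 0.05, features = c("screen_Freq", "screen_Use"),
             trait = "upps_total"),
  gng_latency = list(r = 0.40, icc = 0.60, features = c("screen_Ent", "call_Ent"),
                     trait = "bis_attention"),
  gng_commission = list(r = 0.30, icc = 0.30, features = c("screen_Freq"),
                        trait = "bis_attention"),
  gng_omission = list(r = 0.45, icc = 0.10, features = c("screen_Use"),
                      trait = "bis_attention"),
  bart = list(r = 0.35, icc = 0.55, features = c("battery_Ent", "screen_Freq"),
              trait = "upps_sensation")
)

#' Configuration of the synthetic cohort generator
#'
#' All knobs of the generative model. Defaults encode the study conditions:
#' 26 participants observed for 21 days, per-sensor event-rate and duration
#' distributions calibrated to the reference feature descriptives, planted
#' trait-to-feature links with the reference effect signs, daily outcomes whose
#' feature-linked variance share and intraclass correlation follow the
#' reference per-outcome summaries (with the present-moment and previous-day
#' impulsivity items deliberately unlinked), and agent-simulated task
#' metrics.
#'
#' @param n_participants Cohort size (>= 3).
#' @param n_days Days of sensing per participant.
#' @param seed Master seed; all substreams derive from it, per participant /
#'   sensor, so adding a participant never perturbs existing ones.
#' @param tz Timezone for event timestamps and hour-of-day binning.
#' @param start Study start (midnight, day 0).
#' @param morning_hour Hour of the daily morning assessment.
#' @param ema_missing_rate Probability a participant-day's assessment bundle
#'   is missing.
#' @param trait_cor Exchangeable correlation among trait subscales.
#' @param trait_moments Data frame (`trait`, `mean`, `sd`) of subscale score
#'   moments; defaults to the reference descriptives.
#' @param trait_links Data frame of planted trait-to-feature links (see
#'   `DEFAULT_TRAIT_LINKS` in the sources).
#' @param day_rate_jitter_sd,day_dur_jitter_sd Log-normal day-to-day jitter
#'   of event rates and duration scales (within-person variability).
#' @param circadian_peak_hour,circadian_kappa Peak hour and concentration of
#'   the von-Mises-like circadian template; larger kappa = peakier template
#'   = lower attainable entropy.
#' @param battery_contam_ratio Expected spurious sub-10-s battery events per
#'   clean event (default reproduces roughly the reported 16.5% removal).
#' @param screen_contam_ratio Expected over-2-h screen sessions per clean
#'   event (with naturally long sessions, roughly the reported 0.4% removal).
#' @param dd_delayed_amount,dd_delay,dd_noise Delay-discounting task setup.
#' @param daily_outcomes Data frame of per-outcome generative settings.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 26,
                          n_days = 21,
                          seed = 1,
                          tz = "UTC",
                          start = as.POSIXct("2020-01-06 00:00:00", tz = tz),
                          morning_hour = 8,
                          ema_missing_rate = 0.10,
                          trait_cor = 0.3,
                          trait_moments = TRAIT_MOMENTS,
                          trait_links = DEFAULT_TRAIT_LINKS,
                          day_rate_jitter_sd = 0.30,
                          day_dur_jitter_sd = 0.20,
                          circadian_peak_hour = 15,
                          circadian_kappa = 6,
                          battery_contam_ratio = 0.1976,
                          screen_contam_ratio = 0.0033,
                          dd_delayed_amount = 20,
                          dd_delay = 30,
                          dd_noise = 0.8,
                          daily_outcomes = DAILY_OUTCOME_SPEC) {
  stopifnot(n_participants >= 3, n_days >= 2, ema_missing_rate >= 0,
            ema_missing_rate < 1)
  structure(list(
    n_participants = n_participants, n_days = n_days, seed = seed, tz = tz,
    start = start, morning_hour = morning_hour,
    ema_missing_rate = ema_missing_rate,
    trait_cor = trait_cor, trait_moments = trait_moments,
    trait_links = trait_links,
    sensor_targets = SENSOR_TARGETS,
    day_rate_jitter_sd = day_rate_jitter_sd,
    day_dur_jitter_sd = day_dur_jitter_sd,
    circadian_peak_hour = circadian_peak_hour,
    circadian_kappa = circadian_kappa,
    battery_contam_ratio = battery_contam_ratio,
    screen_contam_ratio = screen_contam_ratio,
    dd_delayed_amount = dd_delayed_amount, dd_delay = dd_delay,
    dd_noise = dd_noise,
    daily_outcomes = daily_outcomes,
    task_links = TASK_LINK_SPEC
  ), class = "cohort_config")
}

#' Remove all planted links from a cohort configuration
#'
#' Produces a null generator: no trait-to-feature links and no
#' feature-to-daily-outcome links, leaving only random between- and
#' within-person variation. Used for type-I-error simulations.
#'
#' @param config A [cohort_config].
#' @return The modified config.
#' @export
null_config <- function(config = cohort_config()) {
  config$trait_links <- config$trait_links[0, ]
  config$daily_outcomes$r <- 0
  config$task_links <- lapply(config$task_links, function(l) {
    l$r <- 0; l
  })
  config
}

#' Generate baseline trait scores
#'
#' Draws the seven BIS-15/UPPS subscale scores from a multivariate normal
#' with the reference means and SDs and an exchangeable correlation, clipped
#' to the 1-4 instrument range; the instrument totals are the means of their
#' subscales.
#'
#' @param config A [cohort_config].
#' @param seed Seed (defaults to a substream of the config seed).
#' @return Data frame: `participant_id`, seven subscales, `bis_total`,
#'   `upps_total`.
#' @export
generate_traits <- function(config = cohort_config(), seed = NULL) {
  seed <- seed %||% config$seed
  n <- config$n_participants
  mom <- config$trait_moments %||% TRAIT_MOMENTS
  k <- nrow(mom)
  R <- matrix(config$trait_cor, k, k); diag(R) <- 1
  S <- diag(mom$sd) %*% R %*% diag(mom$sd)
  if (any(mom$sd > 0) &&
      min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("infeasible trait covariance")
  }
  # one seeded draw per participant, so growing the cohort never perturbs
  # the traits of existing participants
  x <- t(vapply(seq_len(n), function(p) {
    with_seed(derive_seed(seed, 101, p),
              as.vector(MASS::mvrnorm(1, mu = mom$mean, Sigma = S)))
  }, numeric(k)))
  x <- clamp(x, 1, 4)
  colnames(x) <- mom$trait
  df <- as.data.frame(x)
  df$bis_total <- rowMeans(df[, c("bis_motor", "bis_nonplanning", "bis_attention")])
  df$upps_total <- rowMeans(df[, c("upps_urgency", "upps_perseverance",
                                   "upps_premeditation", "upps_sensation")])
  cbind(participant_id = sprintf("P%02d", seq_len(n)), df)
}

# Standardized trait scores against the configured (not sample) moments.
trait_z <- function(traits, moments = TRAIT_MOMENTS) {
  z <- sapply(seq_len(nrow(moments)), function(i) {
    s <- moments$sd[i]
    if (s == 0) rep(0, nrow(traits)) else
      (traits[[moments$trait[i]]] - moments$mean[i]) / s
  })
  colnames(z) <- moments$trait
  tot_m <- c(bis_total = 1.77, upps_total = 2.04)
  tot_s <- c(bis_total = 0.36, upps_total = 0.36)
  z <- cbind(z,
             bis_total = (traits$bis_total - tot_m[1]) / tot_s[1],
             upps_total = (traits$upps_total - tot_m[2]) / tot_s[2])
  z
}

# Circadian template over 24 hours: von-Mises-like bump around the peak hour.
circadian_template <- function(peak = 15, kappa = 3) {
  h <- 0:23
  w <- exp(kappa * cos(2 * pi * (h - peak) / 24))
  w / sum(w)
}

shannon <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }

# Hourly profile with a prescribed entropy: mixture (1-m) * uniform +
# m * template, with m solved by bisection (entropy is strictly decreasing
# in m). Targets above log(24) or below the template entropy are clamped.
profile_from_entropy <- function(H, template) {
  lo <- shannon(template); hi <- log(24)
  H <- clamp(H, lo + 1e-9, hi - 1e-9)
  f <- function(m) shannon((1 - m) / 24 + m * template) - H
  m <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  (1 - m) / 24 + m * template
}

# Per-sensor, per-participant generative parameters implied by the
# calibration targets and the planted trait links.
sensor_person_params <- function(sensor, z, config, seed) {
  tg <- config$sensor_targets[[sensor]]
  lf <- lognormal_params(tg$freq[1], tg$freq[2])
  lm_ <- lognormal_params(tg$dur[1], tg$dur[2])
  links <- config$trait_links[config$trait_links$sensor == sensor, , drop = FALSE]
  n <- nrow(z)
  shift <- function(channel, sd_log) {
    l <- links[links$channel == channel, , drop = FALSE]
    out <- list(mu = numeric(n), a2 = 0,
                a = stats::setNames(numeric(0), character(0)))
    for (i in seq_len(nrow(l))) {
      a <- l$r[i] * sd_log
      out$mu <- out$mu + a * z[, l$trait[i]]
      out$a2 <- out$a2 + a^2
      out$a[l$trait[i]] <- a
    }
    out
  }
  sf <- shift("logf", lf["sdlog"])
  sm <- shift("logm", lm_["sdlog"])
  res_f <- sqrt(max(lf["sdlog"]^2 - sf$a2, 0.01))
  res_m <- sqrt(max(lm_["sdlog"]^2 - sm$a2, 0.01))
  # residual log-log correlation chosen so E[freq * mean duration] matches
  # the usage target despite the marginal freq and duration calibrations;
  # the trait links' cross-product is part of the freq-duration covariance
  target_cov <- log(tg$use / (tg$freq[1] * tg$dur[1]))
  shared <- intersect(names(sf$a), names(sm$a))
  link_cross <- sum(sf$a[shared] * sm$a[shared])
  rho <- clamp((target_cov - link_cross) / (res_f * res_m), -0.95, 0.95)
  se <- shift("ent", tg$ent[2])
  res_e <- sqrt(max(tg$ent[2]^2 - se$a2, 1e-4))
  # one seeded draw triple per participant (seed policy: growing the cohort
  # never perturbs existing participants)
  u <- t(vapply(seq_len(n), function(p) {
    with_seed(derive_seed(seed, 201, match(sensor, SENSORS), p),
              stats::rnorm(3))
  }, numeric(3)))
  u2 <- rho * u[, 1] + sqrt(1 - rho^2) * u[, 2]
  f_p <- exp(lf["meanlog"] + sf$mu + res_f * u[, 1])
  m_p <- exp(lm_["meanlog"] + sm$mu + res_m * u2)
  # within-person duration spread (log scale) from the duration-SD target
  s_w <- sqrt(log(1 + (tg$within_sd / tg$dur[1])^2))
  # observed-entropy target per participant, then a Miller-Madow allowance
  # for plug-in bias at the expected event count
  H_obs <- tg$ent[1] + se$mu + res_e * u[, 3]
  list(f = f_p, m = m_p, s_w = s_w, H_obs = H_obs)
}

#' Generate per-participant sensor event streams
#'
#' For each participant and sensor, event starts follow an inhomogeneous
#' Poisson process whose hourly rates are a participant-specific circadian
#' profile (solved to hit that participant's occurrence-entropy target,
#' including a Miller-Madow allowance for plug-in bias) scaled by a
#' participant event rate with day-to-day lognormal jitter. Durations are
#' lognormal with participant-specific scale and day-to-day jitter. Planted
#' trait links shift log-rates, log-duration-scales, and entropy targets.
#' Spurious events -- sub-10-second battery blips and over-2-hour screen
#' sessions -- are added at configurable rates so the cleaning filters have
#' realistic work to do.
#'
#' @param traits Trait data frame from [generate_traits()].
#' @param config A [cohort_config].
#' @param seed Master seed override.
#' @return Named list (participant id) of lists of three raw [event_stream]s.
#' @export
generate_streams <- function(traits, config = cohort_config(), seed = NULL) {
  seed <- seed %||% config$seed
  z <- trait_z(traits)
  template <- circadian_template(config$circadian_peak_hour,
                                 config$circadian_kappa)
  t0 <- as.double(config$start)
  hours_total <- 24 * config$n_days
  span <- as.POSIXct(c(t0, t0 + hours_total * 3600),
                     origin = "1970-01-01", tz = config$tz)
  params <- list()
  for (sensor in SENSORS) {
    params[[sensor]] <- sensor_person_params(sensor, z, config, seed)
  }
  out <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- traits$participant_id[p]
    streams <- list()
    for (sensor in SENSORS) {
      pp <- params[[sensor]]
      streams[[sensor]] <- with_seed(
        derive_seed(seed, 301, p, match(sensor, SENSORS)),
        {
          N_hat <- pp$f[p] * hours_total
          H_prof <- pp$H_obs[p] + 23 / (2 * max(N_hat, 24))
          w <- profile_from_entropy(H_prof, template)
          day_mult <- exp(stats::rnorm(config$n_days, 0, config$day_rate_jitter_sd) -
                            config$day_rate_jitter_sd^2 / 2)
          dur_mult <- exp(stats::rnorm(config$n_days, 0, config$day_dur_jitter_sd) -
                            config$day_dur_jitter_sd^2 / 2)
          rates <- as.vector(outer(w * 24 * pp$f[p], day_mult))  # hour x day
          counts <- stats::rpois(length(rates), rates)
          # map (hour-of-day, day) grid to absolute hour offsets
          grid_hours <- as.vector(outer(0:23, (seq_len(config$n_days) - 1L) * 24, "+"))
          starts_h <- rep(grid_hours, counts) + stats::runif(sum(counts))
          day_of <- rep(rep(seq_len(config$n_days), each = 24), counts)
          mu_d <- log(pp$m[p] * dur_mult[day_of]) - pp$s_w^2 / 2
          dur_h <- stats::rlnorm(sum(counts), mu_d, pp$s_w)
          start <- t0 + starts_h * 3600
          duration <- dur_h * 3600
          # contaminants the cleaning filters are meant to remove
          if (sensor == "battery" && config$battery_contam_ratio > 0) {
            nc <- stats::rpois(1, config$battery_contam_ratio * N_hat)
            start <- c(start, t0 + stats::runif(nc, 0, hours_total) * 3600)
            duration <- c(duration, stats::runif(nc, 0.5, 9.5))
          }
          if (sensor == "screen" && config$screen_contam_ratio > 0) {
            nc <- stats::rpois(1, config$screen_contam_ratio * N_hat)
            start <- c(start, t0 + stats::runif(nc, 0, hours_total) * 3600)
            duration <- c(duration, stats::runif(nc, 2 * 3600 + 1, 4 * 3600))
          }
          event_stream(pid, sensor,
                       as.POSIXct(start, origin = "1970-01-01", tz = config$tz),
                       duration, span = span, tz = config$tz)
        }
      )
    }
    out[[pid]] <- streams
  }
  out
}

# Standardize selected daily-feature columns and average them into a
# unit-variance link score (pooled across participant-days).
link_score <- function(daily_feats, features) {
  cols <- intersect(features, names(daily_feats))
  if (length(cols) == 0L) return(rep(0, nrow(daily_feats)))
  z <- scale(as.matrix(daily_feats[, cols, drop = FALSE]))
  z[is.na(z)] <- 0
  s <- rowMeans(z)
  sdv <- stats::sd(s)
  if (is.na(sdv) || sdv == 0) rep(0, length(s)) else s / sdv
}

#' Generate daily outcomes linked to daily features
#'
#' Each EMA/affect outcome is a participant random intercept plus a linear
#' combination of that day's standardized features plus noise, scaled so the
#' pooled mean/SD, the feature-carried correlation, and the residual
#' intraclass correlation match the per-outcome configuration; values are
#' clipped to the instrument range. The present-moment and previous-day
#' impulsivity items carry no feature link by default. Task metrics come
#' from simulated task sessions whose agent parameters derive from traits
#' (discount rate increasing in trait impulsivity) plus a day-level feature
#' link.
#'
#' @param traits Trait data frame.
#' @param daily_feats Daily feature table from [daily_features()].
#' @param config A [cohort_config].
#' @param seed Master seed override.
#' @return Data frame of `DailyRecord`s: `participant_id`, `date`,
#'   `morning_time`, 17 EMA/affect columns, 6 task metric columns.
#' @export
generate_daily_outcomes <- function(traits, daily_feats,
                                    config = cohort_config(), seed = NULL) {
  seed <- seed %||% config$seed
  if (any(!stats::complete.cases(daily_feats[, intersect(feature_names(),
                                                         names(daily_feats))]))) {
    bad <- !stats::complete.cases(daily_feats[, intersect(feature_names(),
                                                          names(daily_feats))])
    warning(sum(bad), " participant-days have incomplete features; skipped")
    daily_feats <- daily_feats[!bad, , drop = FALSE]
  }
  z <- trait_z(traits)
  rownames(z) <- traits$participant_id
  pid <- daily_feats$participant_id
  pidx <- match(pid, traits$participant_id)
  n <- nrow(daily_feats)
  out <- data.frame(participant_id = pid,
                    date = as.Date(daily_feats$morning_time),
                    morning_time = daily_feats$morning_time)
  spec <- config$daily_outcomes
  ids <- traits$participant_id
  # per-participant noise draws under derived seeds, so growing the cohort
  # never perturbs existing participants' outcomes
  pnum <- match(pid, ids)
  n_draw <- function(tag, extra) {
    # one value per participant (tag, 1) or one per participant-day (tag, 2)
    v <- numeric(n)
    for (p in unique(pnum)) {
      rows <- which(pnum == p)
      v[rows] <- with_seed(derive_seed(seed, tag, p, extra), {
        draws <- stats::rnorm(1 + length(rows))
        if (extra %% 2 == 1) rep(draws[1], length(rows)) else draws[-1]
      })
    }
    v
  }
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    g <- s$sign * link_score(daily_feats, s$features[[1]])
    resid_sd <- s$sd * sqrt(1 - s$r^2)
    y <- s$mean + s$r * s$sd * g +
      resid_sd * sqrt(s$icc) * n_draw(401 + i, 1) +
      resid_sd * sqrt(1 - s$icc) * n_draw(401 + i, 2)
    hi <- if (startsWith(s$outcome, "pam")) 16 else 10
    out[[s$outcome]] <- clamp(y, 0, hi)
  }
  # --- active tasks --------------------------------------------------------
  tl <- config$task_links
  mix <- function(l, width, tag) {
    u <- n_draw(tag, 1)
    g <- link_score(daily_feats, l$features)
    tz_ <- if (l$trait %in% colnames(z)) z[pidx, l$trait] else 0
    between <- sqrt(l$icc) * (0.6 * tz_ + 0.8 * u)
    within <- sqrt(max(1 - l$icc, 0)) *
      (l$r * g + sqrt(max(1 - l$r^2, 0)) * n_draw(tag, 2))
    width * (between + within)
  }
  res <- list(
    logk = log(0.0065) + mix(tl$dd, 1.1, 471),
    lat_mu = clamp(450 + mix(tl$gng_latency, 25, 473), 250, 495),
    com = stats::plogis(stats::qlogis(0.02) + mix(tl$gng_commission, 0.7, 475)),
    omi = stats::plogis(stats::qlogis(0.02) + mix(tl$gng_omission, 0.7, 477)),
    pumps = clamp(4.8 + mix(tl$bart, 0.8, 479), 0.5, 9.5)
  )
  day_in_p <- stats::ave(seq_len(n), pnum, FUN = seq_along)
  bart_risk <- bart_gains <- gng_latency <- gng_commission <-
    gng_omission <- dd_present_bias <- numeric(n)
  for (j in seq_len(n)) {
    ag <- agent_params(dd_k = exp(res$logk[j]),
                       gng_commission_rate = res$com[j],
                       gng_omission_rate = res$omi[j],
                       gng_latency_mean = res$lat_mu[j],
                       gng_latency_sd = 60,
                       bart_target_pumps = res$pumps[j],
                       dd_noise = config$dd_noise)
    sd_task <- derive_seed(seed, 481, pnum[j], day_in_p[j])
    trials <- generate_gng_session(75, seed = derive_seed(sd_task, 1))
    gng <- simulate_gng(trials, ag, seed = derive_seed(sd_task, 2))
    mdd <- run_mdd(ag, config$dd_delayed_amount, config$dd_delay,
                   seed = derive_seed(sd_task, 3))
    bart <- simulate_bart(ag, seed = derive_seed(sd_task, 4))
    gng_latency[j] <- gng[["latency"]]
    gng_commission[j] <- gng[["commission"]]
    gng_omission[j] <- gng[["omission"]]
    dd_present_bias[j] <- mdd$present_bias
    bart_risk[j] <- bart[["pumps"]]
    bart_gains[j] <- bart[["gains"]]
  }
  out$bart_risk <- bart_risk
  out$bart_gains <- bart_gains
  out$gng_latency <- gng_latency
  out$gng_commission <- gng_commission
  out$gng_omission <- gng_omission
  out$dd_present_bias <- dd_present_bias
  out
}

#' Generate a complete synthetic study bundle
#'
#' Composes the generator stages end to end: traits, raw sensor streams,
#' cleaned streams (with the filter removal fractions), morning assessment
#' times with missing days, prior-24-hour daily features, and daily outcome
#' records. Bit-reproducible under a fixed config seed.
#'
#' @param config A [cohort_config].
#' @return A `study_bundle` list: `traits`, `streams_raw`, `streams`
#'   (cleaned), `filter_fractions`, `assessments`, `trait_features`,
#'   `daily_features`, `daily`, `provenance`.
#' @export
generate_bundle <- function(config = cohort_config()) {
  traits <- generate_traits(config)
  raw <- generate_streams(traits, config)
  fractions <- list()
  clean <- lapply(raw, function(streams) {
    lapply(streams, function(s) clean_stream(s)$stream)
  })
  for (sensor in c("battery", "screen")) {
    removed <- total <- 0
    for (pid in names(raw)) {
      n0 <- n_events(raw[[pid]][[sensor]])
      n1 <- n_events(clean[[pid]][[sensor]])
      removed <- removed + (n0 - n1); total <- total + n0
    }
    fractions[[sensor]] <- if (total) removed / total else 0
  }
  # morning assessments on days 1 .. n_days-1, with missing days dropped
  days <- seq_len(config$n_days - 1)
  assess <- do.call(rbind, lapply(seq_len(config$n_participants), function(p) {
    pid <- traits$participant_id[p]
    keep <- with_seed(derive_seed(config$seed, 501, p),
                      stats::runif(length(days)) >= config$ema_missing_rate)
    if (!any(keep)) keep[1] <- TRUE
    data.frame(
      participant_id = pid,
      morning_time = config$start +
        (days[keep] * 24 + config$morning_hour) * 3600
    )
  }))
  tf <- trait_features(clean)
  df_ <- daily_features(clean, assess)
  daily <- generate_daily_outcomes(traits, df_, config)
  structure(list(
    traits = traits, streams_raw = raw, streams = clean,
    filter_fractions = fractions, assessments = assess,
    trait_features = tf, daily_features = df_, daily = daily,
    provenance = list(seed = config$seed,
                      n_participants = config$n_participants,
                      n_days = config$n_days,
                      generated = "impulsense synthetic bundle")
  ), class = "study_bundle")
}

#' Write a study bundle to interchange files
#'
#' Emits one CSV per participant-sensor (raw streams, in the ingest
#' dialect), `traits.csv`, `daily.csv`, `assessments.csv`, and
#' `provenance.json`.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(bundle$streams_raw)) {
    for (sensor in SENSORS) {
      write_event_log(bundle$streams_raw[[pid]][[sensor]],
                      file.path(dir, sprintf("%s_%s.csv", pid, sensor)))
    }
  }
  utils::write.csv(bundle$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$daily, file.path(dir, "daily.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$assessments, file.path(dir, "assessments.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
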