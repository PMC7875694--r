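# Fixed timing of the mobile go/no-go trial sequence (milliseconds).
GNG_TIMING <- c(fixation = 250, blank = 250, response_window = 500, iti = 250)
GNG_SOAS <- c(100, 200, 300, 400, 500, 750)

#' Behavioural agent parameters
#'
#' Bundles the parameters that drive the simulated performer of the three
#' mobile tasks: a hyperbolic discount rate for delay discounting, go/no-go
#' error rates and response-latency distribution, and a mean intended pump
#' count for the balloon risk task.
#'
#' @param dd_k Hyperbolic discount rate (per delay unit, >= 0).
#' @param gng_commission_rate Probability of responding to a no-go target.
#' @param gng_omission_rate Probability of missing a go target.
#' @param gng_latency_mean,gng_latency_sd Latency distribution (ms) before
#'   truncation to the 500 ms response window.
#' @param bart_target_pumps Mean intended pumps per balloon.
#' @param dd_noise Logistic choice-noise temperature for delay discounting,
#'   in reward units; 0 gives a deterministic chooser.
#' @return An `agent_params` list.
#' @export
agent_params <- function(dd_k = 0.0065,
                         gng_commission_rate = 0.02,
                         gng_omission_rate = 0.02,
                         gng_latency_mean = 450,
                         gng_latency_sd = 70,
                         bart_target_pumps = 4.8,
                         dd_noise = 0) {
  stopifnot(dd_k >= 0,
            gng_commission_rate >= 0, gng_commission_rate <= 1,
            gng_omission_rate >= 0, gng_omission_rate <= 1,
            gng_latency_mean > 0, gng_latency_sd > 0,
            bart_target_pumps >= 0, dd_noise >= 0)
  structure(list(dd_k = dd_k,
                 gng_commission_rate = gng_commission_rate,
                 gng_omission_rate = gng_omission_rate,
                 gng_latency_mean = gng_latency_mean,
                 gng_latency_sd = gng_latency_sd,
                 bart_target_pumps = bart_target_pumps,
                 dd_noise = dd_noise),
            class = "agent_params")
}

#' Generate a mobile go/no-go session
#'
#' Each of the 75 default trials follows the fixed sequence: fixation cross
#' (250 ms), blank (250 ms), horizontal or vertical cue shown for one of six
#' stimulus-onset asynchronies (100-750 ms), then a go (green) or no-go
#' (blue) target until response or 500 ms, and a 250 ms intertrial interval.
#' Cues are drawn uniformly; the target is consistent with its cue
#' (horizontal signals go, vertical no-go) with probability 0.70.
#'
#' @param n_trials Number of trials (default 75).
#' @param seed RNG seed for reproducible sessions.
#' @param cue_validity Probability the target matches its cue (default 0.70).
#' @return Data frame with columns `cue`, `soa`, `target`, `cue_valid`, plus
#'   the fixed timing constants as attributes.
#' @export
generate_gng_session <- function(n_trials = 75, seed = NULL,
                                 cue_validity = 0.70) {
  stopifnot(n_trials >= 1)
  run <- function() {
    cue <- sample(c("horizontal", "vertical"), n_trials, replace = TRUE)
    soa <- sample(GNG_SOAS, n_trials, replace = TRUE)
    valid <- stats::runif(n_trials) < cue_validity
    signalled <- ifelse(cue == "horizontal", "go", "nogo")
    target <- ifelse(valid, signalled,
                     ifelse(signalled == "go", "nogo", "go"))
    out <- data.frame(cue = cue, soa = soa, target = target,
                      cue_valid = valid)
    attr(out, "timing") <- GNG_TIMING
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate an agent performing a go/no-go session
#'
#' The agent responds to go targets with probability `1 - omission_rate`,
#' with a latency drawn from a normal distribution truncated to the (0, 500]
#' ms response window, and erroneously responds to no-go targets with
#' probability `commission_rate`. Returns the conventional summary metrics:
#' mean latency over responded go trials, commission errors / no-go trials,
#' omission errors / go trials. Some task summaries label commission as
#' "go" errors and omission as "no-go" errors (the reverse of
#' convention); set `swap_labels = TRUE` to report under that labelling.
#'
#' @param trials Session data frame from [generate_gng_session()].
#' @param agent An [agent_params].
#' @param seed RNG seed.
#' @param swap_labels Swap the commission/omission labels in the output.
#' @return Named numeric: `latency` (ms, `NA` when no go trial was
#'   responded), `commission`, `omission`.
#' @export
simulate_gng <- function(trials, agent, seed = NULL, swap_labels = FALSE) {
  run <- function() {
    go <- trials$target == "go"
    n_go <- sum(go); n_nogo <- sum(!go)
    respond_go <- stats::runif(n_go) >= agent$gng_omission_rate
    respond_nogo <- stats::runif(n_nogo) < agent$gng_commission_rate
    lat <- if (any(respond_go)) {
      x <- stats::rnorm(sum(respond_go), agent$gng_latency_mean,
                        agent$gng_latency_sd)
      # resample outside the (0, 500] window: truncated normal latencies
      bad <- x <= 0 | x > GNG_TIMING[["response_window"]]
      while (any(bad)) {
        x[bad] <- stats::rnorm(sum(bad), agent$gng_latency_mean,
                               agent$gng_latency_sd)
        bad <- x <= 0 | x > GNG_TIMING[["response_window"]]
      }
      mean(x)
    } else NA_real_
    commission <- if (n_nogo) mean(respond_nogo) else NA_real_
    omission <- if (n_go) mean(!respond_go) else NA_real_
    if (swap_labels) {
      c(latency = lat, commission = omission, omission = commission)
    } else {
      c(latency = lat, commission = commission, omission = omission)
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Adaptive delay-discounting staircase
#'
#' Five choices between an immediate amount and a larger fixed delayed
#' reward, following the adjusting-amount procedure: the immediate offer
#' starts at half the delayed amount and moves away from the last choice
#' with step sizes halving each trial (delayed/4, /8, /16, /32). The agent
#' values the delayed reward hyperbolically, `delayed / (1 + k * delay)`,
#' and chooses the immediate offer when it exceeds that value; with
#' `dd_noise > 0` the choice is a logistic draw on the value difference.
#' Present bias is the fraction of immediate choices; the indifference
#' estimate is the final offer nudged by half a final step in the direction
#' of the last adjustment.
#'
#' @param agent An [agent_params] (uses `dd_k`, `dd_noise`).
#' @param delayed_amount Fixed delayed reward (> 0).
#' @param delay Delay in the same units as `1 / dd_k` (> 0).
#' @param n_trials Number of staircase choices (default 5).
#' @param seed RNG seed (only consulted when `dd_noise > 0`).
#' @return List: `choices` (character), `offers`, `present_bias`,
#'   `indifference`.
#' @export
run_mdd <- function(agent, delayed_amount = 20, delay = 30, n_trials = 5,
                    seed = NULL) {
  if (delayed_amount <= 0 || delay <= 0) stop("amounts and delay must be positive")
  run <- function() {
    pv <- delayed_amount / (1 + agent$dd_k * delay)
    offer <- delayed_amount / 2
    step <- delayed_amount / 4
    offers <- numeric(n_trials)
    choices <- character(n_trials)
    dir <- 0
    for (t in seq_len(n_trials)) {
      offers[t] <- offer
      imm <- if (agent$dd_noise > 0) {
        stats::runif(1) < stats::plogis((offer - pv) / agent$dd_noise)
      } else {
        offer > pv
      }
      choices[t] <- if (imm) "immediate" else "delayed"
      dir <- if (imm) -1 else +1
      offer <- offer + dir * step
      step <- step / 2
    }
    list(choices = choices, offers = offers,
         present_bias = mean(choices == "immediate"),
         indifference = offers[n_trials] + dir * 2 * step)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a balloon risk-task session
#'
#' Fifteen balloons by default; each hides an explosion point uniform on
#' `{1, ..., max_pumps}`. The agent intends a noisy number of pumps around
#' its target and pumps until that intention or the explosion, whichever
#' comes first. Gains accrue per successful pump and are lost when the
#' balloon pops. Returns the mean pumps delivered (risk-taking) and the
#' mean per-trial gains.
#'
#' @param agent An [agent_params] (uses `bart_target_pumps`).
#' @param n_trials Number of balloons (default 15).
#' @param max_pumps Pump capacity (default 10).
#' @param pay_per_pump Reward per successful pump (default 4.13).
#' @param target_sd SD of the per-trial intended pump count (default 1).
#' @param seed RNG seed.
#' @return Named numeric: `pumps` (mean), `gains` (mean per trial).
#' @export
simulate_bart <- function(agent, n_trials = 15, max_pumps = 10,
                          pay_per_pump = 4.13, target_sd = 1, seed = NULL) {
  stopifnot(max_pumps >= 1)
  run <- function() {
    intended <- clamp(round(stats::rnorm(n_trials, agent$bart_target_pumps,
                                         target_sd)), 0, max_pumps)
    explosion <- sample.int(max_pumps, n_trials, replace = TRUE)
    popped <- explosion <= intended
    pumps <- ifelse(popped, explosion, intended)
    gains <- ifelse(popped, 0, pay_per_pump * intended)
    c(pumps = mean(pumps), gains = mean(gains))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
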