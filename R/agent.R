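#' Attractor-model parameters for the synthetic participant
#'
#' The synthetic participant is a two-population rate reduction of a
#' winner-take-all attractor network: each population excites itself,
#' inhibits the other, receives a value-scaled input plus background noise,
#' and the first population to reach threshold determines the choice.
#' Between trials the residual activity decays exponentially with time
#' constant `tau_decay`, which is what produces choice repetition at short
#' inter-trial intervals. tDCS enters twice: `polarization` adds a constant
#' offset to both populations' drive (anodal > 0, cathodal < 0, sham 0) and
#' additionally scales the decay time constant by `1 + c_decay *
#' polarization`, so depolarization slows the decay of residual activity.
#'
#' The defaults are the committed `"default-2021"` parameter set used by the
#' simulation study in this package.
#'
#' @param leak activity leak rate, 1/s.
#' @param w_self self-excitation gain (dimensionless).
#' @param w_inh mutual-inhibition gain (dimensionless).
#' @param noise_sd background-noise SD, activity units per sqrt(s).
#' @param threshold decision threshold, activity units.
#' @param dt integration time step, s.
#' @param t0 non-decision time added to the threshold-crossing time, ms.
#' @param tau_decay inter-trial residual-activity decay time constant, ms.
#' @param polarization membrane-polarization offset, activity units/s
#'   (0 = sham; the anodal magnitude used by [simulate_session] is
#'   `abs(polarization)` of the parameter set it is given).
#' @param c_decay coupling of polarization into the decay time constant
#'   (per unit polarization); either tDCS pathway can be zeroed.
#' @param k_discount hyperbolic distance-discounting rate, 1/field.
#' @param value_gain input current per unit subjective value.
#' @param max_time decision timeout, s (timeouts are resolved toward the
#'   currently larger activity and flagged).
#' @return object of class `agent_params` (validated named list).
#' @examples
#' p <- agent_params()
#' p$tau_decay
#' @export
agent_params <- function(leak = 4, w_self = 6, w_inh = 8, noise_sd = 0.5,
                         threshold = 1, dt = 0.001, t0 = 400,
                         tau_decay = 150, polarization = 0, c_decay = 2,
                         k_discount = 0.2, value_gain = 0.09,
                         max_time = 3) {
  p <- list(leak = leak, w_self = w_self, w_inh = w_inh, noise_sd = noise_sd,
            threshold = threshold, dt = dt, t0 = t0, tau_decay = tau_decay,
            polarization = polarization, c_decay = c_decay,
            k_discount = k_discount, value_gain = value_gain,
            max_time = max_time)
  check_arg(all(vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                         is.finite(x), logical(1))),
            "all agent parameters must be single finite numbers")
  pos <- c("leak", "noise_sd", "threshold", "dt", "tau_decay", "value_gain",
           "max_time")
  check_arg(all(unlist(p[pos]) > 0),
            paste("parameters", paste(pos, collapse = ", "), "must be > 0"))
  check_arg(p$t0 >= 0, "t0 must be >= 0")
  check_arg(p$k_discount >= 0, "k_discount must be >= 0")
  structure(p, class = "agent_params")
}

#' Hyperbolically discounted subjective value
#'
#' Subjective value of a coin worth `value` credits at walking distance
#' `total_distance` fields: `value / (1 + k * total_distance)`. Distance is a
#' time proxy in the coin game, and hyperbolic discounting is the standard
#' form for such delay costs; the rate `k` is per field.
#'
#' @param value coin value in credits (> 0); vectorised.
#' @param total_distance walking distance in fields (>= 1).
#' @param k_discount discounting rate, 1/field (>= 0).
#' @examples
#' subjective_value(80, 4, 0.25)  # 40
#' @export
subjective_value <- function(value, total_distance, k_discount) {
  check_arg(all(value > 0), "value must be positive")
  check_arg(all(total_distance >= 1), "total_distance must be >= 1")
  check_arg(all(k_discount >= 0), "k_discount must be >= 0")
  value / (1 + k_discount * total_distance)
}

#' Analytic indifference ratio of a hyperbolic discounter
#'
#' The SN/LF value ratio at which the subjective values of the two coins are
#' equal: `(1 + k * sn_distance) / (1 + k * (sn_distance + extra_distance))`.
#' Used as ground truth when validating indifference-point recovery.
#'
#' @inheritParams subjective_value
#' @param sn_distance,extra_distance distances in fields.
#' @export
indifference_ratio <- function(sn_distance, extra_distance, k_discount) {
  (1 + k_discount * sn_distance) / (1 + k_discount * (sn_distance + extra_distance))
}

#' Resting agent state
#'
#' @return list with activities `x_sn`, `x_lf` (both 0) and `last_choice`
#'   (`NULL`).
#' @export
agent_rest_state <- function() {
  list(x_sn = 0, x_lf = 0, last_choice = NULL)
}

#' Decay residual activity over an inter-trial interval
#'
#' Residual population activity decays exponentially toward rest during the
#' interval. The effective time constant is `tau_decay * (1 + c_decay *
#' polarization)`: depolarization (anodal, polarization > 0) slows the
#' decay, hyperpolarization speeds it up.
#'
#' @param state agent state as returned by [agent_rest_state] or
#'   [simulate_decision].
#' @param iti interval in ms (>= 0).
#' @param params an [agent_params] object.
#' @export
apply_iti_decay <- function(state, iti, params) {
  if (!is.numeric(iti) || length(iti) != 1 || !is.finite(iti) || iti < 0) {
    stop_choicerep("argument_error", "iti must be a single number >= 0")
  }
  f <- exp(-iti / effective_tau(params))
  state$x_sn <- state$x_sn * f
  state$x_lf <- state$x_lf * f
  state
}

effective_tau <- function(params) {
  tau <- params$tau_decay * (1 + params$c_decay * params$polarization)
  max(tau, 1e-9)
}

# input currents for one trial (value drive + polarization offset)
trial_inputs <- function(sn_value, lf_value, sn_distance, extra_distance,
                         params) {
  v_sn <- subjective_value(sn_value, sn_distance, params$k_discount)
  v_lf <- subjective_value(lf_value, sn_distance + extra_distance,
                           params$k_discount)
  list(I_sn = params$value_gain * v_sn + params$polarization,
       I_lf = params$value_gain * v_lf + params$polarization)
}

#' Simulate a single decision
#'
#' Integrates the two-population attractor dynamics for one trial, starting
#' from the supplied state, until one population's rectified activity
#' crosses threshold. The decision time is the crossing time plus the
#' non-decision time `t0`. Ties within one step are broken by the larger
#' activity, then by a coin flip; a timeout at `max_time` is resolved toward
#' the currently larger activity and flagged.
#'
#' @param trial one trial-specification row (needs `sn_value`, `lf_value`,
#'   `sn_distance`, `extra_distance`).
#' @param state agent state carried over from the previous trial (after
#'   [apply_iti_decay]); use [agent_rest_state] at block starts.
#' @param params an [agent_params] object.
#' @param rng_seed optional integer seed.
#' @return list with `choice` (`"SN"`/`"LF"`), `dt_ms`, `state` (the
#'   post-decision activities, for carry-over) and `timeout`.
#' @export
simulate_decision <- function(trial, state, params, rng_seed = NULL) {
  stopifnot(inherits(params, "agent_params"))
  check_arg(is.finite(state$x_sn) && is.finite(state$x_lf),
            "state activities must be finite")
  maybe_seed(rng_seed)
  inp <- trial_inputs(trial$sn_value[1], trial$lf_value[1],
                      trial$sn_distance[1], trial$extra_distance[1], params)
  res <- decide_cpp(inp$I_sn, inp$I_lf, state$x_sn, state$x_lf,
                    params$leak, params$w_self, params$w_inh,
                    params$noise_sd, params$threshold, params$dt,
                    as.integer(ceiling(params$max_time / params$dt)))
  choice <- if (res[["choice"]] == 1) "LF" else "SN"
  list(choice = choice,
       dt_ms = res[["steps"]] * params$dt * 1000 + params$t0,
       state = list(x_sn = res[["x_sn"]], x_lf = res[["x_lf"]],
                    last_choice = choice),
       timeout = res[["timeout"]] == 1)
}

# polarization offset for a stimulation condition, given the anodal magnitude
stim_polarization <- function(stim, magnitude) {
  switch(stim, sham = 0, anodal = abs(magnitude), cathodal = -abs(magnitude),
         stop_choicerep("argument_error", paste("unknown stimulation:", stim)))
}

# simulate one block of trials; schedule rows must be in play order
simulate_block <- function(schedule, params, stim) {
  pol <- stim_polarization(stim, params$polarization)
  p <- params
  p$polarization <- pol
  inp <- trial_inputs(schedule$sn_value, schedule$lf_value,
                      schedule$sn_distance, schedule$extra_distance, p)
  res <- simulate_block_cpp(inp$I_sn, inp$I_lf, schedule$iti_before_ms,
                            effective_tau(p), p$leak, p$w_self, p$w_inh,
                            p$noise_sd, p$threshold, p$dt,
                            as.integer(ceiling(p$max_time / p$dt)))
  out <- schedule
  out$choice <- ifelse(res$choice == 1L, "LF", "SN")
  out$dt_ms <- res$steps * p$dt * 1000 + p$t0
  out$timeout <- res$timeout == 1L
  out$x_sn_pre <- res$x_sn_pre
  out$x_lf_pre <- res$x_lf_pre
  out
}

#' Simulate one experimental session
#'
#' Plays a trial schedule under a session plan: the agent state is reset to
#' rest at every block start, decays over each inter-trial interval within a
#' block, and the polarization offset is set per block from the plan's
#' stimulation condition (sham = 0, anodal = +, cathodal = -, with magnitude
#' `params$polarization`).
#'
#' @param plan rows of a [make_session_plans] data frame for one
#'   participant-session.
#' @param schedule trial specifications for that session with a `block`
#'   column matching the plan.
#' @param params an [agent_params] object; `params$polarization` is the
#'   anodal magnitude.
#' @param rng_seed optional integer seed.
#' @param keep_state if `TRUE`, retain the pre-trial activities
#'   (`x_sn_pre`, `x_lf_pre`) in the output for instrumentation.
#' @return data frame of choice records: the schedule plus `participant_id`,
#'   `session`, `stim`, `sham_order`, `choice`, `dt_ms`, `timeout`.
#' @export
simulate_session <- function(plan, schedule, params, rng_seed = NULL,
                             keep_state = FALSE) {
  stopifnot(inherits(params, "agent_params"))
  maybe_seed(rng_seed)
  if (!all(schedule$block %in% plan$block)) {
    stop_choicerep("argument_error", "schedule blocks not covered by the session plan")
  }
  if (length(unique(plan$participant_id)) != 1 ||
      length(unique(plan$session)) != 1) {
    stop_choicerep("argument_error", "plan must cover exactly one participant-session")
  }
  out <- lapply(unique(schedule$block), function(b) {
    stim <- plan$stim[plan$block == b]
    rec <- simulate_block(schedule[schedule$block == b, , drop = FALSE],
                          params, stim)
    rec$stim <- stim
    rec
  })
  out <- do.call(rbind, out)
  out$participant_id <- plan$participant_id[1]
  out$session <- plan$session[1]
  out$sham_order <- plan$sham_order[1]
  if (!keep_state) {
    out$x_sn_pre <- NULL
    out$x_lf_pre <- NULL
  }
  rownames(out) <- NULL
  out
}

# lognormal draw parameterised by mean and SD (moment matched); sd = 0
# degenerates to the mean
draw_lognormal <- function(n, mean, sd) {
  check_arg(mean > 0 && sd >= 0, "population mean must be > 0 and SD >= 0")
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Default cohort-level design configuration
#'
#' @param n_measurement_trials trials in the measurement block.
#' @param n_triplets_per_block triplets per experimental block.
#' @param n_blocks experimental blocks per session.
#' @param lf_range LF coin value range in credits.
#' @param ratio_range SN/LF ratio range in the measurement block.
#' @export
design_config <- function(n_measurement_trials = 150L,
                          n_triplets_per_block = 40L, n_blocks = 4L,
                          lf_range = c(65L, 85L),
                          ratio_range = c(0.20, 0.95)) {
  list(n_measurement_trials = as.integer(n_measurement_trials),
       n_triplets_per_block = as.integer(n_triplets_per_block),
       n_blocks = as.integer(n_blocks),
       lf_range = lf_range, ratio_range = ratio_range)
}

#' Default population distribution of agent parameters
#'
#' Per-participant discounting rates and decay time constants are drawn from
#' lognormal distributions (moment-matched to the given mean/SD) to emulate
#' the considerable between-participant variability seen in this paradigm.
#' The discounting spread is wide enough that a realistic fraction of
#' simulated players fails the eligibility screen after the measurement
#' block, mirroring the roughly 30% exclusion rate of the human study.
#'
#' @param k_discount `c(mean, sd)` of the discounting rate, 1/field.
#' @param tau_decay `c(mean, sd)` of the decay time constant, ms.
#' @export
population_spec <- function(k_discount = c(mean = 0.30, sd = 0.55),
                            tau_decay = c(mean = 150, sd = 50)) {
  list(k_discount = unname(k_discount), tau_decay = unname(tau_decay))
}

#' Simulate a full cohort through the two-session protocol
#'
#' For each simulated participant: draw individual parameters from the
#' population, play the measurement block of each session, estimate the
#' indifference-point profile, screen eligibility, and (if eligible) build
#' and play the four experimental blocks per the counterbalanced session
#' plan. Participants whose discounting fails the eligibility screen in
#' either session are excluded and reported, as in the human protocol.
#'
#' @param n_participants number of recruited (not final) participants.
#' @param design a [design_config] list.
#' @param params base [agent_params]; `polarization` is the anodal
#'   magnitude applied in real-stimulation blocks.
#' @param population a [population_spec] list; SDs of 0 give an homogeneous
#'   cohort.
#' @param rng_seed master seed; per-participant substreams are derived from
#'   it, so cohorts are reproducible and extendable.
#' @return object of class `cohort_sim`: list with `records` (choice records
#'   of eligible participants), `excluded` (data frame of exclusions),
#'   `participants` (drawn parameters per participant) and `profiles`
#'   (per participant-session indifference profiles).
#' @export
simulate_cohort <- function(n_participants, design = design_config(),
                            params = agent_params(),
                            population = population_spec(),
                            rng_seed = NULL) {
  check_arg(n_participants >= 1, "n_participants must be >= 1")
  stopifnot(inherits(params, "agent_params"))
  maybe_seed(rng_seed)

  plans <- suppressWarnings(make_session_plans(n_participants))
  seeds <- draw_substream_seeds(n_participants)
  k_i <- draw_lognormal(n_participants, population$k_discount[1],
                        population$k_discount[2])
  tau_i <- draw_lognormal(n_participants, population$tau_decay[1],
                          population$tau_decay[2])

  records <- vector("list", n_participants)
  profiles <- list()
  excluded <- data.frame(participant_id = integer(), session = integer(),
                         reason = character(), stringsAsFactors = FALSE)

  for (p in seq_len(n_participants)) {
    set.seed(seeds[p])
    params_p <- params
    params_p$k_discount <- k_i[p]
    params_p$tau_decay <- tau_i[p]

    p_records <- list()
    eligible <- TRUE
    for (session in 1:2) {
      plan <- plans[plans$participant_id == p & plans$session == session, ]
      meas <- make_measurement_trials(design$n_measurement_trials,
                                      lf_range = design$lf_range,
                                      ratio_range = design$ratio_range)
      meas$block <- 1L
      meas_rec <- simulate_session(plan[plan$block == 1L, ], meas, params_p)
      profile <- estimate_indifference_profile(meas_rec)
      profiles[[sprintf("p%d_s%d", p, session)]] <- profile
      if (!check_eligibility(profile)$eligible) {
        excluded <- rbind(excluded, data.frame(
          participant_id = p, session = session,
          reason = "ineligible discounting", stringsAsFactors = FALSE))
        eligible <- FALSE
        break
      }
      sched <- make_triplet_blocks(profile, design$n_triplets_per_block,
                                   design$n_blocks,
                                   lf_range = design$lf_range)
      sched$block <- sched$block + 1L  # experimental blocks are 2..5
      exp_rec <- simulate_session(plan[plan$block > 1L, ], sched, params_p)
      p_records[[session]] <- rbind(fill_columns(meas_rec, exp_rec), exp_rec)
    }
    if (eligible) records[[p]] <- do.call(rbind, p_records)
  }

  records <- do.call(rbind, records)
  if (is.null(records) || nrow(records) == 0) {
    stop_choicerep("cohort_error", "all simulated participants were ineligible")
  }
  rownames(records) <- NULL
  structure(
    list(records = records, excluded = excluded,
         participants = data.frame(participant_id = seq_len(n_participants),
                                   k_discount = k_i, tau_decay = tau_i,
                                   seed = seeds,
                                   eligible = !(seq_len(n_participants) %in%
                                                  excluded$participant_id)),
         profiles = profiles),
    class = "cohort_sim"
  )
}

# align measurement-record columns with the experimental schema
fill_columns <- function(x, template) {
  for (cn in setdiff(names(template), names(x))) x[[cn]] <- NA
  x[, names(template)]
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("simulated cohort: %d eligible of %d recruited (%d excluded), %d choice records\n",
              sum(x$participants$eligible), nrow(x$participants),
              nrow(x$excluded), nrow(x$records)))
  invisible(x)
}
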