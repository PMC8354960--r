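# shared fixtures, all built in code

# analytic indifference profile of a hyperbolic discounter, averaged over
# the two SN distances used by the design
analytic_profile <- function(k) {
  indifference_profile(
    (indifference_ratio(2, 1:12, k) + indifference_ratio(3, 1:12, k)) / 2
  )
}

# one participant-session plan (scenario 1)
plan_for <- function(blocks = 1:5, session = 1L) {
  plans <- make_session_plans(4)
  plans[plans$participant_id == 1 & plans$session == session &
          plans$block %in% blocks, ]
}

# hand-built toy triplet log: 4 triplets, second-bias choices ok/ok/fail/ok
# (triplet 3 has an unsuccessful second bias trial)
toy_triplet_log <- function() {
  tri <- function(id, type, bias1, bias2, target, dts = c(700, 700, 700)) {
    good <- if (type == "bias_SN") "SN" else "LF"
    data.frame(
      participant_id = 1L, session = 1L, block = 2L,
      trial_index = (id - 1L) * 3L + 1:3,
      triplet_id = sprintf("b2_t%03d", id),
      role = c(type, type, "target"),
      stim = "sham", sham_order = "sham_first",
      sn_value = 40L, lf_value = 80L, sn_distance = 2L, extra_distance = 4L,
      iti_before_ms = c(if (id == 1) NA_real_ else 500, 1500, 500),
      choice = c(bias1, bias2, target),
      dt_ms = dts, timeout = FALSE,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    tri(1, "bias_LF", "LF", "LF", "LF"),
    tri(2, "bias_SN", "SN", "SN", "SN"),
    tri(3, "bias_LF", "LF", "SN", "LF"),   # bias2 failed
    tri(4, "bias_SN", "SN", "SN", "LF")
  )
}

# simulate one experimental block for one synthetic participant and return
# the full records (experimental block 2, chosen stimulation)
sim_block_records <- function(params, n_triplets, stim = "sham",
                              profile = analytic_profile(params$k_discount),
                              seed = NULL, target_iti = NULL,
                              participant_id = 1L) {
  if (!is.null(seed)) set.seed(seed)
  sched <- make_triplet_blocks(profile, n_triplets, 1)
  sched$block <- 2L
  if (!is.null(target_iti)) {
    sched$iti_before_ms[sched$role == "target"] <- target_iti
  }
  plan <- plan_for(blocks = 2L)
  plan$stim <- stim
  rec <- simulate_session(plan, sched, params)
  rec$participant_id <- participant_id
  rec
}

# repetition index of a simulated block
ri_of <- function(records) {
  f <- filter_bias_success(records)
  repetition_summary(f$targets)$repetition_index
}

# small but analysis-complete cohort for pipeline tests (cached per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(
        12, design = design_config(n_measurement_trials = 120,
                                   n_triplets_per_block = 20),
        rng_seed = 20210402)
    }
    cache
  }
})
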