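test_that("subjective value is hyperbolic in distance", {
  expect_equal(subjective_value(80, 7, 0), 80)
  expect_equal(subjective_value(80, 1, 0), 80)
  expect_equal(subjective_value(80, 4, 0.25), 40)
  expect_equal(indifference_ratio(2, 8, 0.2), 1.4 / 3)
  expect_error(subjective_value(0, 4, 0.2), class = "choicerep_argument_error")
  expect_error(subjective_value(-5, 4, 0.2), class = "choicerep_argument_error")
})

test_that("agent parameters are validated", {
  expect_s3_class(agent_params(), "agent_params")
  expect_error(agent_params(leak = -1), class = "choicerep_argument_error")
  expect_error(agent_params(tau_decay = 0), class = "choicerep_argument_error")
  expect_error(agent_params(t0 = -10), class = "choicerep_argument_error")
})

test_that("residual activity decays exponentially over the ITI", {
  p <- agent_params(tau_decay = 800)
  st <- list(x_sn = 1.0, x_lf = -0.3, last_choice = "SN")

  expect_identical(apply_iti_decay(st, 0, p), st)

  dec <- apply_iti_decay(st, 500, p)
  expect_equal(dec$x_sn, 0.5353, tolerance = 1e-4)  # exp(-500/800)
  expect_equal(dec$x_lf, -0.3 * exp(-500 / 800))

  long <- apply_iti_decay(st, 10 * 800, p)
  expect_lte(abs(long$x_sn), 5e-5)

  # depolarization slows the decay, hyperpolarization speeds it up
  p_an <- agent_params(tau_decay = 800, polarization = 0.15, c_decay = 2)
  p_ca <- agent_params(tau_decay = 800, polarization = -0.15, c_decay = 2)
  expect_equal(apply_iti_decay(st, 500, p_an)$x_sn, exp(-500 / (800 * 1.3)))
  expect_gt(apply_iti_decay(st, 500, p_an)$x_sn, dec$x_sn)
  expect_lt(apply_iti_decay(st, 500, p_ca)$x_sn, dec$x_sn)

  expect_error(apply_iti_decay(st, -1, p), class = "choicerep_argument_error")
})

test_that("a symmetric noiseless decision is settled by the rng tie-break", {
  p <- agent_params(noise_sd = 1e-12)
  tr <- list(sn_value = 40, lf_value = 80, sn_distance = 2, extra_distance = 8)
  # equalize inputs exactly: sn at the analytic indifference ratio
  tr$sn_value <- indifference_ratio(2, 8, p$k_discount) * 80
  choices <- vapply(1:200, function(s) {
    simulate_decision(tr, agent_rest_state(), p, rng_seed = s)$choice
  }, character(1))
  frac_lf <- mean(choices == "LF")
  expect_gt(frac_lf, 0.35)
  expect_lt(frac_lf, 0.65)
})

test_that("a residual head start forces and speeds the repeated choice", {
  p <- agent_params(noise_sd = 1e-12)
  tr <- list(sn_value = 40, lf_value = 80, sn_distance = 2, extra_distance = 8)
  tr$sn_value <- indifference_ratio(2, 8, p$k_discount) * 80

  head_start <- list(x_sn = 0, x_lf = 0.4 * p$threshold, last_choice = "LF")
  res <- simulate_decision(tr, head_start, p, rng_seed = 1)
  expect_equal(res$choice, "LF")

  res_rest <- simulate_decision(tr, agent_rest_state(), p, rng_seed = 1)
  expect_lt(res$dt_ms, res_rest$dt_ms)
  expect_gte(res$dt_ms, p$t0)
})

test_that("choice rate at the analytic indifference ratio is 50%", {
  p <- agent_params()
  tr <- list(sn_value = indifference_ratio(2, 8, p$k_discount) * 75,
             lf_value = 75, sn_distance = 2, extra_distance = 8)
  set.seed(123)
  lf <- replicate(10000, simulate_decision(tr, agent_rest_state(), p)$choice == "LF")
  expect_equal(mean(lf), 0.50, tolerance = 0.02)
})

test_that("repetition probability falls with the inter-trial interval", {
  # frozen Monte-Carlo fixtures: forced prior LF state, default params
  p <- agent_params()
  rs <- indifference_ratio(2, 8, p$k_discount)
  tr <- list(sn_value = rs * 75, lf_value = 75, sn_distance = 2,
             extra_distance = 8)
  prior <- list(x_sn = -0.8, x_lf = 1.0, last_choice = "LF")
  p_rep <- function(iti, seed, n = 10000) {
    set.seed(seed)
    mean(replicate(n, {
      st <- apply_iti_decay(prior, iti, p)
      simulate_decision(tr, st, p)$choice == "LF"
    }))
  }
  p500 <- p_rep(500, 101)
  p1500 <- p_rep(1500, 102)
  expect_gt(p500, p1500)
  expect_equal(p500, 0.6301, tolerance = 0.04)
  expect_equal(p1500, 0.5031, tolerance = 0.04)
})

test_that("sessions carry residual state within blocks and reset at block starts", {
  p <- agent_params()
  prof <- analytic_profile(p$k_discount)
  set.seed(5)
  sched <- make_triplet_blocks(prof, 12, 2)
  sched$block <- sched$block + 1L
  plan <- plan_for(blocks = 2:3)
  rec <- simulate_session(plan, sched, p, rng_seed = 6, keep_state = TRUE)

  first_rows <- rec$trial_index == 1
  expect_true(all(rec$x_sn_pre[first_rows] == 0))
  expect_true(all(rec$x_lf_pre[first_rows] == 0))
  expect_true(any(rec$x_lf_pre[!first_rows] != 0))
  expect_true(all(rec$dt_ms >= p$t0))
  expect_setequal(unique(rec$stim), plan$stim[plan$block %in% 2:3])

  expect_error(simulate_session(plan, transform(sched, block = 9L), p),
               class = "choicerep_argument_error")
})

test_that("hysteresis vanishes with instant decay and shows under defaults", {
  p0 <- agent_params(tau_decay = 1e-3)
  rec0 <- sim_block_records(p0, 5000, seed = 77)
  expect_lt(abs(ri_of(rec0)), 3)

  p <- agent_params()
  rec <- sim_block_records(p, 5000, seed = 78)
  expect_gt(ri_of(rec), 5)
})

test_that("cohorts are reproducible, heterogeneous and screened", {
  # degenerate population: zero SDs give identical drawn parameters
  set.seed(1)
  coh0 <- simulate_cohort(4, design = design_config(n_measurement_trials = 120,
                                                    n_triplets_per_block = 4),
                          population = population_spec(k_discount = c(0.2, 0),
                                                       tau_decay = c(150, 0)))
  expect_equal(unique(coh0$participants$k_discount), 0.2)
  expect_equal(unique(coh0$participants$tau_decay), 150)

  # shallow discounting pushes r* toward 1: SN bias infeasible, all excluded
  expect_error(
    simulate_cohort(6, design = design_config(n_measurement_trials = 120),
                    population = population_spec(k_discount = c(0.02, 0)),
                    rng_seed = 7),
    class = "choicerep_cohort_error")

  # determinism: identical master seed, byte-identical choice-log CSV
  cfg <- design_config(n_measurement_trials = 120, n_triplets_per_block = 6)
  md5_of <- function() {
    coh <- simulate_cohort(4, design = cfg, rng_seed = 99)
    f <- tempfile(fileext = ".csv")
    write_choice_log(coh$records, f)
    on.exit(unlink(f))
    unname(tools::md5sum(f))
  }
  expect_identical(md5_of(), md5_of())
})

test_that("a default cohort passes the full preregistered analysis", {
  coh <- small_cohort()
  expect_gt(sum(coh$participants$eligible), 3)
  rep <- preregistered_report(coh$records)
  expect_s3_class(rep, "prereg_report")
  expect_named(rep$hypotheses,
               c("H1.1", "H1.2", "H2.1", "H2.1.1", "H2.1.2",
                 "H2.2", "H2.2.1", "H2.2.2"))
  # bias success strictly between 50 and 100
  expect_true(all(rep$success_rates$success_rate > 50 &
                    rep$success_rates$success_rate < 100))
})
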