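test_that("measurement trials respect the design ranges and constant ITI", {
  m <- make_measurement_trials(1000, rng_seed = 1)
  expect_equal(nrow(m), 1000)
  expect_true(all(m$role == "measurement"))
  expect_true(all(m$iti_before_ms[-1] == 500))
  expect_true(is.na(m$iti_before_ms[1]))
  expect_true(all(m$sn_distance %in% c(2, 3)))
  expect_true(all(m$extra_distance %in% c(1, 4, 8, 12)))
  expect_true(all(m$lf_value >= 65 & m$lf_value <= 85))
  expect_true(all(m$sn_value >= 1 & m$sn_value < m$lf_value))

  expect_error(make_measurement_trials(0), class = "choicerep_argument_error")
  expect_error(make_measurement_trials(10, rng_seed = "x"),
               class = "choicerep_argument_error")
})

test_that("measurement ratios and distance frequencies match their distributions", {
  n <- 10000
  m <- make_measurement_trials(n, rng_seed = 7)
  # the drawn ratio is uniform on [0.20, 0.95]; rounding to whole credits
  # moves the logged ratio by at most 0.5/65
  slack <- 0.5 / 65
  expect_gte(min(m$ratio), 0.20 - slack)
  expect_lte(max(m$ratio), 0.95 + slack)
  # each extra distance within 3 binomial SEs of 1/4
  se3 <- 3 * sqrt(0.25 * 0.75 / n)
  for (d in c(1, 4, 8, 12)) {
    expect_lt(abs(mean(m$extra_distance == d) - 0.25), se3)
  }
})

test_that("triplet blocks implement the bias shift, roles and ITI schedule", {
  prof <- indifference_profile(rep(0.5, 12))
  sched <- make_triplet_blocks(prof, 30, 2, rng_seed = 3)
  expect_equal(nrow(sched), 30 * 3 * 2)

  # roles come in bias, bias, target order with a shared bias type
  expect_equal(nrow(sched) %% 3, 0)
  r1 <- sched$role[seq(1, nrow(sched), 3)]
  r2 <- sched$role[seq(2, nrow(sched), 3)]
  r3 <- sched$role[seq(3, nrow(sched), 3)]
  expect_true(all(r1 %in% c("bias_SN", "bias_LF")))
  expect_identical(r1, r2)
  expect_true(all(r3 == "target"))

  # flat r* = 0.5: every SN-bias ratio 0.80, every LF-bias ratio 0.20,
  # targets at 0.5 (up to credit rounding)
  tol <- 0.5 / 65
  expect_true(all(abs(sched$ratio[sched$role == "bias_SN"] - 0.8) <= tol))
  expect_true(all(abs(sched$ratio[sched$role == "bias_LF"] - 0.2) <= tol))
  expect_true(all(abs(sched$ratio[sched$role == "target"] - 0.5) <= tol))
  expect_true(all(sched$ratio > 0 & sched$ratio < 1))

  # ITI before every target is short; the other two ITIs are {500, 1500}
  expect_true(all(sched$iti_before_ms[sched$role == "target"] == 500))
  iti12 <- matrix(sched$iti_before_ms[sched$role != "target"], nrow = 2)
  # drop triplets clipped by the block-initial NA
  full <- colSums(is.na(iti12)) == 0
  expect_true(all(apply(iti12[, full, drop = FALSE], 2, sort) ==
                    c(500, 1500)))

  expect_error(make_triplet_blocks(indifference_profile(rep(0.95, 12)), 5, 1),
               class = "choicerep_eligibility_error")
})

test_that("session plans counterbalance polarity, order and scenarios", {
  expect_warning(make_session_plans(6), "multiple of 4")
  plans6 <- suppressWarnings(make_session_plans(6))
  counts <- table(unique(plans6[, c("participant_id", "scenario")])$scenario)
  expect_equal(sort(as.integer(counts), decreasing = TRUE), c(2, 2, 1, 1))

  plans <- make_session_plans(52)
  per_p <- unique(plans[, c("participant_id", "scenario")])
  expect_equal(as.integer(table(per_p$scenario)), rep(13, 4))

  exp_blocks <- plans[plans$block_type == "experimental", ]
  for (p in unique(plans$participant_id)) {
    s1 <- exp_blocks[exp_blocks$participant_id == p & exp_blocks$session == 1, ]
    s2 <- exp_blocks[exp_blocks$participant_id == p & exp_blocks$session == 2, ]
    real1 <- setdiff(unique(s1$stim), "sham")
    real2 <- setdiff(unique(s2$stim), "sham")
    # one session anodal, the other cathodal
    expect_setequal(c(real1, real2), c("anodal", "cathodal"))
    # sham/real order flips across sessions
    expect_false(s1$sham_order[1] == s2$sham_order[1])
    # real blocks contiguous: 2-3 or 4-5
    real_pos <- s1$block[s1$stim != "sham"]
    expect_true(identical(real_pos, c(2L, 3L)) ||
                  identical(real_pos, c(4L, 5L)))
    # within a session: 2 real and 2 sham experimental blocks
    expect_equal(sum(s1$stim == "sham"), 2)
  }
  # half the cohort gets anodal in session 1
  s1_real <- exp_blocks[exp_blocks$session == 1 & exp_blocks$stim != "sham", ]
  anodal_first <- tapply(s1_real$stim, s1_real$participant_id,
                         function(x) x[1] == "anodal")
  expect_equal(sum(anodal_first), 26)

  expect_error(make_session_plans(0), class = "choicerep_argument_error")

  # measurement block is always sham
  expect_true(all(plans$stim[plans$block == 1] == "sham"))
})

test_that("grid realization meets distance and angle constraints", {
  manhattan <- function(a, b) sum(abs(a - b))
  angle_ok <- function(av, c1, c2) {
    v1 <- c1 - av; v2 <- c2 - av
    sum(v1 * v2) <= 0
  }
  tr <- list(sn_distance = 2L, extra_distance = 1L)
  got <- realize_on_grid(tr, c(10, 10), rng_seed = 1)
  expect_equal(manhattan(got$sn, c(10, 10)), 2)
  expect_equal(manhattan(got$lf, c(10, 10)), 3)
  expect_true(angle_ok(c(10, 10), got$sn, got$lf))

  # corner avatar, longest design distance still placeable
  tr2 <- list(sn_distance = 3L, extra_distance = 12L)
  got2 <- realize_on_grid(tr2, c(1, 1), rng_seed = 2)
  expect_equal(manhattan(got2$sn, c(1, 1)), 3)
  expect_equal(manhattan(got2$lf, c(1, 1)), 15)
  expect_true(angle_ok(c(1, 1), got2$sn, got2$lf))

  # invariant sweep over random trials and positions
  set.seed(33)
  for (i in 1:200) {
    tr <- list(sn_distance = sample(2:3, 1),
               extra_distance = sample(c(1L, 4L, 8L, 12L), 1))
    av <- sample(5:16, 2, replace = TRUE)
    got <- realize_on_grid(tr, av)
    expect_equal(manhattan(got$sn, av), tr$sn_distance)
    expect_equal(manhattan(got$lf, av), tr$sn_distance + tr$extra_distance)
    expect_true(angle_ok(av, got$sn, got$lf))
    expect_true(all(c(got$sn, got$lf) >= 1 & c(got$sn, got$lf) <= 20))
  }
})
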