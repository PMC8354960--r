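# brute-force within-subject sums-of-squares oracle (independent of aov)
bf_oneway_rm <- function(y, subj, a) {
  grand <- mean(y)
  m_a <- tapply(y, a, mean)
  m_s <- tapply(y, subj, mean)
  n_s <- length(unique(subj)); n_a <- length(unique(a))
  ss_a <- n_s * sum((m_a - grand)^2)
  ss_s <- n_a * sum((m_s - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_a - ss_s
  df1 <- n_a - 1; df2 <- (n_a - 1) * (n_s - 1)
  f <- (ss_a / df1) / (ss_err / df2)
  list(F = f, df1 = df1, df2 = df2, ss = ss_a, ss_err = ss_err,
       pes = ss_a / (ss_a + ss_err))
}

test_that("hedges g reproduces the averaged-SD small-sample estimator", {
  expect_equal(round(hedges_g_av(56.15, 17.53, 40.24, 15.51, 52), 2), 0.95)
  expect_equal(round(hedges_g_av(852.61, 147.37, 798.65, 125.12, 52), 2), 0.39)
  expect_equal(hedges_g_av(5, 2, 5, 3, 20), 0)
  # sign follows the mean difference; correction shrinks toward zero
  set.seed(2)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1); s <- runif(2, 0.5, 3); n <- sample(5:50, 1)
    g <- hedges_g_av(m1, s[1], m2, s[2], n)
    d_unc <- (m1 - m2) / sqrt(mean(s^2))
    expect_equal(sign(g), sign(m1 - m2))
    expect_lt(abs(g), abs(d_unc) + 1e-12)
  }
  expect_error(hedges_g_av(1, 0, 2, 1, 10), class = "choicerep_argument_error")
})

test_that("paired t matches the closed form and tail conventions", {
  y <- c(10, 10, 10, 10)
  x <- y + c(1, 2, 3, 4)
  er <- paired_t(x, y)
  expect_equal(er$statistic, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-6)
  expect_equal(round(er$statistic, 3), 3.873)
  expect_equal(er$df, 3)

  er1 <- paired_t(x, y, tail = "one")
  expect_equal(er1$p, er$p / 2)
  # one-tailed against the hypothesized direction
  er_rev <- paired_t(y, x, tail = "one")
  expect_equal(er_rev$p, 1 - er$p / 2)

  same <- paired_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  expect_error(paired_t(x, x + 1), class = "choicerep_degenerate_test_error")
  expect_error(paired_t(1:2, 2:3), class = "choicerep_argument_error")
})

test_that("repeated-measures ANOVA agrees with a brute-force SS oracle", {
  # 4 subjects x 3 conditions toy table
  d <- expand.grid(subj = 1:4, cond = c("a", "b", "c"))
  set.seed(9)
  d$y <- round(rnorm(12, mean = 10 + 2 * (d$cond == "b")), 2)
  tab <- rm_anova(d, "y", "subj", "cond")
  oracle <- bf_oneway_rm(d$y, d$subj, d$cond)
  expect_equal(tab$F, oracle$F, tolerance = 1e-10)
  expect_equal(tab$df_num, oracle$df1)
  expect_equal(tab$df_den, oracle$df2)
  expect_equal(tab$pes, oracle$pes, tolerance = 1e-10)
  expect_equal(tab$ss, oracle$ss, tolerance = 1e-10)

  # identical values across conditions: zero effect
  d0 <- d; d0$y <- rep(rnorm(4), 3)
  tab0 <- rm_anova(d0, "y", "subj", "cond")
  expect_equal(tab0$F, 0)
  expect_equal(tab0$p, 1)

  # missing cell
  expect_error(rm_anova(d[-1, ], "y", "subj", "cond"),
               class = "choicerep_balance_error")
})

test_that("two-level one-way rm-ANOVA satisfies F = t^2", {
  set.seed(10)
  n <- 16
  d <- data.frame(subj = rep(1:n, 2), cond = rep(c("x", "y"), each = n),
                  y = rnorm(2 * n, mean = rep(c(0, 0.4), each = n)))
  tab <- rm_anova(d, "y", "subj", "cond")
  tt <- paired_t(d$y[d$cond == "x"], d$y[d$cond == "y"])
  expect_equal(tab$F, tt$statistic^2, tolerance = 1e-8)
  expect_equal(tab$p, tt$p, tolerance = 1e-8)
})

test_that("two-factor rm-ANOVA detects constructed additivity", {
  subj <- 1:6
  d <- expand.grid(subj = subj, A = c("a1", "a2"), B = c("b1", "b2"))
  base <- rnorm(6)
  d$y <- base[d$subj] + 2 * (d$A == "a2") + 3 * (d$B == "b2")
  tab <- rm_anova(d, "y", "subj", c("A", "B"))
  expect_setequal(tab$effect, c("A", "B", "A:B"))
  expect_equal(tab$F[tab$effect == "A:B"], 0, tolerance = 1e-8)
  expect_gt(tab$F[tab$effect == "A"], 1e6)  # noiseless additive effect
})

test_that("Holm correction follows the step-down definition", {
  expect_equal(holm_correct(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_correct(0.2), 0.2)
  expect_equal(holm_correct(rep(0.03, 4)), rep(min(4 * 0.03, 1), 4))
  expect_equal(holm_correct(c(0.5, 0.6, 0.7)), c(1, 1, 1))
  expect_error(holm_correct(c(0.1, 1.2)), class = "choicerep_argument_error")
})

test_that("required sample size inverts noncentral-t power", {
  expect_equal(required_n_paired(0.4, 0.05, 0.80, "two"), 52)
  expect_equal(required_n_paired(2.0, 0.05, 0.80, "two"), 5)

  # achieved-power inverse: power(n) >= target > power(n - 1)
  for (d in c(0.3, 0.5, 0.8)) {
    n <- required_n_paired(d)
    expect_gte(power_paired_t(n, d), 0.80)
    expect_lt(power_paired_t(n - 1, d), 0.80)
  }

  # monotone non-increasing in effect size
  ns <- vapply(seq(0.2, 1.0, by = 0.1), required_n_paired, numeric(1))
  expect_true(all(diff(ns) <= 0))

  # cross-check against the one-sample power routine in base R
  for (d in c(0.3, 0.5)) {
    n <- required_n_paired(d)
    expect_equal(power_paired_t(n, d),
                 stats::power.t.test(n = n, delta = d, sd = 1,
                                     type = "one.sample")$power,
                 tolerance = 1e-5)
  }

  expect_error(required_n_paired(-1), class = "choicerep_argument_error")
})

test_that("electrode current density is current over area", {
  expect_equal(current_density(1, 5, 5), 0.04)
  expect_equal(current_density(2, 5, 5), 0.08)
  expect_error(current_density(0, 5, 5), class = "choicerep_argument_error")
})
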