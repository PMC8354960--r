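#' Small-sample-corrected standardized mean difference (Hedges g)
#'
#' Standardized mean difference using the average-SD standardizer,
#' `(m1 - m2) / sqrt((sd1^2 + sd2^2) / 2)`, multiplied by the small-sample
#' correction `J = 1 - 3 / (4 (n - 1) - 1)`. This is the conventional
#' effect size for paired designs when the correlation between conditions is
#' not meant to inflate the standardizer.
#'
#' @param m1,sd1 mean and SD of condition 1.
#' @param m2,sd2 mean and SD of condition 2.
#' @param n number of paired observations (>= 2).
#' @examples
#' hedges_g_av(56.15, 17.53, 40.24, 15.51, 52)  # ~0.95
#' @export
hedges_g_av <- function(m1, sd1, m2, sd2, n) {
  check_arg(sd1 > 0 && sd2 > 0, "SDs must be positive")
  check_arg(n >= 2, "n must be >= 2")
  j <- 1 - 3 / (4 * (n - 1) - 1)
  (m1 - m2) / sqrt((sd1^2 + sd2^2) / 2) * j
}

new_effect_report <- function(label, statistic_name, statistic, df, p, tail,
                              effect_size = NA_real_,
                              effect_size_name = NA_character_,
                              means = NULL, sds = NULL, n = NA_integer_,
                              note = NULL) {
  structure(
    list(label = label, statistic_name = statistic_name,
         statistic = statistic, df = df, p = p, tail = tail,
         effect_size = effect_size, effect_size_name = effect_size_name,
         means = means, sds = sds, n = n, note = note),
    class = "effect_report"
  )
}

#' @export
print.effect_report <- function(x, ...) {
  dfs <- paste(round(x$df, 1), collapse = ",")
  cat(sprintf("%s: %s(%s) = %.3f, p = %.4g (%s-tailed)%s\n",
              x$label, x$statistic_name, dfs, x$statistic, x$p, x$tail,
              if (is.finite(x$effect_size))
                sprintf(", %s = %.3f", x$effect_size_name, x$effect_size)
              else ""))
  if (!is.null(x$means)) {
    cat("  means:", paste(sprintf("%s = %.2f", names(x$means), x$means),
                          collapse = ", "), "\n")
  }
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Paired t test with directional p and Hedges g
#'
#' Classical paired t test on per-subject values. With `tail = "one"` the
#' hypothesized direction is `x > y`: the one-tailed p is half the
#' two-tailed p when the observed effect is in that direction and
#' `1 - p_two/2` otherwise. If all pairwise differences are exactly zero the
#' test is the defined limit t = 0, p(two-tailed) = 1; a zero-variance
#' difference with nonzero mean is a degenerate test and raises an error.
#'
#' @param x,y paired per-subject values (equal length, n >= 3).
#' @param tail `"two"` or `"one"`.
#' @param label description used in the report.
#' @return an `effect_report` with t, df = n - 1, p, and Hedges g computed
#'   from the two conditions' means and SDs via [hedges_g_av].
#' @export
paired_t <- function(x, y, tail = c("two", "one"), label = "paired t") {
  tail <- match.arg(tail)
  check_arg(length(x) == length(y), "x and y must have equal length")
  check_arg(length(x) >= 3, "need n >= 3 pairs")
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(new_effect_report(label, "t", 0, n - 1,
                               p = if (tail == "two") 1 else 0.5, tail = tail,
                               effect_size = 0, effect_size_name = "g",
                               means = c(x = mean(x), y = mean(y)),
                               sds = c(x = sd(x), y = sd(y)), n = n))
    }
    stop_choicerep("degenerate_test_error",
                   "zero variance of paired differences with nonzero mean")
  }
  tt <- t.test(x, y, paired = TRUE)
  t_val <- unname(tt$statistic)
  p_two <- tt$p.value
  p <- if (tail == "two") p_two else if (t_val > 0) p_two / 2 else 1 - p_two / 2
  g <- if (sd(x) > 0 && sd(y) > 0) {
    hedges_g_av(mean(x), sd(x), mean(y), sd(y), n)
  } else NA_real_
  new_effect_report(label, "t", t_val, n - 1, p, tail,
                    effect_size = g, effect_size_name = "g",
                    means = c(x = mean(x), y = mean(y)),
                    sds = c(x = sd(x), y = sd(y)), n = n)
}

#' Holm step-down multiple-testing correction
#'
#' @param p_values vector of p values in [0, 1].
#' @return adjusted p values (same order), monotonicity enforced.
#' @export
holm_correct <- function(p_values) {
  check_arg(all(p_values >= 0 & p_values <= 1), "p values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Repeated-measures ANOVA with one or two within-subject factors
#'
#' Classical sums-of-squares decomposition with subject as a random blocking
#' factor (fitted via `aov` with `Error()` strata). Requires a complete
#' balanced design: exactly one value per subject and factor-level cell.
#' Reports, per effect, F, the df pair, p, partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`) and generalized-total eta squared
#' (`SS_effect / SS_total`).
#'
#' @param data long-format data frame.
#' @param dv name of the value column.
#' @param subject name of the subject identifier column.
#' @param factors character vector of 1 or 2 within-subject factor columns.
#' @return object of class `rm_anova_table`: data frame with one row per
#'   effect (`effect`, `df_num`, `df_den`, `ss`, `ss_error`, `F`, `p`,
#'   `pes`, `eta_sq`).
#' @export
rm_anova <- function(data, dv, subject, factors) {
  check_arg(length(factors) %in% 1:2, "supply 1 or 2 within-subject factors")
  check_arg(all(c(dv, subject, factors) %in% names(data)),
            "dv, subject and factor columns must exist in data")
  d <- data.frame(
    .y = data[[dv]],
    .subj = factor(data[[subject]]),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(factors)) d[[paste0(".f", i)]] <- factor(data[[factors[i]]])

  cells <- table(d[, c(".subj", paste0(".f", seq_along(factors))), drop = FALSE])
  if (any(cells != 1)) {
    stop_choicerep("balance_error",
                   "design is not complete and balanced (need exactly one value per subject x cell)")
  }

  rhs <- paste(paste0(".f", seq_along(factors)), collapse = " * ")
  form <- stats::as.formula(
    sprintf(".y ~ %s + Error(.subj/(%s))", rhs, rhs))
  fit <- aov(form, data = d)
  smry <- summary(fit)

  rows <- list()
  for (stratum in smry) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    eff_idx <- which(terms != "Residuals")
    err_idx <- which(terms == "Residuals")
    if (length(eff_idx) == 0 || length(err_idx) == 0) next
    ss_err <- tab[err_idx, "Sum Sq"]
    df_err <- tab[err_idx, "Df"]
    for (i in eff_idx) {
      ss <- tab[i, "Sum Sq"]
      df1 <- tab[i, "Df"]
      if (ss < 1e-12) {
        f_val <- 0; p_val <- 1
      } else {
        f_val <- (ss / df1) / (ss_err / df_err)
        p_val <- stats::pf(f_val, df1, df_err, lower.tail = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        effect = gsub("\\.f1", factors[1],
                      gsub("\\.f2", factors[length(factors)], terms[i])),
        df_num = df1, df_den = df_err, ss = ss, ss_error = ss_err,
        F = f_val, p = p_val,
        pes = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  ss_total <- sum(vapply(smry, function(s) sum(s[[1]][, "Sum Sq"]), numeric(1)))
  out$eta_sq <- if (ss_total > 0) out$ss / ss_total else 0
  rownames(out) <- NULL
  structure(out, class = c("rm_anova_table", "data.frame"))
}

#' @export
print.rm_anova_table <- function(x, ...) {
  cat("repeated-measures ANOVA:\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 3); df$p <- signif(df$p, 3)
  df$pes <- round(df$pes, 3); df$eta_sq <- round(df$eta_sq, 4)
  print(df[, c("effect", "df_num", "df_den", "F", "p", "pes", "eta_sq")])
  invisible(x)
}

#' Required sample size for a paired t test (noncentral-t inversion)
#'
#' Smallest n such that a paired t test at level `alpha` attains the target
#' power against a standardized effect size `d` (dz). Power is computed
#' exactly from the noncentral t distribution with df = n - 1 and
#' noncentrality `d * sqrt(n)`.
#'
#' @param d standardized effect size (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param tails `"two"` or `"one"`.
#' @param n_max search ceiling.
#' @examples
#' required_n_paired(0.4)  # 52
#' @export
required_n_paired <- function(d, alpha = 0.05, power = 0.80,
                              tails = c("two", "one"), n_max = 1e5) {
  tails <- match.arg(tails)
  check_arg(is.numeric(d) && length(d) == 1 && d > 0, "d must be > 0")
  check_arg(alpha > 0 && alpha < 1 && power > alpha && power < 1,
            "need 0 < alpha < power < 1")
  for (n in 3:n_max) {
    if (power_paired_t(n, d, alpha, tails) >= power) return(n)
  }
  stop_choicerep("argument_error", "target power not reached within n_max")
}

#' Achieved power of a paired t test at given n
#'
#' @param n number of pairs (>= 3).
#' @inheritParams required_n_paired
#' @export
power_paired_t <- function(n, d, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == "two") {
    tc <- qt(1 - alpha / 2, df)
    pt(-tc, df, ncp) + pt(tc, df, ncp, lower.tail = FALSE)
  } else {
    pt(qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  }
}

#' Electrode current density
#'
#' Current density delivered by a rectangular tDCS electrode:
#' current divided by electrode area.
#'
#' @param current_ma stimulation current in mA.
#' @param width_cm,height_cm electrode dimensions in cm.
#' @return current density in mA/cm^2.
#' @examples
#' current_density(1, 5, 5)  # 0.04
#' @export
current_density <- function(current_ma, width_cm, height_cm = width_cm) {
  check_arg(current_ma > 0 && width_cm > 0 && height_cm > 0,
            "current and electrode dimensions must be positive")
  current_ma / (width_cm * height_cm)
}
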