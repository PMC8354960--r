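#' Filter target trials by bias-manipulation success
#'
#' A triplet's bias manipulation succeeded when the engineered more-valuable
#' option was actually chosen in the bias trial (SN choice in an SN-bias
#' trial, LF choice in an LF-bias trial). Only target trials whose required
#' bias trial(s) succeeded enter the repetition analyses. The default mode
#' checks the trial immediately preceding the target (the second bias
#' trial); `mode = "both"` requires both bias trials to have succeeded.
#'
#' @param records choice records containing complete experimental triplets
#'   (roles `bias_SN`/`bias_LF`/`target` in order within each triplet).
#' @param mode `"preceding"` (default) or `"both"`.
#' @return list of class `bias_filter`: `targets` (retained target trials
#'   with `bias_type`, `bias_choice` and `repeated` columns), `bias_trials`
#'   (all bias trials with a `success` flag) and `success_rates`
#'   (per participant, over all bias trials).
#' @export
filter_bias_success <- function(records, mode = c("preceding", "both")) {
  mode <- match.arg(mode)
  exp_rec <- records[records$role %in% c("bias_SN", "bias_LF", "target"), ,
                     drop = FALSE]
  if (nrow(exp_rec) == 0) {
    stop_choicerep("data_integrity_error", "no experimental triplet trials in records")
  }
  key <- paste(exp_rec$participant_id, exp_rec$session, exp_rec$block,
               exp_rec$triplet_id, sep = "\r")
  ord <- order(exp_rec$participant_id, exp_rec$session, exp_rec$block,
               exp_rec$trial_index)
  exp_rec <- exp_rec[ord, , drop = FALSE]
  key <- key[ord]

  runs <- rle(key)
  if (any(runs$lengths != 3)) {
    stop_choicerep("data_integrity_error",
                   "broken triplet structure: each triplet needs exactly 3 consecutive trials")
  }
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  role1 <- exp_rec$role[starts]
  role2 <- exp_rec$role[starts + 1L]
  role3 <- exp_rec$role[starts + 2L]
  if (!all(role1 %in% c("bias_SN", "bias_LF") & role2 == role1 &
             role3 == "target")) {
    stop_choicerep("data_integrity_error",
                   "triplet roles must be bias, bias (same type), target in order")
  }

  bias_idx <- sort(c(starts, starts + 1L))
  bias_trials <- exp_rec[bias_idx, , drop = FALSE]
  bias_trials$success <-
    (bias_trials$role == "bias_SN" & bias_trials$choice == "SN") |
    (bias_trials$role == "bias_LF" & bias_trials$choice == "LF")

  success1 <- bias_trials$success[match(starts, bias_idx)]
  success2 <- bias_trials$success[match(starts + 1L, bias_idx)]
  keep <- if (mode == "preceding") success2 else success1 & success2

  targets <- exp_rec[starts + 2L, , drop = FALSE][keep, , drop = FALSE]
  targets$bias_type <- role2[keep]
  targets$bias_choice <- exp_rec$choice[starts + 1L][keep]
  targets$repeated <- targets$choice == targets$bias_choice

  rates <- aggregate(success ~ participant_id, data = bias_trials, FUN = mean)
  names(rates)[2] <- "success_rate"
  rates$success_rate <- 100 * rates$success_rate

  structure(list(targets = targets, bias_trials = bias_trials,
                 success_rates = rates, mode = mode),
            class = "bias_filter")
}

# per-participant LF percentages after each bias type; errors if a
# participant lacks a condition
lf_pct_by_bias <- function(targets) {
  split_p <- split(targets, targets$participant_id)
  rows <- lapply(split_p, function(tp) {
    for (bt in c("bias_LF", "bias_SN")) {
      if (!any(tp$bias_type == bt)) {
        stop_choicerep("insufficient_data_error",
                       sprintf("participant %s has no targets after %s",
                               tp$participant_id[1], bt))
      }
    }
    data.frame(
      participant_id = tp$participant_id[1],
      pct_lf_after_lf = 100 * mean(tp$choice[tp$bias_type == "bias_LF"] == "LF"),
      pct_lf_after_sn = 100 * mean(tp$choice[tp$bias_type == "bias_SN"] == "LF"),
      n_targets = nrow(tp),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Choice-repetition summary (repetition index)
#'
#' LF-choice percentage in target trials after an LF-bias versus after an
#' SN-bias trial, computed per participant and then averaged. The
#' repetition index is their difference in percentage points: positive
#' values indicate choice repetition.
#'
#' @param targets filtered target trials (the `targets` element of
#'   [filter_bias_success]).
#' @return list of class `repetition_summary`: `by_participant` (per
#'   participant percentages and index), group means `pct_lf_after_lf`,
#'   `pct_lf_after_sn`, `repetition_index`, and `n_targets_used`.
#' @export
repetition_summary <- function(targets) {
  check_arg(nrow(targets) >= 1, "no target trials supplied")
  by_p <- lf_pct_by_bias(targets)
  by_p$repetition_index <- by_p$pct_lf_after_lf - by_p$pct_lf_after_sn
  structure(
    list(by_participant = by_p,
         pct_lf_after_lf = mean(by_p$pct_lf_after_lf),
         pct_lf_after_sn = mean(by_p$pct_lf_after_sn),
         repetition_index = mean(by_p$repetition_index),
         n_targets_used = nrow(targets)),
    class = "repetition_summary"
  )
}

#' @export
print.repetition_summary <- function(x, ...) {
  cat(sprintf("LF%% after LF bias %.2f, after SN bias %.2f -> repetition index %.2f points (%d targets, %d participants)\n",
              x$pct_lf_after_lf, x$pct_lf_after_sn, x$repetition_index,
              x$n_targets_used, nrow(x$by_participant)))
  invisible(x)
}

#' Decision-time contrast: repetitions versus switches
#'
#' Classifies each target trial as a repetition (target choice equal to the
#' preceding bias-trial choice) or a switch, averages log-transformed
#' decision times per participant and condition (the log transform reduces
#' the right skew typical of decision times), and runs a one-tailed paired t
#' test of switch > repetition. Raw-scale means and SDs are reported
#' alongside, and Hedges g is computed on the raw scale.
#'
#' @param targets filtered target trials with `dt_ms`, `choice`,
#'   `bias_choice`.
#' @param tail tail for the paired t test.
#' @return an `effect_report` (t on the log scale; means/SDs in ms).
#' @export
dt_contrast <- function(targets, tail = "one") {
  split_p <- split(targets, targets$participant_id)
  rows <- lapply(split_p, function(tp) {
    rep_idx <- tp$choice == tp$bias_choice
    if (!any(rep_idx) || all(rep_idx)) {
      stop_choicerep("insufficient_data_error",
                     sprintf("participant %s lacks repetition or switch targets",
                             tp$participant_id[1]))
    }
    data.frame(
      participant_id = tp$participant_id[1],
      log_repeat = mean(log(tp$dt_ms[rep_idx])),
      log_switch = mean(log(tp$dt_ms[!rep_idx])),
      raw_repeat = mean(tp$dt_ms[rep_idx]),
      raw_switch = mean(tp$dt_ms[!rep_idx]),
      stringsAsFactors = FALSE
    )
  })
  by_p <- do.call(rbind, rows)
  er <- paired_t(by_p$log_switch, by_p$log_repeat, tail = tail,
                 label = "decision time: switch vs repetition (log ms)")
  n <- nrow(by_p)
  er$means <- c(switch_ms = mean(by_p$raw_switch),
                repeat_ms = mean(by_p$raw_repeat))
  er$sds <- c(switch_ms = sd(by_p$raw_switch),
              repeat_ms = sd(by_p$raw_repeat))
  er$effect_size <- if (n >= 2 && all(er$sds > 0)) {
    hedges_g_av(er$means[["switch_ms"]], er$sds[["switch_ms"]],
                er$means[["repeat_ms"]], er$sds[["repeat_ms"]], n)
  } else if (er$means[["switch_ms"]] == er$means[["repeat_ms"]]) 0 else NA_real_
  er$by_participant <- by_p
  er
}

#' Check and pool the two sham sessions
#'
#' Compares per-participant LF percentages in sham target trials between the
#' two sessions with a paired t test. Data are pooled across sessions
#' regardless (as preplanned), but the report is flagged when the check is
#' significant at 0.05 so the pooling assumption is visible.
#'
#' @param records choice records containing sham experimental blocks from
#'   both sessions of every participant.
#' @return list of class `sham_pooling`: `records` (unchanged; pooling is
#'   performed downstream by grouping on stimulation only), `check` (the
#'   `effect_report`), `flagged`.
#' @export
pool_sham <- function(records) {
  sham <- records[records$stim == "sham" & records$role == "target", ,
                  drop = FALSE]
  pct <- aggregate(list(pct_lf = sham$choice == "LF"),
                   by = list(participant_id = sham$participant_id,
                             session = sham$session),
                   FUN = function(x) 100 * mean(x))
  wide <- merge(pct[pct$session == 1, c("participant_id", "pct_lf")],
                pct[pct$session == 2, c("participant_id", "pct_lf")],
                by = "participant_id", suffixes = c("_s1", "_s2"))
  if (nrow(wide) == 0 || nrow(wide) < length(unique(sham$participant_id))) {
    stop_choicerep("data_error", "every participant needs sham trials in both sessions")
  }
  check <- paired_t(wide$pct_lf_s1, wide$pct_lf_s2, tail = "two",
                    label = "sham LF% session 1 vs session 2")
  structure(list(records = records, check = check,
                 flagged = check$p < 0.05),
            class = "sham_pooling")
}

#' Manipulation check: choice percentages by trial role
#'
#' LF-choice percentage per trial role (SN bias, LF bias, neutral target),
#' per participant and at the group level. A working design shows near-total
#' SN choices in SN-bias trials, near-total LF choices in LF-bias trials and
#' indifference in targets.
#'
#' @param records choice records including bias and target trials.
#' @return list with `by_participant` and `group` data frames of LF
#'   percentages by role.
#' @export
manipulation_check <- function(records) {
  rec <- records[records$role %in% c("bias_SN", "bias_LF", "target"), ,
                 drop = FALSE]
  check_arg(nrow(rec) > 0, "records must include bias and target trials")
  by_p <- aggregate(list(pct_lf = rec$choice == "LF"),
                    by = list(participant_id = rec$participant_id,
                              role = rec$role),
                    FUN = function(x) 100 * mean(x))
  group <- aggregate(pct_lf ~ role, data = by_p, FUN = mean)
  list(by_participant = by_p, group = group)
}
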