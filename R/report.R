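#' Run the full preregistered analysis pipeline
#'
#' Executes, in the preregistered order: the sham-pooling check, the
#' bias-success filter, the confirmatory hypothesis tests and the
#' exploratory block.
#'
#' * H1.1 — choice repetition under sham: one-tailed paired t test of the
#'   per-participant LF percentage in target trials after LF-bias versus
#'   after SN-bias trials (sham blocks, successful-bias trials only).
#' * H1.2 — repetition speed under sham: one-tailed paired t test of
#'   log decision times, switch versus repetition targets.
#' * H2.1 — tDCS on choice repetition: one-way repeated-measures ANOVA of
#'   the repetition index by stimulation (anodal/cathodal/sham pooled),
#'   with directional Holm-corrected post hocs H2.1.1 (anodal > sham) and
#'   H2.1.2 (sham > cathodal).
#' * H2.2 — tDCS on decision times: one-way repeated-measures ANOVA of mean
#'   log decision time over all target trials by stimulation, with post
#'   hocs H2.2.1 (sham > anodal) and H2.2.2 (cathodal > sham).
#' * Exploratory — sham-first versus sham-second overall LF%; stimulation
#'   effect on overall LF%; stimulation effect on bias success; stimulation
#'   x trial-type ANOVA on log decision times; manipulation check by trial
#'   role.
#'
#' @param records choice records covering all three stimulation conditions
#'   and both sessions (e.g. `simulate_cohort(...)$records`).
#' @param filter_mode bias-success filter mode, see [filter_bias_success].
#' @param alpha level used for flags (the tests report exact p values).
#' @return object of class `prereg_report`.
#' @export
preregistered_report <- function(records, filter_mode = "preceding",
                                 alpha = 0.05) {
  need <- c("sham", "anodal", "cathodal")
  if (!all(need %in% unique(records$stim))) {
    stop_choicerep("argument_error",
                   "records must contain sham, anodal and cathodal trials")
  }
  if (!all(1:2 %in% unique(records$session))) {
    stop_choicerep("argument_error", "records must contain both sessions")
  }
  stage <- function(label, expr) {
    tryCatch(expr, choicerep_error = function(e) {
      stop_choicerep("stage_error", sprintf("[stage %s] %s", label, conditionMessage(e)))
    })
  }

  pooling <- stage("pool_sham", pool_sham(records))
  filtered <- stage("filter_bias_success",
                    filter_bias_success(records, mode = filter_mode))
  targets <- filtered$targets
  sham_targets <- targets[targets$stim == "sham", , drop = FALSE]

  # H1.1: repetition of choices under sham
  rep_sham <- stage("H1.1", repetition_summary(sham_targets))
  h11 <- stage("H1.1", paired_t(rep_sham$by_participant$pct_lf_after_lf,
                                rep_sham$by_participant$pct_lf_after_sn,
                                tail = "one",
                                label = "H1.1 LF% after LF vs SN bias (sham)"))

  # H1.2: repetitions faster than switches under sham
  h12 <- stage("H1.2", dt_contrast(sham_targets))
  h12$label <- "H1.2 decision time switch vs repetition (sham)"

  # H2.1: tDCS on the repetition index
  ri <- stage("H2.1", do.call(rbind, lapply(need, function(s) {
    rs <- repetition_summary(targets[targets$stim == s, , drop = FALSE])
    data.frame(participant_id = rs$by_participant$participant_id,
               stim = s, repetition_index = rs$by_participant$repetition_index,
               stringsAsFactors = FALSE)
  })))
  h21 <- stage("H2.1", rm_anova(ri, "repetition_index", "participant_id", "stim"))
  ri_wide <- stats::reshape(ri, idvar = "participant_id", timevar = "stim",
                            direction = "wide")
  h211 <- stage("H2.1.1",
                paired_t(ri_wide$repetition_index.anodal,
                         ri_wide$repetition_index.sham, tail = "one",
                         label = "H2.1.1 repetition index anodal > sham"))
  h212 <- stage("H2.1.2",
                paired_t(ri_wide$repetition_index.sham,
                         ri_wide$repetition_index.cathodal, tail = "one",
                         label = "H2.1.2 repetition index sham > cathodal"))
  holm21 <- holm_correct(c(h211$p, h212$p))
  h211$p_holm <- holm21[1]; h212$p_holm <- holm21[2]

  # H2.2: tDCS on decision times (all target trials, log ms)
  all_targets <- records[records$role == "target", , drop = FALSE]
  dt_by <- aggregate(list(log_dt = log(all_targets$dt_ms)),
                     by = list(participant_id = all_targets$participant_id,
                               stim = all_targets$stim),
                     FUN = mean)
  h22 <- stage("H2.2", rm_anova(dt_by, "log_dt", "participant_id", "stim"))
  dt_wide <- stats::reshape(dt_by, idvar = "participant_id", timevar = "stim",
                            direction = "wide")
  h221 <- stage("H2.2.1", paired_t(dt_wide$log_dt.sham, dt_wide$log_dt.anodal,
                                   tail = "one",
                                   label = "H2.2.1 log dt sham > anodal"))
  h222 <- stage("H2.2.2", paired_t(dt_wide$log_dt.cathodal, dt_wide$log_dt.sham,
                                   tail = "one",
                                   label = "H2.2.2 log dt cathodal > sham"))
  holm22 <- holm_correct(c(h221$p, h222$p))
  h221$p_holm <- holm22[1]; h222$p_holm <- holm22[2]

  # exploratory block
  exp_rec <- records[records$role %in% c("bias_SN", "bias_LF", "target"), ,
                     drop = FALSE]
  sham_all <- exp_rec[exp_rec$stim == "sham", , drop = FALSE]
  so <- aggregate(list(pct_lf = sham_all$choice == "LF"),
                  by = list(participant_id = sham_all$participant_id,
                            sham_order = sham_all$sham_order),
                  FUN = function(x) 100 * mean(x))
  so_wide <- stats::reshape(so, idvar = "participant_id",
                            timevar = "sham_order", direction = "wide")
  ex_order <- stage("exploratory",
                    paired_t(so_wide$pct_lf.sham_first,
                             so_wide$pct_lf.sham_second, tail = "two",
                             label = "overall LF% sham-first vs sham-second"))

  lf_all <- aggregate(list(pct_lf = exp_rec$choice == "LF"),
                      by = list(participant_id = exp_rec$participant_id,
                                stim = exp_rec$stim),
                      FUN = function(x) 100 * mean(x))
  ex_lf <- stage("exploratory",
                 rm_anova(lf_all, "pct_lf", "participant_id", "stim"))

  bs <- aggregate(list(success_rate = filtered$bias_trials$success),
                  by = list(participant_id = filtered$bias_trials$participant_id,
                            stim = filtered$bias_trials$stim),
                  FUN = function(x) 100 * mean(x))
  ex_bias <- stage("exploratory",
                   rm_anova(bs, "success_rate", "participant_id", "stim"))

  ttype <- aggregate(list(log_dt = log(targets$dt_ms)),
                     by = list(participant_id = targets$participant_id,
                               stim = targets$stim,
                               type = ifelse(targets$repeated, "repetition",
                                             "switch")),
                     FUN = mean)
  ex_dt2 <- stage("exploratory",
                  rm_anova(ttype, "log_dt", "participant_id",
                           c("stim", "type")))

  structure(
    list(
      sham_check = pooling$check,
      sham_pooling_flagged = pooling$flagged,
      success_rates = filtered$success_rates,
      repetition_sham = rep_sham,
      hypotheses = list(
        `H1.1` = h11, `H1.2` = h12,
        `H2.1` = h21, `H2.1.1` = h211, `H2.1.2` = h212,
        `H2.2` = h22, `H2.2.1` = h221, `H2.2.2` = h222
      ),
      exploratory = list(
        sham_order = ex_order,
        lf_pct_by_stim = ex_lf,
        bias_success_by_stim = ex_bias,
        stim_by_type_dt = ex_dt2,
        manipulation = manipulation_check(records)
      ),
      meta = list(alpha = alpha, filter_mode = filter_mode,
                  n_participants = length(unique(records$participant_id)),
                  n_records = nrow(records))
    ),
    class = "prereg_report"
  )
}

#' @export
print.prereg_report <- function(x, ...) {
  cat(sprintf("Preregistered analysis report (%d participants, %d records)\n",
              x$meta$n_participants, x$meta$n_records))
  cat(sprintf("sham pooling check: t = %.2f, p = %.3f%s\n",
              x$sham_check$statistic, x$sham_check$p,
              if (x$sham_pooling_flagged) " [FLAGGED]" else ""))
  cat(sprintf("repetition index (sham): %.2f points\n",
              x$repetition_sham$repetition_index))
  for (h in names(x$hypotheses)) {
    obj <- x$hypotheses[[h]]
    if (inherits(obj, "effect_report")) {
      print(obj)
    } else {
      cat(h, "")
      print(obj)
    }
  }
  invisible(x)
}

# ---- serialization to plain lists (stable key order) ----

#' Convert report objects to plain lists for JSON output
#'
#' @param x an `effect_report`, `rm_anova_table` or `prereg_report`.
#' @param ... unused.
#' @export
as_report_list <- function(x, ...) UseMethod("as_report_list")

#' @export
as_report_list.effect_report <- function(x, ...) {
  out <- list(label = x$label, statistic_name = x$statistic_name,
              statistic = x$statistic, df = x$df, p = x$p, tail = x$tail,
              effect_size_name = x$effect_size_name,
              effect_size = x$effect_size,
              means = as.list(x$means), sds = as.list(x$sds), n = x$n)
  if (!is.null(x$p_holm)) out$p_holm <- x$p_holm
  out
}

#' @export
as_report_list.rm_anova_table <- function(x, ...) {
  lapply(seq_len(nrow(x)), function(i) as.list(as.data.frame(x)[i, ]))
}

#' @export
as_report_list.prereg_report <- function(x, ...) {
  list(
    sham_check = as_report_list(x$sham_check),
    sham_pooling_flagged = x$sham_pooling_flagged,
    repetition_index_sham = x$repetition_sham$repetition_index,
    pct_lf_after_lf_sham = x$repetition_sham$pct_lf_after_lf,
    pct_lf_after_sn_sham = x$repetition_sham$pct_lf_after_sn,
    hypotheses = lapply(x$hypotheses, as_report_list),
    exploratory = list(
      sham_order = as_report_list(x$exploratory$sham_order),
      lf_pct_by_stim = as_report_list(x$exploratory$lf_pct_by_stim),
      bias_success_by_stim = as_report_list(x$exploratory$bias_success_by_stim),
      stim_by_type_dt = as_report_list(x$exploratory$stim_by_type_dt),
      manipulation_group = as.list(setNames(
        x$exploratory$manipulation$group$pct_lf,
        x$exploratory$manipulation$group$role))
    ),
    meta = x$meta
  )
}
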