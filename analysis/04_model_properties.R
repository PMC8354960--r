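#!/usr/bin/env Rscript
# Behavior of the attractor-network agent itself: how the repetition index
# depends on the inter-trial interval and on membrane polarization. These
# are the mechanism-level predictions (H2-style) that the synthetic
# participant exhibits when its polarization sensitivity is switched on;
# the human study did not observe them.

suppressPackageStartupMessages(library(choicerep))
dir.create("results", showWarnings = FALSE)

n_triplets <- 4000
plan <- local({
  plans <- make_session_plans(4)
  plans[plans$participant_id == 1 & plans$session == 1 & plans$block == 2, ]
})
prof <- indifference_profile(
  (indifference_ratio(2, 1:12, 0.2) + indifference_ratio(3, 1:12, 0.2)) / 2)

run_block <- function(params, stim, target_iti = NULL, seed) {
  set.seed(seed)
  sched <- make_triplet_blocks(prof, n_triplets, 1)
  sched$block <- 2L
  if (!is.null(target_iti)) {
    sched$iti_before_ms[sched$role == "target"] <- target_iti
  }
  pl <- plan; pl$stim <- stim
  rec <- simulate_session(pl, sched, params)
  f <- filter_bias_success(rec)
  data.frame(
    repetition_index = repetition_summary(f$targets)$repetition_index,
    mean_target_dt = mean(rec$dt_ms[rec$role == "target"]),
    bias_success = mean(f$bias_trials$success) * 100
  )
}

# ITI dependence under sham
p <- agent_params()
iti_tab <- do.call(rbind, lapply(c(500, 1500), function(iti) {
  cbind(target_iti = iti, run_block(p, "sham", iti, seed = 1000 + iti))
}))
cat("repetition index by target ITI (sham):\n"); print(iti_tab)

# polarization dependence (magnitude 0.15, above the sensitivity floor)
p_pol <- agent_params(polarization = 0.15)
pol_tab <- do.call(rbind, lapply(c("anodal", "sham", "cathodal"), function(s) {
  cbind(stim = s, run_block(p_pol, s, seed = 2000))
}))
cat("\nrepetition index and decision time by polarization:\n"); print(pol_tab)

write.csv(iti_tab, "results/ri_by_iti.csv", row.names = FALSE)
write.csv(pol_tab, "results/ri_by_polarization.csv", row.names = FALSE)
cat("wrote results/ri_by_iti.csv, results/ri_by_polarization.csv\n")
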