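#' Generate measurement-block trials
#'
#' Builds the trial list for the measurement block of the coin-collection
#' game, used to estimate a player's indifference points. Each trial offers a
#' small/near (SN) coin and a large/far (LF) coin: the SN coin sits 2 or 3
#' fields from the avatar, the LF coin 1, 4, 8 or 12 fields further (the
#' *extra distance*). The LF value is drawn uniformly from 65--85 credits and
#' the SN value is a uniform fraction (0.20--0.95) of it, rounded to whole
#' credits. The inter-trial interval is held constant at 500 ms.
#'
#' @param n_trials number of trials (>= 1).
#' @param rng_seed optional integer seed; `NULL` uses the current RNG stream.
#' @param lf_range integer range of LF values in credits.
#' @param ratio_range range of the SN/LF value ratio.
#' @return data frame of trial specifications with columns `trial_index`,
#'   `triplet_id` (NA), `role` (`"measurement"`), `sn_distance`,
#'   `extra_distance`, `sn_value`, `lf_value`, `ratio` (recomputed from the
#'   rounded values) and `iti_before_ms`.
#' @examples
#' head(make_measurement_trials(10, rng_seed = 1))
#' @export
make_measurement_trials <- function(n_trials, rng_seed = NULL,
                                    lf_range = c(65L, 85L),
                                    ratio_range = c(0.20, 0.95)) {
  check_arg(is.numeric(n_trials) && length(n_trials) == 1 &&
              is.finite(n_trials) && n_trials >= 1,
            "n_trials must be a single integer >= 1")
  n_trials <- as.integer(n_trials)
  maybe_seed(rng_seed)

  sn_distance <- sample(c(2L, 3L), n_trials, replace = TRUE)
  extra_distance <- sample(c(1L, 4L, 8L, 12L), n_trials, replace = TRUE)
  lf_value <- sample(seq(lf_range[1], lf_range[2]), n_trials, replace = TRUE)
  ratio_drawn <- stats::runif(n_trials, ratio_range[1], ratio_range[2])
  sn_value <- clamp(round_half_up(ratio_drawn * lf_value), 1L, lf_value - 1L)

  data.frame(
    trial_index = seq_len(n_trials),
    triplet_id = NA_character_,
    role = "measurement",
    sn_distance = sn_distance,
    extra_distance = extra_distance,
    sn_value = as.integer(sn_value),
    lf_value = as.integer(lf_value),
    ratio = as.integer(sn_value) / lf_value,
    iti_before_ms = ifelse(seq_len(n_trials) == 1L, NA_real_, 500),
    stringsAsFactors = FALSE
  )
}

#' Construct bias/target triplet blocks
#'
#' Builds experimental blocks made of trial triplets: two bias trials of one
#' type followed by one neutral target trial. Bias trials set the SN/LF value
#' ratio 0.30 above (`bias_SN`) or below (`bias_LF`) the player's indifference
#' point at the drawn distance, so one option is clearly more attractive;
#' the bias distance is drawn from the distances where that shift keeps the
#' ratio inside (0, 1) (indifference point below 0.7 for SN bias, above 0.3
#' for LF bias). Target trials sit exactly at the indifference point, with
#' distance uniform on 1--12. The interval before the target is always 500 ms
#' (residual-activity carry-over is strongest at short intervals); the other
#' two intervals of a triplet are 500 and 1500 ms in randomised order.
#'
#' @param profile an [indifference_profile] for the player.
#' @param n_triplets_per_block triplets per block (default 40, about 120
#'   trials per 6-minute block).
#' @param n_blocks number of experimental blocks (default 4).
#' @param rng_seed optional integer seed.
#' @param lf_range integer range of LF values in credits.
#' @return data frame of trial specifications (one row per trial) with
#'   columns `block`, `trial_index` (within block), `triplet_id`, `role`
#'   (`bias_SN`/`bias_LF`/`target`), `sn_distance`, `extra_distance`,
#'   `sn_value`, `lf_value`, `ratio`, `iti_before_ms` (NA before the first
#'   trial of a block).
#' @export
make_triplet_blocks <- function(profile, n_triplets_per_block = 40L,
                                n_blocks = 4L, rng_seed = NULL,
                                lf_range = c(65L, 85L)) {
  stopifnot(inherits(profile, "indifference_profile"))
  check_arg(n_triplets_per_block >= 1, "n_triplets_per_block must be >= 1")
  check_arg(n_blocks >= 1, "n_blocks must be >= 1")
  elig <- check_eligibility(profile)
  if (!elig$eligible) {
    stop_choicerep("eligibility_error",
                   "profile is not eligible: need >= 2 feasible distances for each bias type")
  }
  maybe_seed(rng_seed)

  r_star <- profile$r_star
  feas <- list(bias_SN = elig$sn_feasible_distances,
               bias_LF = elig$lf_feasible_distances)

  if (length(feas$bias_SN) == 0 || length(feas$bias_LF) == 0) {
    stop_choicerep("internal_error", "empty feasible distance set")
  }
  blocks <- lapply(seq_len(n_blocks), function(b) {
    n_tri <- as.integer(n_triplets_per_block)
    n_trials <- 3L * n_tri
    bias_type <- sample(c("bias_SN", "bias_LF"), n_tri, replace = TRUE)

    # distances: two bias draws from the type's feasible set, one target draw
    d_sn_set <- feas$bias_SN
    d_lf_set <- feas$bias_LF
    d_bias1 <- ifelse(bias_type == "bias_SN",
                      d_sn_set[sample.int(length(d_sn_set), n_tri, replace = TRUE)],
                      d_lf_set[sample.int(length(d_lf_set), n_tri, replace = TRUE)])
    d_bias2 <- ifelse(bias_type == "bias_SN",
                      d_sn_set[sample.int(length(d_sn_set), n_tri, replace = TRUE)],
                      d_lf_set[sample.int(length(d_lf_set), n_tri, replace = TRUE)])
    d_tgt <- sample.int(12L, n_tri, replace = TRUE)

    extra <- as.integer(rbind(d_bias1, d_bias2, d_tgt))
    shift <- rep(ifelse(bias_type == "bias_SN", 0.30, -0.30), each = 3L)
    shift[seq(3L, n_trials, by = 3L)] <- 0  # targets sit at r*
    ratio <- r_star[extra] + shift
    lf <- sample(seq(lf_range[1], lf_range[2]), n_trials, replace = TRUE)
    sn <- as.integer(clamp(round_half_up(ratio * lf), 1L, lf - 1L))

    # ITI before trials 1 and 2: {500, 1500} shuffled; before target: 500
    first_long <- sample(c(TRUE, FALSE), n_tri, replace = TRUE)
    iti <- as.numeric(rbind(ifelse(first_long, 1500, 500),
                            ifelse(first_long, 500, 1500),
                            rep(500, n_tri)))
    iti[1] <- NA_real_  # block-initial trial has no ITI

    out <- data.frame(
      triplet_id = rep(sprintf("b%d_t%03d", b, seq_len(n_tri)), each = 3L),
      role = as.character(rbind(bias_type, bias_type, "target")),
      sn_distance = sample(c(2L, 3L), n_trials, replace = TRUE),
      extra_distance = extra,
      sn_value = sn,
      lf_value = lf,
      ratio = sn / lf,
      iti_before_ms = iti,
      stringsAsFactors = FALSE
    )
    out$block <- b
    out$trial_index <- seq_len(n_trials)
    out
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out[, c("block", "trial_index", "triplet_id", "role", "sn_distance",
          "extra_distance", "sn_value", "lf_value", "ratio", "iti_before_ms")]
}

#' Counterbalanced session plans
#'
#' Assigns each participant one of four counterbalancing scenarios. Each
#' session has 5 blocks: block 1 is the measurement block (sham), blocks 2--5
#' are experimental with real stimulation in two contiguous blocks (2--3 or
#' 4--5) and sham in the other two. Across a participant's two sessions the
#' sham/real order flips and the real polarity switches between anodal and
#' cathodal; across the cohort the four scenarios are cycled so that half the
#' participants receive anodal in session 1.
#'
#' @param n_participants cohort size; a warning is emitted when not a
#'   multiple of 4 (scenario counts then differ by one).
#' @return data frame with one row per participant, session and block:
#'   `participant_id`, `session`, `scenario`, `block`, `block_type`
#'   (`measurement`/`experimental`), `stim` (`sham`/`anodal`/`cathodal`) and
#'   `sham_order` (`sham_first`/`sham_second`, constant within a session).
#' @examples
#' plans <- make_session_plans(4)
#' subset(plans, participant_id == 1 & session == 1)
#' @export
make_session_plans <- function(n_participants) {
  check_arg(is.numeric(n_participants) && length(n_participants) == 1 &&
              is.finite(n_participants) && n_participants >= 1,
            "n_participants must be a single integer >= 1")
  n_participants <- as.integer(n_participants)
  if (n_participants %% 4L != 0L) {
    warning("n_participants is not a multiple of 4; scenarios are not exactly balanced")
  }
  # scenario -> (session 1 real position, session 1 polarity); session 2 flips both
  scen <- data.frame(
    scenario = 1:4,
    s1_real_late = c(FALSE, FALSE, TRUE, TRUE),  # real during blocks 4-5?
    s1_polarity = c("anodal", "cathodal", "anodal", "cathodal"),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(n_participants), function(p) {
    sc <- scen[((p - 1L) %% 4L) + 1L, ]
    per_session <- function(session) {
      real_late <- if (session == 1) sc$s1_real_late else !sc$s1_real_late
      polarity <- if (session == 1) sc$s1_polarity else
        setdiff(c("anodal", "cathodal"), sc$s1_polarity)
      stim <- rep("sham", 5L)
      stim[if (real_late) 4:5 else 2:3] <- polarity
      data.frame(
        participant_id = p, session = session, scenario = sc$scenario,
        block = 1:5,
        block_type = c("measurement", rep("experimental", 4L)),
        stim = stim,
        sham_order = if (real_late) "sham_first" else "sham_second",
        stringsAsFactors = FALSE
      )
    }
    rbind(per_session(1L), per_session(2L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Place the two coins on the game grid
#'
#' Realizes a trial on the 20 x 20 field grid: the SN coin is placed at
#' city-block (Manhattan) distance `sn_distance` from the avatar and the LF
#' coin at `sn_distance + extra_distance`, with the two avatar-to-coin
#' vectors at least 90 degrees apart so that walking toward one coin moves
#' the avatar away from the other. Movement is between horizontally or
#' vertically adjacent fields, so path length equals Manhattan distance.
#'
#' @param trial one trial specification row (needs `sn_distance`,
#'   `extra_distance`).
#' @param avatar_position integer vector `c(x, y)` inside the grid (1--20).
#' @param rng_seed optional integer seed.
#' @param grid_size side length of the square grid.
#' @return list with integer coordinate vectors `sn` and `lf`.
#' @export
realize_on_grid <- function(trial, avatar_position, rng_seed = NULL,
                            grid_size = 20L) {
  check_arg(length(avatar_position) == 2 &&
              all(avatar_position >= 1 & avatar_position <= grid_size),
            "avatar_position must be c(x, y) inside the grid")
  maybe_seed(rng_seed)
  ax <- as.integer(avatar_position[1]); ay <- as.integer(avatar_position[2])
  d_sn <- as.integer(trial$sn_distance[1])
  d_lf <- d_sn + as.integer(trial$extra_distance[1])

  cells_at <- function(d) {
    # all grid cells at Manhattan distance d from the avatar
    dx <- seq(-d, d)
    dy <- d - abs(dx)
    pts <- rbind(cbind(ax + dx, ay + dy),
                 cbind(ax + dx[dy > 0], ay - dy[dy > 0]))
    ok <- pts[, 1] >= 1 & pts[, 1] <= grid_size &
      pts[, 2] >= 1 & pts[, 2] <= grid_size
    pts[ok, , drop = FALSE]
  }
  sn_cells <- cells_at(d_sn)
  lf_cells <- cells_at(d_lf)
  if (nrow(sn_cells) == 0 || nrow(lf_cells) == 0) {
    stop_choicerep("placement_error", "no grid cell at the required distance")
  }
  v_lf <- cbind(lf_cells[, 1] - ax, lf_cells[, 2] - ay)
  for (i in sample.int(nrow(sn_cells))) {
    v_sn <- c(sn_cells[i, 1] - ax, sn_cells[i, 2] - ay)
    dots <- v_lf[, 1] * v_sn[1] + v_lf[, 2] * v_sn[2]
    ok <- which(dots <= 0)  # angle >= 90 degrees
    if (length(ok) > 0) {
      j <- ok[sample.int(length(ok), 1L)]
      return(list(sn = as.integer(sn_cells[i, ]),
                  lf = as.integer(lf_cells[j, ])))
    }
  }
  stop_choicerep("placement_error",
                 "no coin placement satisfies the distance and angle constraints; re-draw the avatar position")
}
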