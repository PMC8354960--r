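#' Fit a logistic psychometric function to choices at one distance
#'
#' Maximum-likelihood logistic regression of the probability of choosing the
#' large/far (LF) option on the SN/LF value ratio, for trials sharing one
#' extra distance. The fitted midpoint — the ratio at which P(LF) = 0.5 — is
#' the indifference point for that distance. Degenerate data (all choices on
#' one side, or perfect separation) are flagged `converged = FALSE` and the
#' midpoint is clipped into [0.05, 0.95]: all-LF data clip to 0.95 (the
#' player tolerates even the steepest ratios), all-SN data to 0.05.
#'
#' @param records data frame of choice records with columns `ratio`,
#'   `choice` (`"SN"`/`"LF"`) and `extra_distance`; at least 10 rows, all at
#'   the same extra distance.
#' @return object of class `psychometric_fit`: list with `midpoint`, `slope`
#'   (on the logit scale; negative when higher SN value means fewer LF
#'   choices), `n_trials` and `converged`.
#' @export
fit_psychometric <- function(records) {
  if (nrow(records) < 10) {
    stop_choicerep("insufficient_data_error",
                   sprintf("need >= 10 records to fit a psychometric function, got %d",
                           nrow(records)))
  }
  if (length(unique(records$extra_distance)) != 1) {
    stop_choicerep("argument_error",
                   "records mix several extra distances; fit one distance at a time")
  }
  check_arg(all(records$choice %in% c("SN", "LF")), "choices must be coded SN/LF")
  check_arg(all(records$ratio > 0 & records$ratio < 1), "ratios must lie in (0,1)")

  y <- as.integer(records$choice == "LF")
  n <- length(y)
  out <- list(midpoint = NA_real_, slope = NA_real_, n_trials = n,
              converged = FALSE)

  if (all(y == 1L)) {
    out$midpoint <- 0.95
    out$slope <- -Inf
  } else if (all(y == 0L)) {
    out$midpoint <- 0.05
    out$slope <- Inf
  } else {
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ratio, family = binomial(), data = records),
      warning = function(w) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    b <- coef(fit)
    midpoint <- unname(-b[1] / b[2])
    out$slope <- unname(b[2])
    out$midpoint <- clamp(midpoint, 0.05, 0.95)
    out$converged <- fit$converged && !separated && is.finite(midpoint) &&
      out$slope < 0 && midpoint >= 0.05 && midpoint <= 0.95
  }
  structure(out, class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("psychometric fit: midpoint %.3f, slope %.2f, n = %d%s\n",
              x$midpoint, x$slope, x$n_trials,
              if (x$converged) "" else " (degenerate)"))
  invisible(x)
}

#' Construct an indifference profile from known values
#'
#' Builds an `indifference_profile` directly from per-distance indifference
#' ratios, e.g. the analytic profile of a hyperbolic discounter
#' ([indifference_ratio]) when ground truth is needed.
#'
#' @param r_star numeric vector of length 12 (distances 1--12), values in
#'   (0, 1); clipped to [0.05, 0.95].
#' @param anchor_distances distances regarded as directly estimated.
#' @export
indifference_profile <- function(r_star, anchor_distances = c(1L, 4L, 8L, 12L)) {
  check_arg(length(r_star) == 12 && all(is.finite(r_star)),
            "r_star must be 12 finite values (distances 1..12)")
  r <- clamp(as.numeric(r_star), 0.05, 0.95)
  names(r) <- 1:12
  structure(
    list(r_star = r, anchor_distances = anchor_distances,
         degenerate = setNames(rep(FALSE, 12), 1:12), fits = NULL),
    class = "indifference_profile"
  )
}

#' Estimate a per-distance indifference-point profile
#'
#' Fits psychometric functions at the four anchor distances used in the
#' measurement block (1, 4, 8, 12 extra fields) and linearly interpolates
#' the indifference points for the remaining distances 1--12. All values are
#' clipped to [0.05, 0.95]. Degenerate anchor fits are flagged, and
#' interpolated distances inherit the flag from a flagged bounding anchor.
#'
#' @param records measurement-block choice records (columns `ratio`,
#'   `choice`, `extra_distance`) containing all four anchor distances.
#' @param anchor_distances the directly estimated distances.
#' @return object of class `indifference_profile`: list with `r_star`
#'   (named numeric, distances 1--12), `anchor_distances`, `degenerate`
#'   (logical, per distance) and `fits` (the four anchor fits).
#' @export
estimate_indifference_profile <- function(records,
                                          anchor_distances = c(1L, 4L, 8L, 12L)) {
  missing_d <- setdiff(anchor_distances, unique(records$extra_distance))
  if (length(missing_d) > 0) {
    stop_choicerep("insufficient_data_error",
                   sprintf("measurement records are missing anchor distance(s): %s",
                           paste(missing_d, collapse = ", ")))
  }
  fits <- lapply(anchor_distances, function(d) {
    fit_psychometric(records[records$extra_distance == d, , drop = FALSE])
  })
  names(fits) <- paste0("d", anchor_distances)
  anchors <- vapply(fits, `[[`, numeric(1), "midpoint")
  flags <- !vapply(fits, `[[`, logical(1), "converged")

  d_all <- 1:12
  r_star <- approx(anchor_distances, anchors, xout = d_all, rule = 2)$y
  r_star <- clamp(r_star, 0.05, 0.95)
  names(r_star) <- d_all

  # interpolants inherit degeneracy from a flagged bounding anchor
  degenerate <- vapply(d_all, function(d) {
    lo <- max(anchor_distances[anchor_distances <= d])
    hi <- min(anchor_distances[anchor_distances >= d])
    any(flags[anchor_distances %in% c(lo, hi)])
  }, logical(1))
  names(degenerate) <- d_all

  structure(
    list(r_star = r_star, anchor_distances = anchor_distances,
         degenerate = degenerate, fits = fits),
    class = "indifference_profile"
  )
}

#' @export
print.indifference_profile <- function(x, ...) {
  cat("indifference profile (r* by extra distance):\n")
  print(round(x$r_star, 3))
  if (any(x$degenerate)) {
    cat("degenerate at:", paste(names(x$r_star)[x$degenerate], collapse = " "), "\n")
  }
  invisible(x)
}

#' Screen a player's discounting for experimental eligibility
#'
#' A bias trial shifts the SN/LF value ratio 0.30 above or below the
#' indifference point, so SN-bias trials are only constructible at distances
#' where r*(d) < 0.7 and LF-bias trials where r*(d) > 0.3. Players whose
#' discounting leaves fewer than two feasible distances for either bias type
#' cannot be run in the experimental blocks and are excluded after the
#' measurement block.
#'
#' @param profile an [indifference_profile].
#' @return object of class `eligibility_report`: list with `eligible`,
#'   `sn_feasible_distances` and `lf_feasible_distances`.
#' @examples
#' prof <- structure(list(r_star = setNames(rep(0.5, 12), 1:12)),
#'                   class = "indifference_profile")
#' check_eligibility(prof)
#' @export
check_eligibility <- function(profile) {
  stopifnot(inherits(profile, "indifference_profile"))
  r <- profile$r_star
  sn_feasible <- as.integer(names(r))[r < 0.7]
  lf_feasible <- as.integer(names(r))[r > 0.3]
  structure(
    list(eligible = length(sn_feasible) >= 2 && length(lf_feasible) >= 2,
         sn_feasible_distances = sn_feasible,
         lf_feasible_distances = lf_feasible),
    class = "eligibility_report"
  )
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("eligible: %s (SN-feasible: %d distances, LF-feasible: %d distances)\n",
              x$eligible, length(x$sn_feasible_distances),
              length(x$lf_feasible_distances)))
  invisible(x)
}
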