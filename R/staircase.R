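#' Weighted up-down staircase configuration
#'
#' A single staircase run targeting one point of the psychometric function:
#' after a "comparison longer" response the comparison decreases by
#' `step_down`, otherwise it increases by `step_up`. Zero drift at the target
#' probability `p` requires `p * step_down = (1 - p) * step_up`, i.e.
#' `step_up / step_down = p / (1 - p)` — the 3:1 ratio for `p = .75` and
#' 1:3 for `p = .25`. If only `base_step` is given, the smaller of the two
#' steps equals it and the other is derived from the target.
#'
#' Dialect options reproduce bias-prone variants found in adaptive
#' duration-discrimination studies: a hard floor at 0 ms (the physical
#' limit), optional ceiling, a prohibition of the comparison crossing the
#' standard (the run stays strictly on its starting side), and estimation
#' from either the reversal values or the comparison values of the last `k`
#' trials.
#'
#' @param target_p Targeted probability of "comparison longer" (.25 for the
#'   lower run, .75 for the upper run).
#' @param standard Standard duration (ms).
#' @param start_c Starting comparison value (ms).
#' @param base_step Magnitude of the smaller step (ms); used when explicit
#'   steps are not given.
#' @param step_down,step_up Explicit step sizes (ms); both must be > 0.
#' @param n_trials Number of staircase trials.
#' @param floor Lowest admissible comparison (ms); default 0, the physical
#'   limit. `-Inf` disables it.
#' @param ceiling Highest admissible comparison, or `NULL` for none.
#' @param forbid_crossing_standard If `TRUE`, the comparison is clamped to
#'   its starting side of the standard, at a distance of at least
#'   `cross_margin`.
#' @param cross_margin Minimal distance to the standard (ms) when crossing is
#'   forbidden.
#' @param estimator `"last_k_mean"` (mean comparison over the last `k`
#'   trials) or `"reversal_mean"`.
#' @param k Number of trailing trials for `last_k_mean`.
#' @return A `staircase_config`.
#' @export
staircase_config <- function(target_p, standard, start_c, base_step = 5,
                             step_down = NULL, step_up = NULL,
                             n_trials = 60, floor = 0, ceiling = NULL,
                             forbid_crossing_standard = FALSE,
                             cross_margin = 1,
                             estimator = c("last_k_mean", "reversal_mean"),
                             k = 20) {
  estimator <- match.arg(estimator)
  stopifnot(is.numeric(target_p), length(target_p) == 1L,
            target_p > 0, target_p < 1,
            is.numeric(standard), is.numeric(start_c), n_trials >= 1)
  ratio <- target_p / (1 - target_p)  # step_up / step_down at equilibrium
  if (is.null(step_down) && is.null(step_up)) {
    if (ratio >= 1) { step_down <- base_step; step_up <- base_step * ratio }
    else { step_up <- base_step; step_down <- base_step / ratio }
  } else if (is.null(step_up)) {
    step_up <- step_down * ratio
  } else if (is.null(step_down)) {
    step_down <- step_up / ratio
  }
  if (step_down <= 0 || step_up <= 0) stop("staircase_config: step sizes must be > 0")
  if (is.finite(floor) && floor > start_c) stop("staircase_config: floor must be <= start_c")
  if (estimator == "last_k_mean" && n_trials < k) {
    stop("staircase_config: n_trials must be >= k for the last-k estimator")
  }
  side <- if (start_c < standard) "lower" else "upper"
  structure(list(target_p = target_p, standard = standard, start_c = start_c,
                 step_down = step_down, step_up = step_up,
                 n_trials = as.integer(n_trials), floor = floor,
                 ceiling = ceiling,
                 forbid_crossing_standard = isTRUE(forbid_crossing_standard),
                 cross_margin = cross_margin, side = side,
                 estimator = estimator, k = as.integer(k)),
            class = "staircase_config")
}

#' One step of the weighted up-down rule
#'
#' @param current_c Current comparison value (ms).
#' @param response_c_longer Was the comparison judged longer?
#' @param config A [staircase_config()].
#' @return The next comparison value, after applying floor/ceiling and (if
#'   enabled) the crossing prohibition.
#' @export
staircase_step <- function(current_c, response_c_longer, config) {
  stopifnot(inherits(config, "staircase_config"))
  nxt <- if (isTRUE(response_c_longer)) current_c - config$step_down
         else current_c + config$step_up
  if (config$forbid_crossing_standard) {
    if (config$side == "lower") {
      nxt <- min(nxt, config$standard - config$cross_margin)
    } else {
      nxt <- max(nxt, config$standard + config$cross_margin)
    }
  }
  if (!is.null(config$ceiling)) nxt <- min(nxt, config$ceiling)
  max(nxt, config$floor)
}

#' Run a weighted up-down staircase against a simulated observer
#'
#' Presents `n_trials` two-interval trials in the given stimulus order, with
#' the comparison driven by the up-down rule. For an IRM observer the
#' reference state is threaded through the run and returned, so that blocked
#' runs within a session can share one evolving reference (pass the returned
#' `state` as the next block's `state`).
#'
#' The threshold estimate is the mean comparison over the last `k` trials or
#' over the reversal values; with no reversals the reversal-mean estimate is
#' flagged invalid (`valid = FALSE`, estimate `NA`).
#'
#' Uses the ambient RNG stream.
#'
#' @param config A [staircase_config()].
#' @param observer A `typeb_observer`.
#' @param order `"sc"` or `"cs"`.
#' @param isi Optional ISI label (ms), recorded only.
#' @param state Optional incoming [irm_state()] for IRM observers.
#' @return A `staircase_run`: list with `config`, `order`, `c_sequence`,
#'   `responses`, `reversals` (indices), `estimate`, `valid`, `state`.
#' @export
run_staircase <- function(config, observer, order = c("sc", "cs"),
                          isi = NULL, state = NULL) {
  order <- match.arg(order)
  stopifnot(inherits(config, "staircase_config"),
            inherits(observer, "typeb_observer"))
  is_irm <- inherits(observer, "irm_observer")
  if (is_irm && is.null(state)) {
    state <- switch(observer$i0_policy,
                    first_sensation = irm_state(),
                    standard_mean = irm_state(config$standard))
  }
  n <- config$n_trials
  c_seq <- numeric(n)
  resp <- logical(n)
  cur <- config$start_c
  s <- config$standard
  for (i in seq_len(n)) {
    c_seq[i] <- cur
    d1 <- if (order == "sc") s else cur
    d2 <- if (order == "sc") cur else s
    x1 <- perceive(d1, observer$noise)
    x2 <- perceive(d2, observer$noise)
    if (is_irm) {
      state <- irm_update(state, x1, observer$g)
      out <- irm_decide(state, x2, observer$gamma)
    } else if (inherits(observer, "swm_observer")) {
      obs <- observer
      if (is.null(obs$r1)) obs$r1 <- s
      if (is.null(obs$r2)) obs$r2 <- s
      out <- swm_decide(x1, x2, obs)
    } else {
      out <- difference_decide(x1, x2, observer$gamma)
    }
    resp[i] <- if (order == "sc") !out$first_judged_longer else out$first_judged_longer
    cur <- staircase_step(cur, resp[i], config)
  }
  # A reversal is a trial whose intended direction differs from the previous
  # trial's ("c longer" = down, otherwise up).
  dir <- ifelse(resp, -1L, 1L)
  reversals <- which(c(FALSE, dir[-1] != dir[-n]))
  if (config$estimator == "last_k_mean") {
    estimate <- mean(utils::tail(c_seq, config$k))
    valid <- TRUE
  } else {
    valid <- length(reversals) > 0
    estimate <- if (valid) mean(c_seq[reversals]) else NA_real_
  }
  structure(list(config = config, order = order, isi = isi,
                 c_sequence = c_seq, responses = resp, reversals = reversals,
                 estimate = estimate, valid = valid, state = state),
            class = "staircase_run")
}

#' DL from a pair of staircase runs
#'
#' `DL = (c_hat_.75 - c_hat_.25) / 2`, half the difference between the upper
#' and lower run estimates. Degenerate runs (e.g. a lower run pinned at the
#' 0 ms floor) can make this negative or inflated relative to the true DL;
#' that is the measurement artifact under study, not an error.
#'
#' @param upper Upper-run (`target_p = .75`) `staircase_run`.
#' @param lower Lower-run (`target_p = .25`) `staircase_run`.
#' @return DL estimate in ms.
#' @export
staircase_dl <- function(upper, lower) {
  stopifnot(inherits(upper, "staircase_run"), inherits(lower, "staircase_run"))
  if (!upper$valid || !lower$valid) {
    stop("staircase_dl: invalid run estimate (no reversals?)")
  }
  (upper$estimate - lower$estimate) / 2
}
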