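#' Sensory noise specification
#'
#' Dispersion of the latent sensation magnitudes. The standard deviation of
#' the perceived duration of a physical duration `d` (in ms) is
#' `sigma(d) = sigma0 + weber * d`, i.e. a constant floor plus Weber-law
#' scaling. Weber scaling keeps Weber fractions comparable across the short
#' (80 ms) and long (500 ms) duration regimes.
#'
#' @param sigma0 Baseline sensation SD in ms (>= 0).
#' @param weber Dimensionless Weber slope (>= 0).
#' @return An object of class `noise_spec`.
#' @examples
#' ns <- noise_spec(sigma0 = 5, weber = 0.1)
#' sigma_at(ns, 500)  # 55
#' @export
noise_spec <- function(sigma0 = 0, weber = 0) {
  stopifnot(is.numeric(sigma0), length(sigma0) == 1L, is.finite(sigma0),
            is.numeric(weber), length(weber) == 1L, is.finite(weber))
  if (sigma0 < 0 || weber < 0) {
    stop("noise_spec: 'sigma0' and 'weber' must be non-negative")
  }
  structure(list(sigma0 = sigma0, weber = weber), class = "noise_spec")
}

#' @rdname noise_spec
#' @param noise A `noise_spec`.
#' @param duration Physical duration(s) in ms.
#' @export
sigma_at <- function(noise, duration) {
  stopifnot(inherits(noise, "noise_spec"))
  noise$sigma0 + noise$weber * duration
}

#' Draw latent sensations for physical durations
#'
#' Realizes the perceived durations X as normal draws with mean equal to the
#' physical duration and SD given by the noise specification. Draws are not
#' truncated at zero: negative values are legitimate latent magnitudes, and a
#' truncation would silently distort short-duration simulations. Any floor at
#' 0 ms belongs to the physical stimulus values (see the staircase engine),
#' not to sensations.
#'
#' @param duration Physical duration(s) in ms (>= 0).
#' @param noise A [noise_spec()].
#' @return Numeric vector of sensations (ms), one per duration.
#' @export
perceive <- function(duration, noise) {
  stopifnot(is.numeric(duration))
  if (any(duration < 0)) stop("perceive: durations must be >= 0")
  stats::rnorm(length(duration), mean = duration, sd = sigma_at(noise, duration))
}

new_observer <- function(fields, subclass) {
  structure(fields, class = c(subclass, "typeb_observer"))
}

#' Difference-model observer
#'
#' The Thurstonian baseline: the decision variable is the plain difference of
#' the two perceived durations, `D = X1 - X2`, compared against a criterion
#' `gamma`. The first stimulus is judged longer iff `D > gamma`; `gamma = 0`
#' is unbiased discrimination. Under this model the psychometric functions
#' for the two stimulus orders differ in location by `2 * gamma` but have
#' identical shape, so the DL cannot depend on stimulus order.
#'
#' @param gamma Decision criterion in ms.
#' @param noise A [noise_spec()].
#' @return A `difference_observer`.
#' @export
difference_observer <- function(gamma = 0, noise = noise_spec()) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            inherits(noise, "noise_spec"))
  new_observer(list(gamma = gamma, noise = noise), "difference_observer")
}

#' Internal-reference-model (IRM) observer
#'
#' The perceived duration of the second stimulus is compared against an
#' internal reference `I` rather than the first sensation itself. The
#' reference is updated every trial as a weighted mix of its previous value
#' and the current first sensation, `I[n] = g * I[n-1] + (1 - g) * X1[n]`,
#' with updating weight `g` in `[0, 1)` giving the relative contribution of
#' the stimulus history. `g = 0` reduces the model to the difference model;
#' `g > 0` produces negative Type B effects (better sensitivity when the
#' standard leads), and the model cannot produce positive ones.
#'
#' @param g Reference-updating weight in `[0, 1)`.
#' @param gamma Decision criterion in ms.
#' @param noise A [noise_spec()].
#' @param i0_policy How the reference is initialized on the very first trial
#'   of a regime: `"first_sensation"` (no history: `I[1] = X1[1]`) or
#'   `"standard_mean"` (`I[0]` set to the standard duration).
#' @return An `irm_observer`.
#' @export
irm_observer <- function(g, gamma = 0, noise = noise_spec(),
                         i0_policy = c("first_sensation", "standard_mean")) {
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            inherits(noise, "noise_spec"))
  if (g < 0 || g >= 1) stop("irm_observer: 'g' must lie in [0, 1)")
  i0_policy <- match.arg(i0_policy)
  new_observer(list(g = g, gamma = gamma, noise = noise,
                    i0_policy = i0_policy), "irm_observer")
}

#' Sensation-weighting-model (SWM) observer
#'
#' Each sensation enters the decision variable as a weighted compromise with
#' its own reference level:
#' `D = [s1 X1 + (1 - s1) R1] - [s2 X2 + (1 - s2) R2]`.
#' A weight below 1 draws the effective magnitude toward its reference
#' (assimilation), above 1 pushes it away (contrast). The sign of the Type B
#' effect follows `sign(s1 - s2)`: stronger weighting of the second stimulus
#' (`s1 < s2`) gives a negative effect, equal weights a null effect, stronger
#' weighting of the first stimulus a positive effect.
#'
#' @param s1,s2 Non-negative sensation weights for the first and second
#'   stimulus.
#' @param r1,r2 Reference levels in ms. `NULL` means "resolve to the standard
#'   duration of the condition" at simulation time; the reference levels are
#'   fixed constants within a condition.
#' @param gamma Decision criterion in ms.
#' @param noise A [noise_spec()].
#' @return An `swm_observer`.
#' @export
swm_observer <- function(s1, s2, r1 = NULL, r2 = NULL, gamma = 0,
                         noise = noise_spec()) {
  stopifnot(is.numeric(s1), length(s1) == 1L, is.finite(s1),
            is.numeric(s2), length(s2) == 1L, is.finite(s2),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            inherits(noise, "noise_spec"))
  if (s1 < 0 || s2 < 0) stop("swm_observer: weights must be non-negative")
  for (r in list(r1, r2)) {
    if (!is.null(r)) stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  }
  new_observer(list(s1 = s1, s2 = s2, r1 = r1, r2 = r2, gamma = gamma,
                    noise = noise), "swm_observer")
}

#' Internal reference state
#'
#' Running state of the IRM reference across trials. A reference of `NA`
#' denotes "not yet initialized" under the `first_sensation` policy; the
#' first update then sets it to the first sensation of trial 1.
#'
#' @param reference Current internal reference in ms (or `NA` before trial 1).
#' @param trial_index Number of updates applied so far.
#' @return An `irm_state`.
#' @export
irm_state <- function(reference = NA_real_, trial_index = 0L) {
  stopifnot(length(reference) == 1L, is.numeric(reference) || is.na(reference),
            length(trial_index) == 1L, trial_index >= 0)
  structure(list(reference = as.numeric(reference),
                 trial_index = as.integer(trial_index)),
            class = "irm_state")
}

#' Update the internal reference with the first sensation of a trial
#'
#' Applies `I[n] = g * I[n-1] + (1 - g) * X1[n]`. With an uninitialized state
#' (reference `NA`) the reference is set to `x1` itself, i.e. trial 1 carries
#' no history.
#'
#' @param state An [irm_state()].
#' @param x1 Perceived duration of the first stimulus (ms).
#' @param g Updating weight in `[0, 1)`.
#' @return The updated `irm_state` (reference replaced, trial index + 1).
#' @export
irm_update <- function(state, x1, g) {
  stopifnot(inherits(state, "irm_state"),
            is.numeric(x1), length(x1) == 1L, is.finite(x1))
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0 || g >= 1) {
    stop("irm_update: 'g' must lie in [0, 1)")
  }
  new_ref <- if (is.na(state$reference)) x1 else g * state$reference + (1 - g) * x1
  irm_state(new_ref, state$trial_index + 1L)
}

decision_outcome <- function(d_value, gamma) {
  structure(list(d_value = d_value,
                 first_judged_longer = d_value > gamma),
            class = "decision_outcome")
}

#' Decide a trial from the current internal reference
#'
#' The decision variable is `D = I - X2`; the first stimulus is judged longer
#' iff `D > gamma`. Ties (`D == gamma`) go to the second stimulus, matching
#' the comparison rule "first longer iff D > gamma, second otherwise".
#'
#' @param state An initialized [irm_state()].
#' @param x2 Perceived duration of the second stimulus (ms).
#' @param gamma Decision criterion (ms).
#' @return A `decision_outcome` with fields `d_value` and
#'   `first_judged_longer`.
#' @export
irm_decide <- function(state, x2, gamma = 0) {
  stopifnot(inherits(state, "irm_state"))
  if (is.na(state$reference)) {
    stop("irm_decide: reference not initialized; call irm_update() first")
  }
  decision_outcome(state$reference - x2, gamma)
}

#' Decide a trial under the sensation weighting model
#'
#' @param x1,x2 Perceived durations (ms) of the first and second stimulus.
#' @param obs An [swm_observer()] with resolved (non-`NULL`) reference levels.
#' @return A `decision_outcome`.
#' @export
swm_decide <- function(x1, x2, obs) {
  stopifnot(inherits(obs, "swm_observer"))
  if (is.null(obs$r1) || is.null(obs$r2)) {
    stop("swm_decide: reference levels r1/r2 must be resolved to numbers")
  }
  d <- (obs$s1 * x1 + (1 - obs$s1) * obs$r1) -
       (obs$s2 * x2 + (1 - obs$s2) * obs$r2)
  decision_outcome(d, obs$gamma)
}

#' Decide a trial under the plain difference model
#'
#' `D = X1 - X2` against criterion `gamma`; equivalent to [swm_decide()] with
#' `s1 = s2 = 1`.
#'
#' @param x1,x2 Perceived durations (ms).
#' @param gamma Decision criterion (ms).
#' @return A `decision_outcome`.
#' @export
difference_decide <- function(x1, x2, gamma = 0) {
  decision_outcome(x1 - x2, gamma)
}

#' Closed-form psychometric function of the difference model
#'
#' Probability of judging the comparison longer than the standard as a
#' function of the comparison duration, for a given stimulus order. With
#' normal sensation noise the difference model gives
#' `P_sc(c) = Phi((c - s + gamma) / sqrt(sigma(s)^2 + sigma(c)^2))` for order
#' standard-first and the same expression with `-gamma` for comparison-first,
#' so the two functions differ in location by `2 * gamma` but share their
#' shape. With zero total noise a step function is returned (not an error).
#'
#' @param s Standard duration (ms).
#' @param c_ Comparison duration(s) (ms).
#' @param order `"sc"` (standard first) or `"cs"` (comparison first).
#' @param obs A [difference_observer()].
#' @return `P("c judged longer")`, vectorized over `c_`.
#' @export
difference_psychometric <- function(s, c_, order = c("sc", "cs"), obs) {
  order <- match.arg(order)
  stopifnot(inherits(obs, "difference_observer"))
  sig <- sqrt(sigma_at(obs$noise, s)^2 + sigma_at(obs$noise, c_)^2)
  shift <- if (order == "sc") obs$gamma else -obs$gamma
  z <- c_ - s + shift
  out <- ifelse(sig > 0, stats::pnorm(z / ifelse(sig > 0, sig, 1)),
                as.numeric(z >= 0))
  # sig == 0, z == 0: deterministic tie; the comparison is the "other"
  # stimulus, and D == gamma judges the second stimulus longer.
  tie <- sig == 0 & z == 0
  if (any(tie)) out[tie] <- as.numeric(order == "sc")
  out
}
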