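#' Aggregate trial records into a psychometric table
#'
#' Counts "comparison judged longer" responses per (stimulus order,
#' comparison level) cell. All records must come from a single regime (one
#' standard duration); mixed regimes are rejected.
#'
#' @param records Data frame of response records (from
#'   [run_constant_stimuli()] or [read_trials()]).
#' @return A `psychometric_table`: data frame with columns `order`,
#'   `comparison`, `n_trials`, `n_c_longer`, carrying the standard and
#'   condition labels as attributes.
#' @export
aggregate_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("aggregate_records: no records")
  }
  needed <- c("order", "standard", "comparison", "response_c_longer")
  if (!all(needed %in% names(records))) {
    stop("aggregate_records: records lack columns ",
         paste(setdiff(needed, names(records)), collapse = ", "))
  }
  if (length(unique(records$standard)) != 1L) {
    stop("aggregate_records: mixed regimes (multiple standard durations)")
  }
  levels_grid <- expand.grid(order = sort(unique(records$order)),
                             comparison = sort(unique(records$comparison)),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(records$order, records$comparison)
  gkey <- paste(levels_grid$order, levels_grid$comparison)
  levels_grid$n_trials <- as.integer(table(factor(key, levels = gkey)))
  sums <- tapply(records$response_c_longer, factor(key, levels = gkey), sum)
  levels_grid$n_c_longer <- as.integer(ifelse(is.na(sums), 0L, sums))
  structure(levels_grid,
            standard = records$standard[1],
            isi = if ("isi" %in% names(records)) records$isi[1] else NA,
            stimulus_type = if ("stimulus_type" %in% names(records))
              records$stimulus_type[1] else NA,
            class = c("psychometric_table", "data.frame"))
}

#' Weighted pool-adjacent-violators monotonization
#'
#' Least-squares isotonic regression: returns the non-decreasing sequence
#' minimizing the weighted squared distance to the input. Within every
#' pooled block the output equals the weighted mean of the inputs; the
#' operation is idempotent and conserves the overall weighted mean. Trial
#' counts are the natural weights for response proportions.
#'
#' @param p Numeric vector (e.g. response proportions).
#' @param w Positive weights, same length.
#' @return Monotone (non-decreasing) numeric vector.
#' @export
monotonize <- function(p, w = rep(1, length(p))) {
  stopifnot(is.numeric(p), is.numeric(w), length(p) == length(w), all(w > 0))
  n <- length(p)
  if (n == 0L) return(numeric(0))
  val <- numeric(n); wt <- numeric(n); cnt <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- p[i]; wt[top] <- w[i]; cnt[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      pooled_w <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / pooled_w
      wt[top - 1L] <- pooled_w
      cnt[top - 1L] <- cnt[top - 1L] + cnt[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = cnt[seq_len(top)])
}

# Core Spearman-Kaerber moments on anchored, monotone proportions.
# Mass p[k+1] - p[k] is spread uniformly on (c[k], c[k+1]).
sk_moments <- function(c_pts, p_pts) {
  dp <- diff(p_pts)
  lo <- utils::head(c_pts, -1)
  hi <- utils::tail(c_pts, -1)
  pse <- sum(dp * (lo + hi) / 2)
  m2 <- sum(dp * (lo^2 + lo * hi + hi^2) / 3)
  list(pse = pse, m2 = m2)
}

#' Spearman-Kaerber estimate of PSE, SD, DL and Weber fraction
#'
#' Non-parametric threshold estimation: response proportions are
#' monotonized (weighted pool-adjacent-violators, trial counts as weights),
#' anchored with probability 0 at `anchor_low` and 1 at `anchor_high`
#' (the comparisons at which responding is assumed certain; 0/160 ms for the
#' short regime and 200/800 ms for the long one), and read as a distribution
#' function placing each probability increment uniformly on its comparison
#' interval. The PSE is that distribution's mean, the SD its standard
#' deviation, `DL = qnorm(.75) * SD` (about 0.6745 SD) and `WF = DL /
#' standard`.
#'
#' Estimates with `sd == 0` or a monotonized response range below
#' `flat_range` are flagged `flat` — the "flat psychometric function" case
#' that cohort-level filters act on.
#'
#' @param table A `psychometric_table` from [aggregate_records()].
#' @param order Which stimulus order's function to estimate.
#' @param anchor_low,anchor_high Anchors bracketing the comparison grid
#'   (must satisfy `anchor_low < min(c)` and `anchor_high > max(c)`).
#' @param standard Standard duration (defaults to the table's attribute).
#' @param flat_range Response-range threshold for the `flat` flag.
#' @return An `sk_estimate`: list with `pse`, `sd`, `dl`, `wf`, the anchors,
#'   `order`, `standard`, the monotonized proportions `p_monotone`, their
#'   `response_range` and the `flat` flag.
#' @export
spearman_karber <- function(table, order = c("sc", "cs"), anchor_low,
                            anchor_high, standard = attr(table, "standard"),
                            flat_range = 0) {
  order <- match.arg(order)
  stopifnot(inherits(table, "psychometric_table"),
            is.numeric(anchor_low), is.numeric(anchor_high))
  rows <- table[table$order == order, , drop = FALSE]
  rows <- rows[base::order(rows$comparison), , drop = FALSE]
  if (nrow(rows) == 0) stop("spearman_karber: no rows for order ", order)
  if (any(rows$n_trials == 0)) stop("spearman_karber: empty design cell")
  cl <- rows$comparison
  if (!(anchor_low < min(cl) && anchor_high > max(cl))) {
    stop("spearman_karber: anchors must strictly bracket the comparison grid")
  }
  p <- rows$n_c_longer / rows$n_trials
  p_mono <- monotonize(p, rows$n_trials)
  c_pts <- c(anchor_low, cl, anchor_high)
  p_pts <- c(0, p_mono, 1)
  mom <- sk_moments(c_pts, p_pts)
  sd_ <- sqrt(max(mom$m2 - mom$pse^2, 0))
  dl <- stats::qnorm(0.75) * sd_
  rng <- max(p_mono) - min(p_mono)
  structure(list(order = order, pse = mom$pse, sd = sd_, dl = dl,
                 wf = dl / standard, anchor_low = anchor_low,
                 anchor_high = anchor_high, standard = standard,
                 c_levels = cl, p_monotone = p_mono,
                 response_range = rng,
                 flat = (sd_ == 0) || (rng < flat_range)),
            class = "sk_estimate")
}

#' DL as half the interquartile range of a psychometric function
#'
#' `DL = (c_.75 - c_.25) / 2`. The function may be given as an R function
#' (monotone map from comparison to probability; quartiles are located by
#' bisection on `[lower, upper]`, robust to jumps and plateaus — a step
#' function yields DL 0) or as discrete points (`c_`, `p`), which are then
#' linearly interpolated. If a quartile is not bracketed by the function's
#' range the result is flagged invalid — the flat-function case.
#'
#' @param f A monotone non-decreasing function of comparison duration, or a
#'   numeric vector of probabilities when `c_` is given.
#' @param lower,upper Search interval for the quartiles (function input).
#' @param c_ Comparison grid when `f` is a vector of probabilities.
#' @param tol Bisection tolerance (ms).
#' @return List with `dl`, `c25`, `c75`, `valid`.
#' @export
dl_from_quartiles <- function(f, lower = NULL, upper = NULL, c_ = NULL,
                              tol = 1e-8) {
  if (!is.function(f)) {
    stopifnot(is.numeric(f), is.numeric(c_), length(f) == length(c_))
    ord <- order(c_)
    c_s <- c_[ord]; p_s <- f[ord]
    fun <- stats::approxfun(c_s, p_s, rule = 2, ties = "ordered")
    lower <- min(c_s); upper <- max(c_s)
    f <- fun
  }
  stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  p_lo <- f(lower); p_hi <- f(upper)
  qs <- c(0.25, 0.75)
  if (any(qs < p_lo) || any(qs > p_hi)) {
    return(list(dl = NA_real_, c25 = NA_real_, c75 = NA_real_, valid = FALSE))
  }
  # Smallest c with f(c) >= q, by bisection (monotone f).
  first_crossing <- function(q) {
    lo <- lower; hi <- upper
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) >= q) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  c25 <- first_crossing(0.25)
  c75 <- first_crossing(0.75)
  list(dl = (c75 - c25) / 2, c25 = c25, c75 = c75, valid = TRUE)
}

#' Type B effect from a pair of order-specific estimates
#'
#' The stimulus-order effect on sensitivity: `delta_dl = DL_sc - DL_cs` and
#' the analogous Weber-fraction difference. Negative values mean better
#' discrimination when the standard comes first.
#'
#' @param est_sc,est_cs `sk_estimate`s for orders `"sc"` and `"cs"` of the
#'   same regime.
#' @return A `type_b_effect`: list with `dl_sc`, `dl_cs`, `delta_dl`,
#'   `wf_sc`, `wf_cs`, `delta_wf`.
#' @export
type_b <- function(est_sc, est_cs) {
  stopifnot(inherits(est_sc, "sk_estimate"), inherits(est_cs, "sk_estimate"))
  if (!isTRUE(all.equal(est_sc$standard, est_cs$standard))) {
    stop("type_b: estimates come from different regimes")
  }
  structure(list(dl_sc = est_sc$dl, dl_cs = est_cs$dl,
                 delta_dl = est_sc$dl - est_cs$dl,
                 wf_sc = est_sc$wf, wf_cs = est_cs$wf,
                 delta_wf = est_sc$wf - est_cs$wf,
                 standard = est_sc$standard),
            class = "type_b_effect")
}
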