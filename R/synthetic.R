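#' @keywords internal
default_anchors <- function(standard) {
  if (isTRUE(standard == 80)) return(c(0, 160))
  if (isTRUE(standard == 500)) return(c(200, 800))
  c(0, 2 * standard)
}

# truncated-normal draw by rejection; sd = 0 gives the (clamped) mean
rtrunc1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

default_param_dists <- function(model) {
  base <- list(
    gamma = list(mean = 0, sd = 5, lo = -Inf, hi = Inf),
    sigma0 = list(mean = 2, sd = 0, lo = 0, hi = Inf),
    weber = list(mean = 0.15, sd = 0.05, lo = 0.03, hi = 0.5))
  extra <- switch(model,
    difference = list(),
    irm = list(g = list(mean = 0.4, sd = 0.1, lo = 0, hi = 0.95)),
    swm = list(s1 = list(mean = 0.7, sd = 0.1, lo = 0.05, hi = 2),
               s2 = list(mean = 1.0, sd = 0.1, lo = 0.05, hi = 2)))
  c(base, extra)
}

#' Configuration of a synthetic study cohort
#'
#' Describes one experiment-like cohort: the observer model and the
#' distributions its parameters are drawn from, the experiment preset
#' (crossing ISI 200/900 ms with filled/empty intervals, as in the four
#' experiments E1-E4), and the two duration regimes (80 and 500 ms
#' standards) every observer completes.
#'
#' Parameter distributions are truncated normals given as
#' `list(mean=, sd=, lo=, hi=)`; entries omitted from `parameter_dists` keep
#' their defaults (criterion near 0 ms, sensory noise
#' `sigma(d) = 2 + weber * d` with `weber` centered on 0.15, updating weight
#' `g` centered on 0.4 for the IRM, weights `s1 = 0.7 < s2 = 1.0` for the
#' SWM). ISI and stimulus type are pure labels with no mechanistic effect;
#' scenarios that want an ISI-dependent updating weight must set `g`
#' explicitly per cohort.
#'
#' @param n_observers Number of retained observers (flat-function exclusions
#'   are replaced by fresh draws).
#' @param model `"difference"`, `"irm"`, or `"swm"`.
#' @param preset `"E1"` (filled, ISI 900), `"E2"` (empty, 900),
#'   `"E3"` (filled, 200), `"E4"` (empty, 200).
#' @param parameter_dists Named list overriding the default parameter
#'   distributions.
#' @param standards Duration regimes (standards, ms).
#' @param n_blocks Blocks per regime (preset 20, i.e. 720 trials/regime).
#' @param flat_threshold Monotonized response-range threshold below which an
#'   observer counts as flat in a condition; observers flat in every
#'   condition are excluded and replaced.
#' @param i0_policy Reference initialization for IRM observers.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n_observers = 40,
                          model = c("irm", "difference", "swm"),
                          preset = c("E1", "E2", "E3", "E4"),
                          parameter_dists = list(),
                          standards = c(80, 500),
                          n_blocks = 20,
                          flat_threshold = 0.25,
                          i0_policy = "first_sensation",
                          seed = 1L) {
  model <- match.arg(model)
  preset <- match.arg(preset)
  stopifnot(n_observers >= 2)
  dists <- utils::modifyList(default_param_dists(model), parameter_dists)
  preset_map <- list(E1 = list(isi = 900, stimulus_type = "filled"),
                     E2 = list(isi = 900, stimulus_type = "empty"),
                     E3 = list(isi = 200, stimulus_type = "filled"),
                     E4 = list(isi = 200, stimulus_type = "empty"))
  structure(list(n_observers = as.integer(n_observers), model = model,
                 preset = preset, isi = preset_map[[preset]]$isi,
                 stimulus_type = preset_map[[preset]]$stimulus_type,
                 parameter_dists = dists, standards = standards,
                 n_blocks = as.integer(n_blocks),
                 flat_threshold = flat_threshold,
                 i0_policy = i0_policy, seed = as.integer(seed)),
            class = "cohort_config")
}

draw_observer_params <- function(config) {
  pd <- config$parameter_dists
  draw <- function(name) {
    d <- pd[[name]]
    rtrunc1(d$mean, d$sd, d$lo, d$hi)
  }
  params <- list(gamma = draw("gamma"), sigma0 = draw("sigma0"),
                 weber = draw("weber"))
  if (config$model == "irm") params$g <- draw("g")
  if (config$model == "swm") { params$s1 <- draw("s1"); params$s2 <- draw("s2") }
  params
}

make_observer <- function(config, params) {
  ns <- noise_spec(params$sigma0, params$weber)
  switch(config$model,
         difference = difference_observer(params$gamma, ns),
         irm = irm_observer(params$g, params$gamma, ns,
                            i0_policy = config$i0_policy),
         swm = swm_observer(params$s1, params$s2, gamma = params$gamma,
                            noise = ns))
}

# Simulate one observer through both regimes; returns per-regime estimates.
simulate_observer <- function(config, params, part_order) {
  observer <- make_observer(config, params)
  stds <- if (part_order == "short_first") sort(config$standards)
          else rev(sort(config$standards))
  res <- lapply(stds, function(s) {
    design <- constant_stimuli_design(
      s, c_levels = c_grid(s), n_blocks = config$n_blocks,
      isi = config$isi, stimulus_type = config$stimulus_type)
    trials <- build_design(design)
    records <- run_constant_stimuli(trials, observer, keep_latents = FALSE)
    tab <- aggregate_records(records)
    anc <- default_anchors(s)
    est_sc <- spearman_karber(tab, "sc", anc[1], anc[2])
    est_cs <- spearman_karber(tab, "cs", anc[1], anc[2])
    props <- vapply(c("sc", "cs"), function(o) {
      rr <- tab[tab$order == o, ]
      rr <- rr[base::order(rr$comparison), ]
      rr$n_c_longer / rr$n_trials
    }, numeric(length(design$c_levels)))
    list(standard = s, est_sc = est_sc, est_cs = est_cs,
         tb = type_b(est_sc, est_cs), props = props)
  })
  names(res) <- paste0("s", stds)
  res
}

#' Flat-psychometric-function exclusion flags
#'
#' Flags observers whose monotonized response range (max minus min
#' proportion) stays below `threshold` in every condition — the synthetic
#' analogue of excluding observers with flat psychometric functions across
#' conditions. `threshold = 0` excludes nobody.
#'
#' @param ranges Data frame with columns `observer` and `response_range`
#'   (one row per observer x condition).
#' @param threshold Range threshold in probability units.
#' @return Data frame with columns `observer` and `excluded`.
#' @export
flat_function_filter <- function(ranges, threshold = 0.25) {
  stopifnot(is.data.frame(ranges),
            all(c("observer", "response_range") %in% names(ranges)))
  mx <- tapply(ranges$response_range, ranges$observer, max)
  out <- data.frame(observer = names(mx),
                    excluded = as.vector(mx < threshold),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic cohort and run the analysis battery
#'
#' Draws observer parameters, simulates both duration regimes per observer
#' (part order counterbalanced; the IRM reference is reset between regimes),
#' estimates order-specific psychometric quantities by Spearman-Kaerber, and
#' runs the cohort-level ANOVAs: per regime a two-way
#' (comparison x order) repeated-measures ANOVA on response proportions and
#' a one-way ANOVA on the DL estimates. Observers flat in every condition
#' are excluded and replaced by fresh draws (replacement count reported).
#'
#' @param config A [cohort_config()].
#' @return A `scenario_result`: list with `config`, `estimates` (one row per
#'   retained observer x regime), `proportions` (per regime: observers x
#'   comparisons x orders array), `anovas` (per regime: `two_way`,
#'   `one_way_dl`), `params` (drawn parameters incl. excluded draws),
#'   `n_replaced`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_observers
  keep <- list(); params_log <- list()
  n_replaced <- 0L; draw_id <- 0L
  while (length(keep) < n) {
    draw_id <- draw_id + 1L
    if (draw_id > 50L * n) stop("simulate_cohort: too many flat observers")
    params <- draw_observer_params(config)
    part_order <- if (length(keep) %% 2L == 0L) "short_first" else "long_first"
    obs_res <- simulate_observer(config, params, part_order)
    ranges <- unlist(lapply(obs_res, function(r)
      c(r$est_sc$response_range, r$est_cs$response_range)))
    flat <- all(ranges < config$flat_threshold)
    params_log[[draw_id]] <- c(list(draw = draw_id, excluded = flat), params)
    if (flat) { n_replaced <- n_replaced + 1L; next }
    keep[[length(keep) + 1L]] <- obs_res
  }
  regimes <- paste0("s", sort(config$standards))
  estimates <- do.call(rbind, lapply(seq_along(keep), function(i) {
    do.call(rbind, lapply(keep[[i]], function(r) {
      data.frame(observer = i, standard = r$standard,
                 pse_sc = r$est_sc$pse, pse_cs = r$est_cs$pse,
                 dl_sc = r$tb$dl_sc, dl_cs = r$tb$dl_cs,
                 delta_dl = r$tb$delta_dl,
                 wf_sc = r$tb$wf_sc, wf_cs = r$tb$wf_cs,
                 delta_wf = r$tb$delta_wf)
    }))
  }))
  rownames(estimates) <- NULL
  proportions <- lapply(regimes, function(rg) {
    nlev <- length(keep[[1]][[rg]]$props[, 1])
    arr <- array(NA_real_, dim = c(length(keep), nlev, 2),
                 dimnames = list(NULL, NULL, c("sc", "cs")))
    for (i in seq_along(keep)) arr[i, , ] <- keep[[i]][[rg]]$props
    arr
  })
  names(proportions) <- regimes
  anovas <- lapply(regimes, function(rg) {
    std <- keep[[1]][[rg]]$standard
    dls <- cbind(sc = estimates$dl_sc[estimates$standard == std],
                 cs = estimates$dl_cs[estimates$standard == std])
    list(two_way = rm_anova_2way(proportions[[rg]],
                                 factor_names = c("c", "order")),
         one_way_dl = rm_anova_1way(dls, effect_name = "order"))
  })
  names(anovas) <- regimes
  params_df <- do.call(rbind, lapply(params_log, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  structure(list(config = config, estimates = estimates,
                 proportions = proportions, anovas = anovas,
                 params = params_df, n_replaced = n_replaced),
            class = "scenario_result")
}

#' Staircase-bias simulation study
#'
#' Applies two measurement procedures to the same generative observers: a
#' bias-prone weighted up-down staircase dialect (separate upper/lower runs
#' per stimulus order presented as blocks within one session, a hard floor
#' at 0 ms, optional prohibition of the comparison crossing the standard,
#' threshold = mean comparison of the last `k` trials) and a
#' constant-stimuli session analyzed with Spearman-Kaerber. With a very
#' short standard the lower runs interact with the floor/crossing clamps, so
#' the staircase Type B estimate can come out non-negative even though the
#' generating internal-reference process implies a negative Type B effect —
#' which the constant-stimuli estimate recovers.
#'
#' @param n_observers Number of simulated observers.
#' @param standard Standard duration (ms); the bias-prone case is very short
#'   (e.g. 50 ms).
#' @param c_levels Comparison grid for the constant-stimuli arm.
#' @param anchors Spearman-Kaerber anchors for that grid.
#' @param model `"irm"` or `"difference"`.
#' @param g IRM updating weight.
#' @param gamma Decision criterion (ms).
#' @param noise A [noise_spec()]. The default puts discrimination near
#'   threshold at a 50 ms standard (sigma(50) = 35 ms), the regime in which
#'   lower runs do approach the 0 ms floor; with substantially smaller noise
#'   the floor never binds and the staircase bias shrinks toward zero.
#' @param base_step Small staircase step (ms).
#' @param n_staircase_trials Trials per staircase run.
#' @param start_offset Start distance from the standard (ms).
#' @param floor Comparison floor (ms); `-Inf` disables.
#' @param forbid_crossing_standard Prohibit crossing the standard?
#' @param k Last-k estimator window.
#' @param n_blocks Constant-stimuli blocks (20 = 720 trials).
#' @param i0_policy IRM reference initialization.
#' @param seed Integer seed.
#' @return A `bias_study_result`: list with `per_observer` (paired Type B
#'   estimates) and `summary` (means and SEs of both procedures).
#' @export
bias_study <- function(n_observers = 200, standard = 50,
                       c_levels = seq(10, 90, by = 10), anchors = c(0, 100),
                       model = c("irm", "difference"), g = 0.5, gamma = 0,
                       noise = noise_spec(sigma0 = 5, weber = 0.6),
                       base_step = 5, n_staircase_trials = 60,
                       start_offset = 4 * base_step, floor = 0,
                       forbid_crossing_standard = TRUE, k = 20,
                       n_blocks = 20, i0_policy = "first_sensation",
                       seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  make_obs <- function() {
    if (model == "irm") irm_observer(g, gamma, noise, i0_policy = i0_policy)
    else difference_observer(gamma, noise)
  }
  run_block <- function(observer, ord, side, state) {
    cfg <- staircase_config(
      target_p = if (side == "upper") 0.75 else 0.25,
      standard = standard,
      start_c = standard + if (side == "upper") start_offset else -start_offset,
      base_step = base_step, n_trials = n_staircase_trials, floor = floor,
      forbid_crossing_standard = forbid_crossing_standard,
      estimator = "last_k_mean", k = k)
    run_staircase(cfg, observer, order = ord, state = state)
  }
  rows <- lapply(seq_len(n_observers), function(i) {
    observer <- make_obs()
    blocks <- expand.grid(ord = c("sc", "cs"), side = c("lower", "upper"),
                          stringsAsFactors = FALSE)
    blocks <- blocks[sample.int(nrow(blocks)), ]
    state <- NULL
    runs <- list()
    for (b in seq_len(nrow(blocks))) {
      r <- run_block(observer, blocks$ord[b], blocks$side[b], state)
      state <- r$state
      runs[[paste(blocks$ord[b], blocks$side[b], sep = "_")]] <- r
    }
    dl_sc <- staircase_dl(runs$sc_upper, runs$sc_lower)
    dl_cs <- staircase_dl(runs$cs_upper, runs$cs_lower)
    # constant-stimuli arm: same generative process, fresh reference
    design <- constant_stimuli_design(standard, c_levels = c_levels,
                                      n_blocks = n_blocks)
    trials <- build_design(design)
    records <- run_constant_stimuli(trials, make_obs(), keep_latents = FALSE)
    tab <- aggregate_records(records)
    est_sc <- spearman_karber(tab, "sc", anchors[1], anchors[2])
    est_cs <- spearman_karber(tab, "cs", anchors[1], anchors[2])
    tb <- type_b(est_sc, est_cs)
    data.frame(observer = i, staircase_dl_sc = dl_sc, staircase_dl_cs = dl_cs,
               staircase_type_b = dl_sc - dl_cs,
               cs_dl_sc = tb$dl_sc, cs_dl_cs = tb$dl_cs,
               cs_type_b = tb$delta_dl)
  })
  per_observer <- do.call(rbind, rows)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- list(
    n_observers = n_observers,
    mean_staircase_type_b = mean(per_observer$staircase_type_b),
    se_staircase_type_b = sem(per_observer$staircase_type_b),
    mean_constant_stimuli_type_b = mean(per_observer$cs_type_b),
    se_constant_stimuli_type_b = sem(per_observer$cs_type_b))
  structure(list(per_observer = per_observer, summary = summary,
                 standard = standard, model = model, g = g),
            class = "bias_study_result")
}

#' Grid-search recovery of the IRM updating weight
#'
#' Estimates `(g, gamma, sigma0, weber)` from a single observer's response
#' records by maximizing a composite marginal likelihood. Because the
#' internal reference is a linear recursion on the first-stimulus
#' sensations, its marginal distribution on every trial is normal with mean
#' and variance following the same recursion, so each trial's marginal
#' response probability has a closed form; the product over trials (which
#' ignores the across-trial dependence induced by the shared reference path)
#' is maximized over the supplied grids. The grid resolution bounds the
#' precision of the estimate.
#'
#' Records may contain a `session` column: the reference (and its moment
#' recursion) restarts at every session boundary.
#'
#' @param records Response records of one observer in one regime, with
#'   columns `order`, `standard`, `comparison`, `response_c_longer`,
#'   optionally `session`.
#' @param g_grid Candidate updating weights.
#' @param gamma_grid Candidate criteria (ms).
#' @param noise_grid Data frame of candidate `sigma0`, `weber` pairs.
#' @param i0_policy Reference initialization assumed by the fit.
#' @return List with `g_hat`, `gamma_hat`, `sigma0_hat`, `weber_hat`,
#'   `loglik`, the full `grid` of log-likelihoods, `grid_step` (g
#'   resolution) and `unidentifiable` (all-identical responses).
#' @export
recover_g <- function(records, g_grid = seq(0, 0.9, by = 0.05),
                      gamma_grid = 0,
                      noise_grid = data.frame(sigma0 = 2, weber = 0.15),
                      i0_policy = c("first_sensation", "standard_mean")) {
  i0_policy <- match.arg(i0_policy)
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("order", "standard", "comparison",
                  "response_c_longer") %in% names(records)),
            all(g_grid >= 0 & g_grid < 1))
  if (length(unique(records$standard)) != 1L) {
    stop("recover_g: records must come from a single regime")
  }
  if (length(unique(records$response_c_longer)) < 2L) {
    return(list(g_hat = NA_real_, gamma_hat = NA_real_,
                sigma0_hat = NA_real_, weber_hat = NA_real_,
                loglik = NA_real_, grid = NULL,
                grid_step = if (length(g_grid) > 1) min(diff(sort(g_grid))) else NA_real_,
                unidentifiable = TRUE))
  }
  std <- records$standard[1]
  d1 <- ifelse(records$order == "sc", std, records$comparison)
  d2 <- ifelse(records$order == "sc", records$comparison, std)
  first_longer <- ifelse(records$order == "sc",
                         1L - records$response_c_longer,
                         records$response_c_longer)
  session <- if ("session" %in% names(records)) records$session
             else rep(1L, nrow(records))
  idx_by_session <- split(seq_len(nrow(records)), session)

  loglik_one <- function(g, gamma, sigma0, weber) {
    s1sd <- sigma0 + weber * d1
    s2sd <- sigma0 + weber * d2
    ll <- 0
    for (idx in idx_by_session) {
      dd1 <- d1[idx]; dd2 <- d2[idx]
      v1 <- (s1sd[idx])^2; v2 <- (s2sd[idx])^2
      nn <- length(idx)
      if (i0_policy == "first_sensation") {
        mu <- as.numeric(stats::filter((1 - g) * dd1, g,
                                       method = "recursive", init = dd1[1]))
        v <- numeric(nn)
        v[1] <- v1[1]
        if (nn > 1) {
          v[-1] <- as.numeric(stats::filter((1 - g)^2 * v1[-1], g^2,
                                            method = "recursive", init = v[1]))
        }
      } else {
        mu <- as.numeric(stats::filter((1 - g) * dd1, g,
                                       method = "recursive", init = std))
        v <- as.numeric(stats::filter((1 - g)^2 * v1, g^2,
                                      method = "recursive", init = 0))
      }
      p_first <- stats::pnorm((mu - dd2 - gamma) / sqrt(v + v2))
      p_first <- pmin(pmax(p_first, 1e-12), 1 - 1e-12)
      ll <- ll + sum(ifelse(first_longer[idx] == 1L,
                            log(p_first), log(1 - p_first)))
    }
    ll
  }

  grid <- expand.grid(g = g_grid, gamma = gamma_grid,
                      noise = seq_len(nrow(noise_grid)),
                      KEEP.OUT.ATTRS = FALSE)
  grid$sigma0 <- noise_grid$sigma0[grid$noise]
  grid$weber <- noise_grid$weber[grid$noise]
  grid$noise <- NULL
  grid$loglik <- mapply(loglik_one, grid$g, grid$gamma, grid$sigma0,
                        grid$weber)
  best <- grid[which.max(grid$loglik), ]
  list(g_hat = best$g, gamma_hat = best$gamma, sigma0_hat = best$sigma0,
       weber_hat = best$weber, loglik = best$loglik, grid = grid,
       grid_step = if (length(g_grid) > 1) min(diff(sort(g_grid))) else NA_real_,
       unidentifiable = FALSE)
}
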