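test_that("simulate_cohort is reproducible and structurally complete", {
  cfg <- cohort_config(n_observers = 4, model = "irm", preset = "E3",
                       n_blocks = 3, seed = 21)
  r1 <- simulate_cohort(cfg)
  r2 <- simulate_cohort(cfg)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$anovas, r2$anovas)
  expect_equal(nrow(r1$estimates), 4 * 2)          # observers x regimes
  expect_equal(sort(unique(r1$estimates$standard)), c(80, 500))
  expect_equal(dim(r1$proportions$s80), c(4, 9, 2))
  expect_s3_class(r1$anovas$s80$two_way, "anova_result")
  expect_equal(nrow(r1$anovas$s500$one_way_dl), 1)
  expect_equal(r1$config$isi, 200)                 # E3 preset
  expect_equal(r1$config$stimulus_type, "filled")
  # a different seed gives different data
  r3 <- simulate_cohort(cohort_config(n_observers = 4, model = "irm",
                                      preset = "E3", n_blocks = 3, seed = 22))
  expect_false(identical(r1$estimates$delta_dl, r3$estimates$delta_dl))
})

test_that("IRM cohorts show negative Type B effects in both regimes", {
  cfg <- cohort_config(n_observers = 12, model = "irm",
                       parameter_dists = list(
                         g = list(mean = 0.5, sd = 0, lo = 0, hi = 0.95),
                         gamma = list(mean = 0, sd = 0, lo = -Inf, hi = Inf)),
                       n_blocks = 10, seed = 23)
  res <- simulate_cohort(cfg)
  for (s in c(80, 500)) {
    d <- res$estimates$delta_dl[res$estimates$standard == s]
    expect_lt(mean(d), 0)
    expect_lt(mean(d) + 2 * sd(d) / sqrt(length(d)), 0)  # clearly negative
  }
})

test_that("difference cohorts produce null Type B effects", {
  cfg <- cohort_config(n_observers = 12, model = "difference",
                       n_blocks = 10, seed = 24)
  res <- simulate_cohort(cfg)
  for (s in c(80, 500)) {
    d <- res$estimates$delta_dl[res$estimates$standard == s]
    expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1e-9)
  }
})

test_that("SWM cohort Type B sign follows the weight asymmetry", {
  mk <- function(s1, s2, seed) {
    cohort_config(n_observers = 10, model = "swm",
                  parameter_dists = list(
                    s1 = list(mean = s1, sd = 0, lo = 0.05, hi = 2),
                    s2 = list(mean = s2, sd = 0, lo = 0.05, hi = 2),
                    gamma = list(mean = 0, sd = 0, lo = -Inf, hi = Inf)),
                  n_blocks = 10, seed = seed)
  }
  neg <- simulate_cohort(mk(0.7, 1.0, 25))   # s1 < s2: negative
  pos <- simulate_cohort(mk(1.0, 0.7, 26))   # s1 > s2: positive
  d80 <- function(r) r$estimates$delta_dl[r$estimates$standard == 80]
  expect_lt(mean(d80(neg)), 0)
  expect_gt(mean(d80(pos)), 0)
})

test_that("flat-function filter flags only all-flat observers", {
  ranges <- data.frame(
    observer = rep(c("flat", "steep", "partial"), each = 4),
    response_range = c(rep(0.05, 4), rep(0.9, 4), c(0.1, 0.1, 0.6, 0.1)))
  out <- flat_function_filter(ranges, threshold = 0.25)
  expect_identical(out$excluded[out$observer == "flat"], TRUE)
  expect_identical(out$excluded[out$observer == "steep"], FALSE)
  # flat in some but not all conditions: retained
  expect_identical(out$excluded[out$observer == "partial"], FALSE)
  # threshold 0 is a vacuous filter
  expect_false(any(flat_function_filter(ranges, threshold = 0)$excluded))
})

test_that("cohorts replace flat observers and log the replacements", {
  # an unsatisfiable threshold (> 1) makes every draw flat: the replacement
  # loop is exercised until its cap aborts
  cfg <- cohort_config(n_observers = 3, model = "difference",
                       n_blocks = 2, flat_threshold = 1.01, seed = 27)
  expect_error(simulate_cohort(cfg), "too many flat")
  # normal noise: nobody is excluded
  cfg2 <- cohort_config(n_observers = 3, model = "difference", n_blocks = 2,
                        seed = 28)
  expect_equal(simulate_cohort(cfg2)$n_replaced, 0)
})

test_that("bias study returns paired estimates and a null difference control", {
  res <- bias_study(n_observers = 25, model = "difference",
                    noise = noise_spec(8, 0.2), seed = 29)
  expect_equal(nrow(res$per_observer), 25)
  expect_true(all(c("staircase_type_b", "cs_type_b") %in%
                  names(res$per_observer)))
  # difference observers: both procedures near zero
  expect_lt(abs(res$summary$mean_staircase_type_b),
            3 * res$summary$se_staircase_type_b)
  expect_lt(abs(res$summary$mean_constant_stimuli_type_b),
            3 * res$summary$se_constant_stimuli_type_b)
})

test_that("without floor interaction the staircase positive bias disappears", {
  # long standard, same IRM process: constant stimuli stay clearly negative
  # and the staircase mean is not significantly positive
  res <- bias_study(n_observers = 40, standard = 500,
                    c_levels = seq(300, 700, 50), anchors = c(200, 800),
                    g = 0.5, noise = noise_spec(8, 0.2), base_step = 25,
                    start_offset = 100, seed = 30)
  expect_lt(res$summary$mean_constant_stimuli_type_b, 0)
  expect_lt(res$summary$mean_staircase_type_b,
            2 * res$summary$se_staircase_type_b)
})

test_that("recover_g finds the updating weight and flags degenerate data", {
  set.seed(122)
  obs <- irm_observer(0.6, 0, noise_spec(2, 0.15))
  recs <- do.call(rbind, lapply(1:2, function(s) {
    r <- run_constant_stimuli(build_design(constant_stimuli_design(80)), obs,
                              keep_latents = FALSE)
    r$session <- s
    r
  }))
  fit <- recover_g(recs, g_grid = seq(0, 0.9, 0.05),
                   noise_grid = data.frame(sigma0 = 2, weber = 0.15))
  expect_false(fit$unidentifiable)
  expect_lt(abs(fit$g_hat - 0.6), 0.1 + 1e-9)
  expect_equal(fit$grid_step, 0.05)
  # likelihood at the true g beats a badly wrong g
  ll <- function(g) fit$grid$loglik[abs(fit$grid$g - g) < 1e-9]
  expect_gt(ll(0.6), ll(0.9))
  expect_gt(ll(0.6), ll(0))
  # degenerate records are unidentifiable
  degen <- recs[1:100, ]
  degen$response_c_longer <- 1L
  expect_true(recover_g(degen)$unidentifiable)
  expect_error(recover_g(transform(recs, standard = seq_len(nrow(recs)))),
               "single regime")
})
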