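test_that("weighted up-down step sizes satisfy the zero-drift equilibrium", {
  up <- staircase_config(0.75, standard = 80, start_c = 110, base_step = 5)
  expect_equal(up$step_down, 5)
  expect_equal(up$step_up, 15)  # p*down = (1-p)*up at p = .75
  expect_equal(0.75 * up$step_down, 0.25 * up$step_up)
  lo <- staircase_config(0.25, standard = 80, start_c = 50, base_step = 5)
  expect_equal(lo$step_up, 5)
  expect_equal(lo$step_down, 15)
  expect_equal(0.25 * lo$step_down, 0.75 * lo$step_up)
  # explicit steps are kept; derived step completes the ratio
  cfg <- staircase_config(0.75, standard = 80, start_c = 110, step_down = 4)
  expect_equal(cfg$step_up, 12)
  expect_error(staircase_config(0.75, 80, start_c = 110, step_down = -1),
               "> 0")
  expect_error(staircase_config(0.75, 80, start_c = 110, floor = 120),
               "floor")
  expect_error(staircase_config(0.75, 80, start_c = 110, n_trials = 10, k = 20),
               ">= k")
})

test_that("staircase_step clamps at the floor and at the standard", {
  lo <- staircase_config(0.25, standard = 50, start_c = 30, base_step = 5,
                         floor = 0)
  # downward move of 15 from c = 10 hits the physical limit of 0 ms
  expect_equal(staircase_step(10, TRUE, lo), 0)
  expect_equal(staircase_step(0, TRUE, lo), 0)
  # crossing prohibition keeps the lower run strictly below the standard
  lo2 <- staircase_config(0.25, standard = 50, start_c = 30, base_step = 5,
                          forbid_crossing_standard = TRUE)
  expect_lt(staircase_step(48, FALSE, lo2), 50)   # 48 + 15 clamped below s
  up2 <- staircase_config(0.75, standard = 50, start_c = 70, base_step = 5,
                          forbid_crossing_standard = TRUE)
  expect_gt(staircase_step(52, TRUE, up2), 50)    # 52 - 5 clamped above s
  # ceiling
  up3 <- staircase_config(0.75, standard = 50, start_c = 70, base_step = 5,
                          ceiling = 100)
  expect_equal(staircase_step(95, FALSE, up3), 100)
})

test_that("a constant 'c longer' responder drives the run to the floor", {
  # deterministic: always judges c longer -> monotone descent, absorbed at 0
  obs <- swm_observer(1, 0, r2 = -1e9, gamma = 0, noise = noise_spec(0, 0))
  cfg <- staircase_config(0.25, standard = 50, start_c = 30, base_step = 5,
                          n_trials = 60, floor = 0)
  run <- run_staircase(cfg, obs, order = "cs")
  expect_true(all(run$responses))
  expect_true(all(run$c_sequence >= 0))
  expect_equal(mean(tail(run$c_sequence, 20)), 0)
  expect_equal(run$estimate, 0)
  # with the reversal estimator this run has no reversals: flagged invalid
  cfg_rev <- staircase_config(0.25, standard = 50, start_c = 30, base_step = 5,
                              n_trials = 60, floor = 0,
                              estimator = "reversal_mean")
  run_rev <- run_staircase(cfg_rev, obs, order = "cs")
  expect_false(run_rev$valid)
  expect_true(is.na(run_rev$estimate))
  expect_error(staircase_dl(run_rev, run_rev), "invalid")
})

test_that("a noiseless threshold observer reproduces the deterministic orbit", {
  # difference observer with zero noise in order cs responds "c longer" iff c > s
  obs <- difference_observer(0, noise_spec(0, 0))
  cfg <- staircase_config(0.75, standard = 50, start_c = 70, base_step = 5,
                          n_trials = 60)
  run <- run_staircase(cfg, obs, order = "cs")
  # independent replay of the deterministic rule
  cc <- 70; expected <- numeric(60)
  for (i in 1:60) {
    expected[i] <- cc
    cc <- if (cc > 50) cc - 5 else cc + 15
  }
  expect_equal(run$c_sequence, expected)
  # last-20 mean sits within one step cycle of the standard
  expect_lt(abs(run$estimate - 50), cfg$step_down + cfg$step_up)
})

test_that("staircase DL is half the upper/lower estimate difference", {
  mk_run <- function(est) {
    structure(list(estimate = est, valid = TRUE), class = "staircase_run")
  }
  expect_equal(staircase_dl(mk_run(60), mk_run(40)), 10)
  # floored lower run inflates the DL: true spread asymmetric around s
  expect_equal(staircase_dl(mk_run(30), mk_run(0)), 15)
  # symmetric runs with equal offsets recover the offset
  expect_equal(staircase_dl(mk_run(50 + 12), mk_run(50 - 12)), 12)
})

test_that("every presented comparison respects floor, ceiling and crossing", {
  set.seed(111)
  obs <- irm_observer(0.5, 0, noise_spec(5, 0.4))
  for (side in c("lower", "upper")) {
    cfg <- staircase_config(if (side == "upper") 0.75 else 0.25,
                            standard = 50,
                            start_c = if (side == "upper") 70 else 30,
                            base_step = 5, n_trials = 80, floor = 0,
                            ceiling = 200, forbid_crossing_standard = TRUE)
    run <- run_staircase(cfg, obs, order = "cs")
    expect_true(all(run$c_sequence >= 0))
    expect_true(all(run$c_sequence <= 200))
    if (side == "lower") expect_true(all(run$c_sequence < 50))
    else expect_true(all(run$c_sequence > 50))
  }
})

test_that("staircase DL agrees with Spearman-Kaerber for a stateless observer", {
  # long regime, no floor interaction; >= 100 replicate runs, 15% tolerance
  set.seed(112)
  ns <- noise_spec(8, 0.1)  # sigma(500) = 58 ms
  n_rep <- 100
  stair <- numeric(n_rep); sk <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    obs <- difference_observer(0, ns)
    # small step relative to the expected DL keeps the oscillation tight
    up <- run_staircase(staircase_config(0.75, 500, 600, base_step = 15,
                                         n_trials = 60), obs, order = "cs")
    lo <- run_staircase(staircase_config(0.25, 500, 400, base_step = 15,
                                         n_trials = 60), obs, order = "cs")
    stair[i] <- staircase_dl(up, lo)
    trials <- build_design(constant_stimuli_design(500))
    rec <- run_constant_stimuli(trials, obs, keep_latents = FALSE)
    tab <- aggregate_records(rec)
    sk[i] <- spearman_karber(tab, "cs", 200, 800)$dl
  }
  expect_lt(abs(mean(stair) - mean(sk)) / mean(sk), 0.15)
})
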