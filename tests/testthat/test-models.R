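test_that("noise spec and perceive behave as a Thurstonian front end", {
  ns0 <- noise_spec(0, 0)
  expect_identical(perceive(500, ns0), 500)
  expect_equal(sigma_at(noise_spec(5, 0.1), 500), 55)
  expect_error(perceive(-1, ns0), "must be >= 0")
  expect_error(noise_spec(-1, 0), "non-negative")
  expect_error(noise_spec(0, -0.1), "non-negative")
  # sigma(d) is non-decreasing in d
  ns <- noise_spec(3, 0.2)
  d <- seq(0, 1000, by = 50)
  expect_true(all(diff(sigma_at(ns, d)) >= 0))
  # law of large numbers: mean of 1e5 draws at 80 ms within 3 SE
  set.seed(101)
  x <- perceive(rep(80, 1e5), noise_spec(10, 0))
  expect_lt(abs(mean(x) - 80), 3 * 10 / sqrt(1e5))
  # sensations are not truncated at zero
  set.seed(102)
  expect_true(any(perceive(rep(5, 1e4), noise_spec(20, 0)) < 0))
})

test_that("internal reference updating follows the leaky-integrator rule", {
  s <- irm_state(500)
  expect_equal(irm_update(s, 500, 0.7)$reference, 500)     # fixed point
  expect_equal(irm_update(irm_state(400), 500, 0.5)$reference, 450)
  expect_equal(irm_update(irm_state(400), 500, 0)$reference, 500) # g=0: no history
  expect_equal(irm_update(s, 480, 0.3)$trial_index, 1L)
  # uninitialized reference adopts the first sensation
  expect_equal(irm_update(irm_state(), 432, 0.8)$reference, 432)
  expect_error(irm_update(s, 500, 1), "\\[0, 1\\)")
  expect_error(irm_update(s, 500, -0.1), "\\[0, 1\\)")
  expect_error(irm_observer(g = 1.2), "\\[0, 1\\)")
})

test_that("decision rules judge the second stimulus longer on ties", {
  out <- irm_decide(irm_state(520), 500, 0)
  expect_equal(out$d_value, 20)
  expect_true(out$first_judged_longer)
  # D == gamma goes to the second stimulus
  expect_false(irm_decide(irm_state(500), 500, 0)$first_judged_longer)
  expect_false(irm_decide(irm_state(500), 490, 15)$first_judged_longer)
  expect_error(irm_decide(irm_state(), 500, 0), "not initialized")
  expect_false(difference_decide(500, 500, 0)$first_judged_longer)
  expect_true(difference_decide(700, 300, 0)$first_judged_longer)
})

test_that("sensation weighting reduces to the difference model at unit weights", {
  obs <- swm_observer(1, 1, r1 = 123, r2 = 456, gamma = 2)
  set.seed(103)
  x1 <- runif(1000, 0, 1000); x2 <- runif(1000, 0, 1000)
  d_swm <- vapply(seq_along(x1),
                  function(i) swm_decide(x1[i], x2[i], obs)$d_value, numeric(1))
  r_swm <- vapply(seq_along(x1),
                  function(i) swm_decide(x1[i], x2[i], obs)$first_judged_longer,
                  logical(1))
  expect_equal(d_swm, x1 - x2)
  expect_identical(r_swm, (x1 - x2) > 2)
})

test_that("sensation weights produce assimilation below 1 and contrast above 1", {
  # s1 = 0.5, R1 = 500: effective first magnitude of x1 = 400 is 450
  obs_a <- swm_observer(0.5, 1, r1 = 500, r2 = 0)
  expect_equal(swm_decide(400, 0, obs_a)$d_value, 450)
  # s1 = 1.5: pushed away from the reference, 400 -> 350
  obs_c <- swm_observer(1.5, 1, r1 = 500, r2 = 0)
  expect_equal(swm_decide(400, 0, obs_c)$d_value, 350)
  expect_error(swm_observer(-0.2, 1), "non-negative")
  expect_error(swm_decide(1, 2, swm_observer(1, 1)), "resolved")
})

test_that("difference-model psychometric function matches theory and simulation", {
  obs <- difference_observer(0, noise_spec(50, 0))
  expect_equal(difference_psychometric(500, 500, "sc", obs), 0.5)
  expect_equal(difference_psychometric(500, 500, "cs", obs), 0.5)
  # the two orders differ in location by 2*gamma, identical shape
  obs_g <- difference_observer(10, noise_spec(40, 0))
  cgrid <- seq(300, 700, by = 10)
  expect_equal(difference_psychometric(500, cgrid, "sc", obs_g),
               difference_psychometric(500, cgrid + 20, "cs", obs_g))
  # Monte-Carlo oracle at s = 500, c = 550, sigma = 50 per stimulus
  set.seed(104)
  nmc <- 1e5
  xs <- rnorm(nmc, 500, 50); xc <- rnorm(nmc, 550, 50)
  # order sc: c longer iff Xs - Xc <= 0
  p_hat <- mean(xs - xc <= 0)
  p_th <- difference_psychometric(500, 550, "sc", obs)
  expect_lt(abs(p_hat - p_th), 3 * sqrt(p_th * (1 - p_th) / nmc))
  # zero-noise limit is a step function, not an error
  obs0 <- difference_observer(0, noise_spec(0, 0))
  expect_equal(difference_psychometric(500, c(480, 500, 520), "sc", obs0),
               c(0, 1, 1))  # tie at c = s: second (= c) judged longer
  expect_equal(difference_psychometric(500, c(480, 500, 520), "cs", obs0),
               c(0, 0, 1))
})

test_that("P(c longer) is non-decreasing in c for all observers at gamma = 0", {
  set.seed(105)
  ns <- noise_spec(2, 0.15)
  observers <- list(difference_observer(0, ns),
                    irm_observer(0.6, 0, ns),
                    swm_observer(0.7, 1.1, gamma = 0, noise = ns))
  design <- constant_stimuli_design(80, reps_per_block = 25, n_blocks = 20)
  trials <- build_design(design)  # 1e4 trials per (order x level) pair of cells
  for (obs in observers) {
    rec <- run_constant_stimuli(trials, obs, keep_latents = FALSE)
    tab <- aggregate_records(rec)
    for (o in c("sc", "cs")) {
      rows <- tab[tab$order == o, ]
      rows <- rows[order(rows$comparison), ]
      p <- rows$n_c_longer / rows$n_trials
      se <- sqrt(0.25 / rows$n_trials[1])
      expect_true(all(diff(p) > -3 * se))
    }
  }
})

test_that("IRM with g = 0 is response-identical to the difference model", {
  design <- constant_stimuli_design(80, seed = 7)
  trials <- build_design(design)
  ns <- noise_spec(3, 0.1)
  set.seed(106)
  rec_irm <- run_constant_stimuli(trials, irm_observer(0, 0, ns))
  set.seed(106)
  rec_diff <- run_constant_stimuli(trials, difference_observer(0, ns))
  expect_identical(rec_irm$response_c_longer, rec_diff$response_c_longer)
  expect_equal(rec_irm$reference, rec_irm$x1)  # g = 0: reference is X1 itself
})
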