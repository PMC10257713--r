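test_that("MAP fitting is deterministic given the seed", {
  set.seed(10)
  p <- hgf_params(omega2 = -2.5, mu3_0 = -1.5)
  trials <- simulate_prl(agent_hgf(p), prl_config(), seed = 11)
  f1 <- hgf_fit(trials$choice, trials$outcome, seed = 3)
  f2 <- hgf_fit(trials$choice, trials$outcome, seed = 3)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$BIC, f2$BIC)
})

test_that("the fitted likelihood matches an independent forward-pass evaluation", {
  set.seed(12)
  p <- hgf_params()
  trials <- simulate_prl(agent_hgf(p), prl_config(), seed = 13)
  f <- hgf_fit(trials$choice, trials$outcome, seed = 1)
  traj <- hgf_forward(f$params, trials$choice,
                      as.integer(trials$outcome == "win"))
  expect_equal(f$loglik, traj$loglik, tolerance = 1e-10)
  expect_equal(f$BIC, 4 * log(nrow(trials)) - 2 * f$loglik,
               tolerance = 1e-10)
})

test_that("refitting with the true parameters as the only start returns them", {
  ## zero-noise self-consistency: the optimizer started at the truth
  ## must not move away from a local optimum by more than its tolerance
  set.seed(14)
  truth <- c(omega2 = -3, omega3 = -6, log_kappa = 0, mu3_0 = -2)
  p <- hgf_params()
  trials <- simulate_prl(agent_hgf(p), prl_config(), seed = 15)
  pri <- hgf_priors(mean = truth, sd = c(omega2 = 1e-4, omega3 = 1e-4,
                                         log_kappa = 1e-4, mu3_0 = 1e-4),
                    n_starts = 1L)
  f <- hgf_fit(trials$choice, trials$outcome, priors = pri, seed = 1)
  expect_equal(unlist(f$estimates), c(omega2 = -3, omega3 = -6, kappa = 1,
                                      mu3_0 = -2), tolerance = 1e-2)
})

test_that("BIC ordering is consistent with likelihood dominance for nested fits", {
  ## the 4-parameter fit must beat a 'restricted' fit whose parameters
  ## are pinned far from the generating values on data from the full model
  set.seed(16)
  gen <- hgf_params(omega2 = -2, mu3_0 = -1)
  trials <- simulate_prl(agent_hgf(gen), prl_config(), seed = 17)
  full <- hgf_fit(trials$choice, trials$outcome, seed = 1)
  pinned <- hgf_priors(mean = c(omega2 = -6, omega3 = -6, log_kappa = 0,
                                mu3_0 = -4),
                       sd = c(omega2 = 1e-5, omega3 = 1e-5,
                              log_kappa = 1e-5, mu3_0 = 1e-5),
                       n_starts = 1L)
  restricted <- hgf_fit(trials$choice, trials$outcome, priors = pinned,
                        seed = 1)
  expect_gt(full$loglik, restricted$loglik)
  expect_lt(full$BIC, restricted$BIC) # same k, so dominance must agree
})

test_that("per-block-pair fitting returns one row per subject and regime", {
  set.seed(18)
  p <- hgf_params()
  trials <- dplyr::bind_rows(
    simulate_prl(agent_hgf(p), prl_config(), seed = 19, subject_id = "a"),
    simulate_prl(agent_hgf(p), prl_config(), seed = 20, subject_id = "b"))
  fits <- fit_hgf(trials, priors = hgf_priors(n_starts = 2L), seed = 1)
  expect_identical(nrow(fits), 4L)
  expect_setequal(fits$block_pair, c("early", "late"))
  expect_true(all(fits$kappa >= 0))
})
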