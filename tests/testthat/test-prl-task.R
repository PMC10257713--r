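test_that("config validation rejects inconsistent task settings", {
  expect_error(prl_config(reversal_k = 11, reversal_window = 10),
               "reversal_k")
  expect_error(prl_config(trials_per_block = 5, reversal_window = 10),
               "trials_per_block")
  expect_error(prl_config(contingencies_early = c(0.9, 0.5)), "length 3")
  expect_error(prl_config(contingencies_early = c(1.2, 0.5, 0.1)),
               "probabilities")
})

test_that("a deterministic best-deck follower triggers the first reversal on trial 9 at the earliest", {
  cfg <- prl_config()
  for (s in 1:5) {
    set.seed(s)
    env <- prl_env(cfg)
    reversal_at <- NA_integer_
    for (t in 1:40) {
      step <- prl_step(env, env$best, cfg)
      if (step$reversal) { reversal_at <- t; break }
      env <- step$env
    }
    expect_identical(reversal_at, 9L) # 9-of-10 rule: 9th trial, never earlier
  }
})

test_that("reversal draws a different best deck and resets the window", {
  cfg <- prl_config()
  set.seed(42)
  env <- prl_env(cfg)
  old_best <- env$best
  for (t in 1:9) {
    step <- prl_step(env, env$best, cfg)
    env <- step$env
  }
  expect_true(step$reversal)
  expect_false(env$best == old_best)
  expect_length(env$window, 0L)
})

test_that("degenerate contingency 1 always wins and 0 always loses", {
  cfg <- prl_config(contingencies_early = c(1, 1, 1),
                    contingencies_late = c(1, 1, 1))
  set.seed(1)
  env <- prl_env(cfg)
  outcomes <- replicate(50, {
    step <- prl_step(env, 2L, cfg)
    env <<- step$env
    step$outcome
  })
  expect_true(all(outcomes == "win"))
  cfg0 <- prl_config(contingencies_early = c(0, 0, 0),
                     contingencies_late = c(0, 0, 0))
  env <- prl_env(cfg0)
  step <- prl_step(env, 1L, cfg0)
  expect_identical(step$outcome, "loss")
})

test_that("invalid deck choices are rejected with a diagnostic", {
  cfg <- prl_config()
  set.seed(1)
  env <- prl_env(cfg)
  expect_error(prl_step(env, 4L, cfg), "Invalid deck")
  expect_error(prl_step(env, 0, cfg), "Invalid deck")
  bad_agent <- list(choose = function(n, t) 7L,
                    observe = function(c, o) NULL)
  expect_error(simulate_prl(bad_agent, cfg, seed = 1), "trial 1")
})

test_that("a default session has 160 trials, 4 blocks, and the late contingency switch at block 3", {
  trials <- simulate_prl(agent_random(), prl_config(), seed = 7)
  expect_identical(nrow(trials), 160L)
  expect_identical(as.integer(table(trials$block)), rep(40L, 4L))
  expect_identical(which(trials$transition), 81L) # first trial of block 3
})

test_that("sessions are reproducible from the seed", {
  a <- simulate_prl(agent_wsls(), prl_config(), seed = 123)
  b <- simulate_prl(agent_wsls(), prl_config(), seed = 123)
  expect_identical(a, b)
  c <- simulate_prl(agent_wsls(), prl_config(), seed = 124)
  expect_false(identical(a, c))
})

test_that("best deck is constant between reversals and reversals never re-select it", {
  trials <- simulate_prl(agent_wsls(p_stay_win = 0.95, p_stay_loss = 0.2),
                         prl_config(), seed = 99)
  rev_idx <- which(trials$reversal)
  for (i in rev_idx) {
    if (i < nrow(trials)) {
      expect_false(trials$best_deck[i + 1L] == trials$best_deck[i])
    }
  }
  segments <- split(trials$best_deck,
                    cumsum(dplyr::lag(trials$reversal, default = FALSE)))
  for (seg in segments) expect_length(unique(seg), 1L)
})

test_that("empirical win rates converge to the configured contingencies", {
  ## random agent, long session, early contingencies only
  cfg <- prl_config(n_blocks = 2L, trials_per_block = 2000L,
                    transition_block = 3L,
                    reversal_k = 2000L, reversal_window = 2000L)
  trials <- simulate_prl(agent_random(), cfg, seed = 5)
  rates <- tapply(trials$outcome == "win", trials$choice, mean)
  counts <- tapply(trials$outcome == "win", trials$choice, length)
  ## sorted empirical rates match the sorted contingencies within 3
  ## binomial standard errors each
  ord <- order(-rates)
  expected <- sort(cfg$contingencies_early, decreasing = TRUE)
  for (k in 1:3) {
    se <- sqrt(expected[k] * (1 - expected[k]) / counts[ord[k]])
    expect_lt(abs(rates[ord[k]] - expected[k]), 3 * se + 1e-12)
  }
})
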