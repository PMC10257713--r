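test_that("symmetric initial beliefs give uniform first-trial choice probabilities", {
  traj <- hgf_forward(hgf_params(), choices = c(1, 2), outcomes = c(1, 0))
  expect_equal(unname(traj$choice_prob[1, ]), rep(1 / 3, 3),
               tolerance = 1e-12)
})

test_that("choice probabilities sum to one on every trial", {
  set.seed(1)
  for (k in 1:5) {
    p <- hgf_params(omega2 = runif(1, -4.5, -1.5), kappa = runif(1, 0.5, 1.5),
                    omega3 = runif(1, -7, -4), mu3_0 = runif(1, -3.5, -0.5))
    n <- 200
    traj <- hgf_forward(p, sample(1:3, n, TRUE), sample(0:1, n, TRUE))
    expect_true(all(abs(rowSums(traj$choice_prob) - 1) < 1e-12))
    expect_true(all(traj$sigma2 > 0))
    expect_true(all(traj$sigma3 > 0))
  }
})

test_that("decoupled level 3 stays at its prior", {
  p <- hgf_params(kappa = 0, phi3 = 1)
  traj <- hgf_forward(p, rep(1L, 50), rep(1L, 50))
  expect_equal(unname(traj$mu3), rep(p$mu3_0, 50), tolerance = 1e-12)
})

test_that("repeated wins drive the chosen deck's belief monotonically toward the win extreme", {
  p <- hgf_params(phi2 = 0) # pure random walk at level 2: no drift pull
  traj <- hgf_forward(p, rep(2L, 1000), rep(1L, 1000))
  mu2 <- traj$mu2[, 2]
  expect_true(all(diff(mu2) > 0))
  expect_gt(traj$mu1hat[1000, 2], 0.95)
})

test_that("the softmax response is uniform for equal values and flattens with volatility", {
  p <- hgf_params()
  expect_equal(hgf_choice_prob(c(0.5, 0.5, 0.5), -2, p), rep(1 / 3, 3),
               tolerance = 1e-12)
  ## huge volatility estimate: inverse temperature -> 0, probabilities
  ## -> uniform regardless of value differences
  expect_equal(hgf_choice_prob(c(1, 0, 0.5), 40, p), rep(1 / 3, 3),
               tolerance = 1e-6)
  ## two decks, values (1, 0), unit inverse temperature: logistic(1)
  p1 <- hgf_params(beta0 = 1, mu3_0 = 0, beta_coupling = "prior")
  pr <- hgf_choice_prob(c(1, 0), 0, p1)
  expect_equal(pr[1], plogis(1), tolerance = 1e-12)
})

test_that("the sequence likelihood equals the product of per-trial choice probabilities", {
  set.seed(2)
  p <- hgf_params()
  n <- 120
  ch <- sample(1:3, n, TRUE); out <- sample(0:1, n, TRUE)
  traj <- hgf_forward(p, ch, out)
  manual <- sum(log(traj$choice_prob[cbind(seq_len(n), ch)]))
  expect_equal(traj$loglik, manual, tolerance = 1e-10)
})

test_that("outcome-independent play keeps average choice probabilities exchangeable across decks", {
  ## symmetric parameters + outcomes independent of choice: no deck is
  ## systematically preferred
  set.seed(3)
  p <- hgf_params()
  probs <- matrix(0, 40, 3)
  for (r in 1:40) {
    n <- 90
    traj <- hgf_forward(p, sample(1:3, n, TRUE), rbinom(n, 1, 0.5))
    probs[r, ] <- colMeans(traj$choice_prob)
  }
  m <- colMeans(probs)
  expect_true(max(abs(m - 1 / 3)) < 3 * max(apply(probs, 2, sd)) / sqrt(40))
})

test_that("invalid inputs and ill-posed updates are rejected", {
  p <- hgf_params()
  expect_error(hgf_forward(p, c(1, 4), c(1, 0)), "deck indices")
  expect_error(hgf_forward(p, c(1, 2), c(2, 0)), "binary")
  expect_error(hgf_params(sigma2_0 = -1), "variances")
  ## an extreme volatility coupling with a confident wrong prior makes
  ## the level-3 posterior precision go non-positive
  bad <- hgf_params(kappa = 20, omega2 = -8, omega3 = -1, mu3_0 = 0,
                    sigma2_0 = 0.1, mu2_0 = 6, phi2 = 0, phi3 = 0)
  expect_error(hgf_forward(bad, rep(1L, 100), rep(0L, 100)),
               "ill-posed.*trial")
})
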