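test_that("Mann-Whitney U matches hand enumeration and the all-pairs oracle", {
  ## complete separation: group a below group b -> U = 0 for a
  expect_identical(mann_whitney(c(1, 2), c(3, 4))$U, 0)
  ## mirrored samples of equal n: U = n^2 / 2
  r <- mann_whitney(c(1, 4, 6), c(6, 4, 1))
  expect_identical(r$U, 9 / 2)
  set.seed(60)
  for (i in 1:500) {
    x <- sample(1:20, sample(3:12, 1), TRUE)
    y <- sample(1:20, sample(3:12, 1), TRUE)
    expect_identical(mann_whitney(x, y)$U, mw_oracle(x, y))
  }
  expect_error(mann_whitney(numeric(0), 1:3), "at least one")
})

test_that("Spearman correlation is monotone-invariant and matches rank-then-Pearson", {
  x <- c(1, 2, 5, 7, 10, 11)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  set.seed(61)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    a <- sample(1:15, n, TRUE); b <- sample(1:15, n, TRUE)
    expect_equal(spearman(a, b)$rho, cor(rank(a), rank(b)),
                 tolerance = 1e-12)
  }
  expect_warning(s <- spearman(rep(1, 5), 1:5), "Constant")
  expect_true(is.na(s$rho))
  ## missing pairs dropped pairwise
  s2 <- spearman(c(1, 2, NA, 4, 5), c(2, 4, 9, 8, 10))
  expect_identical(s2$n, 4L)
})

test_that("residualization behaves on orthogonal, identical and degenerate controls", {
  set.seed(62)
  ctrl <- rnorm(50)
  indep <- rnorm(50)
  r1 <- residualize(indep, ctrl)
  expect_equal(mean(r1), 0, tolerance = 1e-12)
  expect_equal(unname(coef(lm(r1 ~ ctrl))[2]), 0, tolerance = 1e-12)
  expect_equal(residualize(ctrl, ctrl), rep(0, 50), tolerance = 1e-12)
  expect_warning(r3 <- residualize(1:4, rep(2, 4)), "Constant control")
  expect_equal(r3, c(-1.5, -0.5, 0.5, 1.5))
  ## four-point hand example against the normal equations
  out <- c(1, 3, 2, 6); ct <- c(0, 1, 2, 3)
  X <- cbind(1, ct)
  beta <- solve(t(X) %*% X, t(X) %*% out)
  expect_equal(residualize(out, ct), as.numeric(out - X %*% beta),
               tolerance = 1e-12)
})

test_that("the skew-minimizing transform picks identity for symmetric data and reduces skew for lognormal data", {
  set.seed(63)
  sym <- rnorm(300)
  t1 <- log_transform_minimizing_skew(sym)
  expect_identical(t1$transform, "identity")
  skewed <- exp(rnorm(300, 0, 1))
  t2 <- log_transform_minimizing_skew(skewed)
  expect_identical(t2$transform, "log")
  expect_lt(abs(t2$skew_after), abs(t2$skew_before))
  ## monotone: ranks preserved on every input
  expect_identical(rank(t2$values), rank(skewed))
})

test_that("LASSO limiting cases: no penalty keeps everything, a huge penalty drops everything", {
  set.seed(64)
  n <- 60
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
  y <- X %*% c(2, -1, 0.5, 0) + rnorm(n, 0, 0.5)
  all_in <- lasso_select(X, y, lambda = 0)
  expect_setequal(all_in$retained, colnames(X))
  ## at lambda = 0 the coefficients coincide with OLS
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(all_in$coefficients[colnames(X)]), unname(ols),
               tolerance = 1e-3)
  none <- lasso_select(X, y, lambda = 1e6)
  expect_length(none$retained, 0)
})

test_that("a planted single predictor is retained in almost all seeded replicates", {
  set.seed(65)
  hits <- 0
  for (r in 1:50) {
    n <- 80
    X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
    y <- 0.8 * X[, 3] + rnorm(n)
    sel <- lasso_select(X, y, seed = r)
    hits <- hits + ("v3" %in% sel$retained)
  }
  expect_gte(hits / 50, 0.9)
})

test_that("OLS agrees with the normal equations and flags rank deficiency", {
  set.seed(66)
  n <- 40
  d <- tibble::tibble(y = rnorm(n), a = rnorm(n), b = rnorm(n))
  f <- ols_fit(d, "y", c("a", "b"))
  X <- cbind(1, d$a, d$b)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(f$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  ## exact linear outcome -> R^2 = 1
  d$z <- 2 * d$a - d$b + 3
  expect_equal(ols_fit(d, "z", c("a", "b"))$r_squared, 1, tolerance = 1e-12)
  ## pure-noise outcome at large n -> R^2 near zero
  set.seed(67)
  big <- tibble::tibble(y = rnorm(2000), a = rnorm(2000))
  expect_lt(ols_fit(big, "y", "a")$r_squared, 0.01)
  ## duplicated column is rejected by name
  d$dup <- d$a
  expect_error(ols_fit(d, "y", c("a", "dup")), "dup")
  ## empty retained set records the intercept-only outcome
  f0 <- ols_fit(d, "y")
  expect_identical(nrow(f0$coefficients), 1L)
  expect_true(is.na(f0$p_model))
})

test_that("residualize-then-correlate equals the partial-correlation oracle", {
  set.seed(68)
  n <- 120
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + rnorm(n)
  rx <- residualize(x, z); ry <- residualize(y, z)
  r_resid <- cor(rx, ry)
  ## partial correlation from the pairwise correlation matrix
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  r_partial <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(r_resid, r_partial, tolerance = 1e-10)
})
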