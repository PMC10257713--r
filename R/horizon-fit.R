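## Fitting the Kalman/logistic Horizon model.
##
## The likelihood is evaluated on the first free (fifth) choice of every
## game only; later free choices are simulated during play but do not
## enter the fit. Two estimation routes are provided: full hierarchical
## Bayes by MCMC (JAGS), and a fast per-subject MAP with one
## empirical-Bayes shrinkage pass for small cohorts and quick checks.

## Per-game design table consumed by both likelihoods: forced rewards by
## side (padded to 3), counts, information differential, and the binary
## first free choice.
horizon_design <- function(trials) {
  need <- c("subject_id", "game", "horizon", "info", "trial", "side",
            "forced", "reward")
  check_that(all(need %in% names(trials)),
             paste("`trials` must have columns:", paste(need, collapse = ", ")))
  pad3 <- function(x) c(x, rep(0, 3 - length(x)))[1:3]
  trials |>
    dplyr::group_by(.data$subject_id, .data$game, .data$horizon, .data$info) |>
    dplyr::group_modify(function(d, key) {
      f <- d[d$forced, ]
      free1 <- d[!d$forced, ][1, ]
      rl <- f$reward[f$side == "L"]
      rr <- f$reward[f$side == "R"]
      nl <- length(rl); nr <- length(rr)
      tibble(n_left = nl, n_right = nr,
             rl1 = pad3(rl)[1], rl2 = pad3(rl)[2], rl3 = pad3(rl)[3],
             rr1 = pad3(rr)[1], rr2 = pad3(rr)[2], rr3 = pad3(rr)[3],
             dI = if (nl < nr) 1 else if (nr < nl) -1 else 0,
             choice_right = as.integer(free1$side == "R"))
    }) |>
    dplyr::ungroup()
}

## Kalman posterior means for both sides of one design row, given
## learning parameters. Returns c(R_left, R_right).
design_row_R <- function(row, R0, alpha1, alpha_inf) {
  al <- learning_rate_sequence(alpha1, alpha_inf, 3L)
  upd <- function(rs, n) {
    R <- R0
    for (j in seq_len(n)) R <- kalman_update(R, al[j], rs[j])
    R
  }
  c(upd(c(row$rl1, row$rl2, row$rl3), row$n_left),
    upd(c(row$rr1, row$rr2, row$rr3), row$n_right))
}

## Parameter naming shared by both routes.
horizon_par_names <- function() {
  c("R0", "alpha1", "alpha_inf", "A_H1", "A_H6", "B_H1", "B_H6",
    "sigma_H1_equal", "sigma_H1_unequal",
    "sigma_H6_equal", "sigma_H6_unequal")
}

#' Fit the Kalman/logistic Horizon model
#'
#' Estimates, for every subject, the learning parameters (`R0`, `alpha1`,
#' `alpha_inf`) and the decision parameters (information bonus `A` and
#' spatial bias `B` per horizon; decision noise `sigma` per horizon and
#' information condition) of the Horizon task model. Only the first free
#' (fifth) choice of each game enters the likelihood.
#'
#' `method = "mcmc"` (default) is the hierarchical Bayesian route: each
#' subject-level parameter is drawn from a group-level prior whose
#' hyperparameters are estimated jointly by MCMC (JAGS); posterior means
#' are reported as point estimates and sampler diagnostics (effective
#' sample sizes, chain count) are returned. `method = "map"` fits each
#' subject by penalized maximum likelihood under weakly-informative
#' priors, then re-fits once with the priors replaced by the estimated
#' group-level moments (empirical-Bayes shrinkage); it is deterministic
#' given `seed` and suitable for small cohorts.
#'
#' @param trials Trial-level tibble from [horizon_play()] (any number of
#'   subjects, identified by `subject_id`).
#' @param method `"mcmc"` or `"map"`.
#' @param n_chains,n_adapt,n_burn,n_iter,thin MCMC settings.
#' @param seed Integer seed (controls JAGS RNG or the MAP jitter).
#' @param quiet Suppress JAGS progress output.
#' @return A `horizon_fit` object: `$estimates` (tibble, one row per
#'   subject with all eleven parameters), `$sd` (posterior standard
#'   deviations, MCMC only), `$diagnostics`, `$method`, and for MCMC the
#'   group-level posterior means in `$group`.
#' @export
fit_horizon <- function(trials, method = c("mcmc", "map"),
                        n_chains = 2L, n_adapt = 400L, n_burn = 400L,
                        n_iter = 3000L, thin = 3L, seed = 1L,
                        quiet = TRUE) {
  method <- match.arg(method)
  des <- horizon_design(trials)
  check_that(nrow(des) > 0 && !any(is.na(des$choice_right)),
             "Every game must contain at least one free choice.")
  subjects <- sort(unique(des$subject_id))
  if (method == "mcmc") {
    horizon_fit_mcmc(des, subjects, n_chains, n_adapt, n_burn, n_iter,
                     thin, seed, quiet)
  } else {
    horizon_fit_map(des, subjects, seed)
  }
}

horizon_jags_model <- function() {
  "model {
  for (s in 1:S) {
    R0[s] ~ dnorm(muR0, tauR0)
    a1[s] ~ dbeta(aa1, ba1) T(0.001, 0.999)
    afrac[s] ~ dbeta(aaf, baf) T(0.001, 0.999)
    ainf[s] <- afrac[s] * a1[s]
    ad[s] <- pow(ainf[s], 2) / (1 - ainf[s])
    alpha[s, 1] <- a1[s]
    alpha[s, 2] <- 1 / (1 / (alpha[s, 1] + ad[s]) + 1)
    alpha[s, 3] <- 1 / (1 / (alpha[s, 2] + ad[s]) + 1)
    # Kalman weights: row = number of observations on a side,
    # columns = (R0, r1, r2, r3)
    W[s, 1, 1] <- 1 - alpha[s, 1]
    W[s, 1, 2] <- alpha[s, 1]
    W[s, 1, 3] <- 0
    W[s, 1, 4] <- 0
    W[s, 2, 1] <- (1 - alpha[s, 1]) * (1 - alpha[s, 2])
    W[s, 2, 2] <- alpha[s, 1] * (1 - alpha[s, 2])
    W[s, 2, 3] <- alpha[s, 2]
    W[s, 2, 4] <- 0
    W[s, 3, 1] <- (1 - alpha[s, 1]) * (1 - alpha[s, 2]) * (1 - alpha[s, 3])
    W[s, 3, 2] <- alpha[s, 1] * (1 - alpha[s, 2]) * (1 - alpha[s, 3])
    W[s, 3, 3] <- alpha[s, 2] * (1 - alpha[s, 3])
    W[s, 3, 4] <- alpha[s, 3]
    for (h in 1:2) {
      A[s, h] ~ dnorm(muA[h], tauA[h])
      B[s, h] ~ dnorm(muB[h], tauB[h])
      for (c in 1:2) {
        ls[s, h, c] ~ dnorm(muS[h], tauS[h])
        sigma[s, h, c] <- exp(ls[s, h, c])
      }
    }
  }
  for (k in 1:N) {
    Rl[k] <- W[sub[k], nl[k], 1] * R0[sub[k]] + W[sub[k], nl[k], 2] * rl[k, 1] +
             W[sub[k], nl[k], 3] * rl[k, 2] + W[sub[k], nl[k], 4] * rl[k, 3]
    Rr[k] <- W[sub[k], nr[k], 1] * R0[sub[k]] + W[sub[k], nr[k], 2] * rr[k, 1] +
             W[sub[k], nr[k], 3] * rr[k, 2] + W[sub[k], nr[k], 4] * rr[k, 3]
    y[k] ~ dbern(ilogit(-(Rl[k] - Rr[k] + A[sub[k], hidx[k]] * dI[k] +
                          B[sub[k], hidx[k]]) / sigma[sub[k], hidx[k], cidx[k]]))
  }
  muR0 ~ dnorm(50, 1.0E-3)
  sdR0 ~ dunif(0, 30); tauR0 <- pow(sdR0, -2)
  aa1 ~ dunif(1, 10); ba1 ~ dunif(1, 10)
  aaf ~ dunif(1, 10); baf ~ dunif(1, 10)
  for (h in 1:2) {
    muA[h] ~ dnorm(0, 1.0E-3); sdA[h] ~ dunif(0, 30); tauA[h] <- pow(sdA[h], -2)
    muB[h] ~ dnorm(0, 1.0E-3); sdB[h] ~ dunif(0, 30); tauB[h] <- pow(sdB[h], -2)
    muS[h] ~ dnorm(2.3, 1.0E-2); sdS[h] ~ dunif(0, 5); tauS[h] <- pow(sdS[h], -2)
  }
}"
}

horizon_fit_mcmc <- function(des, subjects, n_chains, n_adapt, n_burn,
                             n_iter, thin, seed, quiet) {
  S <- length(subjects)
  sub <- match(des$subject_id, subjects)
  dat <- list(
    N = nrow(des), y = des$choice_right, dI = des$dI, sub = sub,
    hidx = ifelse(des$horizon == 1, 1L, 2L),
    cidx = ifelse(des$info == "equal", 1L, 2L),
    S = S, nl = des$n_left, nr = des$n_right,
    rl = as.matrix(des[, c("rl1", "rl2", "rl3")]),
    rr = as.matrix(des[, c("rr1", "rr2", "rr3")]))
  inits <- lapply(seq_len(n_chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, i))
  })
  jm <- rjags::jags.model(textConnection(horizon_jags_model()), data = dat,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = quiet)
  stats::update(jm, n_burn, progress.bar = "none")
  sm <- rjags::coda.samples(
    jm, c("A", "B", "ls", "R0", "a1", "ainf",
          "muA", "muB", "muS", "muR0"),
    n.iter = n_iter, thin = thin, progress.bar = "none")
  st <- summary(sm)$statistics
  mns <- st[, "Mean"]; sds <- st[, "SD"]
  pick <- function(v, template) unname(v[sprintf(template, seq_len(S))])
  est <- tibble(
    subject_id = subjects,
    R0 = pick(mns, "R0[%d]"),
    alpha1 = pick(mns, "a1[%d]"),
    alpha_inf = pick(mns, "ainf[%d]"),
    A_H1 = pick(mns, "A[%d,1]"),
    A_H6 = pick(mns, "A[%d,2]"),
    B_H1 = pick(mns, "B[%d,1]"),
    B_H6 = pick(mns, "B[%d,2]"),
    sigma_H1_equal = exp(pick(mns, "ls[%d,1,1]")),
    sigma_H1_unequal = exp(pick(mns, "ls[%d,1,2]")),
    sigma_H6_equal = exp(pick(mns, "ls[%d,2,1]")),
    sigma_H6_unequal = exp(pick(mns, "ls[%d,2,2]")))
  sdtb <- tibble(
    subject_id = subjects,
    A_H1 = pick(sds, "A[%d,1]"), A_H6 = pick(sds, "A[%d,2]"),
    B_H1 = pick(sds, "B[%d,1]"), B_H6 = pick(sds, "B[%d,2]"),
    log_sigma_H1_equal = pick(sds, "ls[%d,1,1]"),
    log_sigma_H1_unequal = pick(sds, "ls[%d,1,2]"),
    log_sigma_H6_equal = pick(sds, "ls[%d,2,1]"),
    log_sigma_H6_unequal = pick(sds, "ls[%d,2,2]"))
  ess <- coda::effectiveSize(sm)
  par_ess <- ess[grepl("^(A|ls)\\[", names(ess))]
  diagnostics <- tibble(
    n_chains = n_chains, n_iter = n_iter, thin = thin,
    min_ess = min(par_ess), median_ess = median(par_ess))
  if (diagnostics$min_ess < 50) {
    warn(paste0("Low effective sample size (min ",
                round(diagnostics$min_ess),
                "); consider more iterations."))
  }
  group <- tibble(
    parameter = c("mu_A_H1", "mu_A_H6", "mu_B_H1", "mu_B_H6",
                  "mu_log_sigma_H1", "mu_log_sigma_H6", "mu_R0"),
    mean = unname(c(mns["muA[1]"], mns["muA[2]"], mns["muB[1]"],
                    mns["muB[2]"], mns["muS[1]"], mns["muS[2]"],
                    mns["muR0"])))
  structure(list(estimates = est, sd = sdtb, group = group,
                 diagnostics = diagnostics, method = "mcmc", seed = seed),
            class = "horizon_fit")
}

## Negative penalized log-likelihood for one subject's design rows.
## theta: R0, qlogis(alpha1), qlogis(alpha_inf / alpha1), A_H1, A_H6,
##        B_H1, B_H6, and the four log decision noises.
horizon_nll_map <- function(theta, des, prior_mean, prior_sd) {
  R0 <- theta[1]
  a1 <- plogis(theta[2])
  ainf <- a1 * plogis(theta[3])
  A <- c(theta[4], theta[5]); B <- c(theta[6], theta[7])
  ls <- theta[8:11]
  al <- learning_rate_sequence(a1, max(ainf, 1e-6), 3L)
  wts <- function(n) { # weights on (R0, r1..r3) after n updates
    w <- c(1, 0, 0, 0)
    for (j in seq_len(n)) {
      w <- w * (1 - al[j])
      w[j + 1] <- al[j]
    }
    w
  }
  W <- rbind(wts(1), wts(2), wts(3))
  RL <- W[des$n_left, 1] * R0 + W[des$n_left, 2] * des$rl1 +
    W[des$n_left, 3] * des$rl2 + W[des$n_left, 4] * des$rl3
  RR <- W[des$n_right, 1] * R0 + W[des$n_right, 2] * des$rr1 +
    W[des$n_right, 3] * des$rr2 + W[des$n_right, 4] * des$rr3
  hidx <- ifelse(des$horizon == 1, 1L, 2L)
  sidx <- (hidx - 1L) * 2L + ifelse(des$info == "equal", 1L, 2L)
  sig <- exp(ls)[sidx]
  p <- 1 / (1 + exp((RL - RR + A[hidx] * des$dI + B[hidx]) / sig))
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  ll <- sum(des$choice_right * log(p) + (1 - des$choice_right) * log(1 - p))
  -ll + sum(((theta - prior_mean) / prior_sd)^2) / 2
}

horizon_fit_map <- function(des, subjects, seed) {
  set.seed(derive_seed(seed, 3L))
  prior_mean <- c(50, qlogis(0.85), qlogis(0.4), 0, 0, 0, 0, rep(log(10), 4))
  prior_sd <- c(20, 1.5, 1.5, 8, 8, 5, 5, rep(1.2, 4))
  fit_one <- function(d, pm, ps) {
    o <- optim(pm, horizon_nll_map, des = d, prior_mean = pm, prior_sd = ps,
               method = "BFGS", control = list(maxit = 400))
    c(o$par, converged = as.numeric(o$convergence == 0))
  }
  by_sub <- split(des, des$subject_id)[subjects]
  pass1 <- t(vapply(by_sub, fit_one, numeric(12), pm = prior_mean,
                    ps = prior_sd))
  ## empirical-Bayes pass: priors re-centred on the cohort
  pm2 <- colMeans(pass1[, 1:11, drop = FALSE])
  ps2 <- pmax(apply(pass1[, 1:11, drop = FALSE], 2, sd), 0.2)
  if (length(by_sub) < 3L) { pm2 <- prior_mean; ps2 <- prior_sd }
  pass2 <- t(vapply(by_sub, fit_one, numeric(12), pm = pm2, ps = ps2))
  est <- tibble(
    subject_id = subjects,
    R0 = pass2[, 1],
    alpha1 = plogis(pass2[, 2]),
    alpha_inf = plogis(pass2[, 2]) * plogis(pass2[, 3]),
    A_H1 = pass2[, 4], A_H6 = pass2[, 5],
    B_H1 = pass2[, 6], B_H6 = pass2[, 7],
    sigma_H1_equal = exp(pass2[, 8]),
    sigma_H1_unequal = exp(pass2[, 9]),
    sigma_H6_equal = exp(pass2[, 10]),
    sigma_H6_unequal = exp(pass2[, 11]))
  diagnostics <- tibble(
    n_converged = sum(pass2[, 12]), n_subjects = length(subjects))
  structure(list(estimates = est, sd = NULL, group = NULL,
                 diagnostics = diagnostics, method = "map", seed = seed),
            class = "horizon_fit")
}

#' Log-likelihood of a fitted Horizon model
#'
#' Evaluates the sum of log choice probabilities over the first-free-
#' choice observations at the fitted point estimates -- the exact
#' quantity the fit maximizes (up to priors), exposed for oracle checks
#' and model comparison.
#'
#' @param fit A `horizon_fit`.
#' @param trials The trials the model was fit to.
#' @return Total log-likelihood (numeric scalar).
#' @export
horizon_loglik <- function(fit, trials) {
  des <- horizon_design(trials)
  total <- 0
  for (s in fit$estimates$subject_id) {
    e <- fit$estimates[fit$estimates$subject_id == s, ]
    d <- des[des$subject_id == s, ]
    for (i in seq_len(nrow(d))) {
      R <- design_row_R(d[i, ], e$R0, e$alpha1, e$alpha_inf)
      hh <- if (d$horizon[i] == 1) "H1" else "H6"
      sg <- e[[paste0("sigma_", hh, "_", d$info[i])]]
      p <- horizon_choice_prob(R[1], R[2], d$dI[i], e[[paste0("A_", hh)]],
                               e[[paste0("B_", hh)]], sg)
      obs <- if (d$choice_right[i] == 1) p else 1 - p
      total <- total + log(pmin(pmax(obs, 1e-10), 1 - 1e-10))
    }
  }
  total
}

#' @export
print.horizon_fit <- function(x, ...) {
  cat("<horizon_fit>", nrow(x$estimates), "subjects; method =", x$method, "\n")
  print(x$estimates, n = 5)
  invisible(x)
}
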