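#' Parameter-recovery suite for the Horizon model
#'
#' Simulates a cohort of Kalman/logistic agents with known parameters on
#' the Horizon task, refits the model, and reports true-versus-recovered
#' correlations. Decision noise is treated as a horizon-level trait in
#' the truth draws (the same `sigma` for the equal and unequal
#' information conditions within a horizon); the fitted model estimates
#' it per condition as usual, and the recovered horizon-level value is
#' the mean of the two condition estimates on the log scale.
#'
#' Truth grids reflect the spread typically seen in Horizon-task
#' cohorts: information bonus `A_H6 ~ N(10, 10)` and `A_H1 ~ N(2, 4)`
#' points, spatial bias `B ~ N(0, 3)`, `log sigma_H1 ~ N(log 8, 0.8)`,
#' `log sigma_H6 ~ N(log 14, 0.8)`, `R0 ~ N(50, 5)`,
#' `alpha1 ~ U(0.75, 1)` and `alpha_inf = alpha1 * U(0.15, 0.5)`.
#'
#' @param n_subjects Number of simulated subjects (default 40).
#' @param config [horizon_config()] for the simulated games.
#' @param method,n_iter Passed to [fit_horizon()].
#' @param seed Master seed.
#' @return A `horizon_recovery` object with `$truth`, `$estimates`,
#'   `$summary` (correlations for `A_H6`, horizon-level `log sigma`,
#'   and the learning parameters) and `$fit`.
#' @export
horizon_recovery <- function(n_subjects = 40L, config = horizon_config(),
                             method = c("mcmc", "map"), n_iter = 3000L,
                             seed = 1L) {
  method <- match.arg(method)
  check_count(n_subjects, "n_subjects", min = 3L)
  set.seed(derive_seed(seed, 7L))
  S <- n_subjects
  truth <- tibble(
    subject_id = sprintf("h%03d", seq_len(S)),
    A_H1 = rnorm(S, 2, 4), A_H6 = rnorm(S, 10, 10),
    B_H1 = rnorm(S, 0, 3), B_H6 = rnorm(S, 0, 3),
    sigma_H1 = exp(rnorm(S, log(8), 0.8)),
    sigma_H6 = exp(rnorm(S, log(14), 0.8)),
    R0 = rnorm(S, 50, 5),
    alpha1 = runif(S, 0.75, 1))
  truth$alpha_inf <- truth$alpha1 * runif(S, 0.15, 0.5)
  trials <- purrr::map_dfr(seq_len(S), function(i) {
    pars <- as.list(truth[i, ])
    pars$sigma_H1_equal <- pars$sigma_H1
    pars$sigma_H1_unequal <- pars$sigma_H1
    pars$sigma_H6_equal <- pars$sigma_H6
    pars$sigma_H6_unequal <- pars$sigma_H6
    games <- horizon_games(config, seed = derive_seed(seed, 200L + i))
    horizon_play(games, agent_kalman(pars), config,
                 seed = derive_seed(seed, 600L + i),
                 subject_id = truth$subject_id[i])
  })
  fit <- fit_horizon(trials, method = method, n_iter = n_iter,
                     seed = derive_seed(seed, 13L))
  est <- fit$estimates[match(truth$subject_id, fit$estimates$subject_id), ]
  rec_ls1 <- (log(est$sigma_H1_equal) + log(est$sigma_H1_unequal)) / 2
  rec_ls6 <- (log(est$sigma_H6_equal) + log(est$sigma_H6_unequal)) / 2
  summary <- tibble(
    parameter = c("A_H6", "log_sigma_H1", "log_sigma_H6",
                  "R0", "alpha1", "alpha_inf"),
    pearson = c(cor(truth$A_H6, est$A_H6),
                cor(log(truth$sigma_H1), rec_ls1),
                cor(log(truth$sigma_H6), rec_ls6),
                cor(truth$R0, est$R0),
                cor(truth$alpha1, est$alpha1),
                cor(truth$alpha_inf, est$alpha_inf)),
    spearman = c(cor(truth$A_H6, est$A_H6, method = "spearman"),
                 cor(log(truth$sigma_H1), rec_ls1, method = "spearman"),
                 cor(log(truth$sigma_H6), rec_ls6, method = "spearman"),
                 cor(truth$R0, est$R0, method = "spearman"),
                 cor(truth$alpha1, est$alpha1, method = "spearman"),
                 cor(truth$alpha_inf, est$alpha_inf, method = "spearman")))
  structure(list(truth = truth, estimates = est, summary = summary,
                 fit = fit, seed = seed),
            class = "horizon_recovery")
}

#' @export
print.horizon_recovery <- function(x, ...) {
  cat("<horizon_recovery>", nrow(x$truth), "simulated subjects; method =",
      x$fit$method, "\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn horizon_recovery Scatter of recovered against true values
#'   for the information bonus and horizon-level decision noise.
#' @param object,... A `horizon_recovery` object (for `autoplot`).
#' @method autoplot horizon_recovery
#' @export
autoplot.horizon_recovery <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble(parameter = "A_H6", true = object$truth$A_H6,
           recovered = object$estimates$A_H6),
    tibble(parameter = "log_sigma_H1",
           true = log(object$truth$sigma_H1),
           recovered = (log(object$estimates$sigma_H1_equal) +
                          log(object$estimates$sigma_H1_unequal)) / 2),
    tibble(parameter = "log_sigma_H6",
           true = log(object$truth$sigma_H6),
           recovered = (log(object$estimates$sigma_H6_equal) +
                          log(object$estimates$sigma_H6_unequal)) / 2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "True value", y = "Recovered value",
                  title = "Horizon model parameter recovery")
}
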