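#' Parameter-recovery suite for the HGF bandit model
#'
#' Simulates subjects with known parameters drawn from a plausible grid,
#' lets each play a full reversal-learning session through the HGF agent,
#' refits the model by MAP, and tabulates true-versus-recovered
#' correlations and bias per parameter.
#'
#' Third-level parameters (`mu3_0`, `omega3`) are expected to recover
#' weakly at session length: the first free choice of every trial carries
#' little information about volatility beliefs, so their scatter is
#' reported for inspection rather than held to a high bar. `omega2`
#' recovers well at 160 trials.
#'
#' @param n_subjects Number of simulated subjects.
#' @param grid Named list of `c(lower, upper)` ranges for the uniform
#'   truth draws of `omega2`, `omega3`, `kappa` and `mu3_0`.
#' @param config [prl_config()] for the simulated sessions.
#' @param priors,base Passed to [hgf_fit()].
#' @param seed Master seed.
#' @return An `hgf_recovery` object: `$draws` (tibble of true and
#'   recovered values per subject and parameter) and `$summary` (tibble
#'   of Pearson and Spearman correlations and mean bias per parameter).
#' @export
hgf_recovery <- function(n_subjects = 50L,
                         grid = list(omega2 = c(-4.5, -1.5),
                                     omega3 = c(-7, -4),
                                     kappa = c(0.5, 1.5),
                                     mu3_0 = c(-3.5, -0.5)),
                         config = prl_config(),
                         priors = hgf_priors(),
                         base = hgf_params(),
                         seed = 1L) {
  check_count(n_subjects, "n_subjects", min = 3L)
  set.seed(derive_seed(seed, 11L))
  truth <- tibble(
    subject_id = sprintf("r%03d", seq_len(n_subjects)),
    omega2 = runif(n_subjects, grid$omega2[1], grid$omega2[2]),
    omega3 = runif(n_subjects, grid$omega3[1], grid$omega3[2]),
    kappa = runif(n_subjects, grid$kappa[1], grid$kappa[2]),
    mu3_0 = runif(n_subjects, grid$mu3_0[1], grid$mu3_0[2]))
  est <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    p <- base
    p$omega2 <- truth$omega2[i]; p$omega3 <- truth$omega3[i]
    p$kappa <- truth$kappa[i]; p$mu3_0 <- truth$mu3_0[i]
    p$m3 <- truth$mu3_0[i]
    trials <- simulate_prl(agent_hgf(p), config,
                           seed = derive_seed(seed, 100L + i),
                           subject_id = truth$subject_id[i])
    f <- hgf_fit(trials$choice, trials$outcome, priors = priors,
                 base = base, seed = derive_seed(seed, 500L + i))
    dplyr::bind_cols(tibble(subject_id = truth$subject_id[i]), f$estimates)
  })
  draws <- dplyr::left_join(
    tidyr::pivot_longer(truth, -"subject_id",
                        names_to = "parameter", values_to = "true"),
    tidyr::pivot_longer(est, -"subject_id",
                        names_to = "parameter", values_to = "recovered"),
    by = c("subject_id", "parameter"))
  summary <- draws |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      pearson = cor(.data$true, .data$recovered),
      spearman = cor(.data$true, .data$recovered, method = "spearman"),
      bias = mean(.data$recovered - .data$true),
      .groups = "drop")
  structure(list(draws = draws, summary = summary, n_subjects = n_subjects,
                 seed = seed),
            class = "hgf_recovery")
}

#' @export
print.hgf_recovery <- function(x, ...) {
  cat("<hgf_recovery>", x$n_subjects, "simulated subjects\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn hgf_recovery Scatter of recovered against true values,
#'   one facet per parameter.
#' @param object,... An `hgf_recovery` object (for `autoplot`).
#' @method autoplot hgf_recovery
#' @export
autoplot.hgf_recovery <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "True value", y = "Recovered value",
                  title = "HGF parameter recovery")
}
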