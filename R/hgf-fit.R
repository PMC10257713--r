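#' Priors and optimizer settings for HGF MAP estimation
#'
#' Weakly-informative Gaussian priors on the four free parameters
#' (`omega2`, `omega3`, `log(kappa)`, `mu3_0`); the remaining parameters
#' (initial variances, autoregressive rates, attractors, softmax scale)
#' are fixed at their [hgf_params()] values.
#'
#' @param mean,sd Named numeric vectors over
#'   `c("omega2", "omega3", "log_kappa", "mu3_0")`.
#' @param n_starts Number of optimizer restarts (first start at the prior
#'   mean, the rest jittered).
#' @param maxit Iteration cap per Nelder-Mead run.
#' @param reltol Convergence tolerance.
#' @return An `hgf_priors` list.
#' @export
hgf_priors <- function(mean = c(omega2 = -3, omega3 = -6, log_kappa = 0,
                                mu3_0 = -2),
                       sd = c(omega2 = 2, omega3 = 2, log_kappa = 1,
                              mu3_0 = 2),
                       n_starts = 5L, maxit = 500L, reltol = 1e-6) {
  nm <- c("omega2", "omega3", "log_kappa", "mu3_0")
  check_that(all(nm %in% names(mean)) && all(nm %in% names(sd)),
             "Priors must name omega2, omega3, log_kappa and mu3_0.")
  structure(list(mean = mean[nm], sd = sd[nm], n_starts = as.integer(n_starts),
                 maxit = as.integer(maxit), reltol = reltol),
            class = "hgf_priors")
}

## Negative log joint (likelihood + Gaussian prior penalty) for one
## choice/outcome sequence; ill-posed trajectories get a large finite
## penalty so the optimizer backs away from them.
hgf_neg_log_joint <- function(theta, choices, outcomes, base, priors, n_decks) {
  p <- base
  p$omega2 <- theta[1]; p$omega3 <- theta[2]
  p$kappa <- exp(theta[3]); p$mu3_0 <- theta[4]
  p$m3 <- theta[4] # attractor follows the prior volatility belief
  ll <- tryCatch(
    hgf_forward(p, choices, outcomes, n_decks)$loglik,
    error = function(e) -1e8)
  -ll + sum(((theta - priors$mean) / priors$sd)^2) / 2
}

#' MAP-fit the HGF to one choice/outcome sequence
#'
#' Multi-start Nelder-Mead maximization of the log joint (sequence
#' likelihood under the volatility-coupled softmax plus Gaussian priors).
#' Model fit is summarized by BIC computed from the likelihood at the
#' optimum: `BIC = k * log(n) - 2 * loglik` with `k = 4` free parameters.
#'
#' @param choices,outcomes One subject's sequence, as in [hgf_forward()].
#' @param priors An [hgf_priors()] object.
#' @param base [hgf_params()] supplying the fixed parameters.
#' @param n_decks Number of decks.
#' @param seed Integer seed for the restart jitter (fitting the same data
#'   twice with the same seed gives identical estimates).
#' @return An `hgf_fit` list: `estimates` (tibble with `omega2`, `omega3`,
#'   `kappa`, `mu3_0`), `loglik`, `BIC`, `n_trials`, `convergence` (0 =
#'   converged), and the full `params` at the optimum.
#' @export
hgf_fit <- function(choices, outcomes, priors = hgf_priors(),
                    base = hgf_params(), n_decks = 3L, seed = 1L) {
  if (is.character(outcomes)) outcomes <- as.integer(outcomes == "win")
  check_that(length(choices) >= 10L, "Need at least 10 trials to fit the HGF.")
  set.seed(seed)
  starts <- matrix(rep(priors$mean, priors$n_starts), ncol = 4, byrow = TRUE)
  if (priors$n_starts > 1L) {
    jit <- matrix(rnorm(4 * (priors$n_starts - 1L)), ncol = 4) *
      rep(priors$sd / 2, each = priors$n_starts - 1L)
    starts[-1, ] <- starts[-1, ] + jit
  }
  fits <- apply(starts, 1, function(s) {
    tryCatch(
      optim(s, hgf_neg_log_joint, choices = choices, outcomes = outcomes,
            base = base, priors = priors, n_decks = n_decks,
            method = "Nelder-Mead",
            control = list(maxit = priors$maxit, reltol = priors$reltol)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) abort("All HGF optimizer starts failed.")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- best$par
  params <- base
  params$omega2 <- theta[1]; params$omega3 <- theta[2]
  params$kappa <- exp(theta[3]); params$mu3_0 <- theta[4]
  params$m3 <- theta[4]
  ll <- hgf_forward(params, choices, outcomes, n_decks)$loglik
  k <- 4
  structure(
    list(estimates = tibble(omega2 = theta[1], omega3 = theta[2],
                            kappa = exp(theta[3]), mu3_0 = theta[4]),
         loglik = ll,
         BIC = k * log(length(choices)) - 2 * ll,
         n_trials = length(choices),
         convergence = best$convergence,
         n_starts = length(fits),
         params = params),
    class = "hgf_fit")
}

#' @export
print.hgf_fit <- function(x, ...) {
  cat("<hgf_fit>", x$n_trials, "trials; loglik =", round(x$loglik, 2),
      "; BIC =", round(x$BIC, 2), "\n")
  print(x$estimates)
  invisible(x)
}

#' Fit the HGF per subject (and per block pair) on a trials table
#'
#' Follows the convention of parameterizing the two contingency regimes
#' separately: blocks before the contingency transition form one pair,
#' blocks from the transition onwards the other. Set
#' `by_block_pair = FALSE` to fit one parameter set to the whole session.
#'
#' @param trials A trials tibble from [simulate_prl()] (or the same schema
#'   read from disk), possibly holding several subjects.
#' @param by_block_pair Fit the two contingency regimes separately?
#' @param transition_block First block of the late regime (default 3).
#' @param priors,base,n_decks,seed Passed to [hgf_fit()]; the seed is
#'   re-derived per subject and block pair.
#' @return A tibble with one row per subject x block pair: the four
#'   parameter estimates, `loglik`, `BIC` and `convergence`.
#' @export
fit_hgf <- function(trials, by_block_pair = TRUE, transition_block = 3L,
                    priors = hgf_priors(), base = hgf_params(),
                    n_decks = 3L, seed = 1L) {
  check_that(all(c("subject_id", "choice", "outcome", "block") %in%
                   names(trials)),
             "`trials` must have subject_id, choice, outcome and block columns.")
  trials <- dplyr::mutate(
    trials,
    .pair = if (by_block_pair) {
      ifelse(.data$block < transition_block, "early", "late")
    } else "all")
  grp <- dplyr::group_by(trials, .data$subject_id, .data$.pair)
  dplyr::ungroup(dplyr::group_modify(grp, function(d, key) {
    off <- sum(utf8ToInt(paste(key$subject_id, key$.pair))) %% 997L
    f <- hgf_fit(d$choice, d$outcome, priors = priors, base = base,
                 n_decks = n_decks, seed = derive_seed(seed, off))
    dplyr::bind_cols(f$estimates,
                     tibble(loglik = f$loglik, BIC = f$BIC,
                            convergence = f$convergence))
  })) |>
    dplyr::rename(block_pair = ".pair")
}
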