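#' Parameters of the three-level HGF bandit learner
#'
#' The Hierarchical Gaussian Filter tracks, for each deck, a logit-scale
#' stimulus--outcome tendency (level 2) whose step size is governed by a
#' single environmental log-volatility state shared across decks
#' (level 3). Level 1 is the trial-wise perception of win/loss feedback.
#' Both latent levels follow first-order autoregressive (mean-reverting)
#' dynamics.
#'
#' @param omega2 Baseline (tonic) log-volatility at level 2: the stable
#'   component of the dispersion of the level-2 random walk.
#' @param kappa Phasic volatility coupling (>= 0): how strongly the
#'   current volatility estimate inflates level-2 belief updates, i.e.
#'   sensitivity to unexpected change.
#' @param omega3 Meta-volatility: the dispersion of the level-3 random
#'   walk, controlling how quickly volatility beliefs themselves evolve.
#' @param mu3_0 Prior mean of the level-3 volatility belief -- the
#'   initial belief about how unstable the task environment is. Higher
#'   values mean a stronger expectation of erratic contingency shifts.
#' @param mu2_0 Initial level-2 mean, recycled across decks (default 0,
#'   i.e. a 50% win expectation for every deck).
#' @param sigma2_0,sigma3_0 Initial variances (> 0).
#' @param phi2,phi3 Autoregressive mean-reversion rates in `[0, 1]` for
#'   levels 2 and 3 (0 = pure random walk, 1 = full reversion each trial).
#' @param m2,m3 Attractor values of the autoregressive processes. `m3`
#'   defaults to `mu3_0` so that with `kappa = 0` and `phi3 = 1` the
#'   volatility belief stays at its prior.
#' @param beta0 Scale of the softmax inverse temperature.
#' @param beta_coupling `"trialwise"` (default) couples the inverse
#'   temperature to the current predicted volatility,
#'   `beta_t = beta0 * exp(-mu3hat_t)`; `"prior"` fixes it at
#'   `beta0 * exp(-mu3_0)`. Either way, higher expected volatility means
#'   a lower inverse temperature, i.e. noisier choices.
#' @return An `hgf_params` list.
#' @export
hgf_params <- function(omega2 = -3, kappa = 1, omega3 = -6, mu3_0 = -2,
                       mu2_0 = 0, sigma2_0 = 1, sigma3_0 = 1,
                       phi2 = 0.05, phi3 = 0.05, m2 = 0, m3 = NULL,
                       beta0 = 5,
                       beta_coupling = c("trialwise", "prior")) {
  beta_coupling <- match.arg(beta_coupling)
  check_that(sigma2_0 > 0 && sigma3_0 > 0, "Initial variances must be > 0.")
  check_that(kappa >= 0, "`kappa` must be >= 0.")
  check_that(phi2 >= 0 && phi2 <= 1 && phi3 >= 0 && phi3 <= 1,
             "`phi2` and `phi3` must lie in [0, 1].")
  check_that(beta0 > 0, "`beta0` must be > 0.")
  structure(
    list(omega2 = omega2, kappa = kappa, omega3 = omega3, mu3_0 = mu3_0,
         mu2_0 = mu2_0, sigma2_0 = sigma2_0, sigma3_0 = sigma3_0,
         phi2 = phi2, phi3 = phi3, m2 = m2, m3 = m3 %||% mu3_0,
         beta0 = beta0, beta_coupling = beta_coupling),
    class = "hgf_params")
}

#' Run the HGF forward pass over an observed choice/outcome sequence
#'
#' Applies the three-level binary-outcome HGF variational updates to the
#' chosen deck's level-2 belief on every trial; unchosen decks receive the
#' autoregressive prediction step only, and the shared level-3 volatility
#' state is updated from the chosen deck's volatility prediction error.
#' Trial-wise choice probabilities come from a softmax over the decks'
#' predicted win probabilities whose inverse temperature decreases with
#' the current volatility estimate.
#'
#' @param params An [hgf_params()] object.
#' @param choices Integer vector of chosen decks (1-based).
#' @param outcomes Binary outcomes (1 = win / 0 = loss, or
#'   `"win"`/`"loss"` strings).
#' @param n_decks Number of decks (default 3).
#' @return An `hgf_trajectories` object: per-trial, per-deck predicted and
#'   posterior level-2 means/variances, predicted win probabilities,
#'   choice probabilities, the level-3 trajectory, prediction errors at
#'   levels 1-2, and the sequence log-likelihood (`loglik`).
#' @examples
#' traj <- hgf_forward(hgf_params(), choices = c(1, 2, 3, 1),
#'                     outcomes = c(1, 0, 0, 1))
#' rowSums(traj$choice_prob) # all 1
#' @export
hgf_forward <- function(params, choices, outcomes, n_decks = 3L) {
  stopifnot(inherits(params, "hgf_params"))
  choices <- as.integer(choices)
  if (is.character(outcomes)) outcomes <- as.integer(outcomes == "win")
  outcomes <- as.integer(outcomes)
  check_that(length(choices) == length(outcomes) && length(choices) > 0,
             "`choices` and `outcomes` must be non-empty and equal length.")
  check_that(all(choices >= 1L & choices <= n_decks),
             "All choices must be deck indices in 1..n_decks.")
  check_that(all(outcomes %in% c(0L, 1L)), "Outcomes must be binary.")
  mu2_0 <- rep_len(params$mu2_0, n_decks)
  out <- hgf_forward_cpp(mu2_0, params$sigma2_0, params$mu3_0,
                         params$sigma3_0, params$omega2, params$kappa,
                         params$omega3, params$phi2, params$phi3,
                         params$m2, params$m3, params$beta0,
                         as.integer(params$beta_coupling == "trialwise"),
                         choices, outcomes)
  if (out$bad_trial > 0) {
    abort(paste0("HGF update ill-posed (non-positive precision) at trial ",
                 out$bad_trial,
                 "; parameter values rejected."))
  }
  out$choices <- choices
  out$outcomes <- outcomes
  out$params <- params
  class(out) <- "hgf_trajectories"
  out
}

#' Softmax choice probabilities under the volatility-coupled response model
#'
#' @param values Predicted deck values (one per deck), typically the
#'   predicted win probabilities from the HGF forward pass.
#' @param volatility Current volatility estimate (`mu3hat`); ignored when
#'   `params$beta_coupling == "prior"`.
#' @param params An [hgf_params()] object supplying `beta0`, `mu3_0` and
#'   the coupling mode.
#' @return A probability vector summing to 1. The inverse temperature is
#'   `beta0 * exp(-volatility)`: as the volatility estimate grows, choices
#'   approach uniform.
#' @export
hgf_choice_prob <- function(values, volatility, params = hgf_params()) {
  v <- if (identical(params$beta_coupling, "prior")) params$mu3_0 else volatility
  beta <- params$beta0 * exp(-v)
  z <- beta * values
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

## Internal pure-R state machinery used by agent_hgf() (online play).
hgf_state_init <- function(params, n_decks) {
  list(mu2 = rep_len(params$mu2_0, n_decks),
       sigma2 = rep(params$sigma2_0, n_decks),
       mu3 = params$mu3_0, sigma3 = params$sigma3_0)
}

hgf_predict <- function(state, params) {
  mu3hat <- state$mu3 + params$phi3 * (params$m3 - state$mu3)
  v2 <- exp(params$kappa * mu3hat + params$omega2)
  mu2hat <- state$mu2 + params$phi2 * (params$m2 - state$mu2)
  sigma2hat <- state$sigma2 + v2
  list(mu2hat = mu2hat, sigma2hat = sigma2hat, mu1hat = plogis(mu2hat),
       mu3hat = mu3hat, sigma3hat = state$sigma3 + exp(params$omega3),
       v2 = v2)
}

hgf_softmax <- function(mu1hat, mu3hat, params) {
  hgf_choice_prob(mu1hat, mu3hat, params)
}

hgf_update <- function(state, params, choice, win) {
  p <- hgf_predict(state, params)
  c <- choice
  d1 <- as.numeric(win) - p$mu1hat[c]
  pihat2 <- 1 / p$sigma2hat[c]
  pi2 <- pihat2 + p$mu1hat[c] * (1 - p$mu1hat[c])
  mu2new <- p$mu2hat[c] + d1 / pi2
  w2 <- p$v2 * pihat2
  d2 <- (1 / pi2 + (mu2new - p$mu2hat[c])^2) * pihat2 - 1
  pihat3 <- 1 / p$sigma3hat
  pi3 <- pihat3 + 0.5 * params$kappa^2 * w2 * (w2 + (2 * w2 - 1) * d2)
  if (!(pi3 > 0)) abort("HGF update ill-posed (non-positive level-3 precision).")
  mu3new <- p$mu3hat + 0.5 * params$kappa * (w2 / pi3) * d2
  state$mu2 <- p$mu2hat
  state$sigma2 <- p$sigma2hat
  state$mu2[c] <- mu2new
  state$sigma2[c] <- 1 / pi2
  state$mu3 <- mu3new
  state$sigma3 <- 1 / pi3
  state
}

#' @export
print.hgf_trajectories <- function(x, ...) {
  cat("<hgf_trajectories>", length(x$choices), "trials,",
      ncol(x$choice_prob), "decks; loglik =", round(x$loglik, 3), "\n")
  invisible(x)
}
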