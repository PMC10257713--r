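#' Kalman-filter learning rules for the Horizon task
#'
#' The learning model tracks the expected mean reward `R` of each slot
#' machine with a Kalman filter. After observing reward `r` on a played
#' machine, the estimate moves by a learning-rate-weighted prediction
#' error:
#' \deqn{R_{t+1} = R_t + \alpha_t (r_t - R_t)}
#' Unplayed machines are not updated. The learning rate itself evolves
#' with the (believed) drift of the reward means: with drift increment
#' \eqn{\alpha_d = \sigma_d^2 / \sigma_r^2 + 1},
#' \deqn{1/\alpha_t = 1/(\alpha_{t-1} + \alpha_d) + 1,}
#' which converges to the asymptote
#' \deqn{\alpha_\infty = \tfrac{1}{2}(-\alpha_d + \sqrt{\alpha_d^2 + 4 \alpha_d}).}
#' Fitting works with `alpha1` (initial) and `alpha_inf` (asymptotic)
#' rates; `alpha_drift_from_asymptote()` inverts the closed form to
#' recover \eqn{\alpha_d = \alpha_\infty^2 / (1 - \alpha_\infty)}.
#'
#' @param R Current expected mean reward.
#' @param alpha Learning rate in (0, 1].
#' @param reward Observed reward.
#' @return `kalman_update()`: the updated expectation.
#' @examples
#' kalman_update(10, 0.5, 20) # 15
#' alpha_asymptote(1)         # (sqrt(5) - 1) / 2
#' @export
kalman_update <- function(R, alpha, reward) {
  check_that(all(is.finite(c(R, alpha, reward))), "Inputs must be finite.")
  R + alpha * (reward - R)
}

#' @rdname kalman_update
#' @param alpha_d Drift increment (>= 0).
#' @export
alpha_asymptote <- function(alpha_d) {
  check_that(all(alpha_d >= 0), "`alpha_d` must be >= 0.")
  0.5 * (-alpha_d + sqrt(alpha_d^2 + 4 * alpha_d))
}

#' @rdname kalman_update
#' @param alpha_inf Asymptotic learning rate in (0, 1).
#' @export
alpha_drift_from_asymptote <- function(alpha_inf) {
  check_that(all(alpha_inf > 0) && all(alpha_inf < 1),
             "`alpha_inf` must lie strictly inside (0, 1) to imply a drift.")
  alpha_inf^2 / (1 - alpha_inf)
}

#' @rdname kalman_update
#' @param alpha1 Initial learning rate in (0, 1].
#' @param n_steps Number of played trials.
#' @return `learning_rate_sequence()`: the ordered learning rates
#'   \eqn{\alpha_1, \ldots, \alpha_n}, converging to `alpha_inf`.
#' @export
learning_rate_sequence <- function(alpha1, alpha_inf, n_steps) {
  check_that(alpha1 > 0 && alpha1 <= 1, "`alpha1` must lie in (0, 1].")
  check_count(n_steps, "n_steps")
  ad <- alpha_drift_from_asymptote(alpha_inf)
  a <- numeric(n_steps)
  a[1] <- alpha1
  if (n_steps > 1L) {
    for (t in 2:n_steps) a[t] <- 1 / (1 / (a[t - 1] + ad) + 1)
  }
  a
}

#' Logistic choice rule for the first free choice
#'
#' Implements the printed decision rule
#' \deqn{p(\mathrm{right}) = \frac{1}{1 + \exp\{(\Delta R + A \Delta I + B) / \sigma\}}}
#' with \eqn{\Delta R = R_\mathrm{left} - R_\mathrm{right}} and
#' \eqn{\Delta I = +1} when the left option was more informative (less
#' sampled), \eqn{-1} when the right was, and 0 under equal information.
#' `A` is the information bonus, `B` a spatial bias, and `sigma > 0` the
#' decision noise. A much larger right-hand estimate drives
#' \eqn{p(\mathrm{right}) \to 1}; the rule is exactly complementary for
#' the left option.
#'
#' @param R_left,R_right Learned expected mean rewards.
#' @param dI Information differential in `{-1, 0, +1}`.
#' @param A Information bonus (points).
#' @param B Spatial bias (points).
#' @param sigma Decision noise (points, > 0).
#' @return Probability of choosing the right option.
#' @examples
#' horizon_choice_prob(50, 50, 0, A = 0, B = 0, sigma = 5) # 0.5
#' @export
horizon_choice_prob <- function(R_left, R_right, dI, A, B, sigma) {
  check_that(all(sigma > 0), "`sigma` must be > 0.")
  check_that(all(dI %in% c(-1, 0, 1)), "`dI` must be -1, 0 or +1.")
  1 / (1 + exp((R_left - R_right + A * dI + B) / sigma))
}
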