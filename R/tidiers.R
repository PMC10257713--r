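## broom-style tidiers for the fitted objects.

#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per term/parameter; `glance()` returns a
#' one-row model summary, in the conventional broom shapes.
#'
#' @param x A fitted object (`hgf_fit`, `horizon_fit`, `ols_fit`, or
#'   `vb_analysis`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy hgf_fit
#' @export
tidy.hgf_fit <- function(x, ...) {
  tidyr::pivot_longer(x$estimates, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @rdname tidiers
#' @method glance hgf_fit
#' @export
glance.hgf_fit <- function(x, ...) {
  tibble(logLik = x$loglik, BIC = x$BIC, n_trials = x$n_trials,
         convergence = x$convergence)
}

#' @rdname tidiers
#' @method tidy horizon_fit
#' @export
tidy.horizon_fit <- function(x, ...) {
  tidyr::pivot_longer(x$estimates, -"subject_id",
                      names_to = "term", values_to = "estimate")
}

#' @rdname tidiers
#' @method glance horizon_fit
#' @export
glance.horizon_fit <- function(x, ...) {
  dplyr::bind_cols(tibble(method = x$method,
                          n_subjects = nrow(x$estimates)),
                   x$diagnostics)
}

#' @rdname tidiers
#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) x$coefficients

#' @rdname tidiers
#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, p_model = x$p_model, n = x$n)
}

#' @rdname tidiers
#' @method tidy vb_analysis
#' @export
tidy.vb_analysis <- function(x, ...) x$coefficients

#' @rdname tidiers
#' @method glance vb_analysis
#' @export
glance.vb_analysis <- function(x, ...) {
  r <- x$regressions
  tibble(outcome = r$outcome, predictor_set = r$predictor_set,
         sample = r$sample,
         n_retained = vapply(r$retained, length, integer(1)),
         r_squared = r$r_squared, p_model = r$p_model, n = r$n)
}
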