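#' Metrics table built from planted ground truth
#'
#' Assembles the regression-stage input for a synthetic cohort using the
#' planted agent parameters directly (plus optional Gaussian measurement
#' noise) for the computational columns, instead of model fits:
#' `mu3_0` from the generative HGF parameters and the random-exploration
#' contrasts from the generative decision noises. Behavioral columns
#' (win-switch and lose-stay rates, BADE-EII, questionnaire scores) are
#' still computed from the simulated data.
#'
#' This isolates the statistical stage from estimation noise: it is the
#' oracle input for validating the LASSO-then-OLS selection behavior
#' (does the stage retain planted predictors for the matching outcome
#' and drop them for the mismatched one?), and for power analyses of the
#' planted-effect design. For the full pipeline on fitted parameters use
#' [subject_metrics()] with [fit_hgf()] / [fit_horizon()] results.
#'
#' @param cohort A `vb_cohort` from [generate_cohort()].
#' @param measurement_noise_sd Standard deviation of the noise added to
#'   each true computational column, expressed as a fraction of that
#'   column's cohort SD (default 0.3, emulating estimation error).
#' @param seed Integer seed for the noise draws.
#' @return A metrics tibble as from [subject_metrics()], with `mu3_0`,
#'   `random_explore_equal` and `random_explore_unequal` columns.
#' @export
planted_metrics <- function(cohort, measurement_noise_sd = 0.3, seed = 1L) {
  stopifnot(inherits(cohort, "vb_cohort"))
  m <- subject_metrics(cohort)
  gt <- cohort$ground_truth
  set.seed(derive_seed(seed, 5L))
  noisy <- function(x) x + rnorm(length(x), 0, measurement_noise_sd * sd(x))
  add <- tibble(
    subject_id = gt$subject_id,
    mu3_0 = noisy(gt$mu3_0),
    random_explore_equal = noisy(gt$sigma_H6_equal - gt$sigma_H1_equal),
    random_explore_unequal = noisy(gt$sigma_H6_unequal - gt$sigma_H1_unequal))
  dplyr::left_join(m, add, by = "subject_id")
}
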