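#' Run the whole pipeline: cohort -> metrics -> fits -> analysis
#'
#' Generates (or loads) a cohort, fits both computational models,
#' assembles the metrics table, runs the statistical stage, and writes a
#' report directory (`group_tests.csv`, `correlations.csv`,
#' `regression_results.csv`, `metrics.csv`, `manifest.yaml`). Every
#' stochastic stage's seed derives from the master seed; the manifest
#' records the seeds, transform descriptors, lambda values, and md5
#' hashes of the emitted files, so a rerun with the same configuration
#' reproduces every number.
#'
#' @param out_dir Report directory (created if needed).
#' @param cohort Optional pre-built `vb_cohort`; by default one is
#'   generated from `n_control`, `n_patient`, `plan` and `seed`.
#' @param n_control,n_patient,plan Cohort settings (see
#'   [generate_cohort()]).
#' @param seed Master seed.
#' @param fit_models Fit the HGF and Horizon models (`TRUE`) or run the
#'   behavioral-only analysis with the computational columns absent.
#' @param horizon_method,hgf_starts Speed/quality knobs forwarded to the
#'   fitters.
#' @param rule LASSO lambda rule for [run_analysis()].
#' @return A `vb_pipeline` list: `cohort`, `metrics`, `analysis`, fit
#'   objects, and `manifest`, invisibly also written to `out_dir`.
#' @export
run_pipeline <- function(out_dir, cohort = NULL, n_control = 45L,
                         n_patient = 42L, plan = effect_plan(),
                         seed = 1L, fit_models = TRUE,
                         horizon_method = c("mcmc", "map"),
                         hgf_starts = 3L, rule = "1se") {
  horizon_method <- match.arg(horizon_method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    cohort <- generate_cohort(n_control, n_patient, plan = plan,
                              seed = derive_seed(seed, 1L))
  }
  write_cohort(cohort, file.path(out_dir, "cohort"))

  hgf_fits <- NULL; hz_fit <- NULL
  if (fit_models) {
    hgf_fits <- fit_hgf(cohort$prl_trials,
                        priors = hgf_priors(n_starts = hgf_starts),
                        seed = derive_seed(seed, 2L))
    hz_fit <- fit_horizon(cohort$horizon_trials, method = horizon_method,
                          seed = derive_seed(seed, 3L))
  }
  metrics <- subject_metrics(cohort, hgf_fits = hgf_fits,
                             horizon_fit = hz_fit)
  analysis <- run_analysis(metrics, rule = rule,
                           seed = derive_seed(seed, 4L))

  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(hgf_fits)) {
    utils::write.csv(hgf_fits, file.path(out_dir, "hgf_fits.csv"),
                     row.names = FALSE)
  }
  if (!is.null(hz_fit)) {
    utils::write.csv(tidy(hz_fit), file.path(out_dir, "horizon_fits.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(analysis$group_tests,
                   file.path(out_dir, "group_tests.csv"), row.names = FALSE)
  utils::write.csv(analysis$correlations,
                   file.path(out_dir, "correlations.csv"), row.names = FALSE)
  reg <- analysis$regressions
  reg$retained <- vapply(reg$retained, paste, character(1), collapse = ";")
  utils::write.csv(reg, file.path(out_dir, "regression_results.csv"),
                   row.names = FALSE)

  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE,
                      recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("volbandit")),
    master_seed = seed,
    stage_seeds = list(cohort = derive_seed(seed, 1L),
                       hgf = derive_seed(seed, 2L),
                       horizon = derive_seed(seed, 3L),
                       analysis = derive_seed(seed, 4L)),
    lasso = list(rule = rule),
    transforms = analysis$manifest$transforms,
    hashes = as.list(setNames(unname(tools::md5sum(files)),
                              basename(files))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(structure(
    list(cohort = cohort, metrics = metrics, analysis = analysis,
         hgf_fits = hgf_fits, horizon_fit = hz_fit, manifest = manifest,
         out_dir = out_dir),
    class = "vb_pipeline"))
}
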