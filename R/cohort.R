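#' Planted effect sizes for synthetic cohorts
#'
#' Defines how strongly the latent agent parameters drive the symptom
#' scales in a generated cohort. Effects are on the standardized scale:
#' a symptom latent is built as
#' `beta1 * z(mu3_0) + beta2 * z(random exploration) + e` (paranoia) or
#' `beta * z(JTC propensity) + e` (delusional ideation), with
#' `e ~ N(0, residual_sd)`, then mapped onto each instrument's support.
#' Setting every effect (and the offsets) to zero yields a null cohort.
#'
#' Defaults are tuned so that a cohort of roughly 90 subjects yields
#' regression R-squared values in the 0.07-0.40 band typical of
#' individual-differences work with these instruments.
#'
#' @param beta_paranoia_on_mu3 Standardized effect of the volatility
#'   prior on the paranoia latent (default 0.6).
#' @param beta_paranoia_on_rand_explore Standardized effect of random
#'   exploration (unequal condition) on the paranoia latent (default 0.35).
#' @param beta_delusion_on_jtc Standardized effect of the
#'   jumping-to-conclusions propensity on the delusional-ideation latent
#'   (default 0.6).
#' @param residual_sd Residual standard deviation of the symptom latents
#'   (default 1).
#' @param pdi_group_offset Additive patient-group shift on the PDI-21
#'   total, in raw scale points (default 8).
#' @param group_mu3_offset Additive patient-group shift on the true
#'   volatility prior `mu3_0` (default 0.7, calibrated so the patient
#'   group's win-switch elevation matches the moderate effect size seen
#'   clinically); this is the only planted group difference in task
#'   behavior.
#' @return An `effect_plan` list.
#' @export
effect_plan <- function(beta_paranoia_on_mu3 = 0.6,
                        beta_paranoia_on_rand_explore = 0.35,
                        beta_delusion_on_jtc = 0.6,
                        residual_sd = 1,
                        pdi_group_offset = 8,
                        group_mu3_offset = 0.7) {
  check_that(all(is.finite(c(beta_paranoia_on_mu3,
                             beta_paranoia_on_rand_explore,
                             beta_delusion_on_jtc, residual_sd,
                             pdi_group_offset, group_mu3_offset))),
             "All effect sizes must be finite.")
  check_that(residual_sd >= 0, "`residual_sd` must be >= 0.")
  structure(list(beta_paranoia_on_mu3 = beta_paranoia_on_mu3,
                 beta_paranoia_on_rand_explore = beta_paranoia_on_rand_explore,
                 beta_delusion_on_jtc = beta_delusion_on_jtc,
                 residual_sd = residual_sd,
                 pdi_group_offset = pdi_group_offset,
                 group_mu3_offset = group_mu3_offset),
            class = "effect_plan")
}

#' @rdname effect_plan
#' @export
null_effect_plan <- function() {
  effect_plan(0, 0, 0, residual_sd = 1, pdi_group_offset = 0,
              group_mu3_offset = 0)
}

#' Generate a BADE plausibility-rating grid
#'
#' Builds one participant's ratings for 12 scenarios x 4 explanations x
#' 3 presentation stages on a 0-100 scroll-bar scale. True explanations
#' start moderately possible and become the most possible; Lure
#' explanations start off possible and become less likely; Absurd
#' explanations are consistently implausible. The `impairment` level
#' inflates the Absurd ratings and the final Lure ratings proportionally
#' (these are exactly the cells entering the EII score), so EII is
#' monotone in `impairment` and sits at the floor of the scale when
#' `impairment = 0`.
#'
#' @param impairment Evidence-integration impairment level in `[0, 1]`.
#' @param n_scenarios Number of scenarios (default 12).
#' @return A rating-grid tibble accepted by [bade_eii()].
#' @export
generate_bade_grid <- function(impairment, n_scenarios = 12L) {
  check_that(is.numeric(impairment) && length(impairment) == 1L &&
               impairment >= 0 && impairment <= 1,
             "`impairment` must be a single value in [0, 1].")
  shapes <- list(true = c(50, 65, 85), lure_a = c(65, 45, 25),
                 lure_b = c(60, 45, 20), absurd = c(0, 0, 0))
  grid <- tidyr::expand_grid(scenario = seq_len(n_scenarios),
                             explanation = names(shapes), stage = 1:3)
  base <- vapply(seq_len(nrow(grid)), function(i) {
    shapes[[grid$explanation[i]]][grid$stage[i]]
  }, numeric(1))
  eii_cell <- grid$explanation == "absurd" |
    (grid$explanation %in% c("lure_a", "lure_b") & grid$stage == 3L)
  inflate <- ifelse(grid$explanation == "absurd", 65, 45) * impairment
  ## noise in EII cells scales with impairment so the floor stays exact
  noise <- rnorm(nrow(grid), 0,
                 ifelse(eii_cell, 6 * impairment, 6))
  grid$rating <- round(pmin(pmax(
    ifelse(eii_cell, inflate, base) + noise, 0), 100))
  grid
}

## Likert items monotone in a latent propensity.
likert_items <- function(latent, n_items, lo, hi, slope = 0.8,
                         item_noise = 0.6) {
  p <- plogis(slope * latent + rnorm(n_items, 0, item_noise))
  as.integer(lo + round((hi - lo) * p))
}

clamp_round <- function(x, lo, hi) as.integer(round(pmin(pmax(x, lo), hi)))

#' Generate a full synthetic study cohort
#'
#' Creates control and patient groups with known ("planted") agent
#' parameters, simulates each subject's reversal-learning session (HGF
#' agent) and Horizon games (Kalman agent), generates BADE rating grids
#' and questionnaire items, and builds symptom scores as linear functions
#' of the planted predictors plus Gaussian noise, truncated to each
#' instrument's support:
#'
#' * r-GPTS-b persecutory-ideation total (0-40, all subjects), driven by
#'   the volatility prior `mu3_0` and random exploration.
#' * PDI-21 total (0-336, all subjects), driven by the JTC propensity
#'   plus a patient-group offset.
#' * PANSS P6 (suspiciousness) and P1 (delusions), 1-7, patients only,
#'   driven by the paranoia and delusional-ideation latents respectively.
#'
#' The ground truth (true parameters, latent propensities) is returned
#' alongside the data for recovery scoring; fitting code never reads it.
#'
#' @param n_control,n_patient Group sizes (defaults 45 and 42).
#' @param plan An [effect_plan()].
#' @param seed Master seed; every stage seed derives from it.
#' @param prl,horizon Task configurations.
#' @param simulate_tasks If `FALSE`, skip the (comparatively costly) task
#'   simulations and produce only questionnaires, BADE and symptoms.
#' @return A `vb_cohort` list with tibbles `subjects`, `prl_trials`,
#'   `horizon_trials`, `bade`, `questionnaires`, and `ground_truth`.
#' @export
generate_cohort <- function(n_control = 45L, n_patient = 42L,
                            plan = effect_plan(), seed = 1L,
                            prl = prl_config(), horizon = horizon_config(),
                            simulate_tasks = TRUE) {
  check_that(n_control >= 1L || n_patient >= 1L,
             "At least one group must be non-empty.")
  if (n_patient == 0L &&
      (plan$pdi_group_offset != 0 || plan$group_mu3_offset != 0)) {
    abort("Plan includes patient-group effects but `n_patient` is 0.")
  }
  set.seed(derive_seed(seed, 1L))
  n <- n_control + n_patient
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = c(rep("control", n_control), rep("patient", n_patient)),
    age = clamp_round(rnorm(n, 28.8, 7), 18, 55),
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.65, 0.35)),
    scip_z = round(rnorm(n, ifelse(
      c(rep(FALSE, n_control), rep(TRUE, n_patient)), -0.45, 0.49),
      0.8), 3))

  ## --- latent agent parameters (the planted ground truth) ---
  truth <- tibble(
    subject_id = subjects$subject_id,
    group = subjects$group,
    omega2 = runif(n, -4.5, -1.5),
    omega3 = runif(n, -7, -4),
    kappa = runif(n, 0.5, 1.5),
    mu3_0 = runif(n, -3.5, -0.5) +
      plan$group_mu3_offset * (subjects$group == "patient"),
    R0 = rnorm(n, 50, 5),
    alpha1 = runif(n, 0.75, 1))
  truth$alpha_inf <- truth$alpha1 * runif(n, 0.15, 0.5)
  truth$A_H1 <- rnorm(n, 2, 4)
  truth$A_H6 <- rnorm(n, 10, 10)
  truth$B_H1 <- rnorm(n, 0, 3)
  truth$B_H6 <- rnorm(n, 0, 3)
  ls1 <- rnorm(n, log(8), 0.8); ls6 <- rnorm(n, log(14), 0.8)
  truth$sigma_H1_equal <- exp(ls1 + rnorm(n, 0, 0.15))
  truth$sigma_H1_unequal <- exp(ls1 + rnorm(n, 0, 0.15))
  truth$sigma_H6_equal <- exp(ls6 + rnorm(n, 0, 0.15))
  truth$sigma_H6_unequal <- exp(ls6 + rnorm(n, 0, 0.15))
  truth$jtc_propensity <- rnorm(n)
  truth$bade_impairment <- runif(n, 0.05, 0.9)

  ## --- symptom scores from the planted predictors ---
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  z_mu3 <- zs(truth$mu3_0)
  z_reu <- zs(truth$sigma_H6_unequal - truth$sigma_H1_unequal)
  z_jtc <- zs(truth$jtc_propensity)
  paranoia <- plan$beta_paranoia_on_mu3 * z_mu3 +
    plan$beta_paranoia_on_rand_explore * z_reu +
    rnorm(n, 0, plan$residual_sd)
  delusion <- plan$beta_delusion_on_jtc * z_jtc +
    rnorm(n, 0, plan$residual_sd)
  is_pat <- subjects$group == "patient"
  subjects$rgpts_b <- clamp_round(3 + 3.2 * paranoia, 0, 40)
  subjects$pdi21 <- clamp_round(
    14 + plan$pdi_group_offset * is_pat + 12 * delusion, 0, 336)
  p6 <- clamp_round(2.7 + 1.2 * paranoia +
                      rnorm(n, 0, 0.4 * plan$residual_sd), 1, 7)
  p1 <- clamp_round(2.4 + 1.2 * delusion +
                      rnorm(n, 0, 0.4 * plan$residual_sd), 1, 7)
  subjects$panss_p6 <- ifelse(is_pat, p6, NA_integer_)
  subjects$panss_p1 <- ifelse(is_pat, p1, NA_integer_)

  ## --- questionnaires (item level) ---
  questionnaires <- purrr::map_dfr(seq_len(n), function(i) {
    set.seed(derive_seed(seed, 3000L + i))
    dplyr::bind_rows(
      tibble(subject_id = subjects$subject_id[i], instrument = "dacobs_jtc",
             item = 1:6,
             score = likert_items(truth$jtc_propensity[i], 6L, 1L, 7L)),
      tibble(subject_id = subjects$subject_id[i], instrument = "bcis_sr",
             item = 1:9, score = likert_items(rnorm(1), 9L, 0L, 3L)),
      tibble(subject_id = subjects$subject_id[i], instrument = "bcis_sc",
             item = 1:5, score = likert_items(rnorm(1), 5L, 0L, 3L)))
  })

  ## --- BADE grids ---
  bade <- purrr::map_dfr(seq_len(n), function(i) {
    set.seed(derive_seed(seed, 4000L + i))
    g <- generate_bade_grid(truth$bade_impairment[i])
    g$subject_id <- subjects$subject_id[i]
    g[, c("subject_id", "scenario", "explanation", "stage", "rating")]
  })

  ## --- task play ---
  prl_trials <- NULL; horizon_trials <- NULL
  if (simulate_tasks) {
    prl_trials <- purrr::map_dfr(seq_len(n), function(i) {
      p <- hgf_params(omega2 = truth$omega2[i], kappa = truth$kappa[i],
                      omega3 = truth$omega3[i], mu3_0 = truth$mu3_0[i])
      simulate_prl(agent_hgf(p), prl, seed = derive_seed(seed, 1000L + i),
                   subject_id = subjects$subject_id[i])
    })
    horizon_trials <- purrr::map_dfr(seq_len(n), function(i) {
      pars <- as.list(truth[i, c("R0", "alpha1", "alpha_inf",
                                 "A_H1", "A_H6", "B_H1", "B_H6",
                                 "sigma_H1_equal", "sigma_H1_unequal",
                                 "sigma_H6_equal", "sigma_H6_unequal")])
      games <- horizon_games(horizon, seed = derive_seed(seed, 2000L + i))
      horizon_play(games, agent_kalman(pars), horizon,
                   seed = derive_seed(seed, 2500L + i),
                   subject_id = subjects$subject_id[i])
    })
  }

  structure(list(subjects = subjects,
                 prl_trials = prl_trials,
                 horizon_trials = horizon_trials,
                 bade = bade,
                 questionnaires = questionnaires,
                 ground_truth = truth,
                 plan = plan, seed = seed),
            class = "vb_cohort")
}

#' @export
print.vb_cohort <- function(x, ...) {
  cat("<vb_cohort>", nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "control"), "control /",
      sum(x$subjects$group == "patient"), "patient )\n")
  if (!is.null(x$prl_trials))
    cat("  reversal-learning trials:", nrow(x$prl_trials), "\n")
  if (!is.null(x$horizon_trials))
    cat("  horizon trials:", nrow(x$horizon_trials), "\n")
  invisible(x)
}
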