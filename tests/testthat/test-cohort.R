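test_that("generated cohorts are reproducible and respect instrument supports", {
  co1 <- generate_cohort(n_control = 8, n_patient = 8, seed = 70,
                         simulate_tasks = FALSE)
  co2 <- generate_cohort(n_control = 8, n_patient = 8, seed = 70,
                         simulate_tasks = FALSE)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$questionnaires, co2$questionnaires)
  s <- co1$subjects
  expect_true(all(s$rgpts_b >= 0 & s$rgpts_b <= 40))
  expect_true(all(s$pdi21 >= 0 & s$pdi21 <= 336))
  ## PANSS exists for patients only, on the 1-7 clinical scale
  expect_true(all(is.na(s$panss_p6[s$group == "control"])))
  pat <- s[s$group == "patient", ]
  expect_true(all(pat$panss_p6 >= 1 & pat$panss_p6 <= 7))
  expect_true(all(pat$panss_p1 >= 1 & pat$panss_p1 <= 7))
  ## questionnaire items on their scales
  q <- co1$questionnaires
  expect_true(all(q$score[q$instrument == "dacobs_jtc"] %in% 1:7))
  expect_true(all(q$score[q$instrument %in% c("bcis_sr", "bcis_sc")] %in% 0:3))
})

test_that("ground truth is stored alongside and the plan is rejected when inconsistent", {
  co <- generate_cohort(n_control = 5, n_patient = 5, seed = 71,
                        simulate_tasks = FALSE)
  expect_identical(nrow(co$ground_truth), 10L)
  expect_true(all(c("mu3_0", "jtc_propensity", "sigma_H6_unequal") %in%
                    names(co$ground_truth)))
  expect_error(
    generate_cohort(n_control = 5, n_patient = 0, seed = 1,
                    plan = effect_plan(pdi_group_offset = 8)),
    "patient-group effects")
})

test_that("a null plan yields null associations; a planted plan yields positive ones", {
  null_co <- generate_cohort(n_control = 100, n_patient = 100,
                             plan = null_effect_plan(), seed = 72,
                             simulate_tasks = FALSE)
  rho0 <- cor(null_co$ground_truth$mu3_0, null_co$subjects$rgpts_b,
              method = "spearman")
  expect_lt(abs(rho0), 2 / sqrt(200))
  planted <- generate_cohort(n_control = 100, n_patient = 100,
                             plan = effect_plan(beta_paranoia_on_mu3 = 0.9),
                             seed = 73, simulate_tasks = FALSE)
  sp <- spearman(planted$ground_truth$mu3_0, planted$subjects$rgpts_b)
  expect_gt(sp$rho, 0.3)
  expect_lt(sp$p, 0.001)
  ## delusional ideation follows the JTC propensity, not the volatility prior
  sp_j <- spearman(planted$ground_truth$jtc_propensity,
                   planted$subjects$pdi21)
  expect_gt(sp_j$rho, 0.3)
})

test_that("BADE grids sit at the floor for zero impairment and EII is monotone in impairment", {
  set.seed(74)
  g0 <- generate_bade_grid(0)
  expect_identical(bade_eii(g0), 0)
  expect_true(all(g0$rating >= 0 & g0$rating <= 100))
  eiis <- vapply(c(0.1, 0.4, 0.7, 1), function(im) {
    set.seed(75)
    bade_eii(generate_bade_grid(im))
  }, numeric(1))
  expect_true(all(diff(eiis) > 0))
  g1 <- generate_bade_grid(1)
  expect_true(all(g1$rating <= 100))
})

test_that("patients show elevated win-switch rate under the default plan", {
  co <- generate_cohort(n_control = 40, n_patient = 40, seed = 76)
  m <- subject_metrics(co)
  mw <- mann_whitney(m$wsr[m$group == "patient"],
                     m$wsr[m$group == "control"])
  ## group offset on mu3_0 drives more switching in patients
  expect_gt(mean(m$wsr[m$group == "patient"], na.rm = TRUE),
            mean(m$wsr[m$group == "control"], na.rm = TRUE))
})
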