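make_horizon_cohort <- function(n_subjects, seed, tweak = list()) {
  cfg <- horizon_config()
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    pars <- utils::modifyList(toy_kalman_params(), tweak)
    games <- horizon_games(cfg, seed = seed + 10 * i)
    horizon_play(games, agent_kalman(pars), cfg, seed = seed + 10 * i + 1,
                 subject_id = sprintf("s%02d", i))
  })
}

test_that("the design table extracts forced rewards, counts, and the first free choice", {
  trials <- make_horizon_cohort(1, seed = 30)
  des <- volbandit:::horizon_design(trials)
  expect_identical(nrow(des), 80L)
  expect_true(all(des$n_left + des$n_right == 4L))
  expect_true(all(des$dI[des$info == "equal"] == 0))
  expect_true(all(abs(des$dI[des$info == "unequal"]) == 1))
  ## dI = +1 when the left side is less sampled (more informative)
  expect_true(all(des$dI[des$info == "unequal" & des$n_left == 1] == 1))
})

test_that("MAP fitting is deterministic and likelihood matches the oracle identity", {
  trials <- make_horizon_cohort(4, seed = 31)
  f1 <- fit_horizon(trials, method = "map", seed = 5)
  f2 <- fit_horizon(trials, method = "map", seed = 5)
  expect_identical(f1$estimates, f2$estimates)
  ## the reported model's log-likelihood equals the sum of log choice
  ## probabilities over first-free-choice observations
  ll <- horizon_loglik(f1, trials)
  des <- volbandit:::horizon_design(trials)
  manual <- 0
  for (s in unique(des$subject_id)) {
    e <- f1$estimates[f1$estimates$subject_id == s, ]
    d <- des[des$subject_id == s, ]
    for (i in seq_len(nrow(d))) {
      R <- volbandit:::design_row_R(d[i, ], e$R0, e$alpha1, e$alpha_inf)
      hh <- if (d$horizon[i] == 1) "H1" else "H6"
      pr <- horizon_choice_prob(R[1], R[2], d$dI[i],
                                e[[paste0("A_", hh)]],
                                e[[paste0("B_", hh)]],
                                e[[paste0("sigma_", hh, "_", d$info[i])]])
      manual <- manual + log(if (d$choice_right[i] == 1) pr else 1 - pr)
    }
  }
  expect_equal(ll, manual, tolerance = 1e-8)
})

test_that("a strong spatial bias is recovered with the right sign", {
  ## single subject pushed hard to the right on every free choice
  trials <- make_horizon_cohort(1, seed = 32,
                                tweak = list(B_H1 = -40, B_H6 = -40))
  f <- fit_horizon(trials, method = "map", seed = 1)
  expect_lt(f$estimates$B_H1, 0)
  expect_lt(f$estimates$B_H6, 0)
  ## negative B raises p(right); the subject should mostly go right
  free1 <- trials[!trials$forced & trials$trial == 5, ]
  expect_gt(mean(free1$side == "R"), 0.7)
})

test_that("hierarchical MCMC fitting runs, is seeded, and reports diagnostics", {
  trials <- make_horizon_cohort(3, seed = 33)
  f1 <- suppressWarnings(
    fit_horizon(trials, method = "mcmc", n_adapt = 200, n_burn = 200,
                n_iter = 400, thin = 2, seed = 9))
  f2 <- suppressWarnings(
    fit_horizon(trials, method = "mcmc", n_adapt = 200, n_burn = 200,
                n_iter = 400, thin = 2, seed = 9))
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-12)
  expect_identical(f1$diagnostics$n_chains, 2L)
  expect_true(all(c("mu_A_H6", "mu_R0") %in% f1$group$parameter))
  expect_true(is.finite(f1$diagnostics$min_ess))
  t <- tidy(f1)
  expect_setequal(unique(t$term), setdiff(names(f1$estimates), "subject_id"))
})

test_that("higher H6 information bonus produces more informative fifth choices in H6 than H1", {
  ## ground truth A_H6 > A_H1: the first free choice lands on the
  ## less-sampled side more often under the long horizon
  trials <- make_horizon_cohort(6, seed = 34,
                                tweak = list(A_H1 = 0, A_H6 = 30,
                                             sigma_H6_equal = 8,
                                             sigma_H6_unequal = 8))
  uneq <- trials[trials$info == "unequal", ]
  to_rare <- uneq |>
    dplyr::group_by(.data$subject_id, .data$game, .data$horizon) |>
    dplyr::group_modify(function(g, key) {
      f <- g[g$forced, ]
      rare <- if (sum(f$side == "L") < 2) "L" else "R"
      tibble::tibble(hit = g$side[!g$forced][1] == rare)
    }) |>
    dplyr::group_by(.data$horizon) |>
    dplyr::summarise(p = mean(.data$hit), .groups = "drop")
  expect_gt(to_rare$p[to_rare$horizon == 6], to_rare$p[to_rare$horizon == 1])
})
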