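test_that("win-switch and lose-stay rates match hand-enumerated toy cases", {
  ## W-stay, W-switch, L-stay, W-switch (final trial has no successor)
  toy <- toy_trials(c(1, 1, 2, 2, 1),
                    c("win", "win", "loss", "win", "win"))
  expect_equal(win_switch_rate(toy), 2 / 3)
  expect_equal(lose_stay_rate(toy), 1)
  ## constant-choice agent never switches
  stay <- toy_trials(rep(2, 10), rep(c("win", "loss"), 5))
  expect_identical(win_switch_rate(stay), 0)
  expect_identical(lose_stay_rate(stay), 1)
  ## always-switch agent
  flip <- toy_trials(rep(1:2, 5), rep(c("win", "loss"), 5))
  expect_identical(win_switch_rate(flip), 1)
  expect_identical(lose_stay_rate(flip), 0)
})

test_that("rates flag a missing value when no qualifying trials exist", {
  no_win <- toy_trials(c(1, 2, 3), rep("loss", 3))
  expect_warning(w <- win_switch_rate(no_win), "missing")
  expect_true(is.na(w))
  ## a win on the final trial only has no successor
  last_win <- toy_trials(c(1, 2), c("loss", "win"))
  expect_warning(w2 <- win_switch_rate(last_win), "missing")
  expect_true(is.na(w2))
})

test_that("rate metrics agree with a brute-force recount on random trial lists", {
  set.seed(50)
  for (r in 1:1000) {
    n <- sample(2:30, 1)
    ch <- sample(1:3, n, TRUE)
    out <- sample(c("win", "loss"), n, TRUE)
    t <- toy_trials(ch, out)
    expect_identical(suppressWarnings(win_switch_rate(t)),
                     wsr_oracle(ch, out))
    expect_identical(suppressWarnings(lose_stay_rate(t)),
                     lsr_oracle(ch, out))
  }
})

test_that("EII follows the printed per-scenario formula", {
  ## one scenario: absurd (2, 4, 6), final lures (5, 3) -> 4 + 4 = 8
  g <- uniform_bade_grid(0, n_scenarios = 1L)
  g$rating[g$explanation == "absurd"] <- c(2, 4, 6)
  g$rating[g$explanation == "lure_a" & g$stage == 3] <- 5
  g$rating[g$explanation == "lure_b" & g$stage == 3] <- 3
  expect_equal(bade_eii(g), 8)
  ## all zeros -> 0; uniform rating r -> 2r
  expect_identical(bade_eii(uniform_bade_grid(0)), 0)
  expect_identical(bade_eii(uniform_bade_grid(37)), 74)
})

test_that("EII is invariant to scenario order and excludes incomplete scenarios", {
  set.seed(51)
  g <- uniform_bade_grid(0)
  g$rating <- sample(0:100, nrow(g), TRUE)
  shuffled <- g[sample(nrow(g)), ]
  expect_equal(bade_eii(g), bade_eii(shuffled))
  ## missing one absurd rating drops that scenario
  g2 <- g
  g2$rating[which(g2$scenario == 5 & g2$explanation == "absurd")[1]] <- NA
  expect_warning(e2 <- bade_eii(g2), "excluded")
  expect_equal(e2, bade_eii(g[g$scenario != 5, ]))
  ## all scenarios incomplete -> error
  g3 <- g
  g3$rating[g3$explanation == "absurd"] <- NA
  expect_error(suppressWarnings(bade_eii(g3)), "No complete")
})

test_that("questionnaire scores are plain sums with validated supports", {
  expect_identical(dacobs_jtc(rep(1, 6)), 6L)
  expect_identical(dacobs_jtc(rep(7, 6)), 42L)
  expect_identical(dacobs_jtc(1:6), 21L)
  expect_error(dacobs_jtc(c(1, 2, 3, 4, 5, 8)), "must lie in")
  expect_error(dacobs_jtc(rep(1, 5)), "Expected 6")
  expect_identical(bcis_composite(rep(0, 9), rep(0, 5)), 0L)
  expect_identical(bcis_composite(rep(2, 9), rep(1, 5)), 13L)
  ## swapping the subscales negates the composite (up to item counts)
  sr <- c(3, 1, 2, 0, 3, 2, 1, 0, 2); sc <- c(1, 2, 0, 3, 1)
  expect_identical(bcis_composite(sr, sc),
                   as.integer(sum(sr) - sum(sc)))
  expect_error(bcis_composite(rep(1, 5), rep(1, 5)), "9 items")
})

test_that("exploration contrasts are simple horizon differences", {
  est <- tibble::tibble(
    subject_id = c("a", "b"),
    A_H1 = c(2, 5), A_H6 = c(2, 1),
    sigma_H1_equal = c(7, 10), sigma_H6_equal = c(12, 10),
    sigma_H1_unequal = c(8, 3), sigma_H6_unequal = c(8, 9))
  ec <- exploration_contrasts(est)
  expect_equal(ec$directed_exploration, c(0, -4))
  expect_equal(ec$random_explore_equal, c(5, 0))
  expect_equal(ec$random_explore_unequal, c(0, 6))
  ## identical H1/H6 parameters -> all contrasts zero (subject a, sides)
  expect_true(all(ec[1, c("directed_exploration",
                          "random_explore_unequal")] == 0))
})
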