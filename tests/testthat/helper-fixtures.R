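## Shared fixtures built in code.

toy_trials <- function(choices, outcomes) {
  tibble::tibble(choice = choices, outcome = outcomes)
}

## A small, fully balanced Horizon parameter list.
toy_kalman_params <- function(...) {
  p <- list(R0 = 50, alpha1 = 0.9, alpha_inf = 0.3,
            A_H1 = 2, A_H6 = 10, B_H1 = 0, B_H6 = 0,
            sigma_H1_equal = 8, sigma_H1_unequal = 8,
            sigma_H6_equal = 14, sigma_H6_unequal = 14)
  utils::modifyList(p, list(...))
}

## Complete BADE grid with a single uniform rating.
uniform_bade_grid <- function(rating, n_scenarios = 12L) {
  g <- tidyr::expand_grid(scenario = seq_len(n_scenarios),
                          explanation = c("true", "lure_a", "lure_b", "absurd"),
                          stage = 1:3)
  g$rating <- rating
  g
}

## Brute-force recount oracles for the transition metrics.
wsr_oracle <- function(choice, outcome) {
  num <- 0L; den <- 0L
  for (t in seq_len(length(choice) - 1L)) {
    if (outcome[t] == "win") {
      den <- den + 1L
      if (choice[t + 1L] != choice[t]) num <- num + 1L
    }
  }
  if (den == 0L) NA_real_ else num / den
}

lsr_oracle <- function(choice, outcome) {
  num <- 0L; den <- 0L
  for (t in seq_len(length(choice) - 1L)) {
    if (outcome[t] == "loss") {
      den <- den + 1L
      if (choice[t + 1L] == choice[t]) num <- num + 1L
    }
  }
  if (den == 0L) NA_real_ else num / den
}

## All-pairs Mann-Whitney U count for group x (ties count one half).
mw_oracle <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}
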