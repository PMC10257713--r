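#' Configuration for the Horizon explore/exploit task
#'
#' Each game presents two slot machines whose rewards are Gaussian with a
#' common, fixed standard deviation. Four forced choices (equal `[2 2]`
#' or unequal `[1 3]` sampling) are followed by either 1 (Horizon 1) or 6
#' (Horizon 6) free choices. Game-level factors are exactly balanced
#' across the session, and the generative mean difference between
#' machines is drawn from a symmetric grid.
#'
#' @param n_games Number of games (default 80; must be divisible by 4 so
#'   the horizon x information cells balance exactly).
#' @param n_forced Forced choices per game (default 4).
#' @param horizons Free-choice horizons (default `c(1, 6)`).
#' @param reward_sd Gaussian reward standard deviation, common to all
#'   machines and games (default 8 points).
#' @param mean_diff_range Bound on the absolute generative mean
#'   difference (default 30 points).
#' @param mean_diff_step Grid step for the mean-difference draw (default
#'   2 points; the grid is `seq(-range, range, by = step)`).
#' @param baseline_mean Mean of the two machines' average (default 50
#'   points).
#' @param seed Optional integer seed stored in the config.
#' @return A `horizon_config` list.
#' @export
horizon_config <- function(n_games = 80L, n_forced = 4L,
                           horizons = c(1L, 6L), reward_sd = 8,
                           mean_diff_range = 30, mean_diff_step = 2,
                           baseline_mean = 50, seed = NULL) {
  check_count(n_games, "n_games", min = 4L)
  check_that(n_games %% 4L == 0L,
             "`n_games` must be divisible by 4 for balanced conditions.")
  check_count(n_forced, "n_forced")
  check_that(n_forced == 4L,
             "The information manipulation requires 4 forced choices.")
  check_that(length(horizons) == 2L && all(horizons >= 1),
             "`horizons` must be two positive horizon lengths.")
  check_that(reward_sd > 0, "`reward_sd` must be > 0.")
  check_that(mean_diff_range >= 0, "`mean_diff_range` must be >= 0.")
  structure(
    list(n_games = as.integer(n_games), n_forced = as.integer(n_forced),
         horizons = as.integer(horizons), reward_sd = reward_sd,
         mean_diff_range = mean_diff_range, mean_diff_step = mean_diff_step,
         baseline_mean = baseline_mean, seed = seed),
    class = "horizon_config")
}

## Grid of admissible generative mean differences (left minus right).
mean_diff_grid <- function(config) {
  if (config$mean_diff_range == 0) return(0)
  seq(-config$mean_diff_range, config$mean_diff_range,
      by = config$mean_diff_step)
}

#' Generate Horizon games (choices pending)
#'
#' Draws the game-level design: balanced horizon x information cells
#' (unequal games split evenly between `[3 1]` and `[1 3]` sampling),
#' generative means for each machine, and a uniformly drawn ordering of
#' the forced-choice sides within each game.
#'
#' @param config A [horizon_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with one row per game: `game`, `horizon`,
#'   `info` (`"equal"`/`"unequal"`), `gen_mean_left`, `gen_mean_right`,
#'   `n_forced_left`, `n_forced_right`, and `forced_sequence` (a
#'   character string of `L`/`R` labels of length `n_forced`).
#' @examples
#' games <- horizon_games(horizon_config(seed = 1))
#' table(games$horizon, games$info) # 20 per cell
#' @export
horizon_games <- function(config = horizon_config(), seed = NULL) {
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  per_cell <- config$n_games %/% 4L
  half <- per_cell %/% 2L
  cells <- purrr::map_dfr(config$horizons, function(h) {
    tibble(horizon = h,
           info = rep(c("equal", "unequal"), each = per_cell),
           n_forced_left = c(rep(2L, per_cell),
                             rep(3L, half), rep(1L, per_cell - half)))
  })
  cells$n_forced_right <- config$n_forced - cells$n_forced_left
  cells <- cells[sample.int(nrow(cells)), ]
  dm <- sample(mean_diff_grid(config), config$n_games, replace = TRUE)
  forced <- vapply(seq_len(config$n_games), function(i) {
    paste(sample(c(rep("L", cells$n_forced_left[i]),
                   rep("R", cells$n_forced_right[i]))), collapse = "")
  }, character(1))
  tibble(game = seq_len(config$n_games),
         horizon = cells$horizon,
         info = cells$info,
         gen_mean_left = config$baseline_mean + dm / 2,
         gen_mean_right = config$baseline_mean - dm / 2,
         n_forced_left = cells$n_forced_left,
         n_forced_right = cells$n_forced_right,
         forced_sequence = forced)
}

#' Play Horizon games with an agent
#'
#' Runs each game: the agent observes the forced-trial rewards in their
#' scheduled order, then emits its free choices one at a time; rewards
#' for chosen sides are drawn from that side's Gaussian, and the
#' unchosen side yields no observation.
#'
#' @param games A game table from [horizon_games()].
#' @param agent A Horizon agent, e.g. [agent_kalman()] or
#'   [agent_greedy()]: a list with closures
#'   `start_game(horizon, info)`, `observe(side, reward, forced)` and
#'   `choose(trial)` returning `"L"` or `"R"`.
#' @param config The [horizon_config()] the games were generated from
#'   (supplies `reward_sd`).
#' @param seed Integer seed.
#' @param subject_id Identifier copied into the output.
#' @return A trial-level tibble: `subject_id`, `game`, `horizon`, `info`,
#'   `trial` (1-based within game), `side` (`"L"`/`"R"`), `forced`
#'   (logical), `reward`, plus the game-level generative means.
#' @export
horizon_play <- function(games, agent, config = horizon_config(),
                         seed = NULL, subject_id = "s1") {
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", nrow(games))
  for (i in seq_len(nrow(games))) {
    g <- games[i, ]
    agent$start_game(g$horizon, g$info)
    forced_sides <- strsplit(g$forced_sequence, "")[[1]]
    n_total <- length(forced_sides) + g$horizon
    side <- character(n_total); reward <- numeric(n_total)
    for (t in seq_len(n_total)) {
      forced <- t <= length(forced_sides)
      s <- if (forced) forced_sides[t] else agent$choose(t)
      if (!forced && (t > n_total)) {
        abort(paste0("Agent emitted a choice after the horizon was ",
                     "exhausted in game ", g$game, "."))
      }
      check_that(s %in% c("L", "R"),
                 paste0("Invalid side label in game ", g$game, "."))
      m <- if (s == "L") g$gen_mean_left else g$gen_mean_right
      r <- rnorm(1, m, config$reward_sd)
      agent$observe(s, r, forced)
      side[t] <- s; reward[t] <- r
    }
    rows[[i]] <- tibble(
      subject_id = subject_id, game = g$game, horizon = g$horizon,
      info = g$info, trial = seq_len(n_total), side = side,
      forced = seq_len(n_total) <= length(forced_sides), reward = reward,
      gen_mean_left = g$gen_mean_left, gen_mean_right = g$gen_mean_right)
  }
  dplyr::bind_rows(rows)
}

#' Horizon-task agents
#'
#' `agent_kalman()` learns each machine's mean with the Kalman filter of
#' [kalman_update()] and chooses through the logistic rule of
#' [horizon_choice_prob()], with decision parameters indexed by horizon
#' (and, for the decision noise, by information condition).
#' `agent_greedy()` picks the side with the higher observed mean reward
#' (ties broken to the left) -- useful as a deterministic reference.
#'
#' @param params A named list with `R0`, `alpha1`, `alpha_inf`, `A_H1`,
#'   `A_H6`, `B_H1`, `B_H6`, and decision noises `sigma_H1_equal`,
#'   `sigma_H1_unequal`, `sigma_H6_equal`, `sigma_H6_unequal`.
#' @return An agent list understood by [horizon_play()].
#' @export
agent_kalman <- function(params) {
  need <- c("R0", "alpha1", "alpha_inf", "A_H1", "A_H6", "B_H1", "B_H6",
            "sigma_H1_equal", "sigma_H1_unequal",
            "sigma_H6_equal", "sigma_H6_unequal")
  check_that(all(need %in% names(params)),
             paste("`params` must name:", paste(need, collapse = ", ")))
  R <- c(L = params$R0, R = params$R0)
  k <- c(L = 0L, R = 0L) # observations per side within the game
  h_cur <- NULL; info_cur <- NULL
  alphas <- learning_rate_sequence(params$alpha1, params$alpha_inf, 12L)
  list(
    start_game = function(horizon, info) {
      R <<- c(L = params$R0, R = params$R0)
      k <<- c(L = 0L, R = 0L)
      h_cur <<- horizon; info_cur <<- info
      invisible(NULL)
    },
    observe = function(side, reward, forced) {
      k[side] <<- k[side] + 1L
      R[side] <<- kalman_update(R[side], alphas[k[side]], reward)
      invisible(NULL)
    },
    choose = function(trial) {
      dI <- if (k["L"] < k["R"]) 1 else if (k["R"] < k["L"]) -1 else 0
      hh <- if (h_cur == 1) "H1" else "H6"
      sg <- params[[paste0("sigma_", hh, "_", info_cur)]]
      p_right <- horizon_choice_prob(R[["L"]], R[["R"]], dI,
                                     params[[paste0("A_", hh)]],
                                     params[[paste0("B_", hh)]], sg)
      if (runif(1) < p_right) "R" else "L"
    })
}

#' @rdname agent_kalman
#' @export
agent_greedy <- function() {
  sums <- c(L = 0, R = 0); k <- c(L = 0L, R = 0L)
  list(
    start_game = function(horizon, info) {
      sums <<- c(L = 0, R = 0); k <<- c(L = 0L, R = 0L)
      invisible(NULL)
    },
    observe = function(side, reward, forced) {
      sums[side] <<- sums[side] + reward
      k[side] <<- k[side] + 1L
      invisible(NULL)
    },
    choose = function(trial) {
      mL <- if (k["L"] > 0) sums["L"] / k["L"] else 0
      mR <- if (k["R"] > 0) sums["R"] / k["R"] else 0
      if (mR > mL) "R" else "L"
    })
}
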