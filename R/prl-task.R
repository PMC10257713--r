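#' Configuration for the three-option probabilistic reversal learning task
#'
#' The task presents three decks of cards. Each deck wins with a fixed
#' probability (its contingency); one deck -- the "best" deck -- wins most
#' often. When the participant has chosen the best deck on at least
#' `reversal_k` of the last `reversal_window` trials, the best deck
#' covertly changes (a reversal). Halfway through the session the whole
#' contingency set is replaced by a less discriminable one, without any
#' signal to the participant.
#'
#' @param n_blocks Number of blocks (default 4).
#' @param trials_per_block Trials per block (default 40).
#' @param contingencies_early Win probabilities for blocks before
#'   `transition_block` (default `c(0.9, 0.5, 0.1)`).
#' @param contingencies_late Win probabilities from `transition_block`
#'   onwards (default `c(0.8, 0.4, 0.2)`).
#' @param transition_block 1-based block index at which the late
#'   contingencies begin (default 3).
#' @param reversal_k Number of best-deck choices within the window that
#'   triggers a reversal (default 9).
#' @param reversal_window Width of the rolling choice window (default 10).
#' @param win_points,loss_points Points for a winning / losing card
#'   (defaults +100 / -50). Models consume the binary win/loss outcome;
#'   points are recorded for completeness.
#' @param seed Optional integer seed stored in the config and used by
#'   [simulate_prl()] when no explicit seed is given.
#' @return A `prl_config` list.
#' @export
prl_config <- function(n_blocks = 4L,
                       trials_per_block = 40L,
                       contingencies_early = c(0.9, 0.5, 0.1),
                       contingencies_late = c(0.8, 0.4, 0.2),
                       transition_block = 3L,
                       reversal_k = 9L,
                       reversal_window = 10L,
                       win_points = 100L,
                       loss_points = -50L,
                       seed = NULL) {
  check_count(n_blocks, "n_blocks")
  check_count(trials_per_block, "trials_per_block")
  check_prob(contingencies_early, "contingencies_early")
  check_prob(contingencies_late, "contingencies_late")
  check_that(length(contingencies_early) == 3L && length(contingencies_late) == 3L,
             "Contingency sets must have length 3 (one probability per deck).")
  check_count(transition_block, "transition_block")
  check_count(reversal_k, "reversal_k")
  check_count(reversal_window, "reversal_window")
  check_that(reversal_k <= reversal_window,
             "`reversal_k` must not exceed `reversal_window`.")
  check_that(trials_per_block >= reversal_window,
             "`trials_per_block` must be at least `reversal_window`.")
  check_that(transition_block <= n_blocks + 1L,
             "`transition_block` must be at most `n_blocks` + 1.")
  structure(
    list(n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         contingencies_early = contingencies_early,
         contingencies_late = contingencies_late,
         transition_block = as.integer(transition_block),
         reversal_k = as.integer(reversal_k),
         reversal_window = as.integer(reversal_window),
         win_points = as.integer(win_points),
         loss_points = as.integer(loss_points),
         seed = seed),
    class = "prl_config")
}

#' Low-level 3PRL environment
#'
#' `prl_env()` draws a fresh environment state (the deck-to-contingency
#' assignment is a uniform permutation; the best deck is whichever deck
#' holds the largest contingency). `prl_step()` plays one trial: it draws
#' the outcome for the chosen deck and applies the 9-of-10 reversal rule.
#' Reversals take effect from the next trial; the returned `reversal` flag
#' marks the trial that triggered them, after which a new best deck is
#' drawn uniformly from the other two and the rolling window resets.
#'
#' Most users should call [simulate_prl()]; these primitives are exposed
#' for custom interaction loops and for direct testing of the reversal
#' mechanics.
#'
#' @param config A [prl_config()].
#' @return `prl_env()`: an environment-state list. `prl_step()`: a list
#'   with `outcome` (`"win"`/`"loss"`), the updated `env`, and `reversal`.
#' @export
prl_env <- function(config) {
  values <- sample(config$contingencies_early)
  list(values = values,                 # current win probability per deck
       ranks = rank(-values),           # 1 = best; preserved across transition
       best = which.max(values),
       window = integer(0),             # rolling record: was best deck chosen?
       late = FALSE)
}

#' @rdname prl_env
#' @param env Environment state from `prl_env()` or a previous `prl_step()`.
#' @param choice Chosen deck, an index in 1..3.
#' @export
prl_step <- function(env, choice, config) {
  if (!(is.numeric(choice) && length(choice) == 1L && choice %in% 1:3)) {
    abort(paste0("Invalid deck choice `", deparse(choice),
                 "`: must be a single deck index in 1..3."))
  }
  win <- runif(1) < env$values[choice]
  env$window <- c(tail(env$window, config$reversal_window - 1L),
                  as.integer(choice == env$best))
  reversal <- sum(env$window) >= config$reversal_k
  if (reversal) {
    new_best <- sample(setdiff(1:3, env$best), 1L)
    others <- setdiff(1:3, new_best)
    set <- if (env$late) config$contingencies_late else config$contingencies_early
    set <- sort(set, decreasing = TRUE)
    env$values[new_best] <- set[1]
    env$values[others] <- sample(set[2:3])
    env$ranks <- rank(-env$values)
    env$best <- new_best
    env$window <- integer(0) # counts do not carry across a reversal
  }
  list(outcome = if (win) "win" else "loss", env = env, reversal = reversal)
}

## Switch to the late contingency set, preserving each deck's rank.
## The rolling window is deliberately left intact: the transition is
## unsignalled and independent of the reversal mechanism.
prl_env_transition <- function(env, config) {
  set <- sort(config$contingencies_late, decreasing = TRUE)
  env$values <- set[env$ranks]
  env$late <- TRUE
  env
}

#' Simulate one session of the 3-option probabilistic reversal learning task
#'
#' Plays `agent` against the task environment defined by `config` and
#' returns the trial-by-trial record. Fully reproducible from the seed.
#'
#' @param agent An agent created by one of the `agent_*()` constructors
#'   (see [agent_random()]), i.e. a list with `choose(n_decks, trial)` and
#'   `observe(choice, outcome)` closures.
#' @param config A [prl_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param subject_id Identifier copied into the output.
#' @return A tibble with one row per trial: `subject_id`, `trial` (1-based),
#'   `block`, `choice` (deck 1..3), `outcome` (`"win"`/`"loss"`), `points`,
#'   `best_deck`, `reversal`, `transition`.
#' @examples
#' trials <- simulate_prl(agent_random(), prl_config(seed = 1))
#' nrow(trials) # 160
#' @export
simulate_prl <- function(agent, config = prl_config(), seed = NULL,
                         subject_id = "s1") {
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  env <- prl_env(config)
  n <- config$n_blocks * config$trials_per_block
  choice <- integer(n); outcome <- character(n); best <- integer(n)
  reversal <- logical(n); transition <- logical(n); block <- integer(n)
  for (t in seq_len(n)) {
    block[t] <- ((t - 1L) %/% config$trials_per_block) + 1L
    if (block[t] == config$transition_block &&
        (t - 1L) %% config$trials_per_block == 0L) {
      env <- prl_env_transition(env, config)
      transition[t] <- TRUE
    }
    ch <- agent$choose(3L, t)
    if (!(is.numeric(ch) && length(ch) == 1L && ch %in% 1:3)) {
      abort(paste0("Agent returned an invalid choice at trial ", t, "."))
    }
    best[t] <- env$best
    step <- prl_step(env, ch, config)
    env <- step$env
    choice[t] <- ch
    outcome[t] <- step$outcome
    reversal[t] <- step$reversal
    agent$observe(ch, step$outcome)
  }
  tibble(subject_id = subject_id,
         trial = seq_len(n),
         block = block,
         choice = choice,
         outcome = outcome,
         points = ifelse(outcome == "win", config$win_points, config$loss_points),
         best_deck = best,
         reversal = reversal,
         transition = transition)
}
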