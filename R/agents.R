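#' Task agents
#'
#' Agents encapsulate a choice policy for [simulate_prl()]. Each
#' constructor returns a list of two closures: `choose(n_decks, trial)`
#' returning a deck index, and `observe(choice, outcome)` which feeds the
#' trial outcome back to the agent.
#'
#' * `agent_random()` chooses uniformly at random.
#' * `agent_fixed(deck)` always chooses the same deck.
#' * `agent_wsls(p_stay_win, p_stay_loss)` is a stochastic win-stay /
#'   lose-shift policy: after a win it repeats its choice with probability
#'   `p_stay_win`, after a loss with `p_stay_loss`; otherwise it switches
#'   to one of the other decks uniformly.
#' * `agent_hgf(params, ...)` learns with the three-level HGF
#'   ([hgf_params()]) and chooses through the volatility-coupled softmax;
#'   see [hgf_forward()] for the model.
#'
#' @param deck Deck index for `agent_fixed()`.
#' @param p_stay_win,p_stay_loss Stay probabilities for `agent_wsls()`.
#' @return An agent list with `choose` and `observe` closures.
#' @export
agent_random <- function() {
  list(choose = function(n_decks, trial) sample.int(n_decks, 1L),
       observe = function(choice, outcome) invisible(NULL))
}

#' @rdname agent_random
#' @export
agent_fixed <- function(deck = 1L) {
  force(deck)
  list(choose = function(n_decks, trial) deck,
       observe = function(choice, outcome) invisible(NULL))
}

#' @rdname agent_random
#' @export
agent_wsls <- function(p_stay_win = 0.9, p_stay_loss = 0.5) {
  check_prob(p_stay_win, "p_stay_win")
  check_prob(p_stay_loss, "p_stay_loss")
  last <- NULL
  last_outcome <- NULL
  list(
    choose = function(n_decks, trial) {
      if (is.null(last)) return(sample.int(n_decks, 1L))
      p_stay <- if (identical(last_outcome, "win")) p_stay_win else p_stay_loss
      if (runif(1) < p_stay) last else sample(setdiff(seq_len(n_decks), last), 1L)
    },
    observe = function(choice, outcome) {
      last <<- choice
      last_outcome <<- outcome
      invisible(NULL)
    })
}

#' @rdname agent_random
#' @param params An [hgf_params()] object for `agent_hgf()`.
#' @param n_decks Number of decks the HGF agent tracks.
#' @export
agent_hgf <- function(params, n_decks = 3L) {
  state <- hgf_state_init(params, n_decks)
  list(
    choose = function(n_decks, trial) {
      pred <- hgf_predict(state, params)
      p <- hgf_softmax(pred$mu1hat, pred$mu3hat, params)
      sample.int(n_decks, 1L, prob = p)
    },
    observe = function(choice, outcome) {
      state <<- hgf_update(state, params, choice, outcome == "win")
      invisible(NULL)
    })
}
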