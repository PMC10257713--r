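## ggplot2 displays for simulated sessions and results.

#' Plot a reversal-learning session
#'
#' Shows deck choices over trials, the hidden best deck, and reversal /
#' contingency-transition events for one simulated session.
#'
#' @param trials A trials tibble from [simulate_prl()] (one subject).
#' @return A ggplot object.
#' @export
plot_prl_session <- function(trials) {
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_deck),
                       colour = "grey60", linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$choice,
                                     colour = .data$outcome),
                        size = 1.4, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = trials$trial[trials$reversal],
                        linetype = "dotted", colour = "red3") +
    ggplot2::geom_vline(xintercept = trials$trial[trials$transition],
                        linetype = "dashed", colour = "blue3") +
    ggplot2::scale_y_continuous(breaks = 1:3) +
    ggplot2::labs(x = "Trial", y = "Deck",
                  title = "3PRL session (grey: best deck; red: reversals)")
}

#' Plot horizon-wise first-free-choice behavior
#'
#' For unequal-information games, shows the proportion of first free
#' choices toward the less-sampled (more informative) option by horizon
#' -- the behavioral signature of directed exploration.
#'
#' @param trials A trials tibble from [horizon_play()].
#' @return A ggplot object.
#' @export
plot_horizon_info_choice <- function(trials) {
  d <- trials |>
    dplyr::filter(.data$info == "unequal") |>
    dplyr::group_by(.data$subject_id, .data$game, .data$horizon) |>
    dplyr::group_modify(function(g, key) {
      f <- g[g$forced, ]
      free1 <- g[!g$forced, ][1, ]
      rare <- names(which.min(table(factor(f$side, levels = c("L", "R")))))
      tibble(to_informative = free1$side == rare)
    }) |>
    dplyr::group_by(.data$horizon) |>
    dplyr::summarise(p = mean(.data$to_informative), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$horizon), y = .data$p)) +
    ggplot2::geom_col(width = 0.5, fill = "steelblue") +
    ggplot2::labs(x = "Horizon", y = "P(first free choice to less-sampled)",
                  title = "Directed exploration by horizon")
}

#' @describeIn plot_prl_session Retained-predictor map of an analysis:
#'   which predictors the LASSO kept in each regression cell.
#' @param object,... A `vb_analysis` (for `autoplot`).
#' @method autoplot vb_analysis
#' @export
autoplot.vb_analysis <- function(object, ...) {
  r <- object$regressions
  d <- purrr::map_dfr(seq_len(nrow(r)), function(i) {
    kept <- r$retained[[i]]
    if (!length(kept)) return(NULL)
    tibble(cell = paste(r$outcome[i], r$predictor_set[i], sep = "\n"),
           predictor = kept)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$predictor)) +
    ggplot2::geom_tile(fill = "steelblue", colour = "white") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Predictors retained by LASSO per model cell")
}
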