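#' Win-switch and lose-stay rates
#'
#' `win_switch_rate()` is the proportion of rewarded trials after which
#' the participant switched to a different deck: wins at trial `t`
#' followed by a different choice at `t + 1`, divided by the number of
#' wins that have a successor trial. `lose_stay_rate()` mirrors it for
#' losses followed by the same deck. Transitions are defined on
#' consecutive trials within a session; the final trial contributes no
#' transition, and block boundaries do not break transitions (the task is
#' continuous on screen).
#'
#' @param trials A trials tibble with `choice` and `outcome` columns
#'   (`"win"`/`"loss"`), ordered by trial.
#' @return A proportion in `[0, 1]`, or `NA` (with a warning) when no
#'   qualifying trials exist.
#' @examples
#' toy <- tibble::tibble(choice = c(1, 1, 2, 2, 1),
#'                       outcome = c("win", "win", "loss", "win", "win"))
#' win_switch_rate(toy) # 2/3
#' lose_stay_rate(toy)  # 1
#' @export
win_switch_rate <- function(trials) {
  transition_rate(trials, on = "win", count_switch = TRUE)
}

#' @rdname win_switch_rate
#' @export
lose_stay_rate <- function(trials) {
  transition_rate(trials, on = "loss", count_switch = FALSE)
}

transition_rate <- function(trials, on, count_switch) {
  check_that(all(c("choice", "outcome") %in% names(trials)),
             "`trials` must have `choice` and `outcome` columns.")
  n <- nrow(trials)
  if (n < 2L) {
    warn("Fewer than two trials: transition rate undefined.")
    return(NA_real_)
  }
  idx <- which(trials$outcome[-n] == on)
  if (length(idx) == 0L) {
    warn(paste0("No qualifying '", on, "' trials with a successor; ",
                "rate flagged missing."))
    return(NA_real_)
  }
  switched <- trials$choice[idx + 1L] != trials$choice[idx]
  if (count_switch) mean(switched) else mean(!switched)
}

#' Evidence-integration impairment (EII) from a BADE rating grid
#'
#' Scores the bias-against-disconfirmatory-evidence task: for each
#' scenario, EII is the mean of the three Absurd-explanation ratings plus
#' the mean of the two final (third-presentation) Lure ratings,
#' \deqn{(\mathrm{Absurd}_1 + \mathrm{Absurd}_2 + \mathrm{Absurd}_3)/3 +
#'       (\mathrm{LureA}_3 + \mathrm{LureB}_3)/2,}
#' averaged over scenarios. Higher EII means higher plausibility given to
#' explanations that should have been implausible given the evidence.
#'
#' Scenarios with any missing required rating are excluded (with a
#' warning); if all scenarios are incomplete an error is raised.
#'
#' @param grid A tibble with columns `scenario`, `explanation` (one of
#'   `"true"`, `"lure_a"`, `"lure_b"`, `"absurd"`), `stage` (1-3) and
#'   `rating` (0-100 scroll-bar units by default).
#' @return The EII score (mean-rating units).
#' @examples
#' g <- tidyr::expand_grid(scenario = 1:12,
#'                         explanation = c("true", "lure_a", "lure_b", "absurd"),
#'                         stage = 1:3)
#' g$rating <- 10
#' bade_eii(g) # uniform rating r gives 2 * r
#' @export
bade_eii <- function(grid) {
  need <- c("scenario", "explanation", "stage", "rating")
  check_that(all(need %in% names(grid)),
             paste("`grid` must have columns:", paste(need, collapse = ", ")))
  per <- grid |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      absurd = mean(.data$rating[.data$explanation == "absurd" &
                                   .data$stage %in% 1:3]),
      lure_final = mean(c(
        .data$rating[.data$explanation == "lure_a" & .data$stage == 3],
        .data$rating[.data$explanation == "lure_b" & .data$stage == 3])),
      n_absurd = sum(.data$explanation == "absurd" & .data$stage %in% 1:3 &
                       !is.na(.data$rating)),
      n_lure = sum(.data$explanation %in% c("lure_a", "lure_b") &
                     .data$stage == 3 & !is.na(.data$rating)),
      .groups = "drop")
  complete <- per$n_absurd == 3L & per$n_lure == 2L &
    !is.na(per$absurd) & !is.na(per$lure_final)
  if (!all(complete)) {
    if (!any(complete)) abort("No complete BADE scenario; EII undefined.")
    warn(paste0(sum(!complete), " incomplete BADE scenario(s) excluded."))
  }
  mean(per$absurd[complete] + per$lure_final[complete])
}

#' Questionnaire scores
#'
#' `dacobs_jtc()` sums the jumping-to-conclusions items of the DACOBS
#' (each on a 1-7 Likert scale; six items by default). `bcis_composite()`
#' is the Beck Cognitive Insight Scale composite, self-reflectiveness
#' minus self-certainty (9 and 5 items respectively).
#'
#' @param items Numeric vector of JTC item scores.
#' @param n_items Expected number of JTC items (default 6).
#' @param scale_range Admissible item range (default 1-7).
#' @return An integer sum / composite.
#' @examples
#' dacobs_jtc(c(1, 2, 3, 4, 5, 6)) # 21
#' bcis_composite(rep(2, 9), rep(1, 5)) # 13
#' @export
dacobs_jtc <- function(items, n_items = 6L, scale_range = c(1L, 7L)) {
  check_that(length(items) == n_items,
             paste0("Expected ", n_items, " JTC items, got ", length(items), "."))
  check_that(all(is.finite(items)) &&
               all(items >= scale_range[1] & items <= scale_range[2]),
             paste0("JTC items must lie in [", scale_range[1], ", ",
                    scale_range[2], "]."))
  as.integer(sum(items))
}

#' @rdname dacobs_jtc
#' @param sr_items Nine self-reflectiveness item scores.
#' @param sc_items Five self-certainty item scores.
#' @export
bcis_composite <- function(sr_items, sc_items) {
  check_that(length(sr_items) == 9L,
             "Self-reflectiveness requires 9 items.")
  check_that(length(sc_items) == 5L,
             "Self-certainty requires 5 items.")
  check_that(all(is.finite(c(sr_items, sc_items))),
             "Item scores must be finite.")
  as.integer(sum(sr_items) - sum(sc_items))
}

#' Directed- and random-exploration contrasts from a Horizon fit
#'
#' Directed exploration is the horizon-driven increase in the information
#' bonus, `A_H6 - A_H1`. Random exploration is the horizon-driven
#' increase in decision noise, `sigma_H6 - sigma_H1`, computed separately
#' for the equal and unequal information conditions. Missing condition
#' fits propagate as `NA`.
#'
#' @param fit A `horizon_fit` (from [fit_horizon()]) or its `estimates`
#'   tibble.
#' @return A tibble with one row per subject: `directed_exploration`,
#'   `random_explore_equal`, `random_explore_unequal`.
#' @export
exploration_contrasts <- function(fit) {
  est <- if (inherits(fit, "horizon_fit")) fit$estimates else fit
  need <- c("A_H1", "A_H6", "sigma_H1_equal", "sigma_H6_equal",
            "sigma_H1_unequal", "sigma_H6_unequal")
  check_that(all(need %in% names(est)),
             "Fit is missing per-condition decision parameters.")
  tibble(
    subject_id = est$subject_id,
    directed_exploration = est$A_H6 - est$A_H1,
    random_explore_equal = est$sigma_H6_equal - est$sigma_H1_equal,
    random_explore_unequal = est$sigma_H6_unequal - est$sigma_H1_unequal)
}

#' Assemble the per-subject metrics table
#'
#' Computes every measure the regression stage consumes: win-switch and
#' lose-stay rates from the reversal-learning trials, BADE-EII from the
#' rating grids, DACOBS-JTC and BCIS composites from the questionnaire
#' items, the SCIP z-composite pass-through, and -- when model fits are
#' supplied -- the HGF volatility prior and the exploration contrasts.
#'
#' @param cohort A cohort list as produced by [generate_cohort()] or
#'   [read_cohort()] (`subjects`, `prl_trials`, `bade`, `questionnaires`).
#' @param hgf_fits Optional tibble from [fit_hgf()]; the subject-level
#'   `mu3_0` (and `omega2`, `omega3`, `kappa`) are averaged across block
#'   pairs.
#' @param horizon_fit Optional `horizon_fit` from [fit_horizon()].
#' @return A tibble with one row per subject and one column per metric;
#'   metrics that cannot be computed for a subject are `NA`.
#' @export
subject_metrics <- function(cohort, hgf_fits = NULL, horizon_fit = NULL) {
  subjects <- cohort$subjects
  prl <- if (is.null(cohort$prl_trials)) list() else
    split(cohort$prl_trials, cohort$prl_trials$subject_id)
  bade <- if (is.null(cohort$bade)) list() else
    split(cohort$bade, cohort$bade$subject_id)
  q <- cohort$questionnaires
  one <- function(sid) {
    tr <- prl[[sid]]
    qs <- q[q$subject_id == sid, ]
    jtc_items <- qs$score[qs$instrument == "dacobs_jtc"]
    sr <- qs$score[qs$instrument == "bcis_sr"]
    sc <- qs$score[qs$instrument == "bcis_sc"]
    tibble(
      subject_id = sid,
      wsr = if (is.null(tr)) NA_real_ else
        suppressWarnings(win_switch_rate(tr)),
      lsr = if (is.null(tr)) NA_real_ else
        suppressWarnings(lose_stay_rate(tr)),
      bade_eii = if (is.null(bade[[sid]])) NA_real_ else
        suppressWarnings(bade_eii(bade[[sid]])),
      jtc = if (length(jtc_items)) dacobs_jtc(jtc_items) else NA_integer_,
      bcis = if (length(sr) == 9L && length(sc) == 5L)
        bcis_composite(sr, sc) else NA_integer_)
  }
  m <- purrr::map_dfr(subjects$subject_id, one)
  out <- dplyr::left_join(
    dplyr::select(subjects, dplyr::any_of(
      c("subject_id", "group", "age", "gender", "scip_z",
        "rgpts_b", "pdi21", "panss_p1", "panss_p6"))),
    m, by = "subject_id")
  if (!is.null(hgf_fits)) {
    hs <- hgf_fits |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(mu3_0 = mean(.data$mu3_0),
                       omega2 = mean(.data$omega2),
                       omega3 = mean(.data$omega3),
                       kappa = mean(.data$kappa), .groups = "drop")
    out <- dplyr::left_join(out, hs, by = "subject_id")
  }
  if (!is.null(horizon_fit)) {
    out <- dplyr::left_join(out, exploration_contrasts(horizon_fit),
                            by = "subject_id")
  }
  out
}
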