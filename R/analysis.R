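## The full statistical stage: group tests, zero-order correlations, and
## the residualized-symptom LASSO -> OLS regression cells.

analysis_metric_cols <- function() {
  c("jtc", "bade_eii", "bcis", "wsr", "lsr", "mu3_0",
    "random_explore_equal", "random_explore_unequal", "scip_z")
}

## The eight regression cells: four outcomes x two predictor sets.
## PANSS outcomes are clinician-rated and exist for patients only; the
## self-report outcomes use the whole sample with group as a covariate.
analysis_cells <- function() {
  tibble(
    outcome = rep(c("panss_p6", "rgpts_b", "panss_p1", "pdi21"), each = 2),
    control_scale = rep(c("panss_p1", "pdi21", "panss_p6", "rgpts_b"),
                        each = 2),
    sample = rep(c("patients", "all", "patients", "all"), each = 2),
    predictor_set = rep(c("behavioral", "computational"), times = 4))
}

predictor_sets <- function(include_scip = FALSE) {
  behavioral <- c("wsr", "bade_eii", "jtc", "bcis")
  computational <- c("mu3_0", "random_explore_unequal",
                     "random_explore_equal", "bade_eii", "jtc", "bcis")
  if (include_scip) {
    behavioral <- c(behavioral, "scip_z")
    computational <- c(computational, "scip_z")
  }
  list(behavioral = behavioral, computational = computational)
}

#' Run the full symptom-regression analysis
#'
#' Executes the complete statistical stage on a per-subject metrics
#' table: Mann-Whitney group tests for every decision-making metric,
#' the zero-order Spearman correlation matrix among metrics (overall and
#' per group, uncorrected, with an optional Benjamini-Hochberg column),
#' and the eight regression cells (paranoia and delusional-ideation
#' outcomes x behavioral/computational predictor sets). In each cell the
#' outcome is first residualized on its companion scale (e.g. PANSS-P6
#' controlling for PANSS-P1 in patients), every continuous variable is
#' passed through the skew-minimizing log transform (age, gender and
#' group are exempt), LASSO selects the predictors, and an OLS fit of
#' the retained set gives coefficients, p-values and R-squared.
#' Covariates (age, gender, and group for whole-sample cells) enter the
#' LASSO like any other predictor. Each cell uses complete cases for its
#' own variables, so the effective n differs across cells.
#'
#' @param metrics A metrics tibble from [subject_metrics()]; must
#'   contain the symptom columns (`rgpts_b`, `pdi21`, `panss_p1`,
#'   `panss_p6`), `age`, `gender`, `group`, and the metric columns.
#' @param rule,nfolds,seed Passed to [lasso_select()].
#' @param include_scip Also offer the SCIP z-composite to the LASSO.
#' @return A `vb_analysis` list: `group_tests`, `correlations`,
#'   `regressions` (one row per cell with retained predictors, R-squared,
#'   model p and n), `coefficients` (term-level results across cells),
#'   and `manifest` (seed, lambda values, transform descriptors).
#' @export
run_analysis <- function(metrics, rule = c("1se", "min"), nfolds = 10L,
                         seed = 1L, include_scip = FALSE) {
  rule <- match.arg(rule)
  need <- c("subject_id", "group", "age", "gender",
            "rgpts_b", "pdi21", "panss_p1", "panss_p6")
  check_that(all(need %in% names(metrics)),
             paste("`metrics` must contain:", paste(need, collapse = ", ")))
  mcols <- intersect(analysis_metric_cols(), names(metrics))

  ## --- group tests -------------------------------------------------
  group_tests <- purrr::map_dfr(mcols, function(v) {
    a <- metrics[[v]][metrics$group == "patient"]
    b <- metrics[[v]][metrics$group == "control"]
    if (sum(!is.na(a)) < 1L || sum(!is.na(b)) < 1L) {
      return(tibble(metric = v, U = NA_real_, p = NA_real_,
                    n_x = sum(!is.na(a)), n_y = sum(!is.na(b))))
    }
    dplyr::bind_cols(tibble(metric = v), mann_whitney(a, b))
  })

  ## --- zero-order correlations -------------------------------------
  correlations <- purrr::map_dfr(
    c("all", "control", "patient"), function(gr) {
      d <- if (gr == "all") metrics else metrics[metrics$group == gr, ]
      pairs <- utils::combn(mcols, 2)
      purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
        v1 <- pairs[1, k]; v2 <- pairs[2, k]
        ok <- complete.cases(d[[v1]], d[[v2]])
        if (sum(ok) < 3L || sd(d[[v1]][ok]) == 0 || sd(d[[v2]][ok]) == 0) {
          return(tibble(sample = gr, var1 = v1, var2 = v2,
                        rho = NA_real_, p = NA_real_, n = sum(ok)))
        }
        sp <- suppressWarnings(spearman(d[[v1]], d[[v2]]))
        tibble(sample = gr, var1 = v1, var2 = v2,
               rho = sp$rho, p = sp$p, n = sp$n)
      })
    })
  correlations <- correlations |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(p_bh = stats::p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup()

  ## --- regression cells --------------------------------------------
  cells <- analysis_cells()
  psets <- predictor_sets(include_scip)
  transforms <- list()
  reg_rows <- list(); coef_rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    d <- if (cell$sample == "patients") {
      metrics[metrics$group == "patient", ]
    } else {
      metrics
    }
    cand <- intersect(psets[[cell$predictor_set]], names(d))
    covars <- c("age", "gender_num",
                if (cell$sample == "all") "group_num")
    d$gender_num <- as.numeric(d$gender == "M")
    d$group_num <- as.numeric(d$group == "patient")
    d$.outcome <- residualize(d[[cell$outcome]], d[[cell$control_scale]])
    use <- c(".outcome", cand, "age", "gender_num",
             if (cell$sample == "all") "group_num")
    d <- d[complete.cases(d[, use, drop = FALSE]), use, drop = FALSE]
    cell_id <- paste(cell$outcome, cell$predictor_set, sep = ".")
    if (length(cand) == 0L || nrow(d) < 10L) {
      reg_rows[[cell_id]] <- dplyr::bind_cols(
        cell, tibble(retained = list(character(0)), r_squared = NA_real_,
                     p_model = NA_real_, n = nrow(d),
                     lambda = NA_real_))
      next
    }
    ## skew-minimizing log transform for outcome and candidate metrics;
    ## age, gender and group are exempt
    for (v in c(".outcome", cand)) {
      tr <- log_transform_minimizing_skew(d[[v]])
      d[[v]] <- tr$values
      transforms[[paste(cell_id, v, sep = "/")]] <-
        list(transform = tr$transform, offset = tr$offset)
    }
    sel <- lasso_select(d[, c(cand, covars), drop = FALSE], d$.outcome,
                        rule = rule, nfolds = nfolds,
                        seed = derive_seed(seed, i))
    fit <- ols_fit(d, ".outcome", sel$retained)
    reg_rows[[cell_id]] <- dplyr::bind_cols(
      cell, tibble(retained = list(sel$retained),
                   r_squared = fit$r_squared, p_model = fit$p_model,
                   n = fit$n, lambda = sel$lambda))
    if (length(sel$retained)) {
      coef_rows[[cell_id]] <- dplyr::bind_cols(
        tibble(outcome = cell$outcome,
               predictor_set = cell$predictor_set,
               sample = cell$sample)[rep(1, nrow(fit$coefficients)), ],
        fit$coefficients)
    }
  }

  structure(
    list(group_tests = group_tests,
         correlations = correlations,
         regressions = dplyr::bind_rows(reg_rows),
         coefficients = dplyr::bind_rows(coef_rows),
         manifest = list(seed = seed, rule = rule, nfolds = nfolds,
                         include_scip = include_scip,
                         transforms = transforms)),
    class = "vb_analysis")
}

#' @export
print.vb_analysis <- function(x, ...) {
  cat("<vb_analysis>\n  group tests:", nrow(x$group_tests),
      "metrics\n  regression cells:\n")
  r <- x$regressions
  for (i in seq_len(nrow(r))) {
    cat(sprintf("   %-9s [%s, %s] R^2 = %s; retained: %s\n",
                r$outcome[i], r$predictor_set[i], r$sample[i],
                ifelse(is.na(r$r_squared[i]), "NA",
                       sprintf("%.3f", r$r_squared[i])),
                if (length(r$retained[[i]]))
                  paste(r$retained[[i]], collapse = ", ") else "(none)"))
  }
  invisible(x)
}
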