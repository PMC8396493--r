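# End-to-end driver: split a multi-diet record table into cohorts, build
# life tables, demographic parameters with jackknife SEs, all pairwise
# comparisons with compact letter displays, and the descriptive summaries.

#' Split a record table by diet
#'
#' @param records A `mite_records` data frame, possibly spanning diets.
#' @return Named list of single-diet `mite_records` data frames.
#' @export
split_by_diet <- function(records) {
  parts <- split(seq_len(nrow(records)), records$diet)
  out <- lapply(parts, function(i) {
    r <- records[i, , drop = FALSE]
    rownames(r) <- NULL
    class(r) <- c("mite_records", "data.frame")
    r
  })
  out[unique(records$diet)]
}

#' Run the full life-table analysis on a multi-diet experiment
#'
#' For each diet cohort: builds the life table, the stage and reproductive
#' summaries, and the four demographic parameters (R0, T, rm, lambda) with
#' jackknife pseudovalue standard errors. Across diets: all unadjusted
#' pairwise pooled-variance t comparisons per parameter, summarised as a
#' compact letter display (diets sharing a letter do not differ at
#' `alpha`).
#'
#' @param records A `mite_records` data frame covering one or more diets.
#' @param progeny_female_fraction Fraction of eggs that are female.
#' @param alpha Significance level for the letter display.
#' @param tol Euler-Lotka residual tolerance.
#' @param pivotal_age Use pivotal ages x + 0.5 in the Euler-Lotka sums.
#' @return Object of class `experiment_results`: list with `life_tables`,
#'   `stage_summaries`, `reproductive_summaries`, `jackknife` (per diet x
#'   parameter), `comparisons` (data frame), `parameter_table` (per-diet
#'   estimates +/- SE with letters, one row per parameter and diet) and
#'   `settings`.
#' @export
run_experiment <- function(records, progeny_female_fraction = 0.67,
                           alpha = 0.05, tol = 1e-10, pivotal_age = FALSE) {
  cohorts <- split_by_diet(records)
  diets <- names(cohorts)
  params <- c("R0", "T", "rm", "lambda")

  life_tables <- lapply(cohorts, build_life_table, progeny_female_fraction)
  stage_summaries <- lapply(cohorts, summarize_stages)
  reproductive_summaries <- lapply(cohorts, summarize_reproduction)

  jack <- lapply(params, function(p) {
    lapply(cohorts, jackknife_parameter, parameter = p,
           progeny_female_fraction = progeny_female_fraction,
           tol = tol, pivotal_age = pivotal_age)
  })
  names(jack) <- params

  comparisons <- NULL
  letter_tab <- list()
  if (length(diets) >= 2) {
    pairs <- utils::combn(diets, 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(params, function(p) {
      do.call(rbind, lapply(pairs, function(pr) {
        cmp <- compare_diets(jack[[p]][[pr[1]]], jack[[p]][[pr[2]]])
        data.frame(parameter = p, diet_a = pr[1], diet_b = pr[2],
                   difference = cmp$difference, t = cmp$t_statistic,
                   df = cmp$df, p_value = cmp$p_value,
                   stringsAsFactors = FALSE)
      }))
    }))
    for (p in params) {
      est <- vapply(jack[[p]], `[[`, numeric(1), "estimate")
      letter_tab[[p]] <- letter_groups(
        comparisons[comparisons$parameter == p, ], est, alpha = alpha)
    }
  }

  parameter_table <- do.call(rbind, lapply(params, function(p) {
    do.call(rbind, lapply(diets, function(d) {
      j <- jack[[p]][[d]]
      data.frame(parameter = p, diet = d, estimate = j$estimate,
                 se = j$se, n = j$n,
                 letters = if (length(letter_tab))
                   unname(letter_tab[[p]][d]) else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(life_tables = life_tables,
                 stage_summaries = stage_summaries,
                 reproductive_summaries = reproductive_summaries,
                 jackknife = jack,
                 comparisons = comparisons,
                 parameter_table = parameter_table,
                 settings = list(progeny_female_fraction = progeny_female_fraction,
                                 alpha = alpha, tol = tol,
                                 pivotal_age = pivotal_age)),
            class = "experiment_results")
}

#' @export
print.experiment_results <- function(x, ...) {
  cat("Life-table analysis of", length(x$life_tables), "diet cohort(s)\n\n")
  print(x$parameter_table, digits = 4)
  invisible(x)
}
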