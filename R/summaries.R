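# Descriptive cohort summaries: stage durations and survival (development
# table) and female reproductive parameters and longevity.

mean_se <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  c(mean = if (n) mean(x) else NA_real_,
    se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
    n = n)
}

#' Stage-duration and survival summary of a cohort
#'
#' Computes, per diet cohort, the mean (+/- SE) duration of each immature
#' stage among the individuals completing it, the egg-to-female,
#' egg-to-male and egg-to-adult development times, the stage-specific
#' survival percentages (entered next stage / entered this stage) and the
#' percentage of the initial cohort reaching maturity.
#'
#' @param records A `mite_records` data frame (one diet).
#' @return Object of class `stage_summary`: list with `diet_label`,
#'   `durations` (data frame: stage, mean, se, n), `survival` (data frame:
#'   stage, entered, survived, pct) and `maturity_pct`.
#' @export
summarize_stages <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("input error: empty cohort", call. = FALSE)
  }
  n <- nrow(records)
  trans <- cbind(records$age_hatch, records$age_larva_end,
                 records$age_proto_end, records$age_deuto_end)
  dur <- cbind(trans[, 1], trans[, 2] - trans[, 1],
               trans[, 3] - trans[, 2], trans[, 4] - trans[, 3])

  d_stats <- t(vapply(1:4, function(j) mean_se(dur[, j]), numeric(3)))
  is_adult <- records$died_in_stage == "none"
  e2f <- trans[is_adult & records$sex == "female", 4]
  e2m <- trans[is_adult & records$sex == "male", 4]
  e2a <- trans[is_adult, 4]
  durations <- data.frame(
    stage = c(STAGES, "egg_to_female", "egg_to_male", "egg_to_adult"),
    rbind(d_stats, mean_se(e2f), mean_se(e2m), mean_se(e2a)),
    stringsAsFactors = FALSE
  )
  rownames(durations) <- NULL

  entered <- vapply(1:4, function(j) sum(!is.na(trans[, j])), integer(1))
  entered <- c(n, entered[1:3])          # all eggs enter the egg stage
  survived <- vapply(1:4, function(j) sum(!is.na(trans[, j])), integer(1))
  survival <- data.frame(
    stage = STAGES, entered = entered, survived = survived,
    pct = ifelse(entered > 0, 100 * survived / entered, NA_real_),
    stringsAsFactors = FALSE
  )

  structure(list(diet_label = records$diet[1],
                 durations = durations,
                 survival = survival,
                 maturity_pct = 100 * sum(is_adult) / n),
            class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, ...) {
  cat(sprintf("Stage summary: %s\n", x$diet_label))
  print(x$durations, digits = 4)
  print(x$survival, digits = 4)
  cat(sprintf("Percentage reaching maturity: %.2f%%\n", x$maturity_pct))
  invisible(x)
}

#' Female reproductive parameters and longevity
#'
#' Per-female reproductive summary of a cohort: pre-oviposition period
#' (adult days before the first egg), oviposition period (first to last
#' egg-laying day inclusive), post-oviposition period, total fecundity
#' (eggs per female), oviposition rate (total eggs / longevity, per female)
#' and longevity (adult lifespan, emergence to death; the printed period
#' means sum to it within grid slack). Females
#' that die without ovipositing are included in longevity but excluded from
#' the period and fecundity means.
#'
#' @param records A `mite_records` data frame (one diet).
#' @return Object of class `reproductive_summary`: list with `diet_label`,
#'   a `summary` data frame (quantity, mean, se, n) and
#'   `n_nonovipositing`.
#' @export
summarize_reproduction <- function(records) {
  is_f <- records$sex == "female"
  if (!any(is_f)) {
    stop("analysis error: no adult females in this cohort", call. = FALSE)
  }
  f <- records[is_f, , drop = FALSE]
  nf <- nrow(f)

  first_egg <- vapply(f$daily_eggs, function(e) {
    i <- which(e > 0)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  last_egg <- vapply(f$daily_eggs, function(e) {
    i <- which(e > 0)
    if (length(i)) i[length(i)] else NA_integer_
  }, integer(1))
  adult_days <- vapply(f$daily_eggs, length, integer(1))
  total_eggs <- vapply(f$daily_eggs, sum, numeric(1))

  laid <- !is.na(first_egg)
  preovi <- ifelse(laid, first_egg - 1L, NA_real_)
  ovi <- ifelse(laid, last_egg - first_egg + 1L, NA_real_)
  # post-oviposition = death day minus last egg-laying day (whole-day ages)
  last_egg_age <- floor(f$age_deuto_end) + last_egg - 1L
  postovi <- ifelse(laid, f$adult_death_age - last_egg_age, NA_real_)
  # adult lifespan, emergence to death (the printed periods sum to it)
  longevity <- f$adult_death_age - floor(f$age_deuto_end)
  rate <- ifelse(laid, total_eggs / longevity, NA_real_)
  fec <- ifelse(laid, total_eggs, NA_real_)

  rows <- rbind(
    total_fecundity = mean_se(fec),
    oviposition_rate = mean_se(rate),
    longevity = mean_se(longevity),
    preoviposition = mean_se(preovi),
    oviposition = mean_se(ovi),
    postoviposition = mean_se(postovi)
  )
  out <- data.frame(quantity = rownames(rows), rows,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(diet_label = records$diet[1],
                 summary = out,
                 n_females = nf,
                 n_nonovipositing = sum(!laid)),
            class = "reproductive_summary")
}

#' @export
print.reproductive_summary <- function(x, ...) {
  cat(sprintf("Reproductive summary: %s (%d females, %d never oviposited)\n",
              x$diet_label, x$n_females, x$n_nonovipositing))
  print(x$summary, digits = 4)
  invisible(x)
}
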