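# Cohort life table: age-specific survival lx and fecundity mx on a
# whole-day age grid with age origin at egg deposition.
#
# lx(x) = (fraction of the initial cohort not yet dead as an immature at x)
#         * (fraction of adult females still alive at x, among females)
# which encodes the classical female-based table under the assumption that
# immature survival is sex-independent (immatures cannot be sexed).
# mx(x) = progeny_female_fraction * mean eggs laid at age x per female
#         alive at x.

# Immature deaths carry no recorded death age: they are detected at the
# first half-day check after entering the fatal stage.
immature_death_age <- function(records) {
  entry <- rep(NA_real_, nrow(records))
  st <- records$died_in_stage
  entry[st == "egg"] <- 0
  entry[st == "larva"] <- records$age_hatch[st == "larva"]
  entry[st == "protonymph"] <- records$age_larva_end[st == "protonymph"]
  entry[st == "deutonymph"] <- records$age_proto_end[st == "deutonymph"]
  entry + 0.5
}

#' Build a cohort life table
#'
#' Converts individual rearing records of a single diet cohort into paired
#' age-specific survival (`lx`) and fecundity (`mx`) schedules on a daily
#' age grid starting at egg deposition.
#'
#' Survival combines immature mortality of the whole (unsexed) cohort with
#' adult mortality of females only; males leave both numerator and
#' denominator at adulthood. Fecundity is female eggs per living female per
#' day: daily egg counts multiplied by `progeny_female_fraction` and
#' averaged over the females alive at that age. Females that die without
#' ovipositing stay in the table and contribute zero `mx`.
#'
#' @param records A `mite_records` data frame (one diet).
#' @param progeny_female_fraction Fraction of eggs that are female.
#' @return Object of class `life_table`: list with `diet_label`, `ages`,
#'   `lx`, `mx`, `n_initial`, `n_females`.
#' @export
build_life_table <- function(records, progeny_female_fraction) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("analysis error: empty cohort", call. = FALSE)
  }
  if (length(unique(records$diet)) != 1) {
    stop("input error: records mix diet labels; build one table per diet",
         call. = FALSE)
  }
  if (!is.numeric(progeny_female_fraction) ||
      progeny_female_fraction < 0 || progeny_female_fraction > 1) {
    stop("input error: progeny_female_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  n <- nrow(records)
  is_f <- records$sex == "female"
  nf <- sum(is_f)
  if (nf == 0) {
    stop("analysis error: no females reached adulthood in this cohort",
         call. = FALSE)
  }

  d_imm <- immature_death_age(records)          # NA for adults
  d_f <- records$adult_death_age[is_f]
  max_age <- max(ceiling(stats::na.omit(c(d_imm, d_f))))
  ages <- 0:max_age

  imm_deaths <- sort(d_imm[!is.na(d_imm)])
  s_imm <- 1 - vapply(ages, function(x) sum(imm_deaths <= x), numeric(1)) / n
  alive_f <- vapply(ages, function(x) sum(d_f > x), numeric(1))
  lx <- s_imm * alive_f / nf

  # eggs laid on adult day k are aged floor(adult age) + k - 1
  eggs_total <- numeric(max_age + 1)
  a_f <- records$age_deuto_end[is_f]
  eggs_f <- records$daily_eggs[is_f]
  for (j in seq_len(nf)) {
    e <- eggs_f[[j]]
    if (!length(e)) next
    at <- floor(a_f[j]) + seq_along(e) - 1L
    keep <- at <= max_age
    eggs_total[at[keep] + 1L] <- eggs_total[at[keep] + 1L] + e[keep]
  }
  mx <- ifelse(alive_f > 0,
               progeny_female_fraction * eggs_total / pmax(alive_f, 1), 0)

  structure(list(diet_label = records$diet[1], ages = ages, lx = lx,
                 mx = mx, n_initial = n, n_females = nf),
            class = "life_table")
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  data.frame(age = x$ages, lx = x$lx, mx = x$mx)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Cohort life table: %s (%d eggs, %d adult females)\n",
              x$diet_label, x$n_initial, x$n_females))
  cat(sprintf("  ages 0-%d d; R0 = %.3f\n", max(x$ages), sum(x$lx * x$mx)))
  invisible(x)
}

#' Plot paired survival and fecundity curves
#'
#' Draws the `lx` (solid) and `mx` (dashed) schedules of one or more life
#' tables against age, one panel per diet — the standard paired
#' survival/fecundity figure of cohort life-table studies.
#'
#' @param ... One or more `life_table` objects.
#' @return A ggplot object.
#' @export
plot_life_table <- function(...) {
  lts <- list(...)
  df <- do.call(rbind, lapply(lts, function(lt) {
    data.frame(diet = lt$diet_label,
               age = rep(lt$ages, 2),
               value = c(lt$lx, lt$mx),
               schedule = rep(c("lx", "mx"), each = length(lt$ages)))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = age, y = value,
                                   linetype = schedule)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~diet, ncol = 1) +
    ggplot2::scale_linetype_manual(values = c(lx = "solid", mx = "dashed")) +
    ggplot2::labs(x = "Age (days since egg deposition)", y = NULL,
                  linetype = NULL) +
    ggplot2::theme_minimal()
}
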