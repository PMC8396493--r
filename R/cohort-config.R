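STAGES <- c("egg", "larva", "protonymph", "deutonymph")

#' Configuration of a synthetic rearing cohort
#'
#' Bundles the generative parameters for one diet cohort of the
#' individual-based rearing simulation: initial cohort size, immature
#' stage-duration distributions, stage-specific survival, sexing, and the
#' adult reproductive schedule. All durations are in days since egg
#' deposition; immature development is observed on a half-day grid, adult
#' events on whole days.
#'
#' @param diet_label Character scalar naming the diet (e.g. `"P. taxi"`).
#' @param n_eggs Initial cohort size (number of eggs entering the trial).
#' @param n_trays Number of rearing trays; individuals are assigned
#'   round-robin. Trays carry no effect unless `tray_fecundity_sd > 0`.
#' @param stage_mean_durations Numeric length 4: mean duration (days) of the
#'   egg, larva, protonymph and deutonymph stages.
#' @param stage_duration_cv Coefficient of variation shared by the four
#'   stage-duration gamma distributions; `0` makes development deterministic.
#' @param stage_survival Numeric length 4: probability of surviving each
#'   immature stage.
#' @param proportion_female Probability that an individual reaching
#'   adulthood is female.
#' @param preoviposition_mean,oviposition_mean,postoviposition_mean Mean
#'   lengths (days) of the adult female pre-oviposition, oviposition and
#'   post-oviposition periods.
#' @param adult_period_cv Coefficient of variation of the three adult-period
#'   gamma distributions.
#' @param daily_egg_mean Mean eggs laid per female per day during the
#'   oviposition window.
#' @param progeny_female_fraction Fraction of laid eggs that are female;
#'   used downstream when converting egg counts to female eggs (mx).
#' @param egg_noise `"poisson"` draws daily clutches from a Poisson law with
#'   mean `daily_egg_mean`; `"none"` replaces every clutch by its mean
#'   (useful for deterministic degenerate cohorts).
#' @param tray_fecundity_sd Standard deviation (log scale) of an optional
#'   tray-level multiplicative offset on fecundity; default 0 (off).
#' @param seed Integer seed; `generate_cohort()` is reproducible given the
#'   config.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [default_diet_configs()],
#'   [expected_schedule()]
#' @export
cohort_config <- function(diet_label,
                          n_eggs,
                          n_trays = 6L,
                          stage_mean_durations,
                          stage_duration_cv = 0.25,
                          stage_survival,
                          proportion_female = 0.67,
                          preoviposition_mean,
                          oviposition_mean,
                          postoviposition_mean,
                          adult_period_cv = 0.25,
                          daily_egg_mean,
                          progeny_female_fraction = 0.67,
                          egg_noise = c("poisson", "none"),
                          tray_fecundity_sd = 0,
                          seed = 1L) {
  egg_noise <- match.arg(egg_noise)
  cfg <- list(
    diet_label = diet_label,
    n_eggs = n_eggs,
    n_trays = n_trays,
    stage_mean_durations = stage_mean_durations,
    stage_duration_cv = stage_duration_cv,
    stage_survival = stage_survival,
    proportion_female = proportion_female,
    preoviposition_mean = preoviposition_mean,
    oviposition_mean = oviposition_mean,
    postoviposition_mean = postoviposition_mean,
    adult_period_cv = adult_period_cv,
    daily_egg_mean = daily_egg_mean,
    progeny_female_fraction = progeny_female_fraction,
    egg_noise = egg_noise,
    tray_fecundity_sd = tray_fecundity_sd,
    seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

config_error <- function(field, msg) {
  stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_cohort_config <- function(cfg) {
  chk_scalar <- function(field, ok, msg) {
    x <- cfg[[field]]
    if (length(x) != 1 || is.na(x) || !ok(x)) config_error(field, msg)
  }
  if (!is.character(cfg$diet_label) || length(cfg$diet_label) != 1 ||
      is.na(cfg$diet_label) || !nzchar(cfg$diet_label)) {
    config_error("diet_label", "must be a non-empty string")
  }
  chk_scalar("n_eggs", function(x) is.numeric(x) && x >= 1 && x == floor(x),
             "must be a positive integer (>= 1)")
  chk_scalar("n_trays", function(x) is.numeric(x) && x >= 1 && x == floor(x),
             "must be a positive integer")
  for (field in c("stage_mean_durations", "stage_survival")) {
    if (!is.numeric(cfg[[field]]) || length(cfg[[field]]) != 4 ||
        anyNA(cfg[[field]])) {
      config_error(field, "must be a numeric vector of length 4")
    }
  }
  if (any(cfg$stage_mean_durations <= 0)) {
    config_error("stage_mean_durations", "must be strictly positive")
  }
  if (any(cfg$stage_survival < 0 | cfg$stage_survival > 1)) {
    config_error("stage_survival", "must lie in [0, 1]")
  }
  chk_scalar("stage_duration_cv", function(x) is.numeric(x) && x >= 0,
             "must be a nonnegative real")
  chk_scalar("adult_period_cv", function(x) is.numeric(x) && x >= 0,
             "must be a nonnegative real")
  for (field in c("proportion_female", "progeny_female_fraction")) {
    chk_scalar(field, function(x) is.numeric(x) && x >= 0 && x <= 1,
               "must be a probability in [0, 1]")
  }
  for (field in c("preoviposition_mean", "oviposition_mean",
                  "postoviposition_mean")) {
    chk_scalar(field, function(x) is.numeric(x) && x > 0,
               "must be a positive number of days")
  }
  chk_scalar("daily_egg_mean", function(x) is.numeric(x) && x >= 0,
             "must be a nonnegative real")
  chk_scalar("tray_fecundity_sd", function(x) is.numeric(x) && x >= 0,
             "must be a nonnegative real")
  chk_scalar("seed", function(x) is.numeric(x) && x == floor(x),
             "must be an integer")
  invisible(cfg)
}

#' Reference life-history parameters for *Amblyseius andersoni*
#'
#' Published mean life-history and demographic parameters of the predatory
#' mite *Amblyseius andersoni* reared at 23 degrees C on three diets: larvae
#' and nymphs of the spruce spider mite *Oligonychus ununguis*, larvae and
#' nymphs of the false spider mite *Pentamerismus taxi*, and *Pinus
#' sylvestris* pollen. These values parameterise the default synthetic
#' experiment and serve as fixed inputs to the internal-consistency
#' identities (T = ln(R0)/rm, lambda = exp(rm), survival products,
#' fecundity/longevity ratios).
#'
#' @return A data frame with one row per diet: stage mean durations and
#'   percent survivals (egg, larva, protonymph, deutonymph), percentage
#'   reaching maturity, reproductive-period means, total fecundity,
#'   longevity, oviposition rate, and the demographic parameters R0, T, rm
#'   and lambda.
#' @export
reference_diet_parameters <- function() {
  data.frame(
    diet = c("O. ununguis", "P. taxi", "pine pollen"),
    egg_d = c(1.53, 1.48, 1.79),
    larva_d = c(0.76, 0.62, 0.84),
    protonymph_d = c(1.70, 1.40, 2.09),
    deutonymph_d = c(1.61, 1.66, 1.79),
    egg_surv_pct = c(95.74, 96.36, 98.11),
    larva_surv_pct = c(95.56, 97.67, 96.15),
    protonymph_surv_pct = c(95.35, 97.62, 92.00),
    deutonymph_surv_pct = c(100, 97.56, 91.30),
    maturity_pct = c(87.23, 90.91, 79.25),
    preoviposition_d = c(3.28, 2.02, 3.50),
    oviposition_d = c(20.4, 24.4, 19.1),
    postoviposition_d = c(2.70, 1.83, 1.47),
    total_fecundity = c(29.2, 33.3, 24.2),
    longevity_d = c(26.3, 28.3, 23.1),
    oviposition_rate = c(1.09, 1.18, 1.05),
    R0 = c(18.7, 23.3, 15.4),
    T = c(18.3, 19.0, 19.7),
    rm = c(0.160, 0.166, 0.139),
    lambda = c(1.17, 1.18, 1.15),
    stringsAsFactors = FALSE
  )
}

#' Default three-diet cohort configurations
#'
#' Builds the three [cohort_config()] objects that emulate the rearing
#' experiment at its reference parameterisation: stage-duration means and
#' stage survivals from the observed development/survival table, adult
#' periods and fecundity from the reproductive table (daily egg mean = total
#' fecundity / oviposition days). Initial cohort sizes (47, 55, 53) are the
#' smallest integers whose egg-survival fractions reproduce the observed
#' egg-survival percentages.
#'
#' @param n_eggs Optional common cohort size overriding the per-diet
#'   defaults (used for scaled-up recovery experiments).
#' @param seed Base seed; diet i gets `seed + i - 1`.
#' @return Named list of three `cohort_config` objects.
#' @export
default_diet_configs <- function(n_eggs = NULL, seed = 1L) {
  ref <- reference_diet_parameters()
  n_default <- c(47L, 55L, 53L)
  cfgs <- lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    cohort_config(
      diet_label = r$diet,
      n_eggs = if (is.null(n_eggs)) n_default[i] else n_eggs,
      stage_mean_durations = c(r$egg_d, r$larva_d, r$protonymph_d,
                               r$deutonymph_d),
      stage_survival = c(r$egg_surv_pct, r$larva_surv_pct,
                         r$protonymph_surv_pct, r$deutonymph_surv_pct) / 100,
      preoviposition_mean = r$preoviposition_d,
      oviposition_mean = r$oviposition_d,
      postoviposition_mean = r$postoviposition_d,
      daily_egg_mean = r$total_fecundity / r$oviposition_d,
      seed = seed + i - 1L
    )
  })
  names(cfgs) <- ref$diet
  cfgs
}
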