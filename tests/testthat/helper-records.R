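# Hand-construction of individual rearing records for oracle tests.

rec <- function(id = "i1", diet = "A", tray = "t1",
                trans = c(1, 2, 3, 5), died = "none", sex = "female",
                death = NA_real_, eggs = numeric(0)) {
  trans <- c(trans, rep(NA_real_, 4 - length(trans)))
  r <- data.frame(individual_id = id, diet = diet, tray = tray,
                  age_hatch = trans[1], age_larva_end = trans[2],
                  age_proto_end = trans[3], age_deuto_end = trans[4],
                  died_in_stage = died, sex = sex,
                  adult_death_age = death, stringsAsFactors = FALSE)
  r$daily_eggs <- list(eggs)
  class(r) <- c("mite_records", "data.frame")
  r
}

bind_recs <- function(...) {
  out <- do.call(rbind, lapply(list(...), function(p) {
    class(p) <- "data.frame"
    p
  }))
  rownames(out) <- NULL
  class(out) <- c("mite_records", "data.frame")
  out
}

# the two-female toy cohort: egg day 0, adult day 5, 4 eggs each on day 7
# (adult day 3), death at day 8
toy_two_females <- function() {
  bind_recs(
    rec("f1", trans = c(1.5, 2.5, 3.5, 5), death = 8, eggs = c(0, 0, 4)),
    rec("f2", trans = c(1.5, 2.5, 3.5, 5), death = 8, eggs = c(0, 0, 4))
  )
}

# a 10-record mixed cohort: 3 immature deaths, 2 males, 5 females with
# staggered schedules
mixed_cohort_10 <- function() {
  bind_recs(
    rec("d1", trans = numeric(0), died = "egg", sex = "unknown"),
    rec("d2", trans = c(1.5), died = "larva", sex = "unknown"),
    rec("d3", trans = c(1.5, 2.0, 3.5), died = "deutonymph", sex = "unknown"),
    rec("m1", trans = c(1.5, 2.0, 3.5, 5.0), sex = "male"),
    rec("m2", trans = c(2.0, 2.5, 4.0, 6.0), sex = "male"),
    rec("f1", trans = c(1.5, 2.0, 3.5, 5.0), death = 12,
        eggs = c(0, 0, 2, 3, 1, 0, 0)),
    rec("f2", trans = c(1.5, 2.5, 4.0, 5.5), death = 14,
        eggs = c(0, 1, 2, 2, 2, 1, 0, 0)),
    rec("f3", trans = c(2.0, 2.5, 4.0, 6.0), death = 13,
        eggs = c(0, 0, 0, 3, 2, 1, 0)),
    rec("f4", trans = c(1.5, 2.0, 3.0, 4.5), death = 10,
        eggs = c(0, 2, 2, 1, 0, 0)),
    rec("f5", trans = c(2.0, 3.0, 4.5, 6.5), death = 11, eggs = c(0, 0, 0, 0))
  )
}

# zero-variance, full-survival, all-female configuration (deterministic)
degenerate_config <- function(n = 5, seed = 1) {
  cohort_config(
    diet_label = "degenerate", n_eggs = n,
    stage_mean_durations = c(1.5, 0.5, 1.5, 1.5),
    stage_duration_cv = 0,
    stage_survival = rep(1, 4),
    proportion_female = 1,
    preoviposition_mean = 2, oviposition_mean = 5, postoviposition_mean = 1,
    adult_period_cv = 0,
    daily_egg_mean = 2,
    progeny_female_fraction = 0.5,
    egg_noise = "none",
    seed = seed
  )
}

small_config <- function(n = 40, seed = 1, diet = "O. ununguis") {
  cfg <- default_diet_configs(seed = seed)[[diet]]
  cfg$n_eggs <- n
  cfg$seed <- seed
  cfg
}
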