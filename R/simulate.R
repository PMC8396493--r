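# Individual-based simulation of the rearing experiment: one egg per
# experimental unit, immatures checked twice a day (events recorded at the
# first check after they occur, i.e. rounded up to 0.5 d), adults checked
# every 24 h (whole-day resolution).

ceil_half <- function(x) ceiling(2 * x) / 2

# gamma draw parameterised by mean and CV; cv = 0 degenerates to the mean
rgamma_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Generate a synthetic rearing cohort
#'
#' Simulates `n_eggs` individuals through the four immature stages and (for
#' females) through an adult pre-oviposition / oviposition /
#' post-oviposition schedule with daily egg counts. Stage durations are
#' gamma with the configured mean and CV, rounded up to the half-day
#' observation grid; each stage is survived with the configured Bernoulli
#' probability; sex is assigned at adulthood; adult periods are gamma
#' rounded to whole days (oviposition at least 1 d); daily clutches are
#' Poisson with mean `daily_egg_mean` during the oviposition window. The
#' whole simulation is driven by `config$seed`: identical configs yield
#' byte-identical record tables.
#'
#' @param config A [cohort_config()].
#' @return A `mite_records` data frame, one row per individual, with
#'   columns `individual_id`, `diet`, `tray`, the four transition ages
#'   `age_hatch`, `age_larva_end`, `age_proto_end`, `age_deuto_end` (days
#'   since egg deposition, 0.5-d grid, `NA` from the first failed
#'   transition on), `died_in_stage` (`"egg"`, `"larva"`, `"protonymph"`,
#'   `"deutonymph"` or `"none"`), `sex` (`"female"`, `"male"`, `"unknown"`
#'   for immature deaths), `adult_death_age` (whole days since deposition;
#'   females only) and the list-column `daily_eggs` (eggs laid on each
#'   whole day of adult life; females only).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_eggs

  # immature development: per-stage durations discretised to the 0.5-d grid,
  # cumulated into transition ages
  dur <- vapply(1:4, function(j) {
    ceil_half(rgamma_mean_cv(n, config$stage_mean_durations[j],
                             config$stage_duration_cv))
  }, numeric(n))
  dur <- matrix(dur, nrow = n)
  trans <- t(apply(dur, 1, cumsum))

  # stage-wise Bernoulli survival; the first failed stage is fatal
  alive <- matrix(stats::runif(4 * n), nrow = n) <=
    matrix(config$stage_survival, nrow = n, ncol = 4, byrow = TRUE)
  first_fail <- apply(alive, 1, function(a) {
    i <- which(!a)
    if (length(i)) i[1] else 5L
  })
  died_in_stage <- c(STAGES, "none")[first_fail]

  # transitions recorded only for completed stages
  for (j in 1:4) trans[first_fail <= j, j] <- NA_real_

  is_adult <- first_fail == 5L
  sex <- rep("unknown", n)
  sex[is_adult] <- ifelse(stats::runif(sum(is_adult)) <=
                            config$proportion_female, "female", "male")
  is_f <- sex == "female"
  nf <- sum(is_f)

  # adult female schedule (whole-day resolution)
  pre <- ovi <- post <- integer(0)
  if (nf > 0) {
    pre <- pmax(0, round(rgamma_mean_cv(nf, config$preoviposition_mean,
                                        config$adult_period_cv)))
    ovi <- pmax(1, round(rgamma_mean_cv(nf, config$oviposition_mean,
                                        config$adult_period_cv)))
    post <- pmax(0, round(rgamma_mean_cv(nf, config$postoviposition_mean,
                                         config$adult_period_cv)))
  }

  tray <- sprintf("tray%02d", ((seq_len(n) - 1L) %% config$n_trays) + 1L)
  tray_mult <- rep(1, config$n_trays)
  if (config$tray_fecundity_sd > 0) {
    tray_mult <- exp(stats::rnorm(config$n_trays, -config$tray_fecundity_sd^2 / 2,
                                  config$tray_fecundity_sd))
  }

  daily_eggs <- vector("list", n)
  adult_death_age <- rep(NA_real_, n)
  fi <- which(is_f)
  for (k in seq_along(fi)) {
    i <- fi[k]
    L <- pre[k] + ovi[k] + post[k]
    eggs <- numeric(L)
    mu <- config$daily_egg_mean *
      tray_mult[((i - 1L) %% config$n_trays) + 1L]
    window <- seq.int(pre[k] + 1L, pre[k] + ovi[k])
    eggs[window] <- if (config$egg_noise == "poisson") {
      stats::rpois(ovi[k], mu)
    } else {
      rep(mu, ovi[k])
    }
    daily_eggs[[i]] <- eggs
    adult_death_age[i] <- ceiling(trans[i, 4] + L)
  }
  for (i in which(!is_f)) daily_eggs[[i]] <- numeric(0)

  out <- data.frame(
    individual_id = sprintf("%s-%03d", gsub("[^A-Za-z0-9]+", "", config$diet_label),
                            seq_len(n)),
    diet = config$diet_label,
    tray = tray,
    age_hatch = trans[, 1],
    age_larva_end = trans[, 2],
    age_proto_end = trans[, 3],
    age_deuto_end = trans[, 4],
    died_in_stage = died_in_stage,
    sex = sex,
    adult_death_age = adult_death_age,
    stringsAsFactors = FALSE
  )
  out$daily_eggs <- daily_eggs
  class(out) <- c("mite_records", "data.frame")
  out
}

#' Generate a multi-diet synthetic experiment
#'
#' @param configs List of [cohort_config()] objects (default:
#'   [default_diet_configs()]).
#' @param seed Optional master seed; if given, each config's seed is
#'   replaced by a value derived from it.
#' @return A single `mite_records` data frame stacking all cohorts.
#' @export
generate_experiment <- function(configs = default_diet_configs(),
                                seed = NULL) {
  if (!is.null(seed)) {
    set.seed(seed)
    sub <- sample.int(.Machine$integer.max %/% 2L, length(configs))
    for (i in seq_along(configs)) configs[[i]]$seed <- sub[i]
  }
  rbind_records(lapply(configs, generate_cohort))
}

rbind_records <- function(parts) {
  out <- do.call(rbind, lapply(parts, function(p) {
    class(p) <- "data.frame"
    p
  }))
  rownames(out) <- NULL
  class(out) <- c("mite_records", "data.frame")
  out
}

# Exact distribution of a gamma duration after rounding up to the 0.5-d
# grid: P(ceil2(D) = k/2) = F(k/2) - F((k-1)/2). Returns (support, prob).
discretised_gamma_half <- function(mean, cv, tail = 1e-12) {
  if (cv == 0) {
    return(list(x = ceil_half(mean), p = 1))
  }
  shape <- 1 / cv^2
  rate <- shape / mean
  hi <- ceil_half(stats::qgamma(1 - tail, shape, rate))
  x <- seq(0.5, hi, by = 0.5)
  p <- diff(stats::pgamma(c(0, x), shape, rate))
  p <- p / sum(p)
  list(x = x, p = p)
}

# whole-day rounding used for adult periods: round(), optional floor
discretised_gamma_day <- function(mean, cv, min_days = 0L, tail = 1e-12) {
  if (cv == 0) {
    return(list(x = max(min_days, round(mean)), p = 1))
  }
  shape <- 1 / cv^2
  rate <- shape / mean
  hi <- ceiling(stats::qgamma(1 - tail, shape, rate)) + 1
  x <- seq.int(0L, hi)
  p <- diff(stats::pgamma(c(x - 0.5, hi + 0.5), shape, rate))
  p[1] <- p[1] + stats::pgamma(-0.5, shape, rate)  # zero anyway, keeps sums exact
  if (min_days > 0) {
    p[x == min_days] <- p[x == min_days] + sum(p[x < min_days])
    keep <- x >= min_days
    x <- x[keep]; p <- p[keep]
  }
  p <- p / sum(p)
  list(x = x, p = p)
}

convolve_discrete <- function(a, b, step) {
  ia <- round(a$x / step); ib <- round(b$x / step)
  hi <- max(ia) + max(ib)
  lo <- min(ia) + min(ib)
  p <- numeric(hi - lo + 1)
  for (k in seq_along(ia)) {
    idx <- ia[k] + ib - lo + 1
    p[idx] <- p[idx] + a$p[k] * b$p
  }
  list(x = (lo:hi) * step, p = p)
}

#' Expected net maternity schedule of a cohort configuration
#'
#' Computes analytically, on the whole-day age grid, the expected net
#' maternity `lx*mx` implied by a [cohort_config()]: the expected number of
#' female eggs laid at age x per egg entering the cohort, under exactly the
#' discretisation the simulator applies (stage durations rounded up to
#' 0.5 d, adult periods rounded to whole days). The calculation convolves
#' the exact discretised stage-duration distributions into the adult-age
#' distribution and weights each adult day by the probability that it falls
#' inside the oviposition window.
#'
#' This noiseless schedule is the target in parameter-recovery checks: the
#' demographic parameters of a large simulated cohort converge to those of
#' this schedule.
#'
#' @param config A [cohort_config()].
#' @param tail Probability mass beyond which gamma tails are truncated.
#' @return Data frame with columns `age` (whole days) and `net_maternity`.
#' @export
expected_schedule <- function(config, tail = 1e-12) {
  validate_cohort_config(config)
  s_imm <- prod(config$stage_survival)

  adult <- Reduce(function(a, b) convolve_discrete(a, b, 0.5),
                  lapply(1:4, function(j) {
                    discretised_gamma_half(config$stage_mean_durations[j],
                                           config$stage_duration_cv, tail)
                  }))

  pre <- discretised_gamma_day(config$preoviposition_mean,
                               config$adult_period_cv, 0L, tail)
  ovi <- discretised_gamma_day(config$oviposition_mean,
                               config$adult_period_cv, 1L, tail)

  # W(k) = P(adult day k lies in the oviposition window)
  #      = sum_p P(pre = p, p < k <= p + ovi)
  kmax <- max(pre$x) + max(ovi$x)
  W <- vapply(seq_len(kmax), function(k) {
    ok <- pre$x <= k - 1
    if (!any(ok)) return(0)
    sum(pre$p[ok] * vapply(pre$x[ok], function(p) {
      sum(ovi$p[ovi$x >= k - p])
    }, numeric(1)))
  }, numeric(1))

  # eggs laid on adult day k are recorded at whole-day age floor(a) + k - 1
  fa <- floor(adult$x)
  amax <- max(fa) + kmax - 1
  net <- numeric(amax + 1)  # index = age + 1, ages 0..amax
  for (j in seq_along(adult$x)) {
    ages <- fa[j] + seq_len(kmax) - 1L
    net[ages + 1L] <- net[ages + 1L] + adult$p[j] * W
  }
  # lx carries immature survival and adult *female* survival; mx divides by
  # females alive, so the sex ratio cancels from the product lx*mx
  net <- net * s_imm * config$daily_egg_mean * config$progeny_female_fraction
  data.frame(age = 0:amax, net_maternity = net)
}
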