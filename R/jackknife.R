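# Jackknife pseudovalue inference for cohort-level demographic parameters
# and unadjusted pairwise diet comparisons.
#
# The leave-one-out unit is the individual (an egg entering the cohort).
# For statistic theta on n individuals, pseudovalues are
#   phi_i = n * theta_all - (n - 1) * theta_(-i)
# and se = sd(phi) / sqrt(n). For a linear statistic (the mean) this
# reproduces the classical standard error exactly.

#' Generic jackknife of a statistic over a sample
#'
#' @param x A vector, or any object subsettable by integer index with `[`
#'   whose length is the number of leave-one-out units.
#' @param statistic Function mapping a subsample of `x` to a scalar.
#' @return List with `theta_all`, `pseudovalues`, `estimate`
#'   (mean pseudovalue), `se`, `n`.
#' @export
jackknife <- function(x, statistic) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n < 3) stop("input error: jackknife needs at least 3 units",
                  call. = FALSE)
  sub <- function(i) if (is.data.frame(x)) x[-i, , drop = FALSE] else x[-i]
  theta_all <- statistic(x)
  loo <- vapply(seq_len(n), function(i) statistic(sub(i)), numeric(1))
  phi <- n * theta_all - (n - 1) * loo
  list(theta_all = theta_all, pseudovalues = phi, estimate = mean(phi),
       se = stats::sd(phi) / sqrt(n), n = n)
}

#' Jackknife a demographic parameter over a cohort
#'
#' Recomputes one of the demographic parameters (`R0`, `rm`, `T`,
#' `lambda`) on each leave-one-out cohort, rebuilding the life table every
#' time, and forms pseudovalues, their mean and the jackknife standard
#' error. Leave-one-out replicates in which no female reproduces (possible
#' in tiny cohorts) are excluded with a warning, reducing the effective n.
#'
#' @param records A `mite_records` data frame for one diet.
#' @param parameter One of `"R0"`, `"rm"`, `"T"`, `"lambda"`.
#' @param progeny_female_fraction Fraction of eggs that are female.
#' @param tol Euler-Lotka residual tolerance.
#' @param pivotal_age Passed to [intrinsic_rate()].
#' @return Object of class `jackknife_estimate`: list with `parameter_name`,
#'   `diet_label`, `theta_all`, `pseudovalues`, `estimate`, `se`, `n`
#'   (effective), `n_excluded`.
#' @export
jackknife_parameter <- function(records,
                                parameter = c("rm", "R0", "T", "lambda"),
                                progeny_female_fraction,
                                tol = 1e-10, pivotal_age = FALSE) {
  parameter <- match.arg(parameter)
  n_total <- nrow(records)
  if (n_total < 3) {
    stop("input error: jackknife needs at least 3 records", call. = FALSE)
  }
  stat <- function(rec) {
    lt <- build_life_table(rec, progeny_female_fraction)
    switch(parameter,
           R0 = net_reproductive_rate(lt),
           rm = intrinsic_rate(lt, tol = tol, pivotal_age = pivotal_age),
           T = {
             p <- demographic_params(lt, tol = tol, pivotal_age = pivotal_age)
             p$T
           },
           lambda = finite_rate(intrinsic_rate(lt, tol = tol,
                                               pivotal_age = pivotal_age)))
  }
  theta_all <- stat(records)
  loo <- vapply(seq_len(n_total), function(i) {
    tryCatch(stat(records[-i, , drop = FALSE]),
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- !is.na(loo)
  n <- sum(ok)
  if (n < n_total) {
    warning(sprintf(
      "%d of %d leave-one-out replicates had no reproducing female and were excluded; effective n = %d",
      n_total - n, n_total, n), call. = FALSE)
  }
  if (n < 3) {
    stop("analysis error: fewer than 3 usable leave-one-out replicates",
         call. = FALSE)
  }
  phi <- n * theta_all - (n - 1) * loo[ok]
  structure(list(parameter_name = parameter,
                 diet_label = records$diet[1],
                 theta_all = theta_all,
                 pseudovalues = phi,
                 estimate = mean(phi),
                 se = stats::sd(phi) / sqrt(n),
                 n = n,
                 n_excluded = n_total - n),
            class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf("Jackknife estimate of %s (%s): %.5g +/- %.3g (n = %d%s)\n",
              x$parameter_name, x$diet_label, x$estimate, x$se, x$n,
              if (x$n_excluded > 0)
                sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Pairwise comparison of a demographic parameter between two diets
#'
#' Two-sample pooled-variance t test on the two pseudovalue sets, two-sided,
#' with df = n_a + n_b - 2 and no multiplicity adjustment.
#'
#' @param a,b `jackknife_estimate` objects for the same parameter.
#' @param welch If `TRUE`, uses the Welch (unequal-variance) form instead of
#'   the pooled form.
#' @return Object of class `pairwise_comparison`: list with `diet_a`,
#'   `diet_b`, `parameter_name`, `difference`, `t_statistic`, `df`,
#'   `p_value`.
#' @export
compare_diets <- function(a, b, welch = FALSE) {
  if (!inherits(a, "jackknife_estimate") || !inherits(b, "jackknife_estimate")) {
    stop("input error: compare_diets expects two jackknife_estimate objects",
         call. = FALSE)
  }
  if (a$parameter_name != b$parameter_name) {
    stop(sprintf("input error: parameter mismatch ('%s' vs '%s')",
                 a$parameter_name, b$parameter_name), call. = FALSE)
  }
  pa <- a$pseudovalues; pb <- b$pseudovalues
  na <- length(pa); nb <- length(pb)
  if (na < 2 || nb < 2) {
    stop("input error: need at least 2 pseudovalues per group", call. = FALSE)
  }
  diff <- mean(pa) - mean(pb)
  va <- stats::var(pa); vb <- stats::var(pb)
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  t_stat <- if (se == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / se
  }
  p <- if (t_stat == 0) 1 else 2 * stats::pt(-abs(t_stat), df)
  structure(list(diet_a = a$diet_label, diet_b = b$diet_label,
                 parameter_name = a$parameter_name,
                 difference = diff, t_statistic = t_stat,
                 df = df, p_value = p),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s, diff = %.5g, t = %.3f, df = %.4g, p = %.4g\n",
              x$parameter_name, x$diet_a, x$diet_b, x$difference,
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Compact letter display for pairwise comparisons
#'
#' Assigns letters to diets so that two diets share a letter if and only if
#' their pairwise comparison is non-significant at `alpha` (insert-and-absorb
#' algorithm). Letters are ordered by ascending parameter estimate:
#' the group containing the smallest estimate gets "a". Intransitive
#' significance patterns yield multi-letter labels.
#'
#' @param comparisons List of `pairwise_comparison` objects (or a data frame
#'   with columns `diet_a`, `diet_b`, `p_value`) covering all diet pairs for
#'   one parameter.
#' @param estimates Named numeric vector of parameter estimates, one per
#'   diet; names must cover all diets in `comparisons`.
#' @param alpha Significance threshold (default 0.05).
#' @return Named character vector of letter labels, in ascending-estimate
#'   order.
#' @export
letter_groups <- function(comparisons, estimates, alpha = 0.05) {
  if (is.data.frame(comparisons)) {
    cmp <- comparisons
  } else {
    cmp <- do.call(rbind, lapply(comparisons, function(x) {
      data.frame(diet_a = x$diet_a, diet_b = x$diet_b, p_value = x$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  diets <- names(sort(estimates))
  k <- length(diets)
  in_cmp <- unique(c(cmp$diet_a, cmp$diet_b))
  if (!setequal(in_cmp, diets) || nrow(cmp) < choose(k, 2)) {
    stop("input error: comparisons must cover all pairs of the diets named ",
         "in 'estimates'", call. = FALSE)
  }
  sig <- cmp[cmp$p_value <= alpha, , drop = FALSE]

  # insert-and-absorb: start with one set holding everything; each
  # significant pair splits every set containing both members; absorb
  # redundant subsets
  sets <- list(diets)
  for (r in seq_len(nrow(sig))) {
    pa <- sig$diet_a[r]; pb <- sig$diet_b[r]
    new_sets <- list()
    for (s in sets) {
      if (pa %in% s && pb %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, pa)), list(setdiff(s, pb)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
    sets <- sets[vapply(sets, length, integer(1)) > 0]
  }

  # order letter sets by the smallest estimate they contain
  ord <- order(vapply(sets, function(s) min(estimates[s]), numeric(1)))
  sets <- sets[ord]
  labels <- stats::setNames(rep("", k), diets)
  for (i in seq_along(sets)) {
    lab <- letters[i]
    for (d in sets[[i]]) labels[d] <- paste0(labels[d], lab)
  }
  labels
}
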