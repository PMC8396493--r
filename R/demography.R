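# Birch's demographic parameters from a cohort life table:
#   R0     = sum_x lx * mx                 (net reproductive rate)
#   rm     : sum_x exp(-rm * x) lx mx = 1  (discrete Euler-Lotka equation)
#   T      = ln(R0) / rm                   (mean generation time)
#   lambda = exp(rm)                       (finite rate of increase)
# Ages enter the sums exactly as the whole-day grid values; an optional
# pivotal-age correction (x + 0.5) is available but off by default.

utils::globalVariables(c("age", "value", "schedule"))

net_maternity <- function(x) {
  if (inherits(x, "life_table")) {
    return(list(ages = x$ages, net = x$lx * x$mx))
  }
  if (is.data.frame(x) && all(c("age", "net_maternity") %in% names(x))) {
    return(list(ages = x$age, net = x$net_maternity))
  }
  if (is.data.frame(x) && all(c("age", "lx", "mx") %in% names(x))) {
    return(list(ages = x$age, net = x$lx * x$mx))
  }
  stop("input error: expected a life_table or a data frame with columns ",
       "age and net_maternity (or age, lx, mx)", call. = FALSE)
}

#' Net reproductive rate
#'
#' \eqn{R_0 = \sum_x l_x m_x}: expected daughters per newborn female over a
#' generation.
#'
#' @param lt A `life_table`, or a data frame with columns `age` and
#'   `net_maternity` (or `age`, `lx`, `mx`).
#' @param pivotal_age If `TRUE`, offsets ages by +0.5 d (no effect on R0;
#'   accepted for interface symmetry).
#' @return R0 (dimensionless).
#' @export
net_reproductive_rate <- function(lt, pivotal_age = FALSE) {
  nm <- net_maternity(lt)
  if (all(nm$net == 0)) {
    stop("analysis error: no reproduction in this cohort (all mx zero)",
         call. = FALSE)
  }
  sum(nm$net)
}

#' Intrinsic rate of increase (Euler-Lotka root)
#'
#' Solves the discrete Euler-Lotka equation
#' \eqn{\sum_x e^{-r x} l_x m_x = 1} for the unique real root r. The
#' left-hand side is strictly decreasing in r, so the root is bracketed
#' (starting from \[-1, 2\] per day, doubling up to |r| = 10) and found with
#' Brent's method, then checked against `tol`.
#'
#' @inheritParams net_reproductive_rate
#' @param tol Maximum allowed Euler-Lotka residual at the returned root.
#' @param pivotal_age If `TRUE`, uses pivotal ages x + 0.5 in the sum.
#' @return rm, per day.
#' @export
intrinsic_rate <- function(lt, tol = 1e-10, pivotal_age = FALSE) {
  if (!is.numeric(tol) || tol <= 0) {
    stop("input error: tol must be positive", call. = FALSE)
  }
  nm <- net_maternity(lt)
  if (all(nm$net == 0)) {
    stop("analysis error: no reproduction in this cohort (all mx zero)",
         call. = FALSE)
  }
  ages <- nm$ages + if (pivotal_age) 0.5 else 0
  euler_lotka_rate(ages, nm$net, tol = tol)
}

#' Euler-Lotka residual
#'
#' \eqn{\sum_x e^{-r x} l_x m_x - 1} evaluated at rate `r`.
#'
#' @param ages Age grid (days).
#' @param net Net maternity `lx*mx` at those ages.
#' @param r Growth rate per day.
#' @return The residual (0 at the Euler-Lotka root).
#' @export
euler_lotka_residual <- function(ages, net, r) {
  sum(exp(-r * ages) * net) - 1
}

#' @rdname euler_lotka_residual
#' @param tol Maximum allowed residual at the returned root.
#' @param bracket Initial search bracket for r (per day), expanded by
#'   doubling up to |r| = 10 if it does not straddle the root.
#' @return `euler_lotka_rate`: the root r.
#' @export
euler_lotka_rate <- function(ages, net, tol = 1e-10, bracket = c(-1, 2)) {
  keep <- net > 0
  if (!any(keep)) {
    stop("analysis error: no reproduction (all net maternity zero)",
         call. = FALSE)
  }
  f <- function(r) euler_lotka_residual(ages[keep], net[keep], r)
  lo <- bracket[1]; hi <- bracket[2]
  # f is strictly decreasing: f(lo) must be > 0 and f(hi) < 0
  while (f(hi) > 0 && hi < 10) hi <- hi * 2
  while (f(lo) < 0 && lo > -10) lo <- lo * 2
  if (f(hi) > 0 || f(lo) < 0) {
    stop("numerical error: Euler-Lotka root not bracketed in [-10, 10]/day",
         call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75,
                         maxiter = 2000L)$root
  # Newton polish to machine precision (f' = -sum x e^{-rx} net)
  for (it in 1:3) {
    fr <- f(root)
    dfr <- -sum(ages[keep] * exp(-root * ages[keep]) * net[keep])
    if (dfr == 0) break
    step <- fr / dfr
    if (!is.finite(step) || step == 0) break
    root <- root - step
  }
  if (abs(f(root)) >= tol) {
    stop(sprintf("numerical error: Euler-Lotka residual %.3e exceeds tol %.1e",
                 abs(f(root)), tol), call. = FALSE)
  }
  root
}

#' Mean generation time
#'
#' \eqn{T = \ln(R_0) / r_m}, the mean age of mothers at daughter
#' production, in days.
#'
#' @param R0 Net reproductive rate.
#' @param rm Intrinsic rate of increase per day.
#' @return T in days.
#' @export
mean_generation_time <- function(R0, rm) {
  if (!is.numeric(R0) || R0 <= 0) {
    stop("input error: R0 must be positive", call. = FALSE)
  }
  if (rm == 0) {
    stop("undefined-parameter error: T = ln(R0)/rm is undefined at rm = 0 ",
         "(stationary cohort); for a single-pulse schedule T equals the ",
         "pulse age", call. = FALSE)
  }
  log(R0) / rm
}

#' Finite rate of increase
#'
#' \eqn{\lambda = e^{r_m}}: the daily multiplication factor of the
#' population.
#'
#' @param rm Intrinsic rate of increase per day.
#' @return lambda, per day.
#' @export
finite_rate <- function(rm) {
  if (!is.numeric(rm) || !all(is.finite(rm))) {
    stop("input error: rm must be finite", call. = FALSE)
  }
  exp(rm)
}

#' All four demographic parameters of a cohort
#'
#' @inheritParams intrinsic_rate
#' @return A one-row data frame with `diet`, `R0`, `T`, `rm`, `lambda`.
#' @export
demographic_params <- function(lt, tol = 1e-10, pivotal_age = FALSE) {
  R0 <- net_reproductive_rate(lt)
  rm <- intrinsic_rate(lt, tol = tol, pivotal_age = pivotal_age)
  data.frame(
    diet = if (inherits(lt, "life_table")) lt$diet_label else NA_character_,
    R0 = R0,
    T = if (rm != 0) mean_generation_time(R0, rm) else NA_real_,
    rm = rm,
    lambda = finite_rate(rm),
    stringsAsFactors = FALSE
  )
}
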