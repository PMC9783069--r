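#' Net reproductive rate R0
#'
#' R0 = sum_x l_x m_x: the expected lifetime offspring per individual of
#' the original egg cohort. Because the net maternity schedule is built
#' from observed egg counts, this equals (total eggs laid by all females)
#' / n exactly.
#'
#' @param sch A `schedules` object with fecundity schedules.
#' @return R0 (offspring per individual).
#' @export
compute_R0 <- function(sch) {
  if (is.null(sch$lxmx)) stop("fecundity schedules not computed")
  sum(sch$lxmx)
}

# Euler-Lotka residual g(r) = sum_x exp(-r (x+1)) lxmx - 1 for the
# discrete schedule indexed from age 0; strictly decreasing in r.
euler_lotka_residual <- function(r, lxmx) {
  x <- seq_along(lxmx) - 1
  sum(exp(-r * (x + 1)) * lxmx) - 1
}

# Core solver on a raw net-maternity vector (ages 0,1,2,...).
solve_r_lxmx <- function(lxmx, tol = 1e-12) {
  R0 <- sum(lxmx)
  if (R0 <= 0) stop("r is undefined: net reproductive rate is zero")
  if (R0 == 1) return(0)
  lo <- -5; hi <- 5
  while (euler_lotka_residual(lo, lxmx) < 0) lo <- lo * 2
  while (euler_lotka_residual(hi, lxmx) > 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    g <- euler_lotka_residual(mid, lxmx)
    if (abs(g) <= tol) return(mid)
    if (g > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-16 * max(1, abs(mid))) break
  }
  (lo + hi) / 2
}

#' Intrinsic rate of increase r (discrete Euler-Lotka)
#'
#' Solves `sum_x exp(-r (x+1)) l_x m_x = 1` for the unique real root `r`,
#' with the age index shifted by one day: offspring produced by a mother
#' of age `x` enter the population at age 0 one census day later. The
#' left-hand side is strictly decreasing in `r`, so bisection from an
#' expanding initial bracket converges unconditionally.
#'
#' @param sch A `schedules` object with fecundity schedules (or, for
#'   convenience, a bare numeric net-maternity vector over ages 0,1,...).
#' @param tol Convergence tolerance on the Euler-Lotka residual.
#' @return r (per day). Signals an error when R0 = 0 (no reproduction);
#'   returns exactly 0 without iteration when R0 = 1.
#' @examples
#' solve_r(c(0, 1))            # reproduction of 1 at age 1: r = 0
#' solve_r(exp(1))             # single term e at age 0: r = 1
#' @export
solve_r <- function(sch, tol = 1e-12) {
  lxmx <- if (is.numeric(sch)) sch else sch$lxmx
  if (is.null(lxmx)) stop("fecundity schedules not computed")
  solve_r_lxmx(lxmx, tol)
}

#' Finite rate of increase lambda
#'
#' The per-day multiplication factor of a population growing at intrinsic
#' rate `r`: lambda = exp(r).
#'
#' @param r Intrinsic rate of increase (per day).
#' @return lambda (per day).
#' @export
finite_rate <- function(r) exp(r)

#' Mean generation time T
#'
#' T = ln(R0) / r: the time a population at its stable age-stage
#' distribution needs to grow R0-fold.
#'
#' @param R0 Net reproductive rate (> 0).
#' @param r Intrinsic rate of increase (nonzero).
#' @return T (days).
#' @export
mean_generation_time <- function(R0, r) {
  if (R0 <= 0) stop("T is undefined: R0 must be positive")
  if (r == 0) stop("T is undefined when r = 0")
  log(R0) / r
}

#' Population parameters of a cohort
#'
#' Convenience wrapper: computes the survival and fecundity schedules and
#' returns R0, r, lambda = exp(r) and T = ln(R0)/r.
#'
#' @param co A [cohort()].
#' @param tol Euler-Lotka tolerance passed to [solve_r()].
#' @return A list of class `population_params` with elements `R0`, `r`,
#'   `lambda`, `T`; `r`, `lambda`, `T` are `NA` when the cohort produced
#'   no offspring.
#' @examples
#' co <- simulate_cohort(sim_config(n = 100, seed = 7))
#' population_params(co)
#' @export
population_params <- function(co, tol = 1e-12) {
  sch <- compute_fecundity_schedules(co, compute_sxj(co))
  R0 <- compute_R0(sch)
  if (R0 > 0) {
    r <- solve_r(sch, tol)
    lam <- finite_rate(r)
    Tg <- if (r != 0) mean_generation_time(R0, r) else NA_real_
  } else {
    r <- lam <- Tg <- NA_real_
  }
  structure(list(R0 = R0, r = r, lambda = lam, T = Tg),
            class = "population_params")
}

#' @export
as.data.frame.population_params <- function(x, ...) {
  data.frame(R0 = x$R0, r = x$r, lambda = x$lambda, T = x$T)
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("R0 = %.2f  r = %.4f /d  lambda = %.4f /d  T = %.2f d\n",
              x$R0, x$r, x$lambda, x$T))
  invisible(x)
}
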