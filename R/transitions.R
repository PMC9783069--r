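#' Empirical daily age-stage transition schedule
#'
#' For every (age x, stage j) class with living occupants, estimates the
#' one-day fate probabilities from the observed daily counts: stay in j,
#' advance to a successor stage, or die. Fates are counted per individual
#' (an individual in j at age x is followed to its own state at x + 1), so
#' the three probabilities sum to 1 by construction. Classes with no
#' occupants carry no fates and are flagged absorbing-dead.
#'
#' The propagation of these fates is what turns the cohort's daily counts
#' into the survival-mass trajectories behind life expectancy e_xj,
#' reproductive value v_xj, and the population projection.
#'
#' @param co A [cohort()].
#' @return An object of class `transition_schedule`: list with `ontology`,
#'   `ages` (0..A), `count` ((A+1) x m occupancy counts), `trans`
#'   (A x m x m array: `trans[x, j, y]` = P(in y at age x | in j at age
#'   x - 1), ages 1-based on the first index), and `pdie` (A x m).
#' @export
estimate_transitions <- function(co) {
  M <- cohort_matrices(co)
  m <- co$ontology$m
  A <- co$A
  count <- matrix(0L, A + 1L, m, dimnames = list(0:A, co$ontology$stages))
  for (j in seq_len(m)) count[, j] <- colSums(M$stage == j, na.rm = TRUE)
  trans <- array(0, c(A, m, m),
                 dimnames = list(0:(A - 1L), co$ontology$stages,
                                 co$ontology$stages))
  for (x in seq_len(A)) {          # from age x-1 to age x
    from <- M$stage[, x]
    to <- M$stage[, x + 1L]
    ok <- !is.na(from)
    if (!any(ok)) next
    for (j in unique(from[ok])) {
      sel <- ok & from == j
      n_j <- sum(sel)
      tt <- to[sel]
      tt <- tt[!is.na(tt)]
      if (length(tt))
        for (y in unique(tt))
          trans[x, j, y] <- sum(tt == y) / n_j
    }
  }
  pdie <- 1 - apply(trans, c(1, 2), sum)
  structure(list(ontology = co$ontology, ages = 0:A, count = count,
                 trans = trans, pdie = pdie),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat("<transition_schedule> ages 0..", max(x$ages), ", ",
      sum(x$count[1, ]), " individuals at age 0\n", sep = "")
  invisible(x)
}

# Propagate a survival-mass vector from reference class (x, j): returns a
# matrix s' of dimensions (horizon+1) x m whose row i+1 holds the mass in
# each stage at age x + i, starting from mass 1 in (x, j). Propagation
# stops when total mass < trunc or the transition data run out (classes
# past the observed maximum age are absorbing-dead for this purpose).
propagate_sprime <- function(tr, x, j, horizon = NULL, trunc = 1e-12) {
  m <- tr$ontology$m
  A <- max(tr$ages)
  if (is.null(horizon)) horizon <- A + 200L
  out <- matrix(0, horizon + 1L, m,
                dimnames = list(x + 0:horizon, tr$ontology$stages))
  cur <- numeric(m)
  cur[j] <- 1
  out[1L, ] <- cur
  for (i in seq_len(horizon)) {
    age <- x + i - 1L               # transitioning from this age
    if (age >= A) break             # everyone observed dead past A
    nxt <- as.vector(cur %*% tr$trans[age + 1L, , ])
    if (sum(nxt) < trunc) break
    cur <- nxt
    out[i + 1L, ] <- cur
  }
  out
}

#' Age-stage life expectancy e_xj
#'
#' Expected number of further days an individual now at age `x` in stage
#' `j` will live, computed by propagating unit survival mass through the
#' empirical daily fates and summing the mass over all later ages and
#' stages. The reference day itself counts one day, so a class certain to
#' be found dead at the next census has e = 1.
#'
#' @param co A [cohort()] (used for occupancy), or `NULL` if `tr` given.
#' @param tr A `transition_schedule`; computed from `co` when missing.
#' @param max_horizon Hard cap on the propagation length in days
#'   (default: observed maximum age + 200).
#' @param trunc Truncation threshold on surviving mass.
#' @return An (A+1) x m matrix of life expectancies, `NA` for classes with
#'   no occupants.
#' @export
compute_exj <- function(co = NULL, tr = NULL, max_horizon = NULL,
                        trunc = 1e-12) {
  if (is.null(tr)) tr <- estimate_transitions(co)
  m <- tr$ontology$m
  A <- max(tr$ages)
  exj <- matrix(NA_real_, A + 1L, m,
                dimnames = list(0:A, tr$ontology$stages))
  for (x in 0:A) for (j in seq_len(m)) {
    if (tr$count[x + 1L, j] == 0L) next
    sp <- propagate_sprime(tr, x, j, horizon = max_horizon, trunc = trunc)
    exj[x + 1L, j] <- sum(sp)
  }
  exj
}

#' Age-stage reproductive value v_xj
#'
#' The expected contribution of an individual now at age `x` in stage `j`
#' to the future population, discounted at the intrinsic rate `r`:
#' `v_xj = e^{r(x+1)} * sum_{i >= x} e^{-r(i+1)} sum_y s'_iy f_iy`, where
#' `s'` is the survival mass propagated from the reference class and
#' `f_iy` the age-stage fecundity. A post-reproductive class has v = 0; a
#' class with no occupants is `NA`.
#'
#' @param co A [cohort()], or `NULL` if `tr` and `sch` are given.
#' @param sch A `schedules` object with `fxj` (computed when missing).
#' @param tr A `transition_schedule` (computed when missing).
#' @param r Intrinsic rate of increase; solved from `sch` when missing.
#' @param trunc Truncation threshold on surviving mass.
#' @return An (A+1) x m matrix of reproductive values.
#' @export
compute_vxj <- function(co = NULL, sch = NULL, tr = NULL, r = NULL,
                        trunc = 1e-12) {
  if (is.null(sch)) sch <- compute_fecundity_schedules(co, compute_sxj(co))
  if (is.null(tr)) tr <- estimate_transitions(co)
  if (is.null(r)) r <- solve_r(sch)
  m <- tr$ontology$m
  A <- max(tr$ages)
  fxj <- sch$fxj
  vxj <- matrix(NA_real_, A + 1L, m,
                dimnames = list(0:A, tr$ontology$stages))
  for (x in 0:A) for (j in seq_len(m)) {
    if (tr$count[x + 1L, j] == 0L) next
    sp <- propagate_sprime(tr, x, j, trunc = trunc)
    ages_i <- x + seq_len(nrow(sp)) - 1L           # ages covered by sp
    keep <- ages_i <= A
    fi <- fxj[ages_i[keep] + 1L, , drop = FALSE]
    disc <- exp(-r * (ages_i[keep] + 1))
    vxj[x + 1L, j] <- exp(r * (x + 1)) *
      sum(disc * rowSums(sp[keep, , drop = FALSE] * fi))
  }
  vxj
}

#' Full age-stage two-sex life table
#'
#' One-call wrapper that assembles every schedule and parameter from a
#' cohort: s_xj, l_x, f_xj, m_x, net maternity, the empirical transition
#' schedule, e_xj, v_xj (when the cohort reproduced), and the population
#' parameters R0, r, lambda, T.
#'
#' @param co A [cohort()].
#' @return A list of class `life_table` with `schedules` (including `exj`
#'   and `vxj` matrices), `transitions`, and `params`.
#' @examples
#' co <- simulate_cohort(sim_config(n = 100, seed = 42))
#' lt <- life_table(co)
#' lt$params
#' @export
life_table <- function(co) {
  sch <- compute_fecundity_schedules(co, compute_sxj(co))
  tr <- estimate_transitions(co)
  sch$exj <- compute_exj(tr = tr)
  params <- population_params(co)
  if (!is.na(params$r)) sch$vxj <- compute_vxj(sch = sch, tr = tr,
                                               r = params$r)
  structure(list(schedules = sch, transitions = tr, params = params,
                 treatment = co$treatment),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> treatment=", x$treatment, "\n", sep = "")
  print(x$params)
  invisible(x)
}
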