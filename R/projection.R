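#' Deterministic age-stage-structured population projection
#'
#' Projects the expected population from an initial batch of same-day
#' eggs, using the cohort's empirical daily fates and age-stage fecundity.
#' The projection is an expected-value (real-valued) recursion: on each
#' day, the abundance in every (age, stage) class is distributed over next
#' day's classes by the observed fate probabilities, and the eggs laid on
#' day `t` (sum over female classes of abundance times f_xj) enter the
#' population at age 0 on day `t + 1`.
#'
#' Classes older than the oldest observed age of their stage inherit that
#' stage's last observed fate vector; terminal (adult) stages die one day
#' past their observed maximum age, since the cohort data cannot inform
#' older classes.
#'
#' @param tr A `transition_schedule` from [estimate_transitions()].
#' @param sch A `schedules` object with `fxj` from the same cohort.
#' @param init_eggs Number of age-0 eggs on day 0 (default 10).
#' @param horizon Projection length in days (default 60).
#' @return An object of class `projection_trace`: list with `days`
#'   (0..horizon), `stage_totals` ((horizon+1) x m matrix), `total`
#'   (per-day population size), and `final_state` (age x stage abundance
#'   matrix on the last day).
#' @examples
#' co <- simulate_cohort(sim_config(n = 100, seed = 5))
#' lt <- life_table(co)
#' pr <- project(lt$transitions, lt$schedules, init_eggs = 10, horizon = 60)
#' utils::tail(pr$total)
#' @export
project <- function(tr, sch, init_eggs = 10, horizon = 60) {
  if (horizon < 0) stop("horizon must be >= 0")
  m <- tr$ontology$m
  A <- max(tr$ages)
  stages <- tr$ontology$stages
  term <- stages %in% tr$ontology$terminal
  fem <- match("FEMALE", stages)

  # fate vector lookup with extrapolation beyond observed ages
  last_obs <- apply(tr$count > 0, 2, function(z)
    if (any(z)) max(which(z)) - 1L else NA_integer_)
  fate <- function(x, j) {
    if (!is.na(last_obs[j]) && x > last_obs[j]) {
      if (term[j]) return(numeric(m))                 # dies past max age
      x <- last_obs[j]
    }
    if (x >= A) return(numeric(m))
    tr$trans[x + 1L, j, ]
  }
  fx <- function(x) if (x <= A) sch$fxj[x + 1L, fem] else 0

  maxage <- horizon + A + 1L
  state <- matrix(0, maxage + 1L, m, dimnames = list(NULL, stages))
  state[1L, 1L] <- init_eggs
  stage_totals <- matrix(0, horizon + 1L, m,
                         dimnames = list(0:horizon, stages))
  total <- numeric(horizon + 1L)
  stage_totals[1L, ] <- colSums(state)
  total[1L] <- sum(state)
  for (t in seq_len(horizon)) {
    eggs <- sum(state[, fem] *
                  vapply(seq_len(nrow(state)) - 1L, fx, numeric(1)))
    nxt <- matrix(0, maxage + 1L, m)
    occ <- which(state > 0, arr.ind = TRUE)
    for (k in seq_len(nrow(occ))) {
      x <- occ[k, 1L] - 1L
      j <- occ[k, 2L]
      f <- fate(x, j)
      if (any(f > 0) && x + 2L <= maxage + 1L)
        nxt[x + 2L, ] <- nxt[x + 2L, ] + state[x + 1L, j] * f
    }
    nxt[1L, 1L] <- eggs
    state <- nxt
    stage_totals[t + 1L, ] <- colSums(state)
    total[t + 1L] <- sum(state)
  }
  structure(list(days = 0:horizon, stage_totals = stage_totals,
                 total = total, final_state = state,
                 init_eggs = init_eggs),
            class = "projection_trace")
}

#' @export
print.projection_trace <- function(x, ...) {
  H <- max(x$days)
  cat("<projection_trace> ", x$init_eggs, " eggs -> ",
      signif(x$total[H + 1L], 6), " individuals after ", H, " d\n",
      sep = "")
  invisible(x)
}

#' Per-stage daily abundance table
#'
#' @param trace A `projection_trace` from [project()].
#' @return A tidy data.frame (day, stage, abundance); summing abundance
#'   within a day reproduces the trace total.
#' @export
stage_timeseries <- function(trace) {
  st <- colnames(trace$stage_totals)
  data.frame(day = rep(trace$days, times = length(st)),
             stage = rep(st, each = length(trace$days)),
             abundance = as.vector(trace$stage_totals))
}
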