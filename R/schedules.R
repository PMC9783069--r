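#' Age-stage survival schedule s_xj and age-specific survival l_x
#'
#' `s_xj` is the probability that a newborn egg is alive at age `x` (days
#' since oviposition) in stage `j`, estimated as the fraction of the
#' initial cohort observed alive in stage `j` at age `x`. Summing over
#' stages gives the age-specific survival rate `l_x`, so `l_0 = 1` and
#' `l_x` is non-increasing.
#'
#' @param co A [cohort()] with `n >= 1`.
#' @return An object of class `schedules`: list with `ontology`,
#'   `ages` (0..A), `sxj` ((A+1) x m matrix), `lx`, and `n`.
#' @examples
#' co <- simulate_cohort(sim_config(n = 50, seed = 1))
#' sch <- compute_sxj(co)
#' all.equal(sch$lx, rowSums(sch$sxj))  # identity l_x = sum_j s_xj
#' @export
compute_sxj <- function(co) {
  if (co$n < 1L) stop("cohort is empty (n = 0)")
  M <- cohort_matrices(co)
  m <- co$ontology$m
  sxj <- matrix(0, co$A + 1L, m,
                dimnames = list(0:co$A, co$ontology$stages))
  for (j in seq_len(m))
    sxj[, j] <- colSums(M$stage == j, na.rm = TRUE) / co$n
  structure(list(ontology = co$ontology, ages = 0:co$A, sxj = sxj,
                 lx = unname(rowSums(sxj)), n = co$n),
            class = "schedules")
}

#' Add fecundity schedules f_xj, m_x and net maternity l_x m_x
#'
#' `f_xj` is the mean number of eggs laid at age `x` per individual alive
#' in stage `j` at that age; it is nonzero only for the female adult
#' stage. The age-specific fecundity `m_x` is the s_xj-weighted mean of
#' `f_xj` over stages (zero where no one is alive), and the net maternity
#' `l_x m_x` is the expected egg production at age `x` per original egg.
#'
#' @param co The [cohort()] the schedules came from.
#' @param sch A `schedules` object from [compute_sxj()].
#' @return `sch` extended with `fxj`, `mx`, `lxmx`.
#' @export
compute_fecundity_schedules <- function(co, sch) {
  M <- cohort_matrices(co)
  m <- co$ontology$m
  fem <- match("FEMALE", co$ontology$stages)
  eggs_x <- colSums(M$eggs)
  fem_alive <- colSums(M$stage == fem, na.rm = TRUE)
  if (any(eggs_x > 0 & fem_alive == 0))
    stop("eggs recorded at an age with no living female (data inconsistency)")
  fxj <- matrix(0, co$A + 1L, m, dimnames = dimnames(sch$sxj))
  fxj[fem_alive > 0, fem] <- eggs_x[fem_alive > 0] / fem_alive[fem_alive > 0]
  num <- rowSums(sch$sxj * fxj)
  mx <- ifelse(sch$lx > 0, num / sch$lx, 0)
  sch$fxj <- fxj
  sch$mx <- mx
  sch$lxmx <- sch$lx * mx
  sch
}

#' @export
print.schedules <- function(x, ...) {
  cat("<schedules> ages 0..", max(x$ages), ", m = ", x$ontology$m,
      if (!is.null(x$lxmx)) paste0(", R0 = ", signif(sum(x$lxmx), 6)),
      "\n", sep = "")
  invisible(x)
}

#' Tidy export of schedules
#'
#' @param sch A `schedules` object (with fecundity schedules, and
#'   optionally `exj`/`vxj` matrices attached by [compute_exj()] /
#'   [compute_vxj()]).
#' @return A list of two data.frames: `age_stage` (age, stage, s_xj, f_xj,
#'   and e_xj/v_xj when present) and `age` (age, l_x, m_x, l_x m_x).
#' @export
schedules_tables <- function(sch) {
  st <- sch$ontology$stages
  ages <- sch$ages
  age_stage <- data.frame(age = rep(ages, times = length(st)),
                          stage = rep(st, each = length(ages)),
                          s_xj = as.vector(sch$sxj))
  if (!is.null(sch$fxj)) age_stage$f_xj <- as.vector(sch$fxj)
  if (!is.null(sch$exj)) age_stage$e_xj <- as.vector(sch$exj)
  if (!is.null(sch$vxj)) age_stage$v_xj <- as.vector(sch$vxj)
  age <- data.frame(age = ages, l_x = sch$lx)
  if (!is.null(sch$mx)) { age$m_x <- sch$mx; age$lxmx <- sch$lxmx }
  list(age_stage = age_stage, age = age)
}
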