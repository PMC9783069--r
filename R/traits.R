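#' Summarize development, longevity and reproduction traits
#'
#' Computes the classic cohort trait table: mean and standard error of
#' per-stage development duration, total larval and preadult duration,
#' adult and total preoviposition periods (APOP, TPOP), lifetime fecundity,
#' number of oviposition days, and adult longevity by sex.
#'
#' Qualification rules: a stage duration averages over individuals that
#' *completed* the stage (moved beyond it); total larval duration requires
#' completing the last instar, preadult duration requires reaching an adult
#' stage. APOP is the number of days from adult emergence to the first egg
#' day, TPOP the age at the first egg day; both, with oviposition days,
#' average over females that laid at least one egg. Fecundity (lifetime
#' eggs) and female longevity average over all females; male longevity over
#' all males. Individuals of unknown sex contribute to survival schedules
#' elsewhere but never to adult traits here. A trait with no qualifying
#' individual is reported as `NA`, not zero.
#'
#' @param co A [cohort()].
#' @return A data.frame with columns `trait`, `n`, `mean`, `se`
#'   (`se` = sample SD / sqrt(n); `NA` when `n < 2`).
#' @examples
#' ont <- stage_ontology()
#' co <- cohort(list(
#'   individual_record("f1", c(rep("EGG", 2), rep("L1", 2), rep("L2", 2),
#'     rep("L3", 2), rep("L4", 2), rep("L5", 2), rep("L6", 2),
#'     rep("PREPUPA", 1), rep("PUPA", 3), rep("FEMALE", 4)),
#'     eggs = c(rep(0, 17), 5, 7, 0), sex = "F", ontology = ont)),
#'   ontology = ont)
#' summarize_traits(co)
#' @export
summarize_traits <- function(co) {
  ont <- co$ontology
  pre <- preadult_stages(ont)
  larval <- grep("^L[0-9]+$", pre, value = TRUE)
  stat <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    c(n = n, mean = if (n) mean(x) else NA_real_,
      se = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_)
  }
  per_record <- function(f) vapply(co$records, f, numeric(1))

  stage_dur <- function(stage) per_record(function(r) {
    d <- sum(r$stages == stage)
    nxt <- stage_successors(ont, stage)
    completed <- d > 0 && (length(nxt) > 0 && any(r$stages %in% nxt))
    if (completed) d else NA_real_
  })
  vals <- list()
  for (s in pre) vals[[paste0("duration_", s)]] <- stage_dur(s)

  vals$larval <- per_record(function(r) {
    last <- larval[length(larval)]
    done <- any(r$stages %in% stage_successors(ont, last))
    if (done) sum(r$stages %in% larval) else NA_real_
  })
  vals$preadult <- per_record(function(r) {
    e <- emergence_age(r, ont)
    if (is.na(e)) NA_real_ else e
  })
  vals$APOP <- per_record(function(r) {
    ov <- oviposition_ages(r)
    if (r$sex != "F" || length(ov) == 0L) return(NA_real_)
    ov[1L] - emergence_age(r, ont)
  })
  vals$TPOP <- per_record(function(r) {
    ov <- oviposition_ages(r)
    if (r$sex != "F" || length(ov) == 0L) NA_real_ else ov[1L]
  })
  vals$oviposition_days <- per_record(function(r) {
    if (r$sex != "F" || !any(r$eggs > 0)) NA_real_ else sum(r$eggs > 0)
  })
  vals$fecundity <- per_record(function(r)
    if (r$sex == "F") sum(r$eggs) else NA_real_)
  vals$female_longevity <- per_record(function(r)
    if (r$sex == "F") sum(r$stages %in% ont$terminal) else NA_real_)
  vals$male_longevity <- per_record(function(r)
    if (r$sex == "M") sum(r$stages %in% ont$terminal) else NA_real_)

  out <- do.call(rbind, lapply(vals, stat))
  data.frame(trait = names(vals), n = as.integer(out[, "n"]),
             mean = out[, "mean"], se = out[, "se"], row.names = NULL)
}
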