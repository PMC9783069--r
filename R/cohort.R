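#' A synchronized cohort of individual life-history records
#'
#' Bundles the records of a single egg batch followed daily from
#' oviposition to the death of the last individual, under one treatment
#' label and one stage ontology. The initial cohort size `n` equals the
#' number of records: every egg that entered the study is a record,
#' including eggs that never hatched.
#'
#' @param records List of [individual_record()] objects.
#' @param treatment Treatment label (string).
#' @param ontology A [stage_ontology()].
#'
#' @return An object of class `cohort` with elements `treatment`,
#'   `ontology`, `records`, `n`, and `A` (maximum trajectory length: at age
#'   `A` every individual is dead).
#' @examples
#' ont <- stage_ontology()
#' co <- cohort(list(
#'   individual_record("a", rep("EGG", 3), ontology = ont),
#'   individual_record("b", c(rep("EGG", 3), "L1"), ontology = ont)
#' ), treatment = "demo", ontology = ont)
#' co$n  # 2
#' co$A  # 4
#' @export
cohort <- function(records, treatment = "cohort", ontology = stage_ontology()) {
  if (!is.list(records) ||
      !all(vapply(records, inherits, logical(1), "individual_record")))
    stop("'records' must be a list of individual_record objects")
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (r in records) stage_index(ontology, r$stages)  # all codes known
  A <- if (length(records)) max(vapply(records, `[[`, integer(1), "death_age"))
       else 0L
  structure(list(treatment = as.character(treatment), ontology = ontology,
                 records = records, n = length(records), A = A),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  sexes <- table(factor(vapply(x$records, `[[`, character(1), "sex"),
                        levels = c("F", "M", "U")))
  cat("<cohort> treatment=", x$treatment, " n=", x$n, " A=", x$A,
      " (F:", sexes[["F"]], " M:", sexes[["M"]], " U:", sexes[["U"]], ")\n",
      sep = "")
  invisible(x)
}

# Dense matrix view of a cohort used by the schedule and bootstrap code.
# Returns n x (A + 1) matrices over ages 0..A:
#   stage: integer stage index while alive, NA when dead
#   alive: logical
#   eggs:  daily egg counts (0 when dead)
# plus per-record vectors: sex, total eggs.
cohort_matrices <- function(co) {
  n <- co$n
  A <- co$A
  stage <- matrix(NA_integer_, n, A + 1L)
  eggs <- matrix(0, n, A + 1L)
  for (i in seq_len(n)) {
    r <- co$records[[i]]
    d <- r$death_age
    stage[i, seq_len(d)] <- stage_index(co$ontology, r$stages)
    eggs[i, seq_len(d)] <- r$eggs
  }
  list(stage = stage, alive = !is.na(stage), eggs = eggs,
       sex = vapply(co$records, `[[`, character(1), "sex"),
       total_eggs = rowSums(eggs))
}
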