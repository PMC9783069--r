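#' Individual daily life-history record
#'
#' One individual's trajectory from oviposition (age 0) until death, at a
#' one-observation-per-day census. `stages[k]` is the stage occupied at age
#' `k - 1`; the vector covers living days only, so an individual first found
#' dead at age `length(stages)` was alive through age `length(stages) - 1`.
#' Daily egg counts are aligned with `stages` and may be nonzero only on
#' days the individual was an adult female.
#'
#' @param id Individual identifier (string).
#' @param stages Character vector of stage codes, one per living day,
#'   starting at the day of oviposition.
#' @param eggs Either `NULL` (no eggs), a numeric vector the same length as
#'   `stages`, or a named numeric vector mapping age -> egg count.
#' @param sex `"F"`, `"M"`, or `"U"`. `"U"` (unknown) is required exactly
#'   when the individual died before reaching an adult stage.
#' @param ontology A [stage_ontology()].
#'
#' @return An object of class `individual_record`.
#' @examples
#' ont <- stage_ontology()
#' rec <- individual_record("i1", c("EGG", "EGG", "EGG", "L1", "L1"),
#'                          sex = "U", ontology = ont)
#' rec$death_age   # first found dead at age 5
#' @export
individual_record <- function(id, stages, eggs = NULL, sex = c("U", "F", "M"),
                              ontology = stage_ontology()) {
  sex <- match.arg(sex)
  id <- as.character(id)
  stages <- as.character(stages)
  if (length(stages) < 1L)
    stop("record '", id, "': stage trajectory is empty")
  idx <- stage_index(ontology, stages)

  # monotone stage order, each stage a consecutive block of >= 1 day
  if (any(diff(idx) < 0))
    stop("record '", id, "': stage order violated (stage sequence reverses)")
  r <- rle(stages)
  if (anyDuplicated(r$values))
    stop("record '", id, "': stage re-entered after being left")
  # no skipping within the linear pre-adult chain is not enforced here:
  # a stage may genuinely be passed within one census interval only if the
  # data say so; we require successorship instead.
  for (k in seq_len(length(r$values) - 1L)) {
    succ <- stage_successors(ontology, r$values[k])
    if (!(r$values[k + 1L] %in% succ))
      stop("record '", id, "': illegal transition ", r$values[k], " -> ",
           r$values[k + 1L])
  }

  term <- ontology$terminal
  reached <- intersect(term, stages)
  if (length(reached) > 1L)
    stop("record '", id, "': occupies more than one terminal stage")
  expected_sex <- if (length(reached) == 0L) "U"
                  else if (reached == "FEMALE") "F" else "M"
  if (length(reached) > 0L && !(reached %in% c("FEMALE", "MALE")))
    expected_sex <- sex  # custom ontologies: trust the caller
  if (sex != expected_sex)
    stop("record '", id, "': sex '", sex, "' inconsistent with trajectory ",
         "(expected '", expected_sex, "')")

  ev <- numeric(length(stages))
  if (!is.null(eggs) && length(eggs) > 0L) {
    if (!is.null(names(eggs))) {
      age <- as.integer(names(eggs))
      if (anyNA(age) || any(age < 0) || any(age >= length(stages) & eggs != 0))
        stop("record '", id, "': egg ages outside living days")
      ev[age + 1L] <- as.numeric(eggs)
    } else {
      if (length(eggs) != length(stages))
        stop("record '", id, "': eggs vector length must match trajectory")
      ev <- as.numeric(eggs)
    }
  }
  if (any(ev < 0) || any(ev != floor(ev)))
    stop("record '", id, "': egg counts must be nonnegative integers")
  if (any(ev > 0)) {
    if (sex != "F")
      stop("record '", id, "': eggs recorded for a non-female")
    if (any(ev > 0 & stages != "FEMALE"))
      stop("record '", id, "': eggs recorded outside FEMALE-stage days")
  }

  structure(list(id = id, sex = sex, stages = stages, eggs = ev,
                 death_age = length(stages)),
            class = "individual_record")
}

#' @export
print.individual_record <- function(x, ...) {
  cat("<individual_record> ", x$id, " sex=", x$sex,
      " days=", length(x$stages),
      " stages=", paste(rle(x$stages)$values, collapse = ">"),
      " eggs=", sum(x$eggs), "\n", sep = "")
  invisible(x)
}

# First age at which the record occupies an adult (terminal) stage, or NA.
emergence_age <- function(record, ontology) {
  i <- which(record$stages %in% ontology$terminal)
  if (length(i) == 0L) NA_integer_ else i[1L] - 1L
}

# Ages (0-based) at which the record laid >= 1 egg.
oviposition_ages <- function(record) which(record$eggs > 0) - 1L
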