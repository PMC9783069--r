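#' Stage ontology for an age-stage, two-sex life table
#'
#' Defines the ordered set of developmental stages an individual can occupy.
#' The default ontology follows a noctuid moth life cycle: egg, six larval
#' instars, prepupa, pupa, and two parallel terminal adult stages (female,
#' male). Female and male are alternative successors of the pupal stage;
#' neither succeeds the other. The number of stages is the `m` of the
#' age-stage survival and fecundity sums.
#'
#' @param stages Character vector of stage codes in developmental order.
#'   The last two entries are interpreted as the parallel terminal adult
#'   stages unless `terminal` says otherwise.
#' @param terminal Character vector of terminal (adult) stage codes that are
#'   alternative successors of the last pre-adult stage.
#'
#' @return An object of class `stage_ontology`: a list with elements
#'   `stages`, `terminal`, and `m` (number of stages).
#' @examples
#' ont <- stage_ontology()
#' ont$m          # 11 stages
#' ont$terminal   # "FEMALE" "MALE"
#' @export
stage_ontology <- function(stages = c("EGG", "L1", "L2", "L3", "L4", "L5",
                                      "L6", "PREPUPA", "PUPA", "FEMALE",
                                      "MALE"),
                           terminal = c("FEMALE", "MALE")) {
  stages <- as.character(stages)
  if (anyDuplicated(stages))
    stop("stage codes must be unique")
  if (!all(terminal %in% stages))
    stop("terminal stages must be listed in 'stages'")
  if (!all(terminal %in% utils::tail(stages, length(terminal))))
    stop("terminal stages must come last in 'stages'")
  if ("DEAD" %in% stages)
    stop("'DEAD' is reserved and cannot be a stage code")
  structure(list(stages = stages, terminal = terminal,
                 m = length(stages)),
            class = "stage_ontology")
}

#' @export
print.stage_ontology <- function(x, ...) {
  cat("Stage ontology (m =", x$m, "):", paste(x$stages, collapse = " -> "),
      "\n  terminal:", paste(x$terminal, collapse = ", "), "\n")
  invisible(x)
}

# Index of a stage code in the ontology; error on unknown codes.
stage_index <- function(ontology, code) {
  i <- match(code, ontology$stages)
  if (anyNA(i))
    stop("unknown stage code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "))
  i
}

# Stages an individual in stage j may occupy on the next day: itself plus
# its successor(s). The last pre-adult stage branches into all terminal
# stages; terminal stages have no successor.
stage_successors <- function(ontology, code) {
  term <- ontology$terminal
  if (code %in% term) return(character(0))
  pre <- setdiff(ontology$stages, term)
  k <- match(code, pre)
  if (k < length(pre)) pre[k + 1L] else term
}
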