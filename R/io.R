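#' Read a cohort from CSV
#'
#' Two dialects are supported.
#'
#' * `durations_wide`: one row per individual with columns `id`,
#'   `treatment`, `sex` (`F`/`M`/`U`), one lowercase column per pre-adult
#'   stage (e.g. `egg`, `l1`..`l6`, `prepupa`, `pupa`) holding the days
#'   spent in that stage (including a final partial stage), then
#'   `adult_longevity`, `death_stage`, and fecundity columns
#'   `f_day1..f_dayK` giving eggs laid on each adult day (adult day 1 is
#'   the day of emergence). An empty cell means the stage was never
#'   reached; `death_stage` names the stage occupied on the last living
#'   day.
#' * `daily_long`: one row per individual-day with columns `id`,
#'   `treatment`, `age`, `stage`, `eggs`; ages start at 0 (oviposition)
#'   with no gaps, and each individual's final row has stage `DEAD` on the
#'   day it was first found dead.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect `"durations_wide"` or `"daily_long"`.
#' @param ontology A [stage_ontology()].
#' @return A validated [cohort()].
#' @seealso [write_cohort()] for the inverse; round-tripping is the
#'   identity on valid cohorts.
#' @export
read_cohort <- function(path, dialect = c("durations_wide", "daily_long"),
                        ontology = stage_ontology()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (dialect == "durations_wide") parse_durations_wide(df, ontology)
  else parse_daily_long(df, ontology)
}

preadult_stages <- function(ontology) setdiff(ontology$stages,
                                              ontology$terminal)

num_or_na <- function(x) suppressWarnings(as.numeric(x))

parse_durations_wide <- function(df, ontology) {
  pre <- preadult_stages(ontology)
  need <- c("id", "treatment", "sex", tolower(pre), "adult_longevity",
            "death_stage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("durations-wide file missing column(s): ",
         paste(miss, collapse = ", "))
  fcols <- grep("^f_day[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f_day", "", fcols)))]
  treatment <- unique(df$treatment)
  if (length(treatment) > 1L)
    stop("one cohort per file: multiple treatments found (",
         paste(treatment, collapse = ", "), ")")
  recs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    id <- row$id
    dur <- num_or_na(unlist(row[tolower(pre)]))
    filled <- !is.na(dur) & trimws(unlist(row[tolower(pre)])) != ""
    if (any(filled) && any(diff(which(filled)) != 1L) ||
        (any(filled) && which(filled)[1L] != 1L))
      stop("row '", id, "': stage order violated ",
           "(non-contiguous duration columns)")
    if (!any(filled)) stop("row '", id, "': no stage durations")
    if (any(dur[filled] < 1 | dur[filled] != floor(dur[filled])))
      stop("row '", id, "': durations must be integers >= 1")
    stages <- rep(pre[filled], dur[filled])
    death_stage <- trimws(row$death_stage)
    if (!(death_stage %in% ontology$stages))
      stop("row '", id, "': unknown stage code '", death_stage, "'")
    adult_days <- num_or_na(row$adult_longevity)
    sex <- trimws(row$sex)
    eggs <- NULL
    if (death_stage %in% ontology$terminal) {
      if (is.na(adult_days) || adult_days < 1)
        stop("row '", id, "': adult death requires adult_longevity >= 1")
      if (!all(filled))
        stop("row '", id, "': adult death with unreached pre-adult stage")
      stages <- c(stages, rep(death_stage, adult_days))
      fec <- num_or_na(unlist(row[fcols]))
      fec[is.na(fec)] <- 0
      if (any(fec > 0)) {
        if (max(which(fec > 0)) > adult_days)
          stop("row '", id, "': eggs recorded after death")
        emerg <- sum(dur[filled])
        eggs <- numeric(length(stages))
        eggs[emerg + seq_along(fec[seq_len(min(length(fec), adult_days))])] <-
          fec[seq_len(min(length(fec), adult_days))]
      }
    } else {
      if (pre[max(which(filled))] != death_stage)
        stop("row '", id, "': death_stage '", death_stage,
             "' does not match last filled stage")
    }
    recs[[i]] <- individual_record(id, stages, eggs = eggs,
                                   sex = if (sex == "") "U" else sex,
                                   ontology = ontology)
  }
  cohort(recs, treatment = if (length(treatment)) treatment else "cohort",
         ontology = ontology)
}

parse_daily_long <- function(df, ontology) {
  need <- c("id", "treatment", "age", "stage", "eggs")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("daily-long file missing column(s): ", paste(miss, collapse = ", "))
  treatment <- unique(df$treatment)
  if (length(treatment) > 1L)
    stop("one cohort per file: multiple treatments found")
  recs <- list()
  for (id in unique(df$id)) {
    sub <- df[df$id == id, , drop = FALSE]
    age <- as.integer(sub$age)
    sub <- sub[order(age), , drop = FALSE]
    age <- sort(age)
    if (!identical(age, seq(0L, length.out = length(age))))
      stop("row '", id, "': missing observation day(s); ages must be ",
           "contiguous from 0")
    if (sub$stage[length(age)] != "DEAD")
      stop("row '", id, "': trajectory must end with a DEAD row")
    if (any(sub$stage[-length(age)] == "DEAD"))
      stop("row '", id, "': DEAD before the final day")
    stages <- sub$stage[-length(age)]
    eggs <- num_or_na(sub$eggs[-length(age)])
    eggs[is.na(eggs)] <- 0
    term <- intersect(ontology$terminal, stages)
    sex <- if (length(term) == 0L) "U"
           else if (term[1L] == "FEMALE") "F" else "M"
    recs[[length(recs) + 1L]] <-
      individual_record(id, stages, eggs = eggs, sex = sex,
                        ontology = ontology)
  }
  cohort(recs, treatment = if (length(treatment)) treatment else "cohort",
         ontology = ontology)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]; `read_cohort(write_cohort(co))` reproduces
#' `co` exactly in either dialect. An empty cohort writes a header-only
#' file.
#'
#' @param co A [cohort()].
#' @param path Output file path.
#' @param dialect `"durations_wide"` or `"daily_long"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(co, path, dialect = c("durations_wide",
                                               "daily_long")) {
  dialect <- match.arg(dialect)
  df <- if (dialect == "durations_wide") format_durations_wide(co)
        else format_daily_long(co)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

format_durations_wide <- function(co) {
  pre <- preadult_stages(co$ontology)
  K <- 0L
  for (r in co$records) {
    e <- emergence_age(r, co$ontology)
    if (!is.na(e) && any(r$eggs > 0)) K <- max(K, max(which(r$eggs > 0)) - e)
  }
  rows <- lapply(co$records, function(r) {
    runs <- rle(r$stages)
    dur <- stats::setNames(rep(NA_real_, length(pre)), tolower(pre))
    for (k in seq_along(runs$values))
      if (runs$values[k] %in% pre)
        dur[tolower(runs$values[k])] <- runs$lengths[k]
    e <- emergence_age(r, co$ontology)
    adult <- if (is.na(e)) NA_real_ else r$death_age - e
    fec <- stats::setNames(rep(NA_real_, K),
                           if (K) paste0("f_day", seq_len(K)) else character(0))
    if (!is.na(e) && r$sex == "F" && K > 0) {
      fv <- r$eggs[(e + 1L):r$death_age]
      k <- min(length(fv), K)       # beyond K only zero-egg days remain
      fec[seq_len(k)] <- fv[seq_len(k)]
    }
    c(list(id = r$id, treatment = co$treatment, sex = r$sex),
      as.list(dur), list(adult_longevity = adult,
                         death_stage = r$stages[r$death_age]),
      as.list(fec))
  })
  cols <- c("id", "treatment", "sex", tolower(pre), "adult_longevity",
            "death_stage", if (K) paste0("f_day", seq_len(K)))
  if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols), check.names = FALSE)
    return(df)
  }
  do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, check.names = FALSE)))
}

format_daily_long <- function(co) {
  rows <- lapply(co$records, function(r) {
    data.frame(id = r$id, treatment = co$treatment,
               age = 0:r$death_age,
               stage = c(r$stages, "DEAD"),
               eggs = c(r$eggs, 0))
  })
  if (length(rows) == 0L)
    return(data.frame(id = character(0), treatment = character(0),
                      age = integer(0), stage = character(0),
                      eggs = numeric(0)))
  do.call(rbind, rows)
}
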