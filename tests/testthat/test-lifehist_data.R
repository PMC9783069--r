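test_that("durations-wide rows expand to daily trajectories", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,treatment,sex,egg,l1,l2,l3,l4,l5,l6,prepupa,pupa,adult_longevity,death_stage",
    "a,demo,U,3,3,1,,,,,,,,L2"), path)
  co <- read_cohort(path, "durations_wide")
  expect_equal(co$n, 1)
  expect_equal(co$records[[1]]$stages,
               c("EGG", "EGG", "EGG", "L1", "L1", "L1", "L2"))
  expect_equal(co$records[[1]]$death_age, 7)
  expect_equal(co$records[[1]]$sex, "U")
})

test_that("daily-long files parse with n and A from the data", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- c("id,treatment,age,stage,eggs")
  for (id in c("a", "b")) {
    rows <- c(rows,
              paste(id, "demo", 0:3, c("EGG", "EGG", "L1", "L1"), 0,
                    sep = ","),
              paste(id, "demo", 4, "DEAD", 0, sep = ","))
  }
  writeLines(rows, path)
  co <- read_cohort(path, "daily_long")
  expect_equal(co$n, 2)
  expect_equal(co$A, 4)   # found dead at age 4, alive through age 3
})

test_that("invalid trajectories are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  # L3 filled while L2 empty: stage order violated
  writeLines(c(
    "id,treatment,sex,egg,l1,l2,l3,l4,l5,l6,prepupa,pupa,adult_longevity,death_stage",
    "bad,demo,U,3,3,,2,,,,,,,L3"), path)
  expect_error(read_cohort(path, "durations_wide"), "stage order violated")

  # stage reversal in a daily-long trajectory
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,treatment,age,stage,eggs",
               "x,demo,0,EGG,0", "x,demo,1,L1,0", "x,demo,2,EGG,0",
               "x,demo,3,DEAD,0"), path2)
  expect_error(read_cohort(path2, "daily_long"), "order violated|transition")

  # unknown stage code
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,treatment,age,stage,eggs",
               "x,demo,0,WORM,0", "x,demo,1,DEAD,0"), path3)
  expect_error(read_cohort(path3, "daily_long"), "unknown stage code")

  # gap in observation days
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,treatment,age,stage,eggs",
               "x,demo,0,EGG,0", "x,demo,2,EGG,0", "x,demo,3,DEAD,0"),
             path4)
  expect_error(read_cohort(path4, "daily_long"), "missing observation")
})

test_that("record-level invariants are enforced", {
  expect_error(individual_record("r", c("L2", "L3", "L2"), ontology = ont),
               "order violated")
  expect_error(individual_record("r", c("EGG", "L2"), ontology = ont),
               "illegal transition")
  fem <- make_adult("r", "F")
  expect_error(individual_record("r", fem$stages, sex = "M",
                                 ontology = ont), "inconsistent")
  # eggs outside FEMALE days
  expect_error(individual_record("r", c("EGG", "EGG"), eggs = c(1, 0),
                                 sex = "U", ontology = ont),
               "non-female|FEMALE")
})

test_that("round-trip I/O is the identity in both dialects", {
  co <- simulate_cohort(slitura_config("stem", n = 40), seed = 9)
  for (dia in c("durations_wide", "daily_long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(co, path, dia)
    back <- read_cohort(path, dia)
    expect_equal(back$n, co$n)
    expect_equal(back$A, co$A)
    for (i in seq_len(co$n)) {
      expect_identical(back$records[[i]]$stages, co$records[[i]]$stages)
      expect_identical(back$records[[i]]$sex, co$records[[i]]$sex)
      expect_equal(back$records[[i]]$eggs, co$records[[i]]$eggs)
    }
  }
})

test_that("empty cohorts write a header-only file that reads back", {
  co0 <- cohort(list(), ontology = ont)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co0, path, "durations_wide")
  expect_equal(length(readLines(path)), 1L)  # header only
  expect_equal(read_cohort(path, "durations_wide")$n, 0)
})

test_that("stage durations sum to trajectory length before death", {
  co <- simulate_cohort(slitura_config("leaf", n = 60), seed = 4)
  for (r in co$records)
    expect_equal(sum(rle(r$stages)$lengths), r$death_age)
})

test_that("trait summaries match hand enumeration", {
  # two females, eggs (10,0,5) and (0,20,0) on adult days 1-3
  co <- cohort(list(
    make_adult("f1", "F", adult_days = 3, eggs_adult = c(10, 0, 5)),
    make_adult("f2", "F", adult_days = 3, eggs_adult = c(0, 20, 0))),
    ontology = ont)
  tr <- summarize_traits(co)
  get <- function(t, col = "mean") tr[tr$trait == t, col]
  expect_equal(get("oviposition_days"), 1.5)
  expect_equal(get("fecundity"), 17.5)
  # emergence at age 9 (nine 1-day pre-adult stages): f1 first egg age 9,
  # f2 first egg age 10
  expect_equal(get("APOP"), 0.5)
  expect_equal(get("TPOP"), 9.5)

  # APOP/TPOP definition: first egg at age 30, emerged at age 28
  pre_days <- c(4, 3, 3, 3, 3, 3, 3, 2, 4)  # sums to 28
  f <- make_adult("f3", "F", pre_days = pre_days, adult_days = 4,
                  eggs_adult = c(0, 0, 7, 0))
  tr3 <- summarize_traits(cohort(list(f), ontology = ont))
  expect_equal(tr3[tr3$trait == "APOP", "mean"], 2)
  expect_equal(tr3[tr3$trait == "TPOP", "mean"], 30)
})

test_that("non-qualifying individuals are excluded, not zeroed", {
  co <- cohort(list(make_preadult_death("d1", 2),  # dies as egg
                    make_adult("m1", "M")), ontology = ont)
  tr <- summarize_traits(co)
  # the egg death contributes to no duration trait: only m1 counts
  expect_equal(tr[tr$trait == "duration_EGG", "n"], 1L)
  expect_equal(tr[tr$trait == "duration_EGG", "mean"], 1)
  expect_true(is.na(tr[tr$trait == "fecundity", "mean"]))     # no females
  expect_true(is.na(tr[tr$trait == "APOP", "mean"]))
})

test_that("identical individuals give SE = 0 for every defined trait", {
  co <- identical_female_cohort(5)
  tr <- summarize_traits(co)
  def <- !is.na(tr$mean)
  expect_true(all(tr$se[def] == 0))
})
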