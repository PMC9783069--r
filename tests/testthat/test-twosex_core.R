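test_that("s_xj counts occupancy fractions and l_x sums over stages", {
  # 10 individuals all in EGG at ages 0-2
  co <- cohort(lapply(1:10, function(i) make_preadult_death(paste0("e", i),
                                                            3)),
               ontology = ont)
  sch <- compute_sxj(co)
  expect_equal(sch$sxj[2, "EGG"], 1.0)   # age 1
  expect_equal(sch$lx[2], 1.0)

  # 4 individuals, deaths first recorded at ages 2 and 5
  co2 <- cohort(list(make_preadult_death("a", 2),       # dead at age 2
                     make_preadult_death("b", c(3, 2)), # dead at age 5
                     make_preadult_death("c", c(3, 3)),
                     make_preadult_death("d", c(3, 3))),
                ontology = ont)
  sch2 <- compute_sxj(co2)
  expect_equal(sch2$lx[2], 1.0)   # age 1
  expect_equal(sch2$lx[3], 0.75)  # age 2
  expect_equal(sch2$lx[6], 0.5)   # age 5
  expect_error(compute_sxj(cohort(list(), ontology = ont)), "empty")
})

test_that("l_x = sum_j s_xj holds exactly, l_x non-increasing, l_0 = 1", {
  for (seed in 1:3) {
    co <- simulate_cohort(slitura_config("stem", n = 80), seed = seed)
    sch <- compute_sxj(co)
    expect_identical(sch$lx, unname(rowSums(sch$sxj)))
    expect_equal(sch$lx[1], 1)
    expect_true(all(diff(sch$lx) <= 1e-12))
    expect_true(all(sch$sxj >= 0 & sch$sxj <= 1))
  }
})

test_that("fecundity schedules follow the weighted-mean definition", {
  # n = 4: one female laying 20 eggs at age 10 (sole FEMALE survivor),
  # one male also alive at age 10, two early deaths
  fem <- make_adult("f", "F", adult_days = 3, eggs_adult = c(0, 20, 0))
  mal <- make_adult("m", "M", adult_days = 3)
  co <- cohort(list(fem, mal, make_preadult_death("d1", 1),
                    make_preadult_death("d2", 1)), ontology = ont)
  sch <- compute_fecundity_schedules(co, compute_sxj(co))
  # age 10: s_{10,F} = s_{10,M} = 0.25, l_10 = 0.5, f_{10,F} = 20
  expect_equal(sch$sxj[11, "FEMALE"], 0.25)
  expect_equal(sch$lx[11], 0.5)
  expect_equal(sch$fxj[11, "FEMALE"], 20)
  expect_equal(sch$mx[11], 0.25 * 20 / 0.5)  # = 10
  expect_equal(sch$lxmx[11], 5)
  # f_xj is zero off the FEMALE stage
  expect_true(all(sch$fxj[, colnames(sch$fxj) != "FEMALE"] == 0))

  # two living females at one age laying 100 and 50 -> f = 75
  co2 <- cohort(list(
    make_adult("f1", "F", adult_days = 2, eggs_adult = c(100, 0)),
    make_adult("f2", "F", adult_days = 2, eggs_adult = c(50, 0))),
    ontology = ont)
  sch2 <- compute_fecundity_schedules(co2, compute_sxj(co2))
  expect_equal(sch2$fxj[10, "FEMALE"], 75)

  # no females -> all m_x = 0
  co3 <- cohort(list(make_adult("m1", "M"), make_preadult_death("d", 2)),
                ontology = ont)
  sch3 <- compute_fecundity_schedules(co3, compute_sxj(co3))
  expect_true(all(sch3$mx == 0))
})

test_that("R0 equals the net-maternity sum and total eggs over n", {
  co <- cohort(list(
    make_adult("f1", "F", adult_days = 3, eggs_adult = c(0, 10, 0)),
    make_adult("f2", "F", adult_days = 3, eggs_adult = c(5, 0, 5)),
    make_adult("m1", "M"), make_preadult_death("d", 3)), ontology = ont)
  sch <- compute_fecundity_schedules(co, compute_sxj(co))
  expect_equal(compute_R0(sch), 20 / 4)
  expect_equal(compute_R0(sch), sum(sch$lxmx))

  # single female laying 7 eggs, n = 1
  co1 <- cohort(list(make_adult("f", "F", adult_days = 2,
                                eggs_adult = c(7, 0))), ontology = ont)
  sch1 <- compute_fecundity_schedules(co1, compute_sxj(co1))
  expect_equal(compute_R0(sch1), 7)

  # property: R0 = total eggs / n on simulated cohorts
  co4 <- simulate_cohort(slitura_config("stem", n = 120), seed = 5)
  sch4 <- compute_fecundity_schedules(co4, compute_sxj(co4))
  tot <- sum(vapply(co4$records, function(r) sum(r$eggs), numeric(1)))
  expect_equal(compute_R0(sch4), tot / co4$n, tolerance = 1e-12)
})

test_that("solve_r recovers closed-form roots of the Euler-Lotka equation", {
  expect_equal(solve_r(c(0, 1)), 0)                 # single term at x = 1
  expect_equal(solve_r(exp(1)), 1, tolerance = 1e-10)  # e at x = 0
  # two-term schedule lxmx_1 = lxmx_3 = 1: quadratic in u = e^{-2r},
  # u^2 + u = 1 -> u = (sqrt(5) - 1)/2 -> r = ln((1 + sqrt(5))/2)/2
  r <- solve_r(c(0, 1, 0, 1))
  expect_equal(r, log((1 + sqrt(5)) / 2) / 2, tolerance = 1e-10)
  # R0 = 1 returns exactly 0 without iteration
  expect_identical(solve_r(c(0.25, 0.5, 0.25)), 0)
  # R0 = 0 signals
  expect_error(solve_r(c(0, 0)), "undefined")
})

test_that("Euler-Lotka residual vanishes at the solved r on real schedules", {
  for (tissue in c("stem", "leaf")) {
    co <- simulate_cohort(slitura_config(tissue, n = 100), seed = 8)
    sch <- compute_fecundity_schedules(co, compute_sxj(co))
    r <- solve_r(sch)
    x <- sch$ages
    expect_lt(abs(sum(exp(-r * (x + 1)) * sch$lxmx) - 1), 1e-12)
    # derived identities
    expect_equal(finite_rate(r), exp(r))
    expect_equal(mean_generation_time(compute_R0(sch), r),
                 log(compute_R0(sch)) / r)
  }
})

test_that("scaling fecundity up strictly increases R0 and r", {
  co <- simulate_cohort(slitura_config("stem", n = 100), seed = 13)
  sch <- compute_fecundity_schedules(co, compute_sxj(co))
  for (c_ in c(1.5, 2, 5)) {
    expect_gt(sum(sch$lxmx * c_), compute_R0(sch))
    expect_gt(solve_r(sch$lxmx * c_), solve_r(sch$lxmx))
  }
})

test_that("single-age reproduction gives r = ln(V)/(a+1) analytically", {
  # one sex, reproduction concentrated at age a with net maternity V
  for (case in list(c(a = 4, V = 12), c(a = 9, V = 445), c(a = 2, V = 0.5))) {
    lxmx <- numeric(case["a"] + 1)
    lxmx[case["a"] + 1] <- case["V"]
    expect_equal(solve_r(lxmx), log(case["V"]) / (case["a"] + 1),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("empirical transitions reproduce observed daily fates", {
  # 10 in EGG at some age, 8 advance to L1, 2 die
  recs <- c(lapply(1:8, function(i) make_preadult_death(paste0("s", i),
                                                        c(3, 2))),
            lapply(1:2, function(i) make_preadult_death(paste0("d", i), 3)))
  co <- cohort(recs, ontology = ont)
  tr <- estimate_transitions(co)
  expect_equal(tr$trans[3, "EGG", "L1"], 0.8)   # from age 2 to age 3
  expect_equal(tr$pdie[3, "EGG"], 0.2)
  expect_equal(tr$trans[2, "EGG", "EGG"], 1.0)  # full persistence
  # terminal stage with all dying next day
  co2 <- identical_female_cohort(3, eggs_adult = c(5))
  tr2 <- estimate_transitions(co2)
  A <- co2$A
  expect_equal(tr2$pdie[A, "FEMALE"], 1)
  # probabilities per class sum to 1
  for (x in seq_len(dim(tr$trans)[1])) for (j in seq_len(ont$m)) {
    if (tr$count[x, j] > 0)
      expect_equal(sum(tr$trans[x, j, ]) + tr$pdie[x, j], 1)
  }
})

test_that("life expectancy follows the stated day-counting convention", {
  # class certain to die at the next census contributes e = 1
  co <- cohort(list(make_preadult_death("x", 1)), ontology = ont)
  e <- compute_exj(co)
  expect_equal(e[1, "EGG"], 1)

  # deterministic chain egg(3d) -> L1(2d) -> death: e at egg age 0 equals
  # the total remaining alive-days
  co2 <- cohort(list(make_preadult_death("y", c(3, 2))), ontology = ont)
  e2 <- compute_exj(co2)
  expect_equal(e2[1, "EGG"], 5)
  expect_equal(e2[4, "L1"], 2)   # two living days left at age 3

  # all-die-two-days-later: P(stay) = 1 once, then die
  co3 <- cohort(list(make_preadult_death("z", 2)), ontology = ont)
  expect_equal(compute_exj(co3)[1, "EGG"], 2)
})

test_that("e_xj and v_xj match the brute-force path-enumeration oracle", {
  # small mixed cohort: branching fates, both sexes, one reproducer
  co <- cohort(list(
    make_adult("f1", "F", pre_days = rep(1, 9), adult_days = 3,
               eggs_adult = c(0, 8, 4)),
    make_adult("m1", "M", pre_days = c(2, rep(1, 8)), adult_days = 2),
    make_preadult_death("d1", c(1, 2)),
    make_preadult_death("d2", 2),
    make_adult("f2", "F", pre_days = c(1, 2, rep(1, 7)), adult_days = 2,
               eggs_adult = c(6, 0))), ontology = ont)
  sch <- compute_fecundity_schedules(co, compute_sxj(co))
  tr <- estimate_transitions(co)
  r <- solve_r(sch)
  exj <- compute_exj(tr = tr)
  vxj <- compute_vxj(sch = sch, tr = tr, r = r)
  for (x in 0:co$A) for (j in seq_len(ont$m)) {
    if (tr$count[x + 1, j] == 0) next
    expect_equal(exj[x + 1, j], oracle_exj(tr, x, j), tolerance = 1e-9)
    expect_equal(vxj[x + 1, j], oracle_vxj(tr, sch, x, j, r),
                 tolerance = 1e-9)
  }
})

test_that("reproductive value has the correct limits", {
  # post-reproductive female: all eggs laid on adult day 1, evaluated on
  # the last adult day -> v = 0
  co <- cohort(list(make_adult("f", "F", adult_days = 3,
                               eggs_adult = c(9, 0, 0))), ontology = ont)
  sch <- compute_fecundity_schedules(co, compute_sxj(co))
  tr <- estimate_transitions(co)
  r <- solve_r(sch)
  v <- compute_vxj(sch = sch, tr = tr, r = r)
  expect_equal(v[12, "FEMALE"], 0)   # age 11: day after last egg day

  # single-future-day: female at age x, sure survival, lays F next day
  # -> v = e^{-r} F
  co2 <- cohort(list(make_adult("f", "F", adult_days = 2,
                                eggs_adult = c(0, 10))), ontology = ont)
  sch2 <- compute_fecundity_schedules(co2, compute_sxj(co2))
  tr2 <- estimate_transitions(co2)
  r2 <- solve_r(sch2)
  v2 <- compute_vxj(sch = sch2, tr = tr2, r = r2)
  expect_equal(v2[10, "FEMALE"], exp(-r2) * 10, tolerance = 1e-9)

  # r = 0 with deterministic survival: v equals total future fecundity
  v0 <- compute_vxj(sch = sch2, tr = tr2, r = 0)
  expect_equal(v0[10, "FEMALE"], 10)
  expect_equal(v0[1, "EGG"], 10)
})

test_that("life_table assembles schedules, e_xj, v_xj and parameters", {
  co <- simulate_cohort(slitura_config("stem", n = 60), seed = 21)
  lt <- life_table(co)
  expect_s3_class(lt, "life_table")
  expect_equal(lt$params$lambda, exp(lt$params$r))
  expect_equal(lt$params$T, log(lt$params$R0) / lt$params$r)
  # tidy export carries all columns and reproduces l_x
  tabs <- schedules_tables(lt$schedules)
  expect_true(all(c("s_xj", "f_xj", "e_xj", "v_xj") %in%
                    names(tabs$age_stage)))
  lx <- tapply(tabs$age_stage$s_xj, tabs$age_stage$age, sum)
  expect_equal(as.numeric(lx[as.character(tabs$age$age)]), tabs$age$l_x)
  # e_xj nonnegative wherever defined
  expect_true(all(lt$schedules$exj >= 0, na.rm = TRUE))
})
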