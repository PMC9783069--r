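# Shared builders for hand-constructed cohorts.

ont <- stage_ontology()

# A record that walks the full pre-adult chain with the given days per
# stage, then an adult phase; eggs_adult gives eggs per adult day.
make_adult <- function(id, sex, pre_days = rep(1, 9), adult_days = 3,
                       eggs_adult = NULL) {
  pre <- c("EGG", "L1", "L2", "L3", "L4", "L5", "L6", "PREPUPA", "PUPA")
  stages <- c(rep(pre, times = pre_days),
              rep(if (sex == "F") "FEMALE" else "MALE", adult_days))
  eggs <- NULL
  if (!is.null(eggs_adult)) {
    eggs <- numeric(length(stages))
    eggs[sum(pre_days) + seq_along(eggs_adult)] <- eggs_adult
  }
  individual_record(id, stages, eggs = eggs, sex = sex, ontology = ont)
}

# A record dying in a pre-adult stage: days per reached stage, last entry
# is the partial stay in the death stage.
make_preadult_death <- function(id, days) {
  pre <- c("EGG", "L1", "L2", "L3", "L4", "L5", "L6", "PREPUPA", "PUPA")
  stages <- rep(pre[seq_along(days)], times = days)
  individual_record(id, stages, sex = "U", ontology = ont)
}

# Choice-assay table with one arena row per replicate.
make_choice <- function(stem, leaf, instar = 1, time_h = 0.5, n = 10) {
  data.frame(instar = instar, time_h = time_h,
             replicate = seq_along(stem),
             stem_count = stem, leaf_count = leaf, n = n)
}

# Cohort of k byte-identical reproducing females (plus nothing else).
identical_female_cohort <- function(k = 4, eggs_adult = c(0, 10, 5)) {
  cohort(lapply(seq_len(k), function(i)
    make_adult(paste0("f", i), "F", adult_days = length(eggs_adult),
               eggs_adult = eggs_adult)), ontology = ont)
}
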