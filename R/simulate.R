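#' Configuration for the individual-based cohort simulator
#'
#' Describes the stochastic life history the simulator draws from: integer
#' stage durations (discretized gamma or fixed), a daily mortality hazard
#' per pre-adult stage, the female fraction among emerging adults, adult
#' longevity by sex, and a female fecundity model (adult preoviposition
#' period, number of consecutive oviposition days, lifetime egg total, and
#' a rise-then-fall lognormal daily allocation).
#'
#' Durations are drawn as gamma variates (mean `mean`, shape `shape`) and
#' discretized by mean-preserving stochastic rounding (floor plus a
#' Bernoulli on the fractional part), floored at 1 day; `shape = Inf`
#' gives a fixed duration of `round(mean)` days. APOP and oviposition-day
#' counts are `1 + Poisson(mean - 1)`. A female's longevity draw is raised
#' to APOP + oviposition days when shorter so the laying window fits.
#'
#' @param n Initial number of eggs (cohort size).
#' @param seed Default seed used by [simulate_cohort()].
#' @param stages Named list, one entry per pre-adult stage in ontology
#'   order: `list(mean =, shape =, hazard =)` with `hazard` the daily
#'   probability of dying in that stage.
#' @param female_fraction Probability an emerging adult is female.
#' @param longevity_f,longevity_m Adult longevity distributions
#'   (`list(mean =, shape =)`), in days from emergence.
#' @param apop_mean Mean adult preoviposition period (days, >= 1).
#' @param ovidays_mean Mean number of oviposition days (>= 1).
#' @param fecundity Lifetime eggs per female: `list(mean =, shape =)`.
#' @param allocation_sdlog Spread of the lognormal daily egg pulse.
#' @param ontology A [stage_ontology()] whose pre-adult stages match
#'   `names(stages)`.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n = 100, seed = 1)
#' co <- simulate_cohort(cfg)
#' co
#' @export
sim_config <- function(n = 100, seed = 1,
                       stages = NULL,
                       female_fraction = 0.5,
                       longevity_f = list(mean = 10, shape = 12),
                       longevity_m = list(mean = 10, shape = 12),
                       apop_mean = 2.5,
                       ovidays_mean = 3.5,
                       fecundity = list(mean = 1200, shape = 1.8),
                       allocation_sdlog = 0.8,
                       ontology = stage_ontology()) {
  pre <- preadult_stages(ontology)
  if (is.null(stages))
    stages <- stats::setNames(lapply(pre, function(s)
      list(mean = 3, shape = 25, hazard = 0.01)), pre)
  if (!identical(names(stages), pre))
    stop("'stages' must have one entry per pre-adult stage, in order: ",
         paste(pre, collapse = ", "))
  if (n < 1 || n != floor(n)) stop("invalid 'n': need integer >= 1")
  for (s in names(stages)) {
    st <- stages[[s]]
    if (!is.numeric(st$mean) || st$mean < 1)
      stop("invalid stage '", s, "': duration mean must be >= 1 day")
    if (!is.numeric(st$shape) || st$shape <= 0)
      stop("invalid stage '", s, "': shape must be positive")
    if (!is.numeric(st$hazard) || st$hazard < 0 || st$hazard > 1)
      stop("invalid stage '", s, "': hazard must be in [0, 1]")
  }
  if (female_fraction < 0 || female_fraction > 1)
    stop("invalid 'female_fraction': must be in [0, 1]")
  if (apop_mean < 1) stop("invalid 'apop_mean': must be >= 1")
  if (ovidays_mean < 1) stop("invalid 'ovidays_mean': must be >= 1")
  if (fecundity$mean < 0) stop("invalid 'fecundity': mean must be >= 0")
  structure(list(n = as.integer(n), seed = seed, stages = stages,
                 female_fraction = female_fraction,
                 longevity_f = longevity_f, longevity_m = longevity_m,
                 apop_mean = apop_mean, ovidays_mean = ovidays_mean,
                 fecundity = fecundity,
                 allocation_sdlog = allocation_sdlog,
                 ontology = ontology),
            class = "sim_config")
}

# Mean-preserving integer draw: gamma(mean, shape) stochastically rounded,
# floored at 1 day. shape = Inf -> fixed round(mean).
draw_duration <- function(k, mean, shape) {
  if (is.infinite(shape)) return(rep(round(mean), k))
  g <- stats::rgamma(k, shape = shape, rate = shape / mean)
  pmax(1, floor(g) + stats::rbinom(k, 1, g - floor(g)))
}

# Allocate `total` eggs over k consecutive days with a lognormal
# rise-then-fall pulse; largest-remainder rounding preserves the total,
# and every oviposition day keeps >= 1 egg when total >= k.
allocate_eggs <- function(total, k, sdlog) {
  if (k == 1) return(total)
  w <- stats::dlnorm(seq_len(k), meanlog = log(max(1, k / 3)), sdlog = sdlog)
  w <- w / sum(w)
  raw <- w * total
  alloc <- floor(raw)
  rem <- total - sum(alloc)
  if (rem > 0) {
    ord <- order(raw - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  if (total >= k && any(alloc == 0)) {
    for (i in which(alloc == 0)) {
      j <- which.max(alloc)
      alloc[j] <- alloc[j] - 1
      alloc[i] <- alloc[i] + 1
    }
  }
  alloc
}

#' Simulate a synchronized cohort of individual life histories
#'
#' Draws `n` independent individuals under a [sim_config()]: stage
#' durations, daily within-stage mortality, sex assigned at adult
#' emergence, and for females an adult preoviposition period, a block of
#' consecutive oviposition days and a lifetime egg total spread over them.
#' Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A [cohort()] with treatment label `"sim"`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  set.seed(if (is.null(seed)) config$seed else seed)
  ont <- config$ontology
  pre <- preadult_stages(ont)
  recs <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    stages <- character(0)
    alive <- TRUE
    for (s in pre) {
      st <- config$stages[[s]]
      d <- draw_duration(1, st$mean, st$shape)
      if (st$hazard > 0) {
        # day of death within the stage, if any
        u <- stats::rbinom(d, 1, st$hazard)
        k <- which(u == 1)
        if (length(k)) {
          stages <- c(stages, rep(s, k[1]))
          alive <- FALSE
          break
        }
      }
      stages <- c(stages, rep(s, d))
    }
    if (!alive) {
      recs[[i]] <- individual_record(paste0("sim", i), stages, sex = "U",
                                     ontology = ont)
      next
    }
    female <- stats::runif(1) < config$female_fraction
    if (female) {
      L <- draw_duration(1, config$longevity_f$mean, config$longevity_f$shape)
      a <- 1 + stats::rpois(1, config$apop_mean - 1)
      k <- 1 + stats::rpois(1, config$ovidays_mean - 1)
      tot <- if (config$fecundity$mean > 0)
        draw_duration(1, config$fecundity$mean, config$fecundity$shape)
      else 0
      L <- max(L, a + k)
      eggs_adult <- numeric(L)
      if (tot > 0)
        eggs_adult[a + seq_len(k)] <- allocate_eggs(tot, k,
                                                    config$allocation_sdlog)
      stages <- c(stages, rep("FEMALE", L))
      eggs <- c(numeric(length(stages) - L), eggs_adult)
      recs[[i]] <- individual_record(paste0("sim", i), stages, eggs = eggs,
                                     sex = "F", ontology = ont)
    } else {
      L <- draw_duration(1, config$longevity_m$mean, config$longevity_m$shape)
      stages <- c(stages, rep("MALE", L))
      recs[[i]] <- individual_record(paste0("sim", i), stages, sex = "M",
                                     ontology = ont)
    }
  }
  cohort(recs, treatment = "sim", ontology = ont)
}

#' Simulator configurations emulating S. litura on asparagus
#'
#' Returns a [sim_config()] whose expected trait means match a
#' Spodoptera litura cohort reared on asparagus stems or leaves: stage
#' duration means (egg through pupa), adult longevity, adult
#' preoviposition period, oviposition days and lifetime fecundity per
#' female. Duration shape parameters are set so the individual-level SD
#' matches the reported cohort standard errors at a cohort of about 100
#' eggs; pre-adult daily hazards are uniform across stages and calibrated
#' so that preadult survival times the female fraction reproduces the
#' tissue's net reproductive rate given its mean fecundity.
#'
#' @param tissue `"stem"` or `"leaf"`.
#' @param n Cohort size (default 100 eggs, the classic design).
#' @param seed Default seed stored in the config.
#' @return A [sim_config()].
#' @examples
#' co <- simulate_cohort(slitura_config("stem"), seed = 11)
#' summarize_traits(co)[c(9, 12:17), ]
#' @export
slitura_config <- function(tissue = c("stem", "leaf"), n = 100, seed = 1) {
  tissue <- match.arg(tissue)
  tab <- list(
    stem = list(dur = c(EGG = 3.36, L1 = 3.23, L2 = 2.39, L3 = 2.30,
                        L4 = 2.18, L5 = 2.41, L6 = 2.72, PREPUPA = 1.97,
                        PUPA = 9.42),
                se = c(EGG = 0.07, L1 = 0.07, L2 = 0.05, L3 = 0.07,
                       L4 = 0.08, L5 = 0.09, L6 = 0.10, PREPUPA = 0.08,
                       PUPA = 0.14),
                fec = 1237.92, R0 = 445.65, apop = 2.52, ovidays = 3.65,
                lf = 9.69, lm = 9.66, preadult = 29.88),
    leaf = list(dur = c(EGG = 3.46, L1 = 3.65, L2 = 3.52, L3 = 3.17,
                        L4 = 3.00, L5 = 2.85, L6 = 3.23, PREPUPA = 2.21,
                        PUPA = 10.11),
                se = c(EGG = 0.08, L1 = 0.08, L2 = 0.09, L3 = 0.08,
                       L4 = 0.11, L5 = 0.08, L6 = 0.08, PREPUPA = 0.13,
                       PUPA = 0.19),
                fec = 1168.94, R0 = 385.75, apop = 2.56, ovidays = 3.20,
                lf = 8.52, lm = 9.47, preadult = 35.04))[[tissue]]
  female_fraction <- 0.5
  # survival egg -> female = R0 / mean fecundity; spread as a uniform
  # daily hazard over the mean preadult duration
  surv <- tab$R0 / tab$fec / female_fraction
  hazard <- 1 - surv^(1 / tab$preadult)
  sd_i <- pmax(tab$se * 10, 0.35)          # individual SD from SE at n ~ 100
  stages <- stats::setNames(lapply(names(tab$dur), function(s)
    list(mean = unname(tab$dur[s]),
         shape = unname((tab$dur[s] / sd_i[s])^2),
         hazard = hazard)), names(tab$dur))
  sim_config(n = n, seed = seed, stages = stages,
             female_fraction = female_fraction,
             longevity_f = list(mean = tab$lf, shape = (tab$lf / 2.8)^2),
             longevity_m = list(mean = tab$lm, shape = (tab$lm / 2.8)^2),
             apop_mean = tab$apop, ovidays_mean = tab$ovidays,
             fecundity = list(mean = tab$fec, shape = 1.8))
}
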