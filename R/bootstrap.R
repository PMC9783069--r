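# Internal: compact numeric view of a cohort for fast resampling.
# t_eggs_age: (A+1) x n matrix of daily eggs; total_eggs, is_female: per
# record. Resampling an individual resamples its whole record, preserving
# within-individual correlation between survival and fecundity.
boot_prep <- function(co) {
  M <- cohort_matrices(co)
  list(t_eggs = t(M$eggs), total_eggs = M$total_eggs,
       is_female = M$sex == "F", n = co$n)
}

# One replicate: parameter vector from a resample index count vector w.
boot_stats <- function(prep, w, params) {
  n <- prep$n
  out <- stats::setNames(rep(NA_real_, length(params)), params)
  lxmx <- as.vector(prep$t_eggs %*% w) / n
  R0 <- sum(lxmx)
  if ("R0" %in% params) out["R0"] <- R0
  if (any(c("r", "lambda", "T") %in% params) && R0 > 0) {
    r <- solve_r_lxmx(lxmx)
    if ("r" %in% params) out["r"] <- r
    if ("lambda" %in% params) out["lambda"] <- exp(r)
    if ("T" %in% params && r != 0) out["T"] <- log(R0) / r
  }
  if ("fecundity" %in% params) {
    nf <- sum(w[prep$is_female])
    if (nf > 0)
      out["fecundity"] <- sum(w * prep$total_eggs * prep$is_female) / nf
  }
  out
}

boot_point <- function(prep, params)
  boot_stats(prep, rep(1, prep$n), params)

# Deterministic replicate-level substreams: a master seed yields one
# sub-seed per replicate, so replicate b is reproducible independently of
# execution order.
boot_subseeds <- function(seed, B, stream = 0L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + stream)
  sample.int(.Machine$integer.max - 1L, B)
}

#' Bootstrap standard errors for population parameters and fecundity
#'
#' Resamples whole individual records with replacement (`n` draws per
#' replicate), recomputes the net-maternity schedule and the parameters
#' R0, r, lambda, T and mean lifetime fecundity per female for each
#' replicate, and reports the sample SD over replicates as the bootstrap
#' SE. Replicates whose resample contains no reproduction (R0 = 0) leave
#' r, lambda and T undefined; they are excluded from those SEs (not
#' redrawn) and counted in `n_degenerate`.
#'
#' @param co A [cohort()].
#' @param B Number of bootstrap replicates (the study design uses 1e5;
#'   tests and examples use far fewer).
#' @param seed Integer seed; identical seed and inputs give identical
#'   results.
#' @param params Which parameters to bootstrap.
#' @return An object of class `bootstrap_result`: list with `estimate`
#'   (point estimates from the full cohort), `se`, `samples` (B x
#'   parameter matrix, `NA` where undefined), `B`, `seed`,
#'   `n_degenerate`.
#' @examples
#' co <- simulate_cohort(sim_config(n = 60, seed = 3))
#' bootstrap_params(co, B = 200, seed = 1)
#' @export
bootstrap_params <- function(co, B = 1e5, seed = 1,
                             params = c("R0", "r", "lambda", "T",
                                        "fecundity")) {
  stopifnot(B >= 1)
  params <- match.arg(params, several.ok = TRUE)
  prep <- boot_prep(co)
  sub <- boot_subseeds(seed, B)
  samples <- matrix(NA_real_, B, length(params),
                    dimnames = list(NULL, params))
  for (b in seq_len(B)) {
    set.seed(sub[b])
    w <- tabulate(sample.int(prep$n, prep$n, replace = TRUE), prep$n)
    samples[b, ] <- boot_stats(prep, w, params)
  }
  R0col <- if ("R0" %in% params) samples[, "R0"] else NULL
  ndeg <- if (!is.null(R0col)) sum(R0col == 0)
          else sum(is.na(samples[, 1]))
  se <- apply(samples, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2) stats::sd(x) else 0
  })
  structure(list(estimate = boot_point(prep, params), se = se,
                 samples = samples, B = B, seed = seed,
                 n_degenerate = ndeg),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> B =", x$B, " degenerate =", x$n_degenerate, "\n")
  print(data.frame(estimate = x$estimate, se = x$se))
  invisible(x)
}

#' Paired bootstrap test between two cohorts
#'
#' Draws B replicate pairs (one independent resample of each cohort),
#' forms the per-parameter difference A - B, and reports a two-sided
#' p-value as the doubled smaller tail proportion of the difference
#' distribution around zero, with a +1/(B+1) continuity guard so p is
#' never exactly 0. Pairs in which a parameter is undefined on either
#' side are excluded for that parameter. Significance letters follow the
#' usual life-table table style: cohorts share "a" when not significant
#' at `alpha`, otherwise the larger estimate gets "a" and the smaller
#' "b".
#'
#' @param coA,coB Two [cohort()]s built on the same stage ontology.
#' @param B Number of replicate pairs.
#' @param seed Integer seed.
#' @param params Which parameters to compare.
#' @param alpha Significance level for the flag and letters.
#' @return An object of class `paired_test_result`: data.frame-like list
#'   with per-parameter difference, SE of the difference, p-value,
#'   significance flag and letters.
#' @export
paired_bootstrap_test <- function(coA, coB, B = 1e5, seed = 1,
                                  params = c("R0", "r", "lambda", "T",
                                             "fecundity"),
                                  alpha = 0.05) {
  stopifnot(B >= 1)
  if (!identical(coA$ontology$stages, coB$ontology$stages))
    stop("cohorts must share the same stage ontology")
  params <- match.arg(params, several.ok = TRUE)
  prepA <- boot_prep(coA)
  prepB <- boot_prep(coB)
  subA <- boot_subseeds(seed, B, stream = 0L)
  subB <- boot_subseeds(seed, B, stream = 1L)
  dmat <- matrix(NA_real_, B, length(params),
                 dimnames = list(NULL, params))
  for (b in seq_len(B)) {
    set.seed(subA[b])
    wA <- tabulate(sample.int(prepA$n, prepA$n, replace = TRUE), prepA$n)
    set.seed(subB[b])
    wB <- tabulate(sample.int(prepB$n, prepB$n, replace = TRUE), prepB$n)
    dmat[b, ] <- boot_stats(prepA, wA, params) -
      boot_stats(prepB, wB, params)
  }
  pa <- boot_point(prepA, params)
  pb <- boot_point(prepB, params)
  res <- lapply(params, function(p) {
    d <- dmat[, p]
    d <- d[!is.na(d)]
    Beff <- length(d)
    if (Beff == 0)
      return(data.frame(parameter = p, estimate_A = pa[p],
                        estimate_B = pb[p], difference = pa[p] - pb[p],
                        se_diff = NA_real_, p_value = NA_real_,
                        significant = NA))
    pv <- min(1, 2 * min((sum(d <= 0) + 1) / (Beff + 1),
                         (sum(d >= 0) + 1) / (Beff + 1)))
    data.frame(parameter = p, estimate_A = pa[p], estimate_B = pb[p],
               difference = pa[p] - pb[p],
               se_diff = if (Beff >= 2) stats::sd(d) else 0,
               p_value = pv, significant = pv < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$letter_A <- ifelse(!out$significant | is.na(out$significant), "a",
                         ifelse(out$estimate_A >= out$estimate_B, "a", "b"))
  out$letter_B <- ifelse(!out$significant | is.na(out$significant), "a",
                         ifelse(out$estimate_B > out$estimate_A, "a", "b"))
  class(out) <- c("paired_test_result", "data.frame")
  out
}

#' Treatment comparison table
#'
#' Assembles the familiar population-parameter comparison table (one row
#' per parameter, estimate +/- bootstrap SE per treatment, paired
#' bootstrap p-value and letters), ready to write with
#' [utils::write.csv()].
#'
#' @inheritParams paired_bootstrap_test
#' @return A data.frame with columns parameter, `estimate_A`, `se_A`,
#'   `estimate_B`, `se_B`, `p_value`, `letter_A`, `letter_B`.
#' @export
compare_params <- function(coA, coB, B = 1e5, seed = 1,
                           params = c("R0", "r", "lambda", "T",
                                      "fecundity"),
                           alpha = 0.05) {
  params <- match.arg(params, several.ok = TRUE)
  bA <- bootstrap_params(coA, B, seed, params)
  bB <- bootstrap_params(coB, B, seed + 1L, params)
  tst <- paired_bootstrap_test(coA, coB, B, seed + 2L, params, alpha)
  data.frame(parameter = tst$parameter,
             estimate_A = tst$estimate_A, se_A = bA$se[tst$parameter],
             estimate_B = tst$estimate_B, se_B = bB$se[tst$parameter],
             p_value = tst$p_value,
             letter_A = tst$letter_A, letter_B = tst$letter_B,
             row.names = NULL)
}
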