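#' Two-choice feeding-preference counts
#'
#' Validates a table of arena counts from a stem-versus-leaf choice assay:
#' for each larval instar, observation time and replicate arena, the
#' number of larvae sitting on each tissue out of `n` larvae released.
#' Larvae on neither tissue (undecided) are allowed; the two counts may
#' sum to less than `n` but never more.
#'
#' @param data A data.frame with columns `instar`, `time_h`, `replicate`,
#'   `stem_count`, `leaf_count`, and optionally `n` (larvae per arena,
#'   default 10).
#' @return The validated data.frame with class `choice_data`.
#' @export
choice_data <- function(data) {
  need <- c("instar", "time_h", "replicate", "stem_count", "leaf_count")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("choice data missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(data$n)) data$n <- 10L
  bad <- data$stem_count < 0 | data$leaf_count < 0
  if (any(bad)) stop("negative counts in row(s): ",
                     paste(which(bad), collapse = ", "))
  over <- data$stem_count + data$leaf_count > data$n
  if (any(over))
    stop("counts exceed larvae per arena in row(s): ",
         paste(which(over), collapse = ", "))
  class(data) <- c("choice_data", "data.frame")
  data
}

#' Arcsine-square-root transform of choice proportions
#'
#' Reshapes the counts to long form (one row per arena x tissue) and adds
#' the proportion `p = count / n` and its variance-stabilizing transform
#' `y = asin(sqrt(p))`; p = 0 and p = 1 map to 0 and pi/2 with no
#' correction. The transform is monotone, so higher counts never get
#' lower transformed values.
#'
#' @param data A [choice_data()] table (a plain data.frame is validated
#'   first).
#' @return A data.frame with columns `instar`, `time_h`, `replicate`,
#'   `tissue`, `count`, `n`, `p`, `y`.
#' @examples
#' d <- expand.grid(instar = 1, time_h = 0.5, replicate = 1:3)
#' d$stem_count <- c(5, 0, 10); d$leaf_count <- c(5, 10, 0)
#' transform_proportions(d)$y   # pi/4, 0, pi/2 for the stem side
#' @export
transform_proportions <- function(data) {
  if (!inherits(data, "choice_data")) data <- choice_data(data)
  long <- rbind(
    data.frame(instar = data$instar, time_h = data$time_h,
               replicate = data$replicate, tissue = "stem",
               count = data$stem_count, n = data$n),
    data.frame(instar = data$instar, time_h = data$time_h,
               replicate = data$replicate, tissue = "leaf",
               count = data$leaf_count, n = data$n))
  long$p <- long$count / long$n
  long$y <- asin(sqrt(long$p))
  long
}

# Maximal cliques of an undirected graph given as a logical adjacency
# matrix (diagonal TRUE), by Bron-Kerbosch; group counts here are tiny.
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      cliques[[length(cliques) + 1L]] <<- R
      return()
    }
    for (v in P) {
      nb <- setdiff(which(adj[v, ]), v)
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

# Compact letter display from a pairwise non-significance matrix:
# assign one letter per maximal clique of mutually non-significant
# groups, lettering cliques in order of their best (highest) group mean.
letters_from_nonsig <- function(nonsig, means, upper = FALSE) {
  cl <- maximal_cliques(nonsig)
  cl <- cl[order(-vapply(cl, function(ix) max(means[ix]), numeric(1)))]
  alphabet <- if (upper) LETTERS else letters
  lab <- rep("", length(means))
  for (k in seq_along(cl))
    lab[cl[[k]]] <- paste0(lab[cl[[k]]], alphabet[k])
  ord <- order(-means)
  vapply(seq_along(lab), function(i)
    paste(sort(strsplit(lab[i], "")[[1]]), collapse = ""), character(1))
}

# One-way ANOVA with Tukey HSD on a transformed response; returns F, p,
# group means/SEs (on the proportion scale) and letters. Handles the
# degenerate zero-residual-variance case explicitly.
anova_letters <- function(y, group, p_disp, upper = FALSE, alpha = 0.05) {
  group <- factor(group)
  lv <- levels(group)
  means_y <- tapply(y, group, mean)
  mean_p <- tapply(p_disp, group, mean)
  se_p <- tapply(p_disp, group, function(z)
    if (length(z) >= 2) stats::sd(z) / sqrt(length(z)) else 0)
  ssw <- sum(tapply(y, group, function(z) sum((z - mean(z))^2)))
  ssb <- sum(tapply(y, group, length) * (means_y - mean(y))^2)
  if (ssw <= 1e-24 * max(1, ssb)) {
    # no within-group variance: groups differ exactly when means differ
    if (ssb <= 1e-24) {
      Fv <- 0; pv <- 1
      nonsig <- matrix(TRUE, length(lv), length(lv))
    } else {
      Fv <- Inf; pv <- .Machine$double.xmin
      nonsig <- outer(means_y, means_y,
                      function(a, b) abs(a - b) < 1e-12)
    }
  } else {
    fit <- stats::aov(y ~ group)
    an <- summary(fit)[[1]]
    Fv <- an[1, "F value"]
    pv <- an[1, "Pr(>F)"]
    tk <- stats::TukeyHSD(fit)$group
    nonsig <- matrix(TRUE, length(lv), length(lv),
                     dimnames = list(lv, lv))
    for (k in seq_len(nrow(tk))) {
      ab <- strsplit(rownames(tk)[k], "-", fixed = TRUE)[[1]]
      ns <- tk[k, "p adj"] >= alpha
      nonsig[ab[1], ab[2]] <- nonsig[ab[2], ab[1]] <- ns
    }
  }
  diag(nonsig) <- TRUE
  data.frame(group = lv, mean = as.vector(mean_p), se = as.vector(se_p),
             F = Fv, p = pv,
             letter = letters_from_nonsig(nonsig, as.vector(means_y),
                                          upper = upper))
}

#' ANOVA with Tukey HSD and compact letter display for choice assays
#'
#' Runs, separately at each observation time, a one-way ANOVA on the
#' arcsine-square-root transformed proportions followed by Tukey's HSD,
#' and summarizes the pairwise comparisons as a compact letter display
#' (groups sharing a letter are not significantly different at `alpha`).
#' Two groupings mirror the two conventions of preference figures:
#'
#' * `"tissue"`: compare stem vs leaf within each instar x time cell
#'   (lowercase letters);
#' * `"instar"`: compare instars within each tissue x time cell
#'   (uppercase letters).
#'
#' When every group has zero within-replicate variance but the means
#' differ, the p-value is reported at the machine floor and letters are
#' still assigned from exact mean comparisons.
#'
#' @param transformed Output of [transform_proportions()].
#' @param grouping `"tissue"` or `"instar"`.
#' @param alpha Significance level.
#' @return A data.frame with one row per group within each comparison
#'   cell: the cell identifiers, group mean and SE of the raw proportion,
#'   the cell's F and p, and the letter.
#' @examples
#' d <- expand.grid(instar = 1:2, time_h = 0.5, replicate = 1:5)
#' set.seed(1)
#' d$stem_count <- rbinom(nrow(d), 10, 0.7)
#' d$leaf_count <- 10 - d$stem_count - rbinom(nrow(d), 1, 0.3)
#' anova_tukey(transform_proportions(d), "tissue")
#' @export
anova_tukey <- function(transformed, grouping = c("tissue", "instar"),
                        alpha = 0.05) {
  grouping <- match.arg(grouping)
  if (grouping == "tissue") {
    cells <- unique(transformed[c("instar", "time_h")])
    out <- lapply(seq_len(nrow(cells)), function(k) {
      sub <- transformed[transformed$instar == cells$instar[k] &
                           transformed$time_h == cells$time_h[k], ]
      if (length(unique(sub$tissue)) < 2 ||
          min(table(sub$tissue)) < 2)
        stop("need >= 2 groups with >= 2 replicates in each cell")
      cbind(instar = cells$instar[k], time_h = cells$time_h[k],
            anova_letters(sub$y, sub$tissue, sub$p, upper = FALSE,
                          alpha = alpha))
    })
  } else {
    cells <- unique(transformed[c("tissue", "time_h")])
    out <- lapply(seq_len(nrow(cells)), function(k) {
      sub <- transformed[transformed$tissue == cells$tissue[k] &
                           transformed$time_h == cells$time_h[k], ]
      if (length(unique(sub$instar)) < 2 ||
          min(table(sub$instar)) < 2)
        stop("need >= 2 groups with >= 2 replicates in each cell")
      cbind(tissue = cells$tissue[k], time_h = cells$time_h[k],
            anova_letters(sub$y, sub$instar, sub$p, upper = TRUE,
                          alpha = alpha))
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
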