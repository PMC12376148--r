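# Individual-level bootstrap for life-history and demographic statistics,
# paired-bootstrap treatment comparisons, and compact letter displays.
#
# The resampling unit is the whole individual record (with its daily
# fecundity), never single days: the life table is a function of
# individuals.  Each replicate redraws n0 records with replacement and
# recomputes every statistic.

# Euler-Lotka solve vectorised over replicates.  phi is a B x (X+1) matrix
# of lx*mx rows; returns r per row (NA where sum(phi) <= 0).  The renewal
# function g(r) = sum exp(-r(x+1)) phi_x - 1 is convex and strictly
# decreasing wherever any phi > 0, so Newton from r = 0 converges globally
# and monotonically after at most one overshoot.
solve_rate_many <- function(phi) {
  R0 <- rowSums(phi)
  r <- rep(NA_real_, nrow(phi))
  act <- which(R0 > 0)
  if (length(act) == 0) return(r)
  P <- phi[act, , drop = FALSE]
  xp1 <- seq_len(ncol(P))
  rv <- numeric(length(act))
  floor_r <- -700 / max(xp1)  # keep exp(-r(x+1)) finite
  for (it in 1:60) {
    W <- exp(-outer(rv, xp1)) * P
    gv <- rowSums(W) - 1
    dg <- -as.vector(W %*% xp1)
    step <- gv / dg
    rv <- pmax(rv - step, floor_r)
    if (max(abs(step)) < 1e-13) break
  }
  r[act] <- rv
  r
}

#' Bootstrap standard errors and confidence intervals for one cohort
#'
#' Resamples the `n0` individual records with replacement `B` times and
#' recomputes every life-history statistic (see [life_history_summary()])
#' and demographic parameter (see [demographic_parameters()]) on each
#' replicate.  Replicates on which a statistic is undefined (for example no
#' reproducing female, so r, lambda and T do not exist) are recorded as
#' `NA`, excluded from the SE and percentile CI, and counted in
#' `n_degenerate`; a warning is logged when more than 1\% of replicates are
#' degenerate for a parameter.  A fixed seed gives bit-identical output.
#'
#' @param cohort A validated `"cohort"`.
#' @param B Number of bootstrap resamples (>= 2).  The study-scale default
#'   is 100,000; use a smaller B for interactive work.
#' @param seed Integer seed for the resampling RNG; recorded in the result.
#' @param tpop_origin,oviposition Passed to the summary statistics; see
#'   [life_history_summary()].
#' @return Object of class `"bootstrap_set"`: named list of
#'   `"bootstrap_dist"` objects (one per parameter), each with elements
#'   `parameter`, `B`, `values` (length B, `NA` = undefined replicate),
#'   `estimate` (point estimate from the original cohort), `se`, `ci`
#'   (2.5\% and 97.5\% percentiles), `n_degenerate` and `seed`.
#' @export
bootstrap_estimates <- function(cohort, B = 100000L, seed = 1L,
                                tpop_origin = c("egg", "hatching"),
                                oviposition = c("span", "days")) {
  if (B < 2) stop("B must be at least 2")
  tpop_origin <- match.arg(tpop_origin)
  oviposition <- match.arg(oviposition)
  arr <- cohort_arrays(cohort, tpop_origin, oviposition)
  n <- arr$n

  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  counts <- matrix(0, B, n)
  for (b in seq_len(B)) counts[b, ] <- tabulate(idx[b, ], nbins = n)

  ns <- counts %*% arr$defined
  sums <- counts %*% (arr$stats * arr$defined)
  means <- sums / ns
  means[ns == 0] <- NA_real_

  eggs_x <- counts %*% arr$eggs
  alive_x <- counts %*% arr$alive
  phi <- eggs_x / n
  R0 <- rowSums(phi)
  mx <- eggs_x / alive_x
  mx[alive_x == 0] <- 0
  GRR <- rowSums(mx)
  r <- solve_rate_many(phi)
  lambda <- exp(r)
  T_gen <- ifelse(!is.na(r) & r != 0, log(R0) / r, NA_real_)

  values <- cbind(means, GRR = GRR, R0 = R0, r = r, lambda = lambda,
                  T = T_gen)

  summ <- life_history_summary(cohort, tpop_origin, oviposition)
  point <- stats::setNames(summ$mean, summ$statistic)
  dp <- demographic_parameters(cohort)
  point <- c(point, GRR = dp$GRR, R0 = dp$R0, r = dp$r, lambda = dp$lambda,
             T = dp$T)

  dists <- lapply(colnames(values), function(p) {
    v <- values[, p]
    n_deg <- sum(is.na(v))
    ok <- v[!is.na(v)]
    structure(list(
      parameter = p,
      B = B,
      values = v,
      estimate = unname(point[p]),
      se = if (length(ok) > 1) stats::sd(ok) else NA_real_,
      ci = if (length(ok) > 0) {
        unname(stats::quantile(ok, c(0.025, 0.975)))
      } else c(NA_real_, NA_real_),
      n_degenerate = n_deg,
      seed = as.integer(seed),
      treatment = cohort$treatment
    ), class = "bootstrap_dist")
  })
  names(dists) <- colnames(values)

  deg <- vapply(dists, function(d) d$n_degenerate, numeric(1))
  high <- deg[deg / B > 0.01 & names(deg) %in% DEMOGRAPHIC_STATS]
  if (length(high) > 0) {
    warning(sprintf(
      "treatment '%s': >1%% degenerate bootstrap replicates for %s (max %.1f%%)",
      cohort$treatment, paste(names(high), collapse = ", "),
      100 * max(high) / B))
  }
  structure(dists, class = "bootstrap_set", treatment = cohort$treatment)
}

#' @export
print.bootstrap_dist <- function(x, ...) {
  cat(sprintf("Bootstrap %s: estimate %.4g, SE %.4g, 95%% CI [%.4g, %.4g]\n",
              x$parameter, x$estimate, x$se, x$ci[1], x$ci[2]))
  cat(sprintf("  B = %d (%d degenerate), seed %d\n",
              x$B, x$n_degenerate, x$seed))
  invisible(x)
}

#' @export
print.bootstrap_set <- function(x, ...) {
  cat("Bootstrap set for treatment:", attr(x, "treatment"), "\n")
  for (d in x) print(d)
  invisible(x)
}

#' Paired-bootstrap test between two treatments
#'
#' Compares one parameter between two independently bootstrapped cohorts by
#' pairing the b-th replicates: `delta_b = A_b - B_b` over replicates where
#' both are defined.  The two-sided percentile p-value is
#' `p = 2 min(#\{delta <= 0\}, #\{delta >= 0\}) / B_defined`, clipped to
#' `[2/B_defined, 1]`.  The p-value is symmetric in the two treatments and
#' the difference antisymmetric.
#'
#' @param dA,dB `"bootstrap_dist"` objects for the same parameter and the
#'   same `B` (seeds should differ; the distributions are independent and
#'   pairing is by replicate index).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"pairwise_comparison"`: list with `parameter`,
#'   `treatments`, `difference` (of point estimates, A minus B), `p`,
#'   `significant`, `n_defined` and `unreliable` (`TRUE` when fewer than 30
#'   replicate pairs are jointly defined).
#' @export
paired_bootstrap_test <- function(dA, dB, alpha = 0.05) {
  if (!identical(dA$parameter, dB$parameter)) {
    stop("distributions are for different parameters: ",
         dA$parameter, " vs ", dB$parameter)
  }
  if (dA$B != dB$B) stop("distributions have different B")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ok <- !is.na(dA$values) & !is.na(dB$values)
  n_def <- sum(ok)
  if (n_def == 0) {
    p <- NA_real_
  } else {
    delta <- dA$values[ok] - dB$values[ok]
    p <- 2 * min(sum(delta <= 0), sum(delta >= 0)) / n_def
    p <- min(1, max(p, 2 / n_def))
  }
  structure(list(
    parameter = dA$parameter,
    treatments = c(attr_or(dA, "treatment"), attr_or(dB, "treatment")),
    difference = dA$estimate - dB$estimate,
    p = p,
    significant = !is.na(p) && p < alpha,
    alpha = alpha,
    n_defined = n_def,
    unreliable = n_def < 30
  ), class = "pairwise_comparison")
}

attr_or <- function(x, what) {
  v <- attr(x, what)
  if (is.null(v)) v <- x[[what]]
  if (is.null(v)) NA_character_ else v
}

#' All pairwise paired-bootstrap tests across treatments
#'
#' @param boot_sets Named list of `"bootstrap_set"` objects (names are
#'   treatment labels), all built with the same `B`.
#' @param parameters Parameters to test; defaults to all parameters shared
#'   by the sets.
#' @param alpha Significance level.
#' @return Data frame with one row per parameter and unordered treatment
#'   pair: `parameter`, `A`, `B`, `diff`, `p`, `significant`, `unreliable`.
#' @export
bootstrap_pairwise <- function(boot_sets, parameters = NULL, alpha = 0.05) {
  trts <- names(boot_sets)
  if (length(trts) < 2) stop("need at least two treatments")
  if (is.null(parameters)) {
    parameters <- Reduce(intersect, lapply(boot_sets, names))
  }
  rows <- list()
  for (p in parameters) {
    for (i in seq_len(length(trts) - 1)) {
      for (j in seq((i + 1), length(trts))) {
        dA <- boot_sets[[i]][[p]]
        dB <- boot_sets[[j]][[p]]
        cmp <- paired_bootstrap_test(dA, dB, alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = p, A = trts[i], B = trts[j],
          diff = cmp$difference, p = cmp$p,
          significant = cmp$significant, unreliable = cmp$unreliable,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Compact letter display from a significance matrix
#'
#' Assigns letters to treatments so that two treatments share a letter if
#' and only if their pairwise comparison is non-significant, using the
#' insert-and-absorb algorithm: start from one letter group containing all
#' treatments; for each significant pair, split every group containing both
#' into two groups each missing one member; finally absorb groups contained
#' in another.  The resulting letter groups are the maximal cliques of the
#' non-significance graph.  Treatments are ordered descending by their point
#' estimate, and letters are assigned to groups in order of their
#' highest-ranked member, so "a" marks the top group.
#'
#' @param significant Square logical matrix with treatment dimnames;
#'   `TRUE` = the pair differs significantly.  Must be complete and
#'   symmetric off the diagonal.
#' @param estimates Named numeric vector of point estimates used to order
#'   the display.
#' @param alpha Significance level to record in the result (informational).
#' @return Object of class `"letter_display"`: list with `letters` (named
#'   character vector), `groups` (list of character vectors, one per
#'   letter) and `alpha`.
#' @export
compact_letter_display <- function(significant, estimates, alpha = NA_real_) {
  trts <- rownames(significant)
  if (is.null(trts) || !identical(trts, colnames(significant))) {
    stop("'significant' must have matching row and column treatment names")
  }
  if (any(is.na(significant[upper.tri(significant)]))) {
    stop("incomplete significance matrix")
  }
  if (!all(significant == t(significant))) {
    stop("significance matrix must be symmetric")
  }
  if (!all(trts %in% names(estimates))) {
    stop("estimates missing for some treatments")
  }
  ord <- trts[order(-estimates[trts])]
  groups <- list(ord)
  pairs <- which(significant & upper.tri(significant), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- trts[pairs[k, 1]]; b <- trts[pairs[k, 2]]
    new_groups <- list()
    for (g in groups) {
      if (a %in% g && b %in% g) {
        new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
      } else {
        new_groups <- c(new_groups, list(g))
      }
    }
    # drop duplicates and groups absorbed by a superset
    new_groups <- unique(new_groups)
    keep <- vapply(seq_along(new_groups), function(i) {
      !any(vapply(seq_along(new_groups), function(j) {
        i != j && all(new_groups[[i]] %in% new_groups[[j]]) &&
          length(new_groups[[i]]) < length(new_groups[[j]])
      }, logical(1)))
    }, logical(1))
    groups <- new_groups[keep]
  }
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  # order groups by the rank of their best member (ties by next members)
  rank_of <- stats::setNames(seq_along(ord), ord)
  gkey <- vapply(groups, function(g) {
    paste(sprintf("%03d", sort(rank_of[g])), collapse = "")
  }, character(1))
  groups <- groups[order(gkey)]
  letter_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  lets <- stats::setNames(rep("", length(ord)), ord)
  for (i in seq_along(groups)) {
    for (t in groups[[i]]) lets[t] <- paste0(lets[t], letter_pool[i])
  }
  structure(list(letters = lets, groups = groups, alpha = alpha),
            class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  cat("Compact letter display",
      if (!is.na(x$alpha)) sprintf("(alpha = %g)", x$alpha), "\n")
  print(x$letters)
  invisible(x)
}

#' Significance matrix for one parameter from a pairwise test table
#'
#' @param pairwise Data frame as returned by [bootstrap_pairwise()].
#' @param parameter Parameter name to extract.
#' @return Square logical matrix with treatment dimnames.
#' @export
significance_matrix <- function(pairwise, parameter) {
  d <- pairwise[pairwise$parameter == parameter, , drop = FALSE]
  if (nrow(d) == 0) stop("no pairwise rows for parameter ", parameter)
  trts <- unique(c(d$A, d$B))
  m <- matrix(FALSE, length(trts), length(trts),
              dimnames = list(trts, trts))
  for (i in seq_len(nrow(d))) {
    m[d$A[i], d$B[i]] <- d$significant[i]
    m[d$B[i], d$A[i]] <- d$significant[i]
  }
  m
}
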