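# Age-stage two-sex life table computations for a single cohort.
#
# Census convention: ages are whole days, age 0 is the day the egg is laid,
# and an individual occupies each stage for exactly `*_days` daily censuses.
# An individual with stage boundaries b1 < b2 < ... is in stage j at ages
# b_{j-1} .. b_j - 1, eclosing at age E = egg+larva+prepupa+pupa days, and
# (if it dies as an adult) is alive through age E + adult_longevity - 1.

SUMMARY_STATS <- c("larval_period", "prepupal_period", "pupal_period",
                   "development_time", "preadult_survival",
                   "APOP", "TPOP", "oviposition_period", "fecundity",
                   "female_longevity", "male_longevity")

DEMOGRAPHIC_STATS <- c("GRR", "R0", "r", "lambda", "T")

# Internal: unpack a cohort into aligned per-individual arrays used by the
# matrix builder, the summary statistics and the bootstrap fast path.
#
# Returns: n, X (max age with anyone alive), alive (n x X+1, 0/1), stage
# (n x X+1 integer, 0 = dead, 1..6 per LIFETAB_STAGES), eggs (n x X+1),
# stats (n x S per-individual statistic values) and defined (n x S, 0/1).
cohort_arrays <- function(cohort, tpop_origin = c("egg", "hatching"),
                          oviposition = c("span", "days")) {
  tpop_origin <- match.arg(tpop_origin)
  oviposition <- match.arg(oviposition)
  ind <- cohort$individuals
  fec <- cohort$fecundity
  n <- nrow(ind)
  if (n == 0) stop("empty cohort")

  dur <- as.matrix(ind[, DURATION_COLS])
  storage.mode(dur) <- "double"
  death_idx <- match(ind$death_stage, DEATH_STAGES)
  preadult_days <- rowSums(dur, na.rm = TRUE)
  is_adult <- death_idx == 5L
  eclosion <- ifelse(is_adult, preadult_days, NA_real_)
  longevity <- ifelse(is_adult, ind$adult_longevity_days, NA_real_)
  last_alive <- ifelse(is_adult, eclosion + longevity - 1, preadult_days - 1)
  X <- max(last_alive)
  ages <- 0:X

  alive <- outer(last_alive, ages, ">=") * 1
  # count of stage boundaries passed at each age -> stage index 1..5
  cnt <- matrix(0, n, X + 1L)
  cum <- dur
  for (j in 2:4) cum[, j] <- cum[, j - 1] + cum[, j]
  for (j in 1:4) {
    bj <- cum[, j]
    bj[is.na(bj)] <- Inf
    cnt <- cnt + outer(bj, ages, "<=")
  }
  stage <- (cnt + 1) * alive
  is_male <- !is.na(ind$sex) & ind$sex == "M"
  if (any(is_male)) {
    male_adult <- stage == 5 & matrix(is_male, n, X + 1L)
    stage[male_adult] <- 6
  }

  eggs <- matrix(0, n, X + 1L)
  per_id <- NULL
  if (nrow(fec) > 0) {
    ri <- match(fec$id, ind$id)
    ci <- eclosion[ri] + fec$adult_day - 1 + 1  # cohort age -> column index
    key <- ri + n * (ci - 1)
    agg <- rowsum(as.numeric(fec$eggs), key)
    eggs[as.numeric(rownames(agg))] <- agg[, 1]
    per_id <- do.call(rbind, lapply(split(fec, fec$id), function(d) {
      laying <- d$adult_day[d$eggs > 0]
      data.frame(id = d$id[1],
                 total = sum(d$eggs),
                 first = if (length(laying)) min(laying) else NA_real_,
                 last = if (length(laying)) max(laying) else NA_real_,
                 n_days = sum(d$eggs > 0),
                 stringsAsFactors = FALSE)
    }))
  }

  # per-individual statistics (value + defined mask)
  S <- length(SUMMARY_STATS)
  V <- matrix(0, n, S, dimnames = list(NULL, SUMMARY_STATS))
  D <- matrix(0, n, S, dimnames = list(NULL, SUMMARY_STATS))
  set_stat <- function(name, idx, values) {
    V[idx, name] <<- values
    D[idx, name] <<- 1
  }
  completed <- function(j) death_idx > j  # advanced beyond preadult stage j
  set_stat("larval_period", completed(2L), dur[completed(2L), 2])
  set_stat("prepupal_period", completed(3L), dur[completed(3L), 3])
  set_stat("pupal_period", completed(4L), dur[completed(4L), 4])
  set_stat("development_time", is_adult, eclosion[is_adult])
  set_stat("preadult_survival", rep(TRUE, n), as.numeric(is_adult))
  is_female <- is_adult & !is.na(ind$sex) & ind$sex == "F"
  set_stat("female_longevity", is_female, longevity[is_female])
  male_adult_i <- is_adult & is_male
  set_stat("male_longevity", male_adult_i, longevity[male_adult_i])
  if (!is.null(per_id)) {
    lay <- per_id[per_id$total > 0, , drop = FALSE]
    if (nrow(lay) > 0) {
      li <- match(lay$id, ind$id)
      apop <- lay$first
      set_stat("APOP", li, apop)
      tpop <- eclosion[li] + apop
      if (tpop_origin == "hatching") tpop <- tpop - dur[li, 1]
      set_stat("TPOP", li, tpop)
      ovi <- if (oviposition == "span") lay$last - lay$first + 1 else lay$n_days
      set_stat("oviposition_period", li, ovi)
      set_stat("fecundity", li, lay$total)
    }
  }

  list(n = n, X = X, ages = ages, alive = alive, stage = stage, eggs = eggs,
       stats = V, defined = D, eclosion = eclosion, death_idx = death_idx)
}

#' Build the age-stage survivorship and fecundity matrices
#'
#' For each age x (days since the egg was laid, daily census) and stage j,
#' `s[x, j]` is the proportion of the initial cohort of `n0` eggs alive and
#' in stage j at age x, and `f[x, j]` is the mean number of eggs laid at age
#' x per individual currently in stage j (nonzero only in the female-adult
#' stage).  Ages run from 0 to the last day any individual is alive.
#'
#' @param cohort A validated `"cohort"` object.
#' @return An object of class `"age_stage_matrix"`: list with `ages`
#'   (0..X), `stages` ([LIFETAB_STAGES]), and matrices `s` and `f` of
#'   dimension (X+1) x 6.
#' @export
build_age_stage_matrix <- function(cohort) {
  arr <- cohort_arrays(cohort)
  n0 <- cohort$n0
  k <- length(LIFETAB_STAGES)
  s <- matrix(0, arr$X + 1L, k, dimnames = list(NULL, LIFETAB_STAGES))
  f <- matrix(0, arr$X + 1L, k, dimnames = list(NULL, LIFETAB_STAGES))
  for (j in seq_len(k)) {
    s[, j] <- colSums(arr$stage == j) / n0
  }
  fem_count <- colSums(arr$stage == 5)
  egg_tot <- colSums(arr$eggs)
  f[, 5] <- ifelse(fem_count > 0, egg_tot / fem_count, 0)
  structure(list(ages = arr$ages, stages = LIFETAB_STAGES, s = s, f = f,
                 n0 = n0, treatment = cohort$treatment),
            class = "age_stage_matrix")
}

#' Age-specific survival and fecundity schedules
#'
#' Collapses an age-stage matrix to the classical schedules: the
#' age-specific survival rate `lx = sum_j s_xj` and the age-specific
#' fecundity `mx = sum_j s_xj f_xj / sum_j s_xj` (0 at ages with no
#' survivors, where the ratio is 0/0).
#'
#' @param m An `"age_stage_matrix"`.
#' @return Object of class `"life_schedule"`: list with `age`, `lx`, `mx`.
#' @export
compute_schedules <- function(m) {
  lx <- rowSums(m$s)
  weighted <- rowSums(m$s * m$f)
  mx <- ifelse(lx > 0, weighted / lx, 0)
  structure(list(age = m$ages, lx = lx, mx = mx, treatment = m$treatment),
            class = "life_schedule")
}

#' @export
print.life_schedule <- function(x, ...) {
  cat("Life schedule", if (!is.null(x$treatment)) paste0("(", x$treatment, ")"),
      "- ages 0..", max(x$age), "\n")
  cat("  R0 =", format(sum(x$lx * x$mx), digits = 4),
      " GRR =", format(sum(x$mx), digits = 4), "\n")
  invisible(x)
}

#' Plot the lx and mx schedules
#'
#' @param x A `"life_schedule"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.life_schedule <- function(x, ...) {
  graphics::par(mar = c(4, 4, 2, 4))
  graphics::plot(x$age, x$lx, type = "s", ylim = c(0, 1),
                 xlab = "age (days)", ylab = expression(l[x]), ...)
  graphics::par(new = TRUE)
  graphics::plot(x$age, x$mx, type = "h", col = "grey40", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext(expression(m[x]), side = 4, line = 2.5)
  invisible(x)
}

# Euler-Lotka discrete renewal function: g(r) = sum exp(-r(x+1)) lx mx - 1,
# with ages x = 0..X.  Strictly decreasing in r whenever any lx*mx > 0.
euler_g <- function(r, phi, xp1) {
  sum(exp(-r * xp1) * phi) - 1
}

#' Solve the Euler-Lotka equation for the intrinsic rate of increase
#'
#' Finds r such that `sum_x exp(-r(x+1)) lx mx = 1` by bisection on an
#' initial bracket r in \[-2, 5\], expanded geometrically if the renewal sum
#' does not change sign there.  Iterates until the bracket is narrower than
#' `tol` (or `max_iter` bisections), then polishes by one final midpoint.
#'
#' @param lx,mx Survival and fecundity schedules, same length, age 0 first.
#' @param tol Bracket width tolerance on r.
#' @param max_iter Maximum number of bisections.
#' @return List with `r`, `residual` (the renewal sum minus 1 at the root)
#'   and `iterations`.  If `sum(lx*mx) <= 0` the rate is undefined and `r`
#'   is `NA`.
#' @export
solve_intrinsic_rate <- function(lx, mx, tol = 1e-12, max_iter = 200L) {
  stopifnot(length(lx) == length(mx))
  phi <- lx * mx
  if (sum(phi) <= 0) {
    return(list(r = NA_real_, residual = NA_real_, iterations = 0L))
  }
  xp1 <- seq_along(phi)  # x + 1 for x = 0..X
  lo <- -2; hi <- 5
  tries <- 0L
  while (euler_g(lo, phi, xp1) < 0 && tries < 60L) {
    lo <- lo * 2; tries <- tries + 1L
  }
  tries <- 0L
  while (euler_g(hi, phi, xp1) > 0 && tries < 60L) {
    hi <- hi * 2; tries <- tries + 1L
  }
  if (euler_g(lo, phi, xp1) < 0 || euler_g(hi, phi, xp1) > 0) {
    stop("Euler-Lotka root could not be bracketed after expansion")
  }
  it <- 0L
  while (hi - lo > tol && it < max_iter) {
    mid <- (lo + hi) / 2
    if (euler_g(mid, phi, xp1) >= 0) lo <- mid else hi <- mid
    it <- it + 1L
  }
  r <- (lo + hi) / 2
  list(r = r, residual = euler_g(r, phi, xp1), iterations = it)
}

#' Finite rate of increase from the intrinsic rate
#'
#' The per-day population multiplication factor, `lambda = exp(r)`.
#'
#' @param r Intrinsic rate of increase (day^-1).
#' @return lambda (day^-1).
#' @export
finite_rate <- function(r) exp(r)

#' Demographic parameters of a cohort
#'
#' Computes the five classical life-table parameters from the `lx` and `mx`
#' schedules:
#' gross reproductive rate `GRR = sum mx`, net reproductive rate
#' `R0 = sum lx mx`, intrinsic rate of increase `r` solving the discrete
#' Euler-Lotka equation `sum exp(-r(x+1)) lx mx = 1`, finite rate
#' `lambda = exp(r)` and mean generation time `T = ln(R0)/r`.
#'
#' If `R0 = 0` (no reproduction) the rates are undefined and reported as
#' `NA` with `defined = FALSE` rather than fabricated.  If `R0 = 1` exactly,
#' `r = 0` and `T` is undefined by the ratio formula (reported `NA`).
#'
#' @param x A `"life_schedule"`, `"age_stage_matrix"` or `"cohort"`.
#' @param ... Passed between methods.
#' @return Object of class `"demographic_params"`: list with `GRR`, `R0`,
#'   `r`, `lambda`, `T`, `euler_residual` and `defined`.
#' @export
demographic_parameters <- function(x, ...) UseMethod("demographic_parameters")

#' @rdname demographic_parameters
#' @export
demographic_parameters.cohort <- function(x, ...) {
  demographic_parameters(compute_schedules(build_age_stage_matrix(x)), ...)
}

#' @rdname demographic_parameters
#' @export
demographic_parameters.age_stage_matrix <- function(x, ...) {
  demographic_parameters(compute_schedules(x), ...)
}

#' @rdname demographic_parameters
#' @export
demographic_parameters.life_schedule <- function(x, ...) {
  GRR <- sum(x$mx)
  R0 <- sum(x$lx * x$mx)
  if (R0 <= 0) {
    out <- list(GRR = GRR, R0 = R0, r = NA_real_, lambda = NA_real_,
                T = NA_real_, euler_residual = NA_real_, defined = FALSE)
  } else {
    sol <- solve_intrinsic_rate(x$lx, x$mx)
    T_gen <- if (sol$r != 0) log(R0) / sol$r else NA_real_
    out <- list(GRR = GRR, R0 = R0, r = sol$r, lambda = finite_rate(sol$r),
                T = T_gen, euler_residual = abs(sol$residual), defined = TRUE)
  }
  out$treatment <- x$treatment
  structure(out, class = "demographic_params")
}

#' @export
print.demographic_params <- function(x, ...) {
  cat("Demographic parameters",
      if (!is.null(x$treatment)) paste0("(", x$treatment, ")"), "\n")
  vals <- c(GRR = x$GRR, R0 = x$R0, r = x$r, lambda = x$lambda, T = x$T)
  print(round(vals, 4))
  if (!x$defined) cat("  (R0 <= 0: r, lambda, T undefined)\n")
  invisible(x)
}

#' Life-history summary statistics for one cohort
#'
#' Mean, sample standard error (sd/sqrt(n)) and n for each of the standard
#' life-history statistics:
#' stage periods (over individuals completing the stage), development time
#' (egg to eclosion, over individuals reaching adulthood), preadult survival
#' (fraction of the initial cohort reaching adulthood), APOP (eclosion to
#' first egg, over females that laid), TPOP (start of life to first egg;
#' origin at age 0 by default or at hatching via `tpop_origin`), oviposition
#' period (inclusive first-to-last laying day span, or the count of laying
#' days via `oviposition = "days"`), lifetime fecundity per ovipositing
#' female, and adult longevity by sex.
#'
#' Statistics over empty subsets are reported as `NA` with `n = 0`, never as
#' 0.  The SEs here describe the observed sample; inferential SEs come from
#' [bootstrap_estimates()].
#'
#' @param cohort A validated `"cohort"`.
#' @param tpop_origin `"egg"` (default: day the egg was laid) or
#'   `"hatching"`.
#' @param oviposition `"span"` (default) or `"days"`.
#' @return Data frame with columns `statistic`, `mean`, `se`, `n`.
#' @export
life_history_summary <- function(cohort, tpop_origin = c("egg", "hatching"),
                                 oviposition = c("span", "days")) {
  arr <- cohort_arrays(cohort, tpop_origin = match.arg(tpop_origin),
                       oviposition = match.arg(oviposition))
  out <- lapply(SUMMARY_STATS, function(st) {
    sel <- arr$defined[, st] == 1
    vals <- arr$stats[sel, st]
    n <- sum(sel)
    data.frame(statistic = st,
               mean = if (n > 0) mean(vals) else NA_real_,
               se = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "treatment") <- cohort$treatment
  res
}
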