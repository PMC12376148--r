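# Individual-based synthetic cohort generator with known ground truth, plus
# an analytic oracle for configurations with fixed (degenerate)
# distributions and synthetic enzyme-replicate tables.

#' Distribution specifications for the simulator
#'
#' Small tagged lists describing how a quantity is drawn per individual:
#' `dist_fixed(value)` is degenerate; `dist_gamma(mean, shape)` is a gamma
#' draw (rate = shape/mean) rounded to whole days with a floor of
#' `min`; `dist_nbinom(mu, size)` is a negative-binomial count (used for
#' lifetime fecundity, allowing overdispersion).
#'
#' @param value Fixed value.
#' @param mean,shape Gamma mean and shape (days).
#' @param mu,size Negative-binomial mean and dispersion.
#' @return An object of class `"lt_dist"`.
#' @name lt_dist
NULL

#' @rdname lt_dist
#' @export
dist_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, value >= 0)
  structure(list(dist = "fixed", value = value), class = "lt_dist")
}

#' @rdname lt_dist
#' @export
dist_gamma <- function(mean, shape) {
  stopifnot(mean > 0, shape > 0)
  structure(list(dist = "gamma", mean = mean, shape = shape),
            class = "lt_dist")
}

#' @rdname lt_dist
#' @export
dist_nbinom <- function(mu, size) {
  stopifnot(mu >= 0, size > 0)
  structure(list(dist = "nbinom", mu = mu, size = size), class = "lt_dist")
}

is_fixed <- function(d) inherits(d, "lt_dist") && d$dist == "fixed"

draw_days <- function(d, n, min = 1) {
  switch(d$dist,
    fixed = rep(max(min, round(d$value)), n),
    gamma = pmax(min, round(stats::rgamma(n, shape = d$shape,
                                          rate = d$shape / d$mean))),
    nbinom = pmax(min, stats::rnbinom(n, mu = d$mu, size = d$size)),
    stop("unknown distribution tag: ", d$dist))
}

draw_count <- function(d, n) {
  switch(d$dist,
    fixed = rep(round(d$value), n),
    nbinom = stats::rnbinom(n, mu = d$mu, size = d$size),
    gamma = pmax(0, round(stats::rgamma(n, shape = d$shape,
                                        rate = d$shape / d$mean))),
    stop("unknown distribution tag: ", d$dist))
}

#' Simulation configuration for a synthetic cohort
#'
#' Defines the study conditions a generated cohort emulates: an initial
#' cohort of `n0` same-aged eggs followed daily, stage-specific survival
#' probabilities, stage duration distributions (whole days, the census is
#' daily), sex ratio at eclosion, and a female reproduction model (lifetime
#' fecundity, adult preoviposition period, oviposition period and the
#' within-period daily allocation shape).  Defaults describe a mid-range
#' sesame seed-diet rearing: a 50-egg cohort, ~37-day development, roughly
#' 55\% preadult survival, and a few hundred eggs per female laid over about
#' a week after a 2-3 day preoviposition period.
#'
#' @param n0 Initial cohort size (number of eggs).
#' @param p_female Probability a surviving adult is female.
#' @param stage_durations Named list of `"lt_dist"` for `egg`, `larva`,
#'   `prepupa`, `pupa` (days, floor 1).
#' @param stage_survival Named numeric probabilities in `[0, 1]` of
#'   surviving each preadult stage; an individual that fails a stage dies
#'   there after a uniformly distributed number of the stage's days.
#' @param fecundity List with `eggs` (lifetime fecundity distribution),
#'   `apop` (adult preoviposition period, days, floor 1), `oviposition_period`
#'   (days, floor 1) and `allocation` (`"uniform"` or `"triangular"`, the
#'   shape of the daily egg allocation; triangular peaks a third of the way
#'   into the period).
#' @param longevity Named list of `"lt_dist"` for `female` and `male` adult
#'   longevity (days, floor 1).  Laying days beyond the drawn longevity are
#'   truncated, so realized fecundity can fall below the drawn total.
#' @param seed Optional default seed recorded in the config.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(
    n0 = 50,
    p_female = 0.5,
    stage_durations = list(egg = dist_gamma(3, 40),
                           larva = dist_gamma(18.8, 900),
                           prepupa = dist_gamma(2.8, 60),
                           pupa = dist_gamma(12.9, 400)),
    stage_survival = c(egg = 0.90, larva = 0.75, prepupa = 0.95,
                       pupa = 0.90),
    fecundity = list(eggs = dist_nbinom(300, 3),
                     apop = dist_gamma(2.5, 10),
                     oviposition_period = dist_gamma(7, 6),
                     allocation = "triangular"),
    longevity = list(female = dist_gamma(9.5, 15),
                     male = dist_gamma(10.5, 15)),
    seed = NULL) {
  stopifnot(n0 >= 1, p_female > 0, p_female < 1 || p_female == 1)
  if (p_female < 0 || p_female > 1) stop("p_female must be in (0, 1]")
  stages <- c("egg", "larva", "prepupa", "pupa")
  if (!all(stages %in% names(stage_durations))) {
    stop("stage_durations must name all of: ", paste(stages, collapse = ", "))
  }
  if (!all(stages %in% names(stage_survival))) {
    stop("stage_survival must name all of: ", paste(stages, collapse = ", "))
  }
  if (any(stage_survival < 0 | stage_survival > 1)) {
    stop("stage survival probabilities must lie in [0, 1]")
  }
  if (!fecundity$allocation %in% c("uniform", "triangular")) {
    stop("allocation must be 'uniform' or 'triangular'")
  }
  structure(list(n0 = as.integer(n0), p_female = p_female,
                 stage_durations = stage_durations[stages],
                 stage_survival = stage_survival[stages],
                 fecundity = fecundity, longevity = longevity,
                 seed = seed),
            class = "simulation_config")
}

#' Preset config emulating a highly suitable diet
#'
#' Fast development (~36.5 d), high preadult survival (~0.70), high lifetime
#' fecundity (~740 eggs) over a long oviposition period, and long adult
#' life — the profile of the most suitable cultivar diet in the screening
#' this package targets.
#'
#' @param n0 Cohort size.
#' @return A `"simulation_config"`.
#' @export
config_mohajer_like <- function(n0 = 50) {
  simulation_config(
    n0 = n0,
    stage_durations = list(egg = dist_gamma(3, 60),
                           larva = dist_gamma(19.2, 1000),
                           prepupa = dist_gamma(3.0, 80),
                           pupa = dist_gamma(12.8, 450)),
    stage_survival = c(egg = 0.92, larva = 0.85, prepupa = 0.98,
                       pupa = 0.915),
    fecundity = list(eggs = dist_nbinom(737.6, 6),
                     apop = dist_gamma(1.7, 10),
                     oviposition_period = dist_gamma(11.6, 25),
                     allocation = "triangular"),
    longevity = list(female = dist_gamma(15.1, 40),
                     male = dist_gamma(15.2, 30)))
}

#' Preset config emulating a resistant (poor) diet
#'
#' Slow development (~40.6 d), low preadult survival (~0.40), low lifetime
#' fecundity (~110 eggs), short adult life — the profile of the most
#' resistant cultivar diet in the targeted screening.
#'
#' @param n0 Cohort size.
#' @return A `"simulation_config"`.
#' @export
config_jiroft_like <- function(n0 = 50) {
  simulation_config(
    n0 = n0,
    stage_durations = list(egg = dist_gamma(4.5, 50),
                           larva = dist_gamma(20.4, 700),
                           prepupa = dist_gamma(3.0, 80),
                           pupa = dist_gamma(12.7, 350)),
    stage_survival = c(egg = 0.85, larva = 0.60, prepupa = 0.95,
                       pupa = 0.83),
    fecundity = list(eggs = dist_nbinom(111.8, 2),
                     apop = dist_gamma(2.5, 12),
                     oviposition_period = dist_gamma(5.0, 8),
                     allocation = "triangular"),
    longevity = list(female = dist_gamma(6.9, 15),
                     male = dist_gamma(8.3, 20)))
}

allocation_weights <- function(p_days, shape) {
  if (shape == "uniform") return(rep(1, p_days))
  peak <- max(1, round(p_days / 3))
  w <- ifelse(seq_len(p_days) <= peak,
              seq_len(p_days) / peak,
              (p_days - seq_len(p_days) + 1) / (p_days - peak + 1))
  w
}

#' Simulate a synthetic cohort
#'
#' Individual-based draws per egg: stage-by-stage survival then duration
#' (an individual that fails a stage dies after a uniform number of the
#' stage's days), sex at eclosion, adult longevity by sex, and for females
#' an APOP, an oviposition period and a lifetime egg total allocated to
#' days multinomially under the configured allocation shape (days beyond
#' the adult longevity are truncated).  Fully reproducible by seed.
#'
#' @param cfg A `"simulation_config"`.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @param treatment Treatment label for the generated cohort.
#' @return A validated `"cohort"` of `cfg$n0` records.
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed, treatment = "synthetic") {
  if (!inherits(cfg, "simulation_config")) {
    stop("cfg must be a simulation_config")
  }
  if (is.null(seed)) stop("a seed is required (argument or cfg$seed)")
  set.seed(as.integer(seed))
  n <- cfg$n0
  stages <- names(cfg$stage_durations)
  dur <- sapply(stages, function(s) draw_days(cfg$stage_durations[[s]], n))
  dur <- matrix(dur, nrow = n, dimnames = list(NULL, stages))
  surv <- sapply(stages, function(s)
    stats::runif(n) < cfg$stage_survival[[s]])
  surv <- matrix(surv, nrow = n, dimnames = list(NULL, stages))

  death_idx <- rep(5L, n)  # 5 = adult
  for (j in 4:1) death_idx[!surv[, j]] <- j
  # days survived within the death stage: uniform over 1..duration
  days_in_death <- dur[cbind(seq_len(n), pmin(death_idx, 4L))]
  u <- floor(stats::runif(n) * days_in_death) + 1
  out_dur <- dur
  for (j in 1:4) {
    died_here <- death_idx == j
    out_dur[died_here, j] <- u[died_here]
    if (j < 4) out_dur[death_idx <= j, (j + 1):4] <- NA
  }
  is_adult <- death_idx == 5L
  sex <- rep("unknown", n)
  sex[is_adult] <- ifelse(stats::runif(sum(is_adult)) < cfg$p_female,
                          "F", "M")
  longevity <- rep(NA_real_, n)
  f_idx <- which(sex == "F")
  m_idx <- which(sex == "M")
  longevity[f_idx] <- draw_days(cfg$longevity$female, length(f_idx))
  longevity[m_idx] <- draw_days(cfg$longevity$male, length(m_idx))

  fec_rows <- list()
  if (length(f_idx) > 0) {
    apop <- draw_days(cfg$fecundity$apop, length(f_idx))
    p_len <- draw_days(cfg$fecundity$oviposition_period, length(f_idx))
    totals <- draw_count(cfg$fecundity$eggs, length(f_idx))
    for (k in seq_along(f_idx)) {
      i <- f_idx[k]
      days <- seq(apop[k], apop[k] + p_len[k] - 1)
      days <- days[days <= longevity[i]]
      if (length(days) == 0 || totals[k] == 0) next
      w <- allocation_weights(length(days), cfg$fecundity$allocation)
      eggs <- as.vector(stats::rmultinom(1, totals[k], w))
      keep <- eggs > 0
      if (!any(keep)) next
      fec_rows[[length(fec_rows) + 1L]] <- data.frame(
        id = sprintf("I%04d", i), adult_day = days[keep], eggs = eggs[keep],
        stringsAsFactors = FALSE)
    }
  }
  fec <- if (length(fec_rows) > 0) do.call(rbind, fec_rows) else NULL

  ind <- data.frame(
    id = sprintf("I%04d", seq_len(n)),
    treatment = treatment,
    egg_days = out_dur[, "egg"],
    larva_days = out_dur[, "larva"],
    prepupa_days = out_dur[, "prepupa"],
    pupa_days = out_dur[, "pupa"],
    death_stage = DEATH_STAGES[death_idx],
    sex = sex,
    adult_longevity_days = longevity,
    stringsAsFactors = FALSE)
  new_cohort(ind, fec, treatment = treatment)
}

#' Analytic life-table expectations for a fixed configuration
#'
#' For configurations in the analytic subset — every distribution fixed and
#' an oviposition period of one day, so all of a female's eggs fall on a
#' single known age — the exact expected `lx` and `mx` schedules implied by
#' the config are computed in closed form, and the demographic parameters
#' follow from the same formulas as [demographic_parameters()].  Within a
#' dying stage the survival curve declines linearly, matching the
#' simulator's uniform day-of-death draw.  Used as ground truth for
#' parameter-recovery tests.
#'
#' @param cfg A `"simulation_config"` in the analytic subset.
#' @return List with `schedule` (a `"life_schedule"`) and `params`
#'   (a `"demographic_params"`).
#' @export
analytic_expectations <- function(cfg) {
  fixed_all <- all(vapply(cfg$stage_durations, is_fixed, logical(1))) &&
    is_fixed(cfg$fecundity$eggs) && is_fixed(cfg$fecundity$apop) &&
    is_fixed(cfg$fecundity$oviposition_period) &&
    is_fixed(cfg$longevity$female) && is_fixed(cfg$longevity$male)
  if (!fixed_all) {
    stop("config outside the analytic subset: all distributions must be fixed")
  }
  if (max(1, round(cfg$fecundity$oviposition_period$value)) != 1) {
    stop("config outside the analytic subset: oviposition period must be 1 day")
  }
  D <- vapply(cfg$stage_durations,
              function(d) max(1, round(d$value)), numeric(1))
  s <- cfg$stage_survival
  q <- cfg$p_female
  LF <- max(1, round(cfg$longevity$female$value))
  LM <- max(1, round(cfg$longevity$male$value))
  apop <- max(1, round(cfg$fecundity$apop$value))
  Feggs <- round(cfg$fecundity$eggs$value)

  A <- cumprod(s)          # survive through stage j
  A_prev <- c(1, A[-4])    # survive up to stage j's start
  E <- sum(D)
  lx <- numeric(0)
  for (j in 1:4) {
    t <- 0:(D[j] - 1)
    lx <- c(lx, A_prev[j] * (s[j] + (1 - s[j]) * (D[j] - t) / D[j]))
  }
  Lmax <- max(LF, LM)
  t <- 0:(Lmax - 1)
  lx <- c(lx, A[4] * (q * (t < LF) + (1 - q) * (t < LM)))
  # trim trailing zeros: max age is the last day anyone can be alive
  last <- max(which(lx > 0))
  lx <- lx[1:last]
  mx <- numeric(length(lx))
  if (apop <= LF && A[4] > 0 && q > 0) {
    lay_age <- E + apop - 1
    if (lay_age + 1 <= length(mx)) {
      mx[lay_age + 1] <- A[4] * q * Feggs / lx[lay_age + 1]
    }
  }
  sched <- structure(list(age = seq_along(lx) - 1, lx = lx, mx = mx,
                          treatment = "analytic"),
                     class = "life_schedule")
  list(schedule = sched, params = demographic_parameters(sched))
}

#' Simulate enzyme-activity replicate tables
#'
#' Draws `n` replicate activities per treatment (and enzyme) from a normal
#' distribution matched to the specified group mean and standard error
#' (`sd = se * sqrt(n)`), truncated at zero by rejection.  Used to exercise
#' the ANOVA/Tukey stage when only group-level means and SEs are available.
#'
#' @param table Data frame with columns `treatment`, `mean`, `se` and
#'   optionally `enzyme` (defaults to a single unnamed assay).
#' @param n Replicates per group (>= 2).
#' @param seed Integer seed.
#' @return Data frame with columns `enzyme`, `treatment`, `replicate`,
#'   `activity`.
#' @export
simulate_enzyme_replicates <- function(table, n = 3, seed = 1L) {
  table <- as.data.frame(table)
  if (!all(c("treatment", "mean", "se") %in% names(table))) {
    stop("table must have columns treatment, mean, se")
  }
  if (n < 2) stop("need at least 2 replicates per group")
  if (any(table$se < 0)) stop("negative SEs")
  if (any(table$mean < 0)) stop("negative means")
  if (!"enzyme" %in% names(table)) table$enzyme <- "assay"
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(table)), function(i) {
    sdev <- table$se[i] * sqrt(n)
    vals <- stats::rnorm(n, table$mean[i], sdev)
    tries <- 0L
    while (any(vals < 0) && tries < 1000L) {
      vals[vals < 0] <- stats::rnorm(sum(vals < 0), table$mean[i], sdev)
      tries <- tries + 1L
    }
    vals[vals < 0] <- 0
    data.frame(enzyme = table$enzyme[i], treatment = table$treatment[i],
               replicate = seq_len(n), activity = vals,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
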