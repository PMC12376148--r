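# Age-stage matrix, lx/mx schedules, Euler-Lotka solver and life-history
# summaries against hand-computed values.

test_that("age-stage survivorship counts the daily census by hand", {
  # two eggs; one dies during day 1, the other develops on
  ind <- rbind(record("D", egg = 1, death = "egg"),
               adult_record("S", sex = "F", longevity = 2))
  co <- new_cohort(ind)
  m <- build_age_stage_matrix(co)
  expect_equal(unname(m$s[1, "egg"]), 1)    # age 0: everyone starts as an egg
  expect_equal(unname(m$s[2, "egg"]), 0.5)  # age 1: the early death is gone
  expect_equal(sum(m$s[1, ]), 1)
  # row sums never increase with age
  expect_true(all(diff(rowSums(m$s)) <= 1e-12))
})

test_that("age-stage fecundity is eggs per female present, by stage", {
  # 1-day stages: eclosion at age 4; adult day 2 = age 5
  ind <- rbind(
    adult_record("F1", sex = "F", longevity = 3, egg = 1, larva = 1,
                 prepupa = 1, pupa = 1),
    adult_record("M1", sex = "M", longevity = 3, egg = 1, larva = 1,
                 prepupa = 1, pupa = 1))
  co <- new_cohort(ind, fecundity_rows("F1", 2, 10))
  m <- build_age_stage_matrix(co)
  age5 <- 6  # row index for age 5
  expect_equal(unname(m$f[age5, "female"]), 10)
  expect_equal(unname(m$f[age5, "male"]), 0)
  sc <- compute_schedules(m)
  # both alive at age 5: mx = (0.5 * 10) / 1.0
  expect_equal(sc$lx[age5], 1)
  expect_equal(sc$mx[age5], 5)
})

test_that("schedules define mx = 0 where no one survives", {
  s <- structure(list(age = 0:2,
                      s = matrix(c(1, 0, 0, 0, 0, 0), 3, 2,
                                 dimnames = list(NULL, c("egg", "female"))),
                      f = matrix(0, 3, 2)),
                 class = "age_stage_matrix")
  sc <- compute_schedules(s)
  expect_equal(sc$mx, c(0, 0, 0))
  expect_equal(sc$lx, c(1, 0, 0))
})

test_that("Euler-Lotka solutions match analytic schedules", {
  p <- demographic_parameters(
    structure(list(age = 0:1, lx = c(1, 1), mx = c(0, 4)),
              class = "life_schedule"))
  expect_equal(p$GRR, 4)
  expect_equal(p$R0, 4)
  expect_equal(p$r, log(4) / 2, tolerance = 1e-10)
  expect_equal(p$lambda, 2, tolerance = 1e-10)
  expect_equal(p$T, 2, tolerance = 1e-9)
  expect_lt(p$euler_residual, 1e-10)

  p <- demographic_parameters(
    structure(list(age = 0:2, lx = c(1, 1, 1), mx = c(0, 0, 3)),
              class = "life_schedule"))
  expect_equal(p$r, log(3) / 3, tolerance = 1e-10)
  expect_equal(p$lambda, 3^(1/3), tolerance = 1e-10)
  expect_equal(p$T, 3, tolerance = 1e-9)

  # R0 = 1 pins r at zero
  p <- demographic_parameters(
    structure(list(age = 0:1, lx = c(1, 0.5), mx = c(0, 2)),
              class = "life_schedule"))
  expect_equal(p$R0, 1)
  expect_equal(p$r, 0, tolerance = 1e-10)
  expect_equal(p$lambda, 1, tolerance = 1e-10)
})

test_that("no reproduction leaves the rates undefined, not fabricated", {
  ind <- rbind(record("A", egg = 2, death = "egg"),
               adult_record("M1", sex = "M", longevity = 4))
  p <- demographic_parameters(new_cohort(ind))
  expect_equal(p$R0, 0)
  expect_false(p$defined)
  expect_true(is.na(p$r) && is.na(p$lambda) && is.na(p$T))
})

test_that("solver agrees with a fine grid scan on random schedules", {
  set.seed(11)
  for (i in 1:10) {
    X <- sample(20:60, 1)
    lx <- cumprod(c(1, runif(X, 0.85, 1)))
    mx <- c(rep(0, X - 5), runif(6, 0, 30))
    sol <- solve_intrinsic_rate(lx, mx)
    g <- function(r) sum(exp(-r * seq_along(lx)) * lx * mx) - 1
    coarse <- seq(-1, 2, by = 1e-3)
    gc <- vapply(coarse, g, numeric(1))
    k <- which(diff(sign(gc)) != 0)[1]
    fine <- seq(coarse[k], coarse[k + 1], by = 1e-6)
    gf <- vapply(fine, g, numeric(1))
    r_grid <- fine[which.min(abs(gf))]
    expect_lt(abs(sol$r - r_grid), 1e-5)
    expect_lt(abs(sol$residual), 1e-10)
  }
})

test_that("life-history summary reproduces hand formulas", {
  ind <- rbind(adult_record("A", sex = "F", longevity = 9, pupa = 11),  # 36 d
               adult_record("B", sex = "F", longevity = 7, pupa = 13))  # 38 d
  co <- new_cohort(ind, fecundity_rows("A", 3:7, c(5, 10, 20, 10, 5)))
  s <- life_history_summary(co)
  get <- function(st) s[s$statistic == st, ]
  expect_equal(get("development_time")$mean, 37.0)
  expect_equal(get("development_time")$se, 1.0)
  expect_equal(get("APOP")$mean, 3)            # first egg on adult day 3
  expect_equal(get("oviposition_period")$mean, 5)  # days 3..7 inclusive
  expect_equal(get("TPOP")$mean, 36 + 3)       # origin: day the egg was laid
  expect_equal(get("fecundity")$mean, 50)
  expect_equal(get("fecundity")$n, 1)          # one ovipositing female
  expect_equal(get("male_longevity")$n, 0)     # empty subset: absent, not 0
  expect_true(is.na(get("male_longevity")$mean))
})

test_that("TPOP origin and oviposition definition are configurable", {
  ind <- adult_record("A", sex = "F", longevity = 9, pupa = 11)
  co <- new_cohort(rbind(ind), fecundity_rows("A", c(3, 7), c(5, 5)))
  s_hatch <- life_history_summary(co, tpop_origin = "hatching")
  expect_equal(s_hatch[s_hatch$statistic == "TPOP", "mean"], 36 - 3 + 3)
  s_days <- life_history_summary(co, oviposition = "days")
  expect_equal(s_days[s_days$statistic == "oviposition_period", "mean"], 2)
})

test_that("preadult survival is the fraction of eggs reaching adulthood", {
  ind <- do.call(rbind, c(
    lapply(1:35, function(i) adult_record(paste0("A", i), sex = "M",
                                          longevity = 5)),
    lapply(1:15, function(i) record(paste0("D", i), egg = 2, death = "egg"))))
  s <- life_history_summary(new_cohort(ind))
  expect_equal(s[s$statistic == "preadult_survival", "mean"], 0.70)
  expect_equal(s[s$statistic == "preadult_survival", "n"], 50)
})

test_that("development time mean equals the sum of its stage means over
           the same individuals", {
  co <- random_cohort(3, n0 = 60)
  adults <- co$individuals[co$individuals$death_stage == "adult", ]
  expect_equal(
    mean(rowSums(adults[, c("egg_days", "larva_days", "prepupa_days",
                            "pupa_days")])),
    life_history_summary(co)[4, "mean"])
})

test_that("demography invariants hold on random cohorts", {
  for (seed in 1:8) {
    co <- random_cohort(seed)
    m <- build_age_stage_matrix(co)
    expect_true(all(m$s >= 0 & m$s <= 1))
    sc <- compute_schedules(m)
    expect_equal(sc$lx[1], 1)
    expect_true(all(diff(sc$lx) <= 1e-12))
    p <- demographic_parameters(sc)
    expect_gte(p$GRR, p$R0)
    if (p$defined) {
      expect_equal(p$lambda, exp(p$r))
      expect_equal(p$T, log(p$R0) / p$r)
      expect_lt(p$euler_residual, 1e-10)
      # two-sex identity: R0 = (ovipositing females / n0) * mean fecundity
      fec <- co$fecundity
      tot <- tapply(fec$eggs, fec$id, sum)
      tot <- tot[tot > 0]
      expect_equal(p$R0, length(tot) / co$n0 * mean(tot))
    }
  }
})
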