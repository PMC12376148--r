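# Builders for small hand-checkable cohorts and random fixtures.

# one individual record as a one-row data frame
record <- function(id, treatment = "T1", egg = NA, larva = NA, prepupa = NA,
                   pupa = NA, death = "adult", sex = "unknown",
                   longevity = NA) {
  data.frame(id = id, treatment = treatment,
             egg_days = egg, larva_days = larva, prepupa_days = prepupa,
             pupa_days = pupa, death_stage = death, sex = sex,
             adult_longevity_days = longevity, stringsAsFactors = FALSE)
}

# adult with fixed stage durations (3, 19, 3, 13) -> eclosion at age 38
adult_record <- function(id, sex = "F", longevity = 10, egg = 3, larva = 19,
                         prepupa = 3, pupa = 13, treatment = "T1") {
  record(id, treatment, egg, larva, prepupa, pupa,
         death = "adult", sex = sex, longevity = longevity)
}

fecundity_rows <- function(id, days, eggs) {
  data.frame(id = id, adult_day = days, eggs = eggs, stringsAsFactors = FALSE)
}

# a small fully-consistent mixed cohort used across tests
small_cohort <- function() {
  ind <- rbind(
    record("A", egg = 2, death = "egg"),
    record("B", egg = 3, larva = 10, death = "larva"),
    adult_record("C", sex = "F", longevity = 8),
    adult_record("D", sex = "M", longevity = 6),
    adult_record("E", sex = "F", longevity = 5, larva = 20))
  fec <- rbind(fecundity_rows("C", c(2, 3, 4), c(30, 50, 20)),
               fecundity_rows("E", c(3, 5), c(10, 40)))
  new_cohort(ind, fec)
}

# random valid cohort via the simulator with a seed-indexed config
random_cohort <- function(seed, n0 = 30) {
  set.seed(seed)
  cfg <- simulation_config(
    n0 = n0,
    p_female = runif(1, 0.3, 0.7),
    stage_durations = list(egg = dist_gamma(runif(1, 2, 5), 30),
                           larva = dist_gamma(runif(1, 15, 22), 200),
                           prepupa = dist_gamma(runif(1, 2, 4), 40),
                           pupa = dist_gamma(runif(1, 11, 14), 150)),
    stage_survival = c(egg = runif(1, 0.7, 1), larva = runif(1, 0.5, 1),
                       prepupa = runif(1, 0.8, 1), pupa = runif(1, 0.7, 1)),
    fecundity = list(eggs = dist_nbinom(runif(1, 100, 700), 3),
                     apop = dist_gamma(runif(1, 1.5, 3), 10),
                     oviposition_period = dist_gamma(runif(1, 4, 12), 8),
                     allocation = sample(c("uniform", "triangular"), 1)),
    longevity = list(female = dist_gamma(runif(1, 6, 15), 15),
                     male = dist_gamma(runif(1, 6, 15), 15)))
  simulate_cohort(cfg, seed = seed + 1000L)
}

# brute-force maximal cliques of the non-significance graph (oracle for the
# compact letter display), by exhaustive subset enumeration
brute_force_letter_classes <- function(significant) {
  trts <- rownames(significant)
  n <- length(trts)
  cliques <- list()
  for (bits in 1:(2^n - 1)) {
    members <- trts[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0]
    ok <- TRUE
    if (length(members) > 1) {
      pairs <- utils::combn(members, 2)
      ok <- !any(vapply(seq_len(ncol(pairs)), function(i)
        significant[pairs[1, i], pairs[2, i]], logical(1)))
    }
    if (ok) cliques[[length(cliques) + 1L]] <- members
  }
  maximal <- Filter(function(cl) {
    !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), logical(1)))
  }, cliques)
  lapply(maximal, sort)
}

# canonicalize a list of letter groups for set comparison
group_set <- function(groups) {
  sort(vapply(lapply(groups, sort), paste, character(1), collapse = "|"))
}
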