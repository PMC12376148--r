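# Bootstrap distributions, paired-bootstrap tests and letter displays.

test_that("identical records give zero bootstrap variance everywhere", {
  ind <- do.call(rbind, lapply(1:8, function(i)
    adult_record(paste0("A", i), sex = "F", longevity = 6)))
  fec <- do.call(rbind, lapply(1:8, function(i)
    fecundity_rows(paste0("A", i), c(2, 3), c(40, 60))))
  co <- new_cohort(ind, fec)
  b <- bootstrap_estimates(co, B = 200, seed = 5)
  for (p in c("development_time", "fecundity", "GRR", "R0", "r", "lambda")) {
    expect_equal(b[[p]]$se, 0, info = p)
    expect_equal(b[[p]]$n_degenerate, 0, info = p)
  }
})

test_that("the same seed reproduces the replicate values bit for bit", {
  co <- random_cohort(21)
  b1 <- bootstrap_estimates(co, B = 300, seed = 42)
  b2 <- bootstrap_estimates(co, B = 300, seed = 42)
  for (p in names(b1)) expect_identical(b1[[p]]$values, b2[[p]]$values)
  b3 <- bootstrap_estimates(co, B = 300, seed = 43)
  expect_false(identical(b1$r$values, b3$r$values))
})

test_that("two-record development-time bootstrap matches the closed form", {
  # resampling {36, 38}: mean is 36/37/38 w.p. 1/4, 1/2, 1/4 -> sd = 1/sqrt(2)
  ind <- rbind(adult_record("A", sex = "F", longevity = 5, pupa = 11),
               adult_record("B", sex = "F", longevity = 5, pupa = 13))
  co <- new_cohort(ind)
  # no oviposition here, so the demographic rates are degenerate throughout;
  # the warning about that is expected and irrelevant to this check
  b <- suppressWarnings(bootstrap_estimates(co, B = 4000, seed = 9))
  expect_equal(b$development_time$estimate, 37)
  expect_equal(b$development_time$se, sqrt(0.5), tolerance = 0.05)
})

test_that("replicate means agree with recomputing the statistics directly", {
  co <- random_cohort(31, n0 = 25)
  B <- 40
  b <- bootstrap_estimates(co, B = B, seed = 77)
  set.seed(77)
  idx <- matrix(sample.int(co$n0, co$n0 * B, replace = TRUE), nrow = B)
  for (bi in c(1, 17, 40)) {
    sub <- co$individuals[idx[bi, ], ]
    sub$id <- paste0("R", seq_len(nrow(sub)))
    fec_list <- lapply(seq_len(nrow(sub)), function(k) {
      orig <- co$individuals$id[idx[bi, k]]
      f <- co$fecundity[co$fecundity$id == orig, , drop = FALSE]
      if (nrow(f) > 0) f$id <- sub$id[k]
      f
    })
    rco <- new_cohort(sub, do.call(rbind, fec_list))
    s <- life_history_summary(rco)
    dp <- demographic_parameters(rco)
    for (st in s$statistic) {
      expect_equal(b[[st]]$values[bi],
                   s$mean[s$statistic == st], info = st)
    }
    expect_equal(b$R0$values[bi], dp$R0)
    expect_equal(b$GRR$values[bi], dp$GRR)
    if (dp$defined) expect_equal(b$r$values[bi], dp$r, tolerance = 1e-9)
  }
})

test_that("degenerate replicates are counted and excluded", {
  # one ovipositing female among mostly males: many resamples lack her
  ind <- rbind(adult_record("F1", sex = "F", longevity = 6),
               adult_record("M1", sex = "M", longevity = 6),
               adult_record("M2", sex = "M", longevity = 6))
  co <- new_cohort(ind, fecundity_rows("F1", 2, 50))
  expect_warning(b <- bootstrap_estimates(co, B = 500, seed = 2),
                 "degenerate")
  expect_gt(b$r$n_degenerate, 0)
  expect_equal(b$r$n_degenerate + sum(!is.na(b$r$values)), b$r$B)
  expect_true(all(is.finite(b$r$values[!is.na(b$r$values)])))
})

test_that("bootstrap means converge as B grows", {
  co <- random_cohort(55, n0 = 40)
  b_small <- bootstrap_estimates(co, B = 200, seed = 1)
  b_big <- bootstrap_estimates(co, B = 20000, seed = 1)
  # statistics that are plain means over individuals are bootstrap-unbiased:
  # the replicate mean converges to the point estimate at rate SE/sqrt(B)
  for (p in c("development_time", "R0", "fecundity", "preadult_survival")) {
    d <- b_big[[p]]
    expect_lt(abs(mean(d$values, na.rm = TRUE) - d$estimate),
              4 * d$se / sqrt(sum(!is.na(d$values))) + 1e-10)
  }
  # nonlinear statistics (r) carry genuine O(1/n) bootstrap bias, so the
  # two runs must agree with each other within Monte-Carlo error instead
  for (p in c("r", "lambda", "T")) {
    m_small <- mean(b_small[[p]]$values, na.rm = TRUE)
    m_big <- mean(b_big[[p]]$values, na.rm = TRUE)
    expect_lt(abs(m_small - m_big),
              4 * b_big[[p]]$se / sqrt(200) + 1e-10)
  }
})

test_that("paired-bootstrap test is symmetric and detects separation", {
  co <- random_cohort(8, n0 = 30)
  bA <- bootstrap_estimates(co, B = 400, seed = 100)
  bB <- bootstrap_estimates(co, B = 400, seed = 200)
  cmp <- paired_bootstrap_test(bA$r, bB$r)
  rev <- paired_bootstrap_test(bB$r, bA$r)
  expect_equal(cmp$p, rev$p)
  expect_equal(cmp$difference, -rev$difference)
  # same cohort, different seeds: a null comparison
  expect_gt(cmp$p, 0.05)
  expect_false(cmp$significant)

  # complete separation: all deltas positive
  dA <- bA$r
  dB <- bB$r
  dA$values <- dB$values + 1
  sep <- paired_bootstrap_test(dA, dB)
  expect_equal(sep$p, 2 / sum(!is.na(dA$values) & !is.na(dB$values)))
  expect_true(sep$significant)

  expect_error(paired_bootstrap_test(bA$r, bB$R0), "different parameters")
})

test_that("tests with too few joint replicates are flagged unreliable", {
  d1 <- structure(list(parameter = "r", B = 40,
                       values = c(rnorm(20), rep(NA, 20)),
                       estimate = 0, treatment = "A"),
                  class = "bootstrap_dist")
  d2 <- structure(list(parameter = "r", B = 40,
                       values = c(rep(NA, 25), rnorm(15)),
                       estimate = 0, treatment = "B"),
                  class = "bootstrap_dist")
  cmp <- paired_bootstrap_test(d1, d2)
  expect_true(cmp$unreliable)
})

test_that("letter display covers the degenerate all-alike and all-differ
           cases", {
  est <- c(a1 = 3, a2 = 2, a3 = 1)
  none <- matrix(FALSE, 3, 3, dimnames = list(names(est), names(est)))
  cld <- compact_letter_display(none, est)
  expect_equal(unname(cld$letters), rep("a", 3))

  all_sig <- matrix(TRUE, 3, 3, dimnames = list(names(est), names(est)))
  diag(all_sig) <- FALSE
  cld <- compact_letter_display(all_sig, est)
  expect_equal(unname(cld$letters[order(-est)]), c("a", "b", "c"))
})

test_that("letter classes equal the brute-force maximal cliques", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    trts <- paste0("t", 1:n)
    sig <- matrix(FALSE, n, n, dimnames = list(trts, trts))
    up <- runif(n * (n - 1) / 2) < 0.4
    sig[upper.tri(sig)] <- up
    sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
    est <- setNames(rnorm(n), trts)
    cld <- compact_letter_display(sig, est)
    expect_equal(group_set(cld$groups),
                 group_set(brute_force_letter_classes(sig)))
    # the defining invariant: share a letter iff non-significant
    for (a in trts) for (b in trts) {
      if (a == b) next
      share <- any(strsplit(cld$letters[a], "")[[1]] %in%
                     strsplit(cld$letters[b], "")[[1]])
      expect_equal(share, !sig[a, b])
    }
  }
})

test_that("the reference lambda letter classes are reproduced from their
           own significance structure", {
  # letter suffixes of the finite rate column in the published screening
  lets <- c(Mohajer = "ab", Dashtestan = "c", Barekat = "a", Chamran = "bc",
            Shevin = "c", Sistan = "bc", Hamidieh = "bc", Behbahan = "c",
            Dezful = "c", Jiroft = "c")
  lambda <- c(Mohajer = 1.122, Dashtestan = 1.098, Barekat = 1.127,
              Chamran = 1.105, Shevin = 1.092, Sistan = 1.106,
              Hamidieh = 1.106, Behbahan = 1.100, Dezful = 1.098,
              Jiroft = 1.082)
  trts <- names(lets)
  sig <- outer(trts, trts, Vectorize(function(a, b) {
    !any(strsplit(lets[a], "")[[1]] %in% strsplit(lets[b], "")[[1]])
  }))
  dimnames(sig) <- list(trts, trts)
  diag(sig) <- FALSE
  cld <- compact_letter_display(sig, lambda, alpha = 0.05)
  published_classes <- lapply(c("a", "b", "c"), function(l)
    sort(trts[grepl(l, lets)]))
  expect_equal(group_set(cld$groups), group_set(published_classes))
})

test_that("pairwise tables carry one row per unordered pair and relabeling
           leaves p-values unchanged", {
  cohorts <- lapply(c(7, 8, 9), random_cohort, n0 = 20)
  names(cohorts) <- c("d1", "d2", "d3")
  boots <- lapply(seq_along(cohorts), function(i)
    bootstrap_estimates(cohorts[[i]], B = 150, seed = 10 + i))
  names(boots) <- names(cohorts)
  pw <- bootstrap_pairwise(boots, parameters = c("r", "R0"))
  expect_equal(nrow(pw), 2 * 3)  # 2 parameters x choose(3, 2)
  relabeled <- boots
  names(relabeled) <- c("x1", "x2", "x3")
  for (i in seq_along(relabeled)) {
    for (p in names(relabeled[[i]])) {
      relabeled[[i]][[p]]$treatment <- names(relabeled)[i]
    }
  }
  pw2 <- bootstrap_pairwise(relabeled, parameters = c("r", "R0"))
  expect_equal(pw$p, pw2$p)
})
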