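---
title: "Methods: age-stage two-sex life tables, bootstrap inference and diet clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-stage two-sex life tables, bootstrap inference and diet clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifetab)
```

## The demographic model and its census conventions

`lifetab` implements cohort demography in the age-stage, two-sex framework:
every individual of an initial cohort of `n0` eggs is followed daily until
death, through the ordered stages egg, larva, prepupa, pupa and (split by
sex) adult. Keeping males and preadult deaths in the accounting — rather
than building a female-only table — makes the net reproductive rate obey
the exact identity `R0 = (N_ovipositing_females / n0) × mean lifetime
fecundity`, which the test suite asserts on every simulated cohort.

Conventions that fix all downstream arithmetic:

- **Ages are whole days; age 0 is the day the egg is laid.** The census is
  once daily. Stage durations are whole numbers of daily censuses, so an
  individual occupies stage `j` for exactly `*_days` censuses and the
  survivorship of a record that died in a stage ends after the recorded
  days in that stage. Half-day egg scoring (from twice-daily inspection
  protocols) is not representable; such data must be rounded before import,
  and we deliberately do not guess a half-day convention.
- **Fecundity is recorded against the female's adult age** (adult day 1 is
  the first day after eclosion) and converted internally to cohort age
  `eclosion_age + adult_day − 1`. Oviposition is observed in adult
  containers, so adult age is the natural key for the raw data.
- `s_xj` is a proportion of the *initial* cohort, so `Σ_j s_xj = l_x` is
  non-increasing and `s_{0,egg} = 1` by construction.
- At ages past the last survivor the fecundity formula is 0/0; `m_x` is
  defined as 0 there.

## The Euler–Lotka solver

The intrinsic rate solves `g(r) = Σ_x e^(−r(x+1)) l_x m_x − 1 = 0`, with
the exponent `x + 1` — the convention of the age-stage two-sex literature
in which reproduction at age `x` is credited at the end of day `x`. `g` is
strictly decreasing and convex wherever any `l_x m_x > 0`, so the root is
unique.

Two implementations exist on purpose:

- the scalar path (`solve_intrinsic_rate()`) uses bisection on an initial
  bracket `r ∈ [−2, 5]` day⁻¹, expanded geometrically if `g` does not
  change sign there, to a bracket width of 1e−12 (≤ 200 iterations). The
  residual `|g(r̂)|` is reported and must be below 1e−10.
- the bootstrap path (`solve_rate_many()`) runs safeguarded Newton from
  `r = 0`, vectorised across all replicates. On this convex decreasing
  function Newton converges globally (monotonically after at most one
  overshoot), reaching machine precision in a handful of iterations, which
  is what makes 100,000-replicate bootstraps tractable.

Both are checked against a brute-force grid scan (1e−6 steps around the
sign change) and against each other. If `R0 = 0` the rates are reported as
undefined (`NA`), never fabricated; if `R0 = 1`, `r = 0` and `T` has no
value under the ratio definition `T = ln(R0)/r`.

A caveat the package deliberately embraces: `λ = e^r` and `T = ln(R0)/r`
are asserted on the package's *own point estimates* only. Published tables
of bootstrap means generally do not satisfy these identities, because the
mean of a ratio is not the ratio of means.

## Life-history statistics

Stage-period means are taken over individuals that *completed* the stage
(advanced beyond it); development time over individuals reaching adulthood;
preadult survival is `N_adults / n0`. APOP is the first laying day in adult
age; TPOP defaults to development time + APOP (origin at age 0, the day the
egg was laid) with a `tpop_origin = "hatching"` switch that subtracts the
egg period — field usage is inconsistent about the origin, so it is a
config choice rather than a silent assumption. The oviposition period
defaults to the inclusive first-to-last laying-day span; a count-of-laying-
days alternative is available (`oviposition = "days"`). Statistics over
empty subsets (no males, no ovipositing female) are reported absent with
`n = 0`, never as 0. The `se` column of `life_history_summary()` is the
descriptive sample SE (`sd/√n`); inferential SEs are the bootstrap's job.

## Bootstrap design

- **The resampling unit is the whole individual record** with its daily
  fecundity, never single days: the life table is a functional of
  individuals, and day-level resampling would destroy the within-individual
  schedule structure.
- The study-scale default is `B = 100,000`; the test suite and examples
  use `B` in the hundreds to thousands with fixed seeds.
- **Degenerate replicates** (no reproducing female, hence `R0 = 0` and no
  `r`, `λ`, `T`) are recorded as `NA`, excluded from SE/CI/tests, counted
  per parameter, and flagged with a warning when they exceed 1% of
  replicates. How the original screening software handled them is
  undocumented; exclusion-with-accounting is our choice.
- The **paired-bootstrap test** pairs the b-th replicates of two
  independently bootstrapped cohorts and uses the two-sided percentile
  p-value `2·min(#{Δ≤0}, #{Δ≥0})/B_defined`, clipped to
  `[2/B_defined, 1]`. Whether the original implementations pair or pool
  replicates is not documented; pairing by index is recorded here as this
  package's convention. Comparisons with fewer than 30 jointly defined
  replicates are flagged unreliable. Under the null (the same cohort
  bootstrapped twice) the replicate differences are symmetric around zero,
  so p sits near 1 — the test is conservative there, which the acceptance
  suite checks over 100 seed pairs.
- No multiplicity adjustment is applied across the pairwise tests,
  matching standard practice in this screening literature.

**Compact letter displays** use insert-and-absorb: one group of all
treatments is split on each significant pair and subset groups are
absorbed. The surviving groups are exactly the maximal cliques of the
non-significance graph, so two treatments share a letter *iff* their
comparison is non-significant; the tests verify this against exhaustive
clique enumeration for up to six treatments. Letters are ordered by the
point estimates, "a" marking the group containing the largest.

## Enzyme statistics

Normality is checked (and only logged) via Shapiro–Wilk; the ANOVA is the
classical one-way between/within decomposition and Tukey HSD supplies
studentized-range pairwise p-values. Letters default to α = 0.01 for
enzymes and α = 0.05 for bootstrap comparisons — the conventional pairing
of levels in this literature. Each enzyme is analysed separately.

## Clustering

Features (default `GRR, R0, r, λ, T, SOD, POD, CAT`; configurable) are
z-scored before Ward clustering. The sources are silent on scaling, but raw
scales differ by four orders of magnitude (`λ ≈ 1` vs `GRR` in the
hundreds), and unscaled Ward would simply sort by `GRR`. Agglomeration uses
the ward.D2 convention (Lance–Williams on squared Euclidean distances,
heights on the distance scale, so `height²/2` is the within-cluster
sum-of-squares increase); constant feature columns are rejected. The
"two-step cluster" phrasing that sometimes accompanies Ward analyses in
SPSS workflows is ambiguous, so only Ward agglomeration is implemented, and
reproducing any particular published four-group membership is treated as a
qualitative observation, not an asserted property. Newick export is
ultrametric with node depths equal to merge heights; the round trip is
tested through an independent parser (`ape`).

## The synthetic cohort generator

Raw per-individual rearing records for the motivating screening are not
published, so the generator is the package's source of ground-truthed test
data. Per egg it draws: stage-by-stage survival (an individual failing a
stage dies after a uniform number of that stage's days), discretised gamma
stage durations (rounded to whole days, floor 1 — the census is daily), sex
at eclosion, adult longevity by sex, and for females an APOP, an
oviposition period and a negative-binomial lifetime egg total allocated
multinomially across laying days under a uniform or triangular (peak at
one-third of the period) shape, truncated at the drawn longevity.

Defaults describe a mid-range seed-diet rearing (50-egg cohort, ~37-day
development, ~55% preadult survival, a few hundred eggs per female);
`config_mohajer_like()` and `config_jiroft_like()` encode the suitable and
resistant extremes of the reference screening, parameterised from its
published stage means, survival, fecundity and longevity values. One
consequence worth knowing: the generator's demography satisfies
`T = ln(R0)/r` exactly, while published bootstrap-mean tables need not, so
preset cohorts reproduce the reference R0 and development scale faithfully
but can sit slightly above a published `r` whose printed `T` is
inconsistent with its own `R0`.

For configurations in the **analytic subset** — every distribution fixed
and a one-day oviposition period — `analytic_expectations()` computes the
exact expected `l_x` and `m_x` (the survival curve declines linearly within
a dying stage, matching the uniform day-of-death draw) and hence exact
ground-truth parameters. Recovery tests simulate 5,000-egg cohorts against
this oracle; the acceptance suite requires `r` recovered within 0.002 in at
least 95% of 20 seeds.

What the generator does *not* emulate: density dependence, temperature-
dependent development, within-day event timing, mating failure, and
correlations between development speed and subsequent fecundity. Passing
tests therefore demonstrate the correctness of the estimators under the
stated sampling model, not the biological realism of any particular diet.

## Problem sizes and numerical tolerances

The test suite runs at deliberately scaled sizes chosen to keep Monte-Carlo
error well inside the asserted bounds: bootstrap checks at `B` = 200–4,000
(closed-form two-record SE `1/√2` within 0.05), null paired tests over 100
seed pairs at `B = 2,000`, identity checks over 100 simulated 30-egg
cohorts, recovery at 20 × 5,000 eggs, solver-versus-grid agreement within
1e−5 over 50 random schedules, Euler–Lotka residuals below 1e−10, Ward
against an O(n³) oracle at n = 6, and binomial 3-SE bands for the 200,000-
individual oracle comparison. Degenerate inputs (empty subsets, constant
samples, `R0 ≤ 0`, constant features) error or report absence explicitly
rather than producing numbers.

## Known limitations

- Age-stage life expectancy `e_xj` and reproductive value `v_xj` are out of
  scope, as are projection and timing applications.
- Percentile CIs only; no BCa or studentized intervals.
- The pipeline's run log records stage timings, so it is the one output
  file that is not byte-identical across reruns; all CSVs and the Newick
  export are.
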