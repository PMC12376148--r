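# Reference summary values from a published screening of Helicoverpa
# armigera reared on meridic diets of ten sesame cultivars.  Shipped as
# plain CSVs under extdata; the raw rearing records behind them are not
# public, which is why the package carries a synthetic cohort generator.

#' Reference demographic parameters for ten sesame cultivar diets
#'
#' Published cohort-level point estimates (bootstrap means) of GRR, R0, r,
#' lambda and T for *H. armigera* on ten sesame seed-based diets.  The
#' `r_4dp` column carries the four-decimal extremes of r reported for the
#' most and least suitable diets (Barekat and Jiroft); other entries are
#' printed at three decimals.  Useful as clustering input and as a sanity
#' anchor for `finite_rate()`.
#'
#' @return Data frame with columns `treatment`, `GRR`, `R0`, `r`, `lambda`,
#'   `T`, `r_4dp`.
#' @export
sesame_reference_params <- function() {
  utils::read.csv(system.file("extdata", "sesame_life_table_params.csv",
                              package = "lifetab"),
                  stringsAsFactors = FALSE)
}

#' Reference antioxidant enzyme activities for ten sesame cultivar diets
#'
#' Published group means and standard errors (n = 3 replicates) of SOD, POD
#' and CAT activity (U per mg protein) of fifth-instar *H. armigera* larvae
#' on ten sesame seed-based diets.  Replicate-level data are not public;
#' [simulate_enzyme_replicates()] reconstructs matched synthetic replicate
#' tables from these values.
#'
#' @return Data frame with columns `enzyme`, `treatment`, `mean`, `se`.
#' @export
sesame_reference_enzymes <- function() {
  utils::read.csv(system.file("extdata", "sesame_enzyme_activity.csv",
                              package = "lifetab"),
                  stringsAsFactors = FALSE)
}
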