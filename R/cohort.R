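# Cohort life-history data: construction, reading, validation, writing.

#' Stage labels used throughout the package
#'
#' The age-stage matrix distinguishes k = 6 stages in fixed order:
#' egg, larva, prepupa, pupa, female adult, male adult.
#'
#' @format Character vector of length 6.
#' @export
LIFETAB_STAGES <- c("egg", "larva", "prepupa", "pupa", "female", "male")

# stages an individual can die in (adults are not split by sex here)
DEATH_STAGES <- c("egg", "larva", "prepupa", "pupa", "adult")
DURATION_COLS <- c("egg_days", "larva_days", "prepupa_days", "pupa_days")

INDIVIDUAL_COLS <- c("id", "treatment", DURATION_COLS,
                     "death_stage", "sex", "adult_longevity_days")
FECUNDITY_COLS <- c("id", "adult_day", "eggs")

#' Construct a cohort from individual and fecundity tables
#'
#' A cohort is one treatment's set of individual life-history records: a
#' group of same-aged eggs followed daily until the last death.  The initial
#' cohort size `n0` is the number of records; every started egg must be a
#' record, including those that die as eggs.
#'
#' @param individuals Data frame with columns `id`, `treatment`, `egg_days`,
#'   `larva_days`, `prepupa_days`, `pupa_days` (whole days spent in each
#'   stage, `NA` beyond the stage of death), `death_stage` (one of
#'   `"egg"`, `"larva"`, `"prepupa"`, `"pupa"`, `"adult"`), `sex`
#'   (`"F"`, `"M"`, or `"unknown"` for preadult deaths) and
#'   `adult_longevity_days` (days alive as an adult; `NA` unless
#'   `death_stage == "adult"`).
#' @param fecundity Data frame with columns `id`, `adult_day` (day 1 is the
#'   first day after eclosion) and `eggs`; may be `NULL` or empty for
#'   cohorts without oviposition records.
#' @param treatment Treatment label; defaults to the label shared by the
#'   records.
#' @param check If `TRUE` (default) the cohort is validated and invalid
#'   data raise an error.
#' @return An object of class `"cohort"`: a list with elements `treatment`,
#'   `individuals`, `fecundity` and `n0`.
#' @seealso [read_cohort()], [validate_cohort()]
#' @export
new_cohort <- function(individuals, fecundity = NULL, treatment = NULL,
                       check = TRUE) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  missing_cols <- setdiff(INDIVIDUAL_COLS, names(individuals))
  if (length(missing_cols) > 0) {
    stop("individuals table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(fecundity) || nrow(as.data.frame(fecundity)) == 0) {
    fecundity <- data.frame(id = character(), adult_day = integer(),
                            eggs = integer(), stringsAsFactors = FALSE)
  } else {
    fecundity <- as.data.frame(fecundity, stringsAsFactors = FALSE)
    missing_cols <- setdiff(FECUNDITY_COLS, names(fecundity))
    if (length(missing_cols) > 0) {
      stop("fecundity table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
  }
  individuals$id <- as.character(individuals$id)
  fecundity$id <- as.character(fecundity$id)
  if (anyDuplicated(individuals$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(individuals$id[duplicated(individuals$id)]),
               collapse = ", "))
  }
  unknown <- setdiff(fecundity$id, individuals$id)
  if (length(unknown) > 0) {
    stop("fecundity rows reference unknown id(s): ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(treatment)) {
    treatment <- unique(as.character(individuals$treatment))
    if (length(treatment) > 1) {
      stop("records carry more than one treatment label: ",
           paste(treatment, collapse = ", "))
    }
    if (length(treatment) == 0) treatment <- NA_character_
  }
  obj <- structure(
    list(treatment = treatment,
         individuals = individuals,
         fecundity = fecundity,
         n0 = nrow(individuals)),
    class = "cohort")
  if (check) {
    report <- validate_cohort(obj)
    if (nrow(report) > 0) {
      stop("invalid cohort (", nrow(report), " violation(s)); first: id '",
           report$id[1], "', rule '", report$rule[1], "': ",
           report$message[1])
    }
  }
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", x$treatment, "\n")
  cat("  n0 =", x$n0, "records;",
      sum(x$individuals$death_stage == "adult"), "reached adulthood;",
      nrow(x$fecundity), "daily fecundity rows\n")
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' Reads the per-individual life-history table and (optionally) the daily
#' fecundity table, joins them by `id`, and returns a validated [new_cohort()]
#' object.  Files are comma-separated UTF-8 with a mandatory header; blank
#' cells are `NA`.
#'
#' @param individuals_path Path to `individuals.csv` (see [new_cohort()] for
#'   the column schema).
#' @param fecundity_path Path to `fecundity.csv` with columns `id`,
#'   `adult_day`, `eggs`; `NULL` means no oviposition was recorded
#'   (all-zero fecundity).
#' @return A validated `"cohort"` object.
#' @export
read_cohort <- function(individuals_path, fecundity_path = NULL) {
  if (!file.exists(individuals_path)) {
    stop("individuals file not found: ", individuals_path)
  }
  # sex codes "F"/"M" must never be parsed as logicals
  ind <- utils::read.csv(individuals_path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""),
                         colClasses = c(id = "character",
                                        treatment = "character",
                                        death_stage = "character",
                                        sex = "character"))
  missing_cols <- setdiff(INDIVIDUAL_COLS, names(ind))
  if (length(missing_cols) > 0) {
    stop("individuals file ", individuals_path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- c(DURATION_COLS, "adult_longevity_days")
  for (col in num_cols) {
    bad <- which(!is.na(ind[[col]]) & ind[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative value in column '", col, "' at data row ", bad[1],
           " (id '", ind$id[bad[1]], "') of ", individuals_path)
    }
  }
  fec <- NULL
  if (!is.null(fecundity_path)) {
    if (!file.exists(fecundity_path)) {
      stop("fecundity file not found: ", fecundity_path)
    }
    fec <- utils::read.csv(fecundity_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""),
                           colClasses = c(id = "character"))
    missing_cols <- setdiff(FECUNDITY_COLS, names(fec))
    if (length(missing_cols) > 0) {
      stop("fecundity file ", fecundity_path, " is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
  }
  new_cohort(ind, fec)
}

#' Validate a cohort against the life-history record invariants
#'
#' Checks every record for internal consistency: stage durations present
#' exactly for the stages entered (and at least one day each), valid
#' `death_stage` and `sex` codes, `sex == "unknown"` only for preadult
#' deaths, `adult_longevity_days` present iff the individual reached
#' adulthood, fecundity restricted to adult females with laying days between
#' 1 and the adult longevity, and non-negative integer counts throughout.
#' Violations are returned as data, not raised as errors.
#'
#' @param cohort A `"cohort"` object (checked or unchecked).
#' @return Data frame with columns `id`, `rule` and `message`; zero rows iff
#'   the cohort satisfies all invariants.  The function is pure.
#' @export
validate_cohort <- function(cohort) {
  ind <- cohort$individuals
  fec <- cohort$fecundity
  viol <- list()
  add <- function(id, rule, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      id = id, rule = rule, message = message, stringsAsFactors = FALSE)
  }
  if (cohort$n0 != nrow(ind)) {
    add(NA_character_, "n0_matches_records",
        sprintf("n0 = %d but %d records", cohort$n0, nrow(ind)))
  }
  for (i in seq_len(nrow(ind))) {
    r <- ind[i, ]
    id <- r$id
    if (!r$death_stage %in% DEATH_STAGES) {
      add(id, "death_stage_valid",
          paste0("unknown death_stage '", r$death_stage, "'"))
      next
    }
    if (!identical(as.character(r$treatment), as.character(cohort$treatment))) {
      add(id, "treatment_consistent",
          paste0("treatment '", r$treatment, "' differs from cohort label '",
                 cohort$treatment, "'"))
    }
    d_idx <- match(r$death_stage, DEATH_STAGES)
    n_entered <- min(d_idx, 4L)  # preadult stages entered
    durs <- unlist(r[DURATION_COLS])
    for (j in seq_len(4L)) {
      if (j <= n_entered) {
        if (is.na(durs[j])) {
          add(id, "duration_present",
              paste0(DURATION_COLS[j], " absent for a stage that was entered"))
        } else if (durs[j] < 1 || durs[j] != round(durs[j])) {
          add(id, "duration_positive_integer",
              paste0(DURATION_COLS[j], " = ", durs[j],
                     " is not a whole number of days >= 1"))
        }
      } else if (!is.na(durs[j])) {
        add(id, "duration_beyond_death",
            paste0(DURATION_COLS[j], " present beyond death stage '",
                   r$death_stage, "'"))
      }
    }
    is_adult <- r$death_stage == "adult"
    if (is_adult) {
      if (is.na(r$adult_longevity_days)) {
        add(id, "longevity_present", "adult without adult_longevity_days")
      } else if (r$adult_longevity_days < 0 ||
                 r$adult_longevity_days != round(r$adult_longevity_days)) {
        add(id, "longevity_nonnegative_integer",
            paste0("adult_longevity_days = ", r$adult_longevity_days))
      }
      if (!r$sex %in% c("F", "M")) {
        add(id, "adult_sex_known",
            paste0("adult with sex '", r$sex, "' (must be F or M)"))
      }
    } else {
      if (!is.na(r$adult_longevity_days)) {
        add(id, "longevity_absent",
            "adult_longevity_days present for a preadult death")
      }
      if (!r$sex %in% c("F", "M", "unknown")) {
        add(id, "sex_valid", paste0("unknown sex code '", r$sex, "'"))
      }
    }
  }
  if (nrow(fec) > 0) {
    by_id <- split(fec, fec$id)
    for (id in names(by_id)) {
      fr <- by_id[[id]]
      i <- match(id, ind$id)
      if (is.na(i)) {
        add(id, "fecundity_known_id", "fecundity for unknown id")
        next
      }
      r <- ind[i, ]
      if (r$death_stage != "adult" || !identical(r$sex, "F")) {
        add(id, "fecundity_female_adult_only",
            paste0("fecundity recorded for ", r$sex, " ", r$death_stage,
                   " (only adult females lay)"))
      }
      if (anyDuplicated(fr$adult_day)) {
        add(id, "fecundity_day_unique", "duplicated adult_day")
      }
      if (any(is.na(fr$adult_day)) || any(fr$adult_day < 1) ||
          any(fr$adult_day != round(fr$adult_day))) {
        add(id, "fecundity_day_positive_integer",
            "adult_day must be a whole day >= 1")
      } else if (!is.na(r$adult_longevity_days) &&
                 any(fr$adult_day > r$adult_longevity_days)) {
        add(id, "fecundity_within_longevity",
            paste0("laying day ", max(fr$adult_day),
                   " beyond adult longevity ", r$adult_longevity_days))
      }
      if (any(is.na(fr$eggs)) || any(fr$eggs < 0)) {
        add(id, "eggs_nonnegative", "egg counts must be >= 0")
      }
    }
  }
  if (length(viol) == 0) {
    return(data.frame(id = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}

#' Write a cohort back to the CSV schema
#'
#' Inverse of [read_cohort()]: reading the written files yields a cohort
#' equal field-by-field to the input.
#'
#' @param cohort A `"cohort"` object.
#' @param individuals_path,fecundity_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, individuals_path, fecundity_path) {
  utils::write.csv(cohort$individuals, individuals_path,
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$fecundity, fecundity_path,
                   row.names = FALSE, na = "")
  invisible(c(individuals_path, fecundity_path))
}

#' Write a bundle of result tables as CSV files
#'
#' Writes each table present in a result bundle (as produced by
#' [run_pipeline()]) to `out_dir`: `summary_life_history.csv`,
#' `demographic_params.csv`, `schedules.csv` (long format: treatment, age,
#' lx, mx), `pairwise_tests.csv`, `letters.csv`, `enzyme_anova.csv`,
#' `clusters.csv` and `dendrogram.nwk`.  Re-running with identical inputs
#' and seed produces byte-identical files.
#'
#' @param results Named list of data frames (and optionally a `newick`
#'   string); unknown names are ignored.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  files <- c(summary = "summary_life_history.csv",
             params = "demographic_params.csv",
             schedules = "schedules.csv",
             pairwise = "pairwise_tests.csv",
             letters = "letters.csv",
             enzyme_anova = "enzyme_anova.csv",
             clusters = "clusters.csv")
  written <- character()
  for (nm in names(files)) {
    tab <- results[[nm]]
    if (is.null(tab)) next
    path <- file.path(out_dir, files[[nm]])
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
    written <- c(written, path)
  }
  if (!is.null(results$newick)) {
    path <- file.path(out_dir, "dendrogram.nwk")
    writeLines(results$newick, path)
    written <- c(written, path)
  }
  invisible(written)
}
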