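# Normality check, one-way ANOVA and Tukey HSD for enzyme-activity
# replicate tables (activities in U per mg protein, k treatments with
# >= 2 replicates each).

#' Shapiro-Wilk normality check
#'
#' Thin, logged wrapper around [stats::shapiro.test()].  The result is
#' reported, never used to silently switch methods downstream.
#'
#' @param values Numeric sample, 3 <= n <= 5000, not all equal.
#' @return List with `W` and `p`.
#' @export
shapiro_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 values")
  if (diff(range(values)) == 0) stop("constant sample: normality undefined")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = unname(st$p.value))
}

check_groups <- function(data, response, group) {
  if (!all(c(response, group) %in% names(data))) {
    stop("data must have columns '", group, "' and '", response, "'")
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  tab <- table(data[[group]])
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) {
    stop("every group needs n >= 2 replicates; offending group(s): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  data
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition via
#' [stats::aov()], with the p-value from the F distribution on
#' (k-1, N-k) degrees of freedom.
#'
#' @param data Data frame of replicate measurements.
#' @param response,group Column names (defaults `"activity"` and
#'   `"treatment"` to match the enzyme table schema).
#' @return Object of class `"anova_result"`: list with `F`, `df_between`,
#'   `df_within`, `p` and `groups` (data frame of per-group n, mean, se).
#' @export
one_way_anova <- function(data, response = "activity", group = "treatment") {
  data <- check_groups(data, response, group)
  data[[group]] <- factor(data[[group]])
  fit <- stats::aov(stats::reformulate(group, response), data = data)
  tab <- summary(fit)[[1]]
  gstats <- do.call(rbind, lapply(split(data[[response]], data[[group]]),
    function(v) data.frame(n = length(v), mean = mean(v),
                           se = stats::sd(v) / sqrt(length(v)))))
  gstats <- data.frame(treatment = rownames(gstats), gstats,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(F = tab[1, "F value"],
                 df_between = tab[1, "Df"],
                 df_within = tab[2, "Df"],
                 p = tab[1, "Pr(>F)"],
                 groups = gstats,
                 fit = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$groups)
  invisible(x)
}

#' Tukey HSD pairwise comparisons with letters
#'
#' Studentized-range pairwise p-values via [stats::TukeyHSD()] on the
#' one-way fit, plus a compact letter display at `alpha` (default 0.01, the
#' conventional level for enzyme-activity comparisons here; bootstrap
#' letters for life-table statistics use 0.05).
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the letters.
#' @return List of class `"tukey_result"` with `p` (symmetric matrix, unit
#'   diagonal), `letters` (a `"letter_display"`), `alpha` and `anova` (the
#'   underlying `"anova_result"`).
#' @export
tukey_hsd <- function(data, alpha = 0.01, response = "activity",
                      group = "treatment") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ares <- one_way_anova(data, response, group)
  tk <- stats::TukeyHSD(ares$fit)[[group]]
  trts <- ares$groups$treatment
  pm <- matrix(1, length(trts), length(trts), dimnames = list(trts, trts))
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_len(nrow(tk))) {
    a <- pair_names[[i]][1]; b <- pair_names[[i]][2]
    pm[a, b] <- pm[b, a] <- tk[i, "p adj"]
  }
  est <- stats::setNames(ares$groups$mean, trts)
  cld <- compact_letter_display(pm < alpha, est, alpha)
  structure(list(p = pm, letters = cld, alpha = alpha, anova = ares),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  print(x$anova)
  print(x$letters)
  invisible(x)
}
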