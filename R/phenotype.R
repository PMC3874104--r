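# Mendelian segregation, penetrance, survival and morphometric
# group-comparison statistics for knockout strain characterization.

mendelian_proportions <- function(cross_type) {
  switch(cross_type,
         autosomal_het_x_het = c("+/+" = 0.25, "+/-" = 0.5, "-/-" = 0.25),
         xlinked_hetfemale_x_wtmale = c("F+/+" = 0.25, "F+/-" = 0.25,
                                        "M+/Y" = 0.25, "M-/Y" = 0.25),
         hom_x_hom = c("-/-" = 1),
         stop("unknown cross_type: ", cross_type))
}

#' Expected Mendelian genotype counts
#'
#' Expected (unrounded) class counts for a genotyped total: 1:2:1 for an
#' autosomal heterozygote intercross, uniform quarters over female
#' carriers/non-carriers and hemizygous males for an X-linked
#' carrier-female x wild-type-male cross. Arbitrary designs can be passed
#' as a named proportion vector.
#'
#' @param total Number of genotyped animals.
#' @param cross_type A preset name (see [gen_cross_counts()]) or a named
#'   numeric vector of class proportions summing to 1.
#' @return Named numeric vector of expected counts.
#' @examples
#' expected_mendelian(128)  # c(32, 64, 32)
#' @export
expected_mendelian <- function(total, cross_type = "autosomal_het_x_het") {
  stopifnot(total >= 1)
  props <- if (is.numeric(cross_type)) {
    if (is.null(names(cross_type)) || abs(sum(cross_type) - 1) > 1e-8) {
      stop("custom proportions must be named and sum to 1")
    }
    cross_type
  } else {
    mendelian_proportions(cross_type)
  }
  props * total
}

#' Chi-square goodness-of-fit test of genotype counts
#'
#' `statistic = sum((obs - exp)^2 / exp)` with `df = classes - 1` and the
#' p-value from the upper tail of the chi-square distribution.
#'
#' @param observed Named or unnamed vector of observed class counts.
#' @param expected Expected counts, same classes (all > 0).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_goodness <- function(observed, expected) {
  if (length(observed) != length(expected)) stop("class sets differ in length")
  if (!is.null(names(observed)) && !is.null(names(expected)) &&
      !identical(names(observed), names(expected))) {
    stop("class names differ between observed and expected")
  }
  if (any(expected <= 0)) stop("expected count of zero (or less) in a class")
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = statistic, df = df,
       p = pchisq(statistic, df, lower.tail = FALSE))
}

#' Penetrance of a lethal phenotype
#'
#' The fraction of expected null homozygotes missing at the census:
#' `max(0, 1 - observed / expected)`, clamped at zero because sampling
#' noise can push the observed count above the expectation. The result
#' carries a `percent` attribute rounded to the nearest integer, matching
#' the reporting convention for penetrance figures.
#'
#' @param observed_hom Observed homozygote count.
#' @param expected_hom Expected homozygote count (> 0), e.g. from
#'   [expected_mendelian()].
#' @return Fraction in `[0, 1]` with attribute `percent`.
#' @examples
#' penetrance_of_lethality(6, 17)   # 0.647 -> 65%
#' @export
penetrance_of_lethality <- function(observed_hom, expected_hom) {
  if (expected_hom <= 0) stop("expected_hom must be positive")
  if (observed_hom < 0) stop("observed_hom must be non-negative")
  pen <- max(0, 1 - observed_hom / expected_hom)
  structure(pen, percent = round(100 * pen))
}

#' Estimate lethality penetrance from cross counts
#'
#' Unlike [penetrance_of_lethality()] applied to the paper-style
#' expectation (genotyped total x Mendelian proportion), which is biased
#' downward under lethality because deaths shrink the observed total, this
#' estimator scales the unaffected classes: for an autosomal intercross
#' the expected homozygote count is `(wt + het) / 3`, and for the X-linked
#' cross the mean of the three unaffected classes. The estimate is
#' consistent for the generating penetrance of [gen_cross_counts()].
#'
#' @param counts Named count vector as from [gen_cross_counts()].
#' @param cross_type Cross design (defaulted from the counts' attribute).
#' @return Estimated penetrance in `[0, 1]` with attribute `percent`.
#' @export
estimate_penetrance <- function(counts,
                                cross_type = attr(counts, "cross_type")) {
  props <- mendelian_proportions(cross_type)
  lethal_class <- switch(cross_type,
                         autosomal_het_x_het = "-/-",
                         xlinked_hetfemale_x_wtmale = "M-/Y",
                         stop("no unaffected reference classes for ", cross_type))
  other <- setdiff(names(props), lethal_class)
  expected_hom <- sum(counts[other]) *
    props[[lethal_class]] / sum(props[other])
  penetrance_of_lethality(counts[[lethal_class]], expected_hom)
}

#' Survival proportion
#'
#' `100 * deaths / at_risk`, reported raw with a rounded `percent`
#' attribute.
#'
#' @param deaths Number of deaths.
#' @param at_risk Number at risk (>= 1).
#' @return Percent (raw) with attribute `percent` (nearest integer).
#' @examples
#' survival_proportion(11, 21)  # 52.38 -> 52%
#' @export
survival_proportion <- function(deaths, at_risk) {
  stopifnot(at_risk >= 1)
  if (deaths < 0 || deaths > at_risk) stop("need 0 <= deaths <= at_risk")
  pct <- 100 * deaths / at_risk
  structure(pct, percent = round(pct))
}

#' Per-group mean and standard error
#'
#' SEM uses the sample standard deviation (n - 1 denominator).
#'
#' @param values data.frame with columns `group`, `value` (as produced by
#'   [gen_morphometry()]), or a named list of numeric vectors.
#' @return data.frame with `group`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values) {
  groups <- if (is.data.frame(values)) {
    split(values$value, values$group)
  } else {
    values
  }
  if (any(lengths(groups) < 2L)) stop("every group needs n >= 2")
  data.frame(
    group = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(v) sd(v) / sqrt(length(v)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Unpaired equal-variance (Student) t test
#'
#' Pooled-variance two-sample t statistic with `df = n_A + n_B - 2` and a
#' two-sided p-value. Degenerate inputs follow the conventions: zero
#' pooled variance with equal means gives `t = 0, p = 1`; zero pooled
#' variance with unequal means gives an infinite t and `p = 0`.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return List with `t`, `df`, `p`.
#' @examples
#' ttest_equal_var(c(1, 2, 3), c(2, 3, 4))
#' @export
ttest_equal_var <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  df <- na + nb - 2L
  pooled <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / df
  delta <- mean(group_a) - mean(group_b)
  if (pooled == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  t <- delta / sqrt(pooled * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Signed percent change between two group means
#'
#' `100 * (mean_test - mean_reference) / mean_reference`; morphometric
#' percent changes are conventionally reported to two decimals, which is
#' the default rounding (`digits = NULL` returns the raw value).
#'
#' @param mean_test,mean_reference Group means (`mean_reference != 0`).
#' @param digits Decimal places for the report, or `NULL` for no
#'   rounding.
#' @return Signed percent.
#' @examples
#' percent_change(1432, 1176)  # +21.77
#' @export
percent_change <- function(mean_test, mean_reference, digits = 2) {
  if (mean_reference == 0) stop("reference mean must be non-zero")
  pct <- 100 * (mean_test - mean_reference) / mean_reference
  if (is.null(digits)) pct else round(pct, digits)
}
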