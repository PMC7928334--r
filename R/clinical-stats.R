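#' Clinical correlation with Bonferroni control
#'
#' Pearson correlation between a per-subject imaging feature (e.g. mean
#' z-dALFF over a significant cluster) and a clinical covariate, with the
#' two-tailed p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom, Bonferroni-corrected over `n_tests` comparisons.
#'
#' @param features Numeric vector, one value per subject.
#' @param covariate Numeric vector, paired with `features`.
#' @param n_tests Bonferroni family size (default 1).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A one-row tibble: `r`, `n`, `p_two_tailed`, `n_tests`,
#'   `significant`.
#' @export
correlate_clinical <- function(features, covariate, n_tests = 1,
                               alpha = 0.05) {
  ok <- is.finite(features) & is.finite(covariate)
  x <- features[ok]; y <- covariate[ok]
  n <- length(x)
  if (n < 4L) stop("Need >= 4 paired finite values, got ", n, ".",
                   call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Zero variance in features or covariate.", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    r = unname(ct$estimate), n = n, p_two_tailed = ct$p.value,
    n_tests = n_tests, significant = ct$p.value < alpha / n_tests
  )
}

#' Pooled two-sample t-test from summary statistics
#'
#' Reconstructs the pooled-variance two-sample t-test from per-group mean,
#' SD and n (as printed in a demographics table).
#'
#' @param mean_a,sd_a,n_a First group's moments.
#' @param mean_b,sd_b,n_b Second group's moments.
#' @return A one-row tibble: `t`, `df`, `p_two_tailed`.
#' @export
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("Each group needs n >= 2.", call. = FALSE)
  if (sd_a < 0 || sd_b < 0) stop("SDs must be >= 0.", call. = FALSE)
  df <- n_a + n_b - 2
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df)
  t <- (mean_a - mean_b) / (sp * sqrt(1 / n_a + 1 / n_b))
  tibble::tibble(t = t, df = df, p_two_tailed = 2 * stats::pt(-abs(t), df))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p: the sum of hypergeometric probabilities, over tables
#' with the observed margins, no more probable than the observed table.
#' Used for the group-by-sex contingency comparison.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("Need a 2x2 table.", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("Counts must be non-negative integers.", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("All margins must be positive.", call. = FALSE)
  }
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Demographic summary comparison table
#'
#' Given a cohort covariate tibble, reproduces the standard demographics
#' comparisons: pooled t on age, Fisher's exact on sex.
#'
#' @param covariates Tibble with `group`, `age`, `sex` columns.
#' @return Tibble with one row per comparison: `measure`, `statistic`,
#'   `p_value`.
#' @export
demographics_table <- function(covariates) {
  pa <- covariates[covariates$group == "patient", ]
  co <- covariates[covariates$group == "control", ]
  age <- t_test_from_summary(mean(pa$age), stats::sd(pa$age), nrow(pa),
                             mean(co$age), stats::sd(co$age), nrow(co))
  sex_tab <- rbind(patient = table(factor(pa$sex, c("female", "male"))),
                   control = table(factor(co$sex, c("female", "male"))))
  sex_p <- if (any(rowSums(sex_tab) == 0) || any(colSums(sex_tab) == 0)) {
    NA_real_  # a sex absent from the sample: test undefined
  } else {
    fisher_exact_2x2(sex_tab)
  }
  tibble::tibble(
    measure = c("age", "sex"),
    statistic = c(age$t, NA_real_),
    p_value = c(age$p_two_tailed, sex_p)
  )
}
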