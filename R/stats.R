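#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with the exact null distribution (full
#' enumeration) when the pooled sample is small (n1 + n2 <= 12) and
#' tie-free, and the normal approximation with midranks, tie correction and
#' continuity correction otherwise. The reported statistic is the rank sum
#' of the first sample.
#'
#' @param x,y numeric samples (n1, n2 >= 1).
#' @param alternative "two.sided" (default), "greater" (x tends larger) or
#'   "less".
#' @return a list with \code{statistic} (rank sum of x), \code{p_value},
#'   \code{alternative}, \code{n1}, \code{n2}, \code{exact}.
#' @export
rankSumTest <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2 <= 12L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  W <- unname(wt$statistic)            # Mann-Whitney U of x
  list(statistic = W + n1 * (n1 + 1) / 2,
       p_value = unname(wt$p.value),
       alternative = alternative, n1 = n1, n2 = n2, exact = exact)
}

#' Cohort demographics summary
#'
#' Group sizes, sex counts, and the age mean and sample standard deviation
#' (n - 1 denominator; NA for a single subject).
#'
#' @param subjects data.frame with columns \code{sex} and \code{age}, and
#'   optionally \code{group}.
#' @return a data.frame with one row per group (single group "all" when no
#'   group column): \code{group}, \code{n}, \code{n_male}, \code{n_female},
#'   \code{age_mean}, \code{age_sd}.
#' @export
cohortDemographics <- function(subjects) {
  stopifnot(all(c("sex", "age") %in% names(subjects)))
  if (is.null(subjects$group)) subjects$group <- "all"
  groups <- unique(subjects$group)
  out <- lapply(groups, function(g) {
    s <- subjects[subjects$group == g, ]
    data.frame(group = g, n = nrow(s),
               n_male = sum(tolower(s$sex) == "male"),
               n_female = sum(tolower(s$sex) == "female"),
               age_mean = mean(s$age),
               age_sd = if (nrow(s) > 1L) sd(s$age) else NA_real_)
  })
  do.call(rbind, out)
}

#' Patient information table from the study
#'
#' The printed patient table shipped with the package: sex, age, imaging
#' diagnosis and the affected (anatomical) side of each of the 8 patients.
#'
#' @return a data.frame.
#' @export
patientInfoTable <- function() {
  read.csv(system.file("extdata", "patient_info.csv", package = "mfeitsym"),
           stringsAsFactors = FALSE)
}

## box-and-whisker summary (median, quartiles, 1.5 IQR whiskers, outliers)
boxplotStats <- function(x) {
  x <- x[!is.na(x)]
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  inl <- x[x >= lo & x <= hi]
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = if (length(inl)) min(inl) else NA_real_,
       whisker_high = if (length(inl)) max(inl) else NA_real_,
       outliers = x[x < lo | x > hi], n = length(x))
}
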