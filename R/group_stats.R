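#' Agreement / correlation result container
#'
#' @param kind one of "spearman", "icc", "bland_altman".
#' @param estimate point estimate (r, ICC, or bias).
#' @param ci length-2 numeric 95\% interval (for Bland-Altman: the limits
#'   of agreement).
#' @param category category label implied by the printed thresholds
#'   (correlation and ICC only).
#' @param ... extra fields stored alongside.
#' @return object of class `agreement_result`.
#' @export
agreement_result <- function(kind, estimate, ci, category = NA_character_,
                             ...) {
  structure(list(kind = kind, estimate = estimate, ci = ci,
                 category = category, ...),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s: estimate = %.3f [%.3f, %.3f]%s\n", x$kind, x$estimate,
              x$ci[1], x$ci[2],
              if (is.na(x$category)) "" else paste0(" (", x$category, ")")))
  invisible(x)
}

# category bins are applied to the estimate rounded to 2 decimals, with
# both printed endpoints included
.bin_category <- function(r, edges, labels) {
  r2 <- round(abs(r), 2)
  labels[findInterval(r2, edges, rightmost.closed = TRUE)]
}

correlation_category <- function(r)
  .bin_category(r, c(0, 0.245, 0.495, 0.745, 1), # <=0.24 | 0.25-0.49 | ...
                c("little or no", "fair", "moderate", "good"))

icc_category <- function(icc)
  .bin_category(icc, c(0, 0.205, 0.405, 0.605, 0.805, 1),
                c("poor", "fair", "moderate", "good", "excellent"))

#' Normality gate
#'
#' Kolmogorov-Smirnov-type normality decision used to route two-group
#' comparisons: a Lilliefors test of the sample against a normal
#' distribution with estimated mean and SD, normal iff p >= 0.05.
#' Degenerate (zero-variance) samples are classed non-normal.
#'
#' @param x numeric sample, n >= 5.
#' @param alpha significance level of the gate (default 0.05).
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) stop("normality gate needs n >= 5")
  if (stats::sd(x) == 0) return("non_normal")
  p <- nortest::lillie.test(x)$p.value
  if (p >= alpha) "normal" else "non_normal"
}

#' Two-group comparison with normality routing
#'
#' Independent-samples t-test if both groups pass [normality_gate()],
#' otherwise a two-sided Mann-Whitney U test.
#'
#' @param x,y numeric samples of the two groups.
#' @return list with `test` ("t" or "mann_whitney"), `statistic` and
#'   two-sided `p`.
#' @export
compare_groups <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  both_normal <- normality_gate(x) == "normal" && normality_gate(y) == "normal"
  if (both_normal) {
    tt <- stats::t.test(x, y)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    list(test = "mann_whitney", statistic = unname(wt$statistic),
         p = wt$p.value)
  }
}

#' Spearman correlation with category label
#'
#' Rank correlation of a paired sample with a Fisher-transform 95\% CI
#' (SE sqrt(1.06/(n-3))) and the category implied by the printed bins:
#' <= 0.24 little or no, 0.25-0.49 fair, 0.50-0.74 moderate,
#' 0.75-1.00 good correlation.
#'
#' @param x,y paired numeric vectors, n >= 5.
#' @return an [agreement_result()] with kind "spearman".
#' @export
spearman_with_category <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("a constant (all-ties) input has no rank correlation")
  r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  se <- sqrt(1.06 / (n - 3))
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  agreement_result("spearman", r, ci, correlation_category(r), n = n)
}

#' Intraclass correlation coefficient with category label
#'
#' ICC(2,1): two-way random effects, absolute agreement, single measure —
#' the usual choice for inter-reader agreement of quantitative imaging
#' parameters. 95\% CI per McGraw & Wong. Categories: <= 0.20 poor,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00
#' excellent agreement.
#'
#' @param ratings n x k numeric matrix (n subjects, k >= 2 raters).
#' @return an [agreement_result()] with kind "icc".
#' @export
icc_with_category <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L || k < 2L) stop("need >= 5 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) stop("ratings must be complete")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, mse))
    stop("zero between-subject variance: ICC undefined")
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # McGraw & Wong CI for ICC(A,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(0.975, n - 1, v)
  f_u <- stats::qf(0.975, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  agreement_result("icc", icc, c(lower, upper), icc_category(icc),
                   n_subjects = n, n_raters = k)
}

#' Bland-Altman agreement
#'
#' Bias = mean(x - y); 95\% limits of agreement = bias +/- 1.96 SD(x - y)
#' (conventional normal-quantile multiplier).
#'
#' @param x,y paired numeric vectors, n >= 2.
#' @return an [agreement_result()] with kind "bland_altman"; `ci` holds
#'   the limits of agreement, and fields `bias`, `loa_lower`, `loa_upper`,
#'   `sd_diff` are set.
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  agreement_result("bland_altman", bias, loa,
                   bias = bias, loa_lower = loa[1], loa_upper = loa[2],
                   sd_diff = s, n = length(d))
}
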