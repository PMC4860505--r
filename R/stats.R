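## Significance tests used to compare fiber-assay conditions: 2x2
## chi-squared on fiber counts, pooled-variance t on summary statistics,
## one-sample z on complementary encounter proportions, and a
## Kolmogorov-Smirnov comparison of spacing distributions.

new_test <- function(method, statistic, df, p_value, estimate = NULL,
                     inputs = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, estimate = estimate, inputs = inputs),
            class = "fiber_test")
}

#' @export
print.fiber_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g%s, p = %.4g\n", x$statistic,
              if (!is.null(x$df) && !is.na(x$df))
                sprintf(", df = %g", x$df) else "",
              x$p_value))
  if (!is.null(x$estimate))
    cat("  estimate:", paste(names(x$estimate),
                             signif(unlist(x$estimate), 4),
                             sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Chi-squared test on a 2 x 2 contingency table
#'
#' Uncorrected (no Yates continuity correction):
#' \eqn{\chi^2 = N(ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]}, df = 1,
#' two-sided p from the chi-squared survival function. Used to compare
#' the number of fibers with and without a signal between two
#' conditions.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = conditions,
#'   columns = with/without signal.
#' @return A \code{fiber_test}.
#' @export
#' @examples
#' chi2_2x2(90, 710, 95, 604)  # pooled lower- vs higher-dose fiber counts
chi2_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  margins <- c("a+b" = a + b, "c+d" = c + d, "a+c" = a + c, "b+d" = b + d)
  if (any(margins == 0))
    stop("degenerate margin: ", names(margins)[margins == 0][1], " is zero",
         call. = FALSE)
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / prod(margins)
  new_test("Chi-squared test (2x2, uncorrected)", stat, 1,
           pchisq(stat, df = 1, lower.tail = FALSE),
           estimate = list(p1 = a / (a + b), p2 = c / (c + d)),
           inputs = as.list(cells))
}

#' Two-sample pooled-variance t test from summary statistics
#'
#' Student's t with pooled variance, df = n1 + n2 - 2, two-sided p.
#' Operates on printed summary statistics (means, SDs, replicate
#' counts), as needed when only per-experiment means are available.
#'
#' @param mean1,sd1,n1 First group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return A \code{fiber_test}.
#' @export
#' @examples
#' two_sample_t_summary(2.69, 0.095, 3, 4.48, 0.285, 3)
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("sds must be >= 0", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) {
    if (mean1 == mean2) 0 else sign(mean2 - mean1) * Inf
  } else (mean2 - mean1) / se
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  new_test("Two-sample t test (pooled variance, summary statistics)",
           t, df, p,
           estimate = list(mean1 = mean1, mean2 = mean2),
           inputs = list(mean1 = mean1, sd1 = sd1, n1 = n1,
                         mean2 = mean2, sd2 = sd2, n2 = n2))
}

#' z test on complementary single/double encounter proportions
#'
#' The two categories partition one sample, so comparing their
#' proportions reduces to a one-sample z test of the double-sided
#' proportion against 0.5: with N = k_single + k_double and
#' \eqn{\hat p = k_{double}/N}, \eqn{z = (\hat p - 0.5)/\sqrt{0.25/N}};
#' two-sided p from the normal distribution. A two-independent-sample
#' variant is available via [two_proportion_z_indep()].
#'
#' @param k_single,k_double Category counts (sum >= 1).
#' @return A \code{fiber_test}.
#' @export
#' @examples
#' two_proportion_z(19, 118)  # pooled published encounter counts
two_proportion_z <- function(k_single, k_double) {
  n <- k_single + k_double
  if (n < 1) stop("need at least one classified fiber", call. = FALSE)
  phat <- k_double / n
  z <- (phat - 0.5) / sqrt(0.25 / n)
  new_test("z test of double-sided proportion against 0.5",
           z, NA_real_, 2 * pnorm(-abs(z)),
           estimate = list(single = 1 - phat, double = phat, n = n),
           inputs = list(k_single = k_single, k_double = k_double))
}

#' Two-independent-sample z test for proportions
#'
#' Standard pooled two-proportion z test; provided for comparisons
#' between two independent samples (not the default for complementary
#' categories of one sample).
#'
#' @param k1,n1 Successes and size of sample 1.
#' @param k2,n2 Successes and size of sample 2.
#' @return A \code{fiber_test}.
#' @export
two_proportion_z_indep <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("empty sample", call. = FALSE)
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  new_test("Two-proportion z test (independent samples)", z, NA_real_,
           2 * pnorm(-abs(z)),
           estimate = list(p1 = p1, p2 = p2),
           inputs = list(k1 = k1, n1 = n1, k2 = k2, n2 = n2))
}

#' Compare two inter-adduct spacing distributions
#'
#' Two-sample Kolmogorov-Smirnov test plus empirical summaries
#' (quartiles and mean) of both samples, as used to ask whether
#' lamp-photoactivated and laser-photoactivated fibers show the same
#' adduct spacing.
#'
#' @param distances_a,distances_b Non-empty numeric vectors of spacings
#'   (kb).
#' @return A \code{fiber_test} whose \code{estimate} holds both
#'   distribution summaries.
#' @export
compare_spacing <- function(distances_a, distances_b) {
  if (!length(distances_a) || !length(distances_b))
    stop("both spacing samples must be non-empty", call. = FALSE)
  ks <- suppressWarnings(ks.test(distances_a, distances_b))
  summ <- function(x) c(q1 = unname(quantile(x, 0.25)),
                        median = unname(median(x)),
                        q3 = unname(quantile(x, 0.75)),
                        mean = mean(x), n = length(x))
  new_test("Two-sample Kolmogorov-Smirnov test on spacings",
           unname(ks$statistic), NA_real_, ks$p.value,
           estimate = list(a = summ(distances_a), b = summ(distances_b)))
}
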