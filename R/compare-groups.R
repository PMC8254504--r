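#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Combines the standardized sample skewness and kurtosis into the omnibus
#' statistic `K2 = Z1(sqrt(b1))^2 + Z2(b2)^2`, which is approximately
#' chi-squared with 2 degrees of freedom under normality. Uses D'Agostino's
#' transformation for skewness and the Anscombe-Glynn transformation for
#' kurtosis; both require a sample size of at least 8.
#'
#' @param x Numeric vector, `n >= 8`.
#' @return A list: `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' dagostino_k2(rnorm(50))$p.value
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) abort("K2 normality test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) abort("K2 undefined for a constant sample")
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = 1 - pchisq(k2, df = 2),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Normality-gated two-group comparison
#'
#' Implements the study's test-selection rule: both groups are screened with
#' the D'Agostino-Pearson omnibus K2 normality test; if both pass
#' (`p > alpha`) and both have at least 8 observations (the K2 test is not
#' defined below that), an unpaired two-tailed t test is applied, otherwise
#' an unpaired two-tailed Mann-Whitney U test. The Mann-Whitney p-value is
#' exact for groups of at most 20 without ties and uses the tie-corrected
#' normal approximation otherwise.
#'
#' @param a,b Numeric samples, each with at least 2 observations.
#' @param alpha Significance level of the normality gate.
#' @return An object of class `group_comparison`: `test_used` (`"t_test"`
#'   or `"mann_whitney"`), `statistic`, `p.value`, per-group normality
#'   results, `alpha` and group sizes. Use [tidy()] or [glance()] for
#'   tabular views.
#' @export
#' @examples
#' set.seed(1)
#' cg <- compare_groups(rnorm(20), rnorm(20, 1))
#' tidy(cg)
compare_groups <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 observations")
  }
  norm_a <- if (length(a) >= 8) dagostino_k2(a) else NULL
  norm_b <- if (length(b) >= 8) dagostino_k2(b) else NULL
  use_t <- !is.null(norm_a) && !is.null(norm_b) &&
    norm_a$p.value > alpha && norm_b$p.value > alpha
  if (use_t) {
    ht <- t.test(a, b, var.equal = FALSE)
    test_used <- "t_test"
  } else {
    exact <- max(length(a), length(b)) <= 20 &&
      !any(duplicated(c(a, b)))
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    test_used <- "mann_whitney"
  }
  structure(
    list(test_used = test_used,
         statistic = unname(ht$statistic),
         p.value = ht$p.value,
         normality_a = norm_a, normality_b = norm_b,
         alpha = alpha, n_a = length(a), n_b = length(b)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test_used, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(test_used = x$test_used, statistic = x$statistic,
         p.value = x$p.value)
}

#' @rdname compare_groups
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    test_used = x$test_used,
    p.value = x$p.value,
    n_a = x$n_a, n_b = x$n_b,
    normality_p_a = if (is.null(x$normality_a)) NA_real_
                    else x$normality_a$p.value,
    normality_p_b = if (is.null(x$normality_b)) NA_real_
                    else x$normality_b$p.value,
    alpha_normality = x$alpha
  )
}
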