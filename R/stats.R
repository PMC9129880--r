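#' D'Agostino-Pearson omnibus normality test
#'
#' The K^2 omnibus test combining the transformed sample skewness
#' (D'Agostino 1970) and kurtosis (Anscombe & Glynn 1983) statistics;
#' K^2 = Z_skew^2 + Z_kurt^2 is chi-squared with 2 df under normality.
#' Requires `n >= 8`.
#'
#' @param x numeric sample.
#' @return list with `statistic` (K^2), `p.value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("d'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness transform (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Brown-Forsythe ANOVA (F*)
#'
#' Heteroscedasticity-robust one-way ANOVA with the Brown-Forsythe
#' denominator `sum((1 - n_i/N) s_i^2)` and Satterthwaite degrees of
#' freedom.
#'
#' @param samples list of numeric vectors (one per group).
#' @return list with `statistic`, `df1`, `df2`, `p.value`.
#' @export
brown_forsythe_anova <- function(samples) {
  k <- length(samples)
  stopifnot(k >= 2)
  ni <- vapply(samples, length, integer(1))
  mi <- vapply(samples, mean, numeric(1))
  vi <- vapply(samples, var, numeric(1))
  N <- sum(ni)
  grand <- sum(ni * mi) / N
  num <- sum(ni * (mi - grand)^2)
  ci <- (1 - ni / N) * vi
  den <- sum(ci)
  Fst <- num / den
  df2 <- den^2 / sum(ci^2 / (ni - 1))
  list(statistic = Fst, df1 = k - 1, df2 = df2,
       p.value = pf(Fst, k - 1, df2, lower.tail = FALSE))
}

#' Normality-gated group comparison
#'
#' Implements the statistical decision tree used throughout the analysis:
#' every group is tested for normality with the d'Agostino-Pearson test
#' followed by Shapiro-Wilk (both at alpha = 0.05). When all groups pass
#' both, two groups are compared by an unpaired two-tailed t-test and more
#' groups by one-way ANOVA; otherwise two groups fall back to the
#' Mann-Whitney U-test and more groups to the Brown-Forsythe and Welch
#' ANOVA (Welch p reported as primary, Brown-Forsythe F* alongside).
#' Groups smaller than 8 are gated on Shapiro-Wilk only (the K^2 test is
#' undefined there).
#'
#' @param ... two or more numeric vectors, or a single list of them.
#' @param alpha significance level of the normality gate.
#' @return list with `test_name`, `statistic`, `p`, `branch`
#'   (`"parametric"` or `"nonparametric"`), `normal` (per-group gate
#'   result), plus `bf_statistic`/`bf_p` for the robust-ANOVA branch.
#' @export
auto_compare <- function(..., alpha = 0.05) {
  args <- list(...)
  samples <- if (length(args) == 1 && is.list(args[[1]]) &&
                 !is.numeric(args[[1]])) args[[1]] else args
  samples <- lapply(samples, as.numeric)
  if (length(samples) < 2) stop("need at least two samples")
  ns <- vapply(samples, length, integer(1))
  if (any(ns < 3)) stop("each sample needs n >= 3")

  is_normal <- vapply(samples, function(s) {
    if (length(unique(s)) < 3) return(FALSE)
    sw <- shapiro.test(s)$p.value
    dp <- if (length(s) >= 8) dagostino_pearson(s)$p.value else 1
    dp > alpha && sw > alpha
  }, logical(1))
  parametric <- all(is_normal)

  if (length(samples) == 2) {
    if (parametric) {
      tt <- t.test(samples[[1]], samples[[2]], var.equal = TRUE)
      out <- list(test_name = "t_test", statistic = unname(tt$statistic),
                  p = tt$p.value, branch = "parametric")
    } else {
      wt <- suppressWarnings(wilcox.test(samples[[1]], samples[[2]]))
      out <- list(test_name = "mann_whitney_u",
                  statistic = unname(wt$statistic), p = wt$p.value,
                  branch = "nonparametric")
    }
  } else {
    x <- unlist(samples)
    g <- factor(rep(seq_along(samples), ns))
    if (parametric) {
      ow <- oneway.test(x ~ g, var.equal = TRUE)
      out <- list(test_name = "one_way_anova",
                  statistic = unname(ow$statistic), p = ow$p.value,
                  branch = "parametric")
    } else {
      we <- oneway.test(x ~ g, var.equal = FALSE)
      bf <- brown_forsythe_anova(samples)
      out <- list(test_name = "brown_forsythe_welch_anova",
                  statistic = unname(we$statistic), p = we$p.value,
                  branch = "nonparametric", bf_statistic = bf$statistic,
                  bf_p = bf$p.value)
    }
  }
  out$normal <- is_normal
  out
}
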