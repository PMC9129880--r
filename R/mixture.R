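#' Gaussian mixture fit with BIC model selection
#'
#' Fits one- and two-component Gaussian mixtures to a sample of phase
#' durations by maximum-likelihood EM (10 seeded restarts for k = 2, a
#' variance floor of 1e-3 h^2 against degenerate components) and selects k
#' by BIC. Used to quantify the bimodality of follower phase-duration
#' distributions, whose minor component coincides with the leader peak.
#'
#' @param durations numeric vector of durations (hours), `n >= 10`.
#' @param kmax maximum number of components (1 or 2).
#' @param seed integer seed for the EM restarts.
#' @param n_restarts EM restarts for k = 2.
#' @param var_floor minimum component variance (h^2).
#' @return an object of class `tnc_mixture`: `k`, `weights`, `means`,
#'   `sds`, `minor_weight` (k = 2; weight of the lower-mean component when
#'   it is the minor one, else the smaller weight), `loglik`, `bic`
#'   (named vector per k).
#' @export
fit_mixture <- function(durations, kmax = 2, seed = 1, n_restarts = 10,
                        var_floor = 1e-3) {
  x <- as.numeric(durations)
  n <- length(x)
  if (n < 10) stop("mixture fitting needs at least 10 observations")
  stopifnot(kmax %in% c(1, 2))
  set.seed(seed)

  # k = 1: closed-form MLE
  m1 <- mean(x)
  v1 <- max(mean((x - m1)^2), var_floor)
  ll1 <- sum(dnorm(x, m1, sqrt(v1), log = TRUE))
  bic <- c("1" = -2 * ll1 + 2 * log(n))
  best <- list(k = 1L, weights = 1, means = m1, sds = sqrt(v1),
               loglik = ll1)

  if (kmax == 2) {
    best2 <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(em_gmm2(x, var_floor), error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best2) || fit$loglik > best2$loglik))
        best2 <- fit
    }
    if (!is.null(best2)) {
      bic <- c(bic, "2" = -2 * best2$loglik + 5 * log(n))
      if (bic[["2"]] < bic[["1"]]) {
        ord <- order(best2$means)
        best <- list(k = 2L, weights = best2$weights[ord],
                     means = best2$means[ord], sds = best2$sds[ord],
                     loglik = best2$loglik)
      }
    }
  }
  minor <- if (best$k == 2) min(best$weights) else NA_real_
  structure(c(best, list(minor_weight = minor, bic = bic, n = n)),
            class = "tnc_mixture")
}

# One EM run for a 2-component 1D Gaussian mixture; random initialisation
# from the current RNG stream.
em_gmm2 <- function(x, var_floor, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  mu <- sample(x, 2) + rnorm(2, 0, sd(x) / 10)
  v <- rep(max(var(x) / 4, var_floor), 2)
  w <- runif(1, 0.2, 0.8)
  w <- c(w, 1 - w)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sqrt(v[1]))
    d2 <- w[2] * dnorm(x, mu[2], sqrt(v[2]))
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    g <- d1 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) stop("degenerate component")
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    v <- c(max(sum(g * (x - mu[1])^2) / n1, var_floor),
           max(sum((1 - g) * (x - mu[2])^2) / n2, var_floor))
    w <- c(n1 / n, n2 / n)
  }
  list(weights = w, means = mu, sds = sqrt(v), loglik = ll_old)
}

#' @export
print.tnc_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture, k = %d (BIC: %s)\n", x$k,
              paste(sprintf("k=%s %.1f", names(x$bic), x$bic),
                    collapse = ", ")))
  for (i in seq_len(x$k))
    cat(sprintf("  component %d: weight %.2f, mean %.2f h, sd %.2f h\n",
                i, x$weights[i], x$means[i], x$sds[i]))
  invisible(x)
}
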