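make_table <- function(n_per_class, mu1, mu2, sigma = NULL, seed = 1) {
  set.seed(seed)
  p <- length(mu1)
  if (is.null(sigma)) sigma <- diag(p)
  L <- chol(sigma)
  X1 <- matrix(rnorm(n_per_class * p), n_per_class) %*% L
  X2 <- matrix(rnorm(n_per_class * p), n_per_class) %*% L
  X1 <- sweep(X1, 2, mu1, "+")
  X2 <- sweep(X2, 2, mu2, "+")
  out <- as.data.frame(rbind(X1, X2))
  names(out) <- paste0("f", seq_len(p))
  out$label <- rep(c("leader", "follower"), each = n_per_class)
  out
}

test_that("two-feature identity-covariance case matches the closed form", {
  # with Sw = I (z-scored), the discriminant is the class-mean difference
  tab <- make_table(200, c(2, 0), c(0, 0), seed = 11)
  fit <- fit_lda(tab)
  w <- fit$coefficients
  dmu <- colMeans(scale(tab[, 1:2])[tab$label == "leader", ]) -
    colMeans(scale(tab[, 1:2])[tab$label == "follower", ])
  cosang <- sum(w * dmu) / sqrt(sum(w^2) * sum(dmu^2))
  expect_gt(abs(cosang), 0.995)
})

test_that("the fitted axis equals solve(Sw, dmu) on random instances", {
  set.seed(77)
  for (rep in 1:100) {
    p <- sample(2:4, 1)
    A <- matrix(rnorm(p * p), p)
    sigma <- crossprod(A) + diag(p)
    tab <- make_table(30, rnorm(p, 1), rnorm(p), sigma,
                      seed = sample.int(1e6, 1))
    fit <- fit_lda(tab)
    # independent closed-form oracle on the standardized features
    Z <- scale(as.matrix(tab[, seq_len(p)]))
    y <- factor(tab$label)
    Z1 <- Z[y == levels(y)[1], ]; Z2 <- Z[y == levels(y)[2], ]
    Sw <- ((nrow(Z1) - 1) * cov(Z1) + (nrow(Z2) - 1) * cov(Z2)) /
      (nrow(Z) - 2)
    w0 <- solve(Sw, colMeans(Z1) - colMeans(Z2))
    # oriented towards the class stored first in fit$classes
    if (levels(y)[1] != fit$classes[1]) w0 <- -w0
    cosang <- sum(fit$coefficients * w0) /
      sqrt(sum(fit$coefficients^2) * sum(w0^2))
    expect_gt(abs(cosang), 1 - 1e-6)
  }
})

test_that("the discriminant direction matches MASS::lda up to scale", {
  skip_if_not_installed("MASS")
  tab <- make_table(50, c(1.5, 0.5, 0), c(0, 0, 0), seed = 21)
  fit <- fit_lda(tab)
  m <- MASS::lda(label ~ ., data = tab)
  # compare on the raw scale: our raw coefficients vs MASS scaling
  w1 <- fit$coefficients_raw / sqrt(sum(fit$coefficients_raw^2))
  w2 <- drop(m$scaling) / sqrt(sum(m$scaling^2))
  expect_gt(abs(sum(w1 * w2)), 0.999)
})

test_that("identical class distributions give near-zero separation", {
  same <- make_table(100, c(0, 0), c(0, 0), seed = 5)
  apart <- make_table(100, c(3, 0), c(0, 0), seed = 5)
  expect_lt(fit_lda(same)$separation, 0.1)
  expect_gt(fit_lda(apart)$separation, 1)
})

test_that("rank_features orders by |standardized coefficient|", {
  one <- data.frame(f1 = rnorm(20), label = rep(c("leader", "follower"), 10))
  expect_equal(rank_features(fit_lda(one)), "f1")

  tab <- make_table(100, c(0, 2, 0.5), c(0, 0, 0), seed = 31)
  fit <- fit_lda(tab)
  expect_equal(rank_features(fit)[1], "f2")
  expect_equal(rank_features(fit),
               names(sort(-abs(fit$coefficients))))
})

test_that("ranking is equivariant under feature permutation", {
  tab <- make_table(80, c(2, 0.8, 0.1), c(0, 0, 0), seed = 41)
  perm <- tab[, c(3, 1, 2, 4)]
  expect_setequal(rank_features(fit_lda(tab)), rank_features(fit_lda(perm)))
  expect_equal(rank_features(fit_lda(tab)), rank_features(fit_lda(perm)))
})

test_that("a dominant feature wins the ranking in nearly every run", {
  wins <- 0
  for (rep in 1:100) {
    # feature A separates by 3 SD; the rest are almost pure noise
    tab <- make_table(25, c(3, 0.3, 0.3), c(0, 0, 0), seed = 1000 + rep)
    if (rank_features(fit_lda(tab))[1] == "f1") wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("random controls show no structure and are reproducible", {
  tab <- make_table(30, c(3, 1), c(0, 0), seed = 3)
  ctl <- random_control(tab, seed = 9)
  expect_identical(random_control(tab, seed = 9), ctl)
  expect_identical(ctl$label, tab$label)
  expect_false(identical(ctl$f1, tab$f1))

  # separation of the control stays near the no-structure level
  expect_lt(fit_lda(ctl)$separation, fit_lda(tab)$separation / 3)

  tiny <- data.frame(f1 = rnorm(4), label = c("leader", "leader",
                                              "follower", "follower"))
  expect_s3_class(fit_lda(random_control(tiny, seed = 2)), "tnc_lda")
})

test_that("random-feature coefficients stay below the permutation null", {
  # in most runs no control coefficient exceeds the 95th percentile of a
  # label-permutation null built from the same data
  ok <- 0
  for (rep in 1:50) {
    tab <- make_table(20, c(2, 0, 0), c(0, 0, 0), seed = 2000 + rep)
    ctl <- random_control(tab, seed = 3000 + rep)
    obs <- max(abs(fit_lda(ctl)$coefficients))
    null <- replicate(40, {
      perm <- ctl
      perm$label <- sample(perm$label)
      max(abs(fit_lda(perm)$coefficients))
    })
    if (obs <= quantile(null, 0.95)) ok <- ok + 1
  }
  expect_gte(ok, 40)
})

test_that("degenerate feature tables are rejected with clear errors", {
  bad <- data.frame(f1 = c(1, 2, NA, 4),
                    label = c("leader", "leader", "follower", "follower"))
  expect_error(fit_lda(bad), "missing")
  one_class <- data.frame(f1 = rnorm(6), label = rep("leader", 6))
  expect_error(fit_lda(one_class), "two classes")
})
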