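#' Two-class linear discriminant analysis of migratory identities
#'
#' Fisher discriminant separating leaders from followers: features are
#' z-scored, the pooled within-class covariance is ridge-regularised
#' (`lambda = 1e-6 * trace / p`, for the small cell numbers typical of
#' these data), and the discriminant direction is
#' `solve(Sw) %*% (mu_leader - mu_follower)`. Standardised coefficient
#' magnitudes define feature importance because the features mix units
#' (um, um/hr, dimensionless); raw-scale coefficients are reported too.
#'
#' @param table data.frame of numeric feature columns plus a `label`
#'   column (or factor given via `label_col`) with exactly two classes and
#'   at least two rows per class.
#' @param label_col name of the class-label column.
#' @return an object of class `tnc_lda`: `coefficients` (standardised),
#'   `coefficients_raw`, `class_means`, `projection` (per-row discriminant
#'   scores, oriented so the first class level scores higher),
#'   `separation` (between/within scatter ratio along the axis), `classes`.
#' @export
fit_lda <- function(table, label_col = "label") {
  if (!label_col %in% names(table))
    stop("no '", label_col, "' column in feature table")
  y <- factor(table[[label_col]])
  X <- as.matrix(table[, setdiff(names(table), label_col), drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("feature table contains missing values")
  if (nlevels(y) != 2) stop("fit_lda requires exactly two classes")
  if (any(tabulate(y) < 2)) stop("each class needs at least 2 rows")
  p <- ncol(X)
  if (p < 1) stop("at least one feature is required")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1  # constant features carry no information
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  lev <- levels(y)
  Z1 <- Z[y == lev[1], , drop = FALSE]
  Z2 <- Z[y == lev[2], , drop = FALSE]
  n1 <- nrow(Z1); n2 <- nrow(Z2)
  Sw <- ((n1 - 1) * cov(Z1) + (n2 - 1) * cov(Z2)) / (n1 + n2 - 2)
  lambda <- 1e-6 * sum(diag(Sw)) / p
  Swr <- Sw + diag(lambda, p)
  dmu <- colMeans(Z1) - colMeans(Z2)
  w <- tryCatch(solve(Swr, dmu), error = function(e) {
    cors <- abs(cov2cor_safe(Sw))
    diag(cors) <- 0
    bad <- which(cors > 0.999, arr.ind = TRUE)
    stop("within-class scatter is singular; collinear features: ",
         paste(unique(colnames(Sw)[bad[, 1]]), collapse = ", "))
  })
  w <- w / sqrt(sum(w^2))
  proj <- drop(Z %*% w)
  if (mean(proj[y == lev[1]]) < mean(proj[y == lev[2]])) {
    w <- -w
    proj <- -proj
  }
  mb <- (mean(proj[y == lev[1]]) - mean(proj[y == lev[2]]))^2
  within <- (sum((proj[y == lev[1]] - mean(proj[y == lev[1]]))^2) +
               sum((proj[y == lev[2]] - mean(proj[y == lev[2]]))^2)) /
    (n1 + n2 - 2)
  structure(list(coefficients = setNames(w, colnames(X)),
                 coefficients_raw = setNames(w / sdev, colnames(X)),
                 class_means = rbind(colMeans(X[y == lev[1], , drop = FALSE]),
                                     colMeans(X[y == lev[2], , drop = FALSE])),
                 projection = proj, labels = y,
                 separation = mb / within, classes = lev),
            class = "tnc_lda")
}

cov2cor_safe <- function(S) {
  d <- sqrt(diag(S))
  d[d == 0] <- 1
  S / tcrossprod(d)
}

#' Rank features by discriminative weight
#'
#' Features ordered by decreasing absolute standardised coefficient, ties
#' broken alphabetically.
#'
#' @param model a [fit_lda()] result.
#' @return character vector of feature names, most discriminative first.
#' @export
rank_features <- function(model) {
  co <- abs(model$coefficients)
  names(co)[order(-co, names(co))]
}

#' Random-feature control table
#'
#' Control dataset with the same shape and class labels as `table` but all
#' features replaced by i.i.d. standard normal draws, so any apparent
#' class separation is noise. (A label-shuffling control is available via
#' `shuffle_labels = TRUE`.)
#'
#' @param table feature table as for [fit_lda()].
#' @param seed integer seed.
#' @param label_col label column name.
#' @param shuffle_labels if `TRUE`, keep the features and permute labels
#'   instead.
#' @return a feature table of the same shape.
#' @export
random_control <- function(table, seed = 1, label_col = "label",
                           shuffle_labels = FALSE) {
  set.seed(seed)
  out <- table
  feat <- setdiff(names(table), label_col)
  if (shuffle_labels) {
    out[[label_col]] <- sample(table[[label_col]])
  } else {
    for (f in feat) out[[f]] <- rnorm(nrow(table))
  }
  out
}

#' @export
print.tnc_lda <- function(x, ...) {
  cat("two-class LDA (", paste(x$classes, collapse = " vs "), ")\n",
      sep = "")
  cat("standardised coefficients:\n")
  print(round(x$coefficients, 3))
  cat(sprintf("between/within separation: %.2f\n", x$separation))
  invisible(x)
}
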