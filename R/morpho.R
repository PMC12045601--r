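#' Generalized Procrustes analysis
#'
#' Iteratively centres every landmark configuration, scales it to unit
#' centroid size, rotates it onto the current mean shape by orthogonal
#' Procrustes, and updates the mean until it changes by less than `tol`.
#' Removes translation, size and rotation, leaving Procrustes shape
#' coordinates; centroid sizes are retained.
#'
#' @param configs A 3D array `(n_landmarks, 3, n_specimens)`, a list of
#'   coordinate matrices, or a list of [landmark_set()]s.
#' @param tol Convergence tolerance on the mean shape.
#' @param max_iter Iteration cap.
#' @return A `gpa_fit`: list with `coords` (aligned array), `mean` (mean
#'   shape), `centroid_size` (per specimen), `n_iter`.
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 100) {
  A <- configs_to_array(configs)
  n <- dim(A)[3]
  if (n < 2) stopf("gpa needs at least 2 configurations")
  cs <- numeric(n)
  for (i in seq_len(n)) {
    X <- A[, , i]
    X <- sweep(X, 2, colMeans(X))
    cs[i] <- sqrt(sum(X^2))
    if (cs[i] < 1e-12) stopf("degenerate (all-coincident) configuration")
    A[, , i] <- X / cs[i]
  }
  mean_shape <- A[, , 1]
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      R <- procrustes_rotation(A[, , i], mean_shape)
      A[, , i] <- A[, , i] %*% R
    }
    new_mean <- apply(A, c(1, 2), mean)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  structure(list(coords = A, mean = mean_shape, centroid_size = cs,
                 n_iter = it),
            class = "gpa_fit")
}

# optimal rotation aligning X onto Y (both centred)
procrustes_rotation <- function(X, Y) {
  sv <- svd(crossprod(X, Y))
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  sv$u %*% D %*% t(sv$v)
}

configs_to_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3) return(configs)
  mats <- lapply(configs, function(c)
    if (inherits(c, "landmark_set")) lm_coords(c) else as.matrix(c))
  k <- nrow(mats[[1]])
  for (m in mats) if (nrow(m) != k)
    stopf("configurations differ in landmark count")
  array(unlist(mats), c(k, 3, length(mats)))
}

#' Flatten aligned shape coordinates to a specimen-by-feature matrix
#'
#' @param fit A [gpa()] result.
#' @return Matrix with one row per specimen (landmarks unrolled x,y,z).
#' @export
shape_matrix <- function(fit) {
  t(apply(fit$coords, 3, as.numeric))
}

#' Principal component analysis with a fixed sign convention
#'
#' Centred SVD (no scaling). For reproducibility, each component is flipped
#' so that its largest-magnitude loading is positive.
#'
#' @param X Specimens-by-features matrix.
#' @return A `pc_model`: list with `mean`, `loadings`, `scores`,
#'   `variance_explained` (fractions summing to <= 1).
#' @export
pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("pca needs at least 2 specimens")
  if (all(apply(X, 2, stats::sd) == 0)) stopf("zero-variance matrix")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(mean = pr$center, loadings = pr$rotation, scores = pr$x,
                 variance_explained = ve),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> %d specimens x %d features; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(x$mean),
              100 * x$variance_explained[1],
              100 * (x$variance_explained[2] %||% NA)))
  invisible(x)
}

#' Two-block partial least squares with permutation inference
#'
#' Singular value decomposition of the cross-block covariance of the
#' column-centred blocks; the first pair of singular vectors gives latent
#' scores whose Pearson correlation `r` summarizes the shape-proliferation
#' association. Significance is assessed by permuting the specimen rows of
#' block 1 (the proliferation block) while holding block 2 fixed:
#' `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`, and
#' `z = (r_obs - mean(r_perm)) / sd(r_perm)`.
#'
#' @param block1 Specimens-by-features matrix (proliferation).
#' @param block2 Specimens-by-features matrix (shape coordinates or
#'   binarized tissue), same row order.
#' @param n_perm Number of permutations.
#' @param seed Optional seed for the permutation draw.
#' @param perm_matrix Optional matrix of row orders (one permutation per
#'   row), e.g. the exhaustive set for small n; overrides `n_perm`.
#' @return A `pls_result`: list with `r`, `z`, `p`, `n_perm`, latent
#'   `scores1`/`scores2`, singular axes `axis1`/`axis2`, and `singular_value`.
#' @export
two_block_pls <- function(block1, block2, n_perm = 999, seed = NULL,
                          perm_matrix = NULL) {
  X <- as.matrix(block1)
  Y <- as.matrix(block2)
  if (nrow(X) != nrow(Y)) stopf("blocks must have the same specimens")
  n <- nrow(X)
  if (n < 3) stopf("two_block_pls needs at least 3 specimens")
  if (is.null(perm_matrix) && n_perm < 1) stopf("n_perm must be >= 1")
  pls_r <- function(Xp) {
    Xc <- scale(Xp, center = TRUE, scale = FALSE)
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    C <- crossprod(Xc, Yc) / (n - 1)
    sv <- svd(C, nu = 1, nv = 1)
    s1 <- as.numeric(Xc %*% sv$u)
    s2 <- as.numeric(Yc %*% sv$v)
    list(r = stats::cor(s1, s2), u = sv$u, v = sv$v, d = sv$d[1],
         s1 = s1, s2 = s2)
  }
  obs <- pls_r(X)
  perms <- if (!is.null(perm_matrix)) {
    lapply(seq_len(nrow(perm_matrix)), function(i) perm_matrix[i, ])
  } else {
    gen <- function() replicate(n_perm, sample.int(n), simplify = FALSE)
    if (is.null(seed)) gen() else with_seed(seed, gen())
  }
  r_perm <- vapply(perms, function(o) pls_r(X[o, , drop = FALSE])$r,
                   numeric(1))
  np <- length(r_perm)
  structure(list(r = obs$r, z = (obs$r - mean(r_perm)) / stats::sd(r_perm),
                 p = (sum(r_perm >= obs$r) + 1) / (np + 1), n_perm = np,
                 r_perm = r_perm, scores1 = obs$s1, scores2 = obs$s2,
                 axis1 = as.numeric(obs$u), axis2 = as.numeric(obs$v),
                 singular_value = obs$d, n = n),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> r = %.3f, z = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$z, x$p, x$n_perm))
  invisible(x)
}

#' Residualize a block on somite stage
#'
#' Removes the ontogenetic trend by per-column least-squares regression on
#' somite count; the residuals are exactly uncorrelated with stage.
#'
#' @param block Specimens-by-features matrix.
#' @param somites Numeric somite counts, one per specimen.
#' @return Residual matrix of the same shape.
#' @export
residualize_on_stage <- function(block, somites) {
  X <- as.matrix(block)
  stopifnot(nrow(X) == length(somites), all(is.finite(somites)))
  if (nrow(X) < 3) stopf("need at least 3 specimens")
  if (stats::sd(somites) == 0) stopf("somite counts are constant")
  qr.resid(qr(cbind(1, somites)), X)
}

#' Split a cohort (or metadata table) at a somite boundary
#'
#' @param x A [cohort()] or data frame with a `somites` column.
#' @param boundary Somite count; specimens with `somites <= boundary` go to
#'   the younger side.
#' @return List with `younger` and `older` (same type as the input) and
#'   `sizes`.
#' @export
split_by_somites <- function(x, boundary = 14) {
  if (inherits(x, "cohort")) {
    md <- cohort_metadata(x)
    young <- md$id[md$somites <= boundary]
    old <- md$id[md$somites > boundary]
    out <- list(younger = x$specimens[young], older = x$specimens[old])
  } else {
    young <- x$somites <= boundary
    out <- list(younger = x[young, , drop = FALSE],
                older = x[!young, , drop = FALSE])
  }
  sizes <- if (inherits(x, "cohort"))
    c(younger = length(out$younger), older = length(out$older))
  else c(younger = nrow(out$younger), older = nrow(out$older))
  if (any(sizes == 0)) warnf("split_by_somites: one side is empty")
  c(out, list(sizes = sizes))
}

#' Linear-SVM genotype separation with a permutation test
#'
#' Standardizes (z-scores) the first principal-component scores of the
#' proliferation PCA, fits a linear support vector machine (hinge loss,
#' cost C) separating wild type from the pooled other genotypes, and
#' evaluates the training-set F1 score with the wild-type class positive.
#' Significance is a label-permutation test on F1:
#' `p = (#{F1_perm >= F1_obs} + 1) / (n_perm + 1)`. Training-set F1
#' mirrors the intended usage and is optimistic by construction.
#'
#' @param scores Specimens-by-PC matrix (typically the first 5 PCs).
#' @param labels Character/factor; the `positive` class vs the rest.
#' @param positive Positive class label (default `"WT"`).
#' @param C Regularization parameter.
#' @param n_perm Number of label permutations.
#' @param seed Optional seed.
#' @param max_iter Accepted for interface compatibility; the underlying
#'   libsvm solver runs to its own convergence tolerance.
#' @return An `svm_result`: list with `accuracy`, `f1`, `p`, `n_perm`,
#'   `weights` (hyperplane coefficients in standardized score space),
#'   `bias`.
#' @export
svm_genotype <- function(scores, labels, positive = "WT", C = 1,
                         n_perm = 1000, seed = NULL, max_iter = 10000) {
  X <- as.matrix(scores)
  y <- factor(ifelse(as.character(labels) == positive, positive, "other"),
              levels = c(positive, "other"))
  if (any(table(y) < 2)) stopf("need at least 2 specimens per class")
  Z <- scale(X)
  fit_f1 <- function(yy) {
    fit <- e1071::svm(Z, yy, kernel = "linear", cost = C, scale = FALSE,
                      type = "C-classification")
    pred <- stats::predict(fit, Z)
    tp <- sum(pred == positive & yy == positive)
    fp <- sum(pred == positive & yy != positive)
    fn <- sum(pred != positive & yy == positive)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    list(f1 = f1, acc = mean(pred == yy), fit = fit)
  }
  obs <- fit_f1(y)
  run_perms <- function() vapply(seq_len(n_perm), function(i)
    fit_f1(sample(y))$f1, numeric(1))
  f1_perm <- if (is.null(seed)) run_perms() else with_seed(seed, run_perms())
  w <- t(obs$fit$coefs) %*% obs$fit$SV
  structure(list(accuracy = obs$acc, f1 = obs$f1,
                 p = (sum(f1_perm >= obs$f1) + 1) / (n_perm + 1),
                 n_perm = n_perm, f1_perm = f1_perm,
                 weights = as.numeric(w), bias = -obs$fit$rho),
            class = "svm_result")
}

#' @export
print.svm_result <- function(x, ...) {
  cat(sprintf("<svm_result> training accuracy %.3f, F1 %.3f, permutation p = %.4g\n",
              x$accuracy, x$f1, x$p))
  invisible(x)
}

#' Tidy summaries of fitted results
#'
#' `tidy_result()` returns a one-row tibble of the headline statistics of a
#' `pls_result`, `svm_result` or `null_distribution`.
#'
#' @param x A fitted result object.
#' @return A tibble.
#' @export
tidy_result <- function(x) UseMethod("tidy_result")

#' @export
tidy_result.pls_result <- function(x) {
  tibble::tibble(statistic = "pls_r", estimate = x$r, z = x$z, p = x$p,
                 n_perm = x$n_perm)
}

#' @export
tidy_result.svm_result <- function(x) {
  tibble::tibble(statistic = "svm_f1", estimate = x$f1,
                 accuracy = x$accuracy, p = x$p, n_perm = x$n_perm)
}

#' @export
tidy_result.null_distribution <- function(x) {
  tibble::tibble(statistic = "mean_proliferation", estimate = x$observed,
                 null_mean = mean(x$null), p = x$p,
                 outside_null = x$outside_null,
                 percent_increase = x$percent_increase)
}
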