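test_that("GPA aligns identical and transformed copies to distance zero", {
  A <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.2, 1), ncol = 3,
              byrow = TRUE)
  fit <- gpa(list(A, A))
  expect_lt(sqrt(sum((fit$coords[, , 1] - fit$coords[, , 2])^2)), 1e-10)
  # rotated, translated and scaled copy aligns exactly
  B <- sweep(2.5 * A %*% t(rotation_z(0.8)), 2, c(5, -2, 3), "+")
  fit2 <- gpa(list(A, B))
  expect_lt(max(abs(fit2$coords[, , 1] - fit2$coords[, , 2])), 1e-8)
  expect_equal(fit2$centroid_size[2] / fit2$centroid_size[1], 2.5,
               tolerance = 1e-8)
  expect_error(gpa(list(A * 0, A * 0)), "degenerate")
})

test_that("GPA is invariant to rigid+scale pre-transforms of any input", {
  set.seed(14)
  configs <- lapply(1:4, function(i) matrix(rnorm(30), ncol = 3))
  base <- gpa(configs)
  configs2 <- configs
  configs2[[2]] <- sweep(0.4 * configs[[2]] %*% t(rotation_z(1.1)),
                         2, c(100, 50, -30), "+")
  alt <- gpa(configs2)
  expect_lt(max(abs(base$coords - alt$coords)), 1e-8)
})

test_that("GPA mean recovers a noisy tetrahedron and matches vegan", {
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  set.seed(8)
  sdn <- 0.05
  configs <- lapply(1:3, function(i) tetra + matrix(rnorm(12, 0, sdn), 4))
  fit <- gpa(configs)
  target <- tetra / sqrt(sum(scale(tetra, scale = FALSE)^2))
  R <- prolifatlas:::procrustes_rotation(fit$mean, target)
  expect_lt(max(abs(fit$mean %*% R - target)), sdn / sqrt(3) * 3)
  # pairwise cross-check against vegan's procrustes rotation
  skip_if_not_installed("vegan")
  X <- fit$coords[, , 1]
  Y <- fit$coords[, , 2]
  vg <- vegan::procrustes(X, Y, scale = FALSE)
  ours <- Y %*% prolifatlas:::procrustes_rotation(Y, X)
  expect_lt(max(abs(vg$Yrot - ours)), 1e-8)
})

test_that("PCA contracts hold on rank-1, isotropic and tiny fixtures", {
  set.seed(3)
  v <- rnorm(6)
  scoresT <- rnorm(12)
  rank1 <- outer(scoresT, v)
  pc <- pca(rank1)
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-12)
  iso <- matrix(rnorm(2000), ncol = 2)
  expect_lt(abs(pca(iso)$variance_explained[1] - 0.5), 0.05)
  m3 <- matrix(c(1, 2, 3, 2, 4, 1, 3, 1, 2), 3, byrow = TRUE)
  pc3 <- pca(m3)
  recon <- sweep(m3, 2, pc3$mean) %*% pc3$loadings
  expect_equal(unname(recon), unname(pc3$scores), tolerance = 1e-12)
  expect_error(pca(matrix(1, 4, 3)), "zero-variance")
})

test_that("two-block PLS saturates on identical blocks and validates input", {
  set.seed(5)
  X <- matrix(rnorm(60), nrow = 10)
  pls <- two_block_pls(X, X, n_perm = 19, seed = 1)
  expect_equal(pls$r, 1, tolerance = 1e-10)
  expect_error(two_block_pls(X, X[1:5, ]), "same specimens")
  expect_error(two_block_pls(X[1:2, ], X[1:2, ]), "at least 3")
  expect_gte(pls$p, 1 / 20)
})

test_that("PLS permutation p matches the exhaustive oracle at n = 5", {
  set.seed(77)
  X <- matrix(rnorm(5 * 4), 5)
  Y <- matrix(rnorm(5 * 3), 5)
  perms <- do.call(rbind, combinat_perms(5))
  # exhaustive: all 120 orders including the identity
  r_all <- apply(perms, 1, function(o)
    two_block_pls(X[o, ], Y, n_perm = 1, seed = 1)$r)
  r_obs <- two_block_pls(X, Y, n_perm = 1, seed = 1)$r
  p_exact <- mean(r_all >= r_obs)
  ident <- which(apply(perms, 1, function(o) all(o == 1:5)))
  fit <- two_block_pls(X, Y, perm_matrix = perms[-ident, , drop = FALSE])
  expect_equal(fit$p, p_exact)
  expect_equal(fit$n_perm, 119)
})

test_that("stage residualization is exact least squares", {
  som <- c(8, 11, 15, 19)
  ortho <- cbind(c(1, -1, 1, -1))
  ortho <- ortho - mean(ortho)
  ortho <- qr.resid(qr(cbind(1, som)), ortho)
  expect_equal(residualize_on_stage(ortho, som), ortho, tolerance = 1e-12)
  lin <- cbind(2 * som + 3, -som)
  expect_lt(max(abs(residualize_on_stage(lin, som))), 1e-10)
  y <- c(1.2, 0.7, 2.9, 2.1)
  fit <- lm(y ~ som)
  expect_equal(as.numeric(residualize_on_stage(cbind(y), som)),
               unname(resid(fit)), tolerance = 1e-10)
  r <- residualize_on_stage(matrix(rnorm(12), 4), som)
  expect_lt(max(abs(cor(r, som))), 1e-10)
  expect_error(residualize_on_stage(lin, rep(10, 4)), "constant")
})

test_that("somite splits partition at the boundary inclusively", {
  md <- data.frame(id = letters[1:4], somites = c(8, 13, 15, 20))
  sp <- split_by_somites(md, 14)
  expect_equal(sp$younger$somites, c(8, 13))
  expect_equal(sp$older$somites, c(15, 20))
  expect_warning(one <- split_by_somites(data.frame(somites = 14), 14), "empty")
  expect_equal(one$sizes[["younger"]], 1)
  expect_warning(split_by_somites(data.frame(somites = c(8, 9)), 14),
                 "empty")
})

test_that("the linear SVM separates a separable toy with F1 = 1", {
  set.seed(10)
  n <- 14
  lab <- rep(c("WT", "MUT"), c(5, 9))
  X <- matrix(rnorm(n * 5, sd = 0.3), n)
  X[lab == "WT", 1] <- X[lab == "WT", 1] + 6
  fit <- svm_genotype(X, lab, n_perm = 200, seed = 2)
  expect_equal(fit$f1, 1)
  expect_equal(fit$accuracy, 1)
  expect_equal(fit$p, (sum(fit$f1_perm >= 1) + 1) / 201)
  expect_error(svm_genotype(X, rep("WT", n)), "per class")
})

test_that("the SVM permutation p attains its lower bound", {
  set.seed(10)
  n <- 14
  lab <- rep(c("WT", "MUT"), c(7, 7))
  X <- matrix(rnorm(n * 3, sd = 0.1), n)
  X[lab == "WT", ] <- X[lab == "WT", ] + 50   # trivially separable
  fit <- svm_genotype(X, lab, n_perm = 1000, seed = 3)
  expect_equal(fit$f1, 1)
  # permuted labels essentially never reach F1 = 1 with balanced classes
  expect_equal(fit$p, (sum(fit$f1_perm >= 1) + 1) / 1001)
  expect_gte(fit$p, 1 / 1001)
})

test_that("growth-linked hotspots yield a significant PLS on phantoms", {
  spec <- phantom_spec(grid_shape = 64, n_per_group = 5, seed = 201)
  ch <- generate_cohort(spec)
  res <- run_pipeline(ch, do_vbm = FALSE, do_atlases = FALSE,
                      n_perm = 199, seed = 201)
  pls <- res$morpho$pls
  expect_lte(pls$p, 0.05)
  expect_gt(pls$r, 0.5)
})
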