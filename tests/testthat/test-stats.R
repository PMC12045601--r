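test_that("differential volumes code outward and inward change", {
  v <- cached_specimen()$labels
  D0 <- differential_volume(v, v)
  expect_true(all(D0$values == 0))
  # dilated sample: a +1 boundary shell and no -1 voxels
  arr <- as.array(v) == 1
  dil <- prolifatlas:::binary_closing(arr, 0) # no-op copy
  dil <- array(prolifatlas:::cpp_minmax3(as.numeric(arr),
                                         as.integer(dim(arr)),
                                         rep(1L, 3), TRUE) > 0.5, dim(arr))
  D <- differential_volume(dil, arr)
  expect_true(all(D$values >= 0))
  expect_equal(sum(D$values == 1), sum(dil) - sum(arr))
  # hand-counted proportions
  m <- array(FALSE, c(5, 5, 5)); m[1:10] <- TRUE
  Dv <- D0; Dv$values <- array(0L, c(5, 5, 5))
  Dv$values[1:3] <- 1L; Dv$values[4:5] <- -1L
  pr <- change_proportions(Dv, m)
  expect_equal(pr$frac_outward, 0.3)
  expect_equal(pr$frac_inward, 0.2)
  expect_error(change_proportions(Dv, array(FALSE, c(5, 5, 5))), "empty")
})

test_that("shape-proliferation correlation matches closed-form Pearson", {
  d <- c(5, 5, 5)
  D <- list(values = array(0L, d), spacing = c(1, 1, 1),
            origin = c(0, 0, 0))
  class(D) <- "differential_volume"
  D$values[1:5] <- c(1L, -1L, 0L, 1L, -1L)
  mask <- array(FALSE, d); mask[1:5] <- TRUE
  # perfect linear relation P = 0.5 (D + 1)
  P <- prolif_map(array(0, d), 1)
  Pv <- as.array(P); Pv[1:5] <- 0.5 * (D$values[1:5] + 1)
  expect_equal(shape_prolif_correlation(
    D, prolif_map(Pv, 1), mask), 1)
  # worked 5-voxel fixture against cor() on the listed values
  pvals <- c(0.9, 0.1, 0.4, 0.7, 0.2)
  Pv2 <- as.array(P); Pv2[1:5] <- pvals
  expect_equal(shape_prolif_correlation(D, prolif_map(Pv2, 1), mask),
               cor(c(1, -1, 0, 1, -1), pvals))
  # invariance under increasing affine rescaling of P
  expect_equal(shape_prolif_correlation(D, prolif_map(2 * Pv2 + 1, 1), mask),
               shape_prolif_correlation(D, prolif_map(Pv2, 1), mask))
  expect_error(shape_prolif_correlation(D, prolif_map(array(1, d), 1), mask),
               "zero variance")
})

test_that("within-mask shuffling of P decorrelates from shape change", {
  set.seed(31)
  n <- 400
  d <- c(20, 20, 1)
  mask <- array(TRUE, d)
  D <- structure(list(values = array(sample(c(-1L, 0L, 1L), n, TRUE,
                                            prob = c(0.2, 0.6, 0.2)), d),
                      spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                 class = "differential_volume")
  base <- array(runif(n), d)
  rs <- replicate(500, {
    shape_prolif_correlation(D, prolif_map(array(sample(base), d), 1), mask)
  })
  expect_lt(median(abs(rs)), 3 / sqrt(n))
  expect_gt(mean(abs(rs) < 3 / sqrt(n)), 0.99)
})

test_that("vbm t-maps follow one-sample t arithmetic", {
  d <- c(6, 6, 6)
  ones <- lapply(1:3, function(i) array(1, d))
  tm0 <- vbm_tmap(ones)
  expect_true(all(is.na(tm0$t)))          # zero variance -> masked
  set.seed(4)
  n <- 5
  js <- lapply(seq_len(n), function(i) array(exp(rnorm(prod(d), 0.3, 0.1)), d))
  tm <- vbm_tmap(js)
  expect_equal(tm$df, n - 1)
  expect_lt(abs(median(tm$t) - 0.3 / (0.1 / sqrt(n))), 1.0)
  # a two-group Welch alternative runs and has sensible direction
  tg <- vbm_tmap(c(ones, js), group = rep(c("a", "b"), c(3, 5)))
  expect_gt(mean(tg$t, na.rm = TRUE), 0)
})

test_that("top-t voxels concentrate where expansion was simulated", {
  set.seed(6)
  d <- c(12, 12, 12)
  block <- array(FALSE, d); block[4:9, 4:9, 4:9] <- TRUE
  js <- lapply(1:5, function(i) {
    lj <- array(rnorm(prod(d), 0, 0.05), d)
    lj[block] <- lj[block] + 0.3
    array(exp(lj), d)
  })
  tm <- vbm_tmap(js)
  k <- sum(block)
  top <- order(tm$t, decreasing = TRUE)[seq_len(k)]
  expect_gte(mean(top %in% which(block)), 0.7)
})

test_that("significance masks threshold one-sided expansion", {
  tm <- list(t = array(c(1, 2, 3, 4, NA, 0.5, 2.5, 1.5, 3.5, 0)[1:10],
                       c(10, 1, 1)), df = 4, n = 5)
  class(tm) <- "tmap"
  expect_warning(sm <- significance_mask(tm, t_crit = 10), "empty")
  sm0 <- significance_mask(tm, t_crit = 1e-9)
  expect_equal(sum(sm0$mask), sum(tm$t > 0, na.rm = TRUE))
  sm2 <- significance_mask(tm, t_crit = 2)
  expect_equal(which(sm2$mask), which(!is.na(tm$t) & tm$t > 2))
  expect_equal(sm2$params$fraction, sum(sm2$mask) / 9)
  expect_error(significance_mask(tm, t_crit = -1), "positive")
})

test_that("random-mask nulls handle degenerate and typical cases", {
  d <- c(10, 10, 10)
  P <- prolif_map(array(0.4, d), 1)
  sig <- array(FALSE, d); sig[1:50] <- TRUE
  uni <- array(TRUE, d)
  nd <- random_mask_null(P, sig, uni, R = 50, seed = 1)
  expect_equal(nd$p, 1)
  expect_false(nd$outside_null)
  expect_equal(nd$percent_increase, 0)
  # sig mask = universe: all null means equal the observed mean
  nd2 <- random_mask_null(P, uni, uni, R = 10, seed = 1)
  expect_true(all(nd2$null == nd2$observed))
  expect_error(random_mask_null(P, uni, sig), "smaller")
  # an enriched region is flagged as outside the null range
  set.seed(2)
  Pv <- array(runif(prod(d), 0, 0.2), d)
  Pv[sig] <- Pv[sig] + 0.5
  nd3 <- random_mask_null(prolif_map(Pv, 1), sig, uni, R = 100, seed = 3)
  expect_true(nd3$outside_null)
  expect_equal(nd3$p, 1 / 101)
})

test_that("percent increase reproduces the worked examples", {
  expect_equal(percent_increase(70.14, 57.26), 22.5)
  expect_equal(percent_increase(84.64, 63.23), 33.9)
  expect_equal(percent_increase(5, 5), 0)
  expect_error(percent_increase(1, 0), "positive")
})

test_that("dice is a symmetric overlap with fixed conventions", {
  a <- array(FALSE, c(4, 4, 4)); a[1:3] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[2:4] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(a, b), 2 * 2 / 6)
  expect_equal(dice(a, b), dice(b, a))
  none <- array(FALSE, c(4, 4, 4))
  expect_equal(dice(none, none), 1)
  expect_error(dice(a, array(TRUE, c(2, 2, 2))), "mismatch")
})
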