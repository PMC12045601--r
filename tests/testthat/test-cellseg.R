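test_that("connected components count and measure disjoint cubes", {
  a <- array(0L, c(12, 12, 12))
  a[2:4, 2:4, 2:4] <- 1L
  a[8:10, 8:10, 8:10] <- 1L
  tab <- connected_components(cell_map(a, 10), 26)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$voxel_count, c(27, 27))
  expect_equal(tab$volume_um3, c(27, 27) * 1000)
  expect_equal(tab$cx[1], (3 - 1) * 10) # centroid of the first cube
  empty <- connected_components(cell_map(array(0L, c(4, 4, 4)), 1))
  expect_equal(nrow(empty), 0)
})

test_that("connectivity distinguishes face- from corner-touching pairs", {
  face <- array(0L, c(6, 6, 6))
  face[2, 2, 2] <- 1L; face[3, 2, 2] <- 1L
  expect_equal(nrow(connected_components(cell_map(face, 1), 6)), 1)
  corner <- array(0L, c(6, 6, 6))
  corner[2, 2, 2] <- 1L; corner[3, 3, 3] <- 1L
  expect_equal(nrow(connected_components(cell_map(corner, 1), 6)), 2)
  expect_equal(nrow(connected_components(cell_map(corner, 1), 26)), 1)
  edge <- array(0L, c(6, 6, 6))
  edge[2, 2, 2] <- 1L; edge[3, 3, 2] <- 1L
  expect_equal(nrow(connected_components(cell_map(edge, 1), 6)), 2)
  expect_equal(nrow(connected_components(cell_map(edge, 1), 18)), 1)
})

test_that("volume-percentile filtering removes only distribution tails", {
  # 100 equal-volume components: P1 = P99 = the common volume, none removed
  a <- array(0L, c(40, 40, 10))
  ij <- expand.grid(i = seq(1, 37, by = 4), j = seq(1, 37, by = 4))
  for (k in seq_len(100)) a[ij$i[k], ij$j[k], 5] <- 1L
  res <- filter_by_volume_percentiles(cell_map(a, 1))
  expect_equal(nrow(res$kept), 100)
  expect_equal(nrow(res$rejected), 0)
})

test_that("percentile filtering matches the linear-interpolation oracle", {
  # volumes 1..100: P1 = 1.99, P99 = 99.01 -> components 1 and 100 removed
  n <- 100
  a <- array(0L, c(110, 2 * n + 1, 10))
  for (k in seq_len(n)) a[seq_len(k), 2 * k, 5] <- 1L
  m <- cell_map(a, 1)
  tab <- connected_components(m, 6)
  expect_equal(sort(tab$voxel_count), 1:100)
  expect_equal(unname(quantile(tab$volume_um3, 0.01)), 1.99)
  res <- filter_by_volume_percentiles(m, connectivity = 6)
  expect_equal(sort(res$rejected$voxel_count), c(1, 100))
  expect_equal(sum(as.array(res$map)), sum(2:99))
  # a single component is kept
  single <- filter_by_volume_percentiles(cube_map(8, c(2, 2, 2), c(3, 3, 3)))
  expect_equal(nrow(single$kept), 1)
  # percentile mass bound: at most ceiling(0.02 n) + 2 components removed
  set.seed(7)
  b <- array(as.integer(runif(20^3) < 0.08), c(20, 20, 20))
  resb <- filter_by_volume_percentiles(cell_map(b, 1))
  expect_lte(nrow(resb$rejected), ceiling(0.02 * (nrow(resb$kept) +
                                                  nrow(resb$rejected))) + 2)
})

test_that("proliferative fraction is a voxel ratio with strict edge cases", {
  nuc <- cube_map(8, c(2, 2, 2), c(4, 4, 4))       # 27 voxels
  expect_equal(proliferative_fraction(nuc, nuc), 1)
  none <- cell_map(array(0L, c(8, 8, 8)), 10, channel = "proliferation")
  expect_equal(proliferative_fraction(nuc, none), 0)
  a10 <- array(0L, c(8, 8, 8)); a10[1:8, 2, 2] <- 1L; a10[1:2, 3, 2] <- 1L
  nuc10 <- cell_map(a10, 10)                        # 10 nucleus voxels
  ap <- array(0L, c(8, 8, 8)); ap[1:3, 2, 2] <- 1L  # 3 also proliferating
  pro <- cell_map(ap, 10, channel = "proliferation")
  expect_equal(proliferative_fraction(nuc10, pro), 0.3)
  roi0 <- array(FALSE, c(8, 8, 8))
  expect_error(proliferative_fraction(nuc, nuc, roi0), "empty roi")
  roi_bg <- array(FALSE, c(8, 8, 8)); roi_bg[8, 8, 8] <- TRUE
  expect_error(proliferative_fraction(nuc, nuc, roi_bg), "no nucleus voxels")
})

test_that("fraction is invariant to mirroring everything together", {
  s <- cached_specimen()
  roi <- as.array(s$labels) > 0
  f <- proliferative_fraction(s$nuclei, s$prolif, roi)
  fm <- proliferative_fraction(mirror(s$nuclei), mirror(s$prolif),
                               roi[dim(roi)[1]:1, , ])
  expect_equal(f, fm)
})

test_that("axis profiles recover uniform and hotspot patterns", {
  set.seed(42)
  n <- 40
  roi <- array(TRUE, c(n, n, n))
  nuc <- array(as.integer(runif(n^3) < 0.3), c(n, n, n))
  pro <- array(0L, c(n, n, n))
  pro[nuc == 1] <- as.integer(runif(sum(nuc)) < 0.2)
  sp <- list(nuclei = cell_map(nuc, 10), prolif = cell_map(pro, 10,
             channel = "proliferation"))
  prof <- axis_profile(sp, roi, axis = "ap", K = 10)
  expect_equal(nrow(prof), 10)
  expect_true(all(abs(prof$fraction - 0.2) < 0.03))
  # conservation: binned cell volume sums to the total nucleus volume
  expect_equal(sum(prof$cell_volume_um3), sum(nuc) * 1000)
  # K = 1 reduces to the global proliferative fraction
  p1 <- axis_profile(sp, roi, axis = "ap", K = 1)
  expect_equal(p1$fraction, proliferative_fraction(sp$nuclei, sp$prolif, roi))
  # dorsal-half hotspot: dorsal bins exceed ventral bins
  pro2 <- pro
  zh <- (seq_len(n) > n / 2)
  hot <- nuc == 1 & rep(rep(zh, each = n * n), 1)
  pro2[hot] <- as.integer(runif(sum(hot)) < 0.5)
  sp2 <- list(nuclei = sp$nuclei,
              prolif = cell_map(pro2, 10, channel = "proliferation"))
  prof2 <- axis_profile(sp2, roi, axis = "dv", K = 4)
  expect_gt(mean(prof2$fraction[3:4]), mean(prof2$fraction[1:2]) + 0.1)
  expect_error(axis_profile(sp, roi, axis = c(1, 0, 0) * 0), "sum")
})

test_that("KS uniformity test matches analytic cases", {
  x <- runif(50)
  same <- ks_uniformity(x, "nuclei", nucleus_positions = x)
  expect_equal(same$D, 0)
  # all mass at 0.5 against Uniform(0,1): D = 0.5 by CDF geometry
  half <- ks_uniformity(rep(0.5, 100), "uniform01")
  expect_equal(half$D, 0.5)
  expect_error(ks_uniformity(runif(5), "uniform01"), "at least 10")
  expect_error(ks_uniformity(runif(20), "nuclei"), "requires")
})

test_that("KS type-I error is near nominal for uniform positions", {
  set.seed(11)
  reps <- 300
  pvals <- replicate(reps, ks_uniformity(runif(80), "uniform01")$p)
  rej <- mean(pvals <= 0.05)
  expect_lt(abs(rej - 0.05), 0.04)
})

test_that("the baseline segmenter recovers two-level phantoms", {
  truth <- cube_map(12, c(3, 3, 3), c(8, 8, 8))
  inten <- prolif_map(as.array(truth) * 0.8 + 0.05, 10)
  seg <- baseline_segmenter(inten, "otsu")
  expect_identical(as.array(seg), as.array(truth))
  expect_error(baseline_segmenter(prolif_map(array(0.5, c(4, 4, 4)), 1)),
               "constant")
  empty <- baseline_segmenter(inten, method = 2)
  expect_equal(sum(as.array(empty)), 0)
})
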