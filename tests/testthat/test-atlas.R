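test_that("majority voting counts labels and breaks ties by priority", {
  v <- cached_specimen()$labels
  same <- majority_vote_atlas(list(v, v, v))
  expect_identical(as.array(same$atlas), as.array(v))
  expect_true(all(same$vote_fraction == 1))
  mk <- function(val) labeled_volume(array(val, c(2, 2, 2)), 1)
  tri <- majority_vote_atlas(list(mk(1L), mk(1L), mk(2L)))
  expect_true(all(as.array(tri$atlas) == 1))
  expect_true(all(tri$vote_fraction == 2 / 3))
  tie <- majority_vote_atlas(list(mk(1L), mk(2L)))
  expect_true(all(as.array(tie$atlas) == 2)) # higher label wins ties
  # order invariance
  set.seed(1)
  vols <- lapply(1:4, function(i)
    labeled_volume(array(sample(0:2, 64, TRUE), c(4, 4, 4)), 1))
  expect_identical(as.array(majority_vote_atlas(vols)$atlas),
                   as.array(majority_vote_atlas(rev(vols))$atlas))
  expect_error(majority_vote_atlas(list(mk(1L), ball_volume(8, 2))),
               "mismatch")
})

test_that("windowed proliferation density matches a brute-force oracle", {
  allon <- cell_map(array(1L, c(8, 8, 8)), 50, channel = "proliferation")
  expect_true(all(as.array(proliferation_density(allon, 150)) == 1))
  # single positive voxel: centre value 1 / w^3
  a <- array(0L, c(9, 9, 9)); a[5, 5, 5] <- 1L
  dens <- proliferation_density(cell_map(a, 50, channel = "proliferation"),
                                150)
  expect_equal(as.array(dens)[5, 5, 5], 1 / 3^3)
  # brute force triple loop on a random 16^3 fixture
  set.seed(5)
  b <- array(as.integer(runif(16^3) < 0.2), c(16, 16, 16))
  got <- as.array(proliferation_density(
    cell_map(b, 50, channel = "proliferation"), 250))  # 5-voxel window
  r <- 2
  want <- array(0, dim(b))
  for (k in 1:16) for (j in 1:16) for (i in 1:16) {
    xs <- max(1, i - r):min(16, i + r)
    ys <- max(1, j - r):min(16, j + r)
    zs <- max(1, k - r):min(16, k + r)
    want[i, j, k] <- mean(b[xs, ys, zs])
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(proliferation_density(allon, 10), "smaller than one voxel")
})

test_that("percentile equalization maps the band to [0,1] invariantly", {
  set.seed(9)
  raw <- prolif_map(array(runif(16^3), c(16, 16, 16)), 25)
  out <- percentile_equalize(raw)
  expect_true(all(as.array(out) >= 0 & as.array(out) <= 1))
  q <- quantile(as.array(raw), c(0.01, 0.99), names = FALSE)
  expect_equal(as.array(out)[as.array(raw) <= q[1]],
               rep(0, sum(as.array(raw) <= q[1])))
  expect_true(all(as.array(out)[as.array(raw) >= q[2]] == 1))
  # invariance under positive affine rescaling of the input
  resc <- percentile_equalize(prolif_map(3.7 * as.array(raw) + 0.2, 25))
  expect_equal(as.array(resc), as.array(out), tolerance = 1e-12)
  # 0..100 uniform fixture: value 50 -> (50 - 1) / 98
  vals <- array(0:100, c(101, 1, 1))
  eq <- percentile_equalize(prolif_map(vals, 1))
  expect_equal(as.array(eq)[vals == 50][1], (50 - 1) / 98)
  # constant map degenerates to zero
  expect_true(all(as.array(percentile_equalize(
    prolif_map(array(0.4, c(4, 4, 4)), 1))) == 0))
  # monotone non-decreasing in the input value
  o <- order(as.vector(vals))
  expect_true(all(diff(as.vector(as.array(eq))[o]) >= 0))
})

test_that("box-filter density preserves the global mean within 1%", {
  set.seed(2)
  b <- array(as.integer(runif(20^3) < 0.15), c(20, 20, 20))
  dens <- proliferation_density(cell_map(b, 50, channel = "proliferation"),
                                150)
  expect_lt(abs(mean(as.array(dens)) - mean(b)) / mean(b), 0.01)
})

test_that("mirrored averaging produces symmetric group atlases", {
  sym <- prolif_map(array(0.5, c(6, 6, 6)), 1, normalized = TRUE)
  expect_equal(as.array(mean_proliferation_atlas(list(sym))), as.array(sym))
  set.seed(3)
  m <- prolif_map(array(runif(6^3), c(6, 6, 6)), 1, normalized = TRUE)
  avg <- mean_proliferation_atlas(list(m), include_mirrored = TRUE)
  expect_equal(as.array(avg), as.array(mirror(avg)), tolerance = 1e-12)
  two <- mean_proliferation_atlas(
    list(prolif_map(array(0.2, c(4, 4, 4)), 1, normalized = TRUE),
         prolif_map(array(0.4, c(4, 4, 4)), 1, normalized = TRUE)),
    include_mirrored = FALSE)
  expect_true(all(abs(as.array(two) - 0.3) < 1e-12))
})

test_that("the face mask is the expected surface shell of a ball", {
  # ball radius 1 mm at 25 um spacing; shell depth 390 um
  v <- ball_volume(n = 96, r_vox = 40, spacing = 25)
  fm <- build_face_mask(list(v, v, v), vote_thresh = 0.30,
                        shell_depth_um = 390)
  r_out <- 40 * 25
  # voxels deeper than 390 um are excluded: expected shell volume
  expected <- 4 / 3 * pi * (r_out^3 - (r_out - 390)^3) / 25^3
  expect_lt(abs(sum(fm$mask) - expected) / expected, 0.02)
  left <- array(0L, c(20, 20, 20)); left[2:5, 2:5, 2:5] <- 1L
  right <- array(0L, c(20, 20, 20)); right[14:17, 14:17, 14:17] <- 1L
  expect_error(build_face_mask(list(labeled_volume(left, 25),
                                    labeled_volume(right, 25)),
                               vote_thresh = 0.999), "empty")
  roi_full <- array(TRUE, dim(v))
  fm2 <- build_face_mask(list(v, v, v), 0.30, 390, roi = roi_full)
  expect_identical(fm2$mask, fm$mask)
})

test_that("face mask size is monotone in threshold and shell depth", {
  spec <- phantom_spec(grid_shape = 32, seed = 44)
  vols <- lapply(1:4, function(i) generate_specimen(spec, "E10", i)$labels)
  n1 <- sum(build_face_mask(vols, 0.2, 300)$mask)
  n2 <- sum(build_face_mask(vols, 0.6, 300)$mask)
  expect_gte(n1, n2)
  n3 <- sum(build_face_mask(vols, 0.3, 150)$mask)
  n4 <- sum(build_face_mask(vols, 0.3, 500)$mask)
  expect_lte(n3, n4)
})

test_that("mutant masks close holes and closing is idempotent", {
  solid <- ball_volume(n = 32, r_vox = 10, spacing = 25)
  m1 <- build_mutant_mask(list(solid), closing_vox = 6,
                          shell_depth_um = 1e5)
  expect_identical(m1$mask, as.array(solid) > 0)  # convex: closing = identity
  holed <- as.array(solid)
  holed[15:17, 15:17, 15:17] <- 0L
  hv <- labeled_volume(holed, 25)
  m2 <- build_mutant_mask(list(hv), closing_vox = 8, shell_depth_um = 1e5)
  expect_true(all(m2$mask[15:17, 15:17, 15:17]))  # interior hole filled
  # closing twice equals closing once
  once <- prolifatlas:::binary_closing(holed > 0, 4)
  twice <- prolifatlas:::binary_closing(once, 4)
  expect_identical(once, twice)
})
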