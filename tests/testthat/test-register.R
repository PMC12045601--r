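test_that("landmark transforms recover synthetic similarity maps exactly", {
  src <- random_landmarks(37, seed = 3)
  ident <- fit_landmark_transform(src, src, "rigid")
  expect_equal(ident$A, diag(3), tolerance = 1e-12)
  expect_lt(ident$rms, 1e-9)
  R <- rotation_z(30 * pi / 180)
  s <- 1.5
  t <- c(120, -45, 80)
  tgt <- landmark_set(src$name,
                      sweep(as.matrix(src[, 2:4]) %*% t(R) * s, 2, t, "+"))
  fit <- fit_landmark_transform(src, tgt, "similarity")
  expect_equal(fit$R, R, tolerance = 1e-12)
  expect_equal(fit$s, s, tolerance = 1e-12)
  expect_equal(fit$t, t, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
  # rigid fit of a scaled target cannot absorb scale
  rig <- fit_landmark_transform(src, tgt, "rigid")
  expect_equal(rig$s, 1)
})

test_that("degenerate landmark configurations are rejected", {
  two <- landmark_set(c("a", "b"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(fit_landmark_transform(two, two, "rigid"), "at least 3")
  line <- landmark_set(c("a", "b", "c"),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(fit_landmark_transform(line, line, "rigid"), "collinear")
  named <- random_landmarks(5)
  renamed <- named
  renamed$name <- rev(named$name)
  expect_error(fit_landmark_transform(named, renamed), "names")
})

test_that("apply_transform shifts, inverts and preserves voxel content", {
  v <- cube_map(16, c(4, 4, 4), c(7, 7, 7), spacing = 5)
  ident <- affine_transform(diag(3), c(0, 0, 0))
  expect_identical(as.array(apply_transform(ident, v)), as.array(v))
  # translate by exactly 2 voxels along x
  tr <- affine_transform(diag(3), c(10, 0, 0))
  out <- apply_transform(tr, v)
  expect_identical(as.array(out)[6:9, 4:7, 4:7],
                   as.array(v)[4:7, 4:7, 4:7])
  expect_equal(sum(as.array(out)), sum(as.array(v)))
  # landmarks: forward then inverse returns the originals
  lm <- random_landmarks(8, seed = 5)
  chain <- affine_transform(1.2 * rotation_z(0.4), c(5, 6, 7))
  back <- apply_transform(invert_transform(chain),
                          apply_transform(chain, lm))
  expect_equal(as.matrix(back[, 2:4]), as.matrix(lm[, 2:4]),
               tolerance = 1e-6)
  lab <- cached_specimen()$labels
  expect_error(apply_transform(ident, lab, interpolation = "linear"),
               "nearest")
})

test_that("composition applies transforms in declared order", {
  t1 <- affine_transform(rotation_z(0.3), c(1, 2, 3))
  t2 <- affine_transform(diag(c(2, 2, 2)), c(-5, 0, 5))
  p <- c(10, 20, 30)
  lm <- landmark_set("p", rbind(p))
  via <- apply_transform(t2, apply_transform(t1, lm))
  comp <- apply_transform(compose_transforms(t2, t1), lm)
  expect_equal(as.matrix(via[, 2:4]), as.matrix(comp[, 2:4]),
               tolerance = 1e-10)
})

test_that("jacobian of analytic displacement fields is exact", {
  d <- c(12, 12, 12)
  zero <- displacement_transform(array(0, c(d, 3)), 2)
  expect_true(all(jacobian_determinant(zero)$values == 1))
  s <- 1.1
  h <- 2
  u <- array(0, c(d, 3))
  u[, , , 1] <- array(rep((seq_len(d[1]) - 1) * h, prod(d[2:3])), d)
  u[, , , 2] <- array(rep(rep((seq_len(d[2]) - 1) * h, each = d[1]),
                          d[3]), d)
  u[, , , 3] <- array(rep((seq_len(d[3]) - 1) * h, each = d[1] * d[2]), d)
  J <- jacobian_determinant(displacement_transform(u * (s - 1), h))
  expect_lt(max(abs(J$values - s^3)), 1e-6)
})

test_that("jacobian matches an independent finite-difference oracle", {
  tr <- smooth_random_field(n = 16, spacing = 10, amp = 2, seed = 8)
  J <- jacobian_determinant(tr)$values
  # oracle: direct loops with an independently ordered stencil
  u <- tr$disp
  h <- tr$spacing
  n <- dim(u)[1:3]
  oracle <- array(NA_real_, n)
  for (k in 2:(n[3] - 1)) for (j in 2:(n[2] - 1)) for (i in 2:(n[1] - 1)) {
    G <- matrix(0, 3, 3)
    for (cc in 1:3) {
      G[cc, 1] <- (u[i + 1, j, k, cc] - u[i - 1, j, k, cc]) / (2 * h[1])
      G[cc, 2] <- (u[i, j + 1, k, cc] - u[i, j - 1, k, cc]) / (2 * h[2])
      G[cc, 3] <- (u[i, j, k + 1, cc] - u[i, j, k - 1, cc]) / (2 * h[3])
    }
    oracle[i, j, k] <- det(diag(3) + G)
  }
  inside <- !is.na(oracle)
  expect_lt(max(abs(J[inside] - oracle[inside])), 1e-10)
})

test_that("groupwise registration handles degenerate cohorts", {
  v <- ball_volume(24, 8, 25)
  single <- groupwise_affine(list(v))
  expect_identical(as.array(single$mean), as.array(v))
  same <- groupwise_affine(list(v, v, v), max_outer = 1,
                           resolutions = c(2), max_iterations = 20,
                           step = 1)
  expect_identical(as.array(same$mean), as.array(v))
  for (tr in same$transforms) {
    expect_lt(max(abs(tr$A - diag(3))), 0.02)
    expect_lt(max(abs(tr$t)), 0.75 * 25)
  }
})

test_that("groupwise mean is invariant to cohort ordering", {
  spec <- phantom_spec(grid_shape = 32, seed = 33)
  vols <- lapply(1:3, function(i) generate_specimen(spec, "E10", i)$labels)
  a <- groupwise_affine(vols, reference = 1, max_outer = 1,
                        resolutions = c(2), max_iterations = 25, step = 1)
  b <- groupwise_affine(vols[c(1, 3, 2)], reference = 1, max_outer = 1,
                        resolutions = c(2), max_iterations = 25, step = 1)
  expect_identical(as.array(a$mean), as.array(b$mean))
})

test_that("deformable registration is conservative on identical inputs", {
  v <- ball_volume(24, 8, 25)
  tr <- nonlinear_register(v, v, iterations = c(10, 5))
  expect_lt(max(abs(tr$disp)), 1)          # near-zero displacement (µm)
  J <- jacobian_determinant(tr)
  expect_lt(max(abs(J$values - 1)), 0.05)  # J about 1 everywhere
  expect_gte(attr(tr, "jac_positive"), 0.99)
})

test_that("deformable registration improves label overlap on phantom pairs", {
  spec <- phantom_spec(grid_shape = 48, seed = 12)
  a <- generate_specimen(spec, "E10", 1)$labels
  b <- generate_specimen(spec, "E11.5", 2)$labels
  before <- dice(as.array(a) > 0, as.array(b) > 0)
  tr <- nonlinear_register(a, b, iterations = c(20, 8))
  warped <- apply_transform(tr, a)
  after <- dice(as.array(warped) > 0, as.array(b) > 0)
  expect_gt(after, before)
})
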