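#' Intensity-free registration of label volumes
#'
#' Registration operates on one-hot indicator images of the nonzero tissue
#' labels (mesenchyme, neural ectoderm): inputs are segmentations, so a
#' mean-squared-difference metric on indicators is used rather than an
#' intensity metric. Optimization is multi-resolution with linear
#' interpolation; final resampling of label volumes is nearest neighbour.
#' @name registration
NULL

# Gaussian-smoothed indicator channels of the nonzero labels, as a single
# numeric vector (channels concatenated), plus grid info.
label_indicators <- function(vol, labels = NULL, sigma = 0) {
  arr <- as.array(vol)
  labels <- labels %||% sort(setdiff(unique(as.vector(arr)), 0))
  if (length(labels) == 0) labels <- 1
  d <- dim(arr)
  chans <- lapply(labels, function(L) {
    ch <- as.numeric(arr == L)
    if (sigma > 0) ch <- cpp_gauss3(ch, as.integer(d), rep(sigma, 3))
    ch
  })
  list(ind = unlist(chans), dim = d, nchan = length(labels),
       spacing = spacing(vol), labels = labels)
}

# downsample an indicator set by an integer factor (smooth then resample)
downsample_indicators <- function(ind, factor) {
  if (factor == 1) return(ind)
  d <- ind$dim
  dd <- as.integer(ceiling(d / factor))
  sp2 <- ind$spacing * factor
  n <- prod(d)
  chans <- lapply(seq_len(ind$nchan), function(c) {
    ch <- ind$ind[((c - 1) * n + 1):(c * n)]
    ch <- cpp_gauss3(ch, as.integer(d), rep(factor / 2, 3))
    cpp_resample_affine(ch, as.integer(d), ind$spacing, c(0, 0, 0),
                        dd, sp2, c(0, 0, 0), as.numeric(diag(3)),
                        c(0, 0, 0), FALSE)
  })
  list(ind = unlist(chans), dim = dd, nchan = ind$nchan, spacing = sp2,
       labels = ind$labels)
}

# pull-map affine parameters -> (A, t) acting on origin-relative world coords
params_to_pull <- function(p, cen) {
  M <- diag(3) + matrix(p[1:9], 3, 3)
  t <- p[10:12]
  list(A = M, t = cen + as.numeric(t) - as.numeric(M %*% cen))
}

#' Affine registration of two label volumes
#'
#' Finds the affine transform aligning `moving` to `fixed` by minimizing the
#' mean-squared difference of tissue indicator images over a coarse-to-fine
#' pyramid (BFGS at each level). Both volumes must share one grid (use a
#' landmark rigid pre-alignment first).
#'
#' @param moving,fixed [labeled_volume()]s on a common grid.
#' @param resolutions Integer downsampling factors, coarse to fine.
#' @param max_iterations BFGS iteration cap per level (recycled).
#' @param step Voxel stride of the metric per level (recycled); 2 probes
#'   every other voxel.
#' @param smooth_sigma Gaussian smoothing (voxels) of the indicators.
#' @param init Optional 12-parameter warm start.
#' @return An [affine_transform()] (forward, moving to fixed) with fields
#'   `params` and `metric` (final MSD).
#' @export
affine_register <- function(moving, fixed, resolutions = c(4, 2, 1),
                            max_iterations = c(60, 30, 15), step = c(1, 2, 2),
                            smooth_sigma = 1, init = NULL) {
  if (!same_grid(moving, fixed)) moving <- resample_to_grid(moving, grid_of(fixed))
  mov <- label_indicators(moving, labels = 1:2, sigma = smooth_sigma)
  fix <- label_indicators(fixed, labels = 1:2, sigma = smooth_sigma)
  fit <- affine_register_core(mov, fix, resolutions, max_iterations, step,
                              p0 = init)
  pull <- params_to_pull(fit$par, fit$cen)
  org <- origin(fixed)
  tt <- pull$t + org - as.numeric(pull$A %*% org)
  fwd <- invert_transform(affine_transform(pull$A, tt, "affine"))
  fwd$params <- fit$par
  fwd$metric <- fit$value
  fwd
}

affine_register_core <- function(mov, fix, resolutions, max_iterations,
                                 step, p0 = NULL) {
  max_iterations <- rep_len(max_iterations, length(resolutions))
  step <- rep_len(step, length(resolutions))
  p <- p0 %||% rep(0, 12)
  cen <- NULL
  value <- NA_real_
  for (L in seq_along(resolutions)) {
    f <- resolutions[L]
    mL <- downsample_indicators(mov, f)
    fL <- downsample_indicators(fix, f)
    cen <- (fL$dim - 1) * fL$spacing / 2
    costfun <- function(p) {
      # cpp_msd_affine applies the centring: y = cen + M (w - cen) + t
      cpp_msd_affine(fL$ind, mL$ind, as.integer(fL$dim), fL$nchan,
                     fL$spacing, as.numeric(diag(3) + matrix(p[1:9], 3, 3)),
                     p[10:12], cen, as.integer(step[L]))
    }
    sc <- c(rep(0.05, 9), rep(2 * max(fL$spacing), 3))
    opt <- stats::optim(p, costfun, method = "BFGS",
                        control = list(maxit = max_iterations[L],
                                       parscale = sc, reltol = 1e-9))
    p <- opt$par
    value <- opt$value
  }
  list(par = p, value = value, cen = cen)
}

#' Groupwise affine registration with an evolving majority-vote mean
#'
#' Implements the iterated-mean groupwise scheme: initialize the mean with
#' the reference label volume; affinely register every volume to the mean;
#' recompute the mean by per-voxel majority vote; repeat until the fraction
#' of mean voxels that change label falls below `tol` or `max_outer`
#' iterations are reached. Volumes are expected to be pre-aligned with a
#' landmark rigid transform. The result is invariant to the ordering of the
#' cohort (for a fixed reference) because the vote is symmetric.
#'
#' @param vols List of [labeled_volume()]s on a common grid.
#' @param reference Index or name of the reference volume (initial mean).
#' @param tol Convergence threshold on the mean label-change fraction.
#' @param max_outer Maximum outer iterations.
#' @inheritParams affine_register
#' @return A list with `transforms` (forward affines, one per volume),
#'   `mean` (the final majority-vote [labeled_volume()]), `registered`
#'   (volumes resampled into the mean space, nearest neighbour), `n_outer`,
#'   and `change` (label-change fraction per outer iteration).
#' @export
groupwise_affine <- function(vols, reference = 1, tol = 1e-3, max_outer = 10,
                             resolutions = c(4, 2, 1),
                             max_iterations = c(60, 30, 15),
                             step = c(1, 2, 2), smooth_sigma = 1) {
  stopifnot(length(vols) >= 1)
  for (v in vols) if (!same_grid(v, vols[[1]]))
    stopf("groupwise_affine: all volumes must share one grid")
  if (length(vols) == 1) {
    return(list(transforms = list(affine_transform(diag(3), c(0, 0, 0))),
                mean = vols[[1]], registered = vols, n_outer = 0L,
                change = numeric(0)))
  }
  mov_ind <- lapply(vols, label_indicators, labels = 1:2,
                    sigma = smooth_sigma)
  mean_lab <- vols[[reference]]
  params <- rep(list(rep(0, 12)), length(vols))
  change <- numeric(0)
  fits <- NULL
  for (outer in seq_len(max_outer)) {
    fix_ind <- label_indicators(mean_lab, labels = 1:2, sigma = smooth_sigma)
    fits <- lapply(seq_along(vols), function(i)
      affine_register_core(mov_ind[[i]], fix_ind, resolutions,
                           max_iterations, step, p0 = params[[i]]))
    params <- lapply(fits, `[[`, "par")
    registered <- lapply(seq_along(vols), function(i) {
      pull <- params_to_pull(fits[[i]]$par, fits[[i]]$cen)
      org <- origin(mean_lab)
      tt <- pull$t + org - as.numeric(pull$A %*% org)
      fwd <- invert_transform(affine_transform(pull$A, tt, "affine"))
      apply_transform(fwd, vols[[i]], grid = mean_lab)
    })
    new_mean <- majority_vote_atlas(registered)$atlas
    delta <- mean(as.array(new_mean) != as.array(mean_lab))
    change <- c(change, delta)
    mean_lab <- new_mean
    if (delta < tol) break
  }
  transforms <- lapply(seq_along(vols), function(i) {
    pull <- params_to_pull(fits[[i]]$par, fits[[i]]$cen)
    org <- origin(mean_lab)
    tt <- pull$t + org - as.numeric(pull$A %*% org)
    fwd <- invert_transform(affine_transform(pull$A, tt, "affine"))
    fwd$metric <- fits[[i]]$value
    fwd
  })
  registered <- lapply(seq_along(vols), function(i)
    apply_transform(transforms[[i]], vols[[i]], grid = mean_lab))
  list(transforms = transforms, mean = mean_lab, registered = registered,
       n_outer = length(change), change = change)
}

#' Deformable (demons) registration of label volumes
#'
#' Gaussian-regularized demons on tissue indicator images, multi-resolution.
#' The returned displacement field lives on the fixed grid and maps
#' fixed-space points into the moving volume; [apply_transform()] with it
#' warps the moving volume (or its proliferation map) onto the fixed grid,
#' and [jacobian_determinant()] of the field measures the local volume of
#' the moving anatomy relative to the fixed anatomy (values above 1 where
#' the moving specimen is locally larger). A diagnostic fraction of
#' positive-Jacobian tissue voxels is attached; a warning is raised when it
#' falls below `jac_threshold`.
#'
#' @param moving,fixed [labeled_volume()]s on a common grid (affinely
#'   pre-aligned).
#' @param iterations Demons iterations per level, coarse to fine.
#' @param factors Downsampling factor per level.
#' @param sigma_fluid Gaussian sigma (voxels) smoothing each update.
#' @param sigma_elastic Gaussian sigma (voxels) smoothing the accumulated
#'   field.
#' @param smooth_sigma Indicator pre-smoothing (voxels).
#' @param max_step Per-iteration displacement cap in voxels.
#' @param jac_threshold Minimum acceptable fraction of tissue voxels with
#'   positive Jacobian.
#' @return A [displacement_transform()] with attributes `jac_positive`
#'   (diagnostic fraction) and `metric`.
#' @export
nonlinear_register <- function(moving, fixed, iterations = c(40, 15),
                               factors = c(2, 1), sigma_fluid = 3,
                               sigma_elastic = 0.5, smooth_sigma = 1,
                               max_step = 1.25, jac_threshold = 0.99) {
  if (!same_grid(moving, fixed)) moving <- resample_to_grid(moving, grid_of(fixed))
  mov <- label_indicators(moving, labels = 1:2, sigma = smooth_sigma)
  fix <- label_indicators(fixed, labels = 1:2, sigma = smooth_sigma)
  u <- NULL
  for (L in seq_along(factors)) {
    f <- factors[L]
    mL <- downsample_indicators(mov, f)
    fL <- downsample_indicators(fix, f)
    if (is.null(u)) {
      u_init <- numeric(0)
    } else {
      # upsample previous-level field (µm values carry over unchanged)
      u_init <- unlist(lapply(1:3, function(c)
        cpp_resample_affine(as.numeric(u$comp[[c]]), as.integer(u$dim),
                            u$spacing, c(0, 0, 0), as.integer(fL$dim),
                            fL$spacing, c(0, 0, 0), as.numeric(diag(3)),
                            c(0, 0, 0), FALSE)))
    }
    uf <- cpp_demons(fL$ind, mL$ind, as.integer(fL$dim), fL$nchan,
                     fL$spacing, as.integer(iterations[L]),
                     sigma_fluid, sigma_elastic, max_step, u_init)
    n <- prod(fL$dim)
    u <- list(comp = lapply(1:3, function(c)
      array(uf[((c - 1) * n + 1):(c * n)], fL$dim)),
      dim = fL$dim, spacing = fL$spacing)
  }
  disp <- array(0, c(u$dim, 3))
  for (c in 1:3) disp[, , , c] <- u$comp[[c]]
  tr <- displacement_transform(disp, grid_spacing = u$spacing,
                               grid_origin = origin(fixed))
  J <- jacobian_determinant(tr)
  tissue <- as.array(fixed) > 0
  frac <- mean(J$values[tissue] > 0)
  if (is.finite(frac) && frac < jac_threshold)
    warnf("nonlinear_register: only %.1f%% of tissue voxels have J > 0",
          100 * frac)
  attr(tr, "jac_positive") <- frac
  tr
}

#' Jacobian determinant of a dense displacement field
#'
#' Computes `J(v) = det(I + grad u(v))` per voxel, with central differences
#' in the interior and one-sided differences at the grid borders; gradients
#' are taken in world units so anisotropic spacing is handled. `J` is 1
#' everywhere for a zero field, equals `s^3` for a uniform scaling
#' displacement `u(x) = (s - 1) x`, and integrates to the source-region
#' volume over a warped region.
#'
#' @param transform A [displacement_transform()].
#' @return A `jacobian_field`: list with `values` (3D array), `spacing`,
#'   `origin`.
#' @export
jacobian_determinant <- function(transform) {
  stopifnot(inherits(transform, "displacement_transform"))
  u <- transform$disp
  d <- dim(u)[1:3]
  sp <- transform$spacing
  g <- vector("list", 9) # g[[3*(a-1)+c]] = d u_c / d x_a
  for (a in 1:3) {
    h <- sp[a]
    for (c in 1:3) {
      uc <- u[, , , c]
      gp <- shift_arr(uc, a, 1)   # u at index + 1
      gm <- shift_arr(uc, a, -1)  # u at index - 1
      gr <- (gp - gm) / (2 * h)
      # one-sided at the two faces normal to axis a
      gr <- fix_border(gr, uc, a, h)
      g[[3 * (a - 1) + c]] <- gr
    }
  }
  F11 <- 1 + g[[1]]; F21 <- g[[2]];     F31 <- g[[3]]
  F12 <- g[[4]];     F22 <- 1 + g[[5]]; F32 <- g[[6]]
  F13 <- g[[7]];     F23 <- g[[8]];     F33 <- 1 + g[[9]]
  J <- F11 * (F22 * F33 - F23 * F32) -
       F12 * (F21 * F33 - F23 * F31) +
       F13 * (F21 * F32 - F22 * F31)
  structure(list(values = J, spacing = sp, origin = transform$origin),
            class = "jacobian_field")
}

# shift array along axis by k voxels (replicating the border)
shift_arr <- function(x, axis, k) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] + k, 1), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(x), idx))
}

# replace the central-difference estimate at the two faces normal to `axis`
# with one-sided differences
fix_border <- function(gr, uc, axis, h) {
  d <- dim(uc)
  n <- d[axis]
  if (n < 2) return(gr * 0)
  sel <- function(i) {
    idx <- lapply(d, seq_len)
    idx[[axis]] <- i
    do.call(`[`, c(list(uc), idx, list(drop = FALSE)))
  }
  asn <- function(g, i, val) {
    idx <- lapply(d, seq_len)
    idx[[axis]] <- i
    do.call(`[<-`, c(list(g), idx, list(val)))
  }
  gr <- asn(gr, 1, (sel(2) - sel(1)) / h)
  asn(gr, n, (sel(n) - sel(n - 1)) / h)
}
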