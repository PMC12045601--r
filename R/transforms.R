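#' Spatial transforms
#'
#' An `affine_transform` stores the forward map from moving (source) to
#' fixed (target) world coordinates, `y = A x + t` (µm). Rigid transforms
#' have orthonormal `A` with determinant +1; similarity transforms add a
#' single uniform scale `s`. A `displacement_transform` stores a dense
#' displacement field `u` on the fixed grid, such that resampling the moving
#' image probes it at `x + u(x)` (the field that warps the moving image onto
#' the fixed grid).
#'
#' @param A 3x3 matrix.
#' @param t Length-3 translation (µm).
#' @param kind `"rigid"`, `"similarity"`, or `"affine"`.
#' @return An `affine_transform`.
#' @export
affine_transform <- function(A, t, kind = "affine") {
  stopifnot(all(dim(A) == c(3, 3)), length(t) == 3)
  if (abs(det(A)) < 1e-12) stopf("affine transform must be invertible")
  structure(list(A = A, t = as.numeric(t), kind = kind),
            class = "affine_transform")
}

#' @rdname affine_transform
#' @param disp 4D array `c(dim, 3)` of displacements in µm on the fixed grid.
#' @param grid_spacing,grid_origin Fixed-grid geometry.
#' @export
displacement_transform <- function(disp, grid_spacing, grid_origin = c(0, 0, 0)) {
  stopifnot(length(dim(disp)) == 4, dim(disp)[4] == 3)
  if (length(grid_spacing) == 1) grid_spacing <- rep(grid_spacing, 3)
  structure(list(disp = disp, spacing = as.numeric(grid_spacing),
                 origin = as.numeric(grid_origin)),
            class = "displacement_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> kind=%s\n", x$kind))
  print(cbind(x$A, t = x$t))
  invisible(x)
}

#' Fit a landmark-based rigid or similarity transform
#'
#' Closed-form least-squares absolute orientation (SVD of the cross
#' covariance): finds the rotation, optional uniform scale, and translation
#' mapping `source` landmarks onto `target` landmarks. Used with the 5 head
#' landmarks (rigid, atlas stage) and the 37 face landmarks (similarity,
#' bulk analysis stage).
#'
#' @param source,target [landmark_set()]s with identical names and order.
#' @param kind `"rigid"` (no scale) or `"similarity"` (uniform scale).
#' @return An [affine_transform()] with extra fields `R`, `s`, `rms` (µm).
#' @export
fit_landmark_transform <- function(source, target,
                                   kind = c("rigid", "similarity")) {
  kind <- match.arg(kind)
  if (!identical(source$name, target$name))
    stopf("source and target landmark names/order differ")
  P <- lm_coords(source)
  Q <- lm_coords(target)
  n <- nrow(P)
  if (n < 3) stopf("at least 3 landmarks are required, got %d", n)
  mp <- colMeans(P); mq <- colMeans(Q)
  Pc <- sweep(P, 2, mp); Qc <- sweep(Q, 2, mq)
  H <- crossprod(Pc, Qc) / n
  if (qr(Pc)$rank < 2 || sum(svd(H)$d > 1e-12 * max(svd(H)$d)) < 2)
    stopf("degenerate (collinear) landmark configuration")
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (kind == "similarity")
    sum(diag(D) * sv$d) / mean(rowSums(Pc^2)) else 1
  t <- mq - s * as.numeric(R %*% mp)
  A <- s * R
  res <- sweep(P %*% t(A), 2, t, "+") - Q
  out <- affine_transform(A, t, kind)
  out$R <- R
  out$s <- s
  out$rms <- sqrt(mean(rowSums(res^2)))
  out
}

#' Invert or compose affine transforms
#'
#' @param x An [affine_transform()].
#' @return The inverse transform; `compose_transforms(T2, T1)` applies `T1`
#'   first, then `T2`.
#' @export
invert_transform <- function(x) {
  Ai <- solve(x$A)
  affine_transform(Ai, -as.numeric(Ai %*% x$t), x$kind)
}

#' @rdname invert_transform
#' @param t2,t1 Transforms; `t1` is applied first.
#' @export
compose_transforms <- function(t2, t1) {
  affine_transform(t2$A %*% t1$A, as.numeric(t2$A %*% t1$t) + t2$t, "affine")
}

#' Apply a spatial transform
#'
#' Volumes living in the moving (source) space are resampled onto a fixed
#' grid: each fixed voxel centre is pulled back through the inverse map and
#' the moving volume is interpolated there (nearest neighbour for label and
#' binary volumes, linear otherwise). Landmarks are mapped forward. For a
#' [displacement_transform()] the moving volume is probed at `x + u(x)`.
#'
#' @param transform An [affine_transform()] or [displacement_transform()].
#' @param x A `volume3d` or [landmark_set()].
#' @param grid Fixed grid for volume resampling: a `volume3d` to copy the
#'   grid from, or a list with `dim`, `spacing`, `origin`. Defaults to the
#'   grid of `x`.
#' @param interpolation `"nearest"` or `"linear"`; defaults by volume class.
#' @return The transformed object.
#' @export
apply_transform <- function(transform, x, grid = NULL, interpolation = NULL) {
  if (inherits(x, "landmark_set")) {
    if (!inherits(transform, "affine_transform"))
      stopf("dense displacement transforms apply to volumes only")
    co <- sweep(lm_coords(x) %*% t(transform$A), 2, transform$t, "+")
    return(landmark_set(x$name, co))
  }
  stopifnot(inherits(x, "volume3d"))
  if (inherits(grid, "volume3d")) grid <- grid_of(grid)
  grid <- grid %||% grid_of(x)
  nearest <- if (is.null(interpolation))
    inherits(x, c("labeled_volume", "cell_map"))
  else match.arg(interpolation, c("nearest", "linear")) == "nearest"
  if (inherits(x, "labeled_volume") && !nearest)
    stopf("label volumes require nearest-neighbour interpolation")
  if (inherits(transform, "affine_transform")) {
    inv <- invert_transform(transform)
    out <- cpp_resample_affine(as.numeric(x), as.integer(dim(x)),
                               spacing(x), origin(x), as.integer(grid$dim),
                               grid$spacing, grid$origin,
                               as.numeric(inv$A), inv$t, nearest)
  } else if (inherits(transform, "displacement_transform")) {
    dd <- dim(transform$disp)[1:3]
    out <- cpp_resample_disp(as.numeric(x), as.integer(dim(x)), spacing(x),
                             origin(x), as.numeric(transform$disp),
                             as.integer(dd), transform$spacing,
                             transform$origin, nearest)
    grid <- list(dim = dd, spacing = transform$spacing,
                 origin = transform$origin)
  } else stopf("unknown transform type")
  arr <- array(out, grid$dim)
  if (nearest && inherits(x, "cell_map")) arr <- round(arr)
  if (inherits(x, "prolif_map") && attr(x, "normalized"))
    arr <- pmin(pmax(arr, 0), 1)
  rewrap(x, arr, spacing = grid$spacing, origin = grid$origin)
}
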