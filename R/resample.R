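#' Resample a stack to an isotropic grid
#'
#' Light-sheet stacks are anisotropic (e.g. 0.9 µm in plane, 5 µm between
#' slices); downstream registration and morphometry assume isotropic voxels.
#' The output grid keeps the input origin; the number of voxels per axis is
#' `ceiling(extent / target_spacing)` with `extent = n * spacing`, so tissue
#' is never truncated. Label and binary volumes must use nearest-neighbour
#' interpolation; real-valued maps default to linear.
#'
#' @param vol A `volume3d`.
#' @param target_spacing Isotropic output spacing in µm. Default: the
#'   smallest input spacing (the in-plane resolution).
#' @param interpolation `"nearest"` or `"linear"`; defaults to nearest for
#'   `labeled_volume`/`cell_map` and linear otherwise.
#' @return A volume of the same class on the isotropic grid.
#' @export
resample_isotropic <- function(vol, target_spacing = NULL,
                               interpolation = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  target_spacing <- target_spacing %||% min(spacing(vol))
  if (target_spacing <= 0) stopf("target_spacing must be positive")
  discrete <- inherits(vol, c("labeled_volume", "cell_map"))
  interpolation <- interpolation %||% (if (discrete) "nearest" else "linear")
  interpolation <- match.arg(interpolation, c("nearest", "linear"))
  if (discrete && interpolation == "linear")
    stopf("nearest-neighbour interpolation is required for label/binary volumes")
  d <- dim(vol)
  sp <- spacing(vol)
  if (all(sp == target_spacing)) return(vol)
  dd <- as.integer(ceiling(d * sp / target_spacing))
  out <- cpp_resample_affine(as.numeric(vol), as.integer(d), sp, origin(vol),
                             dd, rep(target_spacing, 3), origin(vol),
                             as.numeric(diag(3)), c(0, 0, 0),
                             interpolation == "nearest")
  rewrap(vol, array(out, dd), spacing = rep(target_spacing, 3))
}

# resample onto an explicit destination grid through an affine pull map
resample_to_grid <- function(vol, grid, M = diag(3), t = c(0, 0, 0),
                             nearest = NULL) {
  nearest <- nearest %||% inherits(vol, c("labeled_volume", "cell_map"))
  out <- cpp_resample_affine(as.numeric(vol), as.integer(dim(vol)),
                             spacing(vol), origin(vol),
                             as.integer(grid$dim), grid$spacing, grid$origin,
                             as.numeric(M), as.numeric(t), nearest)
  rewrap(vol, array(out, grid$dim), spacing = grid$spacing,
         origin = grid$origin)
}

grid_of <- function(vol) {
  list(dim = dim(vol), spacing = spacing(vol), origin = origin(vol))
}

same_grid <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(spacing(a), spacing(b))) &&
    isTRUE(all.equal(origin(a), origin(b)))
}
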