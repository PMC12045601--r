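#' Volumetric data types
#'
#' A `volume3d` is a 3D array carrying voxel spacing (micrometres per voxel,
#' one value per axis) and a world origin (micrometres). Voxel centres sit at
#' `world = origin + (index - 1) * spacing` with 1-based R indices. The axis
#' convention is x: left to right, y: posterior to anterior, z: inferior to
#' superior. Three subclasses cover the pipeline's inputs:
#'
#' * `labeled_volume`: integer tissue classes, 0 = background,
#'   1 = mesenchyme, 2 = neural ectoderm;
#' * `cell_map`: binary occupancy of nucleus or proliferation voxels;
#' * `prolif_map`: real-valued local proliferation density, optionally
#'   normalized to `[0, 1]`.
#'
#' @param voxels A 3D array.
#' @param spacing Micrometres per voxel, length 1 (isotropic) or 3.
#' @param origin World coordinate (µm) of the first voxel centre, length 3.
#' @param labels Named integer vector of admissible label codes.
#' @param channel For [cell_map()], `"nuclei"` or `"proliferation"`.
#' @param normalized For [prolif_map()], whether values are equalized to
#'   `[0, 1]`.
#' @return An object of the corresponding class; the underlying array is
#'   recovered with `as.array()`.
#' @examples
#' v <- labeled_volume(array(0L, c(4, 4, 4)), spacing = 4)
#' spacing(v)
#' @name volume3d
NULL

new_volume3d <- function(voxels, spacing, origin, class) {
  stopifnot(length(dim(voxels)) == 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3)
  structure(voxels, spacing = as.numeric(spacing),
            origin = as.numeric(origin), class = c(class, "volume3d"))
}

#' @rdname volume3d
#' @export
labeled_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                           labels = c(background = 0L, mesenchyme = 1L,
                                      neural_ectoderm = 2L)) {
  vals <- unique(as.vector(voxels))
  if (any(vals != as.integer(vals)))
    stopf("labeled_volume requires integer voxel values")
  if (!all(vals %in% labels))
    stopf("voxel values outside the label set {%s}: %s",
          paste(labels, collapse = ","),
          paste(setdiff(vals, labels), collapse = ","))
  storage.mode(voxels) <- "integer"
  out <- new_volume3d(voxels, spacing, origin, "labeled_volume")
  attr(out, "labels") <- labels
  out
}

#' @rdname volume3d
#' @export
cell_map <- function(voxels, spacing, origin = c(0, 0, 0),
                     channel = c("nuclei", "proliferation")) {
  channel <- match.arg(channel)
  vals <- unique(as.vector(voxels))
  if (!all(vals %in% c(0, 1)))
    stopf("cell_map must be binary; found value(s) %s",
          paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ","))
  storage.mode(voxels) <- "integer"
  out <- new_volume3d(voxels, spacing, origin, "cell_map")
  attr(out, "channel") <- channel
  out
}

#' @rdname volume3d
#' @export
prolif_map <- function(voxels, spacing, origin = c(0, 0, 0),
                       normalized = FALSE) {
  if (any(voxels < 0))
    stopf("prolif_map values must be non-negative")
  if (normalized && any(voxels > 1))
    stopf("normalized prolif_map values must lie in [0, 1]")
  storage.mode(voxels) <- "double"
  out <- new_volume3d(voxels, spacing, origin, "prolif_map")
  attr(out, "normalized") <- normalized
  out
}

#' @rdname volume3d
#' @param x A `volume3d` object.
#' @export
spacing <- function(x) attr(x, "spacing")

#' @rdname volume3d
#' @export
origin <- function(x) attr(x, "origin")

#' @rdname volume3d
#' @export
voxel_volume <- function(x) prod(spacing(x))

#' @export
as.array.volume3d <- function(x, ...) {
  array(as.vector(x), dim(x))
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s um, origin (%s) um\n",
              class(x)[1], paste(dim(x), collapse = "x"),
              paste(signif(spacing(x), 4), collapse = "x"),
              paste(signif(origin(x), 4), collapse = ", ")))
  invisible(x)
}

# rebuild a volume of the same subclass around a new array
rewrap <- function(template, voxels, spacing = NULL, origin = NULL) {
  spacing <- spacing %||% attr(template, "spacing")
  origin <- origin %||% attr(template, "origin")
  cls <- class(template)[1]
  switch(cls,
    labeled_volume = labeled_volume(voxels, spacing, origin,
                                    labels = attr(template, "labels")),
    cell_map = cell_map(voxels, spacing, origin,
                        channel = attr(template, "channel")),
    prolif_map = prolif_map(voxels, spacing, origin,
                            normalized = attr(template, "normalized")),
    new_volume3d(voxels, spacing, origin, cls))
}

#' Convert between world and voxel-index coordinates
#'
#' @param vol A `volume3d`.
#' @param pts Matrix (n x 3) of world coordinates (µm) or 1-based voxel
#'   indices (possibly fractional).
#' @return A matrix of the converted coordinates.
#' @export
world_to_index <- function(vol, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, origin(vol), "-"), 2, spacing(vol), "/") + 1
}

#' @rdname world_to_index
#' @export
index_to_world <- function(vol, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts - 1, 2, spacing(vol), "*"), 2, origin(vol), "+")
}

#' Ordered 3D landmark sets
#'
#' Landmarks are stored as a data frame with columns `name`, `x`, `y`, `z`
#' (world µm). Names must be unique and the row order is the fixed landmark
#' order shared across specimens.
#'
#' @param name Character vector of unique landmark names.
#' @param coords Matrix (n x 3) of world coordinates in µm.
#' @return A `landmark_set` data frame.
#' @export
landmark_set <- function(name, coords) {
  coords <- rbind(coords)
  stopifnot(length(name) == nrow(coords), ncol(coords) == 3)
  if (anyDuplicated(name)) stopf("landmark names must be unique")
  if (!all(is.finite(coords))) stopf("landmark coordinates must be finite")
  structure(data.frame(name = as.character(name), x = coords[, 1],
                       y = coords[, 2], z = coords[, 3],
                       stringsAsFactors = FALSE),
            class = c("landmark_set", "data.frame"))
}

lm_coords <- function(lm) as.matrix(lm[, c("x", "y", "z")])

#' Assemble a specimen cohort
#'
#' A cohort bundles specimens that share one axis convention and (after
#' registration) one grid, together with the identity of the registration
#' reference specimen.
#'
#' @param specimens Named list; each element is a list with components
#'   `id`, `labels` (labeled_volume), `nuclei`, `prolif` (cell_map),
#'   `head5`, `face37` (landmark_set), `group`, `somites`, `genotype`.
#' @param reference_id Id of the reference specimen (must be present).
#' @return A `cohort` object (list).
#' @export
cohort <- function(specimens, reference_id = names(specimens)[1]) {
  stopifnot(length(specimens) >= 1)
  ids <- vapply(specimens, function(s) s$id, character(1))
  names(specimens) <- ids
  if (!reference_id %in% ids)
    stopf("reference_id '%s' not among specimen ids", reference_id)
  structure(list(specimens = specimens, reference_id = reference_id),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  md <- cohort_metadata(x)
  cat(sprintf("<cohort> %d specimens, reference '%s'\n",
              nrow(md), x$reference_id))
  print(table(md$group))
  invisible(x)
}

#' Tabulate cohort metadata
#'
#' @param x A [cohort()].
#' @return A tibble with one row per specimen: id, group, somites, genotype.
#' @export
cohort_metadata <- function(x) {
  tibble::tibble(
    id = vapply(x$specimens, function(s) s$id, character(1)),
    group = vapply(x$specimens, function(s) s$group, character(1)),
    somites = vapply(x$specimens, function(s) as.numeric(s$somites),
                     numeric(1)),
    genotype = vapply(x$specimens, function(s) s$genotype %||% "WT",
                      character(1)))
}

#' Mirror a volume or landmark set about the midsagittal plane
#'
#' Reflection is about the x midplane of the grid (the plane halfway between
#' the first and last voxel centre along x). Applying it twice is the
#' identity, and per-label voxel counts are preserved exactly.
#'
#' @param x A `volume3d` or `landmark_set`.
#' @param about For landmark sets, the world x coordinate of the mirror
#'   plane; supply the accompanying volume's midplane, e.g.
#'   `midplane_x(vol)`.
#' @param ... Unused.
#' @return Object of the same type, reflected.
#' @export
mirror <- function(x, ...) UseMethod("mirror")

#' @rdname mirror
#' @export
mirror.volume3d <- function(x, ...) {
  arr <- as.array(x)[dim(x)[1]:1, , , drop = FALSE]
  rewrap(x, arr)
}

#' @rdname mirror
#' @export
mirror.landmark_set <- function(x, about, ...) {
  out <- x
  out$x <- 2 * about - x$x
  out
}

#' @rdname mirror
#' @export
midplane_x <- function(x) {
  origin(x)[1] + (dim(x)[1] - 1) * spacing(x)[1] / 2
}

#' Distance from the mask surface
#'
#' Euclidean distance (µm) from every voxel centre to the nearest background
#' voxel centre, where "background" is any voxel outside the mask; space
#' beyond the grid is treated as background, so a mask touching the grid
#' boundary still has finite distances. Used to carve surface shells such as
#' the facial analysis mask.
#'
#' @param mask A binary array, `cell_map`, or logical array.
#' @param spacing Micrometres per voxel (length 1 or 3); taken from `mask`
#'   when it is a `volume3d`.
#' @return A 3D array of distances in µm (0 outside the mask).
#' @export
distance_from_surface <- function(mask, spacing = NULL) {
  if (inherits(mask, "volume3d")) {
    spacing <- attr(mask, "spacing")
    mask <- as.array(mask)
  }
  spacing <- spacing %||% c(1, 1, 1)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  m <- mask > 0
  if (!any(m)) stopf("distance_from_surface: empty mask")
  d <- dim(m)
  # pad one background layer so outside-grid counts as background
  pd <- d + 2
  f <- array(0, pd)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- ifelse(m, 1e20, 0)
  sq <- cpp_edt(as.numeric(f), as.integer(pd), as.numeric(spacing))
  sq <- array(sq, pd)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  sqrt(sq) * m
}
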