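#' Majority-vote tissue atlas
#'
#' Per-voxel argmax of label counts over registered label volumes. Ties are
#' broken deterministically by a fixed label priority (the highest label
#' code wins, i.e. neural ectoderm over mesenchyme over background), and the
#' winning-label vote fraction is recorded per voxel.
#'
#' @param vols List of [labeled_volume()]s on a common grid.
#' @return A `tissue_atlas`: list with `atlas` ([labeled_volume()]),
#'   `vote_fraction` (3D array in `(0, 1]`), `n_contributors`.
#' @export
majority_vote_atlas <- function(vols) {
  stopifnot(length(vols) >= 1)
  for (v in vols) if (!same_grid(v, vols[[1]]))
    stopf("majority_vote_atlas: grid mismatch")
  labels <- sort(unique(unlist(lapply(vols, function(v)
    attr(v, "labels") %||% 0:2))))
  d <- dim(vols[[1]])
  n <- length(vols)
  counts <- lapply(labels, function(L) {
    acc <- array(0L, d)
    for (v in vols) acc <- acc + (as.array(v) == L)
    acc
  })
  best <- array(labels[1], d)
  bestc <- counts[[1]]
  for (m in seq_along(labels)[-1]) {
    # >= implements the highest-label-wins tie rule (labels are ascending)
    take <- counts[[m]] >= bestc & counts[[m]] > 0
    best[take] <- labels[m]
    bestc[take] <- counts[[m]][take]
  }
  atlas <- labeled_volume(best, spacing(vols[[1]]), origin(vols[[1]]))
  structure(list(atlas = atlas, vote_fraction = bestc / n,
                 n_contributors = n),
            class = "tissue_atlas")
}

#' @export
print.tissue_atlas <- function(x, ...) {
  cat(sprintf("<tissue_atlas> %d contributors, mean vote fraction %.3f\n",
              x$n_contributors, mean(x$vote_fraction)))
  print(x$atlas)
  invisible(x)
}

#' Windowed proliferation density
#'
#' Local mean of a binary proliferating-cell map over a centred cubic window
#' (default 0.15 mm edge, converted to the nearest odd voxel count so the
#' box filter is centred). Borders use shrinking windows: the mean is taken
#' over the in-grid part of the cube.
#'
#' @param prolif A proliferation [cell_map()].
#' @param window_um Window edge length in µm.
#' @return A raw (unnormalized) [prolif_map()].
#' @export
proliferation_density <- function(prolif, window_um = 150) {
  stopifnot(inherits(prolif, "volume3d"))
  sp <- spacing(prolif)
  w <- round(window_um / sp)
  w <- pmax(w + (w %% 2 == 0), 1)   # nearest odd count, at least 1
  if (any(window_um < sp))
    stopf("window (%g um) smaller than one voxel (%s um)", window_um,
          paste(sp, collapse = "x"))
  r <- (w - 1) / 2
  d <- dim(prolif)
  sums <- cpp_boxsum3(as.numeric(prolif), as.integer(d), as.integer(r))
  cnt1 <- function(n, r) {
    i <- seq_len(n)
    pmin(i + r, n) - pmax(i - r, 1) + 1
  }
  counts <- outer(outer(cnt1(d[1], r[1]), cnt1(d[2], r[2])), cnt1(d[3], r[3]))
  prolif_map(array(sums, d) / counts, sp, origin(prolif), normalized = FALSE)
}

#' Percentile-based equalization of a proliferation map
#'
#' Clipped linear rescaling between the `p_low`-th and `p_high`-th
#' percentiles of the in-ROI voxel values:
#' `v -> clip((v - P_low) / (P_high - P_low), 0, 1)`. Percentiles use linear
#' interpolation between order statistics. A constant map degenerates to all
#' zeros. The output is invariant to positive affine rescaling of the input.
#'
#' @param raw A raw [prolif_map()].
#' @param roi Binary array or `volume3d` mask over which percentiles are
#'   computed; default the full grid.
#' @param p_low,p_high Percentiles (0-100).
#' @return A normalized [prolif_map()] with values in `[0, 1]`.
#' @export
percentile_equalize <- function(raw, roi = NULL, p_low = 1, p_high = 99) {
  arr <- as.array(raw)
  roi <- if (is.null(roi)) array(TRUE, dim(arr)) else as.array(roi) > 0
  if (!any(roi)) stopf("percentile_equalize: empty roi")
  qs <- stats::quantile(arr[roi], c(p_low, p_high) / 100, names = FALSE,
                        type = 7)
  if (qs[2] <= qs[1]) {
    out <- array(0, dim(arr))
  } else {
    out <- pmin(pmax((arr - qs[1]) / (qs[2] - qs[1]), 0), 1)
  }
  prolif_map(out, spacing(raw), origin(raw), normalized = TRUE)
}

#' Mean proliferation atlas of an age group
#'
#' Voxel-wise arithmetic mean of the normalized proliferation maps of a
#' group and (by default) their midsagittally mirrored copies, yielding a
#' left-right symmetric atlas when the grid is midplane-centred.
#'
#' @param maps List of normalized [prolif_map()]s on the atlas grid.
#' @param include_mirrored Average the mirrored maps in as well.
#' @return A normalized [prolif_map()].
#' @export
mean_proliferation_atlas <- function(maps, include_mirrored = TRUE) {
  stopifnot(length(maps) >= 1)
  all_maps <- maps
  if (include_mirrored) all_maps <- c(maps, lapply(maps, mirror))
  acc <- array(0, dim(all_maps[[1]]))
  for (m in all_maps) acc <- acc + as.array(m)
  prolif_map(acc / length(all_maps), spacing(maps[[1]]), origin(maps[[1]]),
             normalized = TRUE)
}

new_analysis_mask <- function(mask, template, provenance, params) {
  if (!any(mask)) stopf("analysis mask is empty")
  structure(list(mask = mask, spacing = spacing(template),
                 origin = origin(template), provenance = provenance,
                 params = params),
            class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> %s: %d voxels (%.1f%% of grid)\n",
              x$provenance, sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Facial analysis mask
#'
#' Voxels labelled mesenchyme in strictly more than `vote_thresh` of the
#' registered segmentations form a primary mask; voxels further than
#' `shell_depth_um` from its surface are then excluded, leaving a surface
#' shell. An optional ROI mask (e.g. from a file) is intersected last,
#' standing in for manual refinement of the mask down to the face.
#'
#' @param vols List of registered [labeled_volume()]s (or binary mesenchyme
#'   masks) on a common grid.
#' @param vote_thresh Fraction of segmentations that must vote mesenchyme
#'   (strict inequality).
#' @param shell_depth_um Maximum distance (µm) from the primary-mask surface.
#' @param roi Optional binary array / `volume3d` to intersect.
#' @return An `analysis_mask`.
#' @export
build_face_mask <- function(vols, vote_thresh = 0.30, shell_depth_um = 390,
                            roi = NULL) {
  for (v in vols) if (!same_grid(v, vols[[1]]))
    stopf("build_face_mask: grid mismatch")
  n <- length(vols)
  acc <- array(0, dim(vols[[1]]))
  for (v in vols) acc <- acc + (as.array(v) == 1 | (is_binary_vol(v) & as.array(v) > 0))
  frac <- acc / n
  primary <- frac > vote_thresh
  if (!any(primary)) stopf("face mask empty at vote threshold %.2f", vote_thresh)
  dist <- distance_from_surface(primary, spacing(vols[[1]]))
  mask <- primary & dist <= shell_depth_um
  if (!is.null(roi)) mask <- mask & (as.array(roi) > 0)
  new_analysis_mask(mask, vols[[1]], "face",
                    list(vote_thresh = vote_thresh,
                         shell_depth_um = shell_depth_um,
                         roi = !is.null(roi), n_contributors = n))
}

is_binary_vol <- function(v) inherits(v, "cell_map")

#' Mutant prominence analysis mask
#'
#' Majority-vote mesenchyme mask, morphologically closed with a cubic
#' structuring element to remove imperfections and discontinuities, reduced
#' to a surface shell, then optionally intersected with an ROI.
#'
#' @param vols List of registered [labeled_volume()]s on a common grid.
#' @param closing_vox Edge length of the cubic closing element in voxels
#'   (converted to the nearest odd count).
#' @inheritParams build_face_mask
#' @return An `analysis_mask`.
#' @export
build_mutant_mask <- function(vols, closing_vox = 40, shell_depth_um = 390,
                              roi = NULL) {
  atl <- majority_vote_atlas(vols)
  mes <- as.array(atl$atlas) == 1
  r <- max(1, floor(closing_vox / 2))
  closed <- binary_closing(mes, r)
  dist <- distance_from_surface(closed, spacing(vols[[1]]))
  mask <- closed & dist <= shell_depth_um
  if (!is.null(roi)) mask <- mask & (as.array(roi) > 0)
  new_analysis_mask(mask, vols[[1]], "prominence",
                    list(closing_vox = closing_vox,
                         shell_depth_um = shell_depth_um,
                         roi = !is.null(roi)))
}

# closing with a cubic element of half-width r (dilate then erode)
binary_closing <- function(mask, r) {
  d <- dim(mask)
  x <- cpp_minmax3(as.numeric(mask), as.integer(d), rep(as.integer(r), 3),
                   TRUE)
  x <- cpp_minmax3(x, as.integer(d), rep(as.integer(r), 3), FALSE)
  array(x > 0.5, d)
}
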