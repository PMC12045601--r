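#' Specification of a synthetic embryo-head phantom cohort
#'
#' The phantom emulates the study design of a light-sheet proliferation
#' experiment: ordered half-day age groups of `n_per_group` specimens, each
#' a labelled head volume (background / mesenchyme / neural ectoderm) built
#' from a superellipsoid head carrying three spheroid prominence lobes (a
#' frontonasal analog on the anterior midline and a left/right maxillary
#' pair), a nucleus map from a hard-core blob process inside tissue, and a
#' proliferating-cell map thinned from the nuclei with a base proliferative
#' fraction, elevated inside growth-site hotspots. Later stages scale the
#' prominence lobes by a known analytic growth field, giving exact ground
#' truth for expansion masks and hotspot fields.
#'
#' @param grid_shape Voxels per axis (length 1 or 3).
#' @param spacing_iso Isotropic voxel size in µm.
#' @param n_per_group Specimens per age group.
#' @param age_groups Ordered stage labels.
#' @param somite_ranges Named list of somite-count ranges per group.
#' @param lobe_growth 3 x n_groups matrix of per-stage scale factors for the
#'   frontonasal, left-maxillary, right-maxillary lobes. `"identity"` gives
#'   all ones.
#' @param hotspots `"lobes"` (a hotspot at each prominence lobe, the
#'   default), `"none"`, or a list of `list(center, radius_um, excess)`
#'   entries in world µm.
#' @param hotspot_excess Relative excess of the proliferation probability
#'   inside a hotspot: local fraction = `base * (1 + excess)` (clipped so it
#'   never exceeds 1).
#' @param base_prolif_fraction Baseline proliferating fraction in `[0, 1]`.
#' @param boundary_jitter Tissue-boundary jitter amplitude in voxels.
#' @param landmark_jitter Landmark jitter standard deviation in µm.
#' @param specimen_scale_sd Per-specimen global size variation (sd of a
#'   multiplicative factor).
#' @param genotype_excess_multiplier Named multipliers applied to
#'   `hotspot_excess` per genotype (mutant phenotype = damped hotspots).
#' @param seed Integer RNG seed; the same spec and seed reproduce the
#'   cohort exactly.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128), spacing_iso = 25,
                         n_per_group = 5,
                         age_groups = c("E10", "E10.5", "E11", "E11.5"),
                         somite_ranges = list(E10 = c(8, 10),
                                              E10.5 = c(11, 14),
                                              E11 = c(15, 17),
                                              E11.5 = c(18, 20)),
                         lobe_growth = NULL, hotspots = "lobes",
                         hotspot_excess = 1, base_prolif_fraction = 0.16,
                         boundary_jitter = 0.5, landmark_jitter = 15,
                         specimen_scale_sd = 0.02,
                         genotype_excess_multiplier = c(WT = 1, HET = 0.6,
                                                        MUT = 0.25),
                         seed = 1) {
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  stopifnot(base_prolif_fraction >= 0, base_prolif_fraction <= 1,
            spacing_iso > 0, n_per_group >= 1)
  ng <- length(age_groups)
  if (is.null(lobe_growth)) {
    # differential outgrowth: the frontonasal analog grows fastest, as the
    # frontonasal prominences dominate mid-gestation facial shape change
    lobe_growth <- rbind(fnp = 1 + 0.15 * (seq_len(ng) - 1),
                         max_l = 1 + 0.05 * (seq_len(ng) - 1),
                         max_r = 1 + 0.05 * (seq_len(ng) - 1))
  } else if (identical(lobe_growth, "identity")) {
    lobe_growth <- matrix(1, 3, ng, dimnames = list(c("fnp", "max_l",
                                                      "max_r"), NULL))
  }
  stopifnot(nrow(lobe_growth) == 3, ncol(lobe_growth) == ng)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_iso = spacing_iso, n_per_group = n_per_group,
                 age_groups = age_groups, somite_ranges = somite_ranges,
                 lobe_growth = lobe_growth, hotspots = hotspots,
                 hotspot_excess = hotspot_excess,
                 base_prolif_fraction = base_prolif_fraction,
                 boundary_jitter = boundary_jitter,
                 landmark_jitter = landmark_jitter,
                 specimen_scale_sd = specimen_scale_sd,
                 genotype_excess_multiplier = genotype_excess_multiplier,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

group_index <- function(spec, group) {
  gi <- match(group, spec$age_groups)
  if (is.na(gi)) stopf("unknown age group '%s'", group)
  gi
}

specimen_seed <- function(spec, gi, index) {
  as.integer((abs(spec$seed) * 1009 + gi * 101 + index) %% 2147483647L)
}

# analytic geometry of one phantom at a given stage; all in world µm
phantom_geometry <- function(spec, gi, scale = 1) {
  d <- spec$grid_shape
  sp <- spec$spacing_iso
  ext <- d * sp
  cen <- (d - 1) * sp / 2
  ax <- scale * c(0.30, 0.28, 0.28) * ext          # head semi-axes
  g <- spec$lobe_growth[, gi]
  lobes <- list(
    fnp = list(center = cen + scale * c(0, 0.30 * ext[2], -0.04 * ext[3]),
               radius = scale * g[1] * 0.125 * ext[1]),
    max_l = list(center = cen + scale * c(-0.20 * ext[1], 0.18 * ext[2],
                                          -0.08 * ext[3]),
                 radius = scale * g[2] * 0.095 * ext[1]),
    max_r = list(center = cen + scale * c(0.20 * ext[1], 0.18 * ext[2],
                                          -0.08 * ext[3]),
                 radius = scale * g[3] * 0.095 * ext[1]))
  ne <- list(center = cen + scale * c(0, -0.06 * ext[2], 0.05 * ext[3]),
             axes = 0.55 * ax)
  list(dims = d, spacing = sp, center = cen, head_axes = ax, lobes = lobes,
       ne = ne, exponent = 2.5)
}

world_grids <- function(d, sp) {
  list(x = (seq_len(d[1]) - 1) * sp,
       y = (seq_len(d[2]) - 1) * sp,
       z = (seq_len(d[3]) - 1) * sp)
}

# implicit function <= 0 inside the superellipsoid head
head_implicit <- function(geom) {
  w <- world_grids(geom$dims, geom$spacing)
  n <- geom$exponent
  qx <- abs((w$x - geom$center[1]) / geom$head_axes[1])^n
  qy <- abs((w$y - geom$center[2]) / geom$head_axes[2])^n
  qz <- abs((w$z - geom$center[3]) / geom$head_axes[3])^n
  outer(outer(qx, qy, "+"), qz, "+") - 1
}

sphere_implicit <- function(geom, center, radius) {
  w <- world_grids(geom$dims, geom$spacing)
  qx <- ((w$x - center[1]) / radius)^2
  qy <- ((w$y - center[2]) / radius)^2
  qz <- ((w$z - center[3]) / radius)^2
  outer(outer(qx, qy, "+"), qz, "+") - 1
}

ellipsoid_implicit <- function(geom, center, axes) {
  w <- world_grids(geom$dims, geom$spacing)
  qx <- ((w$x - center[1]) / axes[1])^2
  qy <- ((w$y - center[2]) / axes[2])^2
  qz <- ((w$z - center[3]) / axes[3])^2
  outer(outer(qx, qy, "+"), qz, "+") - 1
}

phantom_label_array <- function(geom, jitter_field = NULL) {
  inside <- head_implicit(geom) <= (jitter_field %||% 0)
  for (lb in geom$lobes)
    inside <- inside |
      (sphere_implicit(geom, lb$center, lb$radius) <= (jitter_field %||% 0))
  lab <- array(0L, geom$dims)
  lab[inside] <- 1L
  ne <- ellipsoid_implicit(geom, geom$ne$center, geom$ne$axes) <= 0
  lab[inside & ne] <- 2L
  lab
}

hotspot_field <- function(spec, geom) {
  exc <- array(0, geom$dims)
  hs <- spec$hotspots
  if (identical(hs, "none") || is.null(hs)) return(exc)
  if (identical(hs, "lobes")) {
    # hotspots sit at the growth sites, with excess proportional to each
    # lobe's growth rate (proliferation concentrated where growth happens)
    ng <- ncol(spec$lobe_growth)
    rates <- if (ng > 1) (spec$lobe_growth[, ng] - spec$lobe_growth[, 1]) /
      (ng - 1) else rep(0, 3)
    wts <- if (max(rates) > 0) rates / max(rates) else rep(1, 3)
    hs <- lapply(seq_along(geom$lobes), function(i) {
      lb <- geom$lobes[[i]]
      list(center = lb$center, radius_um = 1.15 * lb$radius,
           excess = spec$hotspot_excess * wts[i])
    })
  }
  for (h in hs) {
    inside <- sphere_implicit(geom, h$center, h$radius_um) <= 0
    exc[inside] <- pmax(exc[inside], h$excess)
  }
  exc
}

# deterministic outward directions on a lobe (golden-angle spiral on the
# hemisphere around `outward`)
lobe_directions <- function(n, outward) {
  phi <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  cosT <- 1 - i / n          # polar cap from the pole downwards
  sinT <- sqrt(1 - cosT^2)
  local <- cbind(sinT * cos(phi * seq_len(n)), sinT * sin(phi * seq_len(n)),
                 cosT)
  # rotate local +z onto `outward`
  out <- outward / sqrt(sum(outward^2))
  v <- c(-out[2], out[1], 0)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    R <- if (out[3] > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    v <- v / s
    ang <- acos(out[3])
    K <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  }
  local %*% t(R)
}

#' Generate one phantom specimen
#'
#' Deterministic in `(spec, group, index)`: the same triple always yields
#' bit-identical outputs regardless of the caller's RNG state.
#'
#' @param spec A [phantom_spec()].
#' @param group A stage label from `spec$age_groups`.
#' @param index Specimen index within the group (1-based).
#' @param genotype `"WT"`, `"HET"` or `"MUT"`; scales the hotspot excess by
#'   `spec$genotype_excess_multiplier`.
#' @return A specimen list: `id`, `labels` ([labeled_volume()]), `nuclei`
#'   and `prolif` ([cell_map()]s), `head5` and `face37` ([landmark_set()]s),
#'   `group`, `somites`, `genotype`.
#' @export
generate_specimen <- function(spec, group, index = 1, genotype = "WT") {
  gi <- group_index(spec, group)
  with_seed(specimen_seed(spec, gi, index), {
    d <- spec$grid_shape
    sp <- spec$spacing_iso
    scale <- 1 + stats::rnorm(1, 0, spec$specimen_scale_sd)
    geom <- phantom_geometry(spec, gi, scale = scale)
    jit <- NULL
    if (spec$boundary_jitter > 0) {
      noise <- array(stats::rnorm(prod(d)), d)
      noise <- array(cpp_gauss3(as.numeric(noise), as.integer(d),
                                rep(2, 3)), d)
      noise <- noise / stats::sd(noise)
      # convert a jitter amplitude in voxels to implicit-function units
      jit <- noise * spec$boundary_jitter * geom$exponent * sp /
        min(geom$head_axes)
    }
    lab <- phantom_label_array(geom, jit)
    # nuclei: jittered hard-core lattice of small blobs inside tissue
    pitch <- 4
    cand <- as.matrix(expand.grid(
      x = seq(2, d[1] - 1, by = pitch), y = seq(2, d[2] - 1, by = pitch),
      z = seq(2, d[3] - 1, by = pitch)))
    cand <- cand + matrix(stats::runif(length(cand), -0.5, 0.5),
                          ncol = 3)
    ci <- round(cand)
    keep <- lab[ci] > 0 & stats::runif(nrow(ci)) < 0.9
    centers <- ci[keep, , drop = FALSE]
    offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    stamp <- function(cs) {
      m <- array(0L, d)
      if (nrow(cs) == 0) return(m)
      vox <- cs[rep(seq_len(nrow(cs)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), nrow(cs)), ]
      ok <- vox[, 1] >= 1 & vox[, 2] >= 1 & vox[, 3] >= 1 &
        vox[, 1] <= d[1] & vox[, 2] <= d[2] & vox[, 3] <= d[3]
      vox <- vox[ok, , drop = FALSE]
      vox <- vox[lab[vox] > 0, , drop = FALSE]  # clip blobs to tissue
      m[vox] <- 1L
      m
    }
    nuc <- stamp(centers)
    exc <- hotspot_field(spec, geom)
    gmul <- spec$genotype_excess_multiplier[[genotype]] %||% 1
    pcent <- pmin(spec$base_prolif_fraction * (1 + gmul * exc[centers]), 1)
    prol <- stamp(centers[stats::runif(nrow(centers)) < pcent, ,
                          drop = FALSE])
    prol[nuc == 0L] <- 0L
    # landmarks: analytic surface points of the known geometry plus jitter
    cenw <- geom$center
    ax <- geom$head_axes
    head5 <- rbind(anterior = cenw + c(0, ax[2], 0),
                   posterior = cenw - c(0, ax[2], 0),
                   left = cenw - c(ax[1], 0, 0),
                   right = cenw + c(ax[1], 0, 0),
                   superior = cenw + c(0, 0, ax[3]))
    # 37 face landmarks: 13 on the frontonasal lobe, 8 per maxillary lobe,
    # and 8 on the head surface between the prominences (as the real set
    # spans the whole face, not only the outgrowing structures)
    dirs_f <- lobe_directions(13, c(0, 1, 0))
    dirs_l <- lobe_directions(8, c(-0.6, 0.8, 0))
    dirs_r <- lobe_directions(8, c(0.6, 0.8, 0))
    dirs_h <- lobe_directions(8, c(0, 0.55, 0.85))
    head_r <- apply(dirs_h, 1, function(v)
      1 / sum((abs(v) / ax)^geom$exponent)^(1 / geom$exponent))
    lb <- geom$lobes
    face <- rbind(
      sweep(dirs_f * lb$fnp$radius, 2, lb$fnp$center, "+"),
      sweep(dirs_l * lb$max_l$radius, 2, lb$max_l$center, "+"),
      sweep(dirs_r * lb$max_r$radius, 2, lb$max_r$center, "+"),
      sweep(dirs_h * head_r, 2, cenw, "+"))
    jitpts <- function(m) m + matrix(stats::rnorm(length(m), 0,
                                                  spec$landmark_jitter),
                                     ncol = 3)
    head5 <- jitpts(head5)
    face <- jitpts(face)
    sr <- spec$somite_ranges[[group]]
    somites <- round(seq(sr[1], sr[2],
                         length.out = max(spec$n_per_group, 2)))[
      min(index, max(spec$n_per_group, 2))]
    list(id = sprintf("%s_%02d", group, index),
         labels = labeled_volume(lab, sp),
         nuclei = cell_map(nuc, sp, channel = "nuclei"),
         prolif = cell_map(prol, sp, channel = "proliferation"),
         head5 = landmark_set(c("anterior", "posterior", "left", "right",
                                "superior"), head5),
         face37 = landmark_set(sprintf("f%02d", seq_len(nrow(face))), face),
         group = group, somites = somites, genotype = genotype)
  })
}

#' Generate a phantom cohort
#'
#' @inheritParams generate_specimen
#' @param spec A [phantom_spec()].
#' @param genotypes Optional character vector (recycled over specimens in
#'   generation order) of genotypes.
#' @return A [cohort()] whose reference is the first specimen of the first
#'   group.
#' @export
generate_cohort <- function(spec, genotypes = "WT") {
  combos <- expand.grid(index = seq_len(spec$n_per_group),
                        group = spec$age_groups,
                        stringsAsFactors = FALSE)
  genotypes <- rep_len(genotypes, nrow(combos))
  specimens <- lapply(seq_len(nrow(combos)), function(i)
    generate_specimen(spec, combos$group[i], combos$index[i],
                      genotype = genotypes[i]))
  names(specimens) <- vapply(specimens, `[[`, character(1), "id")
  cohort(specimens, reference_id = specimens[[1]]$id)
}

#' Ground truth growth and hotspot fields of a phantom stage
#'
#' The expansion mask holds the voxels added to the prominence lobes
#' between a group and its predecessor under the analytic (jitter-free,
#' unit-scale) growth field; it is empty for the first group. The hotspot
#' map is the analytic excess-proliferation field of the group.
#'
#' @inheritParams generate_specimen
#' @return List with `expansion_mask` (logical array) and `hotspot_map`
#'   (array of excess fractions).
#' @export
ground_truth <- function(spec, group) {
  gi <- group_index(spec, group)
  geom <- phantom_geometry(spec, gi)
  lobes_mask <- function(g) {
    m <- array(FALSE, g$dims)
    for (lb in g$lobes)
      m <- m | (sphere_implicit(g, lb$center, lb$radius) <= 0)
    m
  }
  cur <- lobes_mask(geom)
  if (gi == 1) {
    expansion <- array(FALSE, geom$dims)
  } else {
    prev <- lobes_mask(phantom_geometry(spec, gi - 1))
    expansion <- cur & !prev
  }
  list(expansion_mask = expansion, hotspot_map = hotspot_field(spec, geom))
}

#' Subsample an isotropic volume into an anisotropic slice stack
#'
#' Emulates light-sheet acquisition geometry: keeps the in-plane grid and
#' samples slices every `slice_interval` µm along z. The output depth is
#' `ceiling(extent_z / slice_interval)`; [resample_isotropic()] inverts the
#' operation up to interpolation error.
#'
#' @param vol A `volume3d` (isotropic or not).
#' @param slice_interval Slice spacing in µm (>= in-plane spacing).
#' @param inplane In-plane spacing; defaults to the volume's x spacing.
#' @return A volume of the same class with spacing `(inplane, inplane,
#'   slice_interval)`.
#' @export
to_anisotropic_stack <- function(vol, slice_interval, inplane = NULL) {
  stopifnot(inherits(vol, "volume3d"))
  inplane <- inplane %||% spacing(vol)[1]
  if (slice_interval <= 0 || inplane <= 0)
    stopf("spacings must be positive")
  if (slice_interval < inplane)
    stopf("slice_interval (%g) must be >= in-plane spacing (%g)",
          slice_interval, inplane)
  d <- dim(vol)
  nz <- as.integer(ceiling(d[3] * spacing(vol)[3] / slice_interval))
  grid <- list(dim = c(d[1], d[2], nz),
               spacing = c(spacing(vol)[1:2], slice_interval),
               origin = origin(vol))
  resample_to_grid(vol, grid)
}
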