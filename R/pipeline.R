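#' Run the full proliferation-morphology pipeline on a cohort
#'
#' Executes the stages of the analysis end to end:
#'
#' 1. per-age atlases: head-landmark rigid pre-alignment to the group
#'    reference, groupwise affine registration of the tissue segmentations,
#'    and a majority-vote tissue atlas per age;
#' 2. bulk space: face-landmark similarity registration (translation,
#'    rotation, scaling — removing size) of every specimen to one global
#'    reference, windowed proliferation density, percentile equalization,
#'    per-age majority-vote atlases and mirrored-averaged proliferation
#'    atlases in the common space, and the facial analysis mask;
#' 3. shape change: differential volumes of every age-N specimen against
#'    the age-(N-1) atlas, outward/inward proportions and the voxel-wise
#'    Pearson correlation with prior-age proliferation inside the face mask;
#' 4. voxel-based morphometry: deformable registration of each age-N
#'    specimen to the age-(N-1) atlas, log-Jacobian t-maps, shape
#'    significance masks, and the random-mask proliferation null per
#'    specimen;
#' 5. morphometrics: GPA + PCA of the face landmarks, two-block PLS of
#'    proliferation against shape, and (when several genotypes are present)
#'    linear-SVM genotype separation on the proliferation PC scores.
#'
#' @param ch A [cohort()], e.g. from [generate_cohort()].
#' @param window_um Proliferation-density window edge (µm).
#' @param vote_thresh,shell_depth_um Face-mask parameters.
#' @param groupwise_args,nonlinear_args Named lists overriding
#'   [groupwise_affine()] / [nonlinear_register()] defaults.
#' @param t_crit Critical t value for the shape-significance mask. The
#'   default 3.2 concentrates the mask on the strongest consistent
#'   expansion (roughly the top decile of tissue voxels at these group
#'   sizes); `NULL` falls back to the Student quantile at
#'   `alpha = 0.05`, which at df = 4 also sweeps up shared registration
#'   bias.
#' @param R_null Random masks per specimen for the enrichment null.
#' @param n_perm Permutations for PLS.
#' @param pls_cell_vox Edge (voxels) of the cubic cells over which in-mask
#'   proliferation is averaged to build the PLS / PCA feature matrix;
#'   pooling suppresses voxel-level noise while keeping the spatial
#'   pattern.
#' @param do_vbm Run the deformable-registration stage (the slowest part).
#' @param do_atlases Run the per-age groupwise atlas stage; the bulk-space
#'   analyses do not depend on it.
#' @param seed Seed for the stochastic stages (null draws, permutations).
#' @return A nested list with components `atlases`, `bulk`, `shapechange`,
#'   `vbm`, `morpho`; see the vignette for a walk-through.
#' @export
run_pipeline <- function(ch, window_um = 150, vote_thresh = 0.30,
                         shell_depth_um = 390,
                         groupwise_args = list(resolutions = c(4, 2),
                                               max_iterations = c(40, 15),
                                               step = c(1, 2), max_outer = 2),
                         nonlinear_args = list(iterations = c(15, 4)),
                         t_crit = 3.2,
                         R_null = 100, n_perm = 199, pls_cell_vox = 8,
                         do_vbm = TRUE, do_atlases = TRUE, seed = 1) {
  md <- cohort_metadata(ch)
  groups <- unique(md$group)
  specs <- ch$specimens

  ## ---- stage 1: per-age groupwise atlases --------------------------------
  atlases <- list()
  if (do_atlases) for (g in groups) {
    ids <- md$id[md$group == g]
    ref <- ids[1]
    aligned <- lapply(ids, function(id) {
      if (id == ref) return(specs[[id]]$labels)
      tr <- fit_landmark_transform(specs[[id]]$head5, specs[[ref]]$head5,
                                   kind = "rigid")
      apply_transform(tr, specs[[id]]$labels, grid = specs[[ref]]$labels)
    })
    gw <- do.call(groupwise_affine, c(list(aligned), groupwise_args))
    atlases[[g]] <- list(atlas = majority_vote_atlas(gw$registered),
                         groupwise = gw, ids = ids, reference = ref)
  }

  ## ---- stage 2: bulk space (similarity, size removed) --------------------
  global_ref <- md$id[1]
  ref_grid <- specs[[global_ref]]$labels
  bulk <- list()
  for (id in md$id) {
    tr <- if (id == global_ref) affine_transform(diag(3), c(0, 0, 0),
                                                 "similarity")
    else fit_landmark_transform(specs[[id]]$face37, specs[[global_ref]]$face37,
                                kind = "similarity")
    lab <- apply_transform(tr, specs[[id]]$labels, grid = ref_grid)
    prolif <- apply_transform(tr, specs[[id]]$prolif, grid = ref_grid)
    dens <- proliferation_density(prolif, window_um = window_um)
    norm <- percentile_equalize(dens, roi = as.array(lab) > 0)
    bulk[[id]] <- list(labels = lab, prolif_norm = norm, transform = tr)
  }
  bulk_atlas <- list()
  prolif_atlas <- list()
  for (g in groups) {
    ids <- md$id[md$group == g]
    bulk_atlas[[g]] <- majority_vote_atlas(lapply(ids, function(i)
      bulk[[i]]$labels))$atlas
    prolif_atlas[[g]] <- mean_proliferation_atlas(
      lapply(ids, function(i) bulk[[i]]$prolif_norm))
  }
  all_labs <- lapply(md$id, function(i) bulk[[i]]$labels)
  face_mask <- build_face_mask(c(all_labs, lapply(all_labs, mirror)),
                               vote_thresh = vote_thresh,
                               shell_depth_um = shell_depth_um)

  ## ---- stage 3: differential volumes vs the previous age -----------------
  shapechange <- list()
  if (length(groups) >= 2) {
    rows <- list()
    for (gi in 2:length(groups)) {
      gN <- groups[gi]; gP <- groups[gi - 1]
      # the correlation mask is the facial mesenchyme: face shell
      # intersected with the previous-age atlas mesenchyme
      mes_mask <- face_mask$mask & (as.array(bulk_atlas[[gP]]) == 1)
      for (id in md$id[md$group == gN]) {
        D <- differential_volume(bulk[[id]]$labels, bulk_atlas[[gP]])
        pr <- change_proportions(D, face_mask)
        r <- shape_prolif_correlation(D, prolif_atlas[[gP]], mes_mask)
        rows[[length(rows) + 1]] <- tibble::tibble(
          id = id, age = gN, prev_age = gP,
          frac_outward = pr$frac_outward, frac_inward = pr$frac_inward,
          r = r, abs_r = abs(r))
      }
    }
    shapechange <- do.call(rbind, rows)
  }

  ## ---- stage 4: VBM + random-mask null -----------------------------------
  vbm <- list()
  if (do_vbm && length(groups) >= 2) {
    for (gi in 2:length(groups)) {
      gN <- groups[gi]; gP <- groups[gi - 1]
      ids <- md$id[md$group == gN]
      atlasP <- bulk_atlas[[gP]]
      regs <- lapply(ids, function(id)
        do.call(nonlinear_register,
                c(list(bulk[[id]]$labels, atlasP), nonlinear_args)))
      names(regs) <- ids
      jacs <- lapply(regs, jacobian_determinant)
      tissueP <- as.array(atlasP) > 0
      tm <- vbm_tmap(jacs, mask = tissueP)
      sm <- suppressWarnings(
        significance_mask(tm, t_crit = t_crit, spacing = spacing(atlasP),
                          origin = origin(atlasP)))
      mesP <- as.array(atlasP) == 1
      nulls <- list()
      if (sum(sm$mask) >= 1 && sum(mesP) > sum(sm$mask)) {
        for (k in seq_along(ids)) {
          id <- ids[k]
          warped <- apply_transform(regs[[id]], bulk[[id]]$prolif_norm)
          nulls[[id]] <- random_mask_null(warped, sm, mesP, R = R_null,
                                          seed = seed + 37 * gi + k)
        }
      }
      vbm[[gN]] <- list(prev_age = gP, tmap = tm, sig_mask = sm,
                        jacobians = jacs, nulls = nulls)
    }
  }

  ## ---- stage 5: landmark + proliferation morphometrics -------------------
  fit <- gpa(lapply(md$id, function(i) specs[[i]]$face37))
  shp <- shape_matrix(fit)
  block1 <- pooled_prolif_matrix(lapply(md$id, function(i)
    bulk[[i]]$prolif_norm), face_mask, cell_vox = pls_cell_vox)
  pls <- two_block_pls(block1, shp, n_perm = n_perm, seed = seed)
  shape_pca <- pca(shp)
  prolif_pca <- pca(block1)
  svm <- NULL
  if (length(unique(md$genotype)) >= 2) {
    k <- min(5, ncol(prolif_pca$scores))
    svm <- svm_genotype(prolif_pca$scores[, seq_len(k), drop = FALSE],
                        md$genotype, n_perm = 1000, seed = seed)
  }

  list(metadata = md,
       atlases = atlases,
       bulk = list(labels = lapply(bulk, `[[`, "labels"),
                   prolif_norm = lapply(bulk, `[[`, "prolif_norm"),
                   atlas = bulk_atlas, prolif_atlas = prolif_atlas,
                   face_mask = face_mask),
       shapechange = shapechange,
       vbm = vbm,
       morpho = list(gpa = fit, shape_pca = shape_pca,
                     prolif_pca = prolif_pca, pls = pls, svm = svm))
}

#' Pooled in-mask proliferation feature matrix
#'
#' Averages each specimen's normalized proliferation map over cubic cells
#' of `cell_vox` voxels intersected with an analysis mask, producing the
#' specimen-by-feature matrix used as the proliferation block in PLS, PCA
#' and genotype classification. Cell averaging suppresses voxel-level
#' binomial noise while preserving the spatial pattern.
#'
#' @param maps List of [prolif_map()]s on one grid (one per specimen).
#' @param mask Binary array or `analysis_mask` restricting the features.
#' @param cell_vox Cubic cell edge in voxels.
#' @return A matrix with one row per specimen and one column per occupied
#'   cell; cell ids are stored in `attr(, "cell")`.
#' @export
pooled_prolif_matrix <- function(maps, mask, cell_vox = 8) {
  m <- tissue_mask(mask)
  idx <- which(m)
  if (length(idx) == 0) stopf("empty mask")
  pos <- which(m, arr.ind = TRUE)
  cell <- paste((pos[, 1] - 1) %/% cell_vox,
                (pos[, 2] - 1) %/% cell_vox,
                (pos[, 3] - 1) %/% cell_vox)
  fac <- factor(cell, levels = unique(cell))
  out <- t(vapply(maps, function(mp)
    as.numeric(tapply(as.array(mp)[idx], fac, mean)),
    numeric(nlevels(fac))))
  attr(out, "cell") <- levels(fac)
  out
}
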