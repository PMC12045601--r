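#' Differential volume between a specimen and the previous-age atlas
#'
#' Voxel-wise -1/0/+1 coding of shape change: +1 where the specimen's
#' mesenchyme extends beyond the atlas mesenchyme (outward change), -1
#' where the atlas has mesenchyme the specimen lacks (inward change), 0
#' where they agree. Inputs should already be size-matched (similarity
#' registration / Procrustes superimposition) and on one grid.
#'
#' @param sample_mes,atlas_mes Binary arrays, [cell_map()]s, or
#'   [labeled_volume()]s (label 1 = mesenchyme is used).
#' @return A `differential_volume`: list with `values` (3D array of -1/0/1),
#'   `spacing`, `origin`.
#' @export
differential_volume <- function(sample_mes, atlas_mes) {
  s <- tissue_mask(sample_mes)
  a <- tissue_mask(atlas_mes)
  if (!identical(dim(s), dim(a))) stopf("differential_volume: grid mismatch")
  vals <- array(0L, dim(s))
  vals[s & !a] <- 1L
  vals[a & !s] <- -1L
  sp <- if (inherits(sample_mes, "volume3d")) spacing(sample_mes) else c(1, 1, 1)
  org <- if (inherits(sample_mes, "volume3d")) origin(sample_mes) else c(0, 0, 0)
  structure(list(values = vals, spacing = sp, origin = org),
            class = "differential_volume")
}

tissue_mask <- function(x) {
  if (inherits(x, "labeled_volume")) return(as.array(x) == 1)
  if (inherits(x, "analysis_mask")) return(x$mask)
  as.array(x) > 0
}

#' Outward and inward change proportions
#'
#' @param D A [differential_volume()].
#' @param mask Binary array / `volume3d` / `analysis_mask` of face voxels.
#' @return A list with `frac_outward` and `frac_inward` in `[0, 1]`.
#' @export
change_proportions <- function(D, mask) {
  m <- tissue_mask(mask)
  if (!any(m)) stopf("empty mask")
  v <- D$values[m]
  list(frac_outward = mean(v == 1), frac_inward = mean(v == -1))
}

#' Correlation of shape change with prior-age proliferation
#'
#' Pearson correlation, over the face-mask voxels, between a specimen's
#' differential volume at age N and the proliferation atlas of age N-1.
#' The absolute value is what group box plots summarize.
#'
#' @param D A [differential_volume()] at age N.
#' @param P A [prolif_map()] (age N-1 atlas) on the same grid.
#' @param mask Face mask (binary / `analysis_mask`).
#' @return Pearson r.
#' @export
shape_prolif_correlation <- function(D, P, mask) {
  m <- tissue_mask(mask)
  if (sum(m) <= 2) stopf("mask must contain more than 2 voxels")
  d <- as.numeric(D$values[m])
  p <- as.numeric(as.array(P)[m])
  if (stats::sd(d) == 0 || stats::sd(p) == 0)
    stopf("zero variance inside the mask")
  stats::cor(d, p)
}

#' Voxel-based morphometry t-map from Jacobian fields
#'
#' One-sample t statistic of the per-specimen log-Jacobian against 0 at
#' every voxel (df = n - 1); positive t marks voxel expansion relative to
#' the reference atlas. A two-group Welch t between consecutive stages is
#' available via `group`.
#'
#' @param jacobians List of `jacobian_field`s (or 3D arrays of J) on one
#'   grid, one per specimen.
#' @param mask Optional tissue mask restricting the analysis.
#' @param log_transform Work on log J (default) or raw J - 1.
#' @param group Optional factor of length `length(jacobians)` with two
#'   levels for a Welch two-group alternative.
#' @return A `tmap`: list with `t` (3D array, NA where undefined), `df`,
#'   `n`, `direction` ("positive = expansion").
#' @export
vbm_tmap <- function(jacobians, mask = NULL, log_transform = TRUE,
                     group = NULL) {
  vals <- lapply(jacobians, function(j)
    if (inherits(j, "jacobian_field")) j$values else j)
  n <- length(vals)
  if (n < 2) stopf("vbm_tmap needs at least 2 specimens")
  d <- dim(vals[[1]])
  X <- vapply(vals, function(v) {
    v <- pmax(v, 1e-8)
    as.numeric(if (log_transform) log(v) else v - 1)
  }, numeric(prod(d)))
  if (is.null(group)) {
    mu <- rowMeans(X)
    s <- apply(X, 1, stats::sd)
    t <- mu / (s / sqrt(n))
    df <- n - 1
  } else {
    group <- as.factor(group)
    stopifnot(nlevels(group) == 2)
    g1 <- group == levels(group)[1]
    m1 <- rowMeans(X[, g1, drop = FALSE])
    m2 <- rowMeans(X[, !g1, drop = FALSE])
    v1 <- apply(X[, g1, drop = FALSE], 1, stats::var)
    v2 <- apply(X[, !g1, drop = FALSE], 1, stats::var)
    n1 <- sum(g1); n2 <- sum(!g1)
    se2 <- v1 / n1 + v2 / n2
    t <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df <- stats::median(df, na.rm = TRUE)
  }
  t[!is.finite(t)] <- NA
  t <- array(t, d)
  if (!is.null(mask)) t[!tissue_mask(mask)] <- NA
  structure(list(t = t, df = df, n = n,
                 direction = "positive = expansion"),
            class = "tmap")
}

#' Shape significance mask from a t-map
#'
#' Voxels with `t > t_crit` (one-sided: regions of local tissue expansion).
#' The default critical value is the Student quantile at `alpha` with the
#' map's degrees of freedom; pass `t_crit` to override directly.
#'
#' @param tmap A [vbm_tmap()] result.
#' @param t_crit Critical t value; overrides `alpha`.
#' @param alpha One-sided significance level for the default threshold.
#' @param spacing,origin Grid metadata for the resulting mask.
#' @return An `analysis_mask` with parameters `t_crit`, `n_voxels`, and
#'   `fraction` (of analyzed, non-NA voxels).
#' @export
significance_mask <- function(tmap, t_crit = NULL, alpha = 0.05,
                              spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  t_crit <- t_crit %||% stats::qt(1 - alpha, df = tmap$df)
  if (t_crit <= 0) stopf("t_crit must be positive")
  analyzed <- is.finite(tmap$t)
  mask <- analyzed & tmap$t > t_crit
  if (!any(mask)) warnf("significance mask is empty at t_crit = %.3f", t_crit)
  structure(list(mask = mask, spacing = spacing, origin = origin,
                 provenance = "significance",
                 params = list(t_crit = t_crit, n_voxels = sum(mask),
                               fraction = sum(mask) / max(sum(analyzed), 1))),
            class = "analysis_mask")
}

#' Random-mask null distribution of mean proliferation
#'
#' Tests whether mean proliferation inside the shape-significance mask
#' exceeds what equally many randomly sampled tissue voxels would show.
#' For each of `R` replicates, `|sig_mask|` voxels are drawn uniformly
#' without replacement from the universe mask and the mean warped
#' proliferation recorded. The empirical p uses the add-one rule
#' `p = (#{null >= observed} + 1) / (R + 1)`, and `outside_null` flags the
#' stricter criterion that the observed mean exceeds every null replicate.
#'
#' @param P_warped A [prolif_map()] (specimen proliferation in atlas space).
#' @param sig_mask Significance mask (binary / `analysis_mask`).
#' @param universe Universe mask to sample from (e.g. atlas tissue).
#' @param R Number of random masks.
#' @param seed Optional RNG seed for reproducible draws.
#' @return A `null_distribution`: list with `observed`, `null` (length R),
#'   `p`, `outside_null`, `percent_increase` (observed vs mean null).
#' @export
random_mask_null <- function(P_warped, sig_mask, universe, R = 100,
                             seed = NULL) {
  sm <- tissue_mask(sig_mask)
  um <- tissue_mask(universe)
  k <- sum(sm)
  if (k < 1) stopf("significance mask is empty")
  if (sum(um) < k)
    stopf("universe (%d voxels) smaller than the significance mask (%d)",
          sum(um), k)
  stopifnot(R >= 1)
  p_arr <- as.array(P_warped)
  observed <- mean(p_arr[sm])
  uvals <- p_arr[um]
  draw <- function() mean(uvals[sample.int(length(uvals), k)])
  null <- if (is.null(seed)) replicate(R, draw())
          else with_seed(seed, replicate(R, draw()))
  p <- (sum(null >= observed) + 1) / (R + 1)
  structure(list(observed = observed, null = null, p = p,
                 outside_null = observed > max(null),
                 percent_increase = percent_increase(observed, mean(null)),
                 R = R, mask_size = k),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(paste0("<null_distribution> observed %.4g vs null mean %.4g ",
                     "(R = %d): p = %.4g%s\n"),
              x$observed, mean(x$null), x$R, x$p,
              if (x$outside_null) ", outside null range" else ""))
  invisible(x)
}

#' Percent increase of mean proliferation over a baseline
#'
#' `100 * (mean_sig - mean_rand) / mean_rand`, rounded to one decimal for
#' reporting.
#'
#' @param mean_sig Mean proliferation in the significance mask.
#' @param mean_rand Baseline mean over random masks.
#' @return Percent increase (one decimal).
#' @export
percent_increase <- function(mean_sig, mean_rand) {
  if (mean_rand <= 0) stopf("baseline mean must be positive")
  round(100 * (mean_sig - mean_rand) / mean_rand, 1)
}

#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)`; two empty masks are defined to overlap
#' perfectly (Dice 1).
#'
#' @param mask_a,mask_b Binary arrays / `analysis_mask`s on one grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- tissue_mask(mask_a)
  b <- tissue_mask(mask_b)
  if (!identical(dim(a), dim(b))) stopf("dice: grid mismatch")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
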