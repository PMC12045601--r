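#' Read and write volumes as NIfTI or TIFF stacks
#'
#' NIfTI files carry spacing and origin in the qform; multi-page TIFF stacks
#' carry them in a sidecar JSON named `<name>.spacing.json` (TIFF z-spacing
#' tags are unreliable across writers, so the sidecar is required). Label and
#' binary volumes are stored as 8-bit TIFF with values scaled by 1/255 and
#' recovered exactly on read; real-valued maps use 32-bit float pages.
#'
#' @param path File path; `.nii`/`.nii.gz` or `.tif`/`.tiff`.
#' @param kind One of `"labels"`, `"nuclei"`, `"proliferation"`,
#'   `"intensity"`; determines the returned class and validation.
#' @return For `read_volume`, a [labeled_volume()], [cell_map()] or
#'   [prolif_map()]; `write_volume` returns `path` invisibly.
#' @export
read_volume <- function(path, kind = c("labels", "nuclei", "proliferation",
                                       "intensity")) {
  kind <- match.arg(kind)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- array(as.vector(img), dim(img))
    xf <- try(RNifti::xform(img), silent = TRUE)
    if (!inherits(xf, "try-error") && is.matrix(xf)) {
      sp <- abs(diag(xf)[1:3])
      org <- xf[1:3, 4]
    } else {
      sp <- RNifti::pixdim(img)[1:3]
      org <- c(0, 0, 0)
    }
    if (any(sp <= 0)) sp <- RNifti::pixdim(img)[1:3]
  } else if (grepl("\\.tiff?$", path)) {
    sidecar <- tiff_sidecar(path)
    if (!file.exists(sidecar))
      stopf("TIFF stack '%s' is missing its spacing sidecar '%s' (field: spacing)",
            path, basename(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$spacing))
      stopf("sidecar '%s' lacks the required field 'spacing'", sidecar)
    sp <- as.numeric(meta$spacing)
    org <- as.numeric(meta$origin %||% c(0, 0, 0))
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    if (kind != "intensity" && isTRUE(meta$scaled255))
      arr <- round(arr * 255)
  } else stopf("unsupported volume format: %s", path)
  switch(kind,
    labels = labeled_volume(round_if_integer(arr), sp, org),
    nuclei = cell_map(arr, sp, org, channel = "nuclei"),
    proliferation = cell_map(arr, sp, org, channel = "proliferation"),
    intensity = prolif_map(arr, sp, org, normalized = all(arr <= 1)))
}

round_if_integer <- function(arr) {
  r <- round(arr)
  if (max(abs(arr - r)) > 1e-6)
    stopf("labeled volume contains non-integer values")
  r
}

tiff_sidecar <- function(path) {
  paste0(sub("\\.tiff?$", "", path), ".spacing.json")
}

#' @rdname read_volume
#' @param vol The volume to write.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(as.array(vol) * 1.0)
    img <- RNifti::`pixdim<-`(img, spacing(vol))
    m <- diag(4)
    diag(m)[1:3] <- spacing(vol)
    m[1:3, 4] <- origin(vol)
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path)) {
    arr <- as.array(vol)
    scaled <- inherits(vol, c("labeled_volume", "cell_map"))
    if (scaled) {
      pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 255)
      tiff::writeTIFF(pages, path, bits.per.sample = 8)
    } else {
      pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
      tiff::writeTIFF(pages, path, bits.per.sample = 32)
    }
    jsonlite::write_json(
      list(spacing = spacing(vol), origin = origin(vol),
           kind = class(vol)[1], scaled255 = scaled),
      tiff_sidecar(path), auto_unbox = FALSE, digits = NA)
  } else stopf("unsupported volume format: %s", path)
  invisible(path)
}

#' Read and write landmark CSV files
#'
#' Columns `name,x,y,z`, coordinates in world µm.
#'
#' @param path CSV path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stopf("landmark CSV must have columns name,x,y,z")
  landmark_set(df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' @rdname read_landmarks
#' @param lm The landmark set to write.
#' @export
write_landmarks <- function(lm, path) {
  utils::write.csv(as.data.frame(lm), path, row.names = FALSE)
  invisible(path)
}

#' Write or read a cohort directory
#'
#' Volumes are written as NIfTI, landmarks as CSV, and a `manifest.json`
#' records per-specimen paths, age group, somite count and genotype.
#'
#' @param x A [cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir`; `read_cohort` returns a [cohort()].
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(x$specimens, function(s) {
    base <- s$id
    write_volume(s$labels, file.path(dir, paste0(base, "_labels.nii.gz")))
    write_volume(s$nuclei, file.path(dir, paste0(base, "_nuclei.nii.gz")))
    write_volume(s$prolif, file.path(dir, paste0(base, "_prolif.nii.gz")))
    write_landmarks(s$head5, file.path(dir, paste0(base, "_head5.csv")))
    write_landmarks(s$face37, file.path(dir, paste0(base, "_face37.csv")))
    list(id = s$id, group = s$group, somites = s$somites,
         genotype = s$genotype %||% "WT",
         labels = paste0(base, "_labels.nii.gz"),
         nuclei = paste0(base, "_nuclei.nii.gz"),
         prolif = paste0(base, "_prolif.nii.gz"),
         head5 = paste0(base, "_head5.csv"),
         face37 = paste0(base, "_face37.csv"))
  })
  jsonlite::write_json(
    list(reference_id = x$reference_id, specimens = unname(manifest)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  specimens <- lapply(man$specimens, function(m) {
    list(id = m$id,
         labels = read_volume(file.path(dir, m$labels), "labels"),
         nuclei = read_volume(file.path(dir, m$nuclei), "nuclei"),
         prolif = read_volume(file.path(dir, m$prolif), "proliferation"),
         head5 = read_landmarks(file.path(dir, m$head5)),
         face37 = read_landmarks(file.path(dir, m$face37)),
         group = m$group, somites = m$somites, genotype = m$genotype)
  })
  names(specimens) <- vapply(specimens, function(s) s$id, character(1))
  cohort(specimens, reference_id = man$reference_id)
}
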