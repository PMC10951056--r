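#' Three-channel glomerulus image
#'
#' In-memory raster container for the automated measurement stage: DACH1
#' (podocyte nuclei), synaptopodin (podocyte cytoplasm) and DAPI (all
#' nuclei) intensity channels of equal shape, the pixel size, the tuft and
#' Bowman's-capsule masks, and the human/generator-supplied sclerosis
#' score. Channels are plain numeric matrices (arbitrary units >= 0); masks
#' are logical matrices.
#'
#' @param dach1,snp,dapi numeric intensity matrices of identical dimension.
#' @param pixel_size micrometres per pixel (> 0).
#' @param tuft_mask,capsule_mask logical matrices of the same dimension
#'   (optional; required by the detection and measurement operations).
#' @param sclerosis_score annotated grade 0..4 carried through to the
#'   measurement record.
#' @param glomerulus_id identifier carried through.
#' @return object of class `glomerulus_image`.
#' @export
glomerulus_image <- function(dach1, snp, dapi, pixel_size,
                             tuft_mask = NULL, capsule_mask = NULL,
                             sclerosis_score = 0L, glomerulus_id = "g1") {
  stopifnot(is.matrix(dach1), is.matrix(snp), is.matrix(dapi))
  if (!identical(dim(dach1), dim(snp)) || !identical(dim(dach1), dim(dapi)))
    stop("channels must have identical dimensions", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0", call. = FALSE)
  for (m in list(tuft_mask, capsule_mask))
    if (!is.null(m) && !identical(dim(m), dim(dach1)))
      stop("masks must match channel dimensions", call. = FALSE)
  structure(list(dach1 = dach1, snp = snp, dapi = dapi,
                 pixel_size = as.numeric(pixel_size),
                 tuft_mask = tuft_mask, capsule_mask = capsule_mask,
                 sclerosis_score = as.integer(sclerosis_score),
                 glomerulus_id = as.character(glomerulus_id)),
            class = "glomerulus_image")
}

#' IsoData (Ridler-Calvard) intensity threshold
#'
#' Iterates t[k+1] = (mean(values <= t[k]) + mean(values > t[k])) / 2 from
#' the image mean until the induced background/foreground partition is
#' stable, so the returned threshold satisfies
#' t = (mean(values <= t) + mean(values > t)) / 2 exactly - the
#' Ridler-Calvard fixed point. A revisited partition (cycle) also stops the
#' iteration. Pixels strictly greater than the returned threshold are
#' foreground.
#'
#' @param raster numeric matrix or vector with at least two distinct finite
#'   values.
#' @param max_iter iteration cap.
#' @return the converged threshold.
#' @export
isodata_threshold <- function(raster, max_iter = 10000L) {
  x <- as.numeric(raster)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L)
    stop("IsoData undefined on a constant raster", call. = FALSE)
  t_cur <- mean(x)
  n_lo_cur <- sum(x <= t_cur)
  seen <- integer()
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t_cur]
    hi <- x[x > t_cur]
    # split at the extreme of the range: nudge back inside
    if (!length(hi)) { t_cur <- max(x[x < max(x)]); next }
    if (!length(lo)) { t_cur <- min(x); next }
    t_new <- (mean(lo) + mean(hi)) / 2
    n_lo_new <- sum(x <= t_new)
    if (n_lo_new == n_lo_cur || n_lo_new %in% seen) return(t_new)
    seen <- c(seen, n_lo_cur)
    t_cur <- t_new
    n_lo_cur <- n_lo_new
  }
  t_cur
}

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation; 8-connectivity by default.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background), relabelled
#'   1..k in first-pixel (column-major) order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1L
  work <- matrix(big, nr, nc)
  work[mask] <- lab[mask]

  shift <- function(m, dr, dc) {
    out <- matrix(big, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))

  repeat {
    new <- work
    for (o in offs) new <- pmin(new, shift(work, o[1], o[2]))
    new[!mask] <- big
    if (identical(new, work)) break
    work <- new
  }
  out <- matrix(0L, nr, nc)
  labs <- work[mask]
  out[mask] <- match(labs, unique(labs))
  out
}

#' Detect podocyte nuclei in a glomerulus image
#'
#' A podocyte nucleus is a connected component of pixels foreground in both
#' the DACH1 and DAPI channels (IsoData threshold per channel, strictly
#' greater = foreground) that lies in the tuft and does not touch the
#' Bowman's capsule: any component overlapping `capsule_mask` is removed
#' entirely (parietal epithelial cells), as are components that never enter
#' `tuft_mask` or whose in-tuft area falls below `min_area_um2`.
#'
#' @param img a [glomerulus_image()] with both masks present.
#' @param min_area_um2 minimum component area, square micrometres
#'   (default 4).
#' @param connectivity component connectivity (default 8).
#' @return list of logical nucleus masks (component intersected with the
#'   tuft), possibly empty.
#' @export
detect_podocyte_nuclei <- function(img, min_area_um2 = 4, connectivity = 8L) {
  stopifnot(inherits(img, "glomerulus_image"))
  if (is.null(img$tuft_mask) || is.null(img$capsule_mask))
    stop("tuft_mask and capsule_mask are required for nucleus detection",
         call. = FALSE)
  fg_dach <- length(unique(as.numeric(img$dach1))) > 1L &&
    any(img$dach1 > 0)
  if (!fg_dach) return(list())
  dach_fg <- img$dach1 > isodata_threshold(img$dach1)
  dapi_fg <- if (length(unique(as.numeric(img$dapi))) > 1L)
    img$dapi > isodata_threshold(img$dapi) else img$dapi > 0
  both <- dach_fg & dapi_fg
  if (!any(both)) return(list())
  lab <- label_components(both, connectivity)
  min_px <- min_area_um2 / img$pixel_size^2
  out <- list()
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    if (any(comp & img$capsule_mask)) next   # parietal epithelial cell
    nucleus <- comp & img$tuft_mask
    if (!any(nucleus)) next
    if (sum(nucleus) < min_px) next
    out[[length(out) + 1L]] <- nucleus
  }
  out
}

#' Axis-aligned XY caliper diameter of a nucleus mask
#'
#' Mean of the x- and y-axis extents (pixel-edge convention: max index -
#' min index + 1) scaled by the pixel size. Axis-aligned by design, hence
#' rotation-sensitive.
#'
#' @param mask non-empty logical matrix.
#' @param pixel_size micrometres per pixel.
#' @return caliper diameter in micrometres.
#' @export
caliper_diameter_xy <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty nucleus mask", call. = FALSE)
  ext_y <- diff(range(idx[, 1])) + 1
  ext_x <- diff(range(idx[, 2])) + 1
  (ext_x + ext_y) / 2 * pixel_size
}

#' Measure one glomerulus image
#'
#' Runs the full automated measurement: tuft area from the tuft mask,
#' synaptopodin-positive area (IsoData foreground of the synaptopodin
#' channel within the tuft), podocyte nucleus detection and per-nucleus
#' XY caliper diameters. The sclerosis score is passed through from the
#' annotation (scoring is not automated).
#'
#' @param img a [glomerulus_image()] with masks.
#' @param min_area_um2 passed to [detect_podocyte_nuclei()].
#' @return a [glomerulus_measurement()].
#' @export
measure_glomerulus <- function(img, min_area_um2 = 4) {
  stopifnot(inherits(img, "glomerulus_image"))
  if (is.null(img$tuft_mask))
    stop("tuft_mask required", call. = FALSE)
  px2 <- img$pixel_size^2
  tuft_area <- sum(img$tuft_mask) * px2
  snp_area <- if (length(unique(as.numeric(img$snp))) < 2L) 0 else {
    snp_fg <- img$snp > isodata_threshold(img$snp)
    sum(snp_fg & img$tuft_mask) * px2
  }
  nuclei <- detect_podocyte_nuclei(img, min_area_um2 = min_area_um2)
  diams <- vapply(nuclei, caliper_diameter_xy, numeric(1),
                  pixel_size = img$pixel_size)
  glomerulus_measurement(img$glomerulus_id, tuft_area, img$sclerosis_score,
                         diams, min(snp_area, tuft_area))
}
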