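#' Separable Gaussian blur
#'
#' @param mat numeric matrix.
#' @param sigma_px kernel standard deviation in pixels; 0 returns the input
#'   unchanged.
#' @return blurred matrix of the same dimension (edge pixels renormalized).
#' @export
gaussian_blur <- function(mat, sigma_px = 1) {
  if (sigma_px <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(m) {
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    wsum <- numeric(nr)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      rows <- seq_len(nr) + off
      ok <- rows >= 1L & rows <= nr
      out[ok, ] <- out[ok, ] + k[j] * m[rows[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + k[j]
    }
    out / wsum
  }
  t(pad_conv(t(pad_conv(mat))))
}

add_disk <- function(mat, cx_px, cy_px, r_px, value) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- max(1L, floor(cy_px - r_px)); r1 <- min(nr, ceiling(cy_px + r_px))
  c0 <- max(1L, floor(cx_px - r_px)); c1 <- min(nc, ceiling(cx_px + r_px))
  if (r0 > r1 || c0 > c1) return(mat)
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cy_px; dx <- cols - cx_px
  inside <- outer(dy^2, dx^2, `+`) <= r_px^2
  sub <- mat[rows, cols, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  mat[rows, cols] <- sub
  mat
}

#' Render a three-channel raster of one optical section
#'
#' Rasterizes the section of a synthetic glomerulus geometry into DACH1,
#' synaptopodin and DAPI channels plus ground-truth tuft and capsule masks.
#' Podocyte nucleus profiles (apparent disks of the sectioning model) are
#' drawn in DACH1 and DAPI; parietal epithelial cells are drawn in DAPI on
#' the Bowman's-capsule ring; the synaptopodin signal is a deterministic
#' annulus inside the tuft whose area equals the true synaptopodin fraction
#' times the profile area. Gaussian blur and per-pixel Poisson noise are
#' applied when enabled. Nuclei whose apparent diameter falls below
#' `min_render_diameter_um` (grazing profiles below the resolution of the
#' downstream detector) are not rendered.
#'
#' The rendered ground truth is attached as attribute `rendered_nuclei`
#' (data frame of centers and apparent diameters) for closed-loop tests.
#'
#' @param geometry a [glomerulus_geometry()].
#' @param offset section mid-plane offset from the tuft center (um),
#'   |offset| < R.
#' @param pixel_size micrometres per pixel (default 0.19, the native frame
#'   scale; a warning is issued if a nucleus spans < 4 pixels).
#' @param n_pixels frame side length in pixels (default 1024).
#' @param thickness_um optical slab thickness (um).
#' @param blur_sigma_px Gaussian blur sigma in pixels (default 1; 0 = off).
#' @param poisson_noise apply Poisson photon noise (default TRUE).
#' @param n_parietal number of parietal (DAPI-only) cells on the capsule.
#' @param background,foreground intensity levels (arbitrary units).
#' @param min_render_diameter_um smallest apparent nucleus diameter drawn.
#' @param sclerosis_score annotation passed through to the image.
#' @param glomerulus_id identifier.
#' @return a [glomerulus_image()] with masks and `rendered_nuclei`
#'   attribute.
#' @export
render_images <- function(geometry, offset, pixel_size = 0.19,
                          n_pixels = 1024L, thickness_um = 0.541,
                          blur_sigma_px = 1, poisson_noise = TRUE,
                          n_parietal = 6L, background = 10,
                          foreground = 200, min_render_diameter_um = 3,
                          sclerosis_score = 0L, glomerulus_id = "g1") {
  stopifnot(inherits(geometry, "glomerulus_geometry"))
  r_tuft <- geometry$tuft_radius
  if (abs(offset) >= r_tuft)
    stop("section plane does not intersect the tuft", call. = FALSE)
  r_prof <- sqrt(r_tuft^2 - offset^2)
  mean_r_nuc <- if (length(geometry$radii)) mean(geometry$radii) else 0
  if (mean_r_nuc > 0 && 2 * mean_r_nuc / pixel_size < 4)
    warning("pixel_size too coarse: nuclei span < 4 pixels", call. = FALSE)

  ctr <- (n_pixels + 1) / 2
  coord <- (seq_len(n_pixels) - ctr) * pixel_size
  d2 <- outer(coord^2, coord^2, `+`)
  tuft_mask <- d2 <= r_prof^2
  # gap of one nuclear diameter so edge podocyte profiles never touch the
  # capsule ring (they would otherwise be excluded as parietal cells)
  gap <- max(2, 2.4 * mean_r_nuc)
  cap_in <- r_prof + gap; cap_out <- cap_in + 3
  capsule_mask <- d2 > cap_in^2 & d2 <= cap_out^2

  dach1 <- matrix(background, n_pixels, n_pixels)
  dapi <- matrix(background, n_pixels, n_pixels)
  snp <- matrix(background, n_pixels, n_pixels)

  # synaptopodin annulus: area f* of the profile
  f <- geometry$truth$snp_fraction
  if (f > 0) {
    inner <- r_prof * sqrt(max(0, 1 - f))
    snp[d2 <= r_prof^2 & d2 > inner^2] <- foreground
  }

  rendered <- list()
  if (nrow(geometry$centers) > 0) {
    z <- abs(geometry$centers[, 3] - offset)
    r <- geometry$radii
    hit <- which(z < r + thickness_um / 2)
    for (i in hit) {
      over <- max(0, z[i] - thickness_um / 2)
      d_app <- 2 * sqrt(r[i]^2 - over^2)
      if (d_app < min_render_diameter_um) next
      # scene convention: only profiles fully inside the tuft profile are
      # drawn (edge overhangers would fall outside the measurement ROI)
      xy <- sqrt(sum(geometry$centers[i, 1:2]^2))
      if (xy + d_app / 2 > r_prof) next
      cx <- ctr + geometry$centers[i, 1] / pixel_size
      cy <- ctr + geometry$centers[i, 2] / pixel_size
      r_px <- d_app / 2 / pixel_size
      dach1 <- add_disk(dach1, cx, cy, r_px, foreground)
      dapi <- add_disk(dapi, cx, cy, r_px, foreground)
      rendered[[length(rendered) + 1L]] <-
        data.frame(x_um = geometry$centers[i, 1],
                   y_um = geometry$centers[i, 2],
                   apparent_diameter_um = d_app)
    }
  }

  if (n_parietal > 0) {
    ang <- stats::runif(n_parietal, 0, 2 * pi)
    rad <- (cap_in + cap_out) / 2
    r_px <- max(1.5, mean_r_nuc / pixel_size * 0.8)
    for (i in seq_len(n_parietal))
      dapi <- add_disk(dapi, ctr + rad * cos(ang[i]) / pixel_size,
                       ctr + rad * sin(ang[i]) / pixel_size, r_px,
                       foreground)
  }

  if (blur_sigma_px > 0) {
    dach1 <- gaussian_blur(dach1, blur_sigma_px)
    dapi <- gaussian_blur(dapi, blur_sigma_px)
    snp <- gaussian_blur(snp, blur_sigma_px)
  }
  if (poisson_noise) {
    dach1[] <- stats::rpois(length(dach1), dach1)
    dapi[] <- stats::rpois(length(dapi), dapi)
    snp[] <- stats::rpois(length(snp), snp)
  }

  img <- glomerulus_image(dach1, snp, dapi, pixel_size, tuft_mask,
                          capsule_mask, sclerosis_score, glomerulus_id)
  attr(img, "rendered_nuclei") <- if (length(rendered))
    do.call(rbind, rendered) else
      data.frame(x_um = numeric(), y_um = numeric(),
                 apparent_diameter_um = numeric())
  img
}
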