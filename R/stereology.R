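#' Stereology configuration
#'
#' Coefficients and correction modes used by the podometric estimators.
#'
#' `shape_coefficient_beta` and `size_distribution_d` parameterize the
#' Weibel-Gomez volume estimator V = (beta/d) * A^(3/2); beta = 1.382 is the
#' value for spheres and d = 1.01 a mild size-distribution adjustment.
#'
#' `diameter_correction_mode` controls how the mean apparent caliper
#' diameter measured in a thin section is converted to the effective
#' diameter used in the density denominator and in the "true diameter"
#' report:
#' * `"identity"` (default) uses the apparent diameter unchanged, matching
#'   the measurement protocol this package models, which lists the apparent
#'   caliper diameter in the density calculation;
#' * `"four_over_pi"` applies the classical caliper correction D = (4/pi) *
#'   d_apparent for spheres sampled by a thin plane - the statistically
#'   consistent choice under the sampling model (see the methods vignette);
#' * `"custom"` multiplies by `custom_correction_factor`.
#'
#' @param shape_coefficient_beta dimensionless shape coefficient (> 0).
#' @param size_distribution_d dimensionless size-distribution coefficient
#'   (>= 1).
#' @param diameter_correction_mode one of "identity", "four_over_pi",
#'   "custom".
#' @param custom_correction_factor multiplier used when mode = "custom"
#'   (> 0).
#' @return object of class `stereology_config`.
#' @export
stereology_config <- function(shape_coefficient_beta = 1.382,
                              size_distribution_d = 1.01,
                              diameter_correction_mode = c("identity",
                                                           "four_over_pi",
                                                           "custom"),
                              custom_correction_factor = 1) {
  diameter_correction_mode <- match.arg(diameter_correction_mode)
  if (!is.finite(shape_coefficient_beta) || shape_coefficient_beta <= 0)
    stop("shape_coefficient_beta must be > 0", call. = FALSE)
  if (!is.finite(size_distribution_d) || size_distribution_d < 1)
    stop("size_distribution_d must be >= 1", call. = FALSE)
  if (!is.finite(custom_correction_factor) || custom_correction_factor <= 0)
    stop("custom_correction_factor must be > 0", call. = FALSE)
  structure(list(shape_coefficient_beta = shape_coefficient_beta,
                 size_distribution_d = size_distribution_d,
                 diameter_correction_mode = diameter_correction_mode,
                 custom_correction_factor = custom_correction_factor),
            class = "stereology_config")
}

diameter_correction_factor <- function(cfg) {
  switch(cfg$diameter_correction_mode,
         identity = 1,
         four_over_pi = 4 / pi,
         custom = cfg$custom_correction_factor)
}

#' Confocal optical section thickness (axial resolution)
#'
#' T = 0.88 * lambda / (n - sqrt(n^2 - NA^2)), with lambda in nm, converted
#' to micrometres. For the DAPI channel defaults (405 nm, oil n = 1.515,
#' NA = 1.25) this gives 0.541 um.
#'
#' @param optics an [optical_config()].
#' @return optical section thickness in micrometres.
#' @export
optical_section_thickness <- function(optics) {
  stopifnot(inherits(optics, "optical_config"))
  n <- optics$refractive_index
  na <- optics$numerical_aperture
  if (na >= n) stop("numerical aperture must be < refractive index",
                    call. = FALSE)
  t_nm <- 0.88 * optics$excitation_wavelength_nm / (n - sqrt(n^2 - na^2))
  t_nm / 1000
}

#' Mean glomerular tuft profile area
#'
#' Arithmetic mean over all measured profiles of a biopsy; sclerotic
#' regions are part of the tuft area by the measurement contract, so fully
#' sclerotic (score 4) profiles contribute.
#'
#' @param biopsy a [biopsy_measurement()].
#' @return mean area in square micrometres.
#' @export
mean_glomerular_area <- function(biopsy) {
  stopifnot(inherits(biopsy, "biopsy_measurement"))
  if (n_glomeruli(biopsy) == 0L)
    stop("biopsy has no glomerular profiles", call. = FALSE)
  mean(glom_field(biopsy, "tuft_area"))
}

#' Weibel-Gomez glomerular volume
#'
#' V = (beta/d) * A^(3/2) with A the mean tuft profile area.
#'
#' @param mean_area mean tuft profile area in square micrometres (>= 0).
#' @param cfg a [stereology_config()].
#' @return volume in cubic micrometres.
#' @export
glomerular_volume <- function(mean_area, cfg = stereology_config()) {
  if (!is.finite(mean_area) || mean_area < 0)
    stop("mean_area must be >= 0", call. = FALSE)
  (cfg$shape_coefficient_beta / cfg$size_distribution_d) * mean_area^1.5
}

#' Estimated true nuclear diameter
#'
#' Applies the configured caliper-diameter correction to the mean apparent
#' caliper diameter: (4/pi) * d in `four_over_pi` mode, d unchanged in
#' `identity` mode, `factor * d` in `custom` mode.
#'
#' @param mean_apparent mean apparent caliper diameter, micrometres (> 0).
#' @param cfg a [stereology_config()].
#' @return estimated true diameter in micrometres.
#' @export
true_nuclear_diameter <- function(mean_apparent, cfg = stereology_config()) {
  if (!is.finite(mean_apparent) || mean_apparent <= 0)
    stop("mean_apparent must be > 0", call. = FALSE)
  diameter_correction_factor(cfg) * mean_apparent
}

#' Podocyte numerical density
#'
#' N_V = (sum Q / sum A) / (D_eff + T): total nuclei counted over all
#' profiles divided by total tuft area, divided by the height of the
#' counting window - the effective nuclear caliper diameter plus the
#' optical section thickness. `D_eff` is the mean caliper diameter after
#' applying the configured correction mode (default identity, i.e. the
#' apparent diameter).
#'
#' @param biopsy a [biopsy_measurement()].
#' @param cfg a [stereology_config()].
#' @return density in nuclei per cubic micrometre.
#' @export
podocyte_density <- function(biopsy, cfg = stereology_config()) {
  stopifnot(inherits(biopsy, "biopsy_measurement"))
  d <- all_diameters(biopsy)
  if (length(d) == 0L)
    stop("biopsy contains no podocyte nuclei; density undefined",
         call. = FALSE)
  total_area <- sum(glom_field(biopsy, "tuft_area"))
  if (total_area <= 0) stop("total tuft area is zero", call. = FALSE)
  d_eff <- diameter_correction_factor(cfg) * mean(d)
  t_um <- optical_section_thickness(biopsy$optics)
  (length(d) / total_area) / (d_eff + t_um)
}

#' Podocyte number per glomerular tuft
#'
#' Density times glomerular volume; real-valued, never rounded (threshold
#' comparisons use the real value).
#'
#' @param density podocyte density, per cubic micrometre (>= 0).
#' @param volume glomerular volume, cubic micrometres (>= 0).
#' @return podocytes per tuft.
#' @export
podocytes_per_tuft <- function(density, volume) {
  if (!is.finite(density) || density < 0) stop("density must be >= 0",
                                               call. = FALSE)
  if (!is.finite(volume) || volume < 0) stop("volume must be >= 0",
                                             call. = FALSE)
  density * volume
}

#' Synaptopodin-positive area fraction
#'
#' Sum of synaptopodin-positive areas over all tuft profiles divided by the
#' sum of all tuft areas; the biopsy-level fraction of glomerular area
#' stained for podocyte cytoplasm.
#'
#' @param biopsy a [biopsy_measurement()].
#' @return dimensionless fraction in \[0, 1\].
#' @export
snp_fraction <- function(biopsy) {
  stopifnot(inherits(biopsy, "biopsy_measurement"))
  total_area <- sum(glom_field(biopsy, "tuft_area"))
  if (!length(biopsy$glomeruli) || total_area <= 0)
    stop("total tuft area is zero", call. = FALSE)
  sum(glom_field(biopsy, "snp_area")) / total_area
}

#' Mean podocyte nuclear volume
#'
#' Sphere volume of the corrected nuclear diameter: with the `four_over_pi`
#' correction, V = (4*pi/3) * ((2/pi) * d_apparent)^3, i.e. a sphere of
#' radius (2/pi) times the apparent caliper diameter. Other modes use
#' radius = corrected diameter / 2.
#'
#' @param mean_apparent mean apparent caliper diameter, micrometres (> 0).
#' @param cfg a [stereology_config()]; the correction mode sets the assumed
#'   true diameter.
#' @return nuclear volume in cubic micrometres.
#' @export
podocyte_nuclear_volume <- function(mean_apparent, cfg = stereology_config()) {
  if (!is.finite(mean_apparent) || mean_apparent <= 0)
    stop("mean_apparent must be > 0", call. = FALSE)
  r <- diameter_correction_factor(cfg) * mean_apparent / 2
  (4 * pi / 3) * r^3
}

#' Mean podocyte cytoplasmic volume
#'
#' V_glom * snp_fraction / podocytes per tuft: the synaptopodin-positive
#' share of the glomerular volume divided among the podocytes.
#'
#' @param glom_volume glomerular volume, cubic micrometres.
#' @param snp_fraction synaptopodin-positive fraction in \[0, 1\].
#' @param n_per_tuft podocytes per tuft (> 0).
#' @return cytoplasmic volume per podocyte, cubic micrometres.
#' @export
podocyte_cytoplasmic_volume <- function(glom_volume, snp_fraction, n_per_tuft) {
  if (!is.finite(n_per_tuft) || n_per_tuft <= 0)
    stop("n_per_tuft must be > 0", call. = FALSE)
  glom_volume * snp_fraction / n_per_tuft
}

#' Total podocyte volume
#'
#' @param nuclear nuclear volume, cubic micrometres.
#' @param cytoplasmic cytoplasmic volume, cubic micrometres.
#' @return their sum.
#' @export
total_podocyte_volume <- function(nuclear, cytoplasmic) nuclear + cytoplasmic

#' Podocyte volumetric density V_V(Pod/Glom)
#'
#' Fraction of glomerular tuft volume occupied by podocytes: total podocyte
#' volume times podocyte number per tuft divided by glomerular volume.
#' Physically consistent inputs give a value in \[0, 1\]; larger values are
#' returned with a warning.
#'
#' @param total_volume total volume per podocyte, cubic micrometres.
#' @param n_per_tuft podocytes per tuft (>= 0).
#' @param glom_volume glomerular volume, cubic micrometres (> 0).
#' @return dimensionless fraction.
#' @export
vv_pod_glom <- function(total_volume, n_per_tuft, glom_volume) {
  if (!is.finite(glom_volume) || glom_volume <= 0)
    stop("glom_volume must be > 0", call. = FALSE)
  vv <- total_volume * n_per_tuft / glom_volume
  if (is.finite(vv) && vv > 1)
    warning("V_V(Pod/Glom) > 1: physically inconsistent inputs",
            call. = FALSE)
  vv
}

#' Full podometric profile of a biopsy
#'
#' Composes every estimator: mean tuft area, Weibel-Gomez volume, optical
#' section thickness, apparent and corrected caliper diameters, density,
#' podocytes per tuft, synaptopodin fraction, nuclear / cytoplasmic / total
#' podocyte volumes, nuclear-to-cytoplasmic ratio and V_V(Pod/Glom).
#' Deterministic in its inputs.
#'
#' @param biopsy a [biopsy_measurement()] that passed the inclusion filter.
#' @param cfg a [stereology_config()].
#' @return a one-row data frame of class `podometric_result`.
#' @export
compute_podometrics <- function(biopsy, cfg = stereology_config()) {
  stopifnot(inherits(biopsy, "biopsy_measurement"))
  a_bar <- mean_glomerular_area(biopsy)
  v_glom <- glomerular_volume(a_bar, cfg)
  t_um <- optical_section_thickness(biopsy$optics)
  d <- all_diameters(biopsy)
  if (length(d) == 0L)
    stop("biopsy contains no podocyte nuclei", call. = FALSE)
  d_app <- mean(d)
  d_true <- true_nuclear_diameter(d_app, cfg)
  nv <- podocyte_density(biopsy, cfg)
  n_tuft <- podocytes_per_tuft(nv, v_glom)
  f_snp <- snp_fraction(biopsy)
  v_nuc <- podocyte_nuclear_volume(d_app, cfg)
  v_cyt <- podocyte_cytoplasmic_volume(v_glom, f_snp, n_tuft)
  v_tot <- total_podocyte_volume(v_nuc, v_cyt)
  res <- data.frame(
    patient_id = biopsy$patient_id,
    n_profiles = n_glomeruli(biopsy),
    mean_glomerular_area = a_bar,
    glomerular_volume = v_glom,
    optical_thickness = t_um,
    mean_apparent_caliper = d_app,
    estimated_true_caliper = d_true,
    podocyte_density = nv,
    podocytes_per_tuft = n_tuft,
    snp_fraction = f_snp,
    nuclear_volume = v_nuc,
    cytoplasmic_volume = v_cyt,
    total_podocyte_volume = v_tot,
    nc_ratio = v_nuc / v_cyt,
    vv_pod_glom = vv_pod_glom(v_tot, n_tuft, v_glom),
    beta = cfg$shape_coefficient_beta,
    size_distribution_d = cfg$size_distribution_d,
    diameter_correction_mode = cfg$diameter_correction_mode,
    stringsAsFactors = FALSE)
  class(res) <- c("podometric_result", class(res))
  res
}
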