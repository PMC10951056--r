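#' Lognormal parameters from a median and IQR
#'
#' Quantile matching: med = exp(mu), quartiles = exp(mu +/- 0.6745 sigma)
#' (0.6745 = standard normal upper quartile).
#'
#' @param med median (> 0).
#' @param q1,q3 quartiles, 0 < q1 < q3.
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormal_from_median_iqr <- function(med, q1, q3) {
  if (!all(is.finite(c(med, q1, q3))) || med <= 0 || q1 <= 0 || q3 <= q1)
    stop("need 0 < q1 < q3 and med > 0", call. = FALSE)
  z <- stats::qnorm(0.75)  # 0.6744898
  list(meanlog = log(med), sdlog = (log(q3) - log(q1)) / (2 * z))
}

rlnorm_miqr <- function(n, med, q1, q3) {
  p <- lognormal_from_median_iqr(med, q1, q3)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

#' Ground truth for one synthetic patient
#'
#' @param patient_id identifier.
#' @param n_podocytes true podocyte number per tuft N*.
#' @param nuclear_diameter_um true podocyte nuclear diameter D* (um).
#' @param tuft_radius_um tuft (sphere) radius R* (um).
#' @param snp_fraction true synaptopodin-positive volume fraction f*.
#' @param score_probs length-5 probability vector over sclerosis grades
#'   0..4.
#' @param group "responder" or "non_responder".
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(patient_id, n_podocytes, nuclear_diameter_um,
                            tuft_radius_um, snp_fraction,
                            score_probs = c(1, 0, 0, 0, 0),
                            group = "responder") {
  if (n_podocytes < 0 || nuclear_diameter_um <= 0 || tuft_radius_um <= 0 ||
      snp_fraction < 0 || snp_fraction > 1)
    stop("invalid truth parameters", call. = FALSE)
  if (length(score_probs) != 5L || any(score_probs < 0) ||
      sum(score_probs) <= 0)
    stop("score_probs must be 5 non-negative weights", call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 n_podocytes = as.integer(round(n_podocytes)),
                 nuclear_diameter_um = nuclear_diameter_um,
                 tuft_radius_um = tuft_radius_um,
                 snp_fraction = snp_fraction,
                 score_probs = score_probs / sum(score_probs),
                 group = group),
            class = "synthetic_truth")
}

#' Generate a glomerulus geometry
#'
#' Places N* podocyte nucleus centers uniformly in the tuft sphere by
#' rejection (dart-throwing) sampling with minimum pairwise spacing equal
#' to the nuclear diameter; nuclear radii are D*/2, optionally with a small
#' lognormal coefficient of variation. Uses the current RNG state - seed
#' with `set.seed()` for reproducibility.
#'
#' @param truth a [synthetic_truth()].
#' @param radius_cv coefficient of variation of nuclear radii (default
#'   0.05).
#' @param spacing_factor multiplier on the minimum pairwise spacing
#'   (default 1 = one nuclear diameter; raise it to guarantee that nucleus
#'   profiles cannot touch in a rendered section).
#' @param max_attempts dart throws allowed per nucleus on average before
#'   declaring the packing infeasible.
#' @return list with `tuft_radius`, and `centers` (N x 3 matrix), `radii`
#'   (length N), class `glomerulus_geometry`.
#' @export
generate_glomerulus <- function(truth, radius_cv = 0.05, spacing_factor = 1,
                                max_attempts = 500L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- truth$n_podocytes
  r_tuft <- truth$tuft_radius_um
  d_nuc <- truth$nuclear_diameter_um
  d_min <- d_nuc * spacing_factor
  centers <- matrix(numeric(0), 0, 3)
  if (n > 0) {
    centers <- matrix(NA_real_, n, 3)
    placed <- 0L
    attempts <- 0L
    budget <- max_attempts * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > budget)
        stop("nucleus packing infeasible: N* too large for tuft radius",
             call. = FALSE)
      # uniform point in the sphere
      p <- stats::runif(3, -r_tuft, r_tuft)
      if (sum(p^2) > r_tuft^2) next
      if (placed > 0L) {
        d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - p)^2)
        if (any(d2 < d_min^2)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- p
    }
  }
  radii <- rep(d_nuc / 2, n)
  if (n > 0 && radius_cv > 0) {
    sdlog <- sqrt(log(1 + radius_cv^2))
    radii <- radii * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  structure(list(tuft_radius = r_tuft, centers = centers, radii = radii,
                 truth = truth),
            class = "glomerulus_geometry")
}

#' Optical section of a glomerulus geometry
#'
#' Models a thin optical slab of thickness T at mid-plane offset h from the
#' tuft center. The tuft profile area is pi (R^2 - h^2). A nucleus of
#' radius r at signed distance z from the mid-plane appears iff
#' |z| < r + T/2; its apparent caliper diameter is the full 2r when the
#' center lies inside the slab (|z| <= T/2) and
#' 2 sqrt(r^2 - (|z| - T/2)^2) when it overhangs. The synaptopodin area is
#' f* times the profile area with multiplicative mean-one lognormal noise;
#' the sclerosis score is drawn from the truth's grade distribution.
#'
#' @param geometry a [glomerulus_geometry()].
#' @param offset mid-plane offset h from the tuft center, |h| < R (um).
#' @param thickness_um slab thickness T (um).
#' @param snp_noise_sd lognormal sigma of the synaptopodin noise (0
#'   disables it).
#' @param glomerulus_id identifier for the resulting measurement.
#' @return a [glomerulus_measurement()].
#' @export
section_glomerulus <- function(geometry, offset, thickness_um = 0.541,
                               snp_noise_sd = 0.1, glomerulus_id = "g1") {
  stopifnot(inherits(geometry, "glomerulus_geometry"))
  r_tuft <- geometry$tuft_radius
  if (abs(offset) >= r_tuft)
    stop("section plane does not intersect the tuft", call. = FALSE)
  area <- pi * (r_tuft^2 - offset^2)
  diams <- numeric(0)
  if (nrow(geometry$centers) > 0) {
    z <- abs(geometry$centers[, 3] - offset)
    r <- geometry$radii
    hit <- z < r + thickness_um / 2
    if (any(hit)) {
      over <- pmax(0, z[hit] - thickness_um / 2)
      diams <- 2 * sqrt(r[hit]^2 - over^2)
    }
  }
  f <- geometry$truth$snp_fraction
  noise <- if (snp_noise_sd > 0)
    stats::rlnorm(1, -snp_noise_sd^2 / 2, snp_noise_sd) else 1
  snp_area <- min(f * area * noise, area)
  score <- sample(0:4, 1, prob = geometry$truth$score_probs)
  glomerulus_measurement(glomerulus_id, area, score, diams, snp_area)
}

#' Simulate a full biopsy from a single truth
#'
#' Draws `n_profiles` independent glomerulus geometries (one glomerulus is
#' sectioned once in a biopsy section) with uniform random mid-plane
#' offsets in (-R, R).
#'
#' @param truth a [synthetic_truth()].
#' @param n_profiles number of glomerular profiles.
#' @param optics an [optical_config()]; the slab thickness is its optical
#'   section thickness.
#' @param snp_noise_sd passed to [section_glomerulus()].
#' @param radius_cv passed to [generate_glomerulus()].
#' @return a [biopsy_measurement()].
#' @export
simulate_biopsy <- function(truth, n_profiles = 14,
                            optics = optical_config(), snp_noise_sd = 0.1,
                            radius_cv = 0.05) {
  t_um <- optical_section_thickness(optics)
  gloms <- vector("list", n_profiles)
  for (i in seq_len(n_profiles)) {
    geom <- generate_glomerulus(truth, radius_cv = radius_cv)
    h <- stats::runif(1, -geom$tuft_radius * 0.999, geom$tuft_radius * 0.999)
    gloms[[i]] <- section_glomerulus(geom, h, t_um, snp_noise_sd,
                                     glomerulus_id = sprintf("g%02d", i))
  }
  biopsy_measurement(truth$patient_id, gloms, optics)
}

#' Default cohort calibration
#'
#' Group-level distribution parameters for the synthetic cohort, stated as
#' median (q1-q3) of lognormal distributions (see the methods vignette for
#' sources and rationale). Groups are 13 responders and 6 non-responders;
#' profile counts are drawn as round(Normal(14, 7)) clamped to \[7, 35\].
#'
#' @return nested list of parameters, element `responder` and
#'   `non_responder`, plus `n_responders`, `n_nonresponders`,
#'   `n_profiles_mean`, `n_profiles_sd`.
#' @export
default_cohort_params <- function() {
  list(
    n_responders = 13L,
    n_nonresponders = 6L,
    n_profiles_mean = 14,
    n_profiles_sd = 7,
    responder = list(
      podocytes = c(279, 203, 507),
      glom_volume_1e6 = c(3.88, 2.76, 4.56),
      true_diameter = c(9.95, 9.67, 10.50),
      snp_pct = c(13, 11, 19),
      score_probs = c(0.62, 0.12, 0.08, 0.06, 0.12),
      score_conc = 8,
      n_male = 7L,
      age = c(35, 23, 53),
      proteinuria_biopsy = c(3.87, 2.14, 6.75),
      creatinine_biopsy = c(88, 65, 114),
      proteinuria_month6 = c(1.00, 0.20, 1.90),
      creatinine_month6 = c(91, 74, 107)),
    non_responder = list(
      podocytes = c(186, 118, 310),
      glom_volume_1e6 = c(2.95, 2.35, 4.85),
      true_diameter = c(10.4, 9.39, 10.90),
      snp_pct = c(12, 9, 18),
      score_probs = c(0.35, 0.15, 0.10, 0.10, 0.30),
      score_conc = 8,
      n_male = 6L,
      age = c(45, 41, 58),
      proteinuria_biopsy = c(5.83, 5.18, 6.77),
      creatinine_biopsy = c(116, 84, 161),
      proteinuria_month6 = c(6.11, 3.92, 9.14),
      creatinine_month6 = c(121, 92, 227)))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

# draw from median/IQR-matched lognormal, truncated to (lo, hi) by resampling
rtrunc_lnorm <- function(med, q1, q3, lo = 0, hi = Inf, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- rlnorm_miqr(1, med, q1, q3)
    if (x > lo && x < hi) return(x)
  }
  min(max(med, lo * 1.01), hi * 0.99)
}

#' Generate a synthetic responder / non-responder cohort
#'
#' Draws per-patient ground truths from lognormal distributions matched to
#' the calibration medians/IQRs, simulates each biopsy section, and emits
#' clinical records consistent with the group label by construction
#' (responder month-6 proteinuria < 3.5 g/day and stable creatinine;
#' non-responder proteinuria >= 3.5 g/day). All randomness flows from the
#' current RNG state: call `set.seed()` first for byte-identical output.
#'
#' @param params as [default_cohort_params()].
#' @param optics an [optical_config()].
#' @param snp_noise_sd synaptopodin measurement noise sigma.
#' @return list with `biopsies` (list of [biopsy_measurement()]),
#'   `clinical` (list of [clinical_record()]), `truth` (data frame of
#'   per-patient ground truth).
#' @export
generate_cohort <- function(params = default_cohort_params(),
                            optics = optical_config(), snp_noise_sd = 0.1) {
  for (g in c("responder", "non_responder")) {
    for (v in c("podocytes", "glom_volume_1e6", "true_diameter", "snp_pct")) {
      q <- params[[g]][[v]]
      if (q[1] <= 0 || q[2] <= 0 || q[3] <= q[2])
        stop("invalid median/IQR for ", g, " ", v, call. = FALSE)
    }
  }
  specs <- c(rep("responder", params$n_responders),
             rep("non_responder", params$n_nonresponders))
  biopsies <- list(); clinical <- list(); truth_rows <- list()
  for (i in seq_along(specs)) {
    grp <- specs[i]
    gp <- params[[grp]]
    pid <- sprintf("P%02d", i)
    # joint (N, V, D) draw, resampled until the nucleus packing is feasible
    # (excluded-volume heuristic: 8x nuclear volume fraction <= 0.5); the
    # marginals lose a little of their upper tail in exchange for geometric
    # consistency (podocyte number and glomerular volume are positively
    # correlated in real glomeruli)
    repeat {
      n_pod <- max(1, round(rlnorm_miqr(1, gp$podocytes[1], gp$podocytes[2],
                                        gp$podocytes[3])))
      v_glom <- rlnorm_miqr(1, gp$glom_volume_1e6[1], gp$glom_volume_1e6[2],
                            gp$glom_volume_1e6[3]) * 1e6
      d_nuc <- rlnorm_miqr(1, gp$true_diameter[1], gp$true_diameter[2],
                           gp$true_diameter[3])
      if (8 * n_pod * (pi / 6) * d_nuc^3 / v_glom <= 0.5) break
    }
    r_tuft <- (3 * v_glom / (4 * pi))^(1 / 3)
    f_snp <- rlnorm_miqr(1, gp$snp_pct[1], gp$snp_pct[2], gp$snp_pct[3]) / 100
    probs <- rdirichlet1(gp$score_probs * gp$score_conc)
    n_prof <- max(7L, min(35L, round(stats::rnorm(1, params$n_profiles_mean,
                                                  params$n_profiles_sd))))
    tr <- synthetic_truth(pid, n_pod, d_nuc, r_tuft, min(f_snp, 1), probs, grp)
    biopsies[[i]] <- simulate_biopsy(tr, n_prof, optics, snp_noise_sd)

    male <- if (grp == "responder") i <= gp$n_male else TRUE
    sex <- if (male) "male" else "female"
    age <- max(18, rlnorm_miqr(1, gp$age[1], gp$age[2], gp$age[3]))
    scr0 <- rlnorm_miqr(1, gp$creatinine_biopsy[1], gp$creatinine_biopsy[2],
                        gp$creatinine_biopsy[3])
    prot0 <- rlnorm_miqr(1, gp$proteinuria_biopsy[1],
                         gp$proteinuria_biopsy[2], gp$proteinuria_biopsy[3])
    if (grp == "responder") {
      prot6 <- rtrunc_lnorm(gp$proteinuria_month6[1], gp$proteinuria_month6[2],
                            gp$proteinuria_month6[3], hi = 3.5)
      scr6 <- rtrunc_lnorm(gp$creatinine_month6[1], gp$creatinine_month6[2],
                           gp$creatinine_month6[3], hi = 1.3 * scr0)
    } else {
      prot6 <- rtrunc_lnorm(gp$proteinuria_month6[1], gp$proteinuria_month6[2],
                            gp$proteinuria_month6[3], lo = 3.5)
      scr6 <- rlnorm_miqr(1, gp$creatinine_month6[1], gp$creatinine_month6[2],
                          gp$creatinine_month6[3])
    }
    clinical[[2 * i - 1]] <- clinical_record(pid, "biopsy", age, sex, scr0,
                                             proteinuria_g24h = prot0)
    clinical[[2 * i]] <- clinical_record(pid, "month6", age + 0.5, sex, scr6,
                                         proteinuria_g24h = prot6)
    truth_rows[[i]] <- data.frame(
      patient_id = pid, group = grp, n_podocytes = n_pod,
      nuclear_diameter_um = d_nuc, tuft_radius_um = r_tuft,
      glomerular_volume_um3 = v_glom, snp_fraction = tr$snp_fraction,
      n_profiles = n_prof, sex = sex, age_years = age,
      stringsAsFactors = FALSE)
  }
  list(biopsies = biopsies, clinical = clinical,
       truth = do.call(rbind, truth_rows))
}
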