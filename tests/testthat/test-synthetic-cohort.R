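test_that("lognormal quantile matching reproduces median and IQR", {
  p <- lognormal_from_median_iqr(279, 203, 507)
  expect_equal(exp(p$meanlog), 279)
  # the fit is (median, IQR width) matching: the quartile RATIO is
  # reproduced exactly (the pair itself is over-determined unless the
  # median is their geometric mean)
  expect_equal(stats::qlnorm(0.75, p$meanlog, p$sdlog) /
                 stats::qlnorm(0.25, p$meanlog, p$sdlog), 507 / 203,
               tolerance = 1e-9)
  # and on a geometric-mean-consistent triple both quartiles are exact
  p2 <- lognormal_from_median_iqr(sqrt(200 * 500), 200, 500)
  expect_equal(stats::qlnorm(0.25, p2$meanlog, p2$sdlog), 200,
               tolerance = 1e-9)
  expect_equal(stats::qlnorm(0.75, p2$meanlog, p2$sdlog), 500,
               tolerance = 1e-9)
  expect_error(lognormal_from_median_iqr(10, 20, 5), "q1 < q3")

  set.seed(51)
  draws <- stats::rlnorm(2000, p$meanlog, p$sdlog)
  expect_lt(abs(stats::median(draws) - 279) / 279, 0.05)
})

test_that("glomerulus generator: packing, determinism, edge cases", {
  tr <- synthetic_truth("P", 500, 9.3, 95, 0.13)
  set.seed(52)
  g <- generate_glomerulus(tr)
  expect_equal(nrow(g$centers), 500)
  # all inside the tuft sphere
  expect_true(all(rowSums(g$centers^2) <= 95^2))
  # pairwise spacing >= one nuclear diameter
  dmat <- as.matrix(stats::dist(g$centers))
  expect_gte(min(dmat[upper.tri(dmat)]), 9.3)

  set.seed(52)
  g2 <- generate_glomerulus(tr)
  expect_identical(g, g2)  # same seed, same geometry

  g0 <- generate_glomerulus(synthetic_truth("P", 0, 9.3, 95, 0.13))
  expect_equal(nrow(g0$centers), 0)

  # infeasible packing: far too many nuclei for the sphere
  expect_error(generate_glomerulus(
    synthetic_truth("P", 400, 9.3, 20, 0.1), max_attempts = 20L),
    "infeasible")
})

test_that("sectioning: closed-form apparent diameters and profile areas", {
  geom <- make_geometry(matrix(c(0, 0, 0,   0, 10, 4.0,   0, -10, 4.93),
                               3, 3, byrow = TRUE),
                        radii = rep(4.65, 3), tuft_radius = 95)
  m <- section_glomerulus(geom, offset = 0, thickness_um = 0.541,
                          snp_noise_sd = 0)
  expect_equal(m$tuft_area, pi * 95^2)
  d <- sort(m$nuclear_caliper_diameters, decreasing = TRUE)
  # center nucleus inside the slab: full diameter
  expect_equal(d[1], 9.3)
  # |z| = 4.0: 2 sqrt(r^2 - (4.0 - T/2)^2)
  expect_equal(d[2], 2 * sqrt(4.65^2 - (4.0 - 0.541 / 2)^2))
  # grazing nucleus |z| = r + T/2 excluded (strict inequality)
  expect_length(d, 2)
  expect_equal(m$snp_area, 0.13 * pi * 95^2)
  expect_error(section_glomerulus(geom, offset = 95), "intersect")
})

test_that("mean apparent diameter matches the analytic slab average", {
  r <- 4.65; t_um <- 0.541
  geom <- make_geometry(matrix(0, 1, 3), radii = r, tuft_radius = 1000)
  set.seed(53)
  offs <- runif(2e4, -(r + t_um / 2), r + t_um / 2)
  diams <- unlist(lapply(offs, function(h)
    section_glomerulus(geom, h, t_um, snp_noise_sd = 0)$nuclear_caliper_diameters))
  expect_equal(mean(diams), analytic_mean_apparent(r, t_um),
               tolerance = 0.01)
})

test_that("Weibel-Gomez recovers sphere volume from uniform random planes", {
  set.seed(54)
  r_tuft <- 95
  geom <- make_geometry(matrix(numeric(0), 0, 3), radii = numeric(0),
                        tuft_radius = r_tuft,
                        truth = synthetic_truth("T", 0, 9.3, r_tuft, 0))
  areas <- vapply(runif(500, -r_tuft, r_tuft), function(h)
    section_glomerulus(geom, h, snp_noise_sd = 0)$tuft_area, numeric(1))
  v_est <- glomerular_volume(mean(areas), stereology_config())
  v_true <- 4 / 3 * pi * r_tuft^3
  expect_lt(abs(v_est - v_true) / v_true, 0.05)
})

test_that("cohort generator: sizes, construction consistency, determinism", {
  set.seed(55)
  co <- generate_cohort()
  expect_length(co$biopsies, 19)
  expect_equal(sum(co$truth$group == "responder"), 13)
  expect_equal(sum(co$truth$group == "non_responder"), 6)
  expect_true(all(vapply(co$biopsies, function(b) length(b$glomeruli),
                         integer(1)) > 6))
  # generated labels match the generating group by construction
  lab <- classify_cohort(co$clinical)
  m <- merge(lab, co$truth[, c("patient_id", "group")], by = "patient_id")
  expect_equal(m$label, m$group)
  # non-responders all male, 7/13 responders male (calibrated proportions)
  expect_true(all(co$truth$sex[co$truth$group == "non_responder"] == "male"))
  expect_equal(sum(co$truth$sex == "male" & co$truth$group == "responder"), 7)

  expect_error(generate_cohort(modifyList(default_cohort_params(),
    list(responder = modifyList(default_cohort_params()$responder,
                                list(podocytes = c(279, 507, 203)))))),
    "invalid median/IQR")
})

test_that("podometric recovery at 14 profiles is within documented noise", {
  set.seed(56)
  co <- generate_cohort()
  cfg <- stereology_config(diameter_correction_mode = "four_over_pi")
  pod <- do.call(rbind, lapply(co$biopsies, compute_podometrics, cfg = cfg))
  m <- merge(pod, co$truth, by = "patient_id")
  rel <- abs(m$podocytes_per_tuft - m$n_podocytes) / m$n_podocytes
  expect_lte(stats::median(rel), 0.25)
})

test_that("rendered frames carry consistent ground truth", {
  set.seed(57)
  tr <- synthetic_truth("P", 200, 9.3, 90, 0.13)
  g <- generate_glomerulus(tr, radius_cv = 0)
  img <- render_images(g, offset = 20, pixel_size = 0.8, n_pixels = 300,
                       poisson_noise = FALSE, blur_sigma_px = 0)
  rn <- attr(img, "rendered_nuclei")
  expect_true(all(rn$apparent_diameter_um >= 3))
  expect_true(all(rn$apparent_diameter_um <= 9.3 + 1e-9))
  # frame coverage sanity: 1024 px at 0.19 um/px spans a 97 um-radius tuft
  expect_gte(1024 * 0.19 / 2, 97)
  expect_warning(render_images(g, offset = 20, pixel_size = 3,
                               n_pixels = 80, poisson_noise = FALSE),
                 "coarse")
})
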