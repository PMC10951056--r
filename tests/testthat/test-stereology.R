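test_that("optical section thickness matches the closed form", {
  expect_equal(round(optical_section_thickness(optical_config()), 3), 0.541)
  # direct evaluation at 488 nm
  expect_equal(optical_section_thickness(optical_config(488, 1.515, 1.25)),
               0.88 * 488 / (1.515 - sqrt(1.515^2 - 1.25^2)) / 1000,
               tolerance = 1e-12)
  expect_error(optical_config(405, 1.3, 1.4), "refractive")
})

test_that("thickness is monotone: decreasing in NA, increasing in lambda", {
  nas <- seq(0.2, 1.4, by = 0.1)
  t_na <- vapply(nas, function(a)
    optical_section_thickness(optical_config(405, 1.515, a)), numeric(1))
  expect_true(all(diff(t_na) < 0))
  lams <- seq(350, 650, by = 25)
  t_l <- vapply(lams, function(l)
    optical_section_thickness(optical_config(l, 1.515, 1.25)), numeric(1))
  expect_true(all(diff(t_l) > 0))
})

test_that("mean glomerular area is the arithmetic mean over all profiles", {
  expect_equal(mean_glomerular_area(make_biopsy(areas = c(10000, 20000))),
               15000)
  expect_equal(mean_glomerular_area(make_biopsy(areas = 12345,
                                                diam = list(7),
                                                snp = 0)), 12345)
  set.seed(3)
  areas <- runif(14, 5000, 40000)
  b <- make_biopsy(areas = areas, diam = rep(list(7), 14),
                   snp = rep(0, 14), scores = rep(0L, 14))
  acc <- 0
  for (a in areas) acc <- acc + a  # brute-force sum oracle
  expect_equal(mean_glomerular_area(b), acc / 14)
})

test_that("Weibel-Gomez volume: value, zero case, homogeneity", {
  cfg <- stereology_config()
  expect_equal(glomerular_volume(10000, cfg), (1.382 / 1.01) * 10000^1.5)
  expect_equal(glomerular_volume(10000, cfg), 1.3683e6, tolerance = 1e-4)
  expect_equal(glomerular_volume(0, cfg), 0)
  expect_error(glomerular_volume(-1, cfg), ">= 0")
  # homogeneous of degree 3/2
  set.seed(4)
  for (a in runif(5, 100, 1e5))
    expect_equal(glomerular_volume(4 * a, cfg), 8 * glomerular_volume(a, cfg))
})

test_that("true diameter correction modes", {
  expect_equal(true_nuclear_diameter(
    7.31, stereology_config(diameter_correction_mode = "custom",
                            custom_correction_factor = 1.3612)),
    9.95, tolerance = 1e-3)
  expect_equal(true_nuclear_diameter(
    7.31, stereology_config(diameter_correction_mode = "four_over_pi")),
    4 / pi * 7.31)
  expect_equal(true_nuclear_diameter(5.5, stereology_config()), 5.5)
  expect_error(true_nuclear_diameter(0, stereology_config()), "> 0")
})

test_that("podocyte density: direct value and linearity in counts", {
  # 100 nuclei of apparent diameter 7.31 over 1e5 um2, identity mode
  b1 <- make_biopsy(areas = c(5e4, 5e4),
                    diam = list(rep(7.31, 60), rep(7.31, 40)),
                    snp = c(0, 0))
  expect_equal(podocyte_density(b1), 100 / (1e5 * (7.31 + 0.541)),
               tolerance = 1e-4)
  expect_equal(podocyte_density(b1) * 1e6, 127.4, tolerance = 1e-3)
  b2 <- make_biopsy(areas = c(5e4, 5e4),
                    diam = list(rep(7.31, 120), rep(7.31, 80)),
                    snp = c(0, 0))
  expect_equal(podocyte_density(b2), 2 * podocyte_density(b1))
  b0 <- make_biopsy(areas = c(5e4, 5e4), diam = list(numeric(), numeric()),
                    snp = c(0, 0))
  expect_error(podocyte_density(b0), "no podocyte nuclei")
})

test_that("podocytes per tuft is the density-volume product", {
  expect_equal(podocytes_per_tuft(76e-6, 3.67e6), 278.92)
  expect_equal(podocytes_per_tuft(0, 3e6), 0)
  expect_error(podocytes_per_tuft(-1, 1), ">= 0")
})

test_that("snp fraction: ratio, saturation, errors", {
  expect_equal(snp_fraction(make_biopsy(areas = c(10000, 10000),
                                        snp = c(1300, 0))), 0.065)
  expect_equal(snp_fraction(make_biopsy(areas = c(8000, 9000),
                                        snp = c(8000, 9000))), 1)
})

test_that("nuclear volume: sphere of the corrected diameter", {
  four <- stereology_config(diameter_correction_mode = "four_over_pi")
  expect_equal(podocyte_nuclear_volume(7.31, four),
               (4 * pi / 3) * ((2 / pi) * 7.31)^3)
  expect_equal(podocyte_nuclear_volume(7.31, four), 422.1, tolerance = 1e-3)
  expect_equal(podocyte_nuclear_volume(pi / 2, four), 4 * pi / 3,
               tolerance = 1e-12)
  # homogeneity of degree 3
  expect_equal(podocyte_nuclear_volume(3 * 7.31, four),
               27 * podocyte_nuclear_volume(7.31, four))
})

test_that("cytoplasmic, total volume and V_V identities", {
  expect_equal(podocyte_cytoplasmic_volume(3.67e6, 0.13, 279),
               3.67e6 * 0.13 / 279)
  expect_equal(podocyte_cytoplasmic_volume(3.67e6, 0, 279), 0)
  expect_equal(podocyte_cytoplasmic_volume(3.67e6, 0.13, 558),
               podocyte_cytoplasmic_volume(3.67e6, 0.13, 279) / 2)
  expect_error(podocyte_cytoplasmic_volume(3.67e6, 0.13, 0), "> 0")

  expect_equal(total_podocyte_volume(399, 1425), 1824)
  expect_equal(399 / 1425, 0.28, tolerance = 0.01)

  expect_equal(vv_pod_glom(1834, 279, 3.0e6), 1834 * 279 / 3.0e6)
  expect_equal(vv_pod_glom(1834, 0, 3.0e6), 0)
  expect_error(vv_pod_glom(1834, 279, 0), "> 0")
  expect_warning(vv_pod_glom(1e6, 500, 1e6), "inconsistent")
})

test_that("compute_podometrics composes consistently", {
  set.seed(9)
  b <- make_biopsy(areas = runif(10, 1e4, 3e4),
                   diam = replicate(10, runif(8, 6, 9), simplify = FALSE),
                   snp = runif(10, 500, 3000), scores = rep(0L, 10))
  for (mode in c("identity", "four_over_pi")) {
    cfg <- stereology_config(diameter_correction_mode = mode)
    p <- compute_podometrics(b, cfg)
    # exact internal identities
    expect_equal(p$total_podocyte_volume,
                 p$nuclear_volume + p$cytoplasmic_volume, tolerance = 1e-9)
    expect_equal(p$vv_pod_glom,
                 p$total_podocyte_volume * p$podocytes_per_tuft /
                   p$glomerular_volume, tolerance = 1e-9)
    # when cytoplasm comes from the snp fraction, V_V decomposes as
    # snp_fraction + nuclear contribution
    expect_equal(p$vv_pod_glom,
                 p$snp_fraction + p$nuclear_volume * p$podocytes_per_tuft /
                   p$glomerular_volume, tolerance = 1e-9)
    expect_identical(p, compute_podometrics(b, cfg))  # deterministic
  }
  b_empty <- make_biopsy(areas = rep(1e4, 8), diam = rep(list(numeric()), 8),
                         snp = rep(0, 8), scores = rep(4L, 8))
  expect_error(compute_podometrics(b_empty), "no podocyte nuclei")
})
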