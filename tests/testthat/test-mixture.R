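test_that("CA mixture ECx is the weighted harmonic mean of component ECx", {
  ray <- fixed_ratio_ray(1, 1)
  crcs <- list(crc_from_ec50(100, 2), crc_from_ec50(1000, 2))
  expect_equal(ca_ecx(ray, crcs, 0.5), 1 / (0.5 / 100 + 0.5 / 1000),
               tolerance = 1e-12)
})

test_that("a sham combination reproduces the single curve under CA exactly", {
  f <- crc_from_ec50(374.87, 3.2)
  for (pa in c(0.1, 1 / 11, 0.5, 0.93)) {
    ray <- fixed_ratio_ray(pa, 1 - pa)
    x <- c(0.05, 0.3, 0.5, 0.8, 0.95)
    expect_equal(ca_ecx(ray, list(f, f), x), ecx(f, x), tolerance = 1e-15)
  }
})

test_that("CA is invariant to swapping component order with fractions", {
  crcs <- list(crc_from_ec50(374.87, 3.2), crc_from_ec50(19988.75, 2.6))
  r1 <- fixed_ratio_ray(1, 10)
  r2 <- fixed_ratio_ray(10, 1)
  x <- seq(0.05, 0.95, by = 0.1)
  expect_equal(ca_ecx(r1, crcs, x), ca_ecx(r2, rev(crcs), x),
               tolerance = 1e-14)
})

test_that("CA collapses to the dominant component as its fraction tends to 1", {
  crcs <- list(crc_from_ec50(100, 2), crc_from_ec50(1e5, 2))
  ray <- fixed_ratio_ray(1 - 1e-9, 1e-9)
  expect_equal(ca_ecx(ray, crcs, 0.5), 100, tolerance = 1e-6)
})

test_that("IA composes component effects as a probabilistic union", {
  # components chosen so the partial-concentration effects are 0.3 and 0.5
  ray <- fixed_ratio_ray(1, 1)
  ct <- 200
  f_a <- crc_from_ec50(100, 2)             # E_B(100) = 0.5 at its EC50
  # solve for the EC50 putting component A at 0.3 when exposed to 100 ug/L:
  # logit(0.3) = beta * (log10(100) - log10(ec50))
  ec50_a <- 10^(2 - stats::qlogis(0.3) / 2)
  f_b <- crc_from_ec50(ec50_a, 2)
  e <- ia_effect(ray, list(f_b, f_a), ct)
  expect_equal(e, 1 - (1 - 0.3) * (1 - 0.5), tolerance = 1e-12)
})

test_that("IA effect is non-decreasing in total concentration", {
  set.seed(31)
  for (i in 1:10) {
    crcs <- list(
      crc(sample(c("Logit", "Weibull"), 1), stats::runif(1, -8, 0),
          stats::runif(1, 0.5, 4)),
      crc(sample(c("Logit", "Weibull"), 1), stats::runif(1, -12, -2),
          stats::runif(1, 0.5, 4))
    )
    ray <- fixed_ratio_ray(stats::runif(1, 0.05, 0.95), 1)
    grid <- 10^seq(-1, 6, length.out = 100)
    expect_true(all(diff(ia_effect(ray, crcs, grid)) >= -1e-12))
  }
})

test_that("the CA curve inverts consistently onto the effect axis", {
  crcs <- list(crc_from_ec50(374.87, 3.2), crc_from_ec50(19988.75, 2.6))
  ray <- fixed_ratio_ray(1, 10)
  for (x in c(0.02, 0.25, 0.5, 0.75, 0.97)) {
    expect_equal(ca_effect(ray, crcs, ca_ecx(ray, crcs, x)), x,
                 tolerance = 1e-8)
  }
  pred <- mixture_prediction(ray, crcs)
  expect_true(all(diff(pred$ca$conc_ugL) > 0))
  expect_true(all(diff(pred$ia$effect_ia) >= -1e-12))
})

test_that("predictions through the observed means classify as additive", {
  crcs <- list(crc_from_ec50(374.87, 3.2), crc_from_ec50(19988.75, 2.6))
  ray <- fixed_ratio_ray(1, 10)
  conc <- concentration_series(2e5, 200, 12)$conc_ugL
  pred <- ca_effect(ray, crcs, conc)
  tab <- tibble::tibble(
    treatment_id = "Rf", ray_id = "Rf",
    conc_A_ugL = ray$p_A * conc, conc_B_ugL = ray$p_B * conc,
    conc_total_ugL = conc, n_reps = 3L,
    effects = purrr::map(pred, \(e) e + c(-0.01, 0, 0.01)),
    effect_mean = pred,
    effect_se = stats::sd(c(-0.01, 0, 0.01)) / sqrt(3)
  )
  pts <- classify_points(tab, ray, crcs, reference = "CA")
  expect_true(all(pts$label_ca == "additive"))
})

test_that("a dose-modified truth is detected as synergy or antagonism", {
  ray <- equray_rays(374.87, 19988.75)[3, ]
  fit_components <- function(sc) {
    list(
      fit_crc(build_effect_table(simulate_single(sc, "A", seed = 61)), "Logit"),
      fit_crc(build_effect_table(simulate_single(sc, "B", seed = 62)), "Logit")
    )
  }
  sc3 <- scenario_as_pb(sigma = 0.02, interaction = "dose_modifier",
                        base_model = "CA", kappa = 3)
  crcs <- fit_components(sc3)
  pts <- classify_points(build_effect_table(simulate_ray(sc3, ray, seed = 63)),
                         ray, crcs, reference = "CA")
  mid <- pts$effect_mean >= 0.2 & pts$effect_mean <= 0.8
  expect_gt(mean(pts$label_ca[mid] == "synergistic"), 0.5)

  sc13 <- scenario_as_pb(sigma = 0.02, interaction = "dose_modifier",
                         base_model = "CA", kappa = 1 / 3)
  pts2 <- classify_points(build_effect_table(simulate_ray(sc13, ray, seed = 64)),
                          ray, crcs, reference = "CA")
  mid2 <- pts2$effect_mean >= 0.2 & pts2$effect_mean <= 0.8
  expect_gt(mean(pts2$label_ca[mid2] == "antagonistic"), 0.5)
})

test_that("flipped orientation swaps the synergy and antagonism labels", {
  sc3 <- scenario_as_pb(sigma = 0.02, interaction = "dose_modifier",
                        base_model = "CA", kappa = 3)
  ray <- equray_rays(374.87, 19988.75)[3, ]
  crcs <- list(sc3$truth_a, sc3$truth_b)
  tab <- build_effect_table(simulate_ray(sc3, ray, seed = 65))
  a <- classify_points(tab, ray, crcs, reference = "CA")
  b <- classify_points(tab, ray, crcs, reference = "CA",
                       orientation = "flipped")
  swap <- c(additive = "additive", synergistic = "antagonistic",
            antagonistic = "synergistic")
  expect_identical(unname(swap[a$label_ca]), b$label_ca)
})

test_that("ray labels follow the majority rule with a conservative tie-break", {
  pts <- tibble::tibble(
    conc_total_ugL = c(500, 5000, 50000),
    effect_mean = c(0.3, 0.5, 0.7),
    oci_lwr = 0, oci_upr = 1,
    pred_ca = 0.5, pred_ia = 0.5,
    label_ca = c("additive", "synergistic", "synergistic"),
    label_ia = c("additive", "additive", "additive")
  )
  s <- summarize_ray(pts)
  expect_equal(unname(s$label["ca"]), "synergistic")
  expect_equal(unname(s$label["ia"]), "additive")
  expect_equal(nrow(s$regions), 6)
  expect_setequal(unique(s$regions$region), c("low", "medium", "high"))
  expect_equal(s$regions$n_points, rep(1L, 6))

  # region counts follow the band edges, not one-per-region
  pts2 <- dplyr::bind_rows(pts, dplyr::mutate(pts, conc_total_ugL = c(700, 800, 3e5)))
  counts <- summarize_ray(pts2)$regions
  expect_equal(counts$n_points[counts$reference == "ca"], c(3L, 1L, 2L))

  tie <- dplyr::mutate(pts,
                       label_ca = c("additive", "additive", "synergistic"),
                       effect_mean = c(0.1, 0.5, 0.7))  # window drops point 1
  expect_equal(unname(summarize_ray(tie)$label["ca"]), "additive")

  outside <- dplyr::mutate(pts, effect_mean = c(0.05, 0.1, 0.95))
  expect_warning(s2 <- summarize_ray(outside), "mid-effect window")
  expect_equal(unname(s2$label["ca"]), "synergistic")
  expect_error(summarize_ray(pts, band_edges_ugL = c(5, 2)), "increasing")
})
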