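test_that("fit statistics match an independent brute-force evaluation", {
  y <- c(0, 0.5, 1); yhat <- c(0.1, 0.5, 0.9)
  got <- goodness_of_fit(y, yhat, n_params = 2)
  want <- gof_oracle(y, yhat, 2)
  expect_equal(got$r2_adj, want$r2_adj, tolerance = 1e-12)
  expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
  # random vectors
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    y <- stats::runif(n); yh <- y + stats::rnorm(n, 0, 0.1)
    got <- goodness_of_fit(y, yh, 2)
    want <- gof_oracle(y, yh, 2)
    expect_equal(got$r2_adj, want$r2_adj, tolerance = 1e-12)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
  }
})

test_that("perfect and degenerate fits are handled", {
  y <- c(0.1, 0.4, 0.9)
  g <- goodness_of_fit(y, y, 2)
  expect_equal(g$r2_adj, 1)
  expect_equal(g$rmse, 0)
  expect_error(goodness_of_fit(rep(0.3, 5), rep(0.3, 5), 2), "zero variance")
  expect_error(goodness_of_fit(1:3, 1:4, 2), "equal length")
})

test_that("noiseless curves are recovered to 1e-6 by both models", {
  for (model in c("Logit", "Weibull")) {
    truth <- crc(model, -6.0, 2.5)
    tab <- noiseless_table(truth, c_high = 10^4.2, c_low = 10^0.6)
    fit <- fit_crc(tab, model)
    expect_equal(fit$alpha, -6.0, tolerance = 1e-6)
    expect_equal(fit$beta, 2.5, tolerance = 1e-6)
    expect_gt(fit$r2_adj, 1 - 1e-10)
  }
})

test_that("degenerate or under-sized effect data are rejected", {
  truth <- crc("Logit", -6, 2.5)
  tab <- noiseless_table(truth, 1e4, 10)
  tab$effect_mean <- 0
  expect_error(fit_crc(tab, "Logit"), "degenerate")
  small <- noiseless_table(truth, 1e4, 10, n_points = 6)
  expect_error(fit_crc(small, "Logit"), "too few distinct concentrations")
})

test_that("Wald intervals cover the generating parameters", {
  # iid effect-scale noise so the fitted model matches the generating one;
  # the shared control-mean error of full plate simulation is a documented
  # source of extra (correlated) uncertainty outside the Wald model
  truth <- crc_from_ec50(374.87, 3.2)
  conc <- concentration_series(10000, 10, 12)$conc_ugL
  hit_a <- hit_b <- 0
  n_sim <- 200
  set.seed(55)
  for (i in seq_len(n_sim)) {
    tab <- data.frame(conc_total_ugL = conc,
                      effect_mean = crc_effect(truth, conc) +
                        stats::rnorm(12, 0, 0.02))
    fit <- fit_crc(tab, "Logit")
    se <- sqrt(diag(fit$vcov))
    z <- stats::qt(0.975, df = fit$n_obs - 2)
    if (abs(fit$alpha - truth$alpha) <= z * se[1]) hit_a <- hit_a + 1
    if (abs(fit$beta - truth$beta) <= z * se[2]) hit_b <- hit_b + 1
  }
  expect_gte(hit_a / n_sim, 0.9)
  expect_gte(hit_b / n_sim, 0.9)
})

test_that("parameter error shrinks as noise vanishes", {
  sc_hi <- scenario_as_pb(sigma = 0.04)
  sc_lo <- scenario_as_pb(sigma = 0.005)
  err <- function(sc) {
    e <- vapply(1:40, function(i) {
      fit <- fit_crc(build_effect_table(simulate_single(sc, "A", seed = 300 + i)),
                     "Logit")
      abs(fit$beta - sc$truth_a$beta)
    }, numeric(1))
    stats::median(e)
  }
  expect_lt(err(sc_lo), err(sc_hi))
})

test_that("model selection prefers larger adjusted R2 with declared tie-breaks", {
  sc <- scenario_as_pb(sigma = 0.02)
  tab <- build_effect_table(simulate_single(sc, "A", seed = 9))
  fl <- fit_crc(tab, "Logit"); fw <- fit_crc(tab, "Weibull")
  best <- select_best(list(fw, fl))
  expect_equal(best$r2_adj, max(fl$r2_adj, fw$r2_adj))
  expect_identical(select_best(list(fw)), fw)
  # exact tie on both criteria resolves to Logit by model order
  fw2 <- fw; fw2$r2_adj <- fl$r2_adj; fw2$rmse <- fl$rmse
  expect_equal(select_best(list(fw2, fl))$model, "Logit")
  expect_error(select_best(list()), "no successful fits")
})

test_that("function-based bands collapse with noiseless data and cover the truth", {
  truth <- crc("Logit", -6, 2.5)
  fit <- fit_crc(noiseless_table(truth, 10^4.2, 10^0.6), "Logit")
  b <- confidence_bands(fit)
  expect_true(all(b$fci_upr - b$fci_lwr < 1e-5))
  expect_true(all(b$fci_lwr <= b$fit & b$fit <= b$fci_upr))

  # pointwise coverage of the true curve at the design points under iid
  # effect noise (the regression model the bands assume)
  truth2 <- crc_from_ec50(374.87, 3.2)
  conc <- concentration_series(10000, 10, 12)$conc_ugL
  e_true <- crc_effect(truth2, conc)
  n_sim <- 150
  cover <- numeric(n_sim)
  set.seed(77)
  for (i in seq_len(n_sim)) {
    tab <- data.frame(conc_total_ugL = conc,
                      effect_mean = e_true + stats::rnorm(12, 0, 0.02))
    fit <- fit_crc(tab, "Logit")
    b <- confidence_bands(fit, conc_ugL = conc, level = 0.95)
    cover[i] <- mean(b$fci_lwr <= e_true & e_true <= b$fci_upr)
  }
  expect_gte(mean(cover), 0.9)
})

test_that("bands degrade gracefully when the covariance is unavailable", {
  truth <- crc("Logit", -6, 2.5)
  fit <- fit_crc(noiseless_table(truth, 10^4.2, 10^0.6), "Logit")
  fit$vcov <- matrix(NA_real_, 2, 2)
  expect_warning(b <- confidence_bands(fit), "covariance unavailable")
  expect_true(all(is.na(b$fci_lwr)))
  expect_equal(b$fit, crc_effect(truth, b$conc_ugL), tolerance = 1e-6)
})

test_that("threshold NOEC/LOEC reproduce the reconstructed single-As ladder", {
  truth <- crc_from_ec50(374.87, 3.2)  # design-rule-consistent truth
  tab <- noiseless_table(truth, 10000, 10)
  nl <- noec_loec(tab, method = "threshold")
  expect_equal(nl$noec_ugL, 10)
  expect_equal(nl$loec_ugL, 18.7381, tolerance = 1e-5)
})

test_that("NOEC/LOEC sentinels mark out-of-range outcomes", {
  truth <- crc_from_ec50(374.87, 3.2)
  tab <- noiseless_table(truth, 10000, 10)
  zero <- dplyr::mutate(tab, effect_mean = 0)
  nl0 <- noec_loec(zero, method = "threshold")
  expect_equal(nl0$noec_ugL, 10000)
  expect_equal(nl0$loec_ugL, Inf)
  all_hit <- dplyr::mutate(tab, effect_mean = 0.5)
  nl1 <- noec_loec(all_hit, method = "threshold")
  expect_equal(nl1$noec_ugL, -Inf)
  expect_equal(nl1$loec_ugL, 10)
})

test_that("Dunnett NOEC/LOEC separate affected from unaffected concentrations", {
  set.seed(21)
  conc <- concentration_series(10000, 10, 12)$conc_ugL
  e_true <- ifelse(conc > 300, 0.4, 0)
  rows <- purrr::map_dfr(seq_along(conc), function(i) {
    tibble::tibble(
      treatment_id = "t", ray_id = "single",
      conc_A_ugL = conc[i], conc_B_ugL = 0, replicate = 1:3,
      od680 = pmax(0.5 * (1 - e_true[i]) + stats::rnorm(3, 0, 0.01), 0),
      is_control = FALSE
    )
  })
  ctrl <- tibble::tibble(
    treatment_id = "control", ray_id = "control",
    conc_A_ugL = 0, conc_B_ugL = 0, replicate = 1:3,
    od680 = 0.5 + stats::rnorm(3, 0, 0.01), is_control = TRUE
  )
  tab <- build_effect_table(dplyr::bind_rows(rows, ctrl))
  nl <- noec_loec(tab, method = "dunnett")
  sorted <- sort(conc)
  expect_equal(nl$noec_ugL, max(sorted[sorted <= 300]))
  expect_equal(nl$loec_ugL, min(sorted[sorted > 300]))
  expect_error(noec_loec(dplyr::mutate(tab, n_reps = 1L), method = "dunnett"),
               "replicates")
})
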