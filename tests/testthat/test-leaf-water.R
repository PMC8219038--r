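test_that("relative water content matches its formula and limits", {
  expect_equal(rwc(100, 20, 100), 100)
  expect_equal(rwc(20, 20, 100), 0)
  expect_equal(rwc(80, 20, 100), 75)
  expect_error(rwc(80, 100, 100), "exceed")
  expect_warning(rwc(120, 20, 100), "outside")
})

test_that("rwc depends only on mass differences", {
  base <- rwc(80, 20, 100)
  # both rescaling and shifting all three masses cancel in the ratio of
  # differences; what must NOT happen is sensitivity to only one term
  expect_equal(rwc(160, 40, 200), base)
  expect_equal(rwc(90, 30, 110), base)
  expect_false(isTRUE(all.equal(rwc(80, 20, 110), base)))  # SW alone
  expect_false(isTRUE(all.equal(rwc(80, 30, 100), base)))  # DW alone
})

test_that("gmin is recovered from the drying-curve identity", {
  # slope 6.66e-7 g/s, area 4e-4 m2, w = 0.01155 -> about 8 mmol
  gmin_hand <- 1000 * (6.66e-7 / 18.01528) / (4e-4 * 0.01155)
  expect_equal(gmin_hand, 8.0, tolerance = 1e-2)

  dc <- generate_drying_series(0.008, noise_sd = 0)
  fit <- fit_gmin(dc)
  expect_lt(abs(fit$gmin - 8) / 8, 1e-9)
  expect_false(fit$no_loss)
  expect_equal(fit$n_points, nrow(dc))
})

test_that("a flat or gaining drying curve reports zero conductance", {
  dc0 <- generate_drying_series(0, noise_sd = 0)
  fit0 <- fit_gmin(dc0)
  expect_equal(fit0$gmin, 0)
  expect_true(fit0$no_loss)
  gain <- drying_curve(times = seq(0, 3600, 600),
                       masses = 0.15 + seq(0, 3600, 600) * 1e-8,
                       area_initial = 4e-4)
  expect_true(fit_gmin(gain)$no_loss)
})

test_that("realistic leaves fall in the 5-10 mmol plausibility band", {
  for (g in c(0.005, 0.0075, 0.01)) {
    dc <- generate_drying_series(g, noise_sd = 5e-4, seed = 31)
    fit <- fit_gmin(dc)
    expect_gt(fit$gmin, 4)
    expect_lt(fit$gmin, 11)
  }
})

test_that("the closure discard window and point minimum are enforced", {
  dc <- generate_drying_series(0.008, noise_sd = 0)
  full <- fit_gmin(dc)
  late <- fit_gmin(dc, discard_s = 3000)
  expect_equal(late$gmin, full$gmin, tolerance = 1e-9)  # linear anyway
  expect_lt(late$n_points, full$n_points)
  expect_error(fit_gmin(dc, discard_s = 11000), ">= 4")
})

test_that("leak coefficient estimation matches its construction", {
  grad <- c(-30, -15, 0, 15, 30)
  resp <- -0.08  # constant dark respiration flux, umol/s
  ds <- tibble::tibble(gradient = grad, flux = resp + 0.40 * grad)
  expect_equal(estimate_leak_coefficient(ds), 0.40, tolerance = 1e-12)
  ds0 <- tibble::tibble(gradient = grad, flux = rep(resp, 5))
  expect_equal(estimate_leak_coefficient(ds0), 0, tolerance = 1e-12)
  flat <- tibble::tibble(gradient = rep(5, 4), flux = rnorm(4))
  expect_error(estimate_leak_coefficient(flat), "degenerate")
})

test_that("the correction magnitude follows the dimensional identity", {
  # k mol/s * gradient umol/mol gives umol/s; per m2 of leaf that is
  # umol m-2 s-1 directly: 0.40 * 10 / 2e-4 = 20000
  recs <- tibble::tibble(A = 5, ca = 400, c_ambient = 410)
  out <- apply_leak_correction(recs, k = 0.40, leaf_area = 2e-4)
  expect_equal(recs$A - out$A, 0.40 * 10 / 2e-4)
})

test_that("leak correction round-trips generated leaky fluxes", {
  set.seed(12)
  k_true <- 0.40
  area <- 2e-4
  A_true <- runif(8, 2, 20)
  grad <- runif(8, -25, 25)
  leaky <- tibble::tibble(A = A_true + k_true * grad / area,
                          ca = 400, c_ambient = 400 + grad)
  # dark calibration series built with the same coefficient
  dark_grad <- c(-30, -15, 0, 15, 30)
  dark <- tibble::tibble(gradient = dark_grad,
                         flux = -0.05 + k_true * dark_grad)
  k_hat <- estimate_leak_coefficient(dark)
  corrected <- apply_leak_correction(leaky, k = k_hat, leaf_area = area)
  expect_lt(max(abs(corrected$A - A_true)), 1e-9)
  expect_true(all(corrected$leak_corrected))
})

test_that("degenerate corrections leave records unchanged", {
  recs <- tibble::tibble(A = c(5, 8), ca = c(400, 400),
                         c_ambient = c(410, 400))
  zero_k <- apply_leak_correction(recs, k = 0, leaf_area = 2e-4)
  expect_equal(zero_k$A, recs$A)
  no_grad <- apply_leak_correction(recs[2, ], k = 0.4, leaf_area = 2e-4)
  expect_equal(no_grad$A, recs$A[2])
  # missing ambient column: warning, flagged, unchanged
  expect_warning(
    out <- apply_leak_correction(recs[, c("A", "ca")], 0.4, 2e-4),
    "skipped")
  expect_equal(out$A, recs$A)
  expect_false(any(out$leak_corrected))
})
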