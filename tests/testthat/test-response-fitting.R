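test_that("the NRH forward model matches hand evaluation", {
  expect_equal(nrh_light(1000, Asat = 15, phi = 0.05, theta = 0.7,
                         Rd = 1), 12.5017, tolerance = 1e-4)
  expect_equal(nrh_light(0, 15, 0.05, 0.7, 1), -1)
})

test_that("noise-free NRH light curves round-trip all four parameters", {
  tr <- synthetic_truth(noise_cv = 0, seed = 1)
  for (pars in list(list(Asat = 15, phi = 0.05, theta = 0.7),
                    list(Asat = 22, phi = 0.08, theta = 0.45),
                    list(Asat = 9, phi = 0.03, theta = 0.9))) {
    lc <- generate_light_curve(tr, mode = "nrh", nrh_params = pars)
    fit <- fit_light_response(lc)
    expect_lt(abs(fit$Asat - pars$Asat) / pars$Asat, 1e-6)
    expect_lt(abs(fit$phi - pars$phi) / pars$phi, 1e-6)
    expect_lt(abs(fit$theta - pars$theta) / pars$theta, 1e-6)
    expect_lt(abs(fit$Rd - tr$fvcb$Rd) / tr$fvcb$Rd, 1e-6)
  }
})

test_that("LCP and I75 satisfy their defining equations", {
  tr <- synthetic_truth(noise_cv = 0, seed = 1)
  lc <- generate_light_curve(tr, mode = "nrh")
  fit <- fit_light_response(lc)
  expect_lt(abs(nrh_light(fit$LCP, fit$Asat, fit$phi, fit$theta,
                          fit$Rd)), 1e-6)
  gross_at_i75 <- nrh_light(fit$I75_gross, fit$Asat, fit$phi, fit$theta,
                            Rd = 0)
  expect_lt(abs(gross_at_i75 - 0.75 * fit$Asat), 1e-6)
  # Rd = 0 puts the compensation point at darkness
  lc0 <- generate_light_curve(tr, mode = "nrh",
                              nrh_params = list(Asat = 15, phi = 0.05,
                                                theta = 0.7, Rd = 0))
  expect_equal(fit_light_response(lc0)$LCP, 0)
})

test_that("the NRH fit is invariant to point order and to I-rescaling", {
  tr <- synthetic_truth(noise_cv = 0.01, seed = 21)
  lc <- generate_light_curve(tr, mode = "nrh")
  base <- fit_light_response(lc)
  shuf <- lc[sample(nrow(lc)), ]
  fit2 <- fit_light_response(shuf)
  expect_equal(fit2$Asat, base$Asat, tolerance = 1e-6)
  expect_equal(fit2$phi, base$phi, tolerance = 1e-6)
  # rescaling irradiance by c rescales phi by 1/c, leaves the rest
  scaled <- dplyr::mutate(tibble::as_tibble(lc), PAR = PAR * 2)
  fit3 <- fit_light_response(scaled)
  expect_equal(fit3$phi, base$phi / 2, tolerance = 1e-5)
  expect_equal(fit3$Asat, base$Asat, tolerance = 1e-5)
  expect_equal(fit3$theta, base$theta, tolerance = 1e-4)
})

test_that("orthogonal-distance mode reproduces the OLS optimum on clean data", {
  tr <- synthetic_truth(noise_cv = 0, seed = 1)
  lc <- generate_light_curve(tr, mode = "nrh")
  ols <- fit_light_response(lc)
  orth <- fit_light_response(lc, method = "orthogonal")
  expect_equal(orth$Asat, ols$Asat, tolerance = 1e-3)
  expect_equal(orth$phi, ols$phi, tolerance = 1e-3)
})

test_that("noise-free A-cc curves recover Vcmax and Jmax", {
  tr <- synthetic_truth(noise_cv = 0, seed = 1)
  ac <- generate_aci_curve(tr)
  fit <- fit_aci(ac, gm = tr$gm_true, Rd = tr$fvcb$Rd,
                 GammaStar = tr$fvcb$GammaStar, Km = tr$fvcb$Km)
  expect_lt(abs(fit$Vcmax - 60) / 60, 1e-4)
  expect_lt(abs(fit$Jmax - 120) / 120, 1e-4)
  # fitted model reproduces the data within the reported residuals
  expect_lt(fit$rss, 1e-10)
  # the limitation switch sits inside the measured cc range
  expect_gt(fit$inflection, min(fit$data$cc))
  expect_lt(fit$inflection, max(fit$data$cc))
})

test_that("fit_aci with gm = Inf equals a fit on ci directly", {
  tr <- synthetic_truth(noise_cv = 0.01, seed = 9)
  ac <- tibble::as_tibble(generate_aci_curve(tr))[
    , c("ci", "A", "PAR")]
  f_inf <- fit_aci(ac, gm = Inf, Rd = tr$fvcb$Rd,
                   GammaStar = tr$fvcb$GammaStar, Km = tr$fvcb$Km)
  ac_ci <- dplyr::rename(ac, cc = ci)
  f_ci <- fit_aci(ac_ci, gm = 1, Rd = tr$fvcb$Rd,
                  GammaStar = tr$fvcb$GammaStar, Km = tr$fvcb$Km)
  expect_equal(f_inf$Vcmax, f_ci$Vcmax, tolerance = 1e-6)
  expect_equal(f_inf$Jmax, f_ci$Jmax, tolerance = 1e-6)
})

test_that("a misspecified (too high) gm biases Vcmax low", {
  tr <- synthetic_truth(noise_cv = 0, seed = 1)
  ac <- generate_aci_curve(tr)
  good <- fit_aci(ac, gm = tr$gm_true, Rd = tr$fvcb$Rd,
                  GammaStar = tr$fvcb$GammaStar, Km = tr$fvcb$Km)
  bad <- fit_aci(ac, gm = 2 * tr$gm_true, Rd = tr$fvcb$Rd,
                 GammaStar = tr$fvcb$GammaStar, Km = tr$fvcb$Km)
  expect_lt(bad$Vcmax, good$Vcmax)
})

test_that("single-branch curves report the unidentified parameter as a bound", {
  # only low-cc, Rubisco-limited points: Jmax unidentifiable
  p <- fvcb_params(Vcmax = 60, Jmax = 500, GammaStar = 40, Km = 620,
                   Rd = 1)
  cc <- seq(50, 200, length.out = 8)
  A <- 60 * (cc - 40) / (cc + 620) - 1
  fit <- fit_aci(tibble::tibble(cc = cc, A = A), gm = 0.2, Rd = 1,
                 GammaStar = 40, Km = 620)
  expect_lt(abs(fit$Vcmax - 60) / 60, 1e-3)
  expect_true(is.na(fit$Jmax))
  expect_true(is.finite(fit$jmax_bound))
})

test_that("a constructed exponential decay trace is recovered exactly", {
  t <- seq(0, 0.008, by = 0.000125)
  trace <- tibble::tibble(time = t, F = 1.5 * exp(-250 * t) + 0.5)
  fit <- fit_exponential_decay(trace)
  expect_lt(abs(fit$k_relative - 250) / 250, 1e-6)
  expect_lt(abs(fit$amplitude - 1.5), 1e-6)
  expect_lt(abs(fit$plateau - 0.5), 1e-6)
  expect_false(fit$no_decay)
})

test_that("samples beyond the window are ignored", {
  t <- seq(0, 0.05, by = 0.000125)
  # decays at 250 inside the window, then drifts; only [0, 8 ms] is fit
  F <- 1.5 * exp(-250 * t) + 0.5
  F[t > 0.008] <- F[t > 0.008] + 0.2
  fit <- fit_exponential_decay(tibble::tibble(time = t, F = F))
  expect_equal(fit$n, sum(t <= 0.008 + 1e-12))
  expect_lt(abs(fit$k_relative - 250) / 250, 1e-6)
})

test_that("a constant or rising trace reports no decay", {
  t <- seq(0, 0.008, by = 0.000125)
  flat <- fit_exponential_decay(tibble::tibble(time = t,
                                               F = rep(1, length(t))))
  expect_true(flat$no_decay)
  expect_equal(flat$k_relative, 0)
  rising <- fit_exponential_decay(tibble::tibble(time = t,
                                                 F = 1 + 10 * t))
  expect_true(rising$no_decay)
  expect_error(fit_exponential_decay(
    tibble::tibble(time = c(0, 0.001, 0.001, 0.002, 0.003),
                   F = c(2, 1.8, 1.7, 1.6, 1.5))), "increasing")
})

test_that("replicated noisy traces recover the rate constant on average", {
  traces <- generate_decay_traces(250, noise_frac = 0.01, seed = 4)
  ks <- traces |>
    dplyr::group_by(replicate, technical) |>
    dplyr::group_map(function(d, key) {
      fit_exponential_decay(d)$k_relative
    }) |>
    unlist()
  expect_length(ks, 18)
  expect_lt(abs(mean(ks) - 250) / 250, 0.05)
})
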