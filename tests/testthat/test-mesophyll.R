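test_that("non-photorespiratory J is 4(A + Rd)", {
  expect_equal(j_nonphotorespiratory(10, 1), 44)
  expect_equal(j_nonphotorespiratory(-1, 1), 0)
  expect_equal(j_nonphotorespiratory(0, 0), 0)
})

test_that("fluorescence J uses the absorptance and partitioning constants", {
  expect_equal(j_from_fluorescence(0, 1000), 0)
  expect_equal(j_from_fluorescence(0.25, 1000, 0.84, 0.5), 105)
  expect_equal(j_from_fluorescence(0.25, 1000, absorptance = 1,
                                   beta = 1), 250)
  expect_error(j_from_fluorescence(1.2, 1000), "0, 1")
  expect_error(j_from_fluorescence(-0.1, 1000), "0, 1")
})

test_that("gm and dCc/dA match hand-evaluated values", {
  est <- gm_variable_j(tibble::tibble(A = 20, ci = 300, J = 150),
                       ci_star = 40, Rd = 1)
  expect_equal(est$gm, 20 / (300 - 40 * (150 + 8 * 21) / (150 - 4 * 21)),
               tolerance = 1e-12)
  expect_equal(est$gm, 0.18644, tolerance = 1e-4)
  expect_equal(est$dCc_dA, 12 * 40 * 150 / (150 - 84)^2,
               tolerance = 1e-12)
  expect_equal(est$dCc_dA, 16.529, tolerance = 1e-4)
  expect_true(est$qc_pass)
  expect_equal(est$reason, "ok")

  hi <- gm_variable_j(tibble::tibble(A = 20, ci = 300, J = 90),
                      ci_star = 40, Rd = 1)
  expect_equal(hi$dCc_dA, 1200, tolerance = 1e-9)
  expect_false(hi$qc_pass)
  expect_equal(hi$reason, "above_50")

  lo <- gm_variable_j(tibble::tibble(A = 5, ci = 300, J = 200),
                      ci_star = 40, Rd = 1)
  expect_equal(lo$dCc_dA, 96000 / 176^2, tolerance = 1e-9)
  expect_equal(lo$dCc_dA, 3.099, tolerance = 1e-3)
  expect_false(lo$qc_pass)
  expect_equal(lo$reason, "below_10")
})

test_that("the singular point J = 4(A + Rd) is reported, not computed", {
  est <- gm_variable_j(tibble::tibble(A = 20, ci = 300, J = 84),
                       ci_star = 40, Rd = 1)
  expect_equal(est$reason, "singular")
  expect_false(est$qc_pass)
  expect_true(is.na(est$gm))
})

test_that("records at exactly 10 or 50 are excluded (strict bounds)", {
  # constructed so the computed statistic is exactly representable:
  # dCc/dA = 12*40*J / (J - 4(A+Rd))^2 with (J, A) chosen to give 10, 50
  at10 <- gm_variable_j(tibble::tibble(A = -1, ci = 300, J = 48),
                        ci_star = 40, Rd = 1)
  expect_equal(at10$dCc_dA, 10)
  expect_false(at10$qc_pass)
  at50 <- gm_variable_j(tibble::tibble(A = 215, ci = 1500, J = 960),
                        ci_star = 40, Rd = 1)
  expect_equal(at50$dCc_dA, 50)
  expect_false(at50$qc_pass)
  expect_equal(at50$reason, "above_50")
})

test_that("variable J recovers gm exactly for RuBP-limited records", {
  for (gm in c(0.05, 0.12, 0.25, 0.5)) {
    tr <- rubp_truth(gm)
    op <- solve_steady_state(400, tr$gs_w, gm, tr$fvcb, PAR = 800)
    expect_equal(op$limitation, "rubp")
    J <- electron_transport(800, tr$fvcb$Jmax, tr$fvcb$theta_J,
                            tr$fvcb$phi_J)
    est <- gm_variable_j(tibble::tibble(A = op$A, ci = op$ci, J = J),
                         ci_star = tr$fvcb$GammaStar, Rd = tr$fvcb$Rd)
    expect_lt(abs(est$gm - gm) / gm, 1e-6)
    # mutual consistency: the RuBP branch at the recovered cc gives A back
    A_back <- rubp_branch_A(est$cc, J, tr$fvcb$GammaStar, tr$fvcb$Rd)
    expect_lt(abs(A_back - op$A) / abs(op$A), 1e-6)
  }
})

test_that("the exclusion filter is idempotent and order-independent", {
  set.seed(3)
  batch <- tibble::tibble(
    A = runif(30, -2, 25), ci = runif(30, 100, 400),
    J = runif(30, 40, 220))
  est1 <- gm_variable_j(batch, ci_star = 40, Rd = 1)
  # idempotent: re-running on the augmented frame changes nothing
  est2 <- gm_variable_j(est1[names(batch)], ci_star = 40, Rd = 1)
  expect_equal(est1$qc_pass, est2$qc_pass)
  expect_equal(est1$reason, est2$reason)
  # order-independent: a permutation permutes the flags identically
  perm <- sample(nrow(batch))
  est3 <- gm_variable_j(batch[perm, ], ci_star = 40, Rd = 1)
  expect_equal(est3$qc_pass, est1$qc_pass[perm])
  expect_equal(est3$gm, est1$gm[perm])
})

test_that("cc_from_gm implements the drawdown with its limits", {
  expect_equal(cc_from_gm(300, 0, 0.2), 300)
  expect_equal(cc_from_gm(326.2, 13.84, 0.20), 326.2 - 13.84 / 0.2)
  expect_equal(cc_from_gm(300, 10, Inf), 300)
  expect_error(cc_from_gm(300, 10, -0.1), "positive")
  expect_error(cc_from_gm(300, 10, 0), "positive")
})
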