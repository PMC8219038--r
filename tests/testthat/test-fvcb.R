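test_that("km_chloroplastic matches its closed form and guards inputs", {
  expect_equal(km_chloroplastic(272.38, 165.82, 0), 272.38)
  expect_equal(km_chloroplastic(272.38, 165.82, 210),
               272.38 * (1 + 210 / 165.82), tolerance = 1e-12)
  expect_equal(round(km_chloroplastic(272.38, 165.82, 210), 2), 617.33)
  expect_error(km_chloroplastic(0, 165.82, 210), "positive")
  expect_error(km_chloroplastic(272.38, -1, 210), "positive")
  expect_equal(km_default, 620.3322)
})

test_that("assimilation demand takes the correct limiting branch", {
  p <- fvcb_params(Vcmax = 60, Jmax = 120, GammaStar = 40, Km = 620,
                   Rd = 1)
  # at the compensation point both branches vanish: A = -Rd
  expect_equal(assimilation_demand(40, p, J = 77)$A, -1)
  expect_equal(assimilation_demand(40, p, J = 0)$A, -1)
  # Rubisco branch: 60*260/920 - 1
  d <- assimilation_demand(300, p, J = 1e9)
  expect_equal(d$A, 60 * 260 / 920 - 1, tolerance = 1e-12)
  expect_equal(d$limitation, "rubisco")
  # RuBP branch: 120*260/1520 - 1
  p2 <- fvcb_params(Vcmax = 1e9, Jmax = 120, GammaStar = 40, Km = 620,
                    Rd = 1)
  d2 <- assimilation_demand(300, p2, J = 120)
  expect_equal(d2$A, 120 * 260 / 1520 - 1, tolerance = 1e-12)
  expect_equal(d2$limitation, "rubp")
})

test_that("demand is continuous across the Ac = Aj crossover", {
  p <- fvcb_params(Vcmax = 60, Jmax = 120, GammaStar = 40, Km = 620,
                   Rd = 1)
  J <- 110
  # crossover cc where Vcmax/(cc+Km) = J/(4cc+8GammaStar)
  cross <- (J * 620 - 8 * 40 * 60) / (4 * 60 - J)
  eps <- 1e-7
  lo <- assimilation_demand(cross - eps, p, J)$A
  hi <- assimilation_demand(cross + eps, p, J)$A
  expect_lt(abs(hi - lo), 1e-6)
  expect_lt(abs(assimilation_demand(cross, p, J)$A - lo), 1e-6)
})

test_that("electron transport satisfies its quadratic and its limits", {
  expect_equal(electron_transport(0, 150), 0)
  expect_lt(abs(electron_transport(1e9, 150, 0.7, 0.3) - 150), 1e-3)
  # quadratic-formula oracle
  Jmax <- 150; phi <- 0.3; theta <- 0.7; I <- 1000
  b <- phi * I + Jmax
  J_oracle <- (b - sqrt(b^2 - 4 * theta * phi * I * Jmax)) / (2 * theta)
  expect_equal(electron_transport(I, Jmax, theta, phi), J_oracle,
               tolerance = 1e-12)
  I <- c(10, 100, 1000)
  J <- electron_transport(I, Jmax, theta, phi)
  expect_true(all(J <= Jmax))
  # each J is a root of the defining quadratic
  resid <- theta * J^2 - (phi * I + Jmax) * J + phi * I * Jmax
  expect_true(all(abs(resid) < 1e-8))
  expect_error(electron_transport(100, 150, theta_J = 1.5), "theta_J")
})

test_that("steady-state solver satisfies supply-demand and diffusion identities", {
  p <- fvcb_params(Vcmax = 60, Jmax = 300, GammaStar = 40, Km = 620,
                   Rd = 1)
  op <- solve_steady_state(400, gs_w = 0.30, gm = 0.20, params = p,
                           J = 1e6)
  expect_equal(op$A, 13.84, tolerance = 1e-2)
  expect_equal(op$ci, 326, tolerance = 1e-2)
  expect_equal(op$cc, 257, tolerance = 1e-2)
  expect_lt(abs(op$residual), 1e-9)
  expect_lt(abs((op$ci - op$cc) - op$A / 0.20), 1e-9)
  # no diffusive drawdown: cc -> ca
  op2 <- solve_steady_state(400, gs_w = 1e9, gm = 1e9, params = p,
                            J = 1e6)
  expect_equal(op2$cc, 400, tolerance = 1e-4)
  expect_equal(op2$A, assimilation_demand(400, p, 1e6)$A,
               tolerance = 1e-4)
  expect_error(solve_steady_state(30, 0.3, 0.2, p), "GammaStar")
})

test_that("solver agrees with an independent bisection oracle", {
  set.seed(42)
  for (i in 1:50) {
    p <- fvcb_params(Vcmax = runif(1, 30, 120),
                     Jmax = runif(1, 60, 250),
                     GammaStar = runif(1, 30, 50),
                     Km = runif(1, 400, 800),
                     Rd = runif(1, 0.5, 2))
    ca <- runif(1, 100, 1500)
    gs <- runif(1, 0.05, 0.5)
    gm <- runif(1, 0.05, 0.5)
    J <- electron_transport(runif(1, 50, 2000), p$Jmax, p$theta_J,
                            p$phi_J)
    A_pkg <- solve_steady_state(ca, gs, gm, p, J = J)$A
    A_oracle <- bisect_steady_state(ca, gs, gm, p, J)
    expect_lt(abs(A_pkg - A_oracle), 1e-6)
  }
})

test_that("assimilation is monotone in both conductances", {
  p <- fvcb_params(Vcmax = 60, Jmax = 150, GammaStar = 40, Km = 620,
                   Rd = 1)
  gms <- seq(0.05, 0.5, length.out = 8)
  A_gm <- vapply(gms, function(g) {
    solve_steady_state(400, 0.3, g, p, PAR = 1000)$A
  }, numeric(1))
  expect_true(all(diff(A_gm) > 0))
  gss <- seq(0.05, 0.6, length.out = 8)
  A_gs <- vapply(gss, function(g) {
    solve_steady_state(400, g, 0.2, p, PAR = 1000)$A
  }, numeric(1))
  expect_true(all(diff(A_gs) > 0))
})

test_that("parameter validation rejects out-of-range constants", {
  expect_error(fvcb_params(Vcmax = -1), "non-negative")
  expect_error(fvcb_params(theta_J = 0), "theta_J")
  expect_error(fvcb_params(phi_J = 1), "phi_J")
  # Km consistency with a Kc/Ko/O triple
  p <- fvcb_params(Kc = 272.38, Ko = 165.82, O = 210)
  expect_equal(p$Km, km_chloroplastic(272.38, 165.82, 210))
})
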