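# Independent oracles used across tests. These deliberately avoid the
# package's own solvers.

# plain bisection on the supply-demand residual; independent of
# solve_steady_state's uniroot path
bisect_steady_state <- function(ca, gs_w, gm, params, J,
                                tol = 1e-6) {
  g_tot <- 1 / (1.6 / gs_w + 1 / gm)
  resid <- function(cc) {
    Ac <- params$Vcmax * (cc - params$GammaStar) / (cc + params$Km)
    Aj <- J * (cc - params$GammaStar) / (4 * cc + 8 * params$GammaStar)
    min(Ac, Aj) - params$Rd - (ca - cc) * g_tot
  }
  lo <- params$GammaStar
  hi <- ca + params$Rd / g_tot + 1
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * 1e-3) break
  }
  cc <- (lo + hi) / 2
  (ca - cc) * g_tot
}

# truth whose demand side is always RuBP-limited (Vcmax effectively
# non-limiting), with ci* aligned to GammaStar so the variable-J
# inversion is exact
rubp_truth <- function(gm, gs_w = 0.3, Rd = 1, GammaStar = 40,
                       Jmax = 150) {
  p <- fvcb_params(Vcmax = 5000, Jmax = Jmax, GammaStar = GammaStar,
                   Rd = Rd, Km = 620.3322)
  tr <- synthetic_truth(fvcb = p, gs_w = gs_w, gm_true = gm,
                        ci_star = GammaStar, noise_cv = 0, seed = 1L)
  # the round-trip convention: the estimator's ci* IS the simulation's
  # GammaStar, so pin both to the same value
  tr$fvcb$GammaStar <- GammaStar
  tr$ci_star <- GammaStar
  tr
}

# a leaf's assimilation with A recomputed from the RuBP branch at cc
rubp_branch_A <- function(cc, J, GammaStar, Rd) {
  J * (cc - GammaStar) / (4 * cc + 8 * GammaStar) - Rd
}
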