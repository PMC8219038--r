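#' Default cuvette CO2 step sequence for A-ci curves
#'
#' First measurement at 400 umol mol-1, an ascending limb to 2000, then a
#' descending limb back down to 50 umol mol-1 (17 steps in total), the
#' sequence a gas-analyser programme steps through for a full A-ci curve.
#' @export
aci_default_steps <- c(400, 450, 550, 650, 750, 850, 1000, 1500, 2000,
                       400, 350, 300, 250, 200, 150, 100, 50)

#' Default irradiance steps for light-response curves
#'
#' Descending from saturating light so the leaf stays induced
#' (umol m-2 s-1).
#' @export
light_default_steps <- c(2000, 1500, 1000, 500, 200, 100, 50, 20, 0)

#' Default design for the Laisk measurement family
#'
#' Sub-saturating irradiances and the low cuvette CO2 steps of each
#' sub-curve, chosen so every sub-curve stays on the near-linear low-CO2
#' limb where the Laisk common-intersection construction holds.
#' @export
laisk_default_par <- c(300, 150, 100, 50)

#' @rdname laisk_default_par
#' @export
laisk_default_co2 <- c(150, 125, 100, 75, 50)

# molar mass of water, g mol-1
M_WATER <- 18.01528

# leaf absorptance and PSII partitioning used to map J <-> phi_PSII
ABSORPTANCE_DEFAULT <- 0.84
BETA_PSII_DEFAULT <- 0.5

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ground-truth parameter set for synthetic gas-exchange data
#'
#' Bundles the generative parameters every synthetic dataset is tagged
#' with, so estimators can be scored against known truth. The apparent
#' photorespiratory compensation point and the chloroplastic one are kept
#' consistent through `GammaStar = ci_star + Rd / gm_true`; supplying
#' `ci_star` overrides the `GammaStar` of `fvcb` accordingly.
#'
#' Defaults emulate a well-watered Arabidopsis leaf at 25 degrees C:
#' `gs_w` in the 0.1-0.4 mol m-2 s-1 range typical of actively transpiring
#' rosette leaves, `gm_true` = 0.2 mol m-2 s-1, and the ci*/Rd pair set to
#' the global averages a Laisk analysis of such leaves yields
#' (ci* = 38.95 umol mol-1, Rd = 0.914 umol m-2 s-1).
#'
#' @param fvcb An [fvcb_params()] object (its `Rd` is the truth `Rd`).
#' @param gs_w Stomatal conductance to water vapour (mol m-2 s-1).
#' @param gm_true Mesophyll conductance to CO2 (mol m-2 s-1), > 0.
#' @param ci_star Apparent photorespiratory compensation point
#'   (umol mol-1); `GammaStar` is re-derived from it.
#' @param noise_cv Relative (multiplicative Gaussian) noise on fluxes.
#' @param seed Integer seed fixing all randomness of generators that use
#'   this truth.
#' @return An object of class `synthetic_truth`.
#' @examples
#' synthetic_truth(gm_true = 0.25, seed = 7)
#' @export
synthetic_truth <- function(fvcb = fvcb_params(), gs_w = 0.3,
                            gm_true = 0.2, ci_star = 38.95,
                            noise_cv = 0.02, seed = 1L) {
  stopifnot(inherits(fvcb, "fvcb_params"), gm_true > 0, gs_w > 0,
            noise_cv >= 0)
  fvcb$GammaStar <- ci_star + fvcb$Rd / gm_true
  structure(
    list(fvcb = fvcb, gs_w = gs_w, gm_true = gm_true, ci_star = ci_star,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat(sprintf("  gm = %g, gs_w = %g mol m-2 s-1; ci* = %g umol mol-1\n",
              x$gm_true, x$gs_w, x$ci_star))
  cat(sprintf("  Rd = %g; noise_cv = %g; seed = %d\n",
              x$fvcb$Rd, x$noise_cv, x$seed))
  invisible(x)
}

# common scaffolding for one simulated cuvette record
new_response_curve <- function(records, curve_type, truth,
                               curve_id = "synthetic") {
  out <- tibble::as_tibble(records)
  out$curve_id <- curve_id
  out <- dplyr::relocate(out, "curve_id")
  attr(out, "curve_type") <- curve_type
  attr(out, "truth") <- truth
  class(out) <- c("response_curve", class(out))
  out
}

# multiplicative Gaussian noise, cv relative
flux_noise <- function(x, cv) {
  if (cv == 0) return(x)
  x * (1 + stats::rnorm(length(x), 0, cv))
}

simulate_record <- function(truth, ca, PAR) {
  p <- truth$fvcb
  op <- solve_steady_state(ca, truth$gs_w, truth$gm_true, p, PAR = PAR)
  J <- electron_transport(PAR, p$Jmax, p$theta_J, p$phi_J)
  phi_PSII <- if (PAR > 0) {
    J / (BETA_PSII_DEFAULT * ABSORPTANCE_DEFAULT * PAR)
  } else {
    NA_real_
  }
  tibble::tibble(
    ca = ca, PAR = PAR, A = op$A, gs_w = truth$gs_w, ci = op$ci,
    cc = op$cc, J = J, phi_PSII = phi_PSII,
    Tleaf = 25, VPD = 1.2, flow = 300, Patm = 101.325,
    limitation = op$limitation, solved = TRUE
  )
}

simulate_curve <- function(truth, ca_steps, par_steps, seed, curve_type,
                           curve_id) {
  grid <- tibble::tibble(ca = ca_steps, PAR = par_steps)
  recs <- purrr::pmap(grid, function(ca, PAR) {
    tryCatch(simulate_record(truth, ca, PAR),
             error = function(e) tibble::tibble(
               ca = ca, PAR = PAR, A = NA_real_, gs_w = truth$gs_w,
               ci = NA_real_, cc = NA_real_, J = NA_real_,
               phi_PSII = NA_real_, Tleaf = 25, VPD = 1.2, flow = 300,
               Patm = 101.325, limitation = NA_character_, solved = FALSE))
  })
  recs <- dplyr::bind_rows(recs)
  with_seed(seed, {
    ok <- recs$solved
    # noise is multiplicative Gaussian on the fluxes only, drawn in
    # record order; ci is recomputed from the noisy fluxes the way an
    # analyser derives it from its measured fluxes
    recs$A[ok] <- flux_noise(recs$A[ok], truth$noise_cv)
    recs$gs_w[ok] <- flux_noise(recs$gs_w[ok], truth$noise_cv)
    recs$ci[ok] <- recs$ca[ok] - 1.6 * recs$A[ok] / recs$gs_w[ok]
  })
  new_response_curve(recs, curve_type, truth, curve_id)
}

#' Simulate a full A-ci curve
#'
#' Steps a simulated leaf through a cuvette CO2 sequence at constant
#' saturating light, solving the coupled FvCB supply-demand system at each
#' step and adding multiplicative Gaussian noise (`truth$noise_cv`) to the
#' fluxes A and gs. Intercellular CO2 is recomputed from the noisy fluxes,
#' as an analyser would. Steps with no steady-state solution are retained
#' with `solved = FALSE`, never dropped.
#'
#' @param truth A [synthetic_truth()] object.
#' @param ca_steps Cuvette CO2 mole fractions (umol mol-1); defaults to
#'   [aci_default_steps].
#' @param PAR Constant irradiance during the curve (umol m-2 s-1).
#' @param seed Seed for the noise stream; defaults to `truth$seed`.
#' @param curve_id Label carried through to outputs.
#' @return A `response_curve` tibble (one row per step) with the truth
#'   attached as an attribute.
#' @examples
#' tr <- synthetic_truth(noise_cv = 0, seed = 1)
#' generate_aci_curve(tr)
#' @export
generate_aci_curve <- function(truth, ca_steps = aci_default_steps,
                               PAR = 1500, seed = truth$seed,
                               curve_id = "aci") {
  stopifnot(inherits(truth, "synthetic_truth"), all(ca_steps > 0))
  simulate_curve(truth, ca_steps, rep(PAR, length(ca_steps)), seed,
                 "aci", curve_id)
}

#' Simulate a light-response curve
#'
#' Irradiance descends from saturating light at constant cuvette CO2.
#' The simulated PSII operating efficiency is consistent with the
#' generating electron transport rate,
#' `phi_PSII = J / (beta * absorptance * PAR)` with the package defaults
#' beta = 0.5 and absorptance = 0.84, so [j_from_fluorescence()] inverts
#' it exactly.
#'
#' Two modes:
#' * `"fvcb"` (default): each record solves the coupled FvCB
#'   supply-demand system; the resulting light response is close to, but
#'   not exactly, a non-rectangular hyperbola.
#' * `"nrh"`: net assimilation follows [nrh_light()] exactly with the
#'   parameters in `nrh_params`, so [fit_light_response()] round-trips
#'   the generating (Asat, phi, theta, Rd) at zero noise.
#'
#' @inheritParams generate_aci_curve
#' @param par_steps Irradiance steps (umol m-2 s-1); defaults to
#'   [light_default_steps].
#' @param ca Constant cuvette CO2 (umol mol-1).
#' @param mode `"fvcb"` or `"nrh"` (see Details).
#' @param nrh_params Generating NRH parameters for `mode = "nrh"`:
#'   list with `Asat` (gross), `phi`, `theta`, `Rd`; `Rd` defaults to the
#'   truth's Rd.
#' @return A `response_curve` tibble.
#' @export
generate_light_curve <- function(truth, par_steps = light_default_steps,
                                 ca = 400, seed = truth$seed,
                                 curve_id = "light",
                                 mode = c("fvcb", "nrh"),
                                 nrh_params = list(Asat = 15, phi = 0.05,
                                                   theta = 0.7)) {
  stopifnot(inherits(truth, "synthetic_truth"), all(par_steps >= 0))
  mode <- match.arg(mode)
  if (mode == "fvcb") {
    return(simulate_curve(truth, rep(ca, length(par_steps)), par_steps,
                          seed, "light", curve_id))
  }
  q <- nrh_params
  q$Rd <- q$Rd %||% truth$fvcb$Rd
  A <- nrh_light(par_steps, q$Asat, q$phi, q$theta, q$Rd)
  recs <- tibble::tibble(
    ca = ca, PAR = par_steps, A = A, gs_w = truth$gs_w,
    ci = ca - 1.6 * A / truth$gs_w, cc = NA_real_, J = NA_real_,
    phi_PSII = NA_real_, Tleaf = 25, VPD = 1.2, flow = 300,
    Patm = 101.325, limitation = NA_character_, solved = TRUE
  )
  with_seed(seed, {
    recs$A <- flux_noise(recs$A, truth$noise_cv)
    recs$gs_w <- flux_noise(recs$gs_w, truth$noise_cv)
    recs$ci <- recs$ca - 1.6 * recs$A / recs$gs_w
  })
  out <- new_response_curve(recs, "light", truth, curve_id)
  attr(out, "nrh_truth") <- q
  out
}

#' Simulate a family of low-CO2 A-ci curves for the Laisk method
#'
#' Generates one sub-curve per sub-saturating irradiance over a common set
#' of low cuvette CO2 steps. Two modes:
#'
#' * `"fvcb"` (default): each record solves the full coupled FvCB model.
#'   Because both FvCB branches vanish at `cc = GammaStar`, every model
#'   curve passes through `(ci*, -Rd)` in A-ci space with
#'   `ci* = GammaStar - Rd/gm`; the sub-curves are near-linear below
#'   150 umol mol-1 but carry the model's slight curvature.
#' * `"idealized"`: exact straight lines through `(ci*, -Rd)` with
#'   per-irradiance slopes proportional to J. This isolates estimator
#'   correctness from model nonlinearity and round-trips exactly at zero
#'   noise.
#'
#' @inheritParams generate_aci_curve
#' @param par_levels Irradiances, one sub-curve each; >= 2 required.
#' @param co2_steps Cuvette CO2 steps per sub-curve; >= 2 required.
#' @param mode `"fvcb"` or `"idealized"` (see Details).
#' @return A list of `response_curve` tibbles, one per irradiance.
#' @examples
#' tr <- synthetic_truth(noise_cv = 0)
#' fam <- generate_laisk_family(tr, mode = "idealized")
#' fit_laisk(fam)
#' @export
generate_laisk_family <- function(truth, par_levels = laisk_default_par,
                                  co2_steps = laisk_default_co2,
                                  seed = truth$seed,
                                  mode = c("fvcb", "idealized")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mode <- match.arg(mode)
  if (length(par_levels) < 2 || length(co2_steps) < 2) {
    stop("the Laisk design needs >= 2 irradiance levels and >= 2 CO2 steps",
         call. = FALSE)
  }
  p <- truth$fvcb
  if (mode == "fvcb") {
    fam <- purrr::imap(par_levels, function(par, i) {
      simulate_curve(truth, co2_steps, rep(par, length(co2_steps)),
                     seed + i - 1, "laisk", paste0("laisk_PAR", par))
    })
  } else {
    J <- electron_transport(par_levels, p$Jmax, p$theta_J, p$phi_J)
    # slope ~ dAj/dcc of the RuBP branch in the low-CO2 window
    slope <- J * 12 * p$GammaStar / (4 * 100 + 8 * p$GammaStar)^2
    fam <- purrr::imap(par_levels, function(par, i) {
      ci <- co2_steps
      A <- slope[i] * (ci - truth$ci_star) - p$Rd
      recs <- tibble::tibble(
        ca = co2_steps, PAR = par, A = A, gs_w = truth$gs_w, ci = ci,
        cc = NA_real_, J = J[i], phi_PSII = NA_real_, Tleaf = 25,
        VPD = 1.2, flow = 300, Patm = 101.325,
        limitation = "rubp", solved = TRUE
      )
      with_seed(seed + i - 1, {
        recs$A <- flux_noise(recs$A, truth$noise_cv)
      })
      new_response_curve(recs, "laisk", truth, paste0("laisk_PAR", par))
    })
  }
  names(fam) <- paste0("PAR", par_levels)
  fam
}

#' Simulate a detached-leaf drying curve
#'
#' After stomatal closure a detached leaf loses water through the cuticle
#' and leaky stomata at a constant rate set by the minimum conductance:
#' `mass(t) = m0 - r t` with
#' `r = gmin_true * (VPD/Patm) * area * M_water` (g s-1), plus additive
#' Gaussian balance noise.
#'
#' @param gmin_true Minimum conductance to water vapour (mol m-2 s-1).
#' @param area Single-sided projected leaf area (m2); used for both the
#'   initial and final photograph.
#' @param env List with `T` (degrees C), `RH` (%), `Patm` (kPa); the VPD
#'   mole-fraction gradient is derived via the Arden Buck saturation
#'   vapour pressure.
#' @param schedule Weighing times (s), strictly increasing; the default
#'   emulates weighing every 25 min for 3.5 h after closure.
#' @param m0 Initial (post-closure) leaf mass (g).
#' @param noise_sd Balance noise standard deviation (g); the default is
#'   0.5 mg, a typical analytical-balance repeatability.
#' @param seed Seed for the noise stream.
#' @return A [drying_curve()] object with attribute `gmin_true`.
#' @examples
#' dc <- generate_drying_series(0.008, seed = 1, noise_sd = 0)
#' fit_gmin(dc)
#' @export
generate_drying_series <- function(gmin_true, area = 4e-4,
                                   env = list(T = 20, RH = 50,
                                              Patm = 101.325),
                                   schedule = seq(0, 3.5 * 3600,
                                                  by = 25 * 60),
                                   m0 = 0.15, noise_sd = 5e-4,
                                   seed = 1L) {
  stopifnot(gmin_true >= 0, area > 0, noise_sd >= 0)
  w <- vpd_kpa(env$T, env$RH) / env$Patm       # mole-fraction gradient
  r <- gmin_true * w * area * M_WATER          # g s-1
  masses <- m0 - r * schedule
  masses <- with_seed(seed, masses + stats::rnorm(length(masses), 0,
                                                  noise_sd))
  out <- drying_curve(times = schedule, masses = masses,
                      area_initial = area, area_final = area, env = env)
  attr(out, "gmin_true") <- gmin_true
  out
}

#' Simulate a gravimetric pot-weight series
#'
#' Builds a pot-weighing record consistent with the whole-plant mass
#' balance `E = (V + Wi - Wf - FW) / At`: the final weight is
#' `Wf = Wi + sum(V) - FW - E_true * At`, with intermediate readings every
#' couple of days interpolating plant growth and cumulative transpiration,
#' and each watering volume reflected in the next reading. Balance noise
#' is additive Gaussian on intermediate readings only, so the mass balance
#' of the endpoints is exact at `noise_sd = 0`.
#'
#' @param E_true Cumulative transpiration per cumulative leaf area
#'   (g m-2).
#' @param leaf_area_series Tibble with `day` and `area_m2`: the weekly
#'   leaf-area record used both to grow the plant and to compute `At`.
#' @param watering_events Tibble with `day` and `volume_ml` (1 ml = 1 g).
#' @param Wi Initial pot + plant weight (g).
#' @param FW Final plant fresh weight (g).
#' @param duration Experiment length (d).
#' @param at_method Integration rule for cumulative leaf area, passed to
#'   [cumulative_leaf_area()].
#' @param noise_sd Balance noise on intermediate readings (g).
#' @param seed Seed for the noise stream.
#' @return A [transpiration_series()] object with attribute `E_true`.
#' @examples
#' ts <- generate_pot_weights(E_true = 20000, seed = 1)
#' whole_plant_E(ts)
#' @export
generate_pot_weights <- function(E_true,
                                 leaf_area_series = tibble::tibble(
                                   day = c(0, 7, 14, 21, 30),
                                   area_m2 = c(5e-4, 2e-3, 5e-3, 9e-3,
                                               1.4e-2)),
                                 watering_events = tibble::tibble(
                                   day = c(6, 13, 20, 27),
                                   volume_ml = c(40, 40, 40, 30)),
                                 Wi = 600, FW = 30, duration = 30,
                                 at_method = "trapezoid",
                                 noise_sd = 5e-4, seed = 1L) {
  stopifnot(E_true >= 0, Wi >= 0, FW >= 0, duration > 0,
            all(watering_events$volume_ml >= 0))
  At <- cumulative_leaf_area(leaf_area_series, method = at_method)
  total_V <- sum(watering_events$volume_ml)
  Wf <- Wi + total_V - FW - E_true * At
  days <- sort(unique(c(seq(0, duration, by = 2), duration)))
  # cumulative leaf-area exposure up to each reading, same rule as At
  at_partial <- purrr::map_dbl(days, function(d) {
    sub <- leaf_area_series[leaf_area_series$day <= d, , drop = FALSE]
    if (nrow(sub) < 1) return(0)
    a_d <- stats::approx(leaf_area_series$day, leaf_area_series$area_m2,
                         xout = d, rule = 2)$y
    cumulative_leaf_area(
      tibble::tibble(day = c(sub$day, d), area_m2 = c(sub$area_m2, a_d)),
      method = at_method)
  })
  cum_v <- purrr::map_dbl(days, function(d) {
    sum(watering_events$volume_ml[watering_events$day < d])
  })
  growth <- FW * days / duration
  weights <- Wi + cum_v - growth - E_true * at_partial
  weights[length(weights)] <- Wf
  if (noise_sd > 0) {
    # the initial weighing defines Wi, so noise enters from reading 2 on
    later <- 2:length(weights)
    weights[later] <- with_seed(
      seed, weights[later] + stats::rnorm(length(later), 0, noise_sd))
  }
  transpiration_series(
    Wi = Wi, Wf = weights[length(weights)], FW = FW,
    waterings = watering_events, leaf_areas = leaf_area_series,
    duration = duration,
    readings = tibble::tibble(day = days, weight_g = weights),
    E_true = E_true, at_method = at_method
  )
}
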