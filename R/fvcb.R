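#' Default effective Michaelis constant for CO2
#'
#' Effective Michaelis-Menten constant of Rubisco carboxylation in the
#' presence of atmospheric oxygen, `Km = Kc * (1 + O / Ko)`, at 25 degrees C.
#' This is the fixed constant used by [fit_aci()] when no `Kc`/`Ko`/`O`
#' triple is supplied. See [km_chloroplastic()] to compute `Km` from its
#' components.
#'
#' @format A length-one numeric, in umol mol-1.
#' @export
km_default <- 620.3322

#' Construct a validated FvCB parameter set
#'
#' Bundles the kinetic constants of the Farquhar-von Caemmerer-Berry (FvCB)
#' leaf photosynthesis model. All constants are taken at 25 degrees C; no
#' temperature-response functions are applied.
#'
#' If `Kc`, `Ko` and `O` are all supplied, `Km` is computed from them via
#' [km_chloroplastic()] and must not contradict an explicitly supplied `Km`.
#'
#' @param Vcmax Maximum Rubisco carboxylation rate (umol m-2 s-1).
#' @param Jmax Maximum electron transport rate (umol m-2 s-1).
#' @param GammaStar Chloroplastic CO2 compensation point in the absence of
#'   day respiration (umol mol-1).
#' @param Rd Day (non-photorespiratory) respiration (umol m-2 s-1).
#' @param Km Effective Michaelis constant `Kc * (1 + O/Ko)` (umol mol-1).
#'   Defaults to [km_default].
#' @param Kc,Ko Michaelis constants of carboxylation (umol mol-1) and
#'   oxygenation (mmol mol-1); optional.
#' @param O Oxygen mole fraction (mmol mol-1); optional.
#' @param theta_J Curvature of the J vs PAR non-rectangular hyperbola,
#'   in (0, 1].
#' @param phi_J Initial quantum yield of electron transport on an incident
#'   photon basis, in (0, 1).
#' @return An object of class `fvcb_params` (a named list).
#' @examples
#' p <- fvcb_params(Vcmax = 60, Jmax = 120, GammaStar = 40, Rd = 1)
#' p$Km
#' @export
fvcb_params <- function(Vcmax = 60, Jmax = 120, GammaStar = 43.52,
                        Rd = 0.914, Km = km_default,
                        Kc = NULL, Ko = NULL, O = NULL,
                        theta_J = 0.7, phi_J = 0.3) {
  stopifnot(is.numeric(Vcmax), is.numeric(Jmax), is.numeric(GammaStar),
            is.numeric(Rd))
  if (any(c(Vcmax, Jmax, GammaStar, Rd) < 0)) {
    stop("Vcmax, Jmax, GammaStar and Rd must all be non-negative",
         call. = FALSE)
  }
  if (!(theta_J > 0 && theta_J <= 1)) {
    stop("theta_J must lie in (0, 1]", call. = FALSE)
  }
  if (!(phi_J > 0 && phi_J < 1)) {
    stop("phi_J must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(Kc) && !is.null(Ko) && !is.null(O)) {
    km_implied <- km_chloroplastic(Kc, Ko, O)
    if (!missing(Km) && abs(Km - km_implied) > 1e-6 * max(1, abs(Km))) {
      stop("supplied Km contradicts Kc * (1 + O/Ko)", call. = FALSE)
    }
    Km <- km_implied
  }
  if (Km <= 0) stop("Km must be positive", call. = FALSE)
  structure(
    list(Vcmax = Vcmax, Jmax = Jmax, GammaStar = GammaStar, Rd = Rd,
         Km = Km, Kc = Kc, Ko = Ko, O = O,
         theta_J = theta_J, phi_J = phi_J),
    class = "fvcb_params"
  )
}

#' @export
print.fvcb_params <- function(x, ...) {
  cat("<fvcb_params>\n")
  cat(sprintf("  Vcmax = %g, Jmax = %g umol m-2 s-1\n", x$Vcmax, x$Jmax))
  cat(sprintf("  GammaStar = %g, Km = %g umol mol-1\n", x$GammaStar, x$Km))
  cat(sprintf("  Rd = %g umol m-2 s-1; theta_J = %g, phi_J = %g\n",
              x$Rd, x$theta_J, x$phi_J))
  invisible(x)
}

#' Effective Michaelis constant from Kc, Ko and oxygen
#'
#' `Km = Kc * (1 + O / Ko)`: the apparent Michaelis constant of Rubisco
#' carboxylation once competitive inhibition by oxygen is folded in.
#'
#' @param Kc Michaelis constant for CO2 (umol mol-1), positive.
#' @param Ko Michaelis constant for O2 (mmol mol-1), positive.
#' @param O Oxygen mole fraction (mmol mol-1), non-negative.
#' @return `Km` in umol mol-1.
#' @examples
#' km_chloroplastic(272.38, 165.82, 210)
#' @export
km_chloroplastic <- function(Kc, Ko, O) {
  if (any(Kc <= 0) || any(Ko <= 0)) {
    stop("Kc and Ko must be positive", call. = FALSE)
  }
  if (any(O < 0)) stop("O must be non-negative", call. = FALSE)
  Kc * (1 + O / Ko)
}

#' Biochemical demand for CO2 at the chloroplast
#'
#' Net assimilation demanded by the FvCB model at chloroplastic CO2 `cc`:
#' the hard minimum of the Rubisco-limited rate
#' `Ac = Vcmax (cc - GammaStar) / (cc + Km)` and the RuBP-regeneration
#' (electron-transport) limited rate
#' `Aj = J (cc - GammaStar) / (4 cc + 8 GammaStar)`, minus `Rd`.
#' No triose-phosphate limitation and no hyperbolic smoothing of the
#' minimum are applied.
#'
#' @param cc Chloroplastic CO2 mole fraction (umol mol-1); vectorised.
#' @param params An [fvcb_params()] object.
#' @param J Electron transport rate actually realised (umol m-2 s-1).
#' @return A tibble with columns `cc`, `A` (net, umol m-2 s-1) and
#'   `limitation` (`"rubisco"` or `"rubp"`).
#' @examples
#' p <- fvcb_params(Vcmax = 60, GammaStar = 40, Km = 620, Rd = 1)
#' assimilation_demand(300, p, J = 120)
#' @export
assimilation_demand <- function(cc, params, J) {
  stopifnot(inherits(params, "fvcb_params"), all(cc >= 0), all(J >= 0))
  if (any(cc + params$Km == 0) || any(4 * cc + 8 * params$GammaStar == 0)) {
    stop("singular denominator in assimilation demand", call. = FALSE)
  }
  Ac <- params$Vcmax * (cc - params$GammaStar) / (cc + params$Km)
  Aj <- J * (cc - params$GammaStar) / (4 * cc + 8 * params$GammaStar)
  # ties go to "rubisco" (at cc = GammaStar both branches vanish)
  lim <- ifelse(Ac <= Aj, "rubisco", "rubp")
  tibble::tibble(cc = cc, A = pmin(Ac, Aj) - params$Rd, limitation = lim)
}

#' Electron transport as a function of irradiance
#'
#' Potential electron transport J(PAR) as the smaller root of the
#' non-rectangular hyperbola
#' `theta_J * J^2 - (phi_J * PAR + Jmax) * J + phi_J * PAR * Jmax = 0`,
#' so that `J(0) = 0` and `J -> Jmax` at saturating light.
#'
#' @param PAR Incident photosynthetically active radiation
#'   (umol m-2 s-1); vectorised.
#' @param Jmax Maximum electron transport rate (umol m-2 s-1).
#' @param theta_J Curvature in (0, 1].
#' @param phi_J Initial quantum yield of J (incident basis).
#' @return J in umol m-2 s-1.
#' @examples
#' electron_transport(c(0, 500, 2000), Jmax = 150)
#' @export
electron_transport <- function(PAR, Jmax, theta_J = 0.7, phi_J = 0.3) {
  if (!(theta_J > 0 && theta_J <= 1)) {
    stop("theta_J must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(all(PAR >= 0), Jmax >= 0)
  b <- phi_J * PAR + Jmax
  disc <- b^2 - 4 * theta_J * phi_J * PAR * Jmax
  # disc >= (b - 2 theta max-term)^2 >= 0 analytically; clamp rounding
  (b - sqrt(pmax(disc, 0))) / (2 * theta_J)
}

#' Steady-state operating point of the supply-demand system
#'
#' Solves for the chloroplastic CO2 mole fraction `cc` at which the FvCB
#' biochemical demand equals the diffusive supply
#' `(ca - cc) * g_tot`, where the total CO2 conductance combines the
#' stomatal conductance to water (divided by the 1.6 diffusivity ratio)
#' and the mesophyll conductance in series:
#' `1 / g_tot = 1.6 / gs_w + 1 / gm`.
#'
#' The root is bracketed on `cc` and refined with [stats::uniroot()] to an
#' absolute supply-demand residual below 1e-9. When net assimilation is
#' negative (darkness), the steady-state `cc` exceeds `ca`; the bracket is
#' extended above `ca` to cover that regime.
#'
#' @param ca Ambient (cuvette) CO2 mole fraction (umol mol-1), > GammaStar.
#' @param gs_w Stomatal conductance to water vapour (mol m-2 s-1), > 0.
#' @param gm Mesophyll conductance to CO2 (mol m-2 s-1), > 0.
#' @param params An [fvcb_params()] object.
#' @param PAR Irradiance (umol m-2 s-1); J is derived through
#'   [electron_transport()] unless `J` is given directly.
#' @param J Optional electron transport rate overriding the light model.
#' @return A one-row tibble: `A`, `ci`, `cc` (umol mol-1 or umol m-2 s-1),
#'   `limitation`, and the achieved `residual`.
#' @examples
#' p <- fvcb_params(Vcmax = 60, GammaStar = 40, Km = 620, Rd = 1)
#' solve_steady_state(400, gs_w = 0.3, gm = 0.2, params = p, PAR = 1500)
#' @export
solve_steady_state <- function(ca, gs_w, gm, params, PAR = 1500, J = NULL) {
  stopifnot(inherits(params, "fvcb_params"))
  if (ca <= params$GammaStar) {
    stop("ca must exceed GammaStar", call. = FALSE)
  }
  if (gs_w <= 0 || gm <= 0) {
    stop("gs_w and gm must be positive", call. = FALSE)
  }
  if (is.null(J)) {
    J <- electron_transport(PAR, params$Jmax, params$theta_J, params$phi_J)
  }
  g_tot <- 1 / (1.6 / gs_w + 1 / gm)
  Vcmax <- params$Vcmax; GammaStar <- params$GammaStar
  Km <- params$Km; Rd <- params$Rd
  resid <- function(cc) {
    Ac <- Vcmax * (cc - GammaStar) / (cc + Km)
    Aj <- J * (cc - GammaStar) / (4 * cc + 8 * GammaStar)
    min(Ac, Aj) - Rd - (ca - cc) * g_tot
  }
  # residual is increasing in cc: demand rises, supply falls.
  # A < 0 pushes cc above ca; Rd/g_tot bounds the overshoot.
  upper <- ca + params$Rd / g_tot + 1
  if (resid(params$GammaStar) > 0 || resid(upper) < 0) {
    stop("no steady-state solution in [GammaStar, ca + Rd/g_tot]",
         call. = FALSE)
  }
  cc <- stats::uniroot(resid, c(params$GammaStar, upper),
                       tol = 1e-12)$root
  dem <- assimilation_demand(cc, params, J)
  A <- (ca - cc) * g_tot   # supply side; equals demand to solver tolerance
  tibble::tibble(
    A = A,
    ci = ca - 1.6 * A / gs_w,
    cc = cc,
    limitation = dem$limitation,
    residual = dem$A - A
  )
}
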