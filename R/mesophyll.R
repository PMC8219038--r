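#' Electron transport under non-photorespiratory conditions
#'
#' With photorespiration suppressed (1% O2), electron transport is set
#' entirely by gross photosynthesis: `J = 4 (A + Rd)`.
#'
#' @param A Net assimilation (umol m-2 s-1); may be negative in darkness.
#' @param Rd Day respiration (umol m-2 s-1).
#' @return J in umol m-2 s-1.
#' @examples
#' j_nonphotorespiratory(10, 1)
#' @export
j_nonphotorespiratory <- function(A, Rd) {
  4 * (A + Rd)
}

#' Electron transport from chlorophyll fluorescence
#'
#' `J = phi_PSII * PAR * absorptance * beta`, the standard conversion of
#' the PSII operating efficiency to a linear electron transport rate.
#' Defaults: leaf absorptance 0.84 and an even (0.5) partitioning of
#' absorbed photons to PSII; both are configurable.
#'
#' @param phi_PSII PSII operating efficiency, in \[0, 1\]; vectorised.
#' @param PAR Incident irradiance (umol m-2 s-1).
#' @param absorptance Leaf absorptance (fraction).
#' @param beta Fraction of absorbed photons reaching PSII.
#' @return J in umol m-2 s-1.
#' @examples
#' j_from_fluorescence(0.25, 1000)
#' @export
j_from_fluorescence <- function(phi_PSII, PAR,
                                absorptance = ABSORPTANCE_DEFAULT,
                                beta = BETA_PSII_DEFAULT) {
  bad <- !is.na(phi_PSII) & (phi_PSII < 0 | phi_PSII > 1)
  if (any(bad)) {
    stop("phi_PSII must lie in [0, 1]", call. = FALSE)
  }
  phi_PSII * PAR * absorptance * beta
}

#' Variable-J estimate of mesophyll conductance with the dCc/dA filter
#'
#' Per-record inversion of the RuBP-limited FvCB equation:
#' \deqn{g_m = A / (c_i - c_i^* [J + 8(A+R_d)] / [J - 4(A+R_d)])}
#' with the chloroplastic CO2 mole fraction recovered as
#' `cc = ci - A/gm`. Each estimate carries the reliability statistic
#' \deqn{\delta C_c/\delta A = 12 c_i^* J / [J - 4(A+R_d)]^2}
#' and a QC flag: an estimate passes only when `10 < dCc/dA < 50`
#' (strict inequalities) and `gm` is finite and positive. Failing records
#' are retained with their reason (`below_10`, `above_50`, `singular`,
#' `nonpositive_gm`), never dropped.
#'
#' `Rd` and `ci_star` enter as global constants (e.g. pooled Laisk
#' averages); pass per-record columns `Rd`/`ci_star` in `data` to
#' override.
#'
#' @param data Data frame with columns `A`, `ci` and either `J` or
#'   (`phi_PSII`, `PAR`) from which J is derived via
#'   [j_from_fluorescence()].
#' @param ci_star Apparent photorespiratory compensation point
#'   (umol mol-1).
#' @param Rd Day respiration (umol m-2 s-1).
#' @param absorptance,beta Passed to [j_from_fluorescence()] when J must
#'   be derived.
#' @return The input tibble with columns `gm` (mol m-2 s-1), `cc`
#'   (umol mol-1), `dCc_dA`, `qc_pass`, `reason` appended.
#' @examples
#' gm_variable_j(tibble::tibble(A = 20, ci = 300, J = 150),
#'               ci_star = 40, Rd = 1)
#' @export
gm_variable_j <- function(data, ci_star = NULL, Rd = NULL,
                          absorptance = ABSORPTANCE_DEFAULT,
                          beta = BETA_PSII_DEFAULT) {
  df <- tibble::as_tibble(data)
  if (!all(c("A", "ci") %in% names(df))) {
    stop("gm_variable_j needs `A` and `ci` columns", call. = FALSE)
  }
  if (!"J" %in% names(df)) {
    if (!all(c("phi_PSII", "PAR") %in% names(df))) {
      stop("supply a `J` column or both `phi_PSII` and `PAR`",
           call. = FALSE)
    }
    df$J <- j_from_fluorescence(df$phi_PSII, df$PAR, absorptance, beta)
  }
  if (is.null(ci_star)) ci_star <- df[["ci_star"]]
  if (is.null(Rd)) Rd <- df[["Rd"]]
  if (is.null(ci_star) || is.null(Rd)) {
    stop("ci_star and Rd are required (arguments or data columns)",
         call. = FALSE)
  }

  gross4 <- 4 * (df$A + Rd)            # = J under non-photorespiration
  denomJ <- df$J - gross4
  singular <- !is.finite(denomJ) | abs(denomJ) < 1e-12 |
    !is.finite(df$A) | !is.finite(df$ci)
  dCc_dA <- ifelse(singular, Inf,
                   12 * ci_star * df$J / denomJ^2)
  denom <- df$ci - ci_star * (df$J + 2 * gross4) / denomJ
  gm <- ifelse(singular | denom == 0, NA_real_, df$A / denom)
  cc <- ifelse(is.finite(gm) & gm != 0, df$ci - df$A / gm, NA_real_)

  gm_ok <- is.finite(gm) & gm > 0
  # window violations are named first: a record at dCc/dA = 1200 is
  # excluded as above_50 even when its gm also comes out nonpositive
  reason <- dplyr::case_when(
    singular ~ "singular",
    dCc_dA <= 10 ~ "below_10",
    dCc_dA >= 50 ~ "above_50",
    !gm_ok ~ "nonpositive_gm",
    .default = "ok"
  )
  df$gm <- ifelse(singular, NA_real_, gm)
  df$cc <- cc
  df$dCc_dA <- dCc_dA
  df$qc_pass <- reason == "ok"
  df$reason <- reason
  df
}

#' Chloroplastic CO2 from mesophyll conductance
#'
#' The Fick's-law drawdown from the intercellular airspace to the
#' chloroplast: `cc = ci - A / gm`.
#'
#' @param ci Intercellular CO2 mole fraction (umol mol-1); vectorised.
#' @param A Net assimilation (umol m-2 s-1).
#' @param gm Mesophyll conductance (mol m-2 s-1), > 0 (may be `Inf`).
#' @return cc in umol mol-1.
#' @examples
#' cc_from_gm(326.2, 13.84, 0.20)
#' @export
cc_from_gm <- function(ci, A, gm) {
  if (any(gm <= 0, na.rm = TRUE)) {
    stop("gm must be positive", call. = FALSE)
  }
  ci - A / gm
}
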