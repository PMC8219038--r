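#' Fit FvCB parameters to an A-cc curve
#'
#' Converts a measured A-ci curve to an A-cc curve through the mesophyll
#' drawdown (`cc = ci - A/gm`, see [cc_from_gm()]) and estimates `Vcmax`
#' and `Jmax` by least squares on the minimum-of-branches FvCB model with
#' `Rd`, `GammaStar` and `Km` held fixed. When the curve carries a `PAR`
#' column, the electron transport of the RuBP branch is
#' `J = electron_transport(PAR, Jmax, theta_J, phi_J)` per record;
#' without `PAR`, light is taken as saturating and `J = Jmax`.
#'
#' The reported `inflection` is the cc at which the Rubisco- and
#' RuBP-limited branches cross (evaluated at the curve's maximum-PAR J).
#' If the fitted points all fall on one branch, the parameter governed by
#' the other branch is unidentified: it is reported as `NA` with a lower
#' bound in `vcmax_bound`/`jmax_bound` instead of a number.
#'
#' @param curve Data frame with columns `ci` (or `cc` directly) and `A`,
#'   optionally `PAR`; at least 6 points.
#' @param gm Mesophyll conductance used for the ci -> cc conversion
#'   (mol m-2 s-1); `Inf` fits on ci directly.
#' @param Rd Day respiration held fixed (umol m-2 s-1).
#' @param GammaStar Chloroplastic compensation point held fixed
#'   (umol mol-1).
#' @param Km Effective Michaelis constant held fixed (umol mol-1);
#'   defaults to [km_default].
#' @param theta_J,phi_J Light-response constants of the J model used when
#'   `PAR` is present.
#' @return An object of class `aci_fit` with `Vcmax`, `Jmax`,
#'   `inflection`, bounds for unidentified parameters, and diagnostics.
#'   Has `tidy()`, `glance()` and `autoplot()` methods.
#' @examples
#' tr <- synthetic_truth(noise_cv = 0)
#' ac <- generate_aci_curve(tr)
#' fit_aci(ac, gm = tr$gm_true, Rd = tr$fvcb$Rd,
#'         GammaStar = tr$fvcb$GammaStar, Km = tr$fvcb$Km)
#' @export
fit_aci <- function(curve, gm, Rd, GammaStar, Km = km_default,
                    theta_J = 0.7, phi_J = 0.3) {
  df <- tibble::as_tibble(curve)
  if (!"A" %in% names(df)) stop("A-ci curve needs an `A` column",
                                call. = FALSE)
  if ("solved" %in% names(df)) df <- df[df$solved %in% TRUE, ]
  # a ci column always wins: cc is (re)derived through the supplied gm,
  # so a pre-existing cc column cannot silently bypass the conversion
  if ("ci" %in% names(df)) {
    df$cc <- cc_from_gm(df$ci, df$A, gm)
  } else if (!"cc" %in% names(df)) {
    stop("A-ci curve needs `ci` (or `cc`) column", call. = FALSE)
  }
  df <- df[is.finite(df$cc) & is.finite(df$A), ]
  if (nrow(df) < 6) stop("need >= 6 finite A-cc points", call. = FALSE)
  has_par <- "PAR" %in% names(df) && all(is.finite(df$PAR))

  j_of <- function(Jmax) {
    if (has_par) electron_transport(df$PAR, Jmax, theta_J, phi_J)
    else rep(Jmax, nrow(df))
  }
  predict_A <- function(Vcmax, Jmax) {
    Ac <- Vcmax * (df$cc - GammaStar) / (df$cc + Km)
    Aj <- j_of(Jmax) * (df$cc - GammaStar) / (4 * df$cc + 8 * GammaStar)
    pmin(Ac, Aj) - Rd
  }
  ss <- function(par) {
    if (any(par <= 0)) return(1e12)
    sum((df$A - predict_A(par[1], par[2]))^2)
  }

  # starts: Rubisco branch from the low-cc points, J from the plateau
  lowcc <- df[df$cc <= stats::quantile(df$cc, 0.5), ]
  v0 <- max((max(lowcc$A) + Rd) * (max(lowcc$cc) + Km) /
              max(max(lowcc$cc) - GammaStar, 1), 10)
  amax <- max(df$A) + Rd
  ccmax <- max(df$cc)
  j0 <- max(amax * (4 * ccmax + 8 * GammaStar) / (ccmax - GammaStar), 20)
  if (has_par) j0 <- j0 * 1.2   # Jmax exceeds realised J
  starts <- list(c(v0, j0), c(v0 * 0.5, j0 * 1.5), c(v0 * 2, j0),
                 c(v0, j0 * 0.7), c(50, 100))
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, ss, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    opt <- stats::optim(opt$par, ss, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  Vcmax <- best$par[1]
  Jmax <- best$par[2]

  # identifiability: which branch does each fitted point sit on?
  Ac <- Vcmax * (df$cc - GammaStar) / (df$cc + Km)
  Aj <- j_of(Jmax) * (df$cc - GammaStar) / (4 * df$cc + 8 * GammaStar)
  on_rubisco <- Ac < Aj - 1e-9
  on_rubp <- Aj < Ac - 1e-9
  vcmax_bound <- jmax_bound <- NA_real_
  if (!any(on_rubisco)) {
    vcmax_bound <- Vcmax
    Vcmax <- NA_real_
  }
  if (!any(on_rubp)) {
    jmax_bound <- Jmax
    Jmax <- NA_real_
  }

  inflection <- NA_real_
  if (is.finite(Vcmax) && is.finite(Jmax)) {
    j_top <- if (has_par) {
      electron_transport(max(df$PAR), Jmax, theta_J, phi_J)
    } else {
      Jmax
    }
    den <- 4 * Vcmax - j_top
    if (abs(den) > 1e-12) {
      infl <- (j_top * Km - 8 * GammaStar * Vcmax) / den
      if (is.finite(infl) && infl > GammaStar) inflection <- infl
    }
  }

  structure(
    list(Vcmax = Vcmax, Jmax = Jmax, inflection = inflection,
         vcmax_bound = vcmax_bound, jmax_bound = jmax_bound,
         rss = best$value, n = nrow(df), gm = gm, Rd = Rd,
         GammaStar = GammaStar, Km = Km, theta_J = theta_J,
         phi_J = phi_J, has_par = has_par,
         data = df[, intersect(c("cc", "A", "PAR"), names(df))]),
    class = "aci_fit"
  )
}

#' @export
print.aci_fit <- function(x, ...) {
  cat("<aci_fit>\n")
  cat(sprintf("  Vcmax = %.4g, Jmax = %.4g umol m-2 s-1\n",
              x$Vcmax, x$Jmax))
  cat(sprintf("  inflection = %.4g umol mol-1; rss = %.3g (n = %d)\n",
              x$inflection, x$rss, x$n))
  if (is.finite(x$vcmax_bound)) {
    cat(sprintf("  Vcmax unidentified (all points RuBP-limited); >= %.4g\n",
                x$vcmax_bound))
  }
  if (is.finite(x$jmax_bound)) {
    cat(sprintf("  Jmax unidentified (all points Rubisco-limited); >= %.4g\n",
                x$jmax_bound))
  }
  invisible(x)
}

#' @rdname fit_aci
#' @param x,object An `aci_fit` object.
#' @param ... Unused.
#' @export
tidy.aci_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Vcmax", "Jmax", "inflection"),
    estimate = c(x$Vcmax, x$Jmax, x$inflection)
  )
}

#' @rdname fit_aci
#' @export
glance.aci_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, gm = x$gm,
                 vcmax_identified = !is.finite(x$vcmax_bound),
                 jmax_identified = !is.finite(x$jmax_bound))
}

#' @rdname fit_aci
#' @export
autoplot.aci_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(cc = seq(min(df$cc), max(df$cc),
                                  length.out = 200))
  v <- if (is.finite(object$Vcmax)) object$Vcmax else object$vcmax_bound
  j <- if (is.finite(object$Jmax)) object$Jmax else object$jmax_bound
  jr <- if (object$has_par) {
    electron_transport(max(df$PAR), j, object$theta_J, object$phi_J)
  } else {
    j
  }
  grid$Ac <- v * (grid$cc - object$GammaStar) / (grid$cc + object$Km) -
    object$Rd
  grid$Aj <- jr * (grid$cc - object$GammaStar) /
    (4 * grid$cc + 8 * object$GammaStar) - object$Rd
  long <- tidyr::pivot_longer(grid, c("Ac", "Aj"), names_to = "branch",
                              values_to = "A")
  ggplot2::ggplot(df, ggplot2::aes(.data$cc, .data$A)) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(linetype = .data$branch)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(c[c] ~ "(umol mol"^-1 * ")"),
      y = expression(A[net] ~ "(umol m"^-2 ~ "s"^-1 * ")"),
      title = sprintf("A-cc fit: Vcmax = %.1f, Jmax = %.1f",
                      object$Vcmax, object$Jmax))
}
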