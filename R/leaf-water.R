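#' Relative water content
#'
#' `RWC = 100 * (FW - DW) / (SW - DW)`: the leaf's water content as a
#' percentage of its content at full saturation.
#'
#' @param FW Fresh weight (g); vectorised.
#' @param DW Oven-dry weight (g).
#' @param SW Saturated (turgid) weight (g); must exceed `DW`.
#' @return RWC in percent. Values outside \[0, 100\] are returned with a
#'   warning, not clamped.
#' @examples
#' rwc(FW = 80, DW = 20, SW = 100)
#' @export
rwc <- function(FW, DW, SW) {
  if (any(SW <= DW)) {
    stop("saturated weight must exceed dry weight", call. = FALSE)
  }
  if (any(FW < 0)) stop("FW must be non-negative", call. = FALSE)
  out <- 100 * (FW - DW) / (SW - DW)
  if (any(out < 0 | out > 100)) {
    warning("RWC outside [0, 100]: check weights", call. = FALSE)
  }
  out
}

#' Saturation vapour pressure (Arden Buck)
#'
#' `es(T) = 0.61121 exp((18.678 - T/234.5) * T / (257.14 + T))` kPa,
#' for temperature in degrees C over liquid water.
#'
#' @param T_c Air/leaf temperature (degrees C); vectorised.
#' @return Saturation vapour pressure (kPa).
#' @export
saturation_vp <- function(T_c) {
  0.61121 * exp((18.678 - T_c / 234.5) * (T_c / (257.14 + T_c)))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' @param T_c Temperature (degrees C).
#' @param RH Relative humidity (%).
#' @return VPD in kPa.
#' @export
vpd_kpa <- function(T_c, RH) {
  saturation_vp(T_c) * (1 - RH / 100)
}

#' Construct a leaf drying curve
#'
#' @param times Weighing times (s), strictly increasing.
#' @param masses Leaf masses (g).
#' @param area_initial,area_final Single-sided projected leaf area (m2)
#'   from the photographs before and after drying.
#' @param env List with `T` (degrees C), `RH` (%), `Patm` (kPa).
#' @return An object of class `drying_curve` (a tibble of `time_s`,
#'   `mass_g` with area/environment attributes).
#' @export
drying_curve <- function(times, masses, area_initial, area_final = NULL,
                         env = list(T = 20, RH = 50, Patm = 101.325)) {
  if (is.null(area_final)) area_final <- area_initial
  stopifnot(length(times) == length(masses), area_initial > 0,
            area_final > 0)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time_s = times, mass_g = masses)
  attr(out, "area_initial") <- area_initial
  attr(out, "area_final") <- area_final
  attr(out, "env") <- env
  class(out) <- c("drying_curve", class(out))
  out
}

#' Minimum (cuticular) conductance from a drying curve
#'
#' After full stomatal closure a detached leaf's mass declines linearly;
#' the slope, normalised by leaf area and the mole-fraction vapour
#' gradient, gives the minimum conductance to water vapour:
#' `gmin = (rate / M_water) / (area * VPD/Patm)`, reported in
#' mmol m-2 s-1. The leaf area is the mean of the initial and final
#' single-sided projected areas. The mass-loss rate is the OLS slope of
#' mass on time over the post-closure window; readings inside an initial
#' `discard_s` interval (stomatal closure) are excluded.
#'
#' @param curve A [drying_curve()] object (or data frame with `time_s`,
#'   `mass_g` plus area/env attributes).
#' @param discard_s Initial interval to discard (s); default 0 because
#'   the weighing protocol starts after closure.
#' @return An object of class `gmin_result`: `gmin` (mmol m-2 s-1),
#'   `mass_loss_rate` (g s-1), `vpd_mole_fraction`, `r_squared`,
#'   `n_points`, `no_loss` flag. Has `tidy()` and `glance()` methods.
#' @examples
#' dc <- generate_drying_series(0.008, noise_sd = 0)
#' fit_gmin(dc)
#' @export
fit_gmin <- function(curve, discard_s = 0) {
  df <- tibble::as_tibble(curve)
  df <- df[df$time_s >= discard_s, ]
  if (nrow(df) < 4) {
    stop("need >= 4 post-closure drying-curve points", call. = FALSE)
  }
  env <- attr(curve, "env")
  area <- mean(c(attr(curve, "area_initial"), attr(curve, "area_final")))
  w <- vpd_kpa(env$T, env$RH) / env$Patm
  m <- stats::lm(mass_g ~ time_s, data = df)
  slope <- stats::coef(m)[["time_s"]]
  r2 <- suppressWarnings(summary(m))$r.squared  # noise-free series are legal
  no_loss <- slope >= -1e-15          # flat within numerical noise
  rate <- if (no_loss) 0 else -slope
  gmin <- 1000 * (rate / M_WATER) / (area * w)
  structure(
    list(gmin = gmin, mass_loss_rate = rate, vpd_mole_fraction = w,
         r_squared = r2, n_points = nrow(df), no_loss = no_loss,
         area_m2 = area),
    class = "gmin_result"
  )
}

#' @export
print.gmin_result <- function(x, ...) {
  cat("<gmin_result>\n")
  cat(sprintf("  gmin = %.4g mmol m-2 s-1 (rate %.3g g s-1, r2 %.4f)\n",
              x$gmin, x$mass_loss_rate, x$r_squared))
  if (x$no_loss) cat("  note: no mass loss detected\n")
  invisible(x)
}

#' @rdname fit_gmin
#' @param x A `gmin_result` object.
#' @param ... Unused.
#' @export
tidy.gmin_result <- function(x, ...) {
  tibble::tibble(term = c("gmin", "mass_loss_rate"),
                 estimate = c(x$gmin, x$mass_loss_rate))
}

#' @rdname fit_gmin
#' @export
glance.gmin_result <- function(x, ...) {
  tibble::tibble(gmin = x$gmin, r_squared = x$r_squared,
                 n_points = x$n_points, no_loss = x$no_loss)
}

#' Chamber leak diffusion coefficient from a dark series
#'
#' With the leaf in darkness its respiration is constant, so any
#' dependence of the apparent CO2 flux on the ambient-to-chamber CO2
#' gradient is diffusion through the chamber gaskets. The OLS slope of
#' apparent flux (umol s-1) on mole-fraction gradient (umol mol-1) is
#' the diffusion coefficient k in mol s-1.
#'
#' @param dark_series Data frame with columns `gradient`
#'   (ambient - chamber CO2, umol mol-1) and `flux` (apparent CO2 flux,
#'   umol s-1); at least 3 gradient levels.
#' @return k in mol s-1.
#' @examples
#' ds <- tibble::tibble(gradient = c(-20, 0, 20),
#'                      flux = -0.05 + 0.40 * c(-20, 0, 20))
#' estimate_leak_coefficient(ds)
#' @export
estimate_leak_coefficient <- function(dark_series) {
  df <- tibble::as_tibble(dark_series)
  if (!all(c("gradient", "flux") %in% names(df))) {
    stop("dark series needs `gradient` and `flux` columns",
         call. = FALSE)
  }
  if (nrow(df) < 3) {
    stop("need >= 3 gradient levels", call. = FALSE)
  }
  if (diff(range(df$gradient)) < 1e-9) {
    stop("degenerate design: no spread in the CO2 gradient",
         call. = FALSE)
  }
  stats::coef(stats::lm(flux ~ gradient, data = df))[["gradient"]]
}

#' Correct assimilation for chamber leak flux
#'
#' Subtracts the gasket diffusion flux from measured assimilation:
#' `A_corrected = A - k * (c_ambient - c_chamber) / leaf_area`, with k in
#' mol s-1, the gradient in umol mol-1 and the area in m2, giving the
#' correction directly in umol m-2 s-1. Records without an ambient CO2
#' column are left unchanged with a warning and `leak_corrected = FALSE`.
#'
#' @param records Data frame of gas-exchange records with columns `A`,
#'   `ca` (chamber CO2) and `c_ambient` (CO2 outside the chamber,
#'   umol mol-1).
#' @param k Leak diffusion coefficient (mol s-1), >= 0.
#' @param leaf_area Leaf area in the chamber (m2).
#' @return The records with `A` corrected and a `leak_corrected`
#'   provenance column.
#' @export
apply_leak_correction <- function(records, k, leaf_area) {
  stopifnot(k >= 0, leaf_area > 0)
  df <- tibble::as_tibble(records)
  if (!"c_ambient" %in% names(df) || all(is.na(df$c_ambient))) {
    warning("no ambient CO2 column: leak correction skipped",
            call. = FALSE)
    df$leak_corrected <- FALSE
    return(df)
  }
  gradient <- df$c_ambient - df$ca
  ok <- is.finite(gradient)
  df$A[ok] <- df$A[ok] - k * gradient[ok] / leaf_area
  df$leak_corrected <- ok
  if (any(!ok)) {
    warning(sum(!ok), " record(s) missing ambient CO2: left uncorrected",
            call. = FALSE)
  }
  df
}
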