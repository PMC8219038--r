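#' Construct a whole-plant gravimetric transpiration record
#'
#' @param Wi Initial pot + plant weight (g).
#' @param Wf Final pot + plant weight (g).
#' @param FW Final plant fresh weight (g).
#' @param waterings Tibble with `day` and `volume_ml`; 1 ml of water is
#'   taken as 1 g.
#' @param leaf_areas Tibble with `day` and `area_m2`: the weekly
#'   leaf-area measurements.
#' @param duration Experiment length (d).
#' @param readings Optional tibble of intermediate weighings
#'   (`day`, `weight_g`).
#' @param At Optional pre-computed cumulative leaf area; overrides the
#'   integration of `leaf_areas`.
#' @param E_true,at_method Generator bookkeeping (optional).
#' @return An object of class `transpiration_series`.
#' @export
transpiration_series <- function(Wi, Wf, FW, waterings, leaf_areas = NULL,
                                 duration = 30, readings = NULL,
                                 At = NULL, E_true = NULL,
                                 at_method = "trapezoid") {
  stopifnot(Wi >= 0, Wf >= 0, FW >= 0, duration > 0)
  if (!is.null(waterings) && any(waterings$volume_ml < 0)) {
    stop("watering volumes must be non-negative", call. = FALSE)
  }
  structure(
    list(Wi = Wi, Wf = Wf, FW = FW, waterings = waterings,
         leaf_areas = leaf_areas, duration = duration,
         readings = readings, At = At, E_true = E_true,
         at_method = at_method),
    class = "transpiration_series"
  )
}

#' @export
print.transpiration_series <- function(x, ...) {
  cat("<transpiration_series>\n")
  cat(sprintf("  Wi = %g, Wf = %g, FW = %g g over %g d; %d waterings\n",
              x$Wi, x$Wf, x$FW, x$duration,
              if (is.null(x$waterings)) 0L else nrow(x$waterings)))
  invisible(x)
}

#' Cumulative leaf area over the experiment
#'
#' Reduces the weekly leaf-area record to the single `At` used to
#' normalise whole-plant transpiration. Two rules:
#'
#' * `"trapezoid"` (default): the time-integral of area over the record
#'   by the trapezoidal rule, divided by the record's time span - i.e.
#'   the time-averaged leaf area (m2). This weights each week by its
#'   duration.
#' * `"sum"`: the plain sum of the weekly measurements (m2).
#'
#' @param leaf_areas Tibble with `day` and `area_m2`.
#' @param method `"trapezoid"` or `"sum"`.
#' @return At in m2.
#' @examples
#' la <- tibble::tibble(day = c(0, 15, 30), area_m2 = c(0, 0.01, 0.02))
#' cumulative_leaf_area(la)
#' @export
cumulative_leaf_area <- function(leaf_areas, method = c("trapezoid",
                                                        "sum")) {
  method <- match.arg(method)
  stopifnot(all(leaf_areas$area_m2 >= 0))
  if (method == "sum") return(sum(leaf_areas$area_m2))
  la <- leaf_areas[order(leaf_areas$day), ]
  if (nrow(la) < 2) return(la$area_m2[1])
  dt <- diff(la$day)
  integral <- sum(dt * (utils::head(la$area_m2, -1) +
                          utils::tail(la$area_m2, -1)) / 2)
  integral / (max(la$day) - min(la$day))
}

#' Whole-plant cumulative transpiration per leaf area
#'
#' The gravimetric mass balance of a sealed pot:
#' `E = (V + Wi - Wf - FW) / At`, where `V` is the total water added,
#' `Wi`/`Wf` the initial/final pot + plant weights, `FW` the final plant
#' fresh weight, and `At` the cumulative leaf area (see
#' [cumulative_leaf_area()]). Soil evaporation is taken as zero (sealed
#' soil surface). 1 ml of added water counts as 1 g.
#'
#' @param series A [transpiration_series()] object.
#' @param at_method Integration rule for `At` when the series does not
#'   carry a pre-computed value; defaults to the series' own rule.
#' @return A one-row tibble with `E` (g m-2), `total_water_added`, `At`,
#'   and `anomalous` (TRUE when the numerator is negative - condensation
#'   or an accounting error; the value is still returned).
#' @examples
#' ts <- generate_pot_weights(E_true = 20000, noise_sd = 0)
#' whole_plant_E(ts)
#' @export
whole_plant_E <- function(series, at_method = NULL) {
  stopifnot(inherits(series, "transpiration_series"))
  At <- series$At
  if (is.null(At)) {
    if (is.null(series$leaf_areas)) {
      stop("series has neither leaf areas nor a pre-computed At",
           call. = FALSE)
    }
    At <- cumulative_leaf_area(series$leaf_areas,
                               method = at_method %||% series$at_method)
  }
  if (At <= 0) stop("cumulative leaf area must be positive",
                    call. = FALSE)
  V <- if (is.null(series$waterings)) 0 else sum(series$waterings$volume_ml)
  num <- V + series$Wi - series$Wf - series$FW
  if (num < 0) {
    warning("negative water balance: condensation or accounting anomaly",
            call. = FALSE)
  }
  tibble::tibble(E = num / At, total_water_added = V, At = At,
                 anomalous = num < 0)
}
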