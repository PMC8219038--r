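#' Laisk estimation of ci* and day respiration
#'
#' Estimates the apparent photorespiratory compensation point `ci*` and
#' day respiration `Rd` from a family of low-CO2 A-ci sub-curves measured
#' at several sub-saturating irradiances. Each sub-curve is fitted by
#' ordinary least squares, `A = a_p + b_p * ci`; because every sub-curve
#' passes (ideally) through the common point `(ci*, -Rd)`, the intercepts
#' are a linear function of the slopes, `a = alpha + beta * b` with
#' `alpha = -Rd` and `beta = -ci*`. The second-stage slope-intercept
#' regression therefore returns `ci* = -beta` and `Rd = -alpha`.
#'
#' @param family Either a list of `response_curve` tibbles (one per
#'   irradiance, as produced by [generate_laisk_family()]) or a single
#'   data frame with columns `ci`, `A` and a grouping column (`curve_id`
#'   or `PAR`).
#' @param group Column that identifies sub-curves when `family` is a
#'   single data frame; defaults to `curve_id` if present, else `PAR`.
#' @return An object of class `laisk_fit`: a list with elements
#'   `ci_star`, `Rd`, `lines` (per-irradiance slope, intercept, r2, n),
#'   `meta_fit` (second-stage coefficients and standard errors),
#'   `n_lines`, and `rd_negative` (QC flag; negative estimates are
#'   reported, never clamped). Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' # three exact lines through (40, -1)
#' fam <- purrr::map(c(0.05, 0.1, 0.2), function(b) {
#'   tibble::tibble(curve_id = paste0("b", b), ci = c(50, 100, 150),
#'                  A = b * (c(50, 100, 150) - 40) - 1)
#' })
#' fit_laisk(dplyr::bind_rows(fam))
#' @export
fit_laisk <- function(family, group = NULL) {
  df <- if (is.data.frame(family)) {
    tibble::as_tibble(family)
  } else {
    dplyr::bind_rows(purrr::map(family, tibble::as_tibble))
  }
  if (!all(c("ci", "A") %in% names(df))) {
    stop("Laisk input needs `ci` and `A` columns", call. = FALSE)
  }
  if (is.null(group)) {
    group <- if ("curve_id" %in% names(df)) "curve_id" else "PAR"
  }
  if (!group %in% names(df)) {
    stop("no sub-curve grouping column (`", group, "`) found",
         call. = FALSE)
  }
  if ("solved" %in% names(df)) df <- df[df$solved %in% TRUE, ]
  df <- df[is.finite(df$ci) & is.finite(df$A), ]

  lines <- df |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        stop("each Laisk sub-curve needs >= 3 (ci, A) points",
             call. = FALSE)
      }
      m <- stats::lm(A ~ ci, data = d)
      s <- suppressWarnings(summary(m))  # exact lines are legitimate here
      tibble::tibble(
        slope = stats::coef(m)[["ci"]],
        intercept = stats::coef(m)[["(Intercept)"]],
        r_squared = s$r.squared,
        n = nrow(d)
      )
    }) |>
    dplyr::ungroup()
  names(lines)[1] <- "line_id"

  if (nrow(lines) < 2) {
    stop("the Laisk method needs >= 2 sub-curves at distinct irradiances",
         call. = FALSE)
  }
  if (diff(range(lines$slope)) < 1e-12) {
    stop("degenerate design: sub-curve slopes are collinear",
         call. = FALSE)
  }

  meta <- stats::lm(intercept ~ slope, data = lines)
  cf <- suppressWarnings(summary(meta))$coefficients
  alpha <- cf["(Intercept)", "Estimate"]
  beta <- cf["slope", "Estimate"]
  meta_fit <- tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(alpha, beta),
    std_error = c(cf["(Intercept)", "Std. Error"],
                  cf["slope", "Std. Error"])
  )
  rd <- -alpha
  structure(
    list(ci_star = -beta, Rd = rd, lines = lines, meta_fit = meta_fit,
         n_lines = nrow(lines), rd_negative = rd < 0,
         data = df[, c(group, "ci", "A")]),
    class = "laisk_fit"
  )
}

#' @export
print.laisk_fit <- function(x, ...) {
  cat("<laisk_fit>\n")
  cat(sprintf("  ci* = %.4g umol mol-1, Rd = %.4g umol m-2 s-1 (%d lines)\n",
              x$ci_star, x$Rd, x$n_lines))
  if (x$rd_negative) cat("  note: Rd estimate is negative (flagged)\n")
  invisible(x)
}

#' @rdname fit_laisk
#' @param x A `laisk_fit` object.
#' @param ... Unused.
#' @export
tidy.laisk_fit <- function(x, ...) {
  x$lines
}

#' @rdname fit_laisk
#' @export
glance.laisk_fit <- function(x, ...) {
  tibble::tibble(
    ci_star = x$ci_star, Rd = x$Rd, n_lines = x$n_lines,
    ci_star_se = x$meta_fit$std_error[x$meta_fit$term == "beta"],
    Rd_se = x$meta_fit$std_error[x$meta_fit$term == "alpha"],
    rd_negative = x$rd_negative
  )
}

#' @rdname fit_laisk
#' @param object A `laisk_fit` object (for `autoplot`).
#' @export
autoplot.laisk_fit <- function(object, ...) {
  lines <- object$lines
  dat <- object$data
  names(dat)[1] <- "line_id"
  dat$line_id <- as.character(dat$line_id)
  lines$line_id <- as.character(lines$line_id)
  ggplot2::ggplot(dat, ggplot2::aes(.data$ci, .data$A,
                                    colour = .data$line_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$line_id)) +
    ggplot2::annotate("point", x = object$ci_star, y = -object$Rd,
                      shape = 4, size = 3) +
    ggplot2::labs(
      x = expression(c[i] ~ "(umol mol"^-1 * ")"),
      y = expression(A ~ "(umol m"^-2 ~ "s"^-1 * ")"),
      colour = "sub-curve",
      title = sprintf("Laisk fit: ci* = %.2f, Rd = %.3f",
                      object$ci_star, object$Rd))
}
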