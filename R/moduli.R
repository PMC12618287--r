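#' @title Initial and tangent Young's moduli
#' @description Elastic moduli summarizing a stress-stretch loading curve:
#'   the initial modulus is the slope near zero load, the tangent modulus
#'   the local slope at a prescribed nominal stress (100 kPa by default).
#'   Both are ordinary least-squares slopes of nominal stress versus
#'   engineering strain (`stretch - 1`) over the points falling in a
#'   stress window, reported in MPa.
#' @name moduli
NULL

.as_curve_df <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("stretch", "nominal_stress_kPa") %in% names(curve)))
  curve
}

.window_slope_MPa <- function(curve, lo, hi, what) {
  curve <- .as_curve_df(curve)
  P <- curve$nominal_stress_kPa
  idx <- which(P >= lo & P <= hi)
  if (length(idx) < 2L)
    stop(length(idx), " point(s) fall in the ", what, " stress window [",
         format(lo), ", ", format(hi), "] kPa; at least 2 are needed - ",
         "resample the curve more densely or change the window ",
         "(curve spans [", format(min(P)), ", ", format(max(P)), "] kPa)",
         call. = FALSE)
  eps <- curve$stretch[idx] - 1
  slope_kPa <- stats::cov(eps, P[idx]) / stats::var(eps)
  if (!is.finite(slope_kPa)) slope_kPa <- 0   # degenerate: no strain spread
  list(E_MPa = slope_kPa / 1000, window = c(lo, hi), n = length(idx))
}

#' Initial Young's modulus
#'
#' Least-squares slope of nominal stress versus engineering strain over
#' the low-load toe of the curve, by default the nominal-stress window
#' 0-0.5 kPa. That default window is deliberately narrow; curves must be
#' sampled densely near the origin to populate it (the window is fully
#' configurable).
#'
#' @param curve Data frame with columns `stretch`, `nominal_stress_kPa`.
#' @param window Length-2 numeric, the nominal-stress window in kPa
#'   (default `c(0, 0.5)`).
#' @return List with `E_ini_MPa`, `window_kPa`, `n_points`.
#' @export
#' @examples
#' lam <- seq(1, 1.002, length.out = 21)
#' curve <- data.frame(stretch = lam, nominal_stress_kPa = 300 * (lam - 1))
#' initial_modulus(curve)$E_ini_MPa   # 0.3 MPa
initial_modulus <- function(curve, window = c(0, 0.5)) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  r <- .window_slope_MPa(curve, window[1], window[2], "initial-modulus")
  list(E_ini_MPa = r$E_MPa, window_kPa = r$window, n_points = r$n)
}

#' Tangent Young's modulus at a prescribed nominal stress
#'
#' Local least-squares slope of nominal stress versus engineering strain
#' in the window `at_stress +/- half_window` (default 100 +/- 10 kPa). A
#' local regression window is used rather than a two-point finite
#' difference so the estimate is robust to sampling noise.
#'
#' @inheritParams initial_modulus
#' @param at_stress Nominal stress at which the tangent is taken (kPa).
#' @param half_window Half-width of the stress window (kPa).
#' @return List with `E_100_MPa` (named for the default 100 kPa level),
#'   `at_stress_kPa`, `window_kPa`, `n_points`.
#' @export
tangent_modulus <- function(curve, at_stress = 100, half_window = 10) {
  stopifnot(at_stress > 0, half_window > 0)
  curve <- .as_curve_df(curve)
  if (max(curve$nominal_stress_kPa) < at_stress + half_window)
    stop("curve reaches only ", format(max(curve$nominal_stress_kPa)),
         " kPa, below the top of the tangent window ",
         format(at_stress + half_window), " kPa", call. = FALSE)
  r <- .window_slope_MPa(curve, at_stress - half_window,
                         at_stress + half_window, "tangent-modulus")
  list(E_100_MPa = r$E_MPa, at_stress_kPa = at_stress,
       window_kPa = r$window, n_points = r$n)
}
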