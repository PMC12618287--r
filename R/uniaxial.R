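#' @title Uniaxial strip mechanics
#' @description Solve the uniaxial strip boundary-value problem: a strip cut
#'   in the circumferential or longitudinal direction is stretched along its
#'   axis; the thickness (radial) face is traction free, which fixes the
#'   hydrostatic multiplier `p = mu * lam_R^2` exactly because no fiber
#'   family has a radial component, and the in-plane transverse stretch is
#'   the root of the remaining zero-transverse-stress equation.
#' @name uniaxial
NULL

.direction_levels <- c("circumferential", "longitudinal")

match_direction <- function(direction) {
  match.arg(direction, .direction_levels)
}

# Zero-transverse-stress residual and its derivative, vectorized over the
# loading stretch lam (and candidate transverse stretch z, same length).
# With p = mu * lam_R^2 = mu / (lam^2 z^2) eliminated, the transverse PK1
# component reduces to
#   g(z) = mu z + z * sum_j k1_j (I4_j - 1) e^{k2_j (I4_j-1)^2} w_j
#          - mu / (lam^2 z^3)
# where w_j projects the family onto the transverse axis.
transverse_residual <- function(z, lam, mu, k1, k2, w_load, w_trans,
                                tension_only = FALSE, deriv = FALSE) {
  lam2 <- lam * lam
  z2 <- z * z
  fib <- 0
  dfib <- 0
  for (j in 1:4) {
    kw <- k1[j] * w_trans[j]
    if (kw == 0) next                    # family does not load this axis
    x <- lam2 * w_load[j] + z2 * w_trans[j] - 1
    if (tension_only) x[x < 0] <- 0
    x2 <- x * x
    E <- exp(pmin(k2[j] * x2, 700))
    fib <- fib + kw * (x * E)
    if (deriv) {
      # d/dz [z x E] = E (x + (dx/dz) z (1 + 2 k2 x^2)), dx/dz = 2 z w_j
      dfib <- dfib + kw * E * (x + 2 * z2 * w_trans[j] * (1 + 2 * k2[j] * x2))
    }
  }
  g <- mu * z + z * fib - mu / (lam2 * z2 * z)
  if (!deriv) return(g)
  gp <- mu + dfib + 3 * mu / (lam2 * z2 * z2)
  list(g = g, gp = gp)
}

# Nominal stress along the loading axis once the transverse stretch z is
# known; p = mu / (lam^2 z^2) from the traction-free thickness face.
loading_stress <- function(z, lam, mu, k1, k2, w_load, w_trans,
                           tension_only = FALSE) {
  lam2 <- lam * lam
  z2 <- z * z
  fib <- 0
  for (j in 1:4) {
    kw <- k1[j] * w_load[j]
    if (kw == 0) next
    x <- lam2 * w_load[j] + z2 * w_trans[j] - 1
    if (tension_only) x[x < 0] <- 0
    fib <- fib + kw * (x * exp(pmin(k2[j] * x * x, 700)))
  }
  mu * lam + lam * fib - mu / (lam2 * lam * z2)
}

# Safeguarded Newton/bisection (compiled) for the transverse stretch at a
# vector of loading stretches. Bracket starts at [1/lam, 1] (between
# incompressible equal contraction and no contraction) and is widened once
# to [0.3, 1.5] if the residual does not change sign there.
solve_transverse_vec <- function(lam, direction, params,
                                 tension_only = FALSE,
                                 tol_stretch = 1e-12, max_iter = 200L) {
  direction <- match_direction(direction)
  geo <- fiber_geometry(params)
  if (direction == "circumferential") {
    w_load <- geo$cos2; w_trans <- geo$sin2
  } else {
    w_load <- geo$sin2; w_trans <- geo$cos2
  }
  sol <- C_solve_transverse(as.numeric(lam), params$mu, geo$k1, geo$k2,
                            w_load, w_trans, tension_only,
                            tol_stretch, as.integer(max_iter))
  if (any(sol$status == -1L))
    stop("transverse-stress equation has no sign change in [0.3, 1.5] ",
         "at loading stretch ",
         format(lam[which(sol$status == -1L)[1]]),
         " (direction ", direction, "); parameters are likely ",
         "inadmissible for this state", call. = FALSE)
  if (any(sol$status == 0L))
    stop("transverse solve did not converge at loading stretch ",
         format(lam[which(sol$status == 0L)[1]]), " (direction ",
         direction, ")", call. = FALSE)
  z <- sol$z
  lam_R <- 1 / (lam * z)
  list(lam_load = lam, lam_trans = z, lam_R = lam_R,
       p = params$mu * lam_R^2, P_load = sol$P_load,
       residual = sol$residual)
}

#' Solve the uniaxial strip problem at one loading stretch
#'
#' Finds the in-plane transverse stretch and hydrostatic multiplier such
#' that only the loading-direction nominal stress is nonzero. The
#' multiplier is eliminated analytically from the traction-free thickness
#' direction (`p = mu * lam_R^2`; exact, since no fiber family has a radial
#' component) and the transverse stretch is found by safeguarded
#' Newton/bisection root-finding, bracketed in `[1/lam, 1]` and widened
#' once to `[0.3, 1.5]` if needed.
#'
#' @param lam_load Loading stretch, `>= 1` (loading branch only).
#' @param direction `"circumferential"` or `"longitudinal"` (may be
#'   abbreviated).
#' @param params A [four_fiber_params()] object.
#' @param tension_only Passed to the constitutive law; see [strain_energy()].
#' @return An object of class `uniaxial_solution`: a list with
#'   `stretches` ([principal_stretches()]), `p` (kPa), `P_load` (nominal
#'   stress, kPa), `residual` (absolute transverse nominal stress, kPa) and
#'   `direction`. The residual satisfies
#'   `residual <= 1e-9 * max(1, P_load)` kPa.
#' @export
#' @examples
#' p <- four_fiber_params(100, 0, 1, 0, 1, 0, 1, 45)
#' s <- solve_transverse(1.2, "circ", p)
#' s$P_load                      # = 100 * (1.2 - 1.2^-2)
solve_transverse <- function(lam_load, direction, params,
                             tension_only = FALSE) {
  direction <- match_direction(direction)
  if (!is.finite(lam_load) || lam_load < 1)
    stop("lam_load must be >= 1 (loading branch only)", call. = FALSE)
  sol <- solve_transverse_vec(lam_load, direction, params, tension_only)
  tol <- 1e-9 * max(1, abs(sol$P_load))
  if (sol$residual > tol)
    stop("transverse stress residual ", format(sol$residual),
         " kPa exceeds tolerance at lam_load = ", format(lam_load),
         call. = FALSE)
  if (direction == "circumferential") {
    st <- principal_stretches(sol$lam_R, lam_load, sol$lam_trans)
  } else {
    st <- principal_stretches(sol$lam_R, sol$lam_trans, lam_load)
  }
  structure(list(stretches = st, p = sol$p, P_load = sol$P_load,
                 residual = sol$residual, direction = direction),
            class = "uniaxial_solution")
}

#' @export
print.uniaxial_solution <- function(x, ...) {
  cat(sprintf("Uniaxial solution (%s strip)\n", x$direction))
  cat(sprintf("  stretches (R, T, Z): %.8f %.8f %.8f\n",
              x$stretches[["lam_R"]], x$stretches[["lam_T"]],
              x$stretches[["lam_Z"]]))
  cat(sprintf("  p = %.6g kPa, P_load = %.6g kPa, residual = %.3g kPa\n",
              x$p, x$P_load, x$residual))
  invisible(x)
}

#' Nominal stress at one or more loading stretches
#'
#' Scalar/vector wrapper over the uniaxial solver; used by the fitting
#' objective, where model stresses are evaluated at the experimental
#' stretches.
#'
#' @inheritParams solve_transverse
#' @param lam_load Numeric vector of loading stretches, all `>= 1`.
#' @return Numeric vector of nominal stresses (kPa).
#' @export
stress_at_stretch <- function(params, direction, lam_load,
                              tension_only = FALSE) {
  direction <- match_direction(direction)
  if (any(!is.finite(lam_load)) || any(lam_load < 1))
    stop("lam_load must be >= 1 (loading branch only)", call. = FALSE)
  solve_transverse_vec(lam_load, direction, params, tension_only)$P_load
}

#' Simulate a uniaxial loading curve
#'
#' Forward-simulates the nominal stress-stretch response of a strip on a
#' uniform stretch grid from 1 to `lam_max`.
#'
#' @inheritParams solve_transverse
#' @param lam_max Maximum loading stretch (> 1).
#' @param n_points Number of grid points (>= 2).
#' @return A data frame with columns `stretch` and `nominal_stress_kPa`,
#'   first row `(1, 0)`.
#' @export
#' @examples
#' p <- four_fiber_params(100, 0, 1, 0, 1, 0, 1, 45)
#' head(simulate_curve(p, "circ", lam_max = 1.3, n_points = 5))
simulate_curve <- function(params, direction, lam_max, n_points = 200L,
                           tension_only = FALSE) {
  direction <- match_direction(direction)
  if (!is.finite(lam_max) || lam_max <= 1) stop("lam_max must be > 1",
                                                call. = FALSE)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  lam <- seq(1, lam_max, length.out = n_points)
  sol <- solve_transverse_vec(lam, direction, params, tension_only)
  data.frame(stretch = lam, nominal_stress_kPa = sol$P_load)
}

# Loading stretch at which the nominal stress reaches P_target (kPa);
# the loading curve is monotone for admissible parameters.
stretch_at_stress <- function(params, direction, P_target,
                              tension_only = FALSE, upper = 1.5) {
  direction <- match_direction(direction)
  f <- function(l) stress_at_stretch(params, direction, l, tension_only) -
    P_target
  stats::uniroot(f, c(1 + 1e-9, upper), extendInt = "upX",
                 tol = 1e-12, maxiter = 200)$root
}
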