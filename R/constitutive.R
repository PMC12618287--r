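#' Principal stretches of a strip in cylindrical material axes
#'
#' The deformation gradient of a strip test is taken diagonal in the
#' cylindrical axes of the vessel (thickness R, circumferential Theta,
#' longitudinal Z); with the two symmetric diagonal fiber families balanced
#' this shear-free form is a consistent modeling assumption for uniaxial
#' strips. Incompressibility, when requested, is enforced to
#' `lam_R * lam_T * lam_Z = 1` within `1e-12`.
#'
#' @param lam_R,lam_T,lam_Z Radial (thickness), circumferential and
#'   longitudinal stretches; all strictly positive.
#' @param check_incompressible If `TRUE`, require `det F = 1` within 1e-12.
#' @return An object of class `principal_stretches` (named numeric vector).
#' @export
#' @examples
#' principal_stretches(1 / 1.2, 1.2, 1)
principal_stretches <- function(lam_R, lam_T, lam_Z,
                                check_incompressible = FALSE) {
  lam <- c(lam_R = as.numeric(lam_R), lam_T = as.numeric(lam_T),
           lam_Z = as.numeric(lam_Z))
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("principal stretches must be finite and > 0", call. = FALSE)
  if (check_incompressible && abs(prod(lam) - 1) > 1e-12)
    stop("stretches violate incompressibility: lam_R*lam_T*lam_Z = ",
         format(prod(lam), digits = 15), call. = FALSE)
  class(lam) <- "principal_stretches"
  lam
}

#' Incompressible stretch state from the two in-plane stretches
#'
#' @param lam_T,lam_Z Circumferential and longitudinal stretches.
#' @return A [principal_stretches()] object with
#'   `lam_R = 1 / (lam_T * lam_Z)`.
#' @export
incompressible_stretches <- function(lam_T, lam_Z) {
  principal_stretches(1 / (lam_T * lam_Z), lam_T, lam_Z)
}

#' Deformation invariants of the four-fiber-family model
#'
#' `I1` is the first principal invariant of the right Cauchy-Green tensor
#' `C = F^T F`; `I4[j]` is the squared stretch of the j-th fiber family,
#' whose unit direction lies in the Theta-Z surface at angle `beta_j` from
#' the circumferential axis, so `I4_j = lam_T^2 cos^2 beta_j +
#' lam_Z^2 sin^2 beta_j`. Families are ordered (circumferential, axial,
#' +beta, -beta); the last two coincide for a diagonal deformation
#' gradient but are carried separately because the energy sums over four
#' families.
#'
#' @param stretches A [principal_stretches()] object.
#' @param params A [four_fiber_params()] object.
#' @return `list(I1 = <scalar>, I4 = <length-4 numeric>)`.
#' @export
#' @examples
#' p <- four_fiber_params(10, 1, 1, 1, 1, 1, 1, 45)
#' invariants(principal_stretches(1, 1, 1), p)   # I1 = 3, all I4 = 1
invariants <- function(stretches, params) {
  stretches <- as_stretches(stretches)
  geo <- fiber_geometry(params)
  I1 <- sum(stretches^2)
  I4 <- stretches[["lam_T"]]^2 * geo$cos2 + stretches[["lam_Z"]]^2 * geo$sin2
  list(I1 = I1, I4 = unname(I4))
}

as_stretches <- function(x) {
  if (inherits(x, "principal_stretches")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(principal_stretches(x[[1]], x[[2]], x[[3]]))
  stop("expected a principal_stretches object or a length-3 numeric",
       call. = FALSE)
}

# Fiber energy term k1/(4 k2) * (exp(k2 x^2) - 1) per family, with x = I4-1.
# k2 -> 0 is a 0/0 limit; below 1e-8 the two-term series
# (k1/4) x^2 (1 + k2 x^2 / 2) is used. Exponent overflow (beyond ~700)
# signals a diverged energy rather than silently returning Inf.
fiber_energy_terms <- function(I4, k1, k2, tension_only = FALSE) {
  x <- I4 - 1
  if (tension_only) x[I4 < 1] <- 0
  e <- k2 * x^2
  if (any(e > 700))
    stop("strain energy diverged: exponential argument ", format(max(e)),
         " exceeds double-precision range", call. = FALSE)
  w <- numeric(length(x))
  small <- k2 < 1e-8
  w[!small] <- k1[!small] / (4 * k2[!small]) * expm1(e[!small])
  w[small] <- k1[small] / 4 * x[small]^2 * (1 + e[small] / 2)
  w
}

# d(fiber energy)/dI4 = (k1/2) (I4-1) exp(k2 (I4-1)^2); finite at k2 = 0.
fiber_dW_dI4 <- function(I4, k1, k2, tension_only = FALSE) {
  x <- I4 - 1
  if (tension_only) x[I4 < 1] <- 0
  0.5 * k1 * x * exp(pmin(k2 * x^2, 700))
}

#' Strain energy density of the four-fiber-family model
#'
#' `W = (mu/2)(I1 - 3) + sum_j k1_j/(4 k2_j) (exp(k2_j (I4_j - 1)^2) - 1)`
#' in kPa, summed over the four families (the two diagonal families are
#' counted separately even though their invariants coincide for a diagonal
#' deformation gradient). `W = 0` at the identity and `W >= 0` for any
#' admissible stretches with non-negative parameters.
#'
#' @inheritParams invariants
#' @param tension_only If `TRUE`, fiber families with `I4 < 1` (shortened
#'   fibers) contribute nothing; the model is phenomenological and the
#'   default evaluates the energy exactly as written, for all `I4`.
#' @return Energy density in kPa (scalar).
#' @export
strain_energy <- function(stretches, params, tension_only = FALSE) {
  stretches <- as_stretches(stretches)
  geo <- fiber_geometry(params)
  inv <- invariants(stretches, params)
  params$mu / 2 * (inv$I1 - 3) +
    sum(fiber_energy_terms(inv$I4, geo$k1, geo$k2, tension_only))
}

#' Analytic first Piola-Kirchhoff principal stresses
#'
#' For a diagonal deformation gradient the nominal (first Piola-Kirchhoff)
#' principal stresses of an incompressible material are
#' `P_ii = dW/dlam_i - p/lam_i`, with `p` the hydrostatic Lagrange
#' multiplier fixed by a traction boundary condition. Fiber families lie in
#' the Theta-Z surface, so they contribute only to `P_TT` and `P_ZZ`:
#' `P_TT = mu lam_T + sum_j k1_j (I4_j - 1) exp(k2_j (I4_j - 1)^2)
#' lam_T cos^2 beta_j - p / lam_T`, and analogously with `sin^2 beta_j`
#' for `P_ZZ`; `P_RR = mu lam_R - p / lam_R`.
#'
#' @inheritParams strain_energy
#' @param p Hydrostatic Lagrange multiplier (kPa).
#' @return Named numeric vector `c(P_RR, P_TT, P_ZZ)` in kPa.
#' @export
#' @examples
#' p <- four_fiber_params(100, 0, 1, 0, 1, 0, 1, 45)
#' # stress-free reference: identity stretches with p = mu
#' pk1_stress(principal_stretches(1, 1, 1), p, p = 100)
pk1_stress <- function(stretches, params, p, tension_only = FALSE) {
  stretches <- as_stretches(stretches)
  geo <- fiber_geometry(params)
  inv <- invariants(stretches, params)
  dWdI4 <- fiber_dW_dI4(inv$I4, geo$k1, geo$k2, tension_only)
  lam_R <- stretches[["lam_R"]]
  lam_T <- stretches[["lam_T"]]
  lam_Z <- stretches[["lam_Z"]]
  # dI4/dlam_T = 2 lam_T cos^2 beta, dI4/dlam_Z = 2 lam_Z sin^2 beta
  c(P_RR = params$mu * lam_R - p / lam_R,
    P_TT = params$mu * lam_T + 2 * lam_T * sum(dWdI4 * geo$cos2) - p / lam_T,
    P_ZZ = params$mu * lam_Z + 2 * lam_Z * sum(dWdI4 * geo$sin2) - p / lam_Z)
}
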