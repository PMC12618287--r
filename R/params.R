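#' Constitutive parameters of the four-fiber-family model
#'
#' Bundles the eight independent parameters of the incompressible
#' four-fiber-family exponential strain energy density function: a
#' neo-Hookean matrix modulus `mu`, a stress-like stiffness `k1` and a
#' dimensionless exponent `k2` for the circumferential (0 degrees),
#' longitudinal (90 degrees) and diagonal fiber families, and the angle
#' `beta_deg` of the two symmetric diagonal families measured from the
#' circumferential axis. The two diagonal families at +/- `beta_deg` share
#' `k1_diag`/`k2_diag` by construction, so only eight numbers are free.
#'
#' @param mu Neo-Hookean shear-like modulus (kPa), strictly positive.
#' @param k1_circ,k1_axial,k1_diag Fiber stiffness parameters (kPa), >= 0.
#' @param k2_circ,k2_axial,k2_diag Dimensionless exponential parameters, > 0
#'   (each appears in a denominator of the energy; values below `1e-8` are
#'   evaluated through a series limit, see [strain_energy()]).
#' @param beta_deg Diagonal-family angle from the circumferential axis, in
#'   degrees, within `[0, 90]`.
#'
#' @return An object of class `four_fiber_params`.
#' @seealso [strain_energy()], [pk1_stress()], [read_params_json()]
#' @export
#' @examples
#' p <- four_fiber_params(mu = 20, k1_circ = 50, k2_circ = 10,
#'                        k1_axial = 30, k2_axial = 5,
#'                        k1_diag = 10, k2_diag = 2, beta_deg = 45)
#' p
four_fiber_params <- function(mu, k1_circ, k2_circ, k1_axial, k2_axial,
                              k1_diag, k2_diag, beta_deg) {
  p <- list(mu = as.numeric(mu),
            k1_circ = as.numeric(k1_circ), k2_circ = as.numeric(k2_circ),
            k1_axial = as.numeric(k1_axial), k2_axial = as.numeric(k2_axial),
            k1_diag = as.numeric(k1_diag), k2_diag = as.numeric(k2_diag),
            beta_deg = as.numeric(beta_deg))
  validate_params(p)
  class(p) <- "four_fiber_params"
  p
}

validate_params <- function(p) {
  for (f in c("mu", "k1_circ", "k2_circ", "k1_axial", "k2_axial",
              "k1_diag", "k2_diag", "beta_deg")) {
    v <- p[[f]]
    if (length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  if (p$mu <= 0) stop("mu must be > 0 (kPa)", call. = FALSE)
  for (f in c("k1_circ", "k1_axial", "k1_diag"))
    if (p[[f]] < 0) stop(f, " must be >= 0 (kPa)", call. = FALSE)
  for (f in c("k2_circ", "k2_axial", "k2_diag"))
    if (p[[f]] <= 0) stop(f, " must be > 0", call. = FALSE)
  if (p$beta_deg < 0 || p$beta_deg > 90)
    stop("beta_deg must lie in [0, 90] degrees", call. = FALSE)
  invisible(p)
}

#' @export
print.four_fiber_params <- function(x, ...) {
  cat("Four-fiber-family constitutive parameters\n")
  cat(sprintf("  mu      = %.6g kPa (neo-Hookean matrix)\n", x$mu))
  cat(sprintf("  circ  (beta = 0):   k1 = %.6g kPa, k2 = %.6g\n",
              x$k1_circ, x$k2_circ))
  cat(sprintf("  axial (beta = 90):  k1 = %.6g kPa, k2 = %.6g\n",
              x$k1_axial, x$k2_axial))
  cat(sprintf("  diag  (beta = +/-%.4g deg): k1 = %.6g kPa, k2 = %.6g\n",
              x$beta_deg, x$k1_diag, x$k2_diag))
  invisible(x)
}

# Per-family geometry and stiffness in the fixed order
# (circumferential, axial, +beta, -beta). Angles are stored internally in
# radians; cos^2/sin^2 of the two diagonal families coincide.
fiber_geometry <- function(params) {
  b <- params$beta_deg * pi / 180
  ang <- c(0, pi / 2, b, -b)
  list(cos2 = cos(ang)^2,
       sin2 = sin(ang)^2,
       k1 = c(params$k1_circ, params$k1_axial, params$k1_diag, params$k1_diag),
       k2 = c(params$k2_circ, params$k2_axial, params$k2_diag, params$k2_diag))
}

.param_json_keys <- c(mu = "mu_kPa",
                      k1_circ = "k1_circ_kPa", k2_circ = "k2_circ",
                      k1_axial = "k1_axial_kPa", k2_axial = "k2_axial",
                      k1_diag = "k1_diag_kPa", k2_diag = "k2_diag",
                      beta_deg = "beta_deg")

#' Read and write constitutive parameter files
#'
#' Flat JSON with keys `mu_kPa`, `k1_circ_kPa`, `k2_circ`, `k1_axial_kPa`,
#' `k2_axial`, `k1_diag_kPa`, `k2_diag`, `beta_deg`. Unknown keys are an
#' error, as are missing or non-scalar values.
#'
#' @param path File path.
#' @return `read_params_json()` returns a [four_fiber_params()] object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(x), unname(.param_json_keys))
  if (length(extra))
    stop("unknown keys in parameter file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(unname(.param_json_keys), names(x))
  if (length(miss))
    stop("missing keys in parameter file: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- lapply(.param_json_keys, function(k) x[[k]])
  do.call(four_fiber_params, stats::setNames(vals, names(.param_json_keys)))
}

#' @rdname read_params_json
#' @param params A [four_fiber_params()] object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "four_fiber_params"))
  out <- stats::setNames(lapply(names(.param_json_keys),
                                function(f) params[[f]]),
                         unname(.param_json_keys))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
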