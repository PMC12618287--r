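#' Configuration of the global parameter identification
#'
#' The eight constitutive parameters are identified by a seeded multistart
#' global search: starting points are drawn by Latin hypercube sampling
#' over the (log-transformed) parameter box and each is refined by
#' bound-constrained L-BFGS-B; the best refined optimum is polished once
#' more. The search space uses log10 scales for `mu`, `k1` and `k2`
#' (tabulated `k2` values for venous tissue span roughly four orders of
#' magnitude) and `beta_deg/90` for the angle.
#'
#' @param lower,upper Named numeric vectors of bounds in natural units
#'   (kPa / dimensionless / degrees) with names `mu`, `k1_circ`,
#'   `k2_circ`, `k1_axial`, `k2_axial`, `k1_diag`, `k2_diag`, `beta_deg`.
#'   Defaults span the magnitudes reported for venous tissue with
#'   headroom: `mu` in \[1e-3, 5e3\] kPa, each `k1` in \[1e-3, 5e4\] kPa
#'   (the lower bound is a log-scale floor, effectively zero), each `k2`
#'   in \[1e-6, 5e4\], `beta_deg` in \[0, 90\].
#' @param n_multistarts Number of Latin hypercube starting points
#'   (default 32).
#' @param max_evals Approximate objective-evaluation budget per start
#'   (default 2000); translated into an L-BFGS-B iteration cap given that
#'   each iteration costs `1 + 2 * 8` evaluations with finite-difference
#'   gradients.
#' @param seed Integer seed fixing the whole optimization trajectory
#'   (default 20230515).
#' @param weights Length-2 numeric, per-direction weights
#'   `c(circ, long)` multiplying each direction's sum of squares
#'   (default `c(1, 1)`, i.e. the plain unweighted objective).
#' @param tension_only Passed to the constitutive law.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(lower = NULL, upper = NULL, n_multistarts = 32L,
                       max_evals = 2000L, seed = 20230515L,
                       weights = c(circ = 1, long = 1),
                       tension_only = FALSE) {
  def_lower <- c(mu = 1e-3, k1_circ = 1e-3, k2_circ = 1e-6,
                 k1_axial = 1e-3, k2_axial = 1e-6,
                 k1_diag = 1e-3, k2_diag = 1e-6, beta_deg = 0)
  def_upper <- c(mu = 5e3, k1_circ = 5e4, k2_circ = 5e4,
                 k1_axial = 5e4, k2_axial = 5e4,
                 k1_diag = 5e4, k2_diag = 5e4, beta_deg = 90)
  lo <- def_lower; up <- def_upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper
  stopifnot(all(lo > 0 | names(lo) == "beta_deg"), all(up > lo),
            n_multistarts >= 1, max_evals >= 10,
            length(weights) == 2, all(weights > 0))
  structure(list(lower = lo, upper = up,
                 n_multistarts = as.integer(n_multistarts),
                 max_evals = as.integer(max_evals),
                 seed = as.integer(seed),
                 weights = stats::setNames(as.numeric(weights),
                                           c("circ", "long")),
                 tension_only = isTRUE(tension_only)),
            class = "fit_config")
}

.check_curve_pair <- function(curves) {
  stopifnot(is.list(curves), all(c("circ", "long") %in% names(curves)))
  lapply(curves[c("circ", "long")], .as_curve_df)
}

#' Least-squares objective of the constitutive fit
#'
#' `Q = sum_i [ w_c (P_circ_exp - P_circ_mod)_i^2 +
#' w_l (P_long_exp - P_long_mod)_i^2 ]` in kPa^2, where the model stresses
#' are evaluated at the experimental stretches through the uniaxial solver
#' (so the zero-transverse-stress constraints are satisfied exactly at
#' every point rather than through penalty terms). Default weights are 1.
#'
#' @param params A [four_fiber_params()] object.
#' @param curves List with elements `circ` and `long`, each a data frame
#'   with columns `stretch` and `nominal_stress_kPa` (typically
#'   [build_representative()] output).
#' @param weights Length-2 per-direction weights `c(circ, long)`.
#' @param tension_only Passed to the constitutive law.
#' @return The objective value (kPa^2). If the uniaxial solver fails at
#'   any point the objective is infeasible: an error of class
#'   `veinfit_infeasible` naming the failing point is thrown.
#' @export
objective <- function(params, curves, weights = c(circ = 1, long = 1),
                      tension_only = FALSE) {
  curves <- .check_curve_pair(curves)
  dirs <- c(circ = "circumferential", long = "longitudinal")
  Q <- 0
  for (d in names(dirs)) {
    cv <- curves[[d]]
    Pmod <- tryCatch(
      stress_at_stretch(params, dirs[[d]], cv$stretch, tension_only),
      error = function(e) {
        cond <- structure(
          class = c("veinfit_infeasible", "error", "condition"),
          list(message = paste0("objective infeasible (", dirs[[d]],
                                " direction): ", conditionMessage(e)),
               call = NULL))
        stop(cond)
      })
    w <- if (d == "circ") weights[[1]] else weights[[2]]
    Q <- Q + w * sum((cv$nominal_stress_kPa - Pmod)^2)
  }
  Q
}

#' Coefficient of determination of the fit in one direction
#'
#' `R^2 = 1 - SS_res / SS_tot` over the curve's nominal stresses, with
#' `SS_tot` taken about the mean experimental stress.
#'
#' @inheritParams objective
#' @param curve Data frame with `stretch` and `nominal_stress_kPa`.
#' @param direction `"circumferential"` or `"longitudinal"`.
#' @return `R^2` (dimensionless, `<= 1`); `NA` with a warning when the
#'   experimental stresses have zero variance (undefined).
#' @export
r_squared <- function(params, curve, direction, tension_only = FALSE) {
  curve <- .as_curve_df(curve)
  direction <- match_direction(direction)
  stopifnot(nrow(curve) >= 2)
  Pmod <- stress_at_stretch(params, direction, curve$stretch, tension_only)
  .r2_values(curve$nominal_stress_kPa, Pmod)
}

# 1 - SS_res/SS_tot on paired stress vectors; NA when SS_tot is zero.
.r2_values <- function(Pexp, Pmod) {
  ss_tot <- sum((Pexp - mean(Pexp))^2)
  if (ss_tot == 0) {
    warning("R^2 undefined: experimental stresses have zero variance")
    return(NA_real_)
  }
  1 - sum((Pexp - Pmod)^2) / ss_tot
}

# <-> transformed optimizer coordinates: log10 for mu/k1/k2, beta/90.
.to_x <- function(v) c(log10(v[1:7]), v[8] / 90)
.from_x <- function(x) c(10^x[1:7], 90 * x[8])

.params_from_vec <- function(v) {
  four_fiber_params(mu = v[[1]], k1_circ = v[[2]], k2_circ = v[[3]],
                    k1_axial = v[[4]], k2_axial = v[[5]],
                    k1_diag = v[[6]], k2_diag = v[[7]], beta_deg = v[[8]])
}

#' Identify the eight constitutive parameters from a pair of curves
#'
#' Constrained global least-squares fit of the four-fiber-family model to
#' a donor's circumferential and longitudinal representative curves, by
#' seeded Latin-hypercube multistart plus L-BFGS-B refinement (see
#' [fit_config()]). The parameter symmetry constraints (shared diagonal
#' family, fixed 0/90-degree families) are enforced by construction of
#' [four_fiber_params()]. The result is deterministic given the seed.
#'
#' @inheritParams objective
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: list with `params`
#'   ([four_fiber_params()]), `Q` (kPa^2, recomputed at the optimum),
#'   `R2_circ`, `R2_long`, `converged`, `n_evals`, `n_starts`, `seed`.
#' @export
fit_four_fiber <- function(curves, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  curves <- .check_curve_pair(curves)

  lo_x <- .to_x(config$lower)
  up_x <- .to_x(config$upper)
  n_evals <- 0L
  penalized <- function(x) {
    n_evals <<- n_evals + 1L
    q <- tryCatch(
      objective(.params_from_vec(.from_x(x)), curves, config$weights,
                config$tension_only),
      veinfit_infeasible = function(e) NA_real_,
      error = function(e) NA_real_)
    if (!is.finite(q)) 1e15 else q
  }

  # starting points: one slope-based heuristic + Latin hypercube draws
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  starts <- c(list(.heuristic_start(curves, config)),
              .staged_starts(curves, config))
  if (config$n_multistarts > 1L) {
    u <- lhs::randomLHS(config$n_multistarts - 1L, 8L)
    for (i in seq_len(nrow(u)))
      starts[[length(starts) + 1L]] <- lo_x + u[i, ] * (up_x - lo_x)
  }

  maxit <- max(10L, config$max_evals %/% 17L)  # fd gradient: 1 + 2*8 evals
  run_local <- function(x0, itcap) {
    stats::optim(pmin(pmax(x0, lo_x), up_x), penalized,
                 method = "L-BFGS-B", lower = lo_x, upper = up_x,
                 control = list(maxit = itcap, factr = 1e7))
  }
  results <- lapply(starts, function(x0)
    tryCatch(run_local(x0, maxit), error = function(e) NULL))
  vals <- vapply(results, function(r) if (is.null(r)) Inf else r$value, 0)
  if (!any(is.finite(vals) & vals < 1e15)) {
    diag <- paste0("start ", seq_along(vals), ": ",
                   ifelse(is.finite(vals) & vals < 1e15, format(vals),
                          "infeasible"), collapse = "; ")
    stop("all multistarts infeasible - ", diag, call. = FALSE)
  }
  best <- results[[which.min(vals)]]

  # basin-hopping refinement: perturbed restarts around the incumbent,
  # cycling wide and narrow steps (log10 units), deterministic under the
  # seed; guards against the strongly correlated k1/k2 landscape trapping
  # the multistart phase
  for (sigma in rep(c(1.0, 0.5, 0.25, 0.1), 4L)) {
    x_try <- best$par + stats::rnorm(8L, 0, sigma)
    # occasional uniform re-draw of single coordinates: a Gaussian hop in
    # log space cannot wake a fiber family parked at the k1 floor
    kick <- stats::runif(8L) < 0.25
    x_try[kick] <- lo_x[kick] +
      stats::runif(sum(kick)) * (up_x - lo_x)[kick]
    cand <- tryCatch(run_local(x_try, maxit), error = function(e) NULL)
    if (!is.null(cand) && is.finite(cand$value) && cand$value < best$value)
      best <- cand
  }
  polish <- tryCatch(run_local(best$par, 2L * maxit), error = function(e) best)
  if (is.finite(polish$value) && polish$value <= best$value) best <- polish

  params <- .params_from_vec(.from_x(best$par))
  Q <- objective(params, curves, config$weights, config$tension_only)
  structure(list(params = params, Q = Q,
                 R2_circ = r_squared(params, curves$circ, "circumferential",
                                     config$tension_only),
                 R2_long = r_squared(params, curves$long, "longitudinal",
                                     config$tension_only),
                 converged = best$convergence == 0,
                 n_evals = n_evals, n_starts = length(starts),
                 seed = config$seed),
            class = "fit_result")
}

# Staged deterministic starts. The four-family model can explain a pair
# of strip curves through several distinct structural hypotheses (on-axis
# families only, circumferential + diagonal, axial + diagonal, diagonal
# dominated); the joint 8-parameter landscape has a separate basin for
# each, so one low-dimensional staged fit per hypothesis supplies the
# global phase with a starting point inside every basin.
.staged_starts <- function(curves, config) {
  lo_mu <- log10(config$lower[["mu"]])
  up_mu <- log10(config$upper[["mu"]])

  # partial objective with a subset of transformed coordinates free and
  # the rest pinned; x_full is in the transformed (log10 / beta-fraction)
  # space of .from_x
  dir_of <- c(circ = "circumferential", long = "longitudinal")
  pinned <- function(free_idx, x_base, dirs) {
    function(x_free) {
      x_full <- x_base
      x_full[free_idx] <- x_free
      q <- tryCatch({
        p <- .params_from_vec(.from_x(x_full))
        s <- 0
        for (d in dirs) {
          cv <- curves[[d]]
          s <- s + sum((cv$nominal_stress_kPa -
                          stress_at_stretch(p, dir_of[[d]], cv$stretch,
                                            config$tension_only))^2)
        }
        s
      }, error = function(e) Inf)
      if (!is.finite(q)) 1e15 else q
    }
  }
  # refine the free block from each initialization and keep the top
  # distinct local optima: a single J-shaped curve constrains (k1, k2)
  # only weakly, and the jointly correct pair is not always the best in
  # the one-direction stage
  sub_opt <- function(free_idx, x_base, inits, lower, upper,
                      dirs = c("circ", "long"), n_keep = 1L) {
    cands <- list()
    for (i in seq_len(nrow(inits))) {
      r <- tryCatch(
        stats::optim(inits[i, ], pinned(free_idx, x_base, dirs),
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 50)),
        error = function(e) NULL)
      if (!is.null(r) && is.finite(r$value)) cands[[length(cands) + 1L]] <- r
    }
    if (!length(cands)) return(NULL)
    cands <- cands[order(vapply(cands, `[[`, 0, "value"))]
    kept <- list()
    for (r in cands) {
      dup <- any(vapply(kept, function(k)
        max(abs(k$par - r$par)) < 0.2, TRUE))
      if (!dup) kept[[length(kept) + 1L]] <- r
      if (length(kept) >= n_keep) break
    }
    lapply(kept, function(r) {
      x_base[free_idx] <- r$par
      x_base
    })
  }
  floor_x <- c(0.7, -3, 0, -3, 0, -3, 0, 0.5)   # all families dormant
  grid3 <- as.matrix(expand.grid(0.7, c(0, 1.5, 3), c(0, 1.5, 3)))
  out <- list()

  # on-axis hypothesis: mu + circumferential family against the circ
  # curve, then mu + axial family against the long curve; the top two
  # distinct (k1, k2) basins of each stage are crossed
  xs_c <- sub_opt(c(1, 2, 3), floor_x, grid3,
                  lower = c(lo_mu, -3, -6), upper = c(up_mu, 4.7, 4.7),
                  dirs = "circ", n_keep = 2L)
  xs_a <- sub_opt(c(1, 4, 5), floor_x, grid3,
                  lower = c(lo_mu, -3, -6), upper = c(up_mu, 4.7, 4.7),
                  dirs = "long", n_keep = 2L)
  first <- TRUE
  for (x_c in xs_c) for (x_a in xs_a) {
    onax <- c(mean(c(x_c[1], x_a[1])), x_c[2], x_c[3], x_a[4], x_a[5],
              -3, 0, 0.5)
    out <- c(out, list(onax))
    if (first)    # low-matrix variant only for the leading pair
      out <- c(out, list(replace(onax, 1, min(x_c[1], x_a[1]))))
    first <- FALSE
  }

  # the two stages generally disagree on the matrix modulus (each absorbs
  # its direction's linear stiffness into mu); the model can realize both
  # at once by keeping the smaller mu and parking the diagonal pair on
  # the stiffer axis (beta -> 90 or 0 deg) as a near-linear (k2 -> 0)
  # pseudo-matrix with the small-strain slope deficit 0.75 (mu_hi - mu_lo)
  if (length(xs_c) && length(xs_a)) {
    x_c <- xs_c[[1]]; x_a <- xs_a[[1]]
    mu_c <- 10^x_c[1]; mu_a <- 10^x_a[1]
    k1d <- log10(max(0.75 * abs(mu_a - mu_c), 1e-3))
    comb <- c(min(x_c[1], x_a[1]), x_c[2], x_c[3], x_a[4], x_a[5],
              k1d, -3, if (mu_a > mu_c) 0.995 else 0.005)
    out <- c(out, list(comb))
  }

  # diagonal-dominated hypothesis: mu + diagonal family (angle free)
  # against both curves
  grid_d <- as.matrix(expand.grid(0.7, c(0.5, 2.5), c(0.5, 2.5), 0.5))
  xs_d <- sub_opt(c(1, 6, 7, 8), floor_x, grid_d,
                  lower = c(lo_mu, -3, -6, 0.01),
                  upper = c(up_mu, 4.7, 4.7, 0.99))
  out <- c(out, xs_d)

  # mixed hypotheses: one on-axis family plus the diagonal pair, the
  # diagonal block refined with the on-axis block pinned
  grid_m <- as.matrix(expand.grid(c(0.5, 2.5), c(0.5, 2.5), 0.5))
  for (x_on in c(xs_c[1], xs_a[1])) {
    if (is.null(x_on)) next
    mix <- sub_opt(c(6, 7, 8), x_on, grid_m,
                   lower = c(-3, -6, 0.01), upper = c(4.7, 4.7, 0.99))
    out <- c(out, mix)
  }
  out
}

# Deterministic starting point: mu from the initial slope of the softer
# curve (small-strain incompressible stiffness E ~ 3 mu), mid-range fiber
# stiffness, diagonal families at 45 degrees.
.heuristic_start <- function(curves, config) {
  slope0 <- function(cv) {
    i <- utils::head(order(cv$nominal_stress_kPa), 5L)
    eps <- cv$stretch[i] - 1
    s <- stats::cov(eps, cv$nominal_stress_kPa[i]) / stats::var(eps)
    if (!is.finite(s) || s <= 0) 100 else s
  }
  mu0 <- min(slope0(curves$circ), slope0(curves$long)) / 3
  clamp <- function(v, f) min(max(v, config$lower[[f]]), config$upper[[f]])
  v <- c(clamp(mu0, "mu"),
         clamp(10, "k1_circ"), clamp(10, "k2_circ"),
         clamp(10, "k1_axial"), clamp(10, "k2_axial"),
         clamp(10, "k1_diag"), clamp(10, "k2_diag"), 45)
  .to_x(v)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Four-fiber-family fit\n")
  cat(sprintf("  Q = %.6g kPa^2, R2 (circ) = %.4f, R2 (long) = %.4f\n",
              x$Q, x$R2_circ, x$R2_long))
  cat(sprintf("  %d starts, %d objective evaluations, seed %d, %s\n",
              x$n_starts, x$n_evals, x$seed,
              if (x$converged) "converged" else "iteration cap reached"))
  print(x$params)
  invisible(x)
}
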