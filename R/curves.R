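#' Specimen record for one uniaxial strip test
#'
#' Holds the identity and raw samples of a single tested strip. Samples are
#' either already reduced to `(stretch, nominal_stress_kPa)` pairs or raw
#' `(elongation_mm, force_N)` pairs, in which case the undeformed strip
#' geometry (width, thickness, gauge length) is needed to convert; see
#' [to_nominal_stress()].
#'
#' @param specimen_id,donor_id Character identifiers.
#' @param vein_type `"BV"` (basilic) or `"GSV"` (great saphenous).
#' @param direction `"circumferential"` or `"longitudinal"`.
#' @param samples Data frame with columns `stretch` and
#'   `nominal_stress_kPa`, or `elongation_mm` and `force_N`.
#' @param width_mm,thickness_mm,gauge_length_mm Undeformed geometry
#'   (optional unless `samples` is force-elongation).
#' @return An object of class `specimen_record`.
#' @export
specimen_record <- function(specimen_id, donor_id, vein_type, direction,
                            samples, width_mm = NA_real_,
                            thickness_mm = NA_real_,
                            gauge_length_mm = NA_real_) {
  direction <- match_direction(direction)
  vein_type <- match.arg(vein_type, c("BV", "GSV"))
  stopifnot(is.data.frame(samples))
  has_stress <- all(c("stretch", "nominal_stress_kPa") %in% names(samples))
  has_force <- all(c("elongation_mm", "force_N") %in% names(samples))
  if (!has_stress && !has_force)
    stop("samples must have columns (stretch, nominal_stress_kPa) or ",
         "(elongation_mm, force_N)", call. = FALSE)
  structure(list(specimen_id = as.character(specimen_id),
                 donor_id = as.character(donor_id),
                 vein_type = vein_type, direction = direction,
                 width_mm = width_mm, thickness_mm = thickness_mm,
                 gauge_length_mm = gauge_length_mm,
                 samples = samples),
            class = "specimen_record")
}

#' @export
print.specimen_record <- function(x, ...) {
  cat(sprintf("Specimen %s (donor %s, %s, %s): %d samples\n",
              x$specimen_id, x$donor_id, x$vein_type, x$direction,
              nrow(x$samples)))
  invisible(x)
}

#' Convert force-elongation samples to nominal stress and stretch
#'
#' Nominal (first Piola-Kirchhoff) stress is force over the undeformed
#' cross-section `width * thickness`; stretch is
#' `1 + elongation / gauge_length`. Records already carrying
#' `(stretch, nominal_stress_kPa)` pass through unchanged.
#'
#' @param record A [specimen_record()].
#' @return The record with `samples` holding `stretch` and
#'   `nominal_stress_kPa` columns (kPa).
#' @export
#' @examples
#' r <- specimen_record("s1", "d1", "BV", "circ",
#'                      data.frame(elongation_mm = c(0, 1),
#'                                 force_N = c(0, 0.5)),
#'                      width_mm = 4, thickness_mm = 0.5,
#'                      gauge_length_mm = 10)
#' to_nominal_stress(r)$samples   # 0.5 N / 2 mm^2 = 250 kPa
to_nominal_stress <- function(record) {
  stopifnot(inherits(record, "specimen_record"))
  s <- record$samples
  if (all(c("stretch", "nominal_stress_kPa") %in% names(s)))
    return(record)
  for (f in c("width_mm", "thickness_mm", "gauge_length_mm"))
    if (!is.finite(record[[f]]) || record[[f]] <= 0)
      stop("force-elongation specimen '", record$specimen_id,
           "' needs positive ", f, " to convert to nominal stress",
           call. = FALSE)
  area_mm2 <- record$width_mm * record$thickness_mm
  # N / mm^2 = MPa; 1 MPa = 1000 kPa
  record$samples <- data.frame(
    stretch = 1 + s$elongation_mm / record$gauge_length_mm,
    nominal_stress_kPa = 1000 * s$force_N / area_mm2)
  record
}

#' Clean a raw loading branch
#'
#' Prepares a specimen's loading branch for averaging: re-references the
#' curve to its first sample (stretch divided by the initial stretch,
#' stress shifted by the initial stress, so the curve starts at `(1, 0)`),
#' then prunes to a strictly increasing envelope in both stretch and
#' stress (greedy isotonic pruning, which also collapses duplicated
#' stretches). Measurement noise and a small pre-load toe are thereby
#' removed without smoothing.
#'
#' @param record A [specimen_record()] with stress-stretch samples.
#' @param min_points Minimum number of surviving samples; fewer is a
#'   rejection (error of class `veinfit_specimen_rejected`).
#' @return The record with cleaned `samples`.
#' @export
clean_loading_branch <- function(record, min_points = 5L) {
  record <- to_nominal_stress(record)
  s <- record$samples
  if (nrow(s) < 1) stop("specimen '", record$specimen_id, "' has no samples",
                        call. = FALSE)
  lam <- s$stretch / s$stretch[1]
  P <- s$nominal_stress_kPa - s$nominal_stress_kPa[1]
  keep <- logical(length(lam))
  keep[1] <- TRUE
  last_lam <- lam[1]
  last_P <- P[1]
  for (i in seq_along(lam)[-1]) {
    if (lam[i] > last_lam && P[i] > last_P) {
      keep[i] <- TRUE
      last_lam <- lam[i]
      last_P <- P[i]
    }
  }
  if (sum(keep) < min_points) {
    cond <- structure(
      class = c("veinfit_specimen_rejected", "error", "condition"),
      list(message = paste0("specimen '", record$specimen_id, "' rejected: ",
                            sum(keep), " samples survive cleaning (minimum ",
                            min_points, ")"),
           call = NULL))
    stop(cond)
  }
  record$samples <- data.frame(stretch = lam[keep],
                               nominal_stress_kPa = P[keep])
  record
}

#' Representative averaged loading curve for one donor and direction
#'
#' Builds the per-donor representative curve fitted by the constitutive
#' model: `m` nominal-stress levels uniformly spaced on
#' `(0, stress_max]` (so `m = 20`, `stress_max = 200` gives the grid 10,
#' 20, ..., 200 kPa); at each level every specimen's stretch is read off by
#' monotone piecewise-linear interpolation of stretch versus stress, and
#' the stretches are averaged arithmetically across specimens.
#'
#' Averaging is stress-parameterized because the representative curves are
#' constructed over a fixed nominal-stress range; set
#' `parameterization = "stretch"` for the transposed convention (average
#' stress at `m` uniform stretch levels), and `anchor = TRUE` to prepend
#' the reference point `(1, 0)`.
#'
#' @param records List of cleaned [specimen_record()]s, all from one donor
#'   and direction; at least 2.
#' @param m Number of grid points (default 20).
#' @param stress_max Upper end of the nominal-stress range (kPa,
#'   default 200).
#' @param on_short What to do when a specimen does not reach `stress_max`:
#'   `"truncate"` (default) lowers the range to the common maximum with a
#'   message, `"reject"` errors.
#' @param anchor Prepend the `(1, 0)` reference point (default `FALSE`).
#' @param parameterization `"stress"` (default) or `"stretch"`.
#' @return An object of class `representative_curve`: a data frame with
#'   columns `stretch`, `nominal_stress_kPa` and attributes `donor_id`,
#'   `direction`, `m`, `stress_max`.
#' @export
build_representative <- function(records, m = 20L, stress_max = 200,
                                 on_short = c("truncate", "reject"),
                                 anchor = FALSE,
                                 parameterization = c("stress", "stretch")) {
  on_short <- match.arg(on_short)
  parameterization <- match.arg(parameterization)
  stopifnot(length(records) >= 2L, m >= 2L, stress_max > 0)
  records <- lapply(records, function(r) {
    stopifnot(inherits(r, "specimen_record"))
    to_nominal_stress(r)
  })
  donor <- unique(vapply(records, `[[`, "", "donor_id"))
  dir <- unique(vapply(records, `[[`, "", "direction"))
  if (length(donor) != 1L || length(dir) != 1L)
    stop("all records must share one donor_id and one direction",
         call. = FALSE)

  max_P <- vapply(records, function(r) max(r$samples$nominal_stress_kPa), 0)
  common <- min(max_P)
  if (common < stress_max) {
    if (on_short == "reject")
      stop("specimen(s) reach only ", format(common),
           " kPa < stress_max = ", stress_max, " kPa", call. = FALSE)
    message("representative curve for donor ", donor, " (", dir,
            "): stress_max truncated from ", stress_max, " to ",
            format(common), " kPa (shortest specimen)")
    stress_max <- common
  }

  if (parameterization == "stress") {
    grid_P <- seq(stress_max / m, stress_max, length.out = m)
    lam_mat <- vapply(records, function(r) {
      s <- r$samples
      stats::approx(s$nominal_stress_kPa, s$stretch, xout = grid_P,
                    method = "linear", ties = "ordered")$y
    }, numeric(m))
    out <- data.frame(stretch = rowMeans(as.matrix(lam_mat)),
                      nominal_stress_kPa = grid_P)
  } else {
    lam_at_max <- vapply(records, function(r) {
      s <- r$samples
      stats::approx(s$nominal_stress_kPa, s$stretch, xout = stress_max,
                    ties = "ordered")$y
    }, 0)
    lam_top <- min(lam_at_max)
    grid_lam <- seq(1 + (lam_top - 1) / m, lam_top, length.out = m)
    P_mat <- vapply(records, function(r) {
      s <- r$samples
      stats::approx(s$stretch, s$nominal_stress_kPa, xout = grid_lam,
                    ties = "ordered")$y
    }, numeric(m))
    out <- data.frame(stretch = grid_lam,
                      nominal_stress_kPa = rowMeans(as.matrix(P_mat)))
  }
  if (anchor)
    out <- rbind(data.frame(stretch = 1, nominal_stress_kPa = 0), out)
  structure(out, donor_id = donor, direction = dir, m = m,
            stress_max = stress_max,
            class = c("representative_curve", "data.frame"))
}
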