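#' @title Synthetic virtual uniaxial experiments
#' @description Generates virtual tensile-test studies with the
#'   statistical structure of a human vein characterization campaign:
#'   a handful of donors, 3-4 strips per direction per donor, J-shaped
#'   anisotropic loading curves reaching beyond 200 kPa nominal stress,
#'   multiplicative stress noise, per-specimen stretch-scale variability
#'   and occasional failed experiments. Every draw is reproducible from
#'   the study seed, so the generated files double as fixtures for
#'   end-to-end parameter-recovery tests.
#' @name synthetic
NULL

#' Synthetic study configuration
#'
#' @param n_donors Number of virtual donors (default 10, half `BV` half
#'   `GSV`).
#' @param specimens_per_direction Candidate specimen counts per donor and
#'   direction; one is drawn uniformly per donor/direction (default
#'   `3:4`).
#' @param noise_stress_rel Standard deviation of the log-normal
#'   multiplicative stress noise per sample point (default 0.05).
#' @param specimen_scale_sd Standard deviation of the log-normal
#'   per-specimen scale applied to engineering strain `stretch - 1`,
#'   emulating gauge/clamping variation (default 0.05).
#' @param dropout_prob Probability that a specimen's experiment fails and
#'   is discarded (default 0.07, roughly 5 failures in 68 attempts); the
#'   dropout mask is redrawn if fewer than 2 specimens per direction would
#'   survive.
#' @param n_points Sample points per specimen (default 150, a
#'   20 Hz-camera-over-minutes regime).
#' @param stress_max Nominal-stress range the study must cover (kPa,
#'   default 200); specimens are simulated to 10% above it.
#' @param seed Integer seed (default 1).
#' @return An object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_donors = 10L,
                                   specimens_per_direction = 3:4,
                                   noise_stress_rel = 0.05,
                                   specimen_scale_sd = 0.05,
                                   dropout_prob = 0.07,
                                   n_points = 150L,
                                   stress_max = 200,
                                   seed = 1L) {
  stopifnot(n_donors >= 1, all(specimens_per_direction >= 2),
            noise_stress_rel >= 0, specimen_scale_sd >= 0,
            dropout_prob >= 0, dropout_prob < 1,
            n_points >= 10, stress_max > 0)
  structure(list(n_donors = as.integer(n_donors),
                 specimens_per_direction = as.integer(specimens_per_direction),
                 noise_stress_rel = noise_stress_rel,
                 specimen_scale_sd = specimen_scale_sd,
                 dropout_prob = dropout_prob,
                 n_points = as.integer(n_points),
                 stress_max = stress_max,
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

#' Draw admissible donor-level constitutive parameters
#'
#' Parameters are drawn from log-uniform ranges bracketing the magnitudes
#' reported for venous tissue (`mu` 1-1e3 kPa, each `k1` 1-2e3 kPa, each
#' `k2` 0.5-5e3, `beta_deg` uniform 30-80 degrees) and screened for
#' admissibility: simulated loading curves in both directions must be
#' strictly monotone up to `stress_max` and reach it at a physically
#' plausible stretch (between 1.02 and 2.2). Inadmissible draws are
#' rejected and redrawn. Uses the current R random number stream.
#'
#' @param group `"BV"` or `"GSV"`; kept as a label (the tabulated ranges
#'   of the two vein groups overlap, so both draw from the same regime).
#' @param stress_max Admissibility screening stress (kPa, default 200).
#' @param max_tries Redraw budget (default 100).
#' @return A [four_fiber_params()] object with attribute `group`.
#' @export
draw_donor_params <- function(group = c("BV", "GSV"), stress_max = 200,
                              max_tries = 100L) {
  group <- match.arg(group)
  runif_log <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  for (try in seq_len(max_tries)) {
    cand <- four_fiber_params(mu = runif_log(1, 1e3),
                              k1_circ = runif_log(1, 2e3),
                              k2_circ = runif_log(0.5, 5e3),
                              k1_axial = runif_log(1, 2e3),
                              k2_axial = runif_log(0.5, 5e3),
                              k1_diag = runif_log(1, 2e3),
                              k2_diag = runif_log(0.5, 5e3),
                              beta_deg = stats::runif(1, 30, 80))
    ok <- tryCatch({
      for (dir in .direction_levels) {
        lam_top <- stretch_at_stress(cand, dir, stress_max)
        if (lam_top < 1.02 || lam_top > 2.2) stop("implausible stretch range")
        P <- simulate_curve(cand, dir, lam_top, n_points = 100L)
        if (any(diff(P$nominal_stress_kPa) <= 0)) stop("non-monotone curve")
      }
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(structure(cand, group = group))
  }
  stop("no admissible parameter draw in ", max_tries, " tries", call. = FALSE)
}

#' Generate one noisy virtual specimen
#'
#' Forward-simulates the loading branch to 10% above `stress_max` on a
#' uniform stretch grid, then applies a per-specimen multiplicative scale
#' `exp(N(0, specimen_scale_sd))` to the engineering strain and i.i.d.
#' multiplicative noise `exp(N(0, noise_stress_rel))` to each stress
#' sample. Noise is multiplicative on stress because tensile data scatter
#' grows with load (heteroscedastic). Uses the current R random number
#' stream.
#'
#' @param truth A [four_fiber_params()] object (the donor's ground truth).
#' @param direction Strip direction.
#' @param specimen_id,donor_id,vein_type Labels for the record.
#' @param noise_stress_rel,specimen_scale_sd,n_points,stress_max See
#'   [synthetic_study_config()].
#' @return A [specimen_record()] with stress-stretch samples.
#' @export
generate_specimen <- function(truth, direction, specimen_id = "spec",
                              donor_id = "donor", vein_type = "BV",
                              noise_stress_rel = 0.05,
                              specimen_scale_sd = 0.05,
                              n_points = 150L, stress_max = 200) {
  direction <- match_direction(direction)
  lam_top <- stretch_at_stress(truth, direction, 1.1 * stress_max)
  base <- simulate_curve(truth, direction, lam_top, n_points = n_points)
  scale <- exp(stats::rnorm(1, 0, specimen_scale_sd))
  noise <- exp(stats::rnorm(n_points, 0, noise_stress_rel))
  specimen_record(specimen_id, donor_id, vein_type, direction,
                  samples = data.frame(
                    stretch = 1 + scale * (base$stretch - 1),
                    nominal_stress_kPa = base$nominal_stress_kPa * noise),
                  width_mm = 4, thickness_mm = 0.5, gauge_length_mm = 10)
}

#' Generate a full synthetic study on disk
#'
#' Draws donor-level ground-truth parameters, generates noisy specimens
#' with dropout, and writes the long-format files consumed by the
#' processing pipeline: `specimens.csv` (columns `specimen_id`,
#' `donor_id`, `vein_type`, `direction`, `stretch`,
#' `nominal_stress_kPa`), `geometry.csv` (per-specimen `width_mm`,
#' `thickness_mm`, `gauge_length_mm`) and `truth.json` (ground-truth
#' parameters and the study configuration, for recovery scoring).
#' Fully deterministic given `config$seed`.
#'
#' @param config A [synthetic_study_config()].
#' @param out_dir Output directory (created if missing). `NULL` skips
#'   writing and only returns the study in memory.
#' @return Invisibly, a list with `specimens` (list of
#'   [specimen_record()]), `truth` (named list of [four_fiber_params()]
#'   per donor), `config` and `files`.
#' @export
generate_study <- function(config = synthetic_study_config(),
                           out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_study_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  groups <- rep(c("BV", "GSV"), length.out = config$n_donors)
  specimens <- list()
  truth <- list()
  for (i in seq_len(config$n_donors)) {
    donor_id <- sprintf("%s_%02d", groups[i], i)
    truth[[donor_id]] <- draw_donor_params(groups[i],
                                           stress_max = config$stress_max)
    for (dir in .direction_levels) {
      n_spec <- if (length(config$specimens_per_direction) == 1L)
        config$specimens_per_direction
      else sample(config$specimens_per_direction, 1L)
      # failed experiments: redraw the dropout mask until >= 2 survive
      repeat {
        keep <- stats::runif(n_spec) >= config$dropout_prob
        if (sum(keep) >= 2L) break
      }
      for (s in seq_len(n_spec)) {
        rec <- generate_specimen(truth[[donor_id]], dir,
                                 specimen_id = sprintf("%s_%s_%d", donor_id,
                                                       substr(dir, 1, 4), s),
                                 donor_id = donor_id, vein_type = groups[i],
                                 noise_stress_rel = config$noise_stress_rel,
                                 specimen_scale_sd = config$specimen_scale_sd,
                                 n_points = config$n_points,
                                 stress_max = config$stress_max)
        if (keep[s]) specimens[[rec$specimen_id]] <- rec
      }
    }
  }

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    long <- do.call(rbind, lapply(specimens, function(r)
      data.frame(specimen_id = r$specimen_id, donor_id = r$donor_id,
                 vein_type = r$vein_type, direction = r$direction,
                 stretch = r$samples$stretch,
                 nominal_stress_kPa = r$samples$nominal_stress_kPa)))
    rownames(long) <- NULL
    geom <- do.call(rbind, lapply(specimens, function(r)
      data.frame(specimen_id = r$specimen_id, width_mm = r$width_mm,
                 thickness_mm = r$thickness_mm,
                 gauge_length_mm = r$gauge_length_mm)))
    rownames(geom) <- NULL
    files <- file.path(out_dir, c("specimens.csv", "geometry.csv",
                                  "truth.json"))
    utils::write.csv(long, files[1], row.names = FALSE)
    utils::write.csv(geom, files[2], row.names = FALSE)
    truth_json <- lapply(truth, function(p)
      stats::setNames(lapply(names(.param_json_keys), function(f) p[[f]]),
                      unname(.param_json_keys)))
    jsonlite::write_json(list(config = unclass(config), truth = truth_json),
                         files[3], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(specimens = specimens, truth = truth, config = config,
                 files = files))
}
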