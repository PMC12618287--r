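#' Pipeline configuration
#'
#' Defaults reproduce the study settings: representative curves with
#' `m = 20` points over 0-200 kPa nominal stress, an initial-modulus
#' window of 0-0.5 kPa and a tangent modulus at 100 +/- 10 kPa.
#'
#' @param m Representative-curve points per direction (default 20).
#' @param stress_max Nominal-stress range (kPa, default 200).
#' @param ini_window Initial-modulus stress window (kPa,
#'   default `c(0, 0.5)`).
#' @param tangent_at,tangent_half_window Tangent-modulus location and
#'   half-window (kPa, defaults 100 and 10).
#' @param fit A [fit_config()].
#' @param min_points Minimum surviving samples per specimen after
#'   cleaning.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(m = 20L, stress_max = 200,
                            ini_window = c(0, 0.5),
                            tangent_at = 100, tangent_half_window = 10,
                            fit = fit_config(), min_points = 5L) {
  stopifnot(inherits(fit, "fit_config"))
  structure(list(m = as.integer(m), stress_max = stress_max,
                 ini_window = ini_window, tangent_at = tangent_at,
                 tangent_half_window = tangent_half_window,
                 fit = fit, min_points = as.integer(min_points)),
            class = "pipeline_config")
}

#' Read and validate a long-format specimen CSV
#'
#' Required columns: `specimen_id`, `donor_id`, `vein_type`, `direction`,
#' then either `stretch` + `nominal_stress_kPa` or `elongation_mm` +
#' `force_N` (the latter needs a geometry sidecar with `specimen_id`,
#' `width_mm`, `thickness_mm`, `gauge_length_mm`). Validation failures
#' name the offending column and rows.
#'
#' @param path Path to the specimen CSV (UTF-8, comma-delimited, header).
#' @param geometry_path Optional path to the geometry sidecar CSV.
#' @return A named list of [specimen_record()]s.
#' @export
read_specimens_csv <- function(path, geometry_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  id_cols <- c("specimen_id", "donor_id", "vein_type", "direction")
  miss <- setdiff(id_cols, names(df))
  if (length(miss))
    stop("specimen CSV '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  has_stress <- all(c("stretch", "nominal_stress_kPa") %in% names(df))
  has_force <- all(c("elongation_mm", "force_N") %in% names(df))
  if (!has_stress && !has_force)
    stop("specimen CSV '", path, "' must carry (stretch, ",
         "nominal_stress_kPa) or (elongation_mm, force_N) columns",
         call. = FALSE)
  val_cols <- if (has_stress) c("stretch", "nominal_stress_kPa")
  else c("elongation_mm", "force_N")
  for (cc in c(val_cols)) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad))
      stop("specimen CSV '", path, "': non-numeric or missing '", cc,
           "' at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  if (has_stress) {
    bad <- which(df$stretch <= 0)
    if (length(bad))
      stop("specimen CSV '", path, "': non-positive stretch at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$direction %in% .direction_levels)
  if (length(bad))
    stop("specimen CSV '", path, "': direction must be one of ",
         paste(.direction_levels, collapse = "/"), "; offending row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)

  geom <- NULL
  if (!is.null(geometry_path)) {
    geom <- utils::read.csv(geometry_path, stringsAsFactors = FALSE)
    gmiss <- setdiff(c("specimen_id", "width_mm", "thickness_mm"),
                     names(geom))
    if (length(gmiss))
      stop("geometry CSV '", geometry_path, "' is missing column(s): ",
           paste(gmiss, collapse = ", "), call. = FALSE)
  }

  split_df <- split(df, df$specimen_id)
  recs <- lapply(split_df, function(d) {
    g <- list(width_mm = NA_real_, thickness_mm = NA_real_,
              gauge_length_mm = NA_real_)
    if (!is.null(geom)) {
      gi <- geom[geom$specimen_id == d$specimen_id[1], , drop = FALSE]
      if (nrow(gi) == 1L)
        for (f in intersect(names(g), names(gi))) g[[f]] <- gi[[f]]
    }
    samples <- d[, val_cols]
    specimen_record(d$specimen_id[1], d$donor_id[1], d$vein_type[1],
                    d$direction[1], samples = samples,
                    width_mm = g$width_mm, thickness_mm = g$thickness_mm,
                    gauge_length_mm = g$gauge_length_mm)
  })
  recs[order(names(recs))]
}

.veinfit_version <- function() {
  as.character(utils::packageVersion("veinfit"))
}

# Stable hash of an arbitrary config list: md5 of its canonical JSON.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full characterization pipeline
#'
#' Cleans every specimen, builds per-donor representative curves in both
#' directions, fits the four-fiber-family model per donor, extracts
#' per-specimen moduli, and assembles a machine-readable report plus a
#' human-readable summary table (donor, specimen count, the eight
#' parameters, per-direction R^2). Donors whose processing fails are
#' isolated and reported, not fatal. The report is a pure function of
#' (input files, config, seed) and carries the seed and a config hash.
#'
#' @param specimens_csv Path to the long-format specimen CSV.
#' @param geometry_csv Optional geometry sidecar path.
#' @param config A [pipeline_config()].
#' @param out_dir If non-`NULL`, `report.json` and `summary.csv` are
#'   written there.
#' @return Invisibly, the report: a list with `version`, `seed`,
#'   `config_hash`, `donors` (per-donor parameters, Q, R^2, moduli,
#'   specimen bookkeeping), `rejected_specimens` and `summary` (data
#'   frame).
#' @export
run_pipeline <- function(specimens_csv, geometry_csv = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  recs <- read_specimens_csv(specimens_csv, geometry_csv)
  message(sprintf("[read] %d specimens from %s", length(recs),
                  specimens_csv))

  cleaned <- list()
  rejected <- list()
  for (id in names(recs)) {
    r <- tryCatch(clean_loading_branch(recs[[id]], config$min_points),
                  error = function(e) e)
    if (inherits(r, "error")) rejected[[id]] <- conditionMessage(r)
    else cleaned[[id]] <- r
  }
  if (length(rejected))
    message(sprintf("[clean] rejected %d specimen(s)", length(rejected)))

  donors <- sort(unique(vapply(cleaned, `[[`, "", "donor_id")))
  dir_key <- c(circumferential = "circ", longitudinal = "long")
  report_donors <- list()
  summary_rows <- list()
  for (donor in donors) {
    t_donor <- proc.time()[["elapsed"]]
    res <- tryCatch({
      drecs <- Filter(function(r) r$donor_id == donor, cleaned)
      curves <- list()
      moduli <- list()
      for (dir in .direction_levels) {
        sub <- Filter(function(r) r$direction == dir, drecs)
        if (length(sub) < 2L)
          stop("donor ", donor, ": only ", length(sub), " usable ", dir,
               " specimen(s); at least 2 are required", call. = FALSE)
        curves[[dir_key[[dir]]]] <-
          build_representative(sub, m = config$m,
                               stress_max = config$stress_max)
        moduli[[dir_key[[dir]]]] <- lapply(sub, function(r) {
          E_ini <- tryCatch(
            initial_modulus(r$samples, config$ini_window)$E_ini_MPa,
            error = function(e) structure(NA_real_,
                                          reason = conditionMessage(e)))
          E_100 <- tryCatch(
            tangent_modulus(r$samples, config$tangent_at,
                            config$tangent_half_window)$E_100_MPa,
            error = function(e) structure(NA_real_,
                                          reason = conditionMessage(e)))
          list(specimen_id = r$specimen_id,
               E_ini_MPa = as.numeric(E_ini),
               E_ini_note = attr(E_ini, "reason"),
               E_100_MPa = as.numeric(E_100),
               E_100_note = attr(E_100, "reason"))
        })
      }
      fit <- fit_four_fiber(curves, config$fit)
      n_spec <- length(drecs)
      message(sprintf("[fit] donor %s: n=%d, Q=%.4g kPa^2, R2=%.4f/%.4f (%.1f s)",
                      donor, n_spec, fit$Q, fit$R2_circ, fit$R2_long,
                      proc.time()[["elapsed"]] - t_donor))
      p <- fit$params
      summary_rows[[donor]] <- data.frame(
        donor_id = donor,
        vein_type = drecs[[1]]$vein_type, n_specimens = n_spec,
        mu_kPa = p$mu, k1_circ_kPa = p$k1_circ, k2_circ = p$k2_circ,
        k1_axial_kPa = p$k1_axial, k2_axial = p$k2_axial,
        k1_diag_kPa = p$k1_diag, k2_diag = p$k2_diag,
        beta_deg = p$beta_deg, R2_circ = fit$R2_circ,
        R2_long = fit$R2_long)
      list(status = "ok", n_specimens = n_spec,
           params = unclass(p), Q = fit$Q,
           R2_circ = fit$R2_circ, R2_long = fit$R2_long,
           seed = fit$seed, moduli = moduli)
    }, error = function(e) {
      message(sprintf("[fit] donor %s FAILED: %s", donor,
                      conditionMessage(e)))
      list(status = "failed", error = conditionMessage(e))
    })
    report_donors[[donor]] <- res
  }

  summary <- if (length(summary_rows)) do.call(rbind, summary_rows)
  else data.frame()
  rownames(summary) <- NULL
  report <- list(version = .veinfit_version(),
                 seed = config$fit$seed,
                 config_hash = config_hash(unclass(config)),
                 n_specimens_read = length(recs),
                 rejected_specimens = rejected,
                 donors = report_donors,
                 summary = summary)
  message(sprintf("[done] %d donor(s) in %.1f s", length(donors),
                  proc.time()[["elapsed"]] - t0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE, dataframe = "rows")
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}
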