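#' Write slice geometries to the long-format contour CSV
#'
#' The contour dialect is a long-format CSV with one vertex per row and
#' columns `patient_id`, `slice_id`, `contour_role` (one of `lumen`,
#' `outer`, `lipid`, `calcification`), `component_idx`, `vertex_idx`,
#' `x_mm`, `y_mm`.  Vertex order is preserved; polygons are implicitly
#' closed.
#'
#' @param geoms a list of [slice_geometry()] objects or a
#'   `synthetic_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(geoms, path) {
  if (inherits(geoms, "synthetic_cohort"))
    geoms <- unlist(lapply(geoms$patients, `[[`, "slices"), recursive = FALSE)
  rows <- lapply(geoms, function(g) {
    stopifnot(inherits(g, "slice_geometry"))
    one <- function(xy, role, idx) {
      data.frame(patient_id = g$patient_id, slice_id = g$slice_id,
                 contour_role = role, component_idx = idx,
                 vertex_idx = seq_len(nrow(xy)), x_mm = xy[, 1L], y_mm = xy[, 2L])
    }
    do.call(rbind, c(list(one(g$lumen, "lumen", 1L), one(g$outer, "outer", 1L)),
                     lapply(seq_along(g$lipid_cores), function(i)
                       one(g$lipid_cores[[i]], "lipid", i)),
                     lapply(seq_along(g$calcifications), function(i)
                       one(g$calcifications[[i]], "calcification", i))))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read slice geometries from the long-format contour CSV
#'
#' Parses and validates the contour dialect written by [write_contours()].
#' Malformed groups (fewer than 3 vertices, unknown roles, containment
#' violations) are rejected with diagnostics naming the offending
#' `(patient_id, slice_id)`.
#'
#' @param path CSV path.
#' @return A list of [slice_geometry()] objects, ordered by patient then
#'   slice id.
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "slice_id", "contour_role", "component_idx",
            "vertex_idx", "x_mm", "y_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("contour file ", path, " is missing columns: ", paste(missing, collapse = ", "))
  bad_role <- setdiff(unique(df$contour_role),
                      c("lumen", "outer", "lipid", "calcification"))
  if (length(bad_role))
    stop("unknown contour_role value(s): ", paste(bad_role, collapse = ", "))
  key <- paste(df$patient_id, df$slice_id, sep = "\r")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(sl) {
    id <- paste0(sl$patient_id[1L], "/", sl$slice_id[1L])
    grab <- function(role) {
      sub <- sl[sl$contour_role == role, , drop = FALSE]
      lapply(split(sub, sub$component_idx), function(g) {
        g <- g[order(g$vertex_idx), , drop = FALSE]
        if (nrow(g) < 3L)
          stop("slice ", id, ": ", role, " polygon with only ", nrow(g), " vertices")
        cbind(g$x_mm, g$y_mm)
      })
    }
    lum <- grab("lumen"); outr <- grab("outer")
    if (length(lum) != 1L || length(outr) != 1L)
      stop("slice ", id, ": expected exactly one lumen and one outer contour")
    slice_geometry(lum[[1L]], outr[[1L]], grab("lipid"), grab("calcification"),
                   patient_id = sl$patient_id[1L], slice_id = sl$slice_id[1L],
                   validate = TRUE)
  })
  unname(out)
}

#' Pipeline configuration
#'
#' @param input path to a contour CSV ([read_contours()] dialect), or
#'   `NULL` to simulate a cohort from `cohort`.
#' @param cohort a [cohort_config()] used when `input` is `NULL`.
#' @param thresholds a [morph_thresholds()].
#' @param intervals a [stress_intervals()], or the string `"calibrate"` to
#'   calibrate the stress cut-points against the morphological index on the
#'   analyzed slices.
#' @param surrogate a [surrogate_params()] (used when no external mechanics
#'   are provided).
#' @param provided_mechanics optional data frame of externally computed
#'   per-slice mechanics with columns `patient_id`, `slice_id`, `cpws_kPa`
#'   and optionally `cpwsn`, `cfss_dyn_cm2`; when given, the surrogate is
#'   skipped for those columns.
#' @param seed integer seed for simulation and surrogate noise.
#' @param out_dir optional directory; when set, [run_pipeline()] writes
#'   `metrics.csv`, `indices.csv`, `correlations.csv`, `agreements.csv` and
#'   `manifest.json` there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, cohort = cohort_config(),
                       thresholds = morph_thresholds(),
                       intervals = stress_intervals(),
                       surrogate = surrogate_params(),
                       provided_mechanics = NULL,
                       seed = 1L, out_dir = NULL) {
  if (is.null(input)) stopifnot(inherits(cohort, "cohort_config"))
  calibrate <- identical(intervals, "calibrate")
  if (!calibrate) stopifnot(inherits(intervals, "stress_intervals"))
  stopifnot(inherits(thresholds, "morph_thresholds"),
            inherits(surrogate, "surrogate_params"))
  if (!is.null(provided_mechanics)) {
    need <- c("patient_id", "slice_id", "cpws_kPa")
    missing <- setdiff(need, names(provided_mechanics))
    if (length(missing))
      stop("provided_mechanics is missing columns: ", paste(missing, collapse = ", "))
  }
  structure(list(input = input, cohort = cohort, thresholds = thresholds,
                 intervals = intervals, calibrate = calibrate,
                 surrogate = surrogate, provided_mechanics = provided_mechanics,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full slice-analysis pipeline
#'
#' Executes the analysis end to end: obtain geometries (simulate a seeded
#' cohort or read contours), extract nodal profiles and slice morphology,
#' compute or accept per-slice mechanics, assign the four vulnerability
#' indices (optionally calibrating the stress intervals), and run the
#' clustered correlation and agreement analyses.  With `out_dir` set, all
#' tables are written as CSV together with a JSON manifest recording the
#' seed and an MD5 hash of the serialized configuration.
#'
#' @param config a [run_config()].
#' @return A list of class `plaque_results` with `metrics` (per-slice
#'   measurements and indices), `intervals` (the stress intervals used),
#'   `calibration` (calibration result or `NULL`), `correlations` (long
#'   table from [correlation_table()]), `per_patient` (per-patient CPWS
#'   correlations), `agreements`, `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input)) {
    cc <- config$cohort; cc$seed <- config$seed
    cohort <- generate_cohort(cc)
    metrics <- cohort$metrics
  } else {
    geoms <- read_contours(config$input)
    set.seed(config$seed)
    rows <- lapply(geoms, function(g) {
      profile <- nodal_profile(g)
      morph <- slice_morphology(g, profile)
      mech <- nodal_mechanics(profile, g, config$surrogate)
      crit <- extract_critical(mech, profile, config$surrogate$shoulder_nodes)
      data.frame(patient_id = g$patient_id, slice_id = g$slice_id,
                 n_lipid_cores = length(g$lipid_cores),
                 min_cap_mm = morph$min_cap_thickness_mm,
                 lipid_pct = 100 * morph$lipid_fraction,
                 lumen_area_mm2 = morph$lumen_area_mm2,
                 outer_area_mm2 = morph$outer_area_mm2,
                 lipid_area_mm2 = morph$lipid_area_mm2,
                 cpws_kPa = crit$cpws_kPa, cpwsn = crit$cpwsn,
                 cfss_dyn_cm2 = crit$cfss_dyn_cm2)
    })
    metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (!is.null(config$provided_mechanics)) {
    pm <- config$provided_mechanics
    key <- paste(metrics$patient_id, metrics$slice_id)
    pk <- paste(pm$patient_id, pm$slice_id)
    hit <- match(key, pk)
    if (anyNA(hit)) stop("provided_mechanics is missing ", sum(is.na(hit)), " slice(s)")
    for (cl in intersect(c("cpws_kPa", "cpwsn", "cfss_dyn_cm2"), names(pm)))
      metrics[[cl]] <- pm[[cl]][hit]
  }
  metrics$cap_index <- assign_cap_index(metrics$min_cap_mm,
                                        metrics$n_lipid_cores > 0,
                                        config$thresholds)
  metrics$lipid_index <- assign_lipid_index(metrics$lipid_pct, config$thresholds)
  metrics$morph_index <- morphological_index(metrics$cap_index, metrics$lipid_index)
  calibration <- NULL
  intervals <- config$intervals
  if (config$calibrate) {
    calibration <- calibrate_stress_intervals(metrics$cpws_kPa, metrics$morph_index)
    intervals <- calibration$intervals
  }
  metrics$stress_index <- assign_stress_index(metrics$cpws_kPa, intervals)
  correlations <- correlation_table(metrics, pooled_fallback = TRUE)
  per_patient <- per_patient_correlations(metrics$min_cap_mm, metrics$cpws_kPa,
                                          metrics$patient_id)
  agreements <- agreement_analysis(metrics$stress_index, metrics$cap_index,
                                   metrics$lipid_index, metrics$morph_index)
  res <- structure(list(metrics = metrics, intervals = intervals,
                        calibration = calibration, correlations = correlations,
                        per_patient = per_patient, agreements = agreements,
                        seed = config$seed),
                   class = "plaque_results")
  if (!is.null(config$out_dir)) .write_results(res, config)
  res
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  # version-pinned serialization so the hash is stable across R sessions
  saveRDS(config, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

.write_results <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  wr(res$metrics, "metrics.csv")
  wr(res$metrics[, c("patient_id", "slice_id", "cap_index", "lipid_index",
                     "morph_index", "stress_index")], "indices.csv")
  wr(res$correlations, "correlations.csv")
  wr(res$agreements$summary, "agreements.csv")
  manifest <- list(seed = res$seed,
                   config_md5 = .config_hash(config),
                   stress_cuts_kPa = res$intervals$cuts_kPa,
                   calibrated = !is.null(res$calibration),
                   n_slices = nrow(res$metrics),
                   n_patients = length(unique(res$metrics$patient_id)),
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' @export
print.plaque_results <- function(x, ...) {
  cat("<plaque_results>", nrow(x$metrics), "slices,",
      length(unique(x$metrics$patient_id)), "patients\n")
  cat("  stress cuts (kPa):", paste(round(x$intervals$cuts_kPa, 2), collapse = ", "),
      if (!is.null(x$calibration)) "(calibrated)" else "(fixed)", "\n")
  cat(sprintf("  stress/morph agreement rate: %.4f\n", x$agreements$vs_morph$rate))
  invisible(x)
}
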