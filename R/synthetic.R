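#' Configuration of a synthetic cross-section cohort
#'
#' Describes a multi-patient cohort of synthetic coronary cross-sections:
#' smooth perturbed-ellipse lumen/outer contours plus annular-sector lipid
#' cores and calcifications built in polar coordinates around the lumen
#' centroid, so the fibrous-cap thickness of each core is controlled by
#' construction.  Defaults emulate a 14-patient, roughly 600-slice diseased
#' coronary cohort with cap thicknesses spanning (0, 0.3] mm and lipid
#' burdens from none to over 40% of the wall area.
#'
#' Distribution specs are lists: `list(mean=, sd=, min=, max=)` for
#' truncated-normal draws, `list(min=, max=)` for uniform draws.
#'
#' @param n_patients number of patients (default 14).
#' @param slices_per_patient single count or `c(min, max)` range sampled per
#'   patient (default `c(34, 57)`).
#' @param lumen_radius_mm truncated-normal spec for the mean lumen radius.
#' @param wall_thickness_mm truncated-normal spec for the mean wall
#'   thickness.
#' @param lipid_prevalence probability a slice carries at least one lipid
#'   core (default 0.85).
#' @param cap_thickness_mm uniform spec for the radial cap offset of a
#'   lipid core (mm); must allow values spanning (0, 0.3].
#' @param lipid_arc_deg uniform spec for the angular extent of a lipid core.
#' @param lipid_thickness_frac uniform spec for the lipid radial thickness
#'   as a fraction of the wall available beyond the cap.
#' @param second_core_prob probability a lipid-bearing slice carries a
#'   second, smaller core on the opposite side (default 0.3).
#' @param calc_prevalence probability of a calcification (default 0.3).
#' @param stress_coupling list `a`, `b`, `noise_sd` forwarded to
#'   [surrogate_params()]; `noise_sd` is the lognormal sd of the
#'   multiplicative stress noise (default 0.1).
#' @param pressure_kPa transmural pressure for the surrogate (default 13.3).
#' @param n_vertices contour discretization (default 128).
#' @param fourier_amp amplitude bound of the low-order Fourier radius
#'   perturbation of the lumen (fraction of radius, default 0.04).
#' @param wall_var_amp amplitude bound of the low-order wall-thickness
#'   variation (fraction of mean wall, default 0.08).
#' @param seed cohort seed (integer).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 14L,
                          slices_per_patient = c(34L, 57L),
                          lumen_radius_mm = list(mean = 1.5, sd = 0.3, min = 0.8, max = 2.5),
                          wall_thickness_mm = list(mean = 1.0, sd = 0.2, min = 0.5, max = 2.0),
                          lipid_prevalence = 0.85,
                          cap_thickness_mm = list(min = 0.02, max = 0.30),
                          lipid_arc_deg = list(min = 40, max = 280),
                          lipid_thickness_frac = list(min = 0.35, max = 0.95),
                          second_core_prob = 0.3,
                          calc_prevalence = 0.3,
                          stress_coupling = list(a = 0, b = 1, noise_sd = 0.1),
                          pressure_kPa = 13.3,
                          n_vertices = 128L,
                          fourier_amp = 0.04,
                          wall_var_amp = 0.08,
                          seed = 1L) {
  probs <- c(lipid_prevalence, calc_prevalence, second_core_prob)
  if (any(probs < 0) || any(probs > 1)) stop("prevalence probabilities must lie in [0, 1]")
  for (sp in list(lumen_radius_mm, wall_thickness_mm, cap_thickness_mm)) {
    if (sp$min <= 0 || sp$max < sp$min) stop("distribution bounds must be positive and ordered")
  }
  if (n_patients < 1L) stop("n_patients must be at least 1")
  if (length(slices_per_patient) == 1L) slices_per_patient <- rep(slices_per_patient, 2L)
  if (slices_per_patient[1L] < 1L || slices_per_patient[2L] < slices_per_patient[1L])
    stop("slices_per_patient must be a positive count or an ordered range")
  if (pressure_kPa <= 0) stop("pressure_kPa must be positive")
  if (n_vertices < 32L) stop("n_vertices must be at least 32")
  structure(list(n_patients = as.integer(n_patients),
                 slices_per_patient = as.integer(slices_per_patient),
                 lumen_radius_mm = lumen_radius_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 lipid_prevalence = lipid_prevalence,
                 cap_thickness_mm = cap_thickness_mm,
                 lipid_arc_deg = lipid_arc_deg,
                 lipid_thickness_frac = lipid_thickness_frac,
                 second_core_prob = second_core_prob,
                 calc_prevalence = calc_prevalence,
                 stress_coupling = utils::modifyList(list(a = 0, b = 1, noise_sd = 0.1),
                                                     as.list(stress_coupling)),
                 pressure_kPa = pressure_kPa,
                 n_vertices = as.integer(n_vertices),
                 fourier_amp = fourier_amp,
                 wall_var_amp = wall_var_amp,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Truncated-normal draw by rejection; degenerate sd gives the mean.
.r_truncnorm <- function(n, spec) {
  if (is.null(spec$sd) || spec$sd == 0) return(rep(spec$mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * n, spec$mean, spec$sd)
    out <- c(out, x[x >= spec$min & x <= spec$max])
  }
  out[seq_len(n)]
}

.r_unif_spec <- function(n, spec) {
  if (spec$min == spec$max) rep(spec$min, n) else stats::runif(n, spec$min, spec$max)
}

# Build an annular-sector component polygon around the lumen: at angular
# samples of the arc, take the lumen boundary point on the centroid ray and
# offset it radially by `cap` (inner edge) and `cap + thick` (outer edge).
# Returns NULL when the component cannot fit inside the wall.
.annular_sector <- function(lumen, outer, centre, arc_centre, arc_width,
                            cap, thick_frac, n_vertices, margin = 0.05) {
  m <- max(10L, ceiling(arc_width / (2 * pi) * n_vertices))
  ang <- seq(arc_centre - arc_width / 2, arc_centre + arc_width / 2, length.out = m)
  D <- cbind(cos(ang), sin(ang))
  t_lum <- .row_max(.ray_poly_t(centre, D, lumen))
  t_out <- .row_min(.ray_poly_t(centre, D, outer))
  if (anyNA(t_lum) || anyNA(t_out)) return(NULL)
  avail <- min(t_out - t_lum) - cap - margin
  if (avail <= 0.02) return(NULL)
  thick <- max(0.02, thick_frac * avail)
  inner <- cbind(centre[1L] + (t_lum + cap) * D[, 1L],
                 centre[2L] + (t_lum + cap) * D[, 2L])
  outer_pts <- cbind(centre[1L] + (t_lum + cap + thick) * D[, 1L],
                     centre[2L] + (t_lum + cap + thick) * D[, 2L])
  rbind(inner, outer_pts[rev(seq_len(m)), , drop = FALSE])
}

#' Generate one synthetic cross-section
#'
#' Draws a single slice from the cohort model: a low-order
#' Fourier-perturbed circular lumen, an outer boundary offset radially by a
#' smoothly varying wall thickness, and (with the configured prevalences)
#' annular-sector lipid cores at a sampled cap offset from the lumen plus
#' optional calcifications placed deeper in the wall.  Draws come from the
#' current RNG stream unless `seed` is given.
#'
#' @param config a [cohort_config()].
#' @param patient_id,slice_id identifiers for the generated slice.
#' @param seed optional integer seed.
#' @param max_retries resampling attempts before giving up when a sampled
#'   component cannot be placed inside the wall (default 20).
#' @return A [slice_geometry()] with attribute `cap_offsets_mm` recording
#'   the generative cap offset of each lipid core.
#' @export
generate_slice <- function(config, patient_id = "P0", slice_id = "S0",
                           seed = NULL, max_retries = 20L) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_retries)) {
    geom <- tryCatch(.generate_slice_once(config, patient_id, slice_id),
                     error = function(e) NULL)
    if (!is.null(geom)) return(geom)
  }
  stop("slice ", patient_id, "/", slice_id, ": could not sample a valid geometry in ",
       max_retries, " attempts; check that cap_thickness_mm and component sizes fit ",
       "inside wall_thickness_mm")
}

.generate_slice_once <- function(config, patient_id, slice_id) {
  nv <- config$n_vertices
  th <- 2 * pi * (seq_len(nv) - 1L) / nv
  r0 <- .r_truncnorm(1L, config$lumen_radius_mm)
  w0 <- .r_truncnorm(1L, config$wall_thickness_mm)
  rl <- rep(r0, nv)
  if (config$fourier_amp > 0) {
    for (k in 2:4) {
      a <- stats::runif(1L, 0, config$fourier_amp)
      ph <- stats::runif(1L, 0, 2 * pi)
      rl <- rl + r0 * a * cos(k * th + ph)
    }
  }
  lumen <- cbind(rl * cos(th), rl * sin(th))
  ctr <- .poly_centroid(lumen)
  u <- cbind(lumen[, 1L] - ctr[1L], lumen[, 2L] - ctr[2L])
  u <- u / sqrt(rowSums(u^2))
  w <- rep(w0, nv)
  if (config$wall_var_amp > 0) {
    for (k in 1:2) {
      b <- stats::runif(1L, 0, config$wall_var_amp)
      ph <- stats::runif(1L, 0, 2 * pi)
      w <- w + w0 * b * cos(k * th + ph)
    }
    w <- pmin(pmax(w, config$wall_thickness_mm$min), config$wall_thickness_mm$max)
  }
  outer <- lumen + w * u

  lipid_cores <- list()
  cap_offsets <- numeric(0)
  if (stats::runif(1L) < config$lipid_prevalence) {
    n_cores <- 1L + (stats::runif(1L) < config$second_core_prob)
    a1 <- stats::runif(1L, 0, 2 * pi)
    arcs <- list(c(a1, .r_unif_spec(1L, config$lipid_arc_deg) * pi / 180))
    if (n_cores == 2L) {
      a2 <- a1 + pi + stats::runif(1L, -0.5, 0.5)
      d2 <- stats::runif(1L, 30, 90) * pi / 180
      # keep the two arcs disjoint
      gap <- pi - abs(abs(a2 - a1) %% (2 * pi) - pi)
      if (gap > (arcs[[1L]][2L] + d2) / 2 + 0.15) arcs[[2L]] <- c(a2, d2)
    }
    for (arc in arcs) {
      cap <- .r_unif_spec(1L, config$cap_thickness_mm)
      frac <- .r_unif_spec(1L, config$lipid_thickness_frac)
      core <- .annular_sector(lumen, outer, ctr, arc[1L], arc[2L], cap, frac, nv)
      if (!is.null(core)) {
        lipid_cores[[length(lipid_cores) + 1L]] <- core
        cap_offsets <- c(cap_offsets, cap)
      }
    }
    if (!length(lipid_cores)) stop("lipid core placement failed")
  }
  calcs <- list()
  if (stats::runif(1L) < config$calc_prevalence) {
    ac <- stats::runif(1L, 0, 2 * pi)
    dc <- stats::runif(1L, 20, 60) * pi / 180
    coff <- stats::runif(1L, 0.25, 0.5) * w0
    calc <- .annular_sector(lumen, outer, ctr, ac, dc, coff, 0.35, nv)
    if (!is.null(calc)) calcs[[1L]] <- calc
  }
  geom <- slice_geometry(lumen, outer, lipid_cores, calcs,
                         patient_id = patient_id, slice_id = slice_id,
                         validate = TRUE)
  attr(geom, "cap_offsets_mm") <- cap_offsets
  geom
}

#' Generate a seeded multi-patient synthetic cohort
#'
#' Generates `n_patients` patients with the configured slice counts and
#' attaches per-slice morphology and surrogate mechanical values
#' (CPWS/CPWSn/CFSS via [nodal_mechanics()] and [extract_critical()], with
#' the configured stress coupling).  One RNG stream per cohort is split
#' hierarchically into per-patient and per-slice seeds, so any slice's
#' draws are independent of generation order.  Regeneration with the same
#' config (including its seed) yields an identical cohort; the caller's RNG
#' state is left untouched.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `patients`
#'   (each a list with `patient_id` and `slices`, a list of
#'   [slice_geometry()]), `metrics` (one row per slice: identifiers,
#'   `n_lipid_cores`, `min_cap_mm`, `lipid_pct`, areas, `cpws_kPa`,
#'   `cpwsn`, `cfss_dyn_cm2`), `config_echo` and `seed`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_patients = 2, slices_per_patient = 5))
#' head(coh$metrics)
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
            suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)), add = TRUE)
  set.seed(config$seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, config$n_patients)
  n_slices_all <- if (config$slices_per_patient[1L] == config$slices_per_patient[2L]) {
    rep(config$slices_per_patient[1L], config$n_patients)
  } else {
    sample(seq(config$slices_per_patient[1L], config$slices_per_patient[2L]),
           config$n_patients, replace = TRUE)
  }
  sp <- surrogate_params(pressure_kPa = config$pressure_kPa,
                         coupling = config$stress_coupling)
  patients <- vector("list", config$n_patients)
  rows <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    set.seed(patient_seeds[p])
    slice_seeds <- sample.int(.Machine$integer.max - 1L, n_slices_all[p])
    slices <- vector("list", n_slices_all[p])
    prow <- vector("list", n_slices_all[p])
    for (s in seq_len(n_slices_all[p])) {
      sid <- sprintf("S%03d", s)
      set.seed(slice_seeds[s])
      geom <- generate_slice(config, patient_id = pid, slice_id = sid)
      profile <- nodal_profile(geom)
      morph <- slice_morphology(geom, profile)
      mech <- nodal_mechanics(profile, geom, sp)
      crit <- extract_critical(mech, profile, sp$shoulder_nodes)
      slices[[s]] <- geom
      prow[[s]] <- data.frame(patient_id = pid, slice_id = sid,
                              n_lipid_cores = length(geom$lipid_cores),
                              min_cap_mm = morph$min_cap_thickness_mm,
                              lipid_pct = 100 * morph$lipid_fraction,
                              lumen_area_mm2 = morph$lumen_area_mm2,
                              outer_area_mm2 = morph$outer_area_mm2,
                              lipid_area_mm2 = morph$lipid_area_mm2,
                              cpws_kPa = crit$cpws_kPa,
                              cpwsn = crit$cpwsn,
                              cfss_dyn_cm2 = crit$cfss_dyn_cm2)
    }
    patients[[p]] <- list(patient_id = pid, slices = slices)
    rows[[p]] <- do.call(rbind, prow)
  }
  structure(list(patients = patients,
                 metrics = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 config_echo = config, seed = config$seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$patients), "patients,",
      nrow(x$metrics), "slices, seed", x$seed, "\n")
  cat("  lipid-bearing slices:", sum(x$metrics$n_lipid_cores > 0), "\n")
  invisible(x)
}
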