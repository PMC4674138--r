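#' Parameters of the mechanical surrogate
#'
#' The surrogate replaces a full fluid-structure interaction solution with
#' closed-form per-node mechanics: thin-wall (Laplace) hoop stress for
#' plaque wall stress, inversion of the equibiaxial Mooney-Rivlin response
#' for wall strain, and Poiseuille wall shear stress for flow shear stress.
#' Magnitudes are physically motivated but deliberately not calibrated to
#' any solver output; only the qualitative couplings (stress up as cap
#' thins, shear down as lumen widens) are relied upon.
#'
#' @param pressure_kPa transmural pressure, kPa (default 13.3, ~100 mmHg).
#' @param viscosity_Pa_s blood dynamic viscosity, Pa s (default 0.0035).
#' @param flow_ml_s volumetric flow rate, ml/s (default 1).
#' @param coupling named list `a`, `b`, `noise_sd`: the nodal wall stress is
#'   `a + b * pressure * r / h` with optional multiplicative lognormal noise
#'   `exp(N(0, noise_sd))` (Gaussian on the log scale, preserving
#'   positivity).
#' @param material a [material_params()] used to convert stress to strain.
#' @param shoulder_nodes dilation width (nodes) of the cap region used for
#'   critical-value extraction; default 2 (~7.2 degrees at 100 nodes).
#' @param seed optional integer seed for the noise draws.
#' @return An object of class `surrogate_params`.
#' @export
surrogate_params <- function(pressure_kPa = 13.3, viscosity_Pa_s = 0.0035,
                             flow_ml_s = 1,
                             coupling = list(a = 0, b = 1, noise_sd = 0),
                             material = material_params(),
                             shoulder_nodes = 2L, seed = NULL) {
  if (pressure_kPa <= 0 || viscosity_Pa_s <= 0 || flow_ml_s <= 0)
    stop("pressure, viscosity and flow must be positive")
  stopifnot(inherits(material, "material_params"))
  coupling <- utils::modifyList(list(a = 0, b = 1, noise_sd = 0), as.list(coupling))
  if (coupling$noise_sd < 0) stop("noise_sd must be non-negative")
  if (coupling$b <= 0) stop("coupling b must be positive")
  structure(list(pressure_kPa = pressure_kPa, viscosity_Pa_s = viscosity_Pa_s,
                 flow_ml_s = flow_ml_s, coupling = coupling,
                 material = material, shoulder_nodes = as.integer(shoulder_nodes),
                 seed = seed),
            class = "surrogate_params")
}

#' Per-node surrogate mechanics
#'
#' Computes plaque wall stress (PWS), plaque wall strain (PWSn) and flow
#' shear stress (FSS) at every node of a slice profile:
#' \itemize{
#'   \item PWS: Laplace hoop stress `a + b * p * r / h` (kPa), with `r` the
#'     distance from the lumen centroid to the lumen point and `h` the cap
#'     thickness at lipid-hit nodes, the wall thickness elsewhere;
#'   \item PWSn: the Green-Lagrange strain at which the equibiaxial
#'     Mooney-Rivlin membrane response equals the nodal PWS, clipped to
#'     `[0, 0.5]`;
#'   \item FSS: Poiseuille wall shear `4 mu Q / (pi r^3)` in dyn/cm^2.
#' }
#' If `noise_sd > 0`, each PWS and FSS value is perturbed by an independent
#' multiplicative lognormal factor; PWSn is recomputed from the perturbed
#' PWS so the two stay consistent.
#'
#' @param profile a [nodal_profile()].
#' @param geom the [slice_geometry()] the profile came from (identifiers
#'   only; all geometry enters through the profile).
#' @param params a [surrogate_params()].
#' @return A data frame with one row per node: `node_idx`, `pws_kPa`,
#'   `pwsn`, `fss_dyn_cm2`.
#' @export
nodal_mechanics <- function(profile, geom = NULL, params = surrogate_params()) {
  stopifnot(inherits(params, "surrogate_params"),
            is.data.frame(profile),
            all(c("r_lumen_mm", "wall_mm", "cap_mm", "hits_lipid") %in% names(profile)))
  h <- ifelse(profile$hits_lipid, profile$cap_mm, profile$wall_mm)
  if (any(h <= 0) || any(profile$r_lumen_mm <= 0))
    stop("non-positive thickness or lumen radius in profile",
         if (!is.null(geom)) paste0(" (slice ", geom$patient_id, "/", geom$slice_id, ")"))
  cp <- params$coupling
  pws <- cp$a + cp$b * params$pressure_kPa * profile$r_lumen_mm / h
  r_m <- profile$r_lumen_mm * 1e-3
  fss_pa <- 4 * params$viscosity_Pa_s * (params$flow_ml_s * 1e-6) / (pi * r_m^3)
  fss <- fss_pa * 10                     # 1 Pa = 10 dyn/cm^2
  if (cp$noise_sd > 0) {
    if (!is.null(params$seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(params$seed)
    }
    n <- length(pws)
    pws <- pws * exp(stats::rnorm(n, 0, cp$noise_sd))
    fss <- fss * exp(stats::rnorm(n, 0, cp$noise_sd))
  }
  pwsn <- equibiaxial_strain_from_stress(params$material, pws)
  data.frame(node_idx = profile$node_idx, pws_kPa = pws, pwsn = pwsn,
             fss_dyn_cm2 = fss)
}

# Circular dilation of a logical mask by `width` positions on each side.
.dilate_circular <- function(mask, width) {
  n <- length(mask)
  out <- mask
  if (width >= 1L && any(mask)) {
    for (k in seq_len(width)) {
      out <- out | mask[((seq_len(n) - 1L + k) %% n) + 1L] |
                   mask[((seq_len(n) - 1L - k) %% n) + 1L]
    }
  }
  out
}

#' Critical mechanical values of a slice
#'
#' Extracts the slice-level critical values CPWS, CPWSn and CFSS: the
#' maximum of each mechanical factor over the thin-cap region, where the
#' cap region is the set of lipid-hit nodes dilated by `shoulder_nodes`
#' positions on each side (the cap shoulder).  The restriction of the node
#' array to this region makes the reported value the largest of the
#' region's local maxima.  A slice without lipid-hit nodes uses all nodes
#' (global maximum), so every slice receives critical values.
#'
#' @param mech a [nodal_mechanics()] data frame.
#' @param profile the matching [nodal_profile()].
#' @param shoulder_nodes dilation width in nodes (default 2).
#' @return A list of class `critical_values` with `cpws_kPa`, `cpwsn`,
#'   `cfss_dyn_cm2` and `critical_node_idx` (named integer vector, one node
#'   per factor).
#' @export
extract_critical <- function(mech, profile, shoulder_nodes = 2L) {
  if (nrow(mech) != nrow(profile))
    stop("mechanics and profile lengths differ (", nrow(mech), " vs ", nrow(profile), ")")
  region <- .dilate_circular(profile$hits_lipid, as.integer(shoulder_nodes))
  if (!any(region)) region <- rep(TRUE, nrow(profile))
  idx <- which(region)
  pick <- function(v) idx[which.max(v[idx])]
  ip <- pick(mech$pws_kPa); is_ <- pick(mech$pwsn); if_ <- pick(mech$fss_dyn_cm2)
  structure(list(cpws_kPa = mech$pws_kPa[ip],
                 cpwsn = mech$pwsn[is_],
                 cfss_dyn_cm2 = mech$fss_dyn_cm2[if_],
                 critical_node_idx = c(pws = mech$node_idx[ip],
                                       pwsn = mech$node_idx[is_],
                                       fss = mech$node_idx[if_])),
            class = "critical_values")
}
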