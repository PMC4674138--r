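#' Pooled correlation with patient clustering (linear mixed-effects)
#'
#' Estimates the association between two per-slice quantities while
#' accounting for the clustering of slices within patients, by fitting the
#' random-intercept model
#' \deqn{y_{ij} = \beta_0 + \beta_1 x_{ij} + u_i + \epsilon_{ij}, \quad
#'   u_i \sim N(0, \sigma_u^2)}
#' by maximum likelihood ([lme4::lmer()]).  The reported correlation-scale
#' effect size is the standardized fixed-effect slope
#' `r = beta1 * sd(x) / sd(y)`, sign-preserving and clipped to `[-1, 1]`
#' (an interpretation choice: it reduces to the Pearson correlation when
#' there is no clustering), with the Wald p-value for `beta1`.
#'
#' With a single patient the random effect is degenerate and the function
#' returns the pooled Pearson correlation.
#'
#' @param x,y numeric per-slice vectors.
#' @param patient_ids patient identifier per slice.
#' @param pooled_fallback if `TRUE`, fall back to the pooled Pearson
#'   correlation when the mixed model cannot be fit (e.g. zero residual
#'   variance); otherwise such fits raise an error.
#' @return An object of class `correlation_result`: a list with `r`,
#'   `p_value`, `n_slices`, `n_patients`, `method` (`"lme"` or
#'   `"pearson_pooled"`).
#' @export
lme_correlation <- function(x, y, patient_ids, pooled_fallback = FALSE) {
  n <- length(x)
  if (length(y) != n || length(patient_ids) != n)
    stop("x, y and patient_ids must have equal length")
  ok <- stats::complete.cases(x, y, patient_ids)
  x <- x[ok]; y <- y[ok]; pid <- factor(patient_ids[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("x has zero variance")
  if (stats::sd(y) == 0) stop("y has zero variance")
  np <- nlevels(pid)
  if (np < 2L) return(.pooled_pearson(x, y, np))
  d <- data.frame(x = x, y = y, pid = pid)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | pid), data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    if (pooled_fallback) return(.pooled_pearson(x, y, np))
    stop("mixed-model fit failed (", conditionMessage(fit),
         "); set pooled_fallback = TRUE to use the pooled Pearson correlation")
  }
  b <- lme4::fixef(fit)[["x"]]
  se <- tryCatch(
    suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit))))[[2L]]),
    error = function(e) NA_real_)
  if (!is.finite(se) || se <= 0) {
    if (pooled_fallback) return(.pooled_pearson(x, y, np))
    stop("degenerate mixed-model fit: standard error of the slope is not positive")
  }
  z <- b / se
  r <- b * stats::sd(x) / stats::sd(y)
  structure(list(r = max(-1, min(1, r)),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 n_slices = n, n_patients = np, method = "lme"),
            class = "correlation_result")
}

.pooled_pearson <- function(x, y, np) {
  ct <- stats::cor.test(x, y)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n_slices = length(x), n_patients = np,
                 method = "pearson_pooled"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.4f, p = %.3g (%s; %d slices, %d patients)\n",
              x$r, x$p_value, x$method, x$n_slices, x$n_patients))
  invisible(x)
}

#' Per-patient Pearson correlations
#'
#' Pearson correlation between two per-slice quantities computed separately
#' for each patient.  Patients with fewer than `min_slices` usable slices
#' are skipped with a warning; patients where either variable is constant
#' are retained with `r = NA` (undefined, not zero).
#'
#' @param x,y numeric per-slice vectors.
#' @param patient_ids patient identifier per slice.
#' @param min_slices minimum slices per patient (default 3).
#' @return A data frame with columns `patient_id`, `n`, `r`, `p_value`.
#' @export
per_patient_correlations <- function(x, y, patient_ids, min_slices = 3L) {
  n <- length(x)
  if (length(y) != n || length(patient_ids) != n)
    stop("x, y and patient_ids must have equal length")
  ids <- unique(patient_ids)
  out <- lapply(ids, function(id) {
    sel <- patient_ids == id & stats::complete.cases(x, y)
    xi <- x[sel]; yi <- y[sel]
    if (length(xi) < min_slices) {
      warning("patient ", id, " skipped: only ", length(xi), " usable slices")
      return(NULL)
    }
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0)
      return(data.frame(patient_id = id, n = length(xi),
                        r = NA_real_, p_value = NA_real_))
    ct <- stats::cor.test(xi, yi)
    data.frame(patient_id = id, n = length(xi),
               r = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Agreement analysis of the stress index against the morphological indices
#'
#' Computes the pairwise match rate of the stress index against the cap,
#' lipid and morphological indices.
#'
#' @param stress_index,cap_index,lipid_index,morph_index equal-length
#'   integer index vectors.
#' @return A list with elements `vs_cap`, `vs_lipid`, `vs_morph` (each an
#'   [agreement_rate()] table) and a `summary` data frame.
#' @export
agreement_analysis <- function(stress_index, cap_index, lipid_index, morph_index) {
  n <- length(stress_index)
  if (length(cap_index) != n || length(lipid_index) != n || length(morph_index) != n)
    stop("all index vectors must have equal length")
  tabs <- list(vs_cap = agreement_rate(stress_index, cap_index),
               vs_lipid = agreement_rate(stress_index, lipid_index),
               vs_morph = agreement_rate(stress_index, morph_index))
  tabs$summary <- data.frame(
    comparison = c("stress_vs_cap", "stress_vs_lipid", "stress_vs_morph"),
    matched = vapply(tabs[1:3], `[[`, integer(1), "matched"),
    unmatched = vapply(tabs[1:3], `[[`, integer(1), "unmatched"),
    rate = vapply(tabs[1:3], `[[`, numeric(1), "rate"),
    row.names = NULL)
  tabs
}

#' Clustered correlation table of mechanical factors vs morphology
#'
#' Builds the pooled correlation table between each mechanical factor
#' (CPWS, CPWSn, CFSS, and optionally the stress index) and the five
#' morphological factors (min cap thickness, cap index, lipid percentage,
#' lipid index, morphological index), each fitted with [lme_correlation()].
#'
#' @param metrics a per-slice data frame with columns `patient_id`,
#'   `min_cap_mm`, `lipid_pct`, `cpws_kPa`, `cpwsn`, `cfss_dyn_cm2` and the
#'   index columns `cap_index`, `lipid_index`, `morph_index` (and
#'   optionally `stress_index`).
#' @param pooled_fallback forwarded to [lme_correlation()].
#' @return A data frame in long form: `mechanical`, `morphological`, `r`,
#'   `p_value`, `n_slices`, `n_patients`, `method`.
#' @export
correlation_table <- function(metrics, pooled_fallback = FALSE) {
  mech_cols <- c(cpws_kPa = "cpws_kPa", cpwsn = "cpwsn", cfss_dyn_cm2 = "cfss_dyn_cm2")
  if ("stress_index" %in% names(metrics))
    mech_cols <- c(mech_cols, stress_index = "stress_index")
  morph_cols <- c(min_cap_mm = "min_cap_mm", cap_index = "cap_index",
                  lipid_pct = "lipid_pct", lipid_index = "lipid_index",
                  morph_index = "morph_index")
  missing <- setdiff(c(mech_cols, morph_cols), names(metrics))
  if (length(missing)) stop("metrics is missing columns: ", paste(missing, collapse = ", "))
  rows <- list()
  for (m in names(mech_cols)) {
    for (f in names(morph_cols)) {
      cr <- lme_correlation(metrics[[morph_cols[[f]]]], metrics[[mech_cols[[m]]]],
                            metrics$patient_id, pooled_fallback = pooled_fallback)
      rows[[length(rows) + 1L]] <- data.frame(
        mechanical = m, morphological = f, r = cr$r, p_value = cr$p_value,
        n_slices = cr$n_slices, n_patients = cr$n_patients, method = cr$method)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
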