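#' Morphological index thresholds
#'
#' Cut-points of the ordinal 0-4 cap and lipid vulnerability indices,
#' aligned with AHA plaque types.  All upper bounds are right-closed,
#' exactly as the classification tables state them.
#'
#' @param cap_cuts_mm increasing cap-thickness cut-points (mm); default
#'   `c(0.065, 0.15, 0.2)`.
#' @param lipid_cuts_pct increasing lipid-percentage cut-points (percent);
#'   default `c(5, 30, 40)`.
#' @return An object of class `morph_thresholds`.
#' @export
morph_thresholds <- function(cap_cuts_mm = c(0.065, 0.15, 0.2),
                             lipid_cuts_pct = c(5, 30, 40)) {
  stopifnot(length(cap_cuts_mm) == 3L, length(lipid_cuts_pct) == 3L)
  if (any(diff(cap_cuts_mm) <= 0) || any(cap_cuts_mm <= 0))
    stop("cap_cuts_mm must be positive and strictly increasing")
  if (any(diff(lipid_cuts_pct) <= 0) || any(lipid_cuts_pct <= 0))
    stop("lipid_cuts_pct must be positive and strictly increasing")
  structure(list(cap_cuts_mm = cap_cuts_mm, lipid_cuts_pct = lipid_cuts_pct),
            class = "morph_thresholds")
}

#' Cap vulnerability index
#'
#' Ordinal 0-4 index from minimum fibrous-cap thickness.  Slices without a
#' lipid core ("no component") get index 0; lipid-bearing slices are binned
#' with right-closed boundaries: index 4 for cap <= 0.065 mm, 3 for
#' (0.065, 0.15], 2 for (0.15, 0.2], 1 above 0.2 mm (defaults).
#'
#' @param min_cap_mm minimum cap thickness(es) in mm, > 0.
#' @param has_lipid logical: does the slice contain a lipid core?
#' @param thresholds a [morph_thresholds()].
#' @return Integer index (vectorized) in `0:4`.
#' @examples
#' assign_cap_index(0.05, TRUE)   # 4
#' assign_cap_index(0.18, TRUE)   # 2
#' assign_cap_index(0.25, FALSE)  # 0
#' @export
assign_cap_index <- function(min_cap_mm, has_lipid, thresholds = morph_thresholds()) {
  stopifnot(inherits(thresholds, "morph_thresholds"))
  if (any(!is.finite(min_cap_mm)) || any(min_cap_mm <= 0))
    stop("min_cap_mm must be positive and finite")
  n <- max(length(min_cap_mm), length(has_lipid))
  min_cap_mm <- rep_len(min_cap_mm, n); has_lipid <- rep_len(has_lipid, n)
  cuts <- thresholds$cap_cuts_mm
  idx <- ifelse(min_cap_mm <= cuts[1L], 4L,
         ifelse(min_cap_mm <= cuts[2L], 3L,
         ifelse(min_cap_mm <= cuts[3L], 2L, 1L)))
  as.integer(ifelse(has_lipid, idx, 0L))
}

#' Lipid vulnerability index
#'
#' Ordinal 0-4 index from the slice lipid percentage: 0 for no lipid,
#' 1 for (0, 5)%, 2 for \[5, 30)%, 3 for \[30, 40)%, 4 for >= 40%
#' (defaults).
#'
#' @param lipid_pct lipid percentage(s) in percent, in `[0, 100)`.
#' @param thresholds a [morph_thresholds()].
#' @return Integer index (vectorized) in `0:4`.
#' @examples
#' assign_lipid_index(35)  # 3
#' assign_lipid_index(40)  # 4
#' @export
assign_lipid_index <- function(lipid_pct, thresholds = morph_thresholds()) {
  stopifnot(inherits(thresholds, "morph_thresholds"))
  if (any(!is.finite(lipid_pct)) || any(lipid_pct < 0) || any(lipid_pct >= 100))
    stop("lipid_pct must lie in [0, 100)")
  cuts <- thresholds$lipid_cuts_pct
  as.integer(ifelse(lipid_pct == 0, 0L,
             ifelse(lipid_pct < cuts[1L], 1L,
             ifelse(lipid_pct < cuts[2L], 2L,
             ifelse(lipid_pct < cuts[3L], 3L, 4L)))))
}

#' Morphological vulnerability index
#'
#' The slice-level morphological index is the maximum of the cap index and
#' the lipid index.
#'
#' @param cap_index,lipid_index integer indices in `0:4` (vectorized).
#' @return Integer index in `0:4`.
#' @export
morphological_index <- function(cap_index, lipid_index) {
  .check_index(cap_index, "cap_index"); .check_index(lipid_index, "lipid_index")
  as.integer(pmax(cap_index, lipid_index))
}

.check_index <- function(x, what) {
  if (any(!is.finite(x)) || any(x != as.integer(x)) || any(x < 0L) || any(x > 4L))
    stop(what, " must contain integers in 0..4")
}

#' Stress-index intervals
#'
#' Four increasing cut-points (kPa) defining the five half-open critical
#' plaque wall stress intervals `(0, t1], (t1, t2], (t2, t3], (t3, t4],
#' (t4, Inf)` mapped to stress indices 0..4.  The defaults are the
#' intervals calibrated against the morphological index on the 617-slice
#' coronary cohort the method was developed on.
#'
#' @param cuts_kPa increasing positive cut-points, length 4; default
#'   `c(35, 55, 89, 140)`.
#' @return An object of class `stress_intervals`.
#' @export
stress_intervals <- function(cuts_kPa = c(35, 55, 89, 140)) {
  if (length(cuts_kPa) != 4L || any(!is.finite(cuts_kPa)) ||
      any(cuts_kPa <= 0) || any(diff(cuts_kPa) <= 0))
    stop("cuts_kPa must be 4 positive strictly increasing values")
  structure(list(cuts_kPa = as.numeric(cuts_kPa)), class = "stress_intervals")
}

#' Stress vulnerability index
#'
#' Assigns the ordinal 0-4 stress index from the critical plaque wall
#' stress (CPWS): the index of the half-open (left-open, right-closed)
#' interval containing the value.
#'
#' @param cpws_kPa critical plaque wall stress(es) in kPa, > 0.
#' @param intervals a [stress_intervals()].
#' @return Integer index (vectorized) in `0:4`.
#' @examples
#' assign_stress_index(100)  # 3 under the default (89, 140] interval
#' assign_stress_index(35)   # 0: the first interval is (0, 35]
#' @export
assign_stress_index <- function(cpws_kPa, intervals = stress_intervals()) {
  stopifnot(inherits(intervals, "stress_intervals"))
  if (any(!is.finite(cpws_kPa)) || any(cpws_kPa <= 0))
    stop("cpws_kPa must be positive and finite")
  cuts <- intervals$cuts_kPa
  as.integer(rowSums(outer(cpws_kPa, cuts, ">")))
}

#' Calibrate stress intervals against the morphological index
#'
#' Finds four stress cut-points that maximize the exact agreement (match)
#' rate between the stress index and a given morphological index, i.e. the
#' fraction of slices whose two indices are equal.  Because the match count
#' only changes when a cut crosses a data value, the problem reduces to a
#' monotone non-decreasing assignment of index levels 0..4 to the sorted
#' unique CPWS values, solved exactly by dynamic programming; index levels
#' may be empty (two cuts can share a gap, or sit below the smallest /
#' above the largest value).  Ties are broken toward the earliest possible
#' cut positions (lexicographically smallest boundary vector), and cuts are
#' placed at gap midpoints — equally spaced when several cuts share a gap,
#' unit-spaced above the data maximum — so the result is deterministic and
#' independent of slice order.
#'
#' @param cpws_kPa positive critical plaque wall stresses, one per slice.
#' @param morph_index integer morphological indices in `0:4`, same length.
#' @return A list with `intervals` (a [stress_intervals()]), `match_rate`,
#'   `matched` and `n`.
#' @examples
#' cal <- calibrate_stress_intervals(c(10, 40, 70, 100, 150), 0:4)
#' cal$match_rate  # 1: perfectly separable
#' @export
calibrate_stress_intervals <- function(cpws_kPa, morph_index) {
  if (length(cpws_kPa) != length(morph_index))
    stop("cpws_kPa and morph_index must have equal length")
  if (length(cpws_kPa) < 5L) stop("calibration needs at least 5 slices")
  if (any(!is.finite(cpws_kPa)) || any(cpws_kPa <= 0))
    stop("cpws_kPa must be positive and finite")
  .check_index(morph_index, "morph_index")
  v <- sort(unique(cpws_kPa))
  u <- length(v)
  if (u < 5L)
    stop("calibration needs at least 5 distinct CPWS values, got ", u)
  block <- match(cpws_kPa, v)
  # cnt[j, l+1]: slices in value-block j with morphological index l
  cnt <- matrix(0L, u, 5L)
  for (l in 0:4) cnt[, l + 1L] <- tabulate(block[morph_index == l], nbins = u)
  # h[j, k+1]: best match count for blocks j..u when every one of them must
  # receive level >= k.  Either block j takes level k (gain cnt[j, k+1]) or
  # the floor is raised to k+1 at this position (an empty or closed level).
  h <- matrix(0, u + 1L, 5L)
  for (j in u:1) {
    h[j, 5L] <- cnt[j, 5L] + h[j + 1L, 5L]
    for (k in 3:0) {
      h[j, k + 1L] <- max(cnt[j, k + 1L] + h[j + 1L, k + 1L], h[j, k + 2L])
    }
  }
  best <- h[1L, 1L]
  # forward reconstruction; raising the level floor at the earliest position
  # that preserves optimality yields the lexicographically smallest boundary
  # vector b (b[l] = last block below cut l, 0..u)
  b <- integer(4L)
  j <- 1L; k <- 0L
  while (j <= u) {
    while (k < 4L && h[j, k + 2L] == h[j, k + 1L]) {
      b[k + 1L] <- j - 1L
      k <- k + 1L
    }
    j <- j + 1L
  }
  if (k < 4L) b[(k + 1L):4L] <- u
  # canonical cut values: midpoints of their gaps, spread evenly when a gap
  # hosts several cuts; the gap above the data maximum is unit-spaced
  cuts <- numeric(4L)
  for (g in unique(b)) {
    ids <- which(b == g)
    m <- length(ids)
    if (g == u) {
      cuts[ids] <- v[u] + seq_len(m)
    } else {
      lo <- if (g == 0L) 0 else v[g]
      hi <- v[g + 1L]
      cuts[ids] <- lo + seq_len(m) * (hi - lo) / (m + 1L)
    }
  }
  n <- length(cpws_kPa)
  list(intervals = stress_intervals(cuts),
       match_rate = best / n, matched = as.integer(best), n = n)
}

#' Agreement (match) rate between two ordinal indices
#'
#' The match rate is the fraction of slices at which two indices take the
#' same value.
#'
#' @param index_a,index_b integer index vectors of equal length.
#' @return A list of class `agreement_table` with `matched`, `unmatched`,
#'   `n` and `rate`.
#' @examples
#' agreement_rate(c(1, 2, 3), c(1, 2, 4))$rate  # 2/3
#' @export
agreement_rate <- function(index_a, index_b) {
  if (length(index_a) != length(index_b))
    stop("index vectors must have equal length (",
         length(index_a), " vs ", length(index_b), ")")
  matched <- sum(index_a == index_b)
  n <- length(index_a)
  structure(list(matched = matched, unmatched = n - matched,
                 n = n, rate = matched / n),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("<agreement_table> matched", x$matched, "of", x$n,
      sprintf("(rate %.4f)\n", x$rate))
  invisible(x)
}
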