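# CGM band occupancy, TIR, the Glycemia Risk Index and its A-E risk zones.
#
# Band cut-points on a continuous glucose value g (mg/dL):
#   very low  g < 54
#   low       54 <= g < 70
#   in range  70 <= g <= 180
#   high      180 < g <= 250
#   very high g > 250
# GRI weights its out-of-range occupancies into a hypoglycemia component
# (vlow + 0.8*low) and a hyperglycemia component (vhigh + 0.5*high), then
# GRI = min(100, 3.0*hypo + 1.6*hyper). Zones are 20-point quintiles,
# upper-closed: A [0,20], B (20,40], C (40,60], D (60,80], E (80,100].

BAND_NAMES <- c("pct_vlow", "pct_low", "pct_tir", "pct_high", "pct_vhigh")

#' Construct a glycemic band-occupancy profile
#'
#' A \code{glycemic_profile} holds the percentage of CGM time spent in each
#' of the five consensus glucose bands: <54, 54-69, 70-180 (time in range),
#' 181-250 and >250 mg/dL.
#'
#' @param pct_vlow,pct_low,pct_tir,pct_high,pct_vhigh band occupancies in
#'   percent; each in \code{[0,100]} and summing to 100 (tolerance
#'   \code{1e-6}).
#' @return object of class \code{glycemic_profile} (named numeric vector).
#' @examples
#' glycemic_profile(2, 4, 70, 20, 4)
#' @export
glycemic_profile <- function(pct_vlow, pct_low, pct_tir, pct_high, pct_vhigh) {
  p <- c(pct_vlow = unname(pct_vlow), pct_low = unname(pct_low),
         pct_tir = unname(pct_tir), pct_high = unname(pct_high),
         pct_vhigh = unname(pct_vhigh))
  if (any(!is.finite(p))) stopf("non-finite band percentage")
  if (any(p < 0) || any(p > 100)) {
    bad <- names(p)[p < 0 | p > 100][1]
    stopf("band percentage out of [0,100]: %s = %g", bad, p[[bad]])
  }
  if (abs(sum(p) - 100) > 1e-6) {
    stopf("band percentages must sum to 100, got %.8f", sum(p))
  }
  structure(p, class = "glycemic_profile")
}

as_profile <- function(x) {
  if (inherits(x, "glycemic_profile")) return(x)
  if (is.numeric(x) && length(x) == 5) return(do.call(glycemic_profile, as.list(unname(x))))
  stopf("cannot interpret object of class '%s' as a glycemic profile", class(x)[1])
}

#' @export
print.glycemic_profile <- function(x, ...) {
  cat("Glycemic profile (% time): <54:", x[["pct_vlow"]],
      " 54-69:", x[["pct_low"]], " 70-180:", x[["pct_tir"]],
      " 181-250:", x[["pct_high"]], " >250:", x[["pct_vhigh"]], "\n")
  invisible(x)
}

#' Construct a CGM glucose trace
#'
#' Validates an ordered CGM time series. Raw glucose values outside the
#' plausible sensor range \code{[20, 600]} mg/dL are rejected; values are
#' then clamped to the CGM reporting range \code{[40, 400]} mg/dL, the
#' convention of current sensor displays.
#'
#' @param time timestamps (\code{POSIXct} or numeric), strictly increasing.
#' @param glucose glucose readings in mg/dL, same length as \code{time}.
#' @return data.frame of class \code{glucose_trace} with columns
#'   \code{time}, \code{glucose}.
#' @export
glucose_trace <- function(time, glucose) {
  if (length(time) != length(glucose)) stopf("time and glucose lengths differ")
  if (length(time) == 0) stopf("empty trace")
  if (any(!is.finite(glucose))) stopf("non-finite glucose value")
  if (any(diff(as.numeric(time)) <= 0)) stopf("timestamps must be strictly increasing")
  if (any(glucose < 20 | glucose > 600)) {
    stopf("glucose value outside plausible range [20, 600] mg/dL: %g",
          glucose[glucose < 20 | glucose > 600][1])
  }
  structure(data.frame(time = time, glucose = pmin(pmax(glucose, 40), 400)),
            class = c("glucose_trace", "data.frame"))
}

# Band index (1..5) of each glucose value under the stated edge convention.
band_of <- function(g) {
  findInterval(g, c(-Inf, 54, 70, 180 + 1e-12, 250 + 1e-12))
}

#' Band occupancy profile of a CGM trace
#'
#' Computes the percentage of time spent in each glucose band. Readings are
#' weighted by the duration of their sampling interval; for uniformly sampled
#' traces this reduces to equal weights. Interval durations are capped at
#' twice the median interval so isolated gaps do not dominate.
#'
#' @param trace a \code{glucose_trace} or data.frame with \code{time} and
#'   \code{glucose} columns.
#' @return a \code{\link{glycemic_profile}}.
#' @examples
#' tr <- glucose_trace(1:5 * 300, c(50, 60, 100, 200, 300))
#' profile_from_trace(tr)
#' @export
profile_from_trace <- function(trace) {
  if (is.data.frame(trace) && !inherits(trace, "glucose_trace")) {
    trace <- glucose_trace(trace$time, trace$glucose)
  }
  if (nrow(trace) == 0) stopf("empty trace")
  g <- trace$glucose
  n <- length(g)
  if (n == 1) {
    w <- 1
  } else {
    dt <- diff(as.numeric(trace$time))
    med <- stats::median(dt)
    w <- pmin(c(dt, med), 2 * med) # last reading carries a median interval
  }
  b <- band_of(g)
  occ <- vapply(1:5, function(k) sum(w[b == k]), numeric(1)) / sum(w) * 100
  # renormalize away float drift before the profile invariant check
  occ <- occ / sum(occ) * 100
  do.call(glycemic_profile, as.list(occ))
}

#' Time in range (70-180 mg/dL)
#'
#' @param profile a \code{\link{glycemic_profile}} (or 5-vector of band
#'   percentages).
#' @return TIR in percent.
#' @export
compute_tir <- function(profile) {
  as_profile(profile)[["pct_tir"]]
}

#' Glycemia Risk Index
#'
#' The GRI summarizes a CGM profile into a single 0-100 risk score weighting
#' hypoglycemia exposure more heavily than hyperglycemia:
#' \deqn{hypo = vlow + 0.8 \cdot low, \quad hyper = vhigh + 0.5 \cdot high}
#' \deqn{GRI = \min(100,\; 3.0 \cdot hypo + 1.6 \cdot hyper)}
#' 0 means no out-of-range time (minimal risk); 100 is the maximal risk. The
#' score maps onto five 20-point risk zones A (minimal) through E (maximal).
#'
#' @param profile a \code{\link{glycemic_profile}}.
#' @return list of class \code{gri_result}: \code{hypo_component},
#'   \code{hyper_component}, \code{gri}, \code{zone}.
#' @examples
#' compute_gri(glycemic_profile(2, 4, 70, 20, 4)) # gri 38, zone B
#' @export
compute_gri <- function(profile) {
  p <- as_profile(profile)
  hypo <- p[["pct_vlow"]] + 0.8 * p[["pct_low"]]
  hyper <- p[["pct_vhigh"]] + 0.5 * p[["pct_high"]]
  gri <- min(100, 3.0 * hypo + 1.6 * hyper)
  structure(list(hypo_component = hypo, hyper_component = hyper,
                 gri = gri, zone = classify_gri_zone(gri)),
            class = "gri_result")
}

#' @export
print.gri_result <- function(x, ...) {
  cat(sprintf("GRI %.2f (zone %s): hypo component %.2f, hyper component %.2f\n",
              x$gri, x$zone, x$hypo_component, x$hyper_component))
  invisible(x)
}

#' GRI risk zone
#'
#' Assigns the A-E risk zone of a GRI score. Zones are the equal 20-point
#' quintiles of the score, upper-closed: A \code{[0,20]}, B \code{(20,40]},
#' C \code{(40,60]}, D \code{(60,80]}, E \code{(80,100]}.
#'
#' @param gri GRI score(s) in \code{[0,100]}.
#' @return character vector of zone labels.
#' @examples
#' classify_gri_zone(c(0, 20, 20.000001, 56.4, 100))
#' @export
classify_gri_zone <- function(gri) {
  if (any(!is.finite(gri)) || any(gri < 0) || any(gri > 100)) {
    stopf("GRI out of [0,100]: %s",
          paste(gri[!is.finite(gri) | gri < 0 | gri > 100][1]))
  }
  LETTERS[pmax(ceiling(gri / 20), 1)]
}

#' Longitudinal change in a glycemic metric
#'
#' Signed change from baseline (M0) to follow-up (M12): \code{m12 - m0}.
#' Positive is an increase (an improvement for TIR); negative is a decrease
#' (an improvement for GRI).
#'
#' @param value_m0,value_m12 metric values in \code{[0,100]}.
#' @return signed change in the metric's units.
#' @examples
#' metric_delta(52.9, 72.7) # TIR gain of 19.8 points
#' @export
metric_delta <- function(value_m0, value_m12) {
  if (any(value_m0 < 0 | value_m0 > 100) || any(value_m12 < 0 | value_m12 > 100)) {
    stopf("metric values must lie in [0,100]")
  }
  value_m12 - value_m0
}

#' GRI zone grid counts for a cohort
#'
#' Tabulates patients of one arm (or the whole cohort) by GRI risk zone at a
#' timepoint and reports the count and fraction in the intermediate-to-high
#' risk zones C-E, the headline summary of a GRI zone grid.
#'
#' @param cohort a cohort data.frame (see \code{\link{generate_cohort}}), one
#'   row per patient-timepoint with columns \code{patient_id},
#'   \code{timepoint}, \code{gri}.
#' @param timepoint timepoint label, e.g. \code{"M0"} or \code{"M12"}.
#' @param arm optional arm label to subset on.
#' @return list: \code{counts} (named integer vector A-E), \code{n},
#'   \code{n_cde}, \code{frac_cde}.
#' @export
zone_grid_counts <- function(cohort, timepoint, arm = NULL) {
  if (!is.null(arm)) cohort <- cohort[cohort$arm == arm, , drop = FALSE]
  rows <- cohort[cohort$timepoint == timepoint, , drop = FALSE]
  ids <- unique(cohort$patient_id)
  missing <- setdiff(ids, rows$patient_id)
  if (length(missing) > 0) {
    stopf("no GRI at timepoint '%s' for patient(s): %s", timepoint,
          paste(utils::head(missing, 10), collapse = ", "))
  }
  zones <- factor(classify_gri_zone(rows$gri), levels = LETTERS[1:5])
  counts <- table(zones)
  n <- nrow(rows)
  n_cde <- sum(counts[c("C", "D", "E")])
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       n = n, n_cde = as.integer(n_cde), frac_cde = n_cde / n)
}
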