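# Incremental cost-effectiveness / cost-safety analysis between two care
# strategies: increments, ICER and ICSR with dominance classification.
#
# Conventions. Effectiveness is TIR (higher is better); safety is GRI
# (lower is better), so a negative incremental safety Delta-S is an
# improvement. Following ISPOR practice a negative ratio is never reported
# bare: every ratio carries the dominance/trade-off label of its quadrant,
# and when the outcome increment is within tolerance of zero a dominance
# flag replaces the ratio entirely.

#' Per-arm summary for cost-effectiveness analysis
#'
#' @param arm arm label.
#' @param n number of patients (>= 1).
#' @param cost_mean,cost_sd per-patient annual cost, EUR.
#' @param effect_mean,effect_sd effectiveness metric (TIR, percent).
#' @param safety_mean,safety_sd safety metric (GRI, score points).
#' @return list of class \code{arm_summary}.
#' @examples
#' arm_summary("CIRDIA", 128, 8373.12, 427.30, 72.65, 11.6, 30.11, 14.1)
#' @export
arm_summary <- function(arm, n, cost_mean, cost_sd, effect_mean, effect_sd,
                        safety_mean, safety_sd) {
  if (n < 1) stopf("n must be >= 1")
  if (cost_sd < 0 || effect_sd < 0 || safety_sd < 0) stopf("SDs must be >= 0")
  if (effect_mean < 0 || effect_mean > 100) stopf("effect mean outside [0,100]")
  if (safety_mean < 0 || safety_mean > 100) stopf("safety mean outside [0,100]")
  structure(list(arm = arm, n = as.integer(n),
                 cost_mean = cost_mean, cost_sd = cost_sd,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 safety_mean = safety_mean, safety_sd = safety_sd),
            class = "arm_summary")
}

#' Incremental cost, effectiveness and safety
#'
#' Componentwise differences, intervention minus comparator.
#'
#' @param intervention,comparator \code{\link{arm_summary}} objects on the
#'   same timepoint and outcome definitions.
#' @return named numeric vector \code{c(d_cost, d_effect, d_safety)}.
#' @examples
#' ci <- arm_summary("CIRDIA", 128, 8373.12, 427.3, 72.65, 11.6, 30.11, 14.1)
#' hc <- arm_summary("HC", 73, 8814.32, 192, 71.95, 10.5, 30.33, 13)
#' incremental(ci, hc) # -441.20, 0.70, -0.22
#' @export
incremental <- function(intervention, comparator) {
  c(d_cost = intervention$cost_mean - comparator$cost_mean,
    d_effect = intervention$effect_mean - comparator$effect_mean,
    d_safety = intervention$safety_mean - comparator$safety_mean)
}

#' Dominance classification on a cost-outcome plane
#'
#' Total classification of an (incremental cost, incremental outcome) pair,
#' where the outcome is oriented so that larger is better. \code{tol} is the
#' equality tolerance: increments within \code{tol} of zero count as "equal".
#'
#' \itemize{
#'   \item cheaper and better, or cheaper and equal: \code{dominant}
#'   \item costlier and worse, or costlier and equal: \code{dominated}
#'   \item costlier and better: \code{tradeoff_NE}
#'   \item cheaper and worse: \code{tradeoff_SW}
#'   \item equal cost: \code{indifferent}
#' }
#'
#' @param d_cost incremental cost (EUR).
#' @param d_outcome incremental outcome, better-is-larger orientation.
#' @param tol equality tolerance (>= 0), default \code{1e-9}.
#' @return one of \code{"dominant"}, \code{"dominated"},
#'   \code{"tradeoff_NE"}, \code{"tradeoff_SW"}, \code{"indifferent"}.
#' @examples
#' classify_dominance(-441.20, 0.70) # dominant
#' @export
classify_dominance <- function(d_cost, d_outcome, tol = 1e-9) {
  if (tol < 0) stopf("tol must be >= 0")
  if (abs(d_cost) <= tol) return("indifferent")
  if (d_cost < -tol) {
    if (d_outcome < -tol) "tradeoff_SW" else "dominant"
  } else {
    if (d_outcome > tol) "tradeoff_NE" else "dominated"
  }
}

# Label used by the ratio operations: unlike the bare plane classifier, an
# outcome gain at (tolerance-)zero incremental cost is dominant, and a loss
# is dominated ("improvement for free" needs no ratio).
ratio_label <- function(d_cost, d_outcome, tol) {
  if (abs(d_cost) <= tol) {
    if (d_outcome > tol) "dominant"
    else if (d_outcome < -tol) "dominated"
    else "indifferent"
  } else {
    classify_dominance(d_cost, d_outcome, tol)
  }
}

#' Incremental cost-effectiveness ratio
#'
#' EUR per percentage point of TIR gained. When the effectiveness increment
#' is within tolerance of zero no ratio exists and the dominance flag alone
#' is returned (cheaper-and-equal is dominant, costlier-and-equal is
#' dominated). A negative ratio is always returned together with its
#' quadrant label, never bare.
#'
#' @param d_cost incremental cost (EUR).
#' @param d_effect incremental effectiveness (TIR percentage points).
#' @param tol equality tolerance on increments.
#' @return list of class \code{cea_ratio}: \code{value} (EUR per TIR point,
#'   \code{NA} when a flag replaces the ratio), \code{label}.
#' @examples
#' icer(-441.20, 0.70) # -630.29, dominant
#' @export
icer <- function(d_cost, d_effect, tol = 1e-9) {
  label <- ratio_label(d_cost, d_effect, tol)
  value <- if (abs(d_effect) <= tol) NA_real_ else d_cost / d_effect
  structure(list(value = value, label = label, plane = "cost-TIR"),
            class = "cea_ratio")
}

#' Incremental cost-safety ratio
#'
#' Safety benefit is a reduction in GRI, so the ratio is expressed as a
#' positive magnitude: EUR per GRI point reduced, \code{|d_cost|/|d_safety|},
#' with the quadrant label computed on the safety plane (better =
#' lower GRI). Cheaper-and-safer is dominant.
#'
#' @param d_cost incremental cost (EUR).
#' @param d_safety incremental safety (GRI points; negative = improvement).
#' @param tol equality tolerance on increments.
#' @return list of class \code{cea_ratio}: \code{value} (positive magnitude,
#'   EUR per GRI point, \code{NA} when flagged), \code{label}.
#' @examples
#' icsr(-441.20, -0.22) # 2005.45, dominant
#' @export
icsr <- function(d_cost, d_safety, tol = 1e-9) {
  label <- ratio_label(d_cost, -d_safety, tol)
  value <- if (abs(d_safety) <= tol) NA_real_ else abs(d_cost) / abs(d_safety)
  structure(list(value = value, label = label, plane = "cost-GRI"),
            class = "cea_ratio")
}

#' @export
print.cea_ratio <- function(x, ...) {
  v <- if (is.na(x$value)) "no ratio (flagged)" else sprintf("%.2f EUR/point", x$value)
  cat(sprintf("%s plane: %s [%s]\n", x$plane, v, x$label))
  invisible(x)
}

#' Base-case cost-effectiveness analysis
#'
#' Full deterministic comparison of two arm summaries: increments on cost,
#' effectiveness (TIR) and safety (GRI), ICER and ICSR with dominance
#' labels on both planes.
#'
#' @inheritParams incremental
#' @param tol equality tolerance on increments.
#' @return list of class \code{cea_result}: \code{increments},
#'   \code{icer}, \code{icsr}, \code{dominance_tir}, \code{dominance_gri},
#'   and the two input summaries.
#' @export
cea_base_case <- function(intervention, comparator, tol = 1e-9) {
  inc <- incremental(intervention, comparator)
  structure(list(
    intervention = intervention, comparator = comparator,
    increments = inc,
    icer = icer(inc[["d_cost"]], inc[["d_effect"]], tol),
    icsr = icsr(inc[["d_cost"]], inc[["d_safety"]], tol),
    dominance_tir = classify_dominance(inc[["d_cost"]], inc[["d_effect"]], tol),
    dominance_gri = classify_dominance(inc[["d_cost"]], -inc[["d_safety"]], tol)),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Base-case CEA: %s vs %s\n", x$intervention$arm, x$comparator$arm))
  cat(sprintf("  incremental cost  %+.2f EUR\n", x$increments[["d_cost"]]))
  cat(sprintf("  incremental TIR   %+.2f points (%s)\n",
              x$increments[["d_effect"]], x$dominance_tir))
  cat(sprintf("  incremental GRI   %+.2f points (%s)\n",
              x$increments[["d_safety"]], x$dominance_gri))
  print(x$icer); print(x$icsr)
  invisible(x)
}

#' Export a base-case CEA as a Table-3-style data.frame
#'
#' @param result a \code{\link{cea_base_case}} result.
#' @return data.frame with \code{parameter}, \code{intervention},
#'   \code{comparator} columns mirroring the usual base-case layout.
#' @export
cea_table <- function(result) {
  i <- result$intervention; c0 <- result$comparator
  data.frame(
    parameter = c("cost_per_patient_eur", "incremental_cost_eur",
                  "mean_effect_tir", "incremental_effect_tir",
                  "mean_safety_gri", "incremental_safety_gri",
                  "icer_eur_per_tir_point", "icsr_eur_per_gri_point"),
    intervention = c(i$cost_mean, result$increments[["d_cost"]],
                     i$effect_mean, result$increments[["d_effect"]],
                     i$safety_mean, result$increments[["d_safety"]],
                     result$icer$value, result$icsr$value),
    comparator = c(c0$cost_mean, NA, c0$effect_mean, NA, c0$safety_mean,
                   NA, NA, NA),
    stringsAsFactors = FALSE)
}
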