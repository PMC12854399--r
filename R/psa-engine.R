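# Probabilistic sensitivity analysis: joint Monte Carlo sampling of all six
# arm-level parameters (cost, TIR, GRI per arm) and classification of every
# draw on the cost-effectiveness (cost vs TIR) and cost-safety (cost vs GRI)
# planes.
#
# Distribution conventions: costs are gamma, moment-matched to the supplied
# mean/SD; effectiveness and safety are normals truncated to [0, 100],
# parameterized by the parent normal's mean/SD (no truncation-moment
# correction). All six parameters are sampled independently.

#' PSA configuration
#'
#' @param n_sims number of Monte Carlo draws (default 10000).
#' @param scale uncertainty scale: \code{"sd"} samples each parameter with
#'   the arm-level SD as printed (default); \code{"se"} rescales each SD to
#'   the standard error of the mean, \code{sd/sqrt(n)}.
#' @param lower,upper truncation bounds for the effectiveness/safety
#'   normals.
#' @param seed integer RNG seed.
#' @return list of class \code{psa_config}.
#' @export
psa_config <- function(n_sims = 10000L, scale = c("sd", "se"),
                       lower = 0, upper = 100, seed = 1L) {
  scale <- match.arg(scale)
  if (n_sims < 1) stopf("n_sims must be >= 1")
  if (!(lower >= 0 && lower < upper && upper <= 100)) {
    stopf("need 0 <= lower < upper <= 100")
  }
  structure(list(n_sims = as.integer(n_sims), scale = scale,
                 lower = lower, upper = upper, seed = as.integer(seed)),
            class = "psa_config")
}

# SD or SE scaling of one arm's uncertainty per the config.
psa_sds <- function(summary, config) {
  f <- if (config$scale == "se") 1 / sqrt(summary$n) else 1
  list(cost = summary$cost_sd * f, effect = summary$effect_sd * f,
       safety = summary$safety_sd * f)
}

#' Sample the PSA parameter draws
#'
#' Draws the six arm-level parameters independently: per-arm cost from a
#' moment-matched gamma, per-arm TIR and GRI from truncated normals. An SD
#' of zero yields a degenerate point mass (with a warning), so a
#' zero-variance configuration collapses the PSA onto the base case.
#'
#' @param intervention,comparator \code{\link{arm_summary}} objects.
#' @param config a \code{\link{psa_config}}.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @return data.frame with \code{n_sims} rows: \code{cost_int},
#'   \code{cost_comp}, \code{effect_int}, \code{effect_comp},
#'   \code{safety_int}, \code{safety_comp}.
#' @export
sample_parameters <- function(intervention, comparator, config = psa_config(),
                              seed = config$seed) {
  n <- config$n_sims
  si <- psa_sds(intervention, config)
  sc <- psa_sds(comparator, config)
  if (any(unlist(si) == 0) || any(unlist(sc) == 0)) {
    warnf("one or more parameter SDs are 0: degenerate point-mass draws")
  }
  withr::local_seed(seed)
  data.frame(
    cost_int = rgamma_mm(n, intervention$cost_mean, si$cost),
    cost_comp = rgamma_mm(n, comparator$cost_mean, sc$cost),
    effect_int = rtnorm(n, intervention$effect_mean, si$effect, config$lower, config$upper),
    effect_comp = rtnorm(n, comparator$effect_mean, sc$effect, config$lower, config$upper),
    safety_int = rtnorm(n, intervention$safety_mean, si$safety, config$lower, config$upper),
    safety_comp = rtnorm(n, comparator$safety_mean, sc$safety, config$lower, config$upper))
}

#' Quadrant of the cost-effectiveness plane
#'
#' Strict-sign classification of an (incremental cost, incremental outcome)
#' pair, with the outcome oriented so larger is better: \code{SE} less
#' costly & more effective, \code{SW} less costly & less effective,
#' \code{NE} more costly & more effective, \code{NW} more costly & less
#' effective. Exact zeros (probability-zero under continuous sampling) are
#' assigned to the side of the base-case increment's sign via
#' \code{tie_cost}/\code{tie_outcome} (+1 or -1).
#'
#' @param d_cost,d_outcome incremental cost and outcome (vectorized).
#' @param tie_cost,tie_outcome sign (+1/-1) used for exact-zero increments.
#' @return character vector of quadrant labels.
#' @examples
#' quadrant_of(c(-1, 1), c(1, -1)) # "SE" "NW"
#' @export
quadrant_of <- function(d_cost, d_outcome, tie_cost = -1, tie_outcome = 1) {
  dc <- ifelse(d_cost == 0, tie_cost, d_cost)
  de <- ifelse(d_outcome == 0, tie_outcome, d_outcome)
  ifelse(dc < 0, ifelse(de > 0, "SE", "SW"),
         ifelse(de > 0, "NE", "NW"))
}

quadrant_props <- function(labels, n) {
  counts <- table(factor(labels, levels = c("SE", "SW", "NE", "NW")))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       props = stats::setNames(as.numeric(counts) / n, names(counts)))
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples all parameters jointly (\code{\link{sample_parameters}}), forms
#' per-draw increments (intervention minus comparator), classifies each draw
#' on the cost-TIR plane (more TIR = better) and the cost-GRI plane (less
#' GRI = better), and summarizes quadrant occupancy. Deterministic given the
#' seed.
#'
#' @inheritParams sample_parameters
#' @return list of class \code{psa_result}: \code{draws} (data.frame with
#'   per-draw increments and quadrant labels), \code{tir_plane} and
#'   \code{gri_plane} (counts and proportions per quadrant),
#'   \code{prop_less_costly}, \code{n_sims}, \code{config}.
#' @examples
#' ci <- arm_summary("CIRDIA", 128, 8373.12, 427.3, 72.7, 11.6, 30.1, 14.1)
#' hc <- arm_summary("HC", 73, 8814.32, 192, 71.9, 10.5, 30.3, 13)
#' res <- run_psa(ci, hc, psa_config(n_sims = 1000, seed = 7))
#' res$prop_less_costly
#' @export
run_psa <- function(intervention, comparator, config = psa_config(),
                    seed = config$seed) {
  if (!inherits(config, "psa_config")) stopf("config must be a psa_config")
  par <- sample_parameters(intervention, comparator, config, seed)
  base <- incremental(intervention, comparator)
  d_cost <- par$cost_int - par$cost_comp
  d_effect <- par$effect_int - par$effect_comp
  d_safety <- par$safety_int - par$safety_comp
  sgn <- function(x, fallback) if (x == 0) fallback else sign(x)
  q_tir <- quadrant_of(d_cost, d_effect,
                       tie_cost = sgn(base[["d_cost"]], -1),
                       tie_outcome = sgn(base[["d_effect"]], 1))
  q_gri <- quadrant_of(d_cost, -d_safety,
                       tie_cost = sgn(base[["d_cost"]], -1),
                       tie_outcome = sgn(-base[["d_safety"]], 1))
  draws <- data.frame(d_cost = d_cost, d_effect = d_effect,
                      d_safety = d_safety, quadrant_tir = q_tir,
                      quadrant_gri = q_gri, stringsAsFactors = FALSE)
  structure(list(
    draws = draws,
    tir_plane = quadrant_props(q_tir, config$n_sims),
    gri_plane = quadrant_props(q_gri, config$n_sims),
    prop_less_costly = mean(d_cost < 0),
    n_sims = config$n_sims,
    config = config),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d Monte Carlo draws (%s scale)\n", x$n_sims, x$config$scale))
  cat(sprintf("  intervention less costly: %.1f%%\n", 100 * x$prop_less_costly))
  p <- x$tir_plane$props
  cat(sprintf("  cost-TIR plane: SE %.1f%%  SW %.1f%%  NE %.1f%%  NW %.1f%%\n",
              100 * p[["SE"]], 100 * p[["SW"]], 100 * p[["NE"]], 100 * p[["NW"]]))
  p <- x$gri_plane$props
  cat(sprintf("  cost-GRI plane: SE %.1f%%  SW %.1f%%  NE %.1f%%  NW %.1f%%\n",
              100 * p[["SE"]], 100 * p[["SW"]], 100 * p[["NE"]], 100 * p[["NW"]]))
  invisible(x)
}

#' Export the cost-effectiveness plane scatter
#'
#' One row per draw with the increments and both quadrant labels, suitable
#' for plotting the two scatter panels (cost vs TIR, cost vs GRI) or for
#' recomputing quadrant counts downstream.
#'
#' @param result a \code{\link{run_psa}} result.
#' @param path optional CSV path; if given the table is also written there.
#' @return the scatter data.frame, invisibly when \code{path} is given.
#' @export
export_ce_plane <- function(result, path = NULL) {
  if (!inherits(result, "psa_result")) stopf("result must be a psa_result")
  if (nrow(result$draws) == 0) stopf("empty PSA result")
  out <- cbind(draw = seq_len(nrow(result$draws)), result$draws)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
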