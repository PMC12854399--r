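# Between-group statistics: Shapiro-Wilk normality gate dispatching a
# two-tailed Student t test or a Wilcoxon rank-sum (Mann-Whitney) test,
# age-class subgroup tables, and inverse probability of treatment weighting
# for the non-randomized arm comparison.

AGE_CLASS_LEVELS <- c("<25", "25-45", "45-65", ">=65")

#' Age class of an age in years
#'
#' Half-open classes \code{[16,25)}, \code{[25,45)}, \code{[45,65)},
#' \code{[65,Inf)}, labeled \code{"<25"}, \code{"25-45"}, \code{"45-65"},
#' \code{">=65"}.
#'
#' @param age numeric age(s) in years.
#' @return factor with the four class levels.
#' @examples
#' age_class_label(c(24, 25, 44, 45, 64, 65, 80))
#' @export
age_class_label <- function(age) {
  cut(age, breaks = c(-Inf, 25, 45, 65, Inf), right = FALSE,
      labels = AGE_CLASS_LEVELS)
}

#' Shapiro-Wilk normality gate
#'
#' Tests a sample for normality; \code{is_normal} is \code{TRUE} when the
#' Shapiro-Wilk p value is at or above \code{alpha}. A constant sample, for
#' which the statistic is undefined, is treated as non-normal with a
#' warning.
#'
#' @param x numeric sample, length >= 3 (and <= 5000, the test's limit).
#' @param alpha gate level (default 0.05).
#' @return list: \code{statistic} (W), \code{p_value}, \code{is_normal}.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3) stopf("normality gate needs n >= 3, got %d", length(x))
  if (stats::var(x) == 0) {
    warnf("constant sample: normality undefined, treated as non-normal")
    return(list(statistic = NA_real_, p_value = NA_real_, is_normal = FALSE))
  }
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       is_normal = sw$p.value >= alpha)
}

#' Normality-gated two-group comparison
#'
#' If both samples pass the Shapiro-Wilk gate, a two-tailed two-sample
#' Student t test is used; otherwise the Wilcoxon rank-sum (Mann-Whitney)
#' test. The result records which branch fired.
#'
#' @param x,y numeric samples, each n >= 3.
#' @param alpha significance threshold (default 0.05), also used by the
#'   normality gate.
#' @param var_equal logical, passed to \code{t.test} (classical Student test
#'   by default).
#' @return list of class \code{comparison_result}: \code{test} ("t" or
#'   "wilcoxon"), \code{statistic}, \code{p_value}, \code{significant},
#'   \code{mean_x}, \code{sd_x}, \code{n_x}, \code{mean_y}, \code{sd_y},
#'   \code{n_y}.
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(40), rnorm(40, 1))
#' @export
compare_groups <- function(x, y, alpha = 0.05, var_equal = TRUE) {
  if (length(x) < 3 || length(y) < 3) stopf("each group needs n >= 3")
  gx <- suppressWarnings(normality_gate(x, alpha))
  gy <- suppressWarnings(normality_gate(y, alpha))
  if (gx$is_normal && gy$is_normal) {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    test <- "t"
  } else {
    tt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    test <- "wilcoxon"
  }
  structure(list(test = test, statistic = unname(tt$statistic),
                 p_value = tt$p.value, significant = tt$p.value < alpha,
                 mean_x = mean(x), sd_x = stats::sd(x), n_x = length(x),
                 mean_y = mean(y), sd_y = stats::sd(y), n_y = length(y)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s test: %.1f (%.1f) n=%d vs %.1f (%.1f) n=%d, P = %.3g%s\n",
              x$test, x$mean_x, x$sd_x, x$n_x, x$mean_y, x$sd_y, x$n_y,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Age-class subgroup comparison table
#'
#' Compares a glycemic metric between the two arms within each age class and
#' overall, mirroring the usual outcome-by-age-class table layout. Classes
#' with fewer than 3 patients in either arm are reported with their n and no
#' test.
#'
#' @param cohort cohort data.frame (one row per patient-timepoint, columns
#'   \code{arm}, \code{age_class} or \code{age}, \code{timepoint} and the
#'   metric).
#' @param metric column name, e.g. \code{"tir"} or \code{"gri"}.
#' @param timepoint timepoint label, e.g. \code{"M12"}.
#' @param arms character(2): intervention and comparator labels; defaults to
#'   the two arms present.
#' @return data.frame with one row per age class plus a \code{"Total"} row:
#'   per-arm n, mean, SD, p value and the test used.
#' @export
subgroup_table <- function(cohort, metric, timepoint, arms = NULL) {
  rows <- cohort[cohort$timepoint == timepoint, , drop = FALSE]
  if (nrow(rows) == 0) stopf("no rows at timepoint '%s'", timepoint)
  if (!metric %in% names(rows)) stopf("metric column '%s' not found", metric)
  if (is.null(rows$age_class)) rows$age_class <- age_class_label(rows$age)
  if (is.null(arms)) arms <- unique(rows$arm)
  if (length(arms) != 2) stopf("need exactly 2 arms, got %d", length(arms))
  groups <- c(as.list(AGE_CLASS_LEVELS), list(NULL))
  labels <- c(AGE_CLASS_LEVELS, "Total")
  out <- lapply(seq_along(groups), function(i) {
    sub <- if (is.null(groups[[i]])) rows else rows[rows$age_class == groups[[i]], , drop = FALSE]
    x <- sub[[metric]][sub$arm == arms[1]]
    y <- sub[[metric]][sub$arm == arms[2]]
    base <- data.frame(
      subgroup = labels[i],
      n_int = length(x), mean_int = if (length(x)) mean(x) else NA_real_,
      sd_int = if (length(x) > 1) stats::sd(x) else NA_real_,
      n_comp = length(y), mean_comp = if (length(y)) mean(y) else NA_real_,
      sd_comp = if (length(y) > 1) stats::sd(y) else NA_real_,
      stringsAsFactors = FALSE)
    if (length(x) >= 3 && length(y) >= 3) {
      cmp <- compare_groups(x, y)
      base$p_value <- cmp$p_value
      base$test <- cmp$test
    } else {
      base$p_value <- NA_real_
      base$test <- NA_character_
    }
    base
  })
  do.call(rbind, out)
}

#' Inverse probability of treatment weighting
#'
#' Adjusts the non-randomized arm comparison for measured confounding:
#' fits a logistic propensity model of arm membership on the covariates,
#' forms stabilized weights (arm prevalence over the propensity for the
#' intervention arm and its complement for the comparator), truncates
#' weights at their 1st/99th percentiles, and returns weighted per-arm
#' summaries of cost/TIR/GRI together with weighted standardized mean
#' differences (SMD) per covariate.
#'
#' @param data one row per patient: \code{arm} plus covariate and outcome
#'   columns.
#' @param covariates character vector of covariate column names (numeric or
#'   two-level factors).
#' @param intervention label of the intervention arm (propensity target);
#'   defaults to the first arm encountered.
#' @param outcomes outcome columns to summarize (those present among
#'   \code{cost_eur}, \code{tir}, \code{gri} by default).
#' @param trunc_probs weight truncation percentiles.
#' @return list of class \code{iptw_result}: \code{weights} (per patient),
#'   \code{summaries} (per arm x outcome: weighted mean/SD), \code{balance}
#'   (per covariate: unweighted and weighted SMD), \code{propensity}.
#' @export
iptw_adjust <- function(data, covariates, intervention = NULL,
                        outcomes = intersect(c("cost_eur", "tir", "gri"), names(data)),
                        trunc_probs = c(0.01, 0.99)) {
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) stopf("missing covariate column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(data[covariates])) stopf("covariates contain missing values")
  arms <- unique(data$arm)
  if (length(arms) != 2) stopf("IPTW needs exactly 2 arms, got %d", length(arms))
  if (is.null(intervention)) intervention <- arms[1]
  treated <- as.integer(data$arm == intervention)
  num_cov <- covariates[vapply(data[covariates], is.numeric, logical(1))]
  constant <- num_cov[vapply(data[num_cov], function(v) stats::var(v) == 0, logical(1))]
  model_cov <- setdiff(covariates, constant)
  if (length(model_cov) == 0) {
    ps <- rep(mean(treated), nrow(data))
    fit <- NULL
  } else {
    fml <- stats::as.formula(paste("treated ~", paste(model_cov, collapse = " + ")))
    fit <- stats::glm(fml, data = cbind(data, treated = treated), family = stats::binomial())
    ps <- stats::fitted(fit)
  }
  eps <- 1e-8
  if (any(ps <= eps & treated == 1) || any(ps >= 1 - eps & treated == 0)) {
    bad <- data$patient_id[(ps <= eps & treated == 1) | (ps >= 1 - eps & treated == 0)]
    stopf("propensity non-overlap for patient(s): %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  prev <- mean(treated)
  w <- ifelse(treated == 1, prev / ps, (1 - prev) / (1 - ps))
  qs <- stats::quantile(w, trunc_probs)
  w <- pmin(pmax(w, qs[1]), qs[2])
  summaries <- do.call(rbind, lapply(arms, function(a) {
    sel <- data$arm == a
    do.call(rbind, lapply(outcomes, function(oc) {
      data.frame(arm = a, outcome = oc,
                 mean_w = wtd_mean(data[[oc]][sel], w[sel]),
                 sd_w = wtd_sd(data[[oc]][sel], w[sel]),
                 stringsAsFactors = FALSE)
    }))
  }))
  balance <- do.call(rbind, lapply(covariates, function(cv) {
    v <- data[[cv]]
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    sel <- treated == 1
    data.frame(covariate = cv,
               smd_unweighted = smd(v[sel], v[!sel]),
               smd_weighted = smd(v[sel], v[!sel], w[sel], w[!sel]),
               stringsAsFactors = FALSE)
  }))
  structure(list(weights = w, summaries = summaries, balance = balance,
                 propensity = ps, intervention = intervention, model = fit),
            class = "iptw_result")
}

# Standardized mean difference, optionally weighted; pooled-SD denominator.
smd <- function(x, y, wx = rep(1, length(x)), wy = rep(1, length(y))) {
  mx <- wtd_mean(x, wx); my <- wtd_mean(y, wy)
  sx <- wtd_sd(x, wx); sy <- wtd_sd(y, wy)
  denom <- sqrt((sx^2 + sy^2) / 2)
  if (denom == 0) return(0)
  (mx - my) / denom
}
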