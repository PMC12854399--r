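# Seeded synthetic two-arm cohort generator.
#
# The generator reproduces the statistical structure of a two-arm
# observational closed-loop initiation cohort: arm sizes, truncated-normal
# TIR/GRI distributions at baseline (M0) and 12 months (M12), demographics,
# care-pathway events and per-patient costs. Marginals are specified as
# parent-normal mean/SD truncated to [0, 100]; within-patient M0->M12
# dependence and the TIR-GRI dependence are induced by a Gaussian copula
# (Kronecker correlation structure: time x metric), so the four latent
# normals stay a valid correlation matrix for any pair of admissible
# correlations.

#' Specification of a synthetic two-arm cohort
#'
#' Collects every parameter the generator needs. Defaults reproduce the
#' structure of a 201-patient closed-loop initiation cohort: 128 patients in
#' an out-of-hospital arm (\code{"CIRDIA"}) and 73 in a hospital arm
#' (\code{"HC"}), with baseline and 12-month TIR/GRI means and SDs, cost
#' targets, demographics and care-pathway event counts.
#'
#' @param n named integer vector: patients per arm.
#' @param tir,gri named lists per arm; each a list with \code{m0} and
#'   \code{m12} entries of \code{c(mean, sd)} (percent / score points,
#'   parent-normal scale; values truncated to \code{[0,100]} at draw time).
#' @param cost_target named list per arm: \code{c(mean, sd)} of per-patient
#'   total annual cost in EUR.
#' @param rho_time within-patient latent correlation between M0 and M12
#'   values of the same metric, in \code{[-1,1]}.
#' @param rho_tir_gri latent correlation between TIR and GRI at the same
#'   timepoint (strongly negative: both summarize one profile).
#' @param age_breaks,age_props age-class boundaries (years) and the
#'   proportion of patients per class (must sum to 1); ages are drawn
#'   uniformly within a class and confined to \code{[16, 80]}.
#' @param prop_women proportion of women.
#' @param bmi named list per arm: \code{c(mean, sd)} of BMI (kg/m^2),
#'   truncated to \code{[15, 60]}.
#' @param dh_fraction fraction of out-of-hospital initiations performed as a
#'   day hospitalization rather than an office visit.
#' @param telemonitoring_fraction fraction of patients (either arm) with the
#'   optional 3-month telemonitoring package.
#' @param n_teleconsultations,n_consultations follow-up event counts per
#'   patient over the year.
#' @param device_months months of device/consumable rental charged.
#' @param seed integer RNG seed.
#' @return validated list of class \code{cohort_spec}.
#' @examples
#' spec <- cohort_spec()
#' spec$n
#' @export
cohort_spec <- function(n = c(CIRDIA = 128L, HC = 73L),
                        tir = list(
                          CIRDIA = list(m0 = c(52.9, 16), m12 = c(72.7, 11.6)),
                          HC = list(m0 = c(65.9, 15.1), m12 = c(71.9, 10.5))),
                        gri = list(
                          CIRDIA = list(m0 = c(56.4, 21), m12 = c(30.1, 14.1)),
                          HC = list(m0 = c(37.8, 19.8), m12 = c(30.3, 13))),
                        cost_target = list(CIRDIA = c(8373.12, 427.3),
                                           HC = c(8814.32, 192)),
                        rho_time = 0.4,
                        rho_tir_gri = -0.85,
                        age_breaks = c(16, 25, 45, 65, 80),
                        age_props = list(CIRDIA = c(0.102, 0.469, 0.359, 0.070),
                                         HC = c(0.110, 0.370, 0.425, 0.095)),
                        prop_women = 0.52,
                        bmi = list(CIRDIA = c(27.5, 4.9), HC = c(27.2, 5.2)),
                        dh_fraction = 0.13,
                        telemonitoring_fraction = 0.5,
                        n_teleconsultations = 3L,
                        n_consultations = 3L,
                        device_months = 12L,
                        seed = 1L) {
  spec <- list(n = n, tir = tir, gri = gri, cost_target = cost_target,
               rho_time = rho_time, rho_tir_gri = rho_tir_gri,
               age_breaks = age_breaks, age_props = age_props,
               prop_women = prop_women, bmi = bmi,
               dh_fraction = dh_fraction,
               telemonitoring_fraction = telemonitoring_fraction,
               n_teleconsultations = as.integer(n_teleconsultations),
               n_consultations = as.integer(n_consultations),
               device_months = as.integer(device_months),
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  arms <- names(spec$n)
  if (is.null(arms) || any(arms == "")) stopf("n: arms must be named")
  if (any(spec$n < 1)) stopf("n: sample sizes must be >= 1")
  for (arm in arms) {
    for (metric in c("tir", "gri")) {
      for (tp in c("m0", "m12")) {
        v <- spec[[metric]][[arm]][[tp]]
        if (is.null(v) || length(v) != 2) {
          stopf("%s$%s$%s: need c(mean, sd)", metric, arm, tp)
        }
        if (v[1] < 0 || v[1] > 100) {
          stopf("%s$%s$%s: mean %g outside [0,100]", metric, arm, tp, v[1])
        }
        if (v[2] < 0) stopf("%s$%s$%s: sd must be >= 0", metric, arm, tp)
      }
    }
    ct <- spec$cost_target[[arm]]
    if (is.null(ct) || ct[1] <= 0 || ct[2] < 0) {
      stopf("cost_target$%s: need mean > 0 and sd >= 0", arm)
    }
    ap <- spec$age_props[[arm]]
    if (length(ap) != length(spec$age_breaks) - 1) {
      stopf("age_props$%s: need %d proportions", arm, length(spec$age_breaks) - 1)
    }
    if (any(ap < 0) || abs(sum(ap) - 1) > 1e-9) {
      stopf("age_props$%s: proportions must be >= 0 and sum to 1", arm)
    }
    if (is.null(spec$bmi[[arm]]) || spec$bmi[[arm]][2] < 0) {
      stopf("bmi$%s: need c(mean, sd) with sd >= 0", arm)
    }
  }
  for (f in c("prop_women", "dh_fraction", "telemonitoring_fraction")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) stopf("%s: must lie in [0,1]", f)
  }
  for (f in c("rho_time", "rho_tir_gri")) {
    if (abs(spec[[f]]) > 1) stopf("%s: must lie in [-1,1]", f)
  }
  if (is.unsorted(spec$age_breaks, strictly = TRUE)) {
    stopf("age_breaks: must be strictly increasing")
  }
  invisible(spec)
}

# 4x4 latent correlation: (M0, M12) x (TIR, GRI) Kronecker product, PSD by
# construction for any admissible rho pair.
latent_chol <- function(rho_time, rho_tir_gri) {
  a <- matrix(c(1, rho_time, rho_time, 1), 2)
  b <- matrix(c(1, rho_tir_gri, rho_tir_gri, 1), 2)
  r <- kronecker(a, b)
  # shrink marginally if a rho of +-1 makes chol() unhappy
  if (abs(rho_time) == 1 || abs(rho_tir_gri) == 1) {
    r <- 0.999999 * r + 0.000001 * diag(4)
  }
  chol(r)
}

#' Generate a synthetic two-arm cohort
#'
#' Draws one row per patient-timepoint (M0 and M12) with demographics,
#' TIR and GRI. TIR and GRI marginals are normals truncated to
#' \code{[0, 100]}; the within-patient M0-M12 dependence and the negative
#' TIR-GRI dependence are induced through a Gaussian copula so marginal
#' distributions are preserved exactly. Regeneration with the same spec is
#' bit-identical.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return data.frame with columns \code{patient_id}, \code{arm},
#'   \code{age}, \code{age_class}, \code{gender}, \code{bmi},
#'   \code{timepoint}, \code{tir}, \code{gri}.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 42))
#' table(coh$arm[coh$timepoint == "M0"])
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  withr::local_seed(spec$seed)
  ch <- latent_chol(spec$rho_time, spec$rho_tir_gri)
  out <- list()
  for (arm in names(spec$n)) {
    n <- spec$n[[arm]]
    # latent draws: columns (TIR_M0, GRI_M0, TIR_M12, GRI_M12)
    z <- matrix(stats::rnorm(n * 4), n, 4) %*% ch
    u <- stats::pnorm(z)
    tir0 <- qtnorm(u[, 1], spec$tir[[arm]]$m0[1], spec$tir[[arm]]$m0[2])
    gri0 <- qtnorm(u[, 2], spec$gri[[arm]]$m0[1], spec$gri[[arm]]$m0[2])
    tir12 <- qtnorm(u[, 3], spec$tir[[arm]]$m12[1], spec$tir[[arm]]$m12[2])
    gri12 <- qtnorm(u[, 4], spec$gri[[arm]]$m12[1], spec$gri[[arm]]$m12[2])
    # demographics
    k <- length(spec$age_props[[arm]])
    cls <- sample.int(k, n, replace = TRUE, prob = spec$age_props[[arm]])
    lo <- spec$age_breaks[cls]
    hi <- spec$age_breaks[cls + 1]
    age <- floor(stats::runif(n, lo, hi))
    age <- pmin(pmax(age, 16), 80)
    gender <- ifelse(stats::runif(n) < spec$prop_women, "F", "M")
    bmi <- rtnorm(n, spec$bmi[[arm]][1], spec$bmi[[arm]][2], 15, 60)
    id <- sprintf("%s-%03d", arm, seq_len(n))
    base <- data.frame(patient_id = id, arm = arm, age = age,
                       age_class = age_class_label(age), gender = gender,
                       bmi = bmi, stringsAsFactors = FALSE)
    m0 <- cbind(base, timepoint = "M0", tir = tir0, gri = gri0)
    m12 <- cbind(base, timepoint = "M12", tir = tir12, gri = gri12)
    out[[arm]] <- rbind(m0, m12)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic CGM trace with prescribed band occupancy
#'
#' Builds a glucose time series whose band occupancy matches a target
#' profile by construction: reading counts are allocated to the five bands
#' by largest-remainder rounding, glucose values are drawn uniformly within
#' each band, and the sequence is shuffled deterministically under the seed.
#' The traces carry no physiological dynamics; they exist so that band
#' occupancy computations can be exercised from raw readings.
#'
#' @param target a \code{\link{glycemic_profile}} (band percentages summing
#'   to 100).
#' @param duration_days trace length in days (>= 1).
#' @param sampling_minutes sampling interval in minutes (>= 1).
#' @param seed integer RNG seed.
#' @param start start time (POSIXct origin of the trace).
#' @return a \code{\link{glucose_trace}} with
#'   \code{duration_days * 1440 / sampling_minutes} readings.
#' @examples
#' tr <- generate_cgm_trace(glycemic_profile(2, 4, 70, 20, 4),
#'                          duration_days = 14, sampling_minutes = 5, seed = 7)
#' profile_from_trace(tr)
#' @export
generate_cgm_trace <- function(target, duration_days = 14, sampling_minutes = 5,
                               seed = 1L,
                               start = as.POSIXct("2024-01-01", tz = "UTC")) {
  target <- as_profile(target)
  if (duration_days < 1) stopf("duration_days must be >= 1")
  if (sampling_minutes < 1) stopf("sampling_minutes must be >= 1")
  n <- floor(duration_days * 1440 / sampling_minutes)
  counts <- largest_remainder(unclass(target), n)
  # draw ranges keep generated values strictly inside each band
  lo <- c(40, 54, 70, 180.001, 250.001)
  hi <- c(53.999, 69.999, 180, 250, 400)
  withr::local_seed(seed)
  g <- unlist(lapply(1:5, function(k) {
    if (counts[k] == 0) return(numeric(0))
    stats::runif(counts[k], lo[k], hi[k])
  }))
  g <- g[sample.int(n)] # deterministic shuffle under the seed
  glucose_trace(start + seq_len(n) * 60 * sampling_minutes, g)
}

#' Generate care-pathway cost items for one arm of a cohort
#'
#' Emits the bottom-up resource-use lines of each patient's first year on a
#' closed loop: one initiation event (day hospitalization or long office
#' visit), 3 teleconsultations, 3 consultations, an optional 3-month
#' telemonitoring package, and 12 months of device/consumable rental. The
#' device/consumable quantity is a continuous months-equivalent drawn from a
#' moment-matched gamma calibrated (see \code{\link{calibrate_device_charge}})
#' so that priced per-arm totals hit the spec's cost mean/SD targets.
#'
#' @param arm arm label present in \code{spec$n}.
#' @param catalog a \code{\link{tariff_catalog}} containing the pathway
#'   codes (see \code{\link{pathway_codes}}).
#' @param spec a \code{\link{cohort_spec}}.
#' @param seed integer RNG seed.
#' @param patient_ids optional ids (defaults to the ids
#'   \code{\link{generate_cohort}} assigns for this arm).
#' @return data.frame of class \code{cost_items}: \code{patient_id},
#'   \code{source}, \code{code}, \code{quantity}, \code{timepoint}.
#' @export
generate_cost_items <- function(arm, catalog, spec, seed = spec$seed,
                                patient_ids = NULL) {
  spec <- validate_cohort_spec(spec)
  if (!arm %in% names(spec$n)) stopf("unknown arm '%s'", arm)
  pc <- pathway_codes()
  for (i in seq_len(nrow(pc))) {
    if (is.na(catalog_tariff(catalog, pc$source[i], pc$code[i]))) {
      stopf("tariff catalog is missing pathway code %s/%s",
            pc$source[i], pc$code[i])
    }
  }
  n <- spec$n[[arm]]
  if (is.null(patient_ids)) patient_ids <- sprintf("%s-%03d", arm, seq_len(n))
  if (length(patient_ids) != n) stopf("need %d patient ids, got %d", n, length(patient_ids))
  dh_frac <- if (arm == "CIRDIA") spec$dh_fraction else 1
  cal <- calibrate_device_charge(arm, catalog, spec)
  withr::local_seed(seed)
  dh <- stats::runif(n) < dh_frac
  tele <- stats::runif(n) < spec$telemonitoring_fraction
  device_eur <- rgamma_mm(n, cal$mean, cal$sd)
  rent <- catalog_tariff(catalog, "LPP", "CL-RENT")
  rows <- lapply(seq_len(n), function(i) {
    it <- data.frame(
      source = c(if (dh[i]) "GHS" else "NGAP",
                 "NGAP", "NGAP",
                 if (tele[i]) "LPP" else character(0),
                 "LPP"),
      code = c(if (dh[i]) "1794" else "INIT-CL",
               "TCG", "CSD",
               if (tele[i]) "TLS-3M" else character(0),
               "CL-RENT"),
      quantity = c(1, spec$n_teleconsultations, spec$n_consultations,
                   if (tele[i]) 1 else numeric(0),
                   device_eur[i] / rent),
      stringsAsFactors = FALSE)
    it$patient_id <- patient_ids[i]
    it
  })
  items <- do.call(rbind, rows)
  items$timepoint <- "Y1"
  structure(items[, c("patient_id", "source", "code", "quantity", "timepoint")],
            class = c("cost_items", "data.frame"))
}

#' Care-pathway event codes
#'
#' The catalog keys the generator charges: closed-loop initiation as a day
#' hospitalization (GHS 1794, diagnosis Z451) or a long office visit,
#' teleconsultations, specialist consultations, the 3-month telemonitoring
#' package and monthly device/consumable rental.
#'
#' @return data.frame with columns \code{source}, \code{code}, \code{event}.
#' @export
pathway_codes <- function() {
  data.frame(
    source = c("GHS", "NGAP", "NGAP", "NGAP", "LPP", "LPP"),
    code = c("1794", "INIT-CL", "TCG", "CSD", "TLS-3M", "CL-RENT"),
    event = c("day hospitalization (Z451 pump adjustment)",
              "closed-loop initiation office visit",
              "teleconsultation", "specialist consultation",
              "telemonitoring package (3 months)",
              "device/consumable rental (per month)"),
    stringsAsFactors = FALSE)
}

#' Calibrate the device/consumable charge to the arm cost target
#'
#' The fixed pathway events (initiation, consultations, telemonitoring)
#' explain only part of the per-arm cost mean and variance; the
#' device/consumable rental absorbs the residual. With Bernoulli initiation
#' mode (day hospitalization with probability \code{p_dh}) and Bernoulli
#' telemonitoring uptake, the fixed component's mean and variance are
#' available in closed form, so the gamma-distributed device charge needs
#' mean \code{target_mean - E[fixed]} and variance
#' \code{max(0, target_sd^2 - Var[fixed])}.
#'
#' @inheritParams generate_cost_items
#' @return list with \code{mean} and \code{sd} of the per-patient annual
#'   device/consumable charge (EUR).
#' @export
calibrate_device_charge <- function(arm, catalog, spec) {
  spec <- validate_cohort_spec(spec)
  p_dh <- if (arm == "CIRDIA") spec$dh_fraction else 1
  p_tl <- spec$telemonitoring_fraction
  t_dh <- catalog_tariff(catalog, "GHS", "1794")
  t_init <- catalog_tariff(catalog, "NGAP", "INIT-CL")
  t_tc <- catalog_tariff(catalog, "NGAP", "TCG")
  t_cs <- catalog_tariff(catalog, "NGAP", "CSD")
  t_tl <- catalog_tariff(catalog, "LPP", "TLS-3M")
  fixed_mean <- p_dh * t_dh + (1 - p_dh) * t_init +
    spec$n_teleconsultations * t_tc + spec$n_consultations * t_cs +
    p_tl * t_tl
  fixed_var <- p_dh * (1 - p_dh) * (t_dh - t_init)^2 + p_tl * (1 - p_tl) * t_tl^2
  target <- spec$cost_target[[arm]]
  dev_mean <- target[1] - fixed_mean
  if (dev_mean <= 0) {
    stopf("cost target %.2f for arm '%s' is below the fixed pathway cost %.2f",
          target[1], arm, fixed_mean)
  }
  dev_var <- target[2]^2 - fixed_var
  if (dev_var < 0) {
    warnf("fixed pathway variance exceeds the cost target SD^2 for arm '%s'; device charge made deterministic", arm)
    dev_var <- 0
  }
  list(mean = dev_mean, sd = sqrt(dev_var))
}

#' Write a cohort and its cost items to CSV
#'
#' One row per patient-timepoint for the cohort; one row per cost item.
#'
#' @param cohort data.frame from \code{\link{generate_cohort}}.
#' @param items data.frame from \code{\link{generate_cost_items}} (or
#'   several arms' items row-bound), or \code{NULL} to skip.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, items = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "cohort.csv")
  utils::write.csv(cohort, paths, row.names = FALSE)
  if (!is.null(items)) {
    p2 <- file.path(dir, "cost_items.csv")
    utils::write.csv(items, p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}

# YAML 1.1 treats a bare key `n` as a boolean; restore it.
fix_yaml_keys <- function(raw) {
  names(raw)[names(raw) == "FALSE" | names(raw) == "no"] <- "n"
  raw
}

#' Read a cohort specification from YAML or JSON
#'
#' Accepts a file holding any subset of \code{\link{cohort_spec}} arguments;
#' unspecified fields keep their defaults.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a \code{\link{cohort_spec}}.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stopf("spec file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    fix_yaml_keys(yaml::read_yaml(path))
  }
  args <- raw[intersect(names(raw), names(formals(cohort_spec)))]
  if (!is.null(args$n)) args$n <- unlist(args$n)
  for (f in c("tir", "gri")) {
    if (!is.null(args[[f]])) {
      args[[f]] <- lapply(args[[f]], function(a) lapply(a, unlist))
    }
  }
  for (f in c("cost_target", "age_props", "bmi")) {
    if (!is.null(args[[f]])) args[[f]] <- lapply(args[[f]], unlist)
  }
  if (!is.null(args$age_breaks)) args$age_breaks <- unlist(args$age_breaks)
  do.call(cohort_spec, args)
}
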