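# End-to-end pipeline: synthetic cohort (or user CSVs) -> glycemic metrics
# -> micro-costing -> group statistics -> base-case CEA -> PSA, with all
# report tables written as CSV and a JSON manifest tying the run together.

#' Pipeline run configuration
#'
#' @param out_dir output directory for report tables and the manifest.
#' @param cohort_spec a \code{\link{cohort_spec}} (synthetic run), or
#'   \code{NULL} when \code{cohort_csv} is given.
#' @param cohort_csv optional path to a cohort CSV (one row per
#'   patient-timepoint with \code{patient_id}, \code{arm}, \code{age},
#'   \code{gender}, \code{bmi}, \code{timepoint}, \code{tir}, \code{gri}).
#' @param cost_items_csv optional path to a cost-items CSV; when absent and
#'   the run is synthetic, items are generated from the spec.
#' @param catalog_path tariff catalog CSV/JSON; defaults to the synthetic
#'   catalog shipped with the package.
#' @param arms character(2): intervention and comparator arm labels.
#' @param timepoints baseline and follow-up timepoint labels.
#' @param psa a \code{\link{psa_config}}.
#' @param iptw_covariates covariate columns for the IPTW stage, or
#'   \code{NULL} to skip it.
#' @param seed master seed; overrides the seeds in \code{cohort_spec} and
#'   \code{psa} when not \code{NULL}.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(out_dir,
                       cohort_spec = NULL,
                       cohort_csv = NULL,
                       cost_items_csv = NULL,
                       catalog_path = system.file("extdata", "tariff_catalog_synthetic.csv",
                                                  package = "cgmcea"),
                       arms = c("CIRDIA", "HC"),
                       timepoints = c(baseline = "M0", followup = "M12"),
                       psa = psa_config(),
                       iptw_covariates = c("age", "bmi", "tir_m0", "gri_m0"),
                       seed = NULL) {
  if (is.null(cohort_spec) && is.null(cohort_csv)) {
    stopf("provide either a cohort_spec or a cohort_csv")
  }
  if (!is.null(cohort_csv) && !file.exists(cohort_csv)) {
    stopf("cohort_csv not found: %s", cohort_csv)
  }
  if (!file.exists(catalog_path)) stopf("catalog not found: %s", catalog_path)
  if (length(arms) != 2) stopf("arms must name the intervention and comparator")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (!is.null(cohort_spec)) cohort_spec$seed <- seed
    psa$seed <- seed
  }
  structure(list(out_dir = out_dir, cohort_spec = cohort_spec,
                 cohort_csv = cohort_csv, cost_items_csv = cost_items_csv,
                 catalog_path = catalog_path, arms = arms,
                 timepoints = timepoints, psa = psa,
                 iptw_covariates = iptw_covariates, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may hold any subset of \code{\link{run_config}} arguments;
#' \code{cohort_spec} is given inline (same fields as
#' \code{\link{read_cohort_spec}} accepts) and \code{psa} as a mapping of
#' \code{\link{psa_config}} arguments.
#'
#' @param path configuration file path.
#' @param out_dir overrides the configured output directory when given.
#' @return a \code{\link{run_config}}.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  if (!is.null(args$cohort_spec)) {
    sp <- fix_yaml_keys(args$cohort_spec)
    f <- tempfile(fileext = ".json")
    on.exit(unlink(f), add = TRUE)
    jsonlite::write_json(sp, f, auto_unbox = TRUE)
    args$cohort_spec <- read_cohort_spec(f)
  }
  if (!is.null(args$psa)) args$psa <- do.call(psa_config, args$psa)
  if (!is.null(args$arms)) args$arms <- unlist(args$arms)
  if (!is.null(args$timepoints)) args$timepoints <- unlist(args$timepoints)
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(run_config, args)
}

#' Run the full cost-effectiveness pipeline
#'
#' Executes, in order: cohort acquisition (synthetic generation or CSV
#' load), cost-item generation/loading and micro-costing, GRI zone grids,
#' per-arm summaries and group statistics (overall and by age class), IPTW
#' adjustment, base-case CEA and the PSA. Writes the report tables as CSV
#' files under \code{config$out_dir} plus a \code{manifest.json} holding
#' every headline number; a failure in any stage aborts the run, names the
#' stage, and removes partial outputs. Idempotent given the seed.
#'
#' @param config a \code{\link{run_config}}.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  out <- config$out_dir
  created <- !dir.exists(out)
  if (created) dir.create(out, recursive = TRUE)
  written <- character(0)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      unlink(written)
      if (created) unlink(out, recursive = TRUE)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    say("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - s0)
    res
  }
  emit <- function(df, file) {
    p <- file.path(out, file)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  tp0 <- config$timepoints[[1]]
  tp1 <- config$timepoints[[2]]
  arms <- config$arms

  catalog <- stage("catalog", read_tariff_catalog(config$catalog_path))

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_csv)) {
      utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
    } else {
      generate_cohort(config$cohort_spec)
    }
  })
  emit(cohort, "cohort.csv")

  items <- stage("cost_items", {
    if (!is.null(config$cost_items_csv)) {
      utils::read.csv(config$cost_items_csv, stringsAsFactors = FALSE,
                      colClasses = c(code = "character"))
    } else {
      sp <- config$cohort_spec
      do.call(rbind, lapply(names(sp$n), function(a) {
        generate_cost_items(a, catalog, sp, seed = sp$seed + match(a, names(sp$n)))
      }))
    }
  })
  emit(items, "cost_items.csv")

  costs <- stage("micro_costing", {
    arm_of <- stats::setNames(cohort$arm[!duplicated(cohort$patient_id)],
                              cohort$patient_id[!duplicated(cohort$patient_id)])
    cohort_cost_table(items, catalog, arms = arm_of)
  })
  emit(costs, "patient_costs.csv")
  cost_sums <- lapply(arms, function(a) arm_cost_summary(costs, a))
  names(cost_sums) <- arms

  zones <- stage("zone_grids", {
    do.call(rbind, lapply(arms, function(a) {
      do.call(rbind, lapply(c(tp0, tp1), function(tp) {
        z <- zone_grid_counts(cohort, tp, arm = a)
        data.frame(arm = a, timepoint = tp, t(z$counts), n = z$n,
                   n_cde = z$n_cde, frac_cde = z$frac_cde)
      }))
    }))
  })
  emit(zones, "gri_zone_grid.csv")

  stats_tabs <- stage("group_stats", {
    list(tir_m0 = subgroup_table(cohort, "tir", tp0, arms),
         tir_m12 = subgroup_table(cohort, "tir", tp1, arms),
         gri_m0 = subgroup_table(cohort, "gri", tp0, arms),
         gri_m12 = subgroup_table(cohort, "gri", tp1, arms))
  })
  outcomes_tab <- do.call(rbind, lapply(names(stats_tabs), function(nm) {
    cbind(metric = sub("_m[0-9]+$", "", nm),
          timepoint = ifelse(grepl("m0$", nm), tp0, tp1), stats_tabs[[nm]])
  }))
  emit(outcomes_tab, "glycemic_outcomes.csv")

  wide <- stage("wide_cohort", {
    b <- cohort[cohort$timepoint == tp0, c("patient_id", "arm", "age", "gender", "bmi", "tir", "gri")]
    names(b)[names(b) %in% c("tir", "gri")] <- c("tir_m0", "gri_m0")
    f <- cohort[cohort$timepoint == tp1, c("patient_id", "tir", "gri")]
    names(f)[names(f) %in% c("tir", "gri")] <- c("tir", "gri")
    m <- merge(b, f, by = "patient_id")
    merge(m, costs[, c("patient_id", "total_eur")], by = "patient_id")
  })

  iptw <- NULL
  if (!is.null(config$iptw_covariates)) {
    iptw <- stage("iptw", {
      d <- wide
      names(d)[names(d) == "total_eur"] <- "cost_eur"
      iptw_adjust(d, config$iptw_covariates, intervention = arms[1])
    })
    emit(iptw$balance, "iptw_balance.csv")
    emit(iptw$summaries, "iptw_summaries.csv")
  }

  summaries <- stage("arm_summaries", {
    lapply(arms, function(a) {
      sel <- wide$arm == a
      arm_summary(a, sum(sel),
                  mean(wide$total_eur[sel]), stats::sd(wide$total_eur[sel]),
                  mean(wide$tir[sel]), stats::sd(wide$tir[sel]),
                  mean(wide$gri[sel]), stats::sd(wide$gri[sel]))
    })
  })
  names(summaries) <- arms

  cea <- stage("cea", cea_base_case(summaries[[arms[1]]], summaries[[arms[2]]]))
  emit(cea_table(cea), "cea_base_case.csv")

  psa <- stage("psa", run_psa(summaries[[arms[1]]], summaries[[arms[2]]], config$psa))
  emit(export_ce_plane(psa), "ce_plane.csv")

  manifest <- list(
    arms = as.list(stats::setNames(
      lapply(arms, function(a) {
        s <- summaries[[a]]
        list(n = s$n, cost = c(s$cost_mean, s$cost_sd),
             tir = c(s$effect_mean, s$effect_sd),
             gri = c(s$safety_mean, s$safety_sd),
             cost_total_eur = cost_sums[[a]]$total_eur)
      }), arms)),
    cea = list(increments = as.list(cea$increments),
               icer = cea$icer$value, icer_label = cea$icer$label,
               icsr = cea$icsr$value, icsr_label = cea$icsr$label,
               dominance_tir = cea$dominance_tir,
               dominance_gri = cea$dominance_gri),
    psa = list(n_sims = psa$n_sims,
               prop_less_costly = psa$prop_less_costly,
               tir_plane = as.list(psa$tir_plane$props),
               gri_plane = as.list(psa$gri_plane$props)),
    zone_grid = split(zones[, setdiff(names(zones), "arm")], zones$arm),
    iptw_balance = if (!is.null(iptw)) as.list(stats::setNames(
      iptw$balance$smd_weighted, iptw$balance$covariate)),
    seed = config$seed,
    files = basename(written))
  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  say("pipeline complete in %.2fs -> %s", proc.time()[["elapsed"]] - t0, out)
  invisible(manifest)
}
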