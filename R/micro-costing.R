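# Bottom-up micro-costing from the payer perspective: care-pathway events
# priced against a tariff catalog keyed by French payer nomenclatures
# (NGAP professional acts, CCAM procedures, NABM laboratory acts, LPP
# devices, GHS hospital-stay tariffs). One-year horizon: no discounting, no
# out-of-pocket share.

CATALOG_SOURCES <- c("NGAP", "CCAM", "NABM", "LPP", "GHS")

#' Construct a tariff catalog
#'
#' A catalog of unit tariffs keyed by (nomenclature source, code). The
#' package ships a synthetic example catalog with plausible placeholder
#' tariffs (\code{system.file("extdata", "tariff_catalog_synthetic.csv",
#' package = "cgmcea")}); real published tariff values are the user's
#' responsibility.
#'
#' @param entries data.frame with columns \code{source} (one of NGAP, CCAM,
#'   NABM, LPP, GHS), \code{code}, \code{description}, \code{tariff_eur}
#'   (>= 0) and \code{year}.
#' @return data.frame of class \code{tariff_catalog}.
#' @export
tariff_catalog <- function(entries) {
  req <- c("source", "code", "description", "tariff_eur", "year")
  miss <- setdiff(req, names(entries))
  if (length(miss) > 0) stopf("catalog is missing column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(entries$source), CATALOG_SOURCES)
  if (length(bad) > 0) stopf("unknown nomenclature source(s): %s", paste(bad, collapse = ", "))
  if (any(entries$tariff_eur < 0)) stopf("tariffs must be >= 0")
  key <- paste(entries$source, entries$code)
  if (anyDuplicated(key)) stopf("duplicate catalog key: %s", key[duplicated(key)][1])
  structure(as.data.frame(entries), class = c("tariff_catalog", "data.frame"))
}

#' Read a tariff catalog from CSV or JSON
#'
#' @param path file with the \code{\link{tariff_catalog}} columns.
#' @return a \code{\link{tariff_catalog}}.
#' @export
read_tariff_catalog <- function(path) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(code = "character"))
  }
  tariff_catalog(entries)
}

# Unit tariff for (source, code); NA if absent.
catalog_tariff <- function(catalog, source, code) {
  hit <- catalog$source == source & catalog$code == code
  if (!any(hit)) return(NA_real_)
  catalog$tariff_eur[which(hit)[1]]
}

#' Price a single cost item
#'
#' \code{quantity * unit tariff}, with no discounting (1-year horizon) and
#' no out-of-pocket share (payer perspective, fully covered condition).
#'
#' @param item list or one-row data.frame with \code{source}, \code{code},
#'   \code{quantity} (> 0).
#' @param catalog a \code{\link{tariff_catalog}}.
#' @return price in EUR.
#' @examples
#' cat <- tariff_catalog(data.frame(source = "NGAP", code = "TCG",
#'   description = "teleconsultation", tariff_eur = 25, year = 2024))
#' price_item(list(source = "NGAP", code = "TCG", quantity = 3), cat) # 75
#' @export
price_item <- function(item, catalog) {
  q <- item$quantity
  if (is.null(q) || !is.finite(q) || q <= 0) stopf("cost item quantity must be > 0")
  t <- catalog_tariff(catalog, item$source, item$code)
  if (is.na(t)) stopf("unknown catalog key: %s/%s", item$source, item$code)
  q * t
}

#' Total cost of one patient's item list
#'
#' Prices every item and aggregates the total with per-nomenclature-source
#' subtotals.
#'
#' @param items data.frame of cost items for one patient (columns
#'   \code{source}, \code{code}, \code{quantity}; optionally
#'   \code{patient_id}, used in error messages and carried through).
#' @param catalog a \code{\link{tariff_catalog}}.
#' @param arm optional arm label carried into the record.
#' @return list of class \code{patient_cost_record}: \code{patient_id},
#'   \code{arm}, \code{total_eur}, \code{subtotals_eur} (named by source).
#' @export
patient_total_cost <- function(items, catalog, arm = NA_character_) {
  pid <- if ("patient_id" %in% names(items) && nrow(items) > 0) items$patient_id[1] else NA_character_
  if (nrow(items) == 0) {
    return(structure(list(patient_id = pid, arm = arm, total_eur = 0,
                          subtotals_eur = numeric(0)),
                     class = "patient_cost_record"))
  }
  prices <- vapply(seq_len(nrow(items)), function(i) {
    tryCatch(price_item(items[i, ], catalog), error = function(e) {
      stopf("patient %s: %s", pid, conditionMessage(e))
    })
  }, numeric(1))
  sub <- tapply(prices, items$source, sum)
  structure(list(patient_id = pid, arm = arm, total_eur = sum(prices),
                 subtotals_eur = stats::setNames(as.numeric(sub), names(sub))),
            class = "patient_cost_record")
}

#' Per-patient cost table for a whole set of items
#'
#' Convenience wrapper applying \code{\link{patient_total_cost}} per patient.
#'
#' @param items cost items for many patients (needs \code{patient_id}).
#' @param catalog a \code{\link{tariff_catalog}}.
#' @param arms optional named character vector mapping patient id to arm; if
#'   missing and ids look like \code{"<arm>-<number>"} the prefix is used.
#' @return data.frame: \code{patient_id}, \code{arm}, \code{total_eur}, one
#'   \code{eur_<source>} column per nomenclature source present.
#' @export
cohort_cost_table <- function(items, catalog, arms = NULL) {
  ids <- unique(items$patient_id)
  if (is.null(arms)) {
    arms <- stats::setNames(sub("-[0-9]+$", "", ids), ids)
  }
  recs <- lapply(ids, function(id) {
    patient_total_cost(items[items$patient_id == id, , drop = FALSE],
                       catalog, arm = unname(arms[id]))
  })
  sources <- sort(unique(unlist(lapply(recs, function(r) names(r$subtotals_eur)))))
  out <- data.frame(patient_id = ids,
                    arm = vapply(recs, function(r) r$arm, character(1)),
                    total_eur = vapply(recs, function(r) r$total_eur, numeric(1)),
                    stringsAsFactors = FALSE)
  for (s in sources) {
    out[[paste0("eur_", s)]] <- vapply(recs, function(r) {
      v <- r$subtotals_eur[s]
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1))
  }
  out
}

#' Per-arm cost summary
#'
#' @param records data.frame from \code{\link{cohort_cost_table}} (needs
#'   \code{arm} and \code{total_eur}).
#' @param arm arm label to summarize.
#' @return list: \code{arm}, \code{n}, \code{mean_eur}, \code{sd_eur}
#'   (sample SD, n-1 denominator; 0 with a warning for a single patient),
#'   \code{total_eur} (equal to \code{n * mean_eur}).
#' @examples
#' recs <- data.frame(arm = "A", total_eur = c(100, 200, 300))
#' arm_cost_summary(recs, "A")
#' @export
arm_cost_summary <- function(records, arm) {
  x <- records$total_eur[records$arm == arm]
  if (length(x) == 0) stopf("no cost records for arm '%s'", arm)
  s <- if (length(x) == 1) {
    warnf("arm '%s' has a single patient; SD reported as 0", arm)
    0
  } else {
    stats::sd(x)
  }
  list(arm = arm, n = length(x), mean_eur = mean(x), sd_eur = s,
       total_eur = sum(x))
}
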