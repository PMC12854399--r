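# Shared fixtures: a tiny in-code tariff catalog and the published per-arm
# summaries used across CEA/PSA tests.

fixture_catalog <- function() {
  tariff_catalog(data.frame(
    source = c("GHS", "NGAP", "NGAP", "NGAP", "LPP", "LPP", "NABM"),
    code = c("1794", "INIT-CL", "TCG", "CSD", "TLS-3M", "CL-RENT", "HGLY"),
    description = c("day hospitalization", "initiation visit",
                    "teleconsultation", "consultation",
                    "telemonitoring 3m", "device rental/month", "glucose panel"),
    tariff_eur = c(500, 120, 25, 57, 330, 600, 12.15),
    year = 2024,
    stringsAsFactors = FALSE))
}

shipped_catalog <- function() {
  read_tariff_catalog(system.file("extdata", "tariff_catalog_synthetic.csv",
                                  package = "cgmcea"))
}

# Base-case arm summaries (published per-arm means/SDs at 12 months).
arm_cirdia <- function() {
  arm_summary("CIRDIA", 128, 8373.12, 427.30, 72.65, 11.6, 30.11, 14.1)
}
arm_hc <- function() {
  arm_summary("HC", 73, 8814.32, 192, 71.95, 10.5, 30.33, 13)
}

random_profile <- function() {
  p <- stats::runif(5)
  do.call(glycemic_profile, as.list(p / sum(p) * 100))
}
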