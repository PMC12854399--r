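# Synthetic cohort generator: structure, determinism, degenerate cases,
# trace construction and cost-item generation.

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(n = c(CIRDIA = 0L, HC = 73L)), "sample sizes")
  expect_error(cohort_spec(dh_fraction = 1.2), "dh_fraction")
  expect_error(cohort_spec(rho_time = 1.5), "rho_time")
  expect_error(cohort_spec(age_props = list(CIRDIA = c(0.5, 0.4, 0.05, 0.04),
                                            HC = c(0.25, 0.25, 0.25, 0.25))),
               "age_props\\$CIRDIA")
  expect_error(
    cohort_spec(tir = list(CIRDIA = list(m0 = c(120, 5), m12 = c(70, 5)),
                           HC = list(m0 = c(60, 5), m12 = c(70, 5)))),
    "tir\\$CIRDIA\\$m0")
})

test_that("generate_cohort returns the requested structure within bounds", {
  coh <- generate_cohort(cohort_spec(seed = 42))
  m0 <- coh[coh$timepoint == "M0", ]
  expect_equal(nrow(m0), 201)
  expect_equal(sum(m0$arm == "CIRDIA"), 128)
  expect_equal(sum(m0$arm == "HC"), 73)
  expect_equal(nrow(coh), 2 * 201)
  expect_true(all(coh$age >= 16 & coh$age <= 80))
  expect_true(all(coh$tir >= 0 & coh$tir <= 100))
  expect_true(all(coh$gri >= 0 & coh$gri <= 100))
})

test_that("same seed regenerates a bit-identical cohort; seeds differ otherwise", {
  a <- generate_cohort(cohort_spec(seed = 7))
  b <- generate_cohort(cohort_spec(seed = 7))
  c <- generate_cohort(cohort_spec(seed = 8))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("zero-SD spec collapses every patient onto the arm means", {
  spec <- cohort_spec(
    n = c(CIRDIA = 10L, HC = 5L),
    tir = list(CIRDIA = list(m0 = c(52.9, 0), m12 = c(72.7, 0)),
               HC = list(m0 = c(65.9, 0), m12 = c(71.9, 0))),
    gri = list(CIRDIA = list(m0 = c(56.4, 0), m12 = c(30.1, 0)),
               HC = list(m0 = c(37.8, 0), m12 = c(30.3, 0))),
    seed = 3)
  coh <- generate_cohort(spec)
  sel <- coh$arm == "CIRDIA" & coh$timepoint == "M0"
  expect_true(all(coh$tir[sel] == 52.9))
  expect_true(all(coh$gri[sel] == 56.4))
  sel <- coh$arm == "HC" & coh$timepoint == "M12"
  expect_true(all(coh$tir[sel] == 71.9))
})

test_that("large-n sample moments recover the truncated-normal targets", {
  spec <- cohort_spec(n = c(CIRDIA = 5000L, HC = 5000L), seed = 11)
  coh <- generate_cohort(spec)
  for (arm in c("CIRDIA", "HC")) {
    for (metric in c("tir", "gri")) {
      for (tp in c("M0", "M12")) {
        par <- spec[[metric]][[arm]][[tolower(tp)]]
        mom <- tnorm_moments(par[1], par[2], 0, 100)
        x <- coh[[metric]][coh$arm == arm & coh$timepoint == tp]
        se_mean <- mom$sd / sqrt(5000)
        expect_lt(abs(mean(x) - mom$mean), 3 * se_mean)
        se_sd <- mom$sd / sqrt(2 * (5000 - 1)) # normal-theory SE of the SD
        expect_lt(abs(sd(x) - mom$sd), 4 * se_sd)
      }
    }
  }
})

test_that("generated TIR and GRI are strongly negatively correlated within patients", {
  coh <- generate_cohort(cohort_spec(n = c(CIRDIA = 2000L, HC = 10L), seed = 9))
  sel <- coh$arm == "CIRDIA" & coh$timepoint == "M0"
  expect_lt(cor(coh$tir[sel], coh$gri[sel], method = "spearman"), -0.7)
})

test_that("cgm trace hits the target occupancy by construction", {
  target <- glycemic_profile(2, 4, 70, 20, 4)
  tr <- generate_cgm_trace(target, duration_days = 14, sampling_minutes = 5, seed = 7)
  expect_equal(nrow(tr), 4032)
  back <- profile_from_trace(tr)
  expect_true(all(abs(unclass(back) - unclass(target)) <= 100 / 4032 + 1e-9))
  # single-band target stays in band
  tr2 <- generate_cgm_trace(glycemic_profile(0, 0, 100, 0, 0), 14, 5, seed = 1)
  expect_true(all(tr2$glucose >= 70 & tr2$glucose <= 180))
  # determinism
  expect_identical(tr, generate_cgm_trace(target, 14, 5, seed = 7))
  expect_error(generate_cgm_trace(c(2, 4, 70, 20, 5), 14, 5, 1), "sum to 100")
})

test_that("cost items follow the care pathway of each arm", {
  cat <- fixture_catalog()
  spec <- cohort_spec(n = c(CIRDIA = 40L, HC = 25L), seed = 4)
  hc <- generate_cost_items("HC", cat, spec, seed = 2)
  # every hospital patient has exactly one day hospitalization
  dh_per_pat <- tapply(hc$code == "1794", hc$patient_id, sum)
  expect_true(all(dh_per_pat == 1))
  # 3 teleconsultations + 3 consultations each
  expect_true(all(hc$quantity[hc$code == "TCG"] == 3))
  expect_true(all(hc$quantity[hc$code == "CSD"] == 3))
  expect_true(all(hc$quantity > 0))
  # out-of-hospital arm with DH fraction 0 has none
  spec0 <- cohort_spec(n = c(CIRDIA = 40L, HC = 25L), dh_fraction = 0, seed = 4)
  ci0 <- generate_cost_items("CIRDIA", cat, spec0, seed = 2)
  expect_false(any(ci0$code == "1794"))
  expect_equal(sum(ci0$code == "INIT-CL"), 40)
  # missing code is reported by name
  cat2 <- fixture_catalog()
  cat2 <- tariff_catalog(cat2[cat2$code != "TLS-3M", ])
  expect_error(generate_cost_items("HC", cat2, spec, seed = 2), "TLS-3M")
})

test_that("device-charge calibration reproduces the arm cost targets", {
  cat <- shipped_catalog()
  spec <- cohort_spec(seed = 42)
  items <- rbind(generate_cost_items("CIRDIA", cat, spec, seed = 1),
                 generate_cost_items("HC", cat, spec, seed = 2))
  tab <- cohort_cost_table(items, cat)
  ci <- arm_cost_summary(tab, "CIRDIA")
  hc <- arm_cost_summary(tab, "HC")
  expect_lt(abs(ci$mean_eur - 8373.12) / 8373.12, 0.01)
  expect_lt(abs(hc$mean_eur - 8814.32) / 8814.32, 0.01)
  expect_true(all(tab$total_eur > 0))
  # at large n the calibrated mean and SD converge on the targets
  spec_big <- cohort_spec(n = c(CIRDIA = 5000L, HC = 5000L), seed = 13)
  items_big <- generate_cost_items("CIRDIA", cat, spec_big, seed = 3)
  tab_big <- cohort_cost_table(items_big, cat)
  s <- arm_cost_summary(tab_big, "CIRDIA")
  expect_lt(abs(s$mean_eur - 8373.12), 3 * 427.3 / sqrt(5000))
  expect_lt(abs(s$sd_eur - 427.3), 4 * 427.3 / sqrt(2 * 4999))
})

test_that("cohort spec round-trips through YAML and JSON files", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n:", "  CIRDIA: 12", "  HC: 7", "seed: 99",
               "dh_fraction: 0.25"), f)
  sp <- read_cohort_spec(f)
  expect_equal(unname(sp$n), c(12, 7))
  expect_equal(sp$dh_fraction, 0.25)
  expect_equal(sp$seed, 99L)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n = list(CIRDIA = 5, HC = 4), seed = 2), fj,
                       auto_unbox = TRUE)
  spj <- read_cohort_spec(fj)
  expect_equal(unname(spj$n), c(5, 4))
  coh <- generate_cohort(spj)
  expect_equal(nrow(coh), 18)
})
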