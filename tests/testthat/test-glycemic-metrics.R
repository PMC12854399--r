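# Band occupancy, TIR, GRI and risk zones.

test_that("profile construction enforces the band invariants", {
  p <- glycemic_profile(2, 4, 70, 20, 4)
  expect_s3_class(p, "glycemic_profile")
  expect_equal(sum(p), 100)
  expect_error(glycemic_profile(2, 4, 70, 20, 5), "sum to 100")
  expect_error(glycemic_profile(-1, 5, 70, 20, 6), "out of \\[0,100\\]")
})

test_that("profile_from_trace partitions readings by the band cut-points", {
  # all in range
  tr <- glucose_trace(1:10 * 300, rep(100, 10))
  expect_equal(unclass(profile_from_trace(tr)),
               c(pct_vlow = 0, pct_low = 0, pct_tir = 100, pct_high = 0, pct_vhigh = 0))
  # one reading per band
  tr2 <- glucose_trace(1:5 * 300, c(50, 60, 100, 200, 300))
  expect_equal(unname(unclass(profile_from_trace(tr2))), rep(20, 5))
  # edge convention: 54 is low, 70 and 180 are in range, 250 is high
  tr3 <- glucose_trace(1:4 * 300, c(54, 70, 180, 250))
  p3 <- profile_from_trace(tr3)
  expect_equal(p3[["pct_low"]], 25)
  expect_equal(p3[["pct_tir"]], 50)
  expect_equal(p3[["pct_high"]], 25)
  expect_error(profile_from_trace(glucose_trace(numeric(0), numeric(0))), "empty")
})

test_that("trace validation rejects implausible input and clamps to CGM range", {
  expect_error(glucose_trace(1:2, c(100, 10)), "plausible range")
  expect_error(glucose_trace(c(2, 1), c(100, 100)), "increasing")
  tr <- glucose_trace(1:2, c(25, 500))
  expect_equal(tr$glucose, c(40, 400))
})

test_that("GRI components, composite and clipping follow the published formula", {
  r <- compute_gri(glycemic_profile(2, 4, 70, 20, 4))
  expect_equal(r$hypo_component, 2 + 0.8 * 4)
  expect_equal(r$hyper_component, 4 + 0.5 * 20)
  expect_equal(r$gri, 3.0 * 5.2 + 1.6 * 14.0) # 38.0
  expect_equal(r$zone, "B")
  # no out-of-range time -> zero risk
  r0 <- compute_gri(glycemic_profile(0, 0, 100, 0, 0))
  expect_equal(r0$gri, 0)
  expect_equal(r0$zone, "A")
  # raw score 3*56 + 1.6*30 = 216 clips at 100
  rE <- compute_gri(glycemic_profile(40, 20, 0, 20, 20))
  expect_equal(rE$gri, 100)
  expect_equal(rE$zone, "E")
})

test_that("GRI is monotone in out-of-range occupancy and zero iff no risk", {
  set.seed(11)
  for (i in 1:50) {
    p <- unclass(random_profile())
    g0 <- compute_gri(glycemic_profile(p[1], p[2], p[3], p[4], p[5]))$gri
    # move mass from the in-range band to an out-of-range band
    take <- min(p[3], 5)
    for (k in c(1, 2, 4, 5)) {
      q <- p
      q[k] <- q[k] + take
      q[3] <- q[3] - take
      g1 <- compute_gri(glycemic_profile(q[1], q[2], q[3], q[4], q[5]))$gri
      expect_gte(g1, g0)
    }
    r <- compute_gri(glycemic_profile(p[1], p[2], p[3], p[4], p[5]))
    expect_identical(r$gri == 0, r$hypo_component == 0 && r$hyper_component == 0)
    expect_lte(r$gri, 100)
  }
})

test_that("zone classification is total, gap-free and upper-closed", {
  expect_equal(classify_gri_zone(c(0, 20, 56.4, 100)), c("A", "A", "C", "E"))
  expect_equal(classify_gri_zone(20.000001), "B")
  grid <- (0:10000) / 100 # exact representation of the 20-point boundaries
  z <- classify_gri_zone(grid)
  expect_true(all(z %in% LETTERS[1:5]))
  # boundaries: zone changes exactly after 20, 40, 60, 80
  expect_equal(as.vector(table(z)[LETTERS[1:5]]),
               c(2001L, 2000L, 2000L, 2000L, 2000L))
  expect_error(classify_gri_zone(100.5), "out of")
})

test_that("metric_delta reproduces longitudinal changes and the identity case", {
  expect_equal(metric_delta(52.9, 72.7), 19.8)
  expect_equal(metric_delta(56.4, 30.1), -26.3)
  expect_equal(metric_delta(33.3, 33.3), 0)
  expect_error(metric_delta(-1, 50), "\\[0,100\\]")
})

test_that("zone grid counts partition the cohort and report the C-E fraction", {
  coh <- data.frame(patient_id = sprintf("P%d", 1:4), arm = "A",
                    timepoint = "M12", gri = c(10, 30, 50, 90))
  z <- zone_grid_counts(coh, "M12")
  expect_equal(unname(z$counts), c(1L, 1L, 1L, 0L, 1L))
  expect_equal(z$frac_cde, 0.5)
  expect_equal(sum(z$counts), z$n)
  # all minimal risk
  coh0 <- transform(coh, gri = 0)
  expect_equal(zone_grid_counts(coh0, "M12")$frac_cde, 0)
  # missing timepoint errors with the ids
  expect_error(zone_grid_counts(coh, "M0"), "P1")
})

test_that("a high-risk baseline cohort lands mostly in zones C-E", {
  # truncated-normal GRI with mean 56.4, SD 21 puts ~3/4 of patients at
  # GRI > 40 (zones C-E); check the Monte Carlo fraction at large n
  spec <- cohort_spec(n = c(CIRDIA = 4000L, HC = 10L), seed = 5)
  coh <- generate_cohort(spec)
  z <- zone_grid_counts(coh, "M0", arm = "CIRDIA")
  # P(GRI > 40) under the truncated normal, in closed form
  p_cde <- (pnorm(100, 56.4, 21) - pnorm(40, 56.4, 21)) /
    (pnorm(100, 56.4, 21) - pnorm(0, 56.4, 21))
  se <- sqrt(p_cde * (1 - p_cde) / 4000)
  expect_lt(abs(z$frac_cde - p_cde), 4 * se)
})
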