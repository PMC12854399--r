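# Monte Carlo probabilistic sensitivity analysis.

test_that("config validation enforces sims and truncation bounds", {
  expect_error(psa_config(n_sims = 0), "n_sims")
  expect_error(psa_config(lower = 50, upper = 40), "lower")
  expect_equal(psa_config(scale = "se")$scale, "se")
})

test_that("parameter draws match their target distributions (Monte Carlo oracle)", {
  cfg <- psa_config(n_sims = 200000L, seed = 5)
  draws <- sample_parameters(arm_cirdia(), arm_hc(), cfg)
  n <- cfg$n_sims
  # gamma cost margins: moment matching
  expect_lt(abs(mean(draws$cost_comp) - 8814.32), 3 * 192 / sqrt(n))
  expect_lt(abs(sd(draws$cost_comp) - 192), 4 * 192 / sqrt(2 * n))
  expect_lt(abs(mean(draws$cost_int) - 8373.12), 3 * 427.3 / sqrt(n))
  # truncated normal margins stay in bounds
  expect_true(all(draws$effect_int >= 0 & draws$effect_int <= 100))
  expect_true(all(draws$safety_comp >= 0 & draws$safety_comp <= 100))
  mom <- tnorm_moments(72.65, 11.6, 0, 100)
  expect_lt(abs(mean(draws$effect_int) - mom$mean), 3 * mom$sd / sqrt(n))
  expect_true(all(draws$cost_int > 0))
})

test_that("zero-variance configuration collapses to the base case", {
  a <- arm_summary("A", 10, 8000, 0, 70, 0, 30, 0)
  b <- arm_summary("B", 10, 8400, 0, 69, 0, 31, 0)
  expect_warning(res <- run_psa(a, b, psa_config(n_sims = 100, seed = 1)),
                 "degenerate")
  expect_equal(res$prop_less_costly, 1)
  expect_equal(unname(res$tir_plane$props["SE"]), 1) # cheaper, more effective
  expect_equal(unname(res$gri_plane$props["SE"]), 1) # cheaper, safer
  base <- cea_base_case(a, b)
  expect_equal(base$dominance_tir, "dominant")
})

test_that("quadrant_of equals brute-force sign enumeration on random points", {
  set.seed(6)
  n <- 100000
  dc <- runif(n, -1, 1)
  de <- runif(n, -1, 1)
  got <- quadrant_of(dc, de)
  brute <- ifelse(dc < 0 & de > 0, "SE",
           ifelse(dc < 0 & de < 0, "SW",
           ifelse(dc > 0 & de > 0, "NE", "NW")))
  expect_identical(got, brute)
  # documented tie convention for exact zeros
  expect_equal(quadrant_of(0, 1, tie_cost = -1), "SE")
  expect_equal(quadrant_of(0, 1, tie_cost = 1), "NE")
  expect_equal(quadrant_of(-1, 0, tie_outcome = -1), "SW")
})

test_that("quadrant proportions sum to one and less-costly equals SE+SW", {
  res <- run_psa(arm_cirdia(), arm_hc(), psa_config(n_sims = 5000, seed = 3))
  for (plane in list(res$tir_plane, res$gri_plane)) {
    expect_equal(sum(plane$props), 1, tolerance = 1e-12)
    expect_equal(sum(plane$counts), res$n_sims)
  }
  expect_equal(res$prop_less_costly,
               unname(res$tir_plane$props["SE"] + res$tir_plane$props["SW"]))
  expect_equal(res$prop_less_costly,
               unname(res$gri_plane$props["SE"] + res$gri_plane$props["SW"]))
})

test_that("the engine is seed-deterministic and seed-sensitive within noise", {
  cfg <- psa_config(n_sims = 10000, seed = 17)
  r1 <- run_psa(arm_cirdia(), arm_hc(), cfg)
  r2 <- run_psa(arm_cirdia(), arm_hc(), cfg)
  expect_identical(r1$draws, r2$draws)
  r3 <- run_psa(arm_cirdia(), arm_hc(), cfg, seed = 18)
  expect_false(identical(r1$draws, r3$draws))
  p <- r1$prop_less_costly
  expect_lt(abs(r3$prop_less_costly - p), 4 * sqrt(p * (1 - p) / 10000))
})

test_that("proportion less costly agrees with the normal-approximation closed form", {
  # both gammas have shape > 100, so the difference is near-normal:
  # P(cost_int < cost_comp) ~ Phi(441.20 / sqrt(427.3^2 + 192^2))
  res <- run_psa(arm_cirdia(), arm_hc(), psa_config(n_sims = 20000, seed = 8))
  p_analytic <- pnorm(441.20 / sqrt(427.3^2 + 192^2))
  se <- sqrt(p_analytic * (1 - p_analytic) / 20000)
  expect_lt(abs(res$prop_less_costly - p_analytic), 4 * se + 0.005)
})

test_that("estimates converge between n and 10n simulations", {
  r1 <- run_psa(arm_cirdia(), arm_hc(), psa_config(n_sims = 2000, seed = 19))
  r2 <- run_psa(arm_cirdia(), arm_hc(), psa_config(n_sims = 20000, seed = 20))
  p <- r2$prop_less_costly
  expect_lt(abs(r1$prop_less_costly - p), 5 * sqrt(p * (1 - p) / 2000))
})

test_that("ce-plane export has one row per draw and reproduces the counts", {
  res <- run_psa(arm_cirdia(), arm_hc(), psa_config(n_sims = 10, seed = 2))
  tab <- export_ce_plane(res)
  expect_equal(nrow(tab), 10)
  res2 <- run_psa(arm_cirdia(), arm_hc(), psa_config(n_sims = 3000, seed = 4))
  tab2 <- export_ce_plane(res2)
  recount <- table(factor(tab2$quadrant_tir, levels = c("SE", "SW", "NE", "NW")))
  expect_equal(as.vector(recount), unname(res2$tir_plane$counts))
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  export_ce_plane(res2, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 3000)
  expect_equal(back$d_cost, tab2$d_cost)
})

test_that("se scaling shrinks parameter uncertainty by sqrt(n)", {
  cfg <- psa_config(n_sims = 50000, scale = "se", seed = 9)
  draws <- sample_parameters(arm_cirdia(), arm_hc(), cfg)
  expect_lt(abs(sd(draws$cost_int) - 427.3 / sqrt(128)), 2)
  # under SE uncertainty the cost advantage is near-certain
  res <- run_psa(arm_cirdia(), arm_hc(), cfg)
  expect_gt(res$prop_less_costly, 0.99)
})
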