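test_that("hdi equals the brute-force shortest-window search", {
  ## all-tie case: integers 1..100 at mass 0.89 -> width-88 window at 1
  x <- as.numeric(1:100)
  expect_equal(hdi(x, 0.89), c(1, 89))

  set.seed(14)
  samples <- list(rnorm(500), rexp(301), rbeta(1000, 2, 8),
                  c(rnorm(300, -3), rnorm(200, 3)), runif(173))
  for (x in samples) for (mass in c(0.5, 0.89, 0.95)) {
    expect_equal(hdi(x, mass), oracle_hdi(x, mass), tolerance = 0)
  }
  expect_equal(hdi(rep(2.5, 50), 0.89), c(2.5, 2.5))
  expect_error(hdi(rnorm(10), 1.2), "mass")

  ## large standard normal: 89% HDI ~ [-1.60, 1.60]
  set.seed(15)
  z <- rnorm(2e5)
  expect_equal(hdi(z, 0.89), c(-1.598, 1.598), tolerance = 0.03)
})

test_that("hdi is never wider than the equal-tailed interval", {
  set.seed(16)
  for (x in list(rnorm(400), rexp(400), rbeta(400, 0.5, 3))) {
    for (mass in c(0.5, 0.89, 0.95)) {
      h <- hdi(x, mass)
      ci <- credible_interval(x, mass)
      expect_lte(h[2] - h[1], ci[2] - ci[1] + 1e-12)
    }
  }
})

test_that("credible intervals are equal-tailed quantiles and nested", {
  set.seed(17)
  u <- runif(5e4)
  expect_equal(credible_interval(u, 0.95), c(0.025, 0.975),
               tolerance = 0.005)
  x <- rnorm(2000)
  c90 <- credible_interval(x, 0.90)
  c95 <- credible_interval(x, 0.95)
  expect_gte(c90[1], c95[1])
  expect_lte(c90[2], c95[2])
  expect_equal(credible_interval(rep(1, 100), 0.95), c(1, 1))
  expect_error(credible_interval(x, 0), "level")
})

test_that("MAP estimation finds the density mode", {
  expect_equal(map_estimate(rep(3.7, 200)), 3.7)
  ## the KDE grid-mode of a Normal(5, 2) sample: each estimate within a
  ## 3-SD band of the estimator's own Monte-Carlo noise (~0.08 sigma at
  ## n = 2e5 with the Silverman bandwidth), and the replicate median well
  ## inside it
  set.seed(18)
  maps <- replicate(5, map_estimate(rnorm(2e5, 5, 2)))
  expect_true(all(abs(maps - 5) < 3 * 0.08 * 2))
  expect_lt(abs(median(maps) - 5), 0.05 * 2)
  ## right-skewed: mode < mean
  y <- rexp(5000) + rnorm(5000, 0, 0.05)
  expect_lt(map_estimate(y), mean(y))
  expect_error(map_estimate(rnorm(50)), "at least 100")
})

test_that("the HDI+ROPE decision rule reproduces the reference patterns", {
  ## a posterior like the body-mass coefficient row: HDI entirely below
  ## the ROPE -> 0% inside, significant
  set.seed(19)
  x <- rnorm(4000, -0.814, 0.33)
  x <- x[x >= -1.452 & x <= -0.302]       # confine to the reported HDI
  rd <- rope_decision(x, rope_spec(), 0.89)
  expect_equal(rd$pct_inside, 0)
  expect_true(rd$significant)

  ## HDI entirely inside the ROPE: 100%, not significant
  z <- runif(2000, -0.05, 0.05)
  rz <- rope_decision(z, rope_spec(), 0.89)
  expect_equal(rz$pct_inside, 1)
  expect_false(rz$significant)

  ## partial overlap (like the PV2 row [-0.162, 0.061]): 0 < pct < 1
  w <- runif(4000, -0.162, 0.061)
  rw <- rope_decision(w, rope_spec(), 0.89)
  expect_gt(rw$pct_inside, 0)
  expect_lt(rw$pct_inside, 1)
  expect_false(rw$significant)

  ## draw-fraction and length-fraction conventions agree at the decisions
  for (draws in list(x, z)) {
    a <- rope_decision(draws, rope_spec(), 0.89, convention = "draws")
    b <- rope_decision(draws, rope_spec(), 0.89, convention = "length")
    expect_equal(a$pct_inside, b$pct_inside, tolerance = 0.02)
    expect_identical(a$significant, b$significant)
  }

  ## translation consistency: shifting far from the ROPE empties it
  rs <- rope_decision(z + 10, rope_spec(), 0.89)
  expect_equal(rs$pct_inside, 0)
  expect_true(rs$significant)
})

test_that("CI significance is zero-exclusion of the equal-tailed interval", {
  expect_true(ci_significance(runif(100, 0.2, 0.9)))
  set.seed(20)
  expect_false(ci_significance(rnorm(5000)))
  ## a CI barely excluding zero (like PV1's [-0.435, -0.0002]) counts
  expect_true(ci_significance(runif(1000, -0.435, -0.0002), 0.999))
})

test_that("rank-normalized split-Rhat detects non-convergence", {
  set.seed(21)
  base <- rnorm(1000)
  ## chains that are permutations of each other
  m <- cbind(base, sample(base), sample(base), sample(base))
  expect_lt(abs(rhat(m) - 1), 0.01)
  ## one chain offset by 10 SD
  m2 <- cbind(rnorm(500), rnorm(500), rnorm(500) + 10)
  expect_gt(rhat(m2), 1.5)
  ## within-chain trend (non-stationarity) is caught by splitting
  m3 <- cbind(seq(0, 1, length.out = 600) + rnorm(600, 0, 0.05),
              seq(0, 1, length.out = 600) + rnorm(600, 0, 0.05))
  expect_gt(rhat(m3), 1.1)
  ## white noise, 4 chains of 1000
  m4 <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(m4), 1.01)
  expect_true(is.na(rhat(matrix(1, 100, 4))))
})

test_that("posterior predictive checks are calibrated and deterministic", {
  sim <- simulate_diet_data(
    simulation_truth(n_species = 4, psi = 0.8, seed = 33, n_pv_axes = 1),
    diet_design(n_records = 60, n_species = 4, seed = 33))
  f <- tpb_sample(tpb_model1(sim$records),
                  tpb_config(chains = 2, iter = 500, warmup = 300,
                             seed = 9))
  p1 <- posterior_predictive(f, seed = 4)
  p2 <- posterior_predictive(f, seed = 4)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), sum(!is.na(sim$records$y)))
  ## data were simulated from the model family: coverage near 0.95
  expect_gt(attr(p1, "coverage95"), 0.85)
  expect_true(all(p1$inside == (p1$y >= p1$yrep_lower &
                                  p1$y <= p1$yrep_upper)))
})

test_that("fit summaries expose the full decision schema", {
  rec <- make_records(30, J = 3, seed = 44)
  f <- tpb_sample(tpb_model1(rec),
                  tpb_config(chains = 2, iter = 400, warmup = 250,
                             seed = 2))
  s <- summary(f)
  expect_true(all(c("parameter", "MAP", "hdi_lower", "hdi_upper", "EAP",
                    "ci95_lower", "ci95_upper", "ci90_lower", "ci90_upper",
                    "pct_hdi_in_rope", "significant_rope",
                    "significant_ci", "rhat") %in% names(s)))
  expect_true(all(s$ci90_lower >= s$ci95_lower - 1e-12))
  expect_true(all(s$ci90_upper <= s$ci95_upper + 1e-12))
  expect_true(all(s$pct_hdi_in_rope >= 0 & s$pct_hdi_in_rope <= 1))
  ## methods on the fit object
  expect_length(predict(f), 30L)
  expect_true(all(is.na(residuals(f)) == is.na(rec$y)))
  ys <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(ys), c(3L, 30L))
  expect_true(all(ys <= matrix(rec$N, 3, 30, byrow = TRUE)))
  expect_silent(grDevices::pdf(NULL))
  expect_silent(plot(f, pars = c("psi", "alpha[S1]")))
  grDevices::dev.off()
})
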