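mentioned_records <- function(n = 30, seed = 2, mentioned_prob = 0.5) {
  rec <- make_records(n, J = 3, seed = seed, psi = 0.4,
                      mentioned_prob = mentioned_prob, with_env = TRUE)
  validate_diet_records(rec)
}

test_that("random imputation follows the grid-draw and clamp rules", {
  ## clamp rule at the grid edges
  expect_equal(tpbinom:::.impute_count(0.01, 10), 1)   # round gives 0
  expect_equal(tpbinom:::.impute_count(1.00, 17), 17)
  expect_equal(tpbinom:::.impute_count(0.5, 10), 5)
  expect_equal(tpbinom:::.impute_count(0.05, 10), 1)   # half rounds up

  rec <- mentioned_records()
  imp <- impute_random(rec, seed = 3)
  rows <- attr(imp, "imputed_rows")
  expect_true(length(rows) > 0)
  expect_true(all(imp$y[rows] >= 1 & imp$y[rows] <= imp$N[rows]))
  ## untouched rows identical
  expect_identical(imp$y[-rows], rec$y[-rows])
  expect_identical(imp[, setdiff(names(rec), c("y", "reported"))],
                   rec[, setdiff(names(rec), c("y", "reported"))])
  ## reproducible
  expect_identical(impute_random(rec, seed = 3)$y, imp$y)
  expect_false(identical(impute_random(rec, seed = 4)$y, imp$y))

  norec <- rec; norec$mentioned <- FALSE
  expect_warning(out <- impute_random(norec, seed = 1), "nothing to impute")
  expect_identical(out$y, rec$y)
})

test_that("random imputation draws uniformly over the 100-value grid", {
  set.seed(7)
  grid <- seq(0.01, 1, by = 0.01)
  draws <- numeric(0)
  rec1 <- data.frame(record_id = "r1", species_id = "S1",
                     y = NA_integer_, N = 100L, mentioned = TRUE)
  for (b in 1:20) {
    imp <- impute_random(rec1[rep(1, 500), ], seed = 1000 + b)
    draws <- c(draws, attr(imp, "imputed_p"))
  }
  expect_length(draws, 10000L)
  counts <- table(factor(draws, levels = grid))
  gof <- chisq.test(counts, p = rep(1 / 100, 100))
  expect_gt(gof$p.value, 0.01)
})

test_that("posterior binning excludes zero and renormalizes", {
  sim <- simulate_diet_data(
    simulation_truth(n_species = 3, psi = 0.6, seed = 55, n_pv_axes = 1,
                     mentioned_prob = 0.8),
    diet_design(n_records = 30, n_species = 3, seed = 55))
  f <- tpb_sample(tpb_model1(sim$records),
                  tpb_config(chains = 2, iter = 400, warmup = 250,
                             seed = 3))
  for (w in c(0.005, 0.01)) {
    b <- bin_posterior(f, 1, bin_width = w)
    expect_equal(sum(b$prob), 1, tolerance = 1e-12)
    expect_true(all(b$prob >= 0))
    expect_true(all(b$bin_mid > w / 2 - 1e-12))  # zero bin excluded
  }
})

test_that("binning a point mass or a uniform spread behaves analytically", {
  ## a fit stub with constant p draws in one bin
  stub <- structure(list(
    draws = array(0.503, dim = c(200, 2, 1),
                  dimnames = list(NULL, NULL, "p[1]"))), class = "tpb_fit")
  b <- bin_posterior(stub, 1, bin_width = 0.01)
  expect_equal(b$prob, 1)
  expect_equal(b$bin_mid, 0.505)

  set.seed(8)
  stub2 <- structure(list(
    draws = array(runif(20000), dim = c(10000, 2, 1),
                  dimnames = list(NULL, NULL, "p[1]"))), class = "tpb_fit")
  b2 <- bin_posterior(stub2, 1, bin_width = 0.01)
  expect_gte(length(b2$bin_mid), 98)
  expect_lt(max(b2$prob), 3 / 99)

  stub0 <- structure(list(
    draws = array(1e-9, dim = c(200, 2, 1),
                  dimnames = list(NULL, NULL, "p[1]"))), class = "tpb_fit")
  expect_error(bin_posterior(stub0, 1, bin_width = 0.01), "zero bin")
})

test_that("posterior imputation samples the bin distribution", {
  rec <- mentioned_records(n = 20, seed = 9)
  rows <- which(rec$mentioned)
  one_bin <- structure(list(bin_mid = 0.105, prob = 1, bin_width = 0.01),
                       class = "posterior_bins")
  bins <- setNames(rep(list(one_bin), length(rows)), as.character(rows))
  imp <- impute_from_posterior(rec, bins, seed = 1)
  expect_equal(imp$y[rows],
               pmin(pmax(floor(0.105 * rec$N[rows] + 0.5), 1),
                    rec$N[rows]))
  ## N = 20 -> 0.105 * 20 = 2.1 -> 2
  rec1 <- rec[rows[1], , drop = FALSE]; rec1$N <- 20L
  imp1 <- impute_from_posterior(rec1, setNames(list(one_bin), "1"),
                                seed = 1)
  expect_equal(imp1$y[1], 2)
  expect_error(impute_from_posterior(rec, bins[-1], seed = 1),
               "no posterior bins")
  expect_identical(impute_from_posterior(rec, bins, seed = 5)$y,
                   impute_from_posterior(rec, bins, seed = 5)$y)
})

test_that("sampled frequencies reproduce the bin distribution (KS)", {
  set.seed(10)
  mids <- seq(0.105, 0.505, by = 0.01)
  probs <- dnorm(mids, 0.3, 0.08); probs <- probs / sum(probs)
  b <- structure(list(bin_mid = mids, prob = probs, bin_width = 0.01),
                 class = "posterior_bins")
  rec1 <- data.frame(record_id = "r1", species_id = "S1",
                     y = NA_integer_, N = 1000L, mentioned = TRUE)
  ps <- numeric(0)
  for (k in 1:20) {
    imp <- impute_from_posterior(rec1[rep(1, 500), ],
                                 setNames(rep(list(b), 500),
                                          as.character(1:500)),
                                 seed = 2000 + k)
    ps <- c(ps, attr(imp, "imputed_p"))
  }
  cdf_ref <- function(x) sapply(x, function(v) sum(probs[mids <= v + 1e-12]))
  ks <- max(abs(cdf_ref(sort(unique(ps))) -
                  ecdf(ps)(sort(unique(ps)))))
  expect_lt(ks, 1.63 / sqrt(10000))   # KS critical value at alpha = 0.01
})

test_that("imputed counts always satisfy 1 <= y <= N over random draws", {
  set.seed(11)
  p <- runif(10000)
  N <- sample(1:500, 10000, replace = TRUE)
  yy <- tpbinom:::.impute_count(p, N)
  expect_true(all(yy >= 1))
  expect_true(all(yy <= N))
  expect_true(all(yy == floor(yy)))
})

test_that("posterior imputation beats random imputation on species means", {
  ## true frequencies are small, so uniform random imputation of mentioned
  ## records (mean 0.5) distorts species means far more than imputation
  ## from each record's own posterior
  sim <- simulate_diet_data(
    simulation_truth(n_species = 4, psi = 0.4, global_intercept = -2.5,
                     omega = 0.3, theta = 0.5, mentioned_prob = 0.9,
                     seed = 88, n_pv_axes = 1),
    diet_design(n_records = 80, n_species = 4, seed = 88))
  rec <- validate_diet_records(sim$records)
  expect_gt(sum(rec$mentioned), 3)
  src <- tpb_sample(tpb_model1(rec),
                    tpb_config(chains = 2, iter = 600, warmup = 350,
                               seed = 31))
  cfg <- tpb_config(chains = 2, iter = 450, warmup = 300, seed = 14)
  rmse <- function(fit) {
    est <- species_frequency(fit)$EAP
    truth <- plogis(sim$truth$species_intercepts[species_frequency(fit)$species_id])
    sqrt(mean((est - truth)^2))
  }
  f_post <- suppressWarnings(
    replicate_fit_and_pool(rec, model = 1, method = "posterior",
                           n_replicates = 3, config = cfg,
                           psi_source = src))
  f_rand <- suppressWarnings(
    replicate_fit_and_pool(rec, model = 1, method = "random",
                           n_replicates = 3, config = cfg,
                           psi_source = src))
  expect_lt(rmse(f_post), rmse(f_rand))
})

test_that("replicate pooling stacks thinned draws and preserves psi handling", {
  sim <- simulate_diet_data(
    simulation_truth(n_species = 3, psi = 0.5, seed = 66, n_pv_axes = 1,
                     mentioned_prob = 0.6),
    diet_design(n_records = 30, n_species = 3, seed = 66))
  rec <- validate_diet_records(sim$records)
  src <- tpb_sample(tpb_model1(rec),
                    tpb_config(chains = 2, iter = 500, warmup = 300,
                               seed = 21))
  cfg <- tpb_config(chains = 2, iter = 320, warmup = 200, seed = 8)
  pooled <- suppressWarnings(
    replicate_fit_and_pool(rec, model = 1, method = "random",
                           n_replicates = 3, config = cfg,
                           psi_source = src))
  ## 120 post-warmup draws per replicate, thinned 1/2 -> 60; 3 reps -> 180
  expect_equal(dim(pooled$draws)[1L], 180L)
  expect_true(pooled$pooled)
  expect_equal(pooled$replicates$n_replicates, 3L)
  expect_equal(length(unique(pooled$replicates$seeds)), 3L)
  ## psi is carried from the non-imputed posterior, not re-estimated
  psi_draws <- as.vector(pooled$draws[, , "psi"])
  src_range <- range(tpbinom:::draw_vector(src, "psi"))
  expect_true(all(psi_draws >= src_range[1] & psi_draws <= src_range[2]))

  ## single replicate: pooled equals that replicate's thinned fit
  pooled1 <- suppressWarnings(
    replicate_fit_and_pool(rec, model = 1, method = "posterior",
                           n_replicates = 1, config = cfg,
                           psi_source = src))
  expect_equal(dim(pooled1$draws)[1L], 60L)

  ## pooled mean is the mean of replicate means (equal draw counts)
  a_all <- pooled$draws[, , paste0("alpha[", pooled$species[1], "]")]
  rep_means <- c(mean(a_all[1:60, ]), mean(a_all[61:120, ]),
                 mean(a_all[121:180, ]))
  expect_equal(mean(a_all), mean(rep_means), tolerance = 1e-12)
})
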