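test_that("lambda matches the Poisson closed form over a (k, n) grid", {
  for (n in c(1000L, 8000L, 20000L)) {
    for (k in c(0L, 1L, 10L, n %/% 10, n %/% 2, n - 1L)) {
      m <- estimate_concentration(k, n, droplet_volume = 0.00085)
      expect_equal(m$lambda_hat, -log(1 - k / n), tolerance = 1e-12)
      expect_equal(m$concentration, m$lambda_hat / 0.00085, tolerance = 1e-12)
    }
  }
})

test_that("worked examples: half-positive and 9.5%-positive wells", {
  m <- estimate_concentration(10000, 20000, droplet_volume = 0.00085)
  expect_equal(m$lambda_hat, log(2), tolerance = 1e-12)
  expect_equal(m$concentration, 815.4673, tolerance = 1e-6)

  m2 <- estimate_concentration(1900, 20000, droplet_volume = 0.00085)
  expect_equal(m2$lambda_hat, 0.09982036, tolerance = 1e-6)
  expect_equal(m2$concentration, 117.4357, tolerance = 1e-6)
})

test_that("saturated and invalid counts are rejected", {
  expect_error(estimate_concentration(20000, 20000), "saturated well")
  expect_error(estimate_concentration(21000, 20000), "exceed")
  expect_error(estimate_concentration(-1, 20000), "k_pos")
  expect_error(estimate_concentration(10, 0), "n_total")
})

test_that("an all-negative well has zero concentration but a positive upper bound", {
  m <- estimate_concentration(0, 20000)
  expect_equal(m$concentration, 0)
  expect_equal(m$ci_low, 0)
  expect_gt(m$ci_high, 0)
})

test_that("lambda is strictly increasing in k at fixed n", {
  lam <- vapply(0:1999, function(k) {
    estimate_concentration(k, 2000)$lambda_hat
  }, numeric(1))
  expect_true(all(diff(lam) > 0))
})

test_that("delta and exact intervals both cover the point estimate", {
  for (method in c("delta", "exact")) {
    m <- estimate_concentration(1900, 20000, ci_method = method)
    expect_lte(m$ci_low, m$concentration)
    expect_gte(m$ci_high, m$concentration)
  }
  # the exact interval transforms the Clopper-Pearson interval on p
  m <- estimate_concentration(50, 10000, ci_method = "exact")
  cp <- binom.test(50, 10000)$conf.int
  expect_equal(m$ci_low, -log(1 - cp[1]) / 0.00085, tolerance = 1e-9)
  expect_equal(m$ci_high, -log(1 - cp[2]) / 0.00085, tolerance = 1e-9)
})

test_that("merging one well is the identity and counts pool additively", {
  a <- estimate_concentration(100, 10000)
  expect_equal(merge_wells(list(a)), a)

  b <- estimate_concentration(100, 10000)
  pooled <- merge_wells(list(a, b))
  direct <- estimate_concentration(200, 20000)
  expect_equal(pooled$lambda_hat, direct$lambda_hat)
  expect_equal(pooled$concentration, direct$concentration)
})

test_that("pooling counts differs from averaging concentrations at unequal n", {
  a <- estimate_concentration(10, 1000)
  b <- estimate_concentration(1000, 19000)
  pooled <- merge_wells(list(a, b))
  averaged <- (a$concentration + b$concentration) / 2
  expect_equal(pooled$lambda_hat, -log(1 - 1010 / 20000))
  expect_gt(abs(pooled$concentration - averaged), 1)
})

test_that("wells with mixed targets or volumes refuse to merge", {
  wt <- estimate_concentration(100, 10000, target = "WT")
  mut <- estimate_concentration(100, 10000, target = "MUT")
  expect_error(merge_wells(list(wt, mut)), "mixed targets")
  v2 <- estimate_concentration(100, 10000, droplet_volume = 0.001,
                               target = "WT")
  expect_error(merge_wells(list(wt, v2)), "droplet volumes")
})

test_that("estimator is unbiased through the generator at moderate lambda", {
  vol <- 0.00085
  lambda <- 0.3
  lam_hat <- vapply(1:50, function(i) {
    spec <- simulation_spec(lambda / vol, 0, n_droplets = 20000,
                            droplet_volume = vol, seed = 400 + i,
                            amplitude_model = rainless_model())
    w <- simulate_well(spec)
    estimate_concentration(classify(w, MID_THRESHOLDS)$k_ch1_pos,
                           20000)$lambda_hat
  }, numeric(1))
  expect_lt(abs(mean(lam_hat) - lambda) / lambda, 0.01)
})

test_that("classify + estimate recovers a rain-free truth within 3 SE", {
  vol <- 0.00085
  spec <- simulation_spec(300, 100, n_droplets = 20000, droplet_volume = vol,
                          seed = 31, amplitude_model = rainless_model())
  w <- simulate_well(spec)
  fit <- ddpcr_fit(w, thresholds = MID_THRESHOLDS)
  for (target in c("WT", "MUT")) {
    m <- fit$measurements[[target]]
    truth <- if (target == "WT") 300 else 100
    se_conc <- m$se_lambda / vol
    expect_lt(abs(m$concentration - truth), 3 * se_conc)
  }
})

test_that("total_concentration adds rates and propagates error in quadrature", {
  wt <- estimate_concentration(4000, 20000, target = "WT")
  mut <- estimate_concentration(1500, 20000, target = "MUT")
  tot <- total_concentration(wt, mut)
  expect_equal(tot$lambda_hat, wt$lambda_hat + mut$lambda_hat)
  expect_equal(tot$se_lambda, sqrt(wt$se_lambda^2 + mut$se_lambda^2))
  expect_equal(tot$concentration, wt$concentration + mut$concentration)
})
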