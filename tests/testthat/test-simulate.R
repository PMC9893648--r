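test_that("empty sample puts every droplet in the negative/negative cluster", {
  spec <- simulation_spec(0, 0, n_droplets = 5000, seed = 4,
                          amplitude_model = rainless_model())
  w <- simulate_well(spec)
  expect_false(any(w$labels$occ_wt))
  expect_false(any(w$labels$occ_mut))
  expect_true(all(w$amplitudes$ch1 < 4000))
  expect_true(all(w$amplitudes$ch2 < 4000))
  expect_equal(w$accepted_count, 5000)
})

test_that("occupancy follows the Poisson partitioning model (binomial oracle)", {
  # lambda = 0.1 on the WT channel: the positive-droplet count is Binomial
  # with p = 1 - exp(-0.1); check a 3-sigma band around the expectation.
  n <- 20000
  vol <- 0.00085
  lambda <- 0.1
  spec <- simulation_spec(conc_wt = lambda / vol, conc_mut = 0,
                          n_droplets = n, droplet_volume = vol, seed = 42)
  w <- simulate_well(spec)
  p <- 1 - exp(-lambda)
  k <- sum(w$labels$occ_wt)
  expect_lt(abs(k - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("the two targets partition independently", {
  n <- 20000
  spec <- simulation_spec(300, 200, n_droplets = n, seed = 9)
  w <- simulate_well(spec)
  p1 <- mean(w$labels$occ_wt)
  p2 <- mean(w$labels$occ_mut)
  p12 <- mean(w$labels$occ_wt & w$labels$occ_mut)
  # SE of the double-positive fraction under independence
  se <- sqrt(p1 * p2 * (1 - p1 * p2) / n)
  expect_lt(abs(p12 - p1 * p2), 4 * se)
})

test_that("identical spec and seed give bit-identical wells; seeds differ", {
  spec <- simulation_spec(300, 100, n_droplets = 2000, seed = 77)
  w1 <- simulate_well(spec)
  w2 <- simulate_well(spec)
  expect_identical(w1$amplitudes, w2$amplitudes)
  expect_identical(w1$labels, w2$labels)
  spec2 <- simulation_spec(300, 100, n_droplets = 2000, seed = 78)
  expect_false(identical(simulate_well(spec2)$amplitudes, w1$amplitudes))
})

test_that("simulation does not disturb the caller's random state", {
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(simulate_well(simulation_spec(100, 100, n_droplets = 500, seed = 1)))
  expect_identical(runif(3), expected)
})

test_that("mean positive fraction over replicate wells matches 1 - exp(-lambda)", {
  vol <- 0.00085
  lambda <- 0.3
  p_true <- 1 - exp(-lambda)
  p_hat <- vapply(1:200, function(i) {
    spec <- simulation_spec(lambda / vol, 0, n_droplets = 20000,
                            droplet_volume = vol, seed = 1000 + i,
                            amplitude_model = rainless_model())
    mean(simulate_well(spec)$labels$occ_wt)
  }, numeric(1))
  expect_lt(abs(mean(p_hat) - p_true) / p_true, 0.01)
})

test_that("rain bookkeeping: rain scales with each channel's positives", {
  spec <- simulation_spec(300, 100, n_droplets = 10000, seed = 3,
                          amplitude_model = amplitude_model(rain_fraction = 0.02))
  w <- simulate_well(spec)
  expect_equal(sum(w$labels$rain_ch1), round(0.02 * sum(w$labels$occ_wt)))
  expect_equal(sum(w$labels$rain_ch2), round(0.02 * sum(w$labels$occ_mut)))
  # rain droplets are occupied and lie between the cluster means
  expect_true(all(w$labels$occ_wt[w$labels$rain_ch1]))
  expect_true(all(w$amplitudes$ch1[w$labels$rain_ch1] >= 2000 &
                    w$amplitudes$ch1[w$labels$rain_ch1] <= 8000))
  # an empty well has no rain even at the default rain fraction
  empty <- simulate_well(simulation_spec(0, 0, n_droplets = 5000, seed = 3))
  expect_true(all(empty$amplitudes$ch1 < 4000))
  expect_false(any(empty$labels$rain_ch1))
})

test_that("saturating concentrations flag the well instead of erroring", {
  # lambda = 10 -> expected positive fraction > 0.999
  spec <- simulation_spec(10 / 0.00085, 100, n_droplets = 1000, seed = 5)
  w <- simulate_well(spec)
  expect_true(w$saturated[["ch1"]])
  expect_false(w$saturated[["ch2"]])
})

test_that("amplitude model and spec validation reject nonsense", {
  expect_error(amplitude_model(rain_fraction = 0.6), "rain_fraction")
  expect_error(amplitude_model(neg_mean_ch1 = 9000), "exceed")
  expect_error(amplitude_model(neg_sd = 0), "neg_sd")
  expect_error(simulation_spec(-1, 0), "conc_wt")
  expect_error(simulation_spec(1, 1, n_droplets = 0), "n_droplets")
  expect_error(simulation_spec(1, 1, droplet_volume = 0), "droplet_volume")
})

test_that("mixture_series design mirrors the seven-sample validation plate", {
  ex <- simulate_experiment("mixture_series", seed = 2)
  expect_equal(nrow(ex$metadata), 7)
  expect_equal(ex$metadata$sample_id, c("I", "II", "III", "IV", "V", "VI", "VII"))
  expect_equal(ex$truth$conc_wt, 400 * c(1, .9, .75, .5, .25, .1, 0))
  expect_equal(ex$truth$conc_wt + ex$truth$conc_mut, rep(400, 7))
  expect_true(all(ex$metadata$material == "plasmid"))
})

test_that("het_gdna and knockdown designs carry the expected metadata", {
  het <- simulate_experiment("het_gdna", seed = 2)
  expect_equal(nrow(het$metadata), 3)
  expect_true(all(het$metadata$material == "gDNA"))
  expect_equal(het$truth$conc_wt, het$truth$conc_mut)

  kd <- simulate_experiment("knockdown", seed = 2)
  expect_equal(nrow(kd$metadata), 12)
  expect_setequal(unique(kd$metadata$group), c("control", "treated"))
  expect_setequal(unique(kd$metadata$assay_id), c("duplex_snp", "reference"))
  ref <- kd$truth[kd$metadata$assay_id == "reference", ]
  expect_true(all(ref$conc_mut == 0))

  expect_error(simulate_experiment("no_such_design", seed = 1), "unknown design")
})

test_that("snp count simulation is seeded and converges with depth", {
  a <- simulate_snp_counts(0.747, 5000, n_snps = 3, seed = 10)
  b <- simulate_snp_counts(0.747, 5000, n_snps = 3, seed = 10)
  expect_identical(a, b)
  expect_equal(a$wt_count + a$mut_count, rep(5000L, 3))

  # aggregated fraction near truth within binomial error (4 sigma)
  f_hat <- sum(a$wt_count) / sum(a$wt_count + a$mut_count)
  se <- sqrt(0.747 * 0.253 / 15000)
  expect_lt(abs(f_hat - 0.747), 4 * se)

  # law of large numbers at depth 1e6
  big <- simulate_snp_counts(0.3, 1e6, n_snps = 1, seed = 11)
  expect_lt(abs(big$wt_count / 1e6 - 0.3), 0.005)

  expect_error(simulate_snp_counts(1.5, 100, 1, seed = 1), "true_fraction")
  expect_error(simulate_snp_counts(0.5, 0, 1, seed = 1), "depths")
})
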