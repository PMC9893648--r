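test_that("transcripts per diploid genome: worked ratios", {
  pg <- copies_per_diploid_genome(540, 20, diploid_factor = 2)
  expect_equal(pg$transcripts_per_diploid_genome, 54)

  expect_equal(copies_per_diploid_genome(0, 20)$transcripts_per_diploid_genome, 0)

  # halving the diploid factor halves the estimate on identical inputs
  f2 <- copies_per_diploid_genome(540, 20, diploid_factor = 2)
  f1 <- copies_per_diploid_genome(540, 20, diploid_factor = 1)
  expect_equal(f1$transcripts_per_diploid_genome,
               f2$transcripts_per_diploid_genome / 2)

  # scaling is a plain multiplier on the ratio
  sc <- copies_per_diploid_genome(540, 20, scaling = 0.8)
  expect_equal(sc$transcripts_per_diploid_genome, 54 * 0.8)

  expect_error(copies_per_diploid_genome(540, 0), "gDNA")
})

test_that("per-genome CI propagates the two Poisson errors", {
  cdna <- estimate_concentration(6000, 20000, target = "total")
  gdna <- estimate_concentration(300, 20000, target = "total")
  pg <- copies_per_diploid_genome(cdna, gdna)
  expect_lt(pg$ci_low, pg$transcripts_per_diploid_genome)
  expect_gt(pg$ci_high, pg$transcripts_per_diploid_genome)
  rel <- sqrt((cdna$se_lambda / cdna$lambda_hat)^2 +
                (gdna$se_lambda / gdna$lambda_hat)^2)
  expect_equal(pg$ci_high - pg$ci_low,
               2 * 1.96 * rel * pg$transcripts_per_diploid_genome,
               tolerance = 1e-9)
})

test_that("CNV read-out: ratio times reference copies", {
  cn <- cnv(8.5, 1, reference_copies = 2)
  expect_equal(cn$cn_total, 17)
  expect_equal(cn$cn_total_int, 17)

  expect_equal(cnv(100, 100)$cn_total, 2)   # diploid identity
  expect_equal(cnv(0, 100)$cn_total, 0)
  expect_error(cnv(100, 0), "reference concentration")

  # homogeneous in the concentrations
  for (c_ in c(0.1, 3, 1000)) {
    expect_equal(cnv(8.5 * c_, 1 * c_)$cn_total, 17)
  }
})

test_that("allele partitioning splits, rounds half away from zero, conserves", {
  cn <- partition_cn(cnv(8.5, 1), 0.645)
  expect_equal(cn$cn_wt, 10.965)
  expect_equal(cn$cn_mut, 6.035)
  expect_equal(cn$cn_wt_int, 11)
  expect_equal(cn$cn_mut_int, 6)

  even <- partition_cn(5, 0.5)
  expect_equal(even$cn_wt, even$cn_mut)
  expect_equal(even$cn_wt_int, 3)  # 2.5 rounds away from zero, not to even

  for (f in seq(0, 1, by = 0.13)) {
    p <- partition_cn(cnv(8.5, 1), f)
    expect_equal(p$cn_wt + p$cn_mut, p$cn_total)
  }

  # an allelic_result measured on gDNA works as the fraction input
  r <- allelic_fraction(estimate_concentration(2000, 20000, target = "WT"),
                        estimate_concentration(1000, 20000, target = "MUT"))
  p <- partition_cn(cnv(8.5, 1), r)
  expect_equal(p$cn_wt, 17 * r$f_wt)
})

test_that("knockdown arithmetic on reference-normalized expression", {
  kd <- knockdown(control = list(wt = 200, mut = 110),
                  treated = list(wt = 100, mut = 55),
                  reference = list(control = 500, treated = 500))
  expect_equal(unname(kd$knockdown_pct["total"]), 50)
  expect_equal(unname(kd$knockdown_pct["wt"]), 50)

  none <- knockdown(control = list(wt = 200, mut = 110),
                    treated = list(wt = 200, mut = 110),
                    reference = list(control = 500, treated = 500))
  expect_equal(unname(none$knockdown_pct["total"]), 0)

  # allele-selective signature: WT at 80%, MUT at 40% of control
  sel <- knockdown(control = list(wt = 100, mut = 100),
                   treated = list(wt = 80, mut = 40),
                   reference = list(control = 500, treated = 500))
  expect_equal(unname(sel$knockdown_pct["wt"]), 20)
  expect_equal(unname(sel$knockdown_pct["mut"]), 60)

  # reference drift rescales both groups
  drift <- knockdown(control = list(wt = 200, mut = 110),
                     treated = list(wt = 100, mut = 55),
                     reference = list(control = 500, treated = 250))
  expect_equal(unname(drift$knockdown_pct["total"]), 0)

  expect_error(knockdown(list(wt = 1, mut = 1), list(wt = 1, mut = 1),
                         list(control = 0, treated = 500)), "reference-gene")
  expect_error(knockdown(list(wt = 0, mut = 0), list(wt = 1, mut = 1),
                         list(control = 500, treated = 500)),
               "control expression")
})

test_that("end-to-end per-genome recovery across realistic transcript loads", {
  vol <- 0.00085
  for (t_star in c(10, 16, 37, 54)) {
    ex <- simulate_experiment("paired_cdna_gdna", seed = 50 + t_star,
                              cdna_total = t_star * 10, gdna_total = 20)
    fits <- lapply(ex$wells, fit_mid)
    pooled_total <- function(material) {
      sel <- ex$metadata$material == material
      total_concentration(
        merge_wells(lapply(fits[sel], function(f) f$measurements$WT)),
        merge_wells(lapply(fits[sel], function(f) f$measurements$MUT)))
    }
    pg <- copies_per_diploid_genome(pooled_total("cDNA"), pooled_total("gDNA"),
                                    diploid_factor = 2)
    expect_lt(abs(pg$transcripts_per_diploid_genome - t_star) / t_star, 0.1)
  }
})

test_that("knockdown recovery on the simulated silencing design", {
  ex <- simulate_experiment("knockdown", seed = 60)
  fits <- lapply(ex$wells, fit_mid)
  md <- ex$metadata
  pool <- function(group, assay, target) {
    sel <- md$group == group & md$assay_id == assay
    merge_wells(lapply(fits[sel], function(f) f$measurements[[target]]))
  }
  kd <- knockdown(
    control = list(wt = pool("control", "duplex_snp", "WT"),
                   mut = pool("control", "duplex_snp", "MUT")),
    treated = list(wt = pool("treated", "duplex_snp", "WT"),
                   mut = pool("treated", "duplex_snp", "MUT")),
    reference = list(control = pool("control", "reference", "WT"),
                     treated = pool("treated", "reference", "WT")))
  expect_lt(abs(kd$knockdown_pct[["total"]] - 50), 3)
})
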