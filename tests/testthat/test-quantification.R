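test_that("colony counts scale to cfu per gram with quality flags", {
  expect_equal(cfu_per_gram(30, 1e5, 0.1, 10, 1)$cfu_per_g, 3e8)
  expect_equal(cfu_per_gram(17, 1, 1, 1, 1)$cfu_per_g, 17)
  zero <- cfu_per_gram(0, 10, 0.1, 10, 1)
  expect_equal(zero$cfu_per_g, 0)
  expect_true(zero$below_detection)
  expect_true(cfu_per_gram(400, 10, 0.1, 10, 1)$uncountable)
  expect_error(cfu_per_gram(10, 10, 0.1, 10, 0), "sample_mass")
  # linear in the count
  expect_equal(cfu_per_gram(60, 1e5, 0.1, 10, 1)$cfu_per_g,
               2 * cfu_per_gram(30, 1e5, 0.1, 10, 1)$cfu_per_g)
})

test_that("MPN estimator solves the closed-form single-level case", {
  est <- mpn_estimate(1, 10, 5)
  expect_equal(est$mpn, log(2), tolerance = 1e-8)
  expect_equal(est$status, "ok")
  expect_true(est$ci[1] < est$mpn && est$mpn < est$ci[2])
})

test_that("MPN handles the degenerate outcome patterns", {
  allneg <- mpn_estimate(c(0.1, 0.01), c(3, 3), c(0, 0))
  expect_equal(allneg$mpn, 0)
  expect_equal(allneg$status, "below_detection")
  expect_gt(allneg$ci[2], 0)
  expect_error(mpn_estimate(c(0.1, 0.01), c(3, 3), c(3, 3)), "upper bound")
  expect_error(mpn_estimate(c(0.1, 0.01), c(3, 3), c(1, 4)), "between")
  expect_error(mpn_estimate(c(0.01, 0.1), c(3, 3), c(1, 0)), "decreasing")
})

test_that("MPN maximum likelihood agrees with a likelihood-grid oracle on every 3x3 outcome", {
  inoculum <- c(0.1, 0.01, 0.001)
  tubes <- c(3, 3, 3)
  for (p1 in 0:3) for (p2 in 0:3) for (p3 in 0:3) {
    pos <- c(p1, p2, p3)
    if (all(pos == 0) || all(pos == 3)) next
    est <- mpn_estimate(inoculum, tubes, pos)$mpn
    oracle <- mpn_grid_oracle(inoculum, tubes, pos)
    expect_equal(est, oracle, tolerance = 5e-3,
                 info = paste(pos, collapse = ","))
  }
})

test_that("MPN is scale-equivariant and monotone in added positives", {
  inoculum <- c(0.1, 0.01, 0.001)
  tubes <- c(5, 5, 5)
  set.seed(31)
  for (i in 1:25) {
    pos <- c(sample(0:5, 1), sample(0:5, 1), sample(0:5, 1))
    if (all(pos == 0) || all(pos == 5)) next
    est <- mpn_estimate(inoculum, tubes, pos)$mpn
    # scaling the inocula by c divides the density estimate by c
    est_scaled <- mpn_estimate(inoculum * 10, tubes, pos)$mpn
    expect_equal(est_scaled, est / 10, tolerance = 1e-6)
    # adding a positive tube at any level never decreases the estimate
    for (lvl in which(pos < 5)) {
      bumped <- pos
      bumped[lvl] <- bumped[lvl] + 1
      if (all(bumped == 5)) next
      expect_gte(mpn_estimate(inoculum, tubes, bumped)$mpn, est - 1e-9)
    }
  }
})

test_that("DNA yields convert to cells at 8.14 fg per cell", {
  expect_equal(tde_cells_per_gram(8.14e-6, 1), 1)
  expect_equal(tde_cells_per_gram(1, 1), 1e6 / 8.14)
  expect_equal(tde_cells_per_gram(0, 1), 0)
  # linear in yield and inverse in mass
  expect_equal(tde_cells_per_gram(2, 0.5), 4 * tde_cells_per_gram(1, 1))
})

test_that("epifluorescence mosaics scale to cells per gram", {
  res <- epi_cells_per_gram(rep(40, 25), rep(10, 25), 1e4, 1e8, 10, 0.01, 1)
  expect_equal(res$viable_per_g, 4e8)
  expect_equal(res$total_per_g, 5e8)
  expect_equal(res$viability_fraction, 0.8)
  expect_equal(epi_cells_per_gram(rep(5, 25), rep(0, 25), 1, 10, 1, 1,
                                  1)$viability_fraction, 1)
  one <- epi_cells_per_gram(3, 1, 1, 10, 1, 1, 1)
  expect_equal(one$n_fields, 1)
  expect_true(is.na(one$field_cv))
  expect_true(is.na(epi_cells_per_gram(0, 0, 1, 1, 1, 1,
                                       1)$viability_fraction))
})

test_that("method comparison flags censored rows and separates culturable from total counts", {
  tab <- data.frame(sample_id = "s1", compartment = "soil",
                    method = c("CFU_bacteria", "MPN", "TDE", "EPI"),
                    value = c(0, 1e7, 1e9, 8e8))
  out <- method_comparison(tab)
  expect_equal(nrow(out), 4)
  expect_true(out$censored[1])
  expect_true(is.na(out$log10_value[1]))

  # on the default synthetic bundle the DNA and microscopy methods sit
  # about two orders of magnitude above the culture-dependent ones
  rep <- run_pipeline(simulate_study(default_design(), seed = 5),
                      n_perm = 99, seed = 5)
  q <- rep$quantification
  soil <- q[q$compartment == "soil" & !q$censored, ]
  means <- tapply(soil$log10_value, soil$method, mean)
  gap <- mean(means[c("TDE", "EPI")]) -
    mean(means[c("CFU_bacteria", "MPN")])
  expect_gt(gap, 1.5)
  expect_lt(gap, 2.5)
})
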