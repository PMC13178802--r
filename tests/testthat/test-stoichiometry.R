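test_that("enzyme pools follow the supply-minus-consumption construction", {
  rec <- activity_record(beta_glucosidase = 0.358, cellulase = 0.146,
                         xylanase = 0.391, dehydrogenase = 2.35e-3,
                         urease = 10.775, protease = 0.217,
                         acid_phosphatase = 27.415)
  pooled <- eea_pools(rec)
  expect_equal(round(pooled$CE, 3), 0.893)
  expect_equal(pooled$NE, 10.992)
  expect_equal(pooled$PE, 27.415)

  rec2 <- activity_record(beta_glucosidase = 0.550, cellulase = 0.086,
                          xylanase = 0.428, dehydrogenase = 7.06e-3,
                          urease = 7.191, protease = 0.237,
                          acid_phosphatase = 29.308)
  pooled2 <- eea_pools(rec2)
  expect_equal(round(pooled2$CE, 3), 1.057)
  expect_equal(round(pooled2$NE, 3), 7.428)

  zero <- eea_pools(activity_record())
  expect_equal(unlist(zero[c("CE", "NE", "PE")], use.names = FALSE),
               c(0, 0, 0))
  expect_true(is.na(vector_components(zero$CE, zero$NE, zero$PE)$x))
})

test_that("missing or invalid activities are rejected by name", {
  rec <- activity_record()
  expect_error(eea_pools(rec[setdiff(names(rec), "urease")]), "urease")
  rec$cellulase <- -0.1
  expect_error(eea_pools(rec), "cellulase")
})

test_that("stoichiometric ratios are plain quotients with flagged zeros", {
  r <- stoich_ratios(0.893, 10.992, 27.415)
  expect_equal(r$CE_PE, 0.0326, tolerance = 1e-3)
  expect_equal(unlist(stoich_ratios(1, 1, 1), use.names = FALSE),
               c(1, 1, 1))
  expect_equal(stoich_ratios(1.057, 7.428, 1)$CE_NE, 0.1423,
               tolerance = 1e-3)
  expect_true(is.na(stoich_ratios(1, 0, 1)$CE_NE))
})

test_that("vector components, length and angle match direct evaluation", {
  v <- vector_components(0.893, 10.992, 27.415)
  expect_equal(v$x, 0.031546, tolerance = 1e-4)
  expect_equal(v$y, 0.075137, tolerance = 1e-4)
  expect_equal(unlist(vector_components(1, 0, 0), use.names = FALSE),
               c(1, 1))
  expect_equal(unlist(vector_components(1, 1, 1), use.names = FALSE),
               c(0.5, 0.5))

  la <- vector_length_angle(0.031546, 0.075137)
  expect_equal(la$VL, 0.0815, tolerance = 1e-3)
  expect_equal(la$VA, 67.23, tolerance = 1e-3)
  expect_equal(vector_length_angle(0.1, 0.1)$VA, 45)
  expect_equal(vector_length_angle(0.1, 0.1)$VL, 0.1414, tolerance = 1e-3)

  # pools of the H400f group means
  v2 <- vector_components(1.05694, 7.428, 29.308)
  expect_equal(vector_length_angle(v2$x, v2$y)$VA, 74.39, tolerance = 1e-3)

  expect_true(is.na(vector_length_angle(0, 0)$VA))
})

test_that("limitation classification applies the angle and length rules", {
  expect_equal(unlist(classify_limitation(0.118, 72.12), use.names = FALSE),
               c("P_limited", "weak"))
  expect_equal(unlist(classify_limitation(1.2, 40), use.names = FALSE),
               c("N_limited", "strong"))
  cl <- classify_limitation(0.5, 45)
  expect_equal(cl$limitation, "balanced")
  expect_true(is.na(cl$strength))
  expect_equal(classify_limitation(NA_real_, NA_real_)$limitation,
               "undefined")
})

test_that("alkaline/acid phosphatase index encodes the liming rule", {
  idx <- alk_acid_index(42.207, 32.196)
  expect_equal(idx$alk_acid_ratio, 1.311, tolerance = 1e-3)
  expect_equal(idx$liming_flag, "no correction needed")
  expect_equal(alk_acid_index(1, 1)$alk_acid_ratio, 1)
  expect_equal(alk_acid_index(0.2, 1)$liming_flag, "liming indicated")
  expect_true(is.na(alk_acid_index(1, 0)$alk_acid_ratio))
})

test_that("group aggregation modes agree on identical replicates and show a Jensen gap otherwise", {
  rec <- activity_record(beta_glucosidase = 0.4, xylanase = 0.3,
                         urease = 5, protease = 0.2, acid_phosphatase = 20,
                         alkaline_phosphatase = 25)
  reps <- do.call(rbind, replicate(5, rec, simplify = FALSE))
  reps$sample_id <- paste0("s", 1:5)
  of_means <- summarize_group(reps, mode = "of_means")
  per_rep <- summarize_group(reps, mode = "per_replicate")
  for (v in c("CE", "NE", "PE", "CE_NE", "VL", "VA")) {
    expect_equal(of_means[[v]], per_rep[[v]], info = v)
  }

  # two replicates with CE/NE 0.1 and 0.2: per-replicate mean is 0.15
  two <- rbind(activity_record(beta_glucosidase = 1, urease = 10,
                               acid_phosphatase = 1, sample_id = "a"),
               activity_record(beta_glucosidase = 2, urease = 10,
                               acid_phosphatase = 1, sample_id = "b"))
  expect_equal(summarize_group(two, mode = "per_replicate")$CE_NE, 0.15)
  expect_equal(summarize_group(two, mode = "of_means")$CE_NE, 1.5 / 10)
  # the gap appears for the non-linear vector length
  expect_false(isTRUE(all.equal(
    summarize_group(two, mode = "per_replicate")$VL,
    summarize_group(two, mode = "of_means")$VL)))

  expect_error(summarize_group(reps[0, ]), "no records")
})

test_that("angle discriminates P from N limitation and respects symmetries", {
  set.seed(11)
  for (i in 1:200) {
    CE <- runif(1, 0.01, 5); NE <- runif(1, 0.01, 50)
    PE <- runif(1, 0.01, 50)
    v <- vector_components(CE, NE, PE)
    la <- vector_length_angle(v$x, v$y)
    expect_gt(la$VA, 0); expect_lt(la$VA, 90)
    expect_equal(la$VA > 45, PE > NE)
    expect_equal(la$VL, sqrt(v$x^2 + v$y^2))

    # exchanging NE and PE mirrors the vector about the diagonal
    v_sw <- vector_components(CE, PE, NE)
    la_sw <- vector_length_angle(v_sw$x, v_sw$y)
    expect_equal(la_sw$VL, la$VL)
    expect_equal(la_sw$VA, 90 - la$VA)

    # pools are linear in the activities; the vector is scale-free
    c_scale <- runif(1, 0.1, 10)
    v_sc <- vector_components(c_scale * CE, c_scale * NE, c_scale * PE)
    expect_equal(v_sc$x, v$x)
    expect_equal(v_sc$y, v$y)
  }
})

test_that("pools round-trip through a record built to match them", {
  set.seed(12)
  for (i in 1:50) {
    target <- runif(3, 0.05, 40) # CE, NE, PE
    rec <- activity_record(beta_glucosidase = target[1] / 2,
                           xylanase = target[1] / 2,
                           urease = target[2] / 2, protease = target[2] / 2,
                           acid_phosphatase = target[3])
    pooled <- eea_pools(rec)
    expect_equal(unlist(pooled[c("CE", "NE", "PE")], use.names = FALSE),
                 target)
  }
})

test_that("pool linearity: scaling all activities scales the pools", {
  rec <- activity_record(beta_glucosidase = 0.3, cellulase = 0.1,
                         xylanase = 0.2, dehydrogenase = 0.01,
                         urease = 4, protease = 0.5, acid_phosphatase = 12)
  scaled <- rec
  enz <- setdiff(names(rec), c("sample_id", "group"))
  scaled[enz] <- lapply(rec[enz], function(v) 3 * v)
  p1 <- eea_pools(rec); p2 <- eea_pools(scaled)
  expect_equal(3 * unlist(p1[c("CE", "NE", "PE")]),
               unlist(p2[c("CE", "NE", "PE")]))
})
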