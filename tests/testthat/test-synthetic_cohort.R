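test_that("cohort generation is seed-reproducible and leaves RNG alone", {
  p <- cohort_params(seed = 11)
  a <- generate_cohort(p)
  set.seed(999)
  before <- .Random.seed
  b <- generate_cohort(p)
  expect_identical(after <- .Random.seed, before)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(cohort_params(seed = 12))
  expect_false(identical(a$serum_txb2, c$serum_txb2))
  expect_error(cohort_params(n = 1), ">= 2")
})

test_that("all generated platelet counts respect the eligibility floor", {
  for (s in 1:20) {
    coh <- generate_cohort(cohort_params(seed = s))
    expect_gte(min(coh$platelet_count), 150)
    expect_true(all(coh$serum_txb2 > 0))
    expect_true(all(coh$urinary_txm > 0))
    expect_true(all(coh$iso_pgf2a > 0))
  }
})

test_that("per-platelet TXB2 uses the printed pg/platelet scale", {
  expect_equal(per_platelet_txb2(8.2, 344), 8.2 / 344 * 1000)
  expect_equal(round(per_platelet_txb2(8.2, 344)), 24)
  expect_equal(per_platelet_txb2(0, 500), 0)
  expect_equal(per_platelet_txb2(10, 1000), 10)
  expect_error(per_platelet_txb2(5, 0), "> 0")
  expect_error(per_platelet_txb2(-1, 100), ">= 0")
})

test_that("threshold classification is boundary-inclusive at 10 ng/ml", {
  coh <- data.frame(serum_txb2 = c(9.9, 10, 10.0000001, 25))
  cls <- classify_threshold(coh)
  expect_equal(as.character(cls$inhibition),
               c("adequate", "adequate", "inadequate", "inadequate"))
  all_low <- classify_threshold(data.frame(serum_txb2 = rep(5, 4)))
  expect_equal(sum(all_low$inhibition == "inadequate"), 0)
  expect_error(classify_threshold(data.frame(serum_txb2 = numeric(0))),
               "empty")
})

test_that("about one-third of patients classify as inadequate", {
  frac <- vapply(1:60, function(s) {
    cls <- classify_threshold(generate_cohort(cohort_params(seed = s)))
    mean(cls$inhibition == "inadequate")
  }, numeric(1))
  expect_gt(mean(frac), 0.25)
  expect_lt(mean(frac), 0.48)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  coh <- generate_cohort(cohort_params(seed = 3))
  rho <- cohort_correlations(coh)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 5))
  expect_true(all(rho >= -1 & rho <= 1))
  # a duplicated column correlates perfectly
  coh$iso_pgf2a <- coh$urinary_txm
  rho2 <- cohort_correlations(coh)
  expect_equal(rho2["urinary_txm", "iso_pgf2a"], 1)
  # constant columns are flagged and reported as NA
  coh$serum_txb2 <- 5
  coh$per_platelet_txb2 <- per_platelet_txb2(coh$serum_txb2,
                                             coh$platelet_count)
  expect_warning(rho3 <- cohort_correlations(coh), "constant")
  expect_true(all(is.na(rho3["serum_txb2", -2])))
  expect_error(cohort_correlations(coh[1:2, ]), "at least 3")
})

test_that("switching off the dependence links decorrelates the chain", {
  p0 <- cohort_params(seed = 1, b_count_txb2 = 0, b_txb2_txm = 0,
                      b_iso_txm = 0)
  rhos <- sapply(1:60, function(s) {
    p <- p0
    p$seed <- s
    rho <- cohort_correlations(generate_cohort(p))
    c(rho["platelet_count", "serum_txb2"],
      rho["urinary_txm", "serum_txb2"],
      rho["urinary_txm", "iso_pgf2a"])
  })
  expect_true(all(abs(rhos) < 0.55))         # n = 49 sampling noise
  expect_true(all(abs(rowMeans(rhos)) < 0.05))
})

test_that("generated marginals match the study cohort statistics", {
  stats <- sapply(1:60, function(s) {
    coh <- generate_cohort(cohort_params(seed = s))
    c(plt = median(coh$platelet_count),
      txb2 = median(coh$serum_txb2),
      txm = median(coh$urinary_txm),
      pp = median(coh$per_platelet_txb2))
  })
  m <- rowMeans(stats)
  expect_equal(m[["plt"]], 344, tolerance = 30 / 344)
  expect_equal(m[["txb2"]], 8.2, tolerance = 1.5 / 8.2)
  expect_equal(m[["txm"]], 509, tolerance = 80 / 509)
  expect_equal(m[["pp"]], 24, tolerance = 5 / 24)
})

test_that("cohort summary aggregates counts, medians and correlations", {
  coh <- generate_cohort(cohort_params(seed = 7))
  smry <- cohort_summary(coh)
  expect_equal(smry$n, 49)
  expect_equal(sum(smry$group_counts), 49)
  expect_equal(dim(smry$spearman), c(5, 5))
  expect_true(all(smry$marginals[, "p2.5"] <= smry$marginals[, "median"]))
  expect_true(all(smry$marginals[, "median"] <= smry$marginals[, "p97.5"]))
  expect_output(print(smry), "inhibition")
})
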