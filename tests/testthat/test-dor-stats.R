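# Contingency tables, continuity correction, DOR, chi-square, intervals.

test_that("margin-preserving correction reproduces the worked values", {
  t <- correct_zero_cells(contingency(10, 77, 0, 378))
  expect_equal(c(t$tp, t$fn, t$fp, t$tn), c(10, 77, 0.5, 377.5))
  expect_true(t$corrected)
  expect_equal(dor(t), 98.05, tolerance = 1e-4)

  # no zeros: unchanged
  t2 <- correct_zero_cells(contingency(14, 73, 1, 377))
  expect_false(t2$corrected)
  expect_equal(c(t2$tp, t2$fn, t2$fp, t2$tn), c(14, 73, 1, 377))

  t3 <- correct_zero_cells(contingency(9, 78, 0, 378))
  expect_equal(c(t3$fp, t3$tn), c(0.5, 377.5))
  expect_equal(dor(t3), 87.12, tolerance = 1e-4)

  # the naive all-cells convention differs and is not the default
  t4 <- correct_zero_cells(contingency(10, 77, 0, 378), method = "all")
  expect_equal(dor(t4), 102.56, tolerance = 1e-4)

  expect_error(correct_zero_cells(contingency(0, 0, 5, 5)), "class total")
})

test_that("correction preserves class margins on random zero tables", {
  set.seed(5)
  for (i in 1:200) {
    cells <- rpois(4, 3) * rbinom(4, 1, 0.7)
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    t0 <- contingency(cells[1], cells[2], cells[3], cells[4])
    t1 <- correct_zero_cells(t0)
    expect_equal(t1$tp + t1$fn, cells[1] + cells[2])
    expect_equal(t1$fp + t1$tn, cells[3] + cells[4])
    if (all(cells > 0)) expect_identical(t1, t0)
    else expect_true(all(c(t1$tp, t1$fn, t1$fp, t1$tn) > 0))
  }
})

test_that("dor, risk/protection and their identities", {
  expect_equal(dor(contingency(14, 73, 1, 377)), 72.30, tolerance = 1e-4)
  expect_equal(dor(contingency(3, 5, 3, 5)), 1)
  expect_error(dor(contingency(1, 0, 2, 3)), "zero cell")

  expect_equal(100 * risk_protection(98.05)[["R"]], 98.99, tolerance = 1e-2)
  expect_equal(100 * risk_protection(2.46)[["R"]], 71.1, tolerance = 5e-2)
  expect_equal(risk_protection(1), c(R = 0.5, P = 0.5))
  r <- risk_protection(runif(1, 0, 50))
  expect_equal(r[["R"]] + r[["P"]], 1)

  # class-swap antisymmetry and monotonicity of R in DOR
  set.seed(8)
  for (i in 1:100) {
    cells <- rpois(4, 5) + 1
    t <- contingency(cells[1], cells[2], cells[3], cells[4])
    sw <- contingency(cells[3], cells[4], cells[1], cells[2])
    expect_equal(dor(sw), 1 / dor(t))
    expect_equal(risk_protection(dor(sw))[["R"]],
                 risk_protection(dor(t))[["P"]])
  }
  d <- sort(runif(20, 0, 100))
  expect_true(all(diff(vapply(d, function(x)
    risk_protection(x)[["R"]], 0)) > 0))
})

test_that("MH chi-square and test-based intervals match the printed CIs", {
  expect_equal(mh_chisq(contingency(4, 9, 4, 9)), 0)
  expect_equal(mh_chisq(contingency(6, 81, 1, 377)), 20.93, tolerance = 1e-3)
  t <- correct_zero_cells(contingency(10, 77, 0, 378))
  expect_equal(mh_chisq(t), 41.28, tolerance = 1e-3)

  ci <- dor_ci(contingency(6, 81, 1, 377))
  expect_equal(unname(ci), c(6.71, 116.26), tolerance = 1e-3)
  ci2 <- dor_ci(contingency(14, 73, 109, 269))
  expect_equal(unname(ci2), c(0.26, 0.87), tolerance = 2e-2)
  expect_equal(dor_ci(t)[["low"]], 24.21, tolerance = 1e-3)

  expect_error(dor_ci(contingency(4, 9, 4, 9)), "chi-square is zero")
  expect_error(mh_chisq(contingency(0, 0, 4, 9)), "zero")

  # CI brackets the point estimate; excludes 1 iff chi2 > z^2
  set.seed(13)
  for (i in 1:200) {
    cells <- rpois(4, 6) + 1
    t <- contingency(cells[1], cells[2], cells[3], cells[4])
    if (mh_chisq(t) == 0) next
    d <- dor(t); ci <- dor_ci(t)
    expect_lte(ci[["low"]], d); expect_gte(ci[["high"]], d)
    expect_equal(ci[["low"]] > 1 || ci[["high"]] < 1,
                 mh_chisq(t) > qnorm(0.975)^2)
  }
})

test_that("is_jep and the interestingness measures", {
  expect_true(is_jep(10, 0))
  expect_false(is_jep(14, 1))
  expect_false(is_jep(5, 5))
  expect_true(is_jep(0, 3))
  expect_error(is_jep(0, 0), "unsupported")

  m <- pattern_measures(contingency(10, 77, 0, 378))
  expect_equal(m[["sensitivity"]], 10 / 87)
  expect_equal(m[["specificity"]], 1)
  expect_equal(m[["prevalence"]], 87 / 465)
  expect_equal(m[["support"]], 10 / 465)
  # all-died table: prevalence 1, specificity undefined -> NA
  m2 <- pattern_measures(contingency(5, 5, 0, 0))
  expect_equal(m2[["prevalence"]], 1)
  expect_true(is.na(m2[["specificity"]]))

  # formulas agree with independent recomputation on random tables
  set.seed(17)
  for (i in 1:50) {
    cells <- rpois(4, 4) + 1
    m <- pattern_measures(contingency(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(m[["confidence"]], cells[1] / (cells[1] + cells[3]))
    expect_equal(m[["accuracy"]], (cells[1] + cells[4]) / sum(cells))
    expect_equal(m[["relative_risk"]],
                 (cells[1] / (cells[1] + cells[3])) /
                   (cells[2] / (cells[2] + cells[4])))
  }
})

test_that("pattern_stats assembles corrected summaries per pattern", {
  st <- stats_from_counts(
    pattern = c("PH_4", "PH_4 < PH_4", "PH_4 < PH_4 < BE_1"),
    parent = c(NA, "PH_4", "PH_4 < PH_4"),
    n_died = c(30, 14, 6), n_survived = c(150, 109, 1))
  expect_s3_class(st, "pattern_stats")
  i <- match("PH_4 < PH_4 < BE_1", st$pattern)
  expect_equal(st$dor[i], 27.93, tolerance = 1e-3)
  expect_equal(st$ci_low[i], 6.71, tolerance = 1e-3)
  expect_false(st$jep[i])
  j <- match("PH_4 < PH_4", st$pattern)
  expect_equal(st$dor[j], 0.47, tolerance = 1e-2)
  expect_false(st$corrected[j])
})
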