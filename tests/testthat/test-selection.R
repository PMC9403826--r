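# The five selection strategies and their algebra.

worked_stats <- function() {
  # chains built from the printed worked counts (totals 87/378):
  #   PH_4 -> PH_4 < PH_4 -> PH_4 < PH_4 < BE_1      (protective -> risk)
  #   BIC_1 -> BIC_1 < BIC_2 -> BIC_1 < BIC_2 < PH_1 (risk jump 27.77%)
  #   DIUR_3 -> DIUR_3 < BE_2 -> DIUR_3 < BE_2 < PH_4 (protection jump)
  stats_from_counts(
    pattern = c("PH_4", "PH_4 < PH_4", "PH_4 < PH_4 < BE_1",
                "BIC_1", "BIC_1 < BIC_2", "BIC_1 < BIC_2 < PH_1",
                "DIUR_3", "DIUR_3 < BE_2", "DIUR_3 < BE_2 < PH_4"),
    parent = c(NA, "PH_4", "PH_4 < PH_4",
               NA, "BIC_1", "BIC_1 < BIC_2",
               NA, "DIUR_3", "DIUR_3 < BE_2"),
    n_died = c(40, 14, 6, 60, 44, 9, 60, 43, 5),
    n_survived = c(180, 109, 1, 260, 111, 0, 250, 150, 70))
}

test_that("select_jep keeps exactly the single-class patterns", {
  st <- stats_from_counts(c("A_0", "B_0", "C_0"), c(NA, NA, NA),
                          n_died = c(10, 14, 0), n_survived = c(0, 1, 3))
  sel <- select_jep(st)
  expect_setequal(sel$pattern, c("A_0", "C_0"))
  expect_equal(nrow(select_jep(st[0, ])), 0L)
})

test_that("select_dor_threshold uses strict two-sided thresholds", {
  st <- worked_stats()
  sel <- select_dor_threshold(st, dor_lo = 0.04, dor_hi = 32)
  # DOR 72.30-style strong patterns survive the exigent thresholds
  expect_true("BIC_1 < BIC_2 < PH_1" %in% sel$pattern)   # corrected 87.12
  expect_false("BIC_1 < BIC_2" %in% sel$pattern)         # 2.46 dropped
  sel2 <- select_dor_threshold(st, dor_lo = 0.08, dor_hi = 16)
  expect_true("PH_4 < PH_4 < BE_1" %in% sel2$pattern)    # 27.93
  expect_false("DIUR_3 < BE_2" %in% sel2$pattern)        # 1.49

  # boundary: a DOR exactly at the threshold is dropped
  stb <- stats_from_counts("X_0", NA_character_, 20, 30,
                           totals = c(n_died = 40, n_survived = 120))
  expect_equal(stb$dor, 3)
  expect_equal(nrow(select_dor_threshold(stb, dor_hi = 3, dor_lo = 1 / 3)), 0L)
})

test_that("select_diff_dor follows the worked differential jumps", {
  st <- worked_stats()
  sel <- select_diff_dor(st, delta_R = 0.25, delta_P = 0.30)
  # risk jump 71.1% -> 98.87% (27.77 > 25)
  expect_true("BIC_1 < BIC_2 < PH_1" %in% sel$pattern)
  # protection jump 40.23% -> 78.85% (38.62 > 30)
  expect_true("DIUR_3 < BE_2 < PH_4" %in% sel$pattern)
  # protective-to-risk flip: R 32.1% -> 96.5%
  expect_true("PH_4 < PH_4 < BE_1" %in% sel$pattern)
  # a child equal to its parent is never kept
  steq <- stats_from_counts(c("A_0", "A_0 < B_0"), c(NA, "A_0"),
                            c(20, 20), c(40, 40))
  expect_equal(nrow(select_diff_dor(steq)), 0L)
  # roots are never selected by the differential rule
  expect_false(any(is.na(st$parent[match(sel$pattern, st$pattern)])))
  # orphans are an error
  sto <- stats_from_counts("A_0 < B_0", "A_0", 10, 2)
  expect_error(select_diff_dor(sto), "without a resolvable parent")
})

test_that("select_ci_nonoverlap demands exclusion of 1 and disjoint CIs", {
  st <- worked_stats()
  sel <- select_ci_nonoverlap(st)
  # worked pair: child (6.71, 116.26) vs parent (0.26, 0.87) -> kept
  expect_true("PH_4 < PH_4 < BE_1" %in% sel$pattern)
  # parent (0.26, 0.87) excludes 1 but overlaps ITS parent's interval?
  # PH_4 root: eligible only via excludes-1
  root <- st[st$pattern == "PH_4", ]
  straddles <- root$ci_low < 1 & root$ci_high > 1
  expect_equal("PH_4" %in% sel$pattern, !straddles)
  # child with interval straddling 1 is dropped
  expect_false("DIUR_3 < BE_2" %in% sel$pattern)

  # worked pair from the combined experiment: (24.21, 397.18) vs
  # (1.20, 3.57) -> disjoint
  stq <- stats_from_counts(
    c("DIUR_3", "DIUR_3 < INC_0", "DIUR_3 < INC_0 < INC_0",
      "DIUR_3 < INC_0 < INC_0 < DIUR_3"),
    c(NA, "DIUR_3", "DIUR_3 < INC_0", "DIUR_3 < INC_0 < INC_0"),
    n_died = c(60, 40, 27, 10), n_survived = c(250, 160, 70, 0))
  sel2 <- select_ci_nonoverlap(stq)
  expect_true("DIUR_3 < INC_0 < INC_0 < DIUR_3" %in% sel2$pattern)
})

test_that("beam search keeps one child per parent, deterministically", {
  st <- stats_from_counts(
    c("A_0", "A_0 < B_0", "A_0 < C_0", "A_0 < D_0"),
    c(NA, "A_0", "A_0", "A_0"),
    n_died = c(50, 30, 30, 20), n_survived = c(200, 10, 10, 12))
  sel <- select_diff_dor(st, beam = TRUE)
  expect_equal(nrow(sel), 1L)
  # tie on |dR| between B and C resolves to the canonically smaller
  expect_equal(sel$pattern, "A_0 < B_0")
  selnb <- select_diff_dor(st, beam = FALSE)
  expect_true(all(sel$pattern %in% selnb$pattern))
  expect_gte(nrow(selnb), nrow(sel))
})

test_that("combined selection is the intersection and is monotone", {
  st <- worked_stats()
  for (beam in c(FALSE, TRUE)) {
    a <- select_diff_dor(st, beam = beam)
    b <- select_ci_nonoverlap(st, beam = beam)
    cmb <- select_combined(st, beam = beam)
    expect_setequal(cmb$pattern, intersect(a$pattern, b$pattern))
  }
  # order-independence: permuting rows does not change the result
  set.seed(2)
  perm <- st[sample(nrow(st)), ]
  class(perm) <- class(st)
  expect_equal(select_combined(perm)$pattern, select_combined(st)$pattern)
})

test_that("selection_config validates thresholds and dispatches", {
  expect_error(selection_config(dor_lo = 2), "dor_lo < 1 < dor_hi")
  expect_error(selection_config(delta_R = 1.5), "delta_R")
  st <- worked_stats()
  cfg <- selection_config("dor_threshold", dor_hi = 16, dor_lo = 0.08)
  expect_equal(select_patterns(st, cfg)$pattern,
               select_dor_threshold(st, 0.08, 16)$pattern)
  cfg2 <- selection_config("combined", beam = TRUE)
  expect_equal(select_patterns(st, cfg2)$pattern,
               select_combined(st, beam = TRUE)$pattern)
})
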