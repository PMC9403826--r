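# Pattern/sequence data types, containment, parsing and long-CSV I/O.

test_that("parse/render round-trips, canonicalizes and reports lengths", {
  p <- parse_pattern("BIC_1 < BAL_4 < PH_1")
  expect_length(p, 3L)
  expect_equal(pattern_length(p), 3L)
  expect_equal(render_pattern(p), "BIC_1 < BAL_4 < PH_1")

  p2 <- parse_pattern("INC_2 = PH_3")
  expect_length(p2, 1L)
  expect_equal(pattern_length(p2), 2L)

  # canonical alphabetical reordering inside an itemset
  expect_equal(render_pattern(parse_pattern("PH_1 = BIC_0")), "BIC_0 = PH_1")
  # bins order numerically, not as strings
  expect_equal(render_pattern(parse_pattern("X_10 = X_2")), "X_2 = X_10")

  # a 6-itemset pattern whose itemset sizes sum to 12
  p12 <- pattern(c("a_0", "b_0"), c("c_0", "d_0", "e_0"), "f_0",
                 c("a_0", "g_0"), c("b_0", "c_0", "f_0"), "g_0")
  expect_equal(pattern_length(p12), 12L)
  expect_equal(pattern_length(pattern("a_0")), 1L)

  set.seed(1)
  alphabet <- c("A_0", "A_1", "B_0", "C_0", "C_1")
  for (i in 1:25) {
    p <- random_pattern(alphabet, 4)
    expect_equal(unclass(parse_pattern(render_pattern(p))), unclass(p))
  }
})

test_that("malformed pattern text is rejected with the offending token", {
  expect_error(parse_pattern("PH_1 < < BIC_0"), "empty itemset")
  expect_error(parse_pattern(""), "empty")
  expect_error(parse_pattern("PH_x"), "malformed.*PH_x")
  expect_error(parse_pattern("PH"), "malformed.*PH")
  expect_error(parse_pattern("PH_1 = PH_1"), "duplicate.*PH_1")
  expect_error(pattern(character(0)), "empty itemset")
})

test_that("containment matches direct witnesses and handles unknowns", {
  s <- patient_sequence("x", c(1, 2, 4),
                        list(c("a_0", "b_0"), "c_0", c("a_0", "d_0")))
  expect_true(contains(s, pattern("a_0", c("a_0", "d_0"))))
  # the full day list of the sequence is contained (identity case)
  expect_true(contains(s, pattern(c("a_0", "b_0"), "c_0", c("a_0", "d_0"))))
  expect_false(contains(s, pattern(c("a_0", "c_0"))))
  expect_false(contains(s, pattern("d_0", "a_0")))
  # unknown items never match
  expect_false(contains(s, pattern("z_9")))
})

test_that("containment equals the exhaustive day-combination oracle", {
  set.seed(42)
  for (rep in 1:20) {
    db <- random_db(n_seq = 5, n_days = 5, n_var = 3, n_bin = 2)
    pats <- replicate(50, random_pattern(db$alphabet, 4), simplify = FALSE)
    for (p in pats) {
      got <- db_contains(db, p)
      want <- vapply(db$sequences, oracle_contains, TRUE, p = unclass(p))
      expect_identical(got, want)
    }
  }
})

test_that("containment is monotone under item deletion", {
  set.seed(7)
  for (rep in 1:30) {
    db <- random_db(n_seq = 4, n_days = 5)
    p <- random_pattern(db$alphabet, 4)
    # delete one random item
    q <- unclass(p)
    k <- sample(length(q), 1L)
    if (length(q[[k]]) > 1L) q[[k]] <- q[[k]][-sample(length(q[[k]]), 1L)]
    else q[[k]] <- NULL
    if (length(q) == 0L) next
    q <- do.call(pattern, q)
    hit_p <- db_contains(db, p)
    hit_q <- db_contains(db, q)
    expect_true(all(hit_q[hit_p]))
  }
})

test_that("sequence and database invariants are enforced", {
  expect_error(patient_sequence("x", c(2, 1), list("a_0", "b_0")),
               "strictly increasing")
  expect_error(patient_sequence("x", 1, list(c("a_0", "a_0"))),
               "at most once per day")
  s1 <- patient_sequence("a", 1:2, list("a_0", "b_0"))
  s2 <- patient_sequence("b", 1, list("a_0"))
  expect_error(sequence_db(list(s1, s2), c(a = 1)), "without outcome")
  expect_error(sequence_db(list(s1, s2), c(a = 1, b = 2)), "binary")
  db <- sequence_db(list(s1, s2), c(b = 0, a = 1))  # named: order-free
  expect_equal(db$n_died, 1L)
  expect_equal(unname(db$labels[["a"]]), 1L)
})

test_that("long CSV reading validates and round-trips", {
  dir <- withr::local_tempdir()
  series <- data.frame(patient_id = c("p1", "p1", "p2", "p2"),
                       day = c(1, 2, 1, 2), variable = "PH",
                       value = c(7.2, 7.4, 7.41, 7.5))
  outc <- data.frame(patient_id = c("p1", "p2"), outcome = c(1, 0))
  write.csv(series, file.path(dir, "s.csv"), row.names = FALSE)
  write.csv(outc, file.path(dir, "o.csv"), row.names = FALSE)
  raw <- read_long_csv(file.path(dir, "s.csv"), file.path(dir, "o.csv"))
  db <- apply_bins(raw, bin_spec(list(PH = c(7.35, 7.45))))
  expect_equal(length(db$sequences), 2L)
  expect_equal(db$sequences[[1]]$itemsets, list("PH_0", "PH_1"))

  # duplicated cell names the offender
  bad <- rbind(series, series[1, ])
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_long_csv(file.path(dir, "bad.csv"),
                             file.path(dir, "o.csv")),
               "duplicated.*p1/1/PH")

  # patient without outcome is listed
  write.csv(outc[1, ], file.path(dir, "o1.csv"), row.names = FALSE)
  expect_error(read_long_csv(file.path(dir, "s.csv"),
                             file.path(dir, "o1.csv")),
               "without outcome: p2")

  # generator output round-trips through the files
  sim <- simulate_cohort(sim_config(n_patients = 30), seed = 5)
  paths <- write_cohort(sim, file.path(dir, "cohort"))
  back <- read_long_csv(paths[["series"]], paths[["outcomes"]])
  db1 <- apply_bins(sim$raw, sim$bin_spec)
  db2 <- apply_bins(back, read_bin_spec(paths[["bins"]]))
  expect_equal(db2$labels, db1$labels)
  for (i in seq_along(db1$sequences))
    expect_equal(db2$sequences[[i]]$itemsets, db1$sequences[[i]]$itemsets)
})
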