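# Independent oracles and random-case generators shared by the suite.
# Test alphabets use single-character variables and single-digit bins so
# that plain string comparison coincides with canonical item order.

# exhaustive containment: try every increasing day combination
oracle_contains <- function(seq, p) {
  nd <- length(seq$itemsets)
  m <- length(p)
  if (m > nd) return(FALSE)
  combos <- utils::combn(nd, m)
  for (j in seq_len(ncol(combos))) {
    ok <- TRUE
    for (i in seq_len(m)) {
      if (!all(p[[i]] %in% seq$itemsets[[combos[i, j]]])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# every canonical pattern over `alphabet` (sorted item strings) with at
# most `max_len` items, as lists of itemsets
oracle_all_patterns <- function(alphabet, max_len) {
  res <- list()
  rec <- function(itemsets, len) {
    res[[length(res) + 1L]] <<- itemsets
    if (len >= max_len) return(invisible())
    last <- itemsets[[length(itemsets)]]
    for (it in alphabet) {
      rec(c(itemsets, list(it)), len + 1L)                    # S-extension
      if (it > last[[length(last)]])                          # I-extension
        rec(c(itemsets[-length(itemsets)],
              list(c(last, it))), len + 1L)
    }
  }
  for (it in alphabet) rec(list(it), 1L)
  res
}

# brute-force frequent mining over the full canonical pattern space
oracle_mine <- function(db, minsup, class, max_len) {
  target <- if (class == "died") 1L else 0L
  subset <- which(unname(db$labels) == target)
  thr <- ceiling(minsup * length(subset))
  pats <- oracle_all_patterns(db$alphabet, max_len)
  rows <- list()
  for (pl in pats) {
    hit <- which(vapply(db$sequences, oracle_contains, TRUE, p = pl))
    if (sum(hit %in% subset) >= thr) {
      str <- paste(vapply(pl, paste, "", collapse = " = "), collapse = " < ")
      rows[[length(rows) + 1L]] <- list(
        pattern = str,
        cover_died = hit[unname(db$labels[hit]) == 1L],
        cover_survived = hit[unname(db$labels[hit]) == 0L])
    }
  }
  rows[order(vapply(rows, `[[`, "", "pattern"), method = "radix")]
}

# random toy database: <= n_seq sequences, <= n_days days, alphabet of
# n_var variables x n_bin bins, each item present per day with prob p
random_db <- function(n_seq = 6, n_days = 4, n_var = 3, n_bin = 2,
                      p = 0.35) {
  alphabet <- as.vector(outer(LETTERS[seq_len(n_var)],
                              seq_len(n_bin) - 1L, paste, sep = "_"))
  seqs <- list()
  for (i in seq_len(n_seq)) {
    nd <- sample(n_days, 1L)
    itemsets <- lapply(seq_len(nd), function(d)
      alphabet[stats::runif(length(alphabet)) < p])
    keep <- lengths(itemsets) > 0L
    if (!any(keep)) itemsets[[1L]] <- sample(alphabet, 1L)
    itemsets <- itemsets[lengths(itemsets) > 0L]
    seqs[[i]] <- patient_sequence(paste0("s", i), seq_along(itemsets),
                                  itemsets)
  }
  labels <- c(1L, 0L, sample(0:1, n_seq - 2L, replace = TRUE))
  sequence_db(seqs, stats::setNames(labels,
                                    vapply(seqs, `[[`, "", "patient_id")))
}

random_pattern <- function(alphabet, max_items = 3) {
  n <- sample(max_items, 1L)
  itemsets <- list()
  left <- n
  while (left > 0L) {
    size <- sample(min(left, 2L), 1L)
    itemsets[[length(itemsets) + 1L]] <- sort(sample(alphabet, size))
    left <- left - size
  }
  do.call(pattern, itemsets)
}

# is p a (not necessarily proper) subpattern of q? (treat q's itemsets as
# the days of a sequence)
is_subpattern <- function(p, q) {
  oracle_contains(list(itemsets = unclass(q)), unclass(p))
}

# pattern_stats table built straight from per-class counts (no mining)
stats_from_counts <- function(pattern, parent, n_died, n_survived,
                              totals = c(n_died = 87, n_survived = 378)) {
  mined <- data.frame(pattern = pattern, parent = parent, ext_kind = "S",
                      length = vapply(lapply(pattern, parse_pattern),
                                      pattern_length, 0L),
                      n_died = n_died, n_survived = n_survived,
                      stringsAsFactors = FALSE)
  mined$cover_died <- lapply(n_died, seq_len)
  mined$cover_survived <- lapply(n_survived, seq_len)
  attr(mined, "db_totals") <- totals
  class(mined) <- c("mined_patterns", "data.frame")
  pattern_stats(mined)
}

# small labelled database with a planted separating pattern
# "A_0 = B_0 < A_0 = B_0"; survivor backgrounds never produce the
# {A_0, B_0} pair, so the motif separates the classes exactly
toy_labelled_db <- function(n_died = 20, n_surv = 60, seed = 7) {
  set.seed(seed)
  alphabet <- c("A_0", "A_1", "B_0", "B_1")
  pairs <- utils::combn(alphabet, 2L, simplify = FALSE)
  surv_pairs <- Filter(function(p) !setequal(p, c("A_0", "B_0")), pairs)
  seqs <- list()
  labels <- integer(0)
  for (i in seq_len(n_died + n_surv)) {
    died <- i <= n_died
    itemsets <- sample(surv_pairs, 3L, replace = TRUE)
    if (died) {
      itemsets[[1L]] <- c("A_0", "B_0")
      itemsets[[3L]] <- c("A_0", "B_0")
    }
    seqs[[i]] <- patient_sequence(paste0("p", i), 1:3, itemsets)
    labels <- c(labels, as.integer(died))
  }
  sequence_db(seqs, stats::setNames(labels,
                                    vapply(seqs, `[[`, "", "patient_id")))
}
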