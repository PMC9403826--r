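# Pattern selection strategies.
#
# Five strategies operate on the pattern_stats table produced by
# pattern_stats(): the Jumping-Emerging-Pattern frequency baseline, a
# plain DOR threshold, the differential risk/protection probability of a
# pattern against its enumeration parent (optionally as a beam search
# keeping one child per parent), non-overlap of the test-based 95%
# intervals, and the intersection of the last two.  All selectors are
# deterministic, order-independent, and return their input rows filtered
# and sorted canonically.

#' Selection configuration
#'
#' @param method one of `"jep"`, `"dor_threshold"`, `"diff_dor"`,
#'   `"ci_nonoverlap"`, `"combined"`.
#' @param dor_hi,dor_lo strict thresholds for [select_dor_threshold()];
#'   must satisfy `dor_lo < 1 < dor_hi`.
#' @param delta_R,delta_P strict thresholds (fractions) for the
#'   differential risk / protection probabilities.
#' @param beam keep only the best retained extension per parent.
#' @return A `selection_config` list.
#' @export
selection_config <- function(method = c("jep", "dor_threshold", "diff_dor",
                                        "ci_nonoverlap", "combined"),
                             dor_hi = 16, dor_lo = 0.08,
                             delta_R = 0.25, delta_P = 0.30, beam = FALSE) {
  method <- match.arg(method)
  if (!(dor_lo < 1 && 1 < dor_hi))
    stop("thresholds must satisfy dor_lo < 1 < dor_hi")
  if (delta_R <= 0 || delta_R >= 1 || delta_P <= 0 || delta_P >= 1)
    stop("delta_R and delta_P must be in (0, 1)")
  structure(list(method = method, dor_hi = dor_hi, dor_lo = dor_lo,
                 delta_R = delta_R, delta_P = delta_P, beam = isTRUE(beam)),
            class = "selection_config")
}

finalize_selection <- function(stats, keep) {
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$pattern, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select Jumping Emerging Patterns
#'
#' Keeps exactly the patterns present in one class and absent from the
#' other (the frequency-based baseline).
#'
#' @param stats a `pattern_stats` table.
#' @return The selected subset, canonically sorted.
#' @export
select_jep <- function(stats) {
  stopifnot(inherits(stats, "pattern_stats"))
  finalize_selection(stats, stats$jep)
}

#' Select patterns by DOR threshold
#'
#' Keeps patterns with `dor > dor_hi` (risk) or `dor < dor_lo`
#' (protection); inequalities are strict, so a DOR exactly at a threshold
#' is dropped.
#'
#' @param stats a `pattern_stats` table.
#' @param dor_lo,dor_hi thresholds with `dor_lo < 1 < dor_hi`.
#' @return The selected subset.
#' @export
select_dor_threshold <- function(stats, dor_lo = 0.08, dor_hi = 16) {
  stopifnot(inherits(stats, "pattern_stats"), dor_lo < 1, dor_hi > 1)
  finalize_selection(stats, stats$dor > dor_hi | stats$dor < dor_lo)
}

# parent row lookup; errors on orphan non-root patterns
parent_rows <- function(stats) {
  idx <- match(stats$parent, stats$pattern)
  orphan <- !is.na(stats$parent) & is.na(idx)
  if (any(orphan))
    stop("non-root patterns without a resolvable parent: ",
         paste(utils::head(stats$pattern[orphan], 5L), collapse = "; "))
  idx
}

#' Select patterns by differential risk/protection probability
#'
#' A child pattern is kept when its risk probability exceeds its
#' enumeration parent's by more than `delta_R`, or its protection
#' probability exceeds the parent's by more than `delta_P` (strict).
#' Length-1 patterns have no parent and are never selected by this rule.
#' With `beam = TRUE`, among the retained children of each parent only the
#' one with the largest absolute risk-probability change is kept (ties
#' broken toward the canonically smallest serialization).
#'
#' @param stats a `pattern_stats` table containing every pattern's parent.
#' @param delta_R,delta_P strict thresholds in (0, 1).
#' @param beam keep only the best retained child per parent.
#' @return The selected subset.
#' @export
select_diff_dor <- function(stats, delta_R = 0.25, delta_P = 0.30,
                            beam = FALSE) {
  stopifnot(inherits(stats, "pattern_stats"))
  idx <- parent_rows(stats)
  has_parent <- !is.na(idx)
  dR <- dP <- rep(NA_real_, nrow(stats))
  dR[has_parent] <- stats$R[has_parent] - stats$R[idx[has_parent]]
  dP[has_parent] <- stats$P[has_parent] - stats$P[idx[has_parent]]
  keep <- has_parent & (dR > delta_R | dP > delta_P)
  keep[is.na(keep)] <- FALSE
  if (beam) keep <- beam_filter(stats, keep, idx, abs(dR))
  finalize_selection(stats, keep)
}

# among kept children sharing a parent, retain the argmax of `score`
beam_filter <- function(stats, keep, parent_idx, score) {
  kept <- which(keep)
  if (!length(kept)) return(keep)
  by_parent <- split(kept, parent_idx[kept])
  out <- logical(length(keep))
  for (grp in by_parent) {
    best <- grp[order(-score[grp], stats$pattern[grp], method = "radix")][1L]
    out[best] <- TRUE
  }
  out
}

#' Select patterns by non-overlapping confidence intervals
#'
#' A pattern is kept when its 95% interval excludes 1 and, unless it is a
#' length-1 root, is disjoint from its enumeration parent's interval.
#' Patterns with an undefined interval (chi-square 0) are dropped with a
#' message.  With `beam = TRUE`, among retained children of one parent
#' only the child with the largest absolute log-DOR change is kept.
#'
#' @param stats a `pattern_stats` table.
#' @param beam keep only the best retained child per parent.
#' @return The selected subset.
#' @export
select_ci_nonoverlap <- function(stats, beam = FALSE) {
  stopifnot(inherits(stats, "pattern_stats"))
  idx <- parent_rows(stats)
  has_parent <- !is.na(idx)
  undef <- is.na(stats$ci_low)
  if (any(undef))
    message(sum(undef), " pattern(s) dropped: interval undefined at DOR = 1")
  excl1 <- !undef & (stats$ci_low > 1 | stats$ci_high < 1)
  disjoint <- rep(FALSE, nrow(stats))
  hp <- which(has_parent & !undef & !undef[idx])
  disjoint[hp] <- stats$ci_low[hp] > stats$ci_high[idx[hp]] |
    stats$ci_high[hp] < stats$ci_low[idx[hp]]
  keep <- excl1 & (!has_parent | disjoint)
  if (beam) {
    score <- rep(NA_real_, nrow(stats))
    score[has_parent] <- abs(log(stats$dor[has_parent]) -
                               log(stats$dor[idx[has_parent]]))
    child_keep <- beam_filter(stats, keep & has_parent, idx, score)
    keep <- (keep & !has_parent) | child_keep
  }
  finalize_selection(stats, keep)
}

#' Combined selection: differential and non-overlapping intervals
#'
#' The intersection of [select_diff_dor()] and [select_ci_nonoverlap()]
#' under identical thresholds and beam flag.
#'
#' @inheritParams select_diff_dor
#' @return The selected subset (a subset of both single-criterion
#'   outputs).
#' @export
select_combined <- function(stats, delta_R = 0.25, delta_P = 0.30,
                            beam = FALSE) {
  a <- select_diff_dor(stats, delta_R, delta_P, beam)
  b <- select_ci_nonoverlap(stats, beam)
  finalize_selection(stats, stats$pattern %in% intersect(a$pattern, b$pattern))
}

#' Apply a selection configuration
#'
#' Dispatches to the selector named in `cfg$method`.
#'
#' @param stats a `pattern_stats` table.
#' @param cfg a [selection_config()].
#' @return The selected subset.
#' @export
select_patterns <- function(stats, cfg) {
  stopifnot(inherits(cfg, "selection_config"))
  switch(cfg$method,
         jep = select_jep(stats),
         dor_threshold = select_dor_threshold(stats, cfg$dor_lo, cfg$dor_hi),
         diff_dor = select_diff_dor(stats, cfg$delta_R, cfg$delta_P, cfg$beam),
         ci_nonoverlap = select_ci_nonoverlap(stats, cfg$beam),
         combined = select_combined(stats, cfg$delta_R, cfg$delta_P, cfg$beam))
}
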