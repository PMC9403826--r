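# Frequent multivariate sequential pattern mining.
#
# Depth-first enumeration over the canonical prefix tree: every pattern is
# reached exactly once, either by an S-extension (append a new singleton
# itemset) or by an I-extension (grow the final itemset with an item
# canonically greater than its current maximum).  Support is
# anti-monotone, so a child's cover is computed only over its parent's
# cover; both are exact sets of supporting sequences.  The minimum support
# is relative to the mined class subset (patterns are mined per outcome
# class and contingency counts over the full database are attached
# afterwards).

#' Mine frequent sequential patterns
#'
#' @param db a [sequence_db()].
#' @param minsup minimum relative support in (0, 1]; a pattern is frequent
#'   in the mined class when at least `ceiling(minsup * n_class)` of that
#'   class's sequences contain it.
#' @param class class subset to mine: `"died"`, `"survived"`, or `"both"`
#'   (mine each class separately and take the union).
#' @param max_length optional cap on pattern length (total items).
#' @return A `mined_patterns` data frame, one row per pattern, ordered
#'   lexicographically on the canonical serialization, with columns
#'   `pattern`, `parent` (`NA` for length-1 patterns), `ext_kind`
#'   (`"S"`/`"I"`), `length`, `n_died`, `n_survived` (full-database class
#'   counts) and list columns `cover_died` / `cover_survived` holding the
#'   supporting sequence indices.
#' @export
mine_frequent <- function(db, minsup, class = c("died", "survived", "both"),
                          max_length = 10L) {
  stopifnot(inherits(db, "sequence_db"))
  if (!is.numeric(minsup) || minsup <= 0 || minsup > 1)
    stop("minsup must be a fraction in (0, 1]")
  class <- match.arg(class)
  if (class == "both") {
    a <- mine_frequent(db, minsup, "died", max_length)
    b <- mine_frequent(db, minsup, "survived", max_length)
    extra <- b[!(b$pattern %in% a$pattern), , drop = FALSE]
    out <- rbind(a, extra)
    out <- out[order(out$pattern, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "db_totals") <- c(n_died = db$n_died, n_survived = db$n_survived)
    class(out) <- c("mined_patterns", "data.frame")
    return(out)
  }

  target <- if (class == "died") 1L else 0L
  subset_idx <- which(unname(db$labels) == target)
  if (length(subset_idx) == 0L)
    stop("cannot mine an empty class subset")
  thr <- ceiling(minsup * length(subset_idx))

  rows <- new.env(parent = emptyenv())
  rows$acc <- list()
  in_subset <- unname(db$labels) == target
  died <- unname(db$labels) == 1L

  # frequent singleton alphabet (anti-monotone: any item of a frequent
  # pattern is itself frequent in the subset)
  n_items <- length(db$alphabet)
  root_cov <- cpp_extend_covers(db$encoded, seq_along(db$sequences), list(),
                                seq_len(n_items), integer(0))$s_covers
  freq_codes <- which(vapply(root_cov, function(cv) sum(in_subset[cv]), 0L) >= thr)

  emit <- function(pat_codes, cover, parent_str, kind) {
    p_str <- render_codes(pat_codes, db$alphabet)
    rows$acc[[length(rows$acc) + 1L]] <- list(
      pattern = p_str, parent = parent_str, ext_kind = kind,
      length = sum(lengths(pat_codes)),
      cover_died = cover[died[cover]],
      cover_survived = cover[!died[cover]])
    p_str
  }

  dfs <- function(pat_codes, cover, pat_str) {
    len <- sum(lengths(pat_codes))
    if (len >= max_length) return(invisible())
    last <- pat_codes[[length(pat_codes)]]
    s_cand <- freq_codes
    i_cand <- freq_codes[freq_codes > last[[length(last)]]]
    ext <- cpp_extend_covers(db$encoded, cover, pat_codes, s_cand, i_cand)
    for (j in seq_along(s_cand)) {
      cv <- ext$s_covers[[j]]
      if (sum(in_subset[cv]) >= thr) {
        child <- c(pat_codes, list(s_cand[[j]]))
        cstr <- emit(child, cv, pat_str, "S")
        dfs(child, cv, cstr)
      }
    }
    for (j in seq_along(i_cand)) {
      cv <- ext$i_covers[[j]]
      if (sum(in_subset[cv]) >= thr) {
        child <- pat_codes
        child[[length(child)]] <- c(last, i_cand[[j]])
        cstr <- emit(child, cv, pat_str, "I")
        dfs(child, cv, cstr)
      }
    }
    invisible()
  }

  for (code in freq_codes) {
    cv <- root_cov[[code]]
    pat <- list(code)
    pstr <- emit(pat, cv, NA_character_, "S")
    if (max_length > 1L) dfs(pat, cv, pstr)
  }

  acc <- rows$acc
  out <- data.frame(
    pattern = vapply(acc, `[[`, "", "pattern"),
    parent = vapply(acc, `[[`, "", "parent"),
    ext_kind = vapply(acc, `[[`, "", "ext_kind"),
    length = vapply(acc, `[[`, 0L, "length"),
    n_died = vapply(acc, function(r) length(r$cover_died), 0L),
    n_survived = vapply(acc, function(r) length(r$cover_survived), 0L),
    stringsAsFactors = FALSE)
  out$cover_died <- lapply(acc, `[[`, "cover_died")
  out$cover_survived <- lapply(acc, `[[`, "cover_survived")
  out <- out[order(out$pattern, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "db_totals") <- c(n_died = db$n_died, n_survived = db$n_survived)
  attr(out, "minsup") <- minsup
  attr(out, "class_mined") <- class
  class(out) <- c("mined_patterns", "data.frame")
  out
}

render_codes <- function(pat_codes, alphabet) {
  paste(vapply(pat_codes, function(is) paste(alphabet[is], collapse = " = "),
               ""), collapse = " < ")
}

#' @export
print.mined_patterns <- function(x, ...) {
  tot <- attr(x, "db_totals")
  cat("<mined_patterns> ", nrow(x), " patterns (db: ", tot[["n_died"]],
      " died / ", tot[["n_survived"]], " survived)\n", sep = "")
  if (nrow(x))
    print.data.frame(utils::head(x[c("pattern", "parent", "length",
                                     "n_died", "n_survived")], 10L))
  invisible(x)
}
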