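# Items, itemsets and point-based multivariate sequential patterns.
#
# An item is a token "VARIABLE_b" pairing a variable name with a
# non-negative discretization interval index (bin 0 is the lowest
# interval).  An itemset is a set of distinct items observed at the same
# time point; itemsets are kept in canonical order (variable name, then
# bin).  A pattern is an ordered list of itemsets related by "<" (strictly
# later day) with "=" joining items inside an itemset (same day).

ITEM_RE <- "^[A-Za-z][A-Za-z0-9.]*_[0-9]+$"

item_fields <- function(items) {
  pos <- regexpr("_[0-9]+$", items)
  list(variable = substr(items, 1L, pos - 1L),
       bin = as.integer(substring(items, pos + 1L)))
}

# canonical order: variable name (C collation), then bin index
item_order <- function(items) {
  f <- item_fields(items)
  order(f$variable, f$bin, method = "radix")
}

sort_items <- function(items) items[item_order(items)]

new_pattern <- function(itemsets) {
  structure(itemsets, class = "seq_pattern")
}

#' Create a sequential pattern from itemsets
#'
#' @param ... character vectors, one per itemset in temporal order; each
#'   contains items of the form `"VAR_b"` with `b` a non-negative bin index.
#' @return A `seq_pattern`: an ordered list of canonically sorted itemsets.
#' @examples
#' pattern(c("BIC_1"), c("BAL_4"), c("PH_1"))
#' pattern(c("INC_2", "PH_3"))
#' @export
pattern <- function(...) {
  itemsets <- lapply(list(...), as.character)
  if (length(itemsets) == 0L)
    stop("a pattern needs at least one itemset")
  itemsets <- lapply(seq_along(itemsets), function(i) {
    is <- itemsets[[i]]
    if (length(is) == 0L)
      stop("empty itemset at position ", i)
    bad <- is[!grepl(ITEM_RE, is)]
    if (length(bad))
      stop("malformed item token: '", bad[[1L]], "'")
    if (anyDuplicated(is))
      stop("duplicate item within an itemset: '", is[duplicated(is)][[1L]], "'")
    sort_items(is)
  })
  new_pattern(itemsets)
}

#' @export
print.seq_pattern <- function(x, ...) {
  cat("<pattern> ", render_pattern(x), "  (length ",
      pattern_length(x), ")\n", sep = "")
  invisible(x)
}

#' Parse a pattern from its text notation
#'
#' The notation joins items of one itemset with `" = "` and itemsets with
#' `" < "`, e.g. `"DIUR_3 < INC_0 < INC_0 < DIUR_3"` or `"INC_2 = PH_3"`.
#' Items inside an itemset are reordered canonically, so
#' `parse_pattern(render_pattern(p))` is the identity on canonical patterns.
#'
#' @param text a single pattern string.
#' @return A [pattern()] object.
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  groups <- strsplit(text, "<", fixed = TRUE)[[1L]]
  if (length(groups) == 0L || !nzchar(trimws(text)))
    stop("empty pattern string")
  itemsets <- lapply(groups, function(g) {
    toks <- trimws(strsplit(g, "=", fixed = TRUE)[[1L]])
    if (any(!nzchar(toks)) || length(toks) == 0L)
      stop("empty itemset in pattern: '", text, "'")
    toks
  })
  do.call(pattern, itemsets)
}

#' Render a pattern in text notation
#'
#' @param p a [pattern()].
#' @return A string such as `"BIC_0 = PH_1 < BAL_4"`.
#' @export
render_pattern <- function(p) {
  stopifnot(inherits(p, "seq_pattern"))
  paste(vapply(p, paste, "", collapse = " = "), collapse = " < ")
}

#' @export
format.seq_pattern <- function(x, ...) render_pattern(x)

#' @export
as.character.seq_pattern <- function(x, ...) render_pattern(x)

#' Total number of items in a pattern
#'
#' The length of a pattern is the number of item instances summed over its
#' itemsets, not the number of itemsets.
#'
#' @param p a [pattern()].
#' @return Integer item count.
#' @export
pattern_length <- function(p) {
  stopifnot(inherits(p, "seq_pattern"))
  sum(lengths(p))
}

#' Extend a pattern with an item
#'
#' `s_extend()` appends a new singleton itemset at a strictly later time
#' point; `i_extend()` adds the item to the final itemset (same time
#' point).  To guarantee that every canonical pattern is enumerated exactly
#' once, `i_extend()` only accepts items canonically greater than the last
#' item of the final itemset.
#'
#' @param p a [pattern()].
#' @param item a single item token.
#' @return The extended pattern; its length grows by one.
#' @export
s_extend <- function(p, item) {
  stopifnot(inherits(p, "seq_pattern"))
  check_item(item)
  new_pattern(c(unclass(p), list(item)))
}

#' @rdname s_extend
#' @export
i_extend <- function(p, item) {
  stopifnot(inherits(p, "seq_pattern"))
  check_item(item)
  last <- p[[length(p)]]
  if (item_le(item, last[[length(last)]]))
    stop("i_extend: item '", item,
         "' is not canonically greater than the final item '",
         last[[length(last)]], "'")
  out <- unclass(p)
  out[[length(out)]] <- c(last, item)
  new_pattern(out)
}

check_item <- function(item) {
  if (!is.character(item) || length(item) != 1L || !grepl(ITEM_RE, item))
    stop("malformed item token: '", paste(item, collapse = " "), "'")
  invisible(item)
}

# is a <= b in canonical item order?
item_le <- function(a, b) {
  fa <- item_fields(a); fb <- item_fields(b)
  if (fa$variable != fb$variable) {
    # C-collation comparison
    return(sort(c(fa$variable, fb$variable), method = "radix")[[1L]] == fa$variable)
  }
  fa$bin <= fb$bin
}

#' Enumeration-tree parent of a pattern
#'
#' The parent is the pattern with its last-added item removed: the largest
#' item of the final itemset (I-extensions always add canonically
#' increasing items), or the whole final itemset when it is a singleton.
#'
#' @param p a [pattern()].
#' @return The parent pattern, or `NULL` for a length-1 pattern.
#' @export
pattern_parent <- function(p) {
  stopifnot(inherits(p, "seq_pattern"))
  out <- unclass(p)
  last <- out[[length(out)]]
  if (length(last) > 1L) {
    out[[length(out)]] <- last[-length(last)]
  } else {
    out[[length(out)]] <- NULL
  }
  if (length(out) == 0L) return(NULL)
  new_pattern(out)
}
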