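# Patient sequences and the labelled sequence database.
#
# A patient sequence records, per integer day (1-based, strictly
# increasing), the itemset of discretized observations made that day.
# Patterns are order-only; the day indices of a sequence only matter
# through their order, and pattern itemsets may map to non-consecutive
# days.  The database attaches a binary outcome to every patient: died = 1
# (the target class of the 2x2 tables), survived = 0.

#' Create a patient sequence
#'
#' @param patient_id opaque identifier.
#' @param days integer vector of day indices, strictly increasing, >= 1.
#' @param itemsets list of character vectors (one itemset per day).
#' @return A `patient_seq` object.
#' @export
patient_sequence <- function(patient_id, days, itemsets) {
  days <- as.integer(days)
  stopifnot(length(days) == length(itemsets))
  if (length(days) && (any(days < 1L) || any(diff(days) <= 0L)))
    stop("day indices must be >= 1 and strictly increasing")
  itemsets <- lapply(itemsets, function(is) {
    is <- as.character(is)
    if (anyDuplicated(is))
      stop("an item can occur at most once per day: '",
           is[duplicated(is)][[1L]], "'")
    sort_items(is)
  })
  structure(list(patient_id = patient_id, days = days, itemsets = itemsets),
            class = "patient_seq")
}

#' Create a labelled sequence database
#'
#' @param sequences list of [patient_sequence()] objects.
#' @param labels binary outcomes aligned with `sequences` (1/"died" =
#'   target class, 0/"survived"), or a named vector keyed by patient id.
#' @return A `sequence_db` with class totals `n_died`, `n_survived` and the
#'   item alphabet in canonical order.
#' @export
sequence_db <- function(sequences, labels) {
  ids <- vapply(sequences, function(s) as.character(s$patient_id), "")
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss))
      stop("patients without outcome: ", paste(miss, collapse = ", "))
    labels <- labels[ids]
  }
  if (length(labels) != length(sequences))
    stop("one outcome label is required per sequence")
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "died")
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary (died = 1, survived = 0)")
  alphabet <- sort_items(unique(unlist(lapply(sequences,
                                              function(s) unlist(s$itemsets)))))
  db <- structure(list(sequences = sequences,
                       labels = stats::setNames(labels, ids),
                       n_died = sum(labels == 1L),
                       n_survived = sum(labels == 0L),
                       alphabet = alphabet),
                  class = "sequence_db")
  db$encoded <- encode_db(db)
  db
}

# integer-encode all sequences against the canonical alphabet
encode_db <- function(db) {
  lapply(db$sequences, function(s)
    lapply(s$itemsets, function(is) sort.int(match(is, db$alphabet))))
}

encode_pattern <- function(p, alphabet) {
  lapply(p, function(is) {
    codes <- match(is, alphabet)
    # NA codes (unknown items) sort last and simply never match
    sort.int(codes, na.last = TRUE, method = "radix")
  })
}

#' @export
print.sequence_db <- function(x, ...) {
  cat("<sequence_db> ", length(x$sequences), " patients (",
      x$n_died, " died, ", x$n_survived, " survived), alphabet of ",
      length(x$alphabet), " items\n", sep = "")
  invisible(x)
}

#' Pattern containment
#'
#' Tests whether a pattern embeds into a patient sequence: an
#' order-preserving injective mapping of the pattern's itemsets onto
#' strictly increasing days such that each itemset is a subset of the
#' mapped day's itemset.  Days need not be consecutive.
#'
#' @param seq a [patient_sequence()].
#' @param p a [pattern()].
#' @return `TRUE` or `FALSE`. Items absent from the sequence vocabulary
#'   never match.
#' @export
contains <- function(seq, p) {
  stopifnot(inherits(seq, "patient_seq"), inherits(p, "seq_pattern"))
  alphabet <- sort_items(unique(unlist(seq$itemsets)))
  enc <- lapply(seq$itemsets, function(is) sort.int(match(is, alphabet)))
  cpp_contains_many(list(enc), encode_pattern(p, alphabet))[[1L]]
}

#' Containment of one pattern over a whole database
#'
#' @param db a [sequence_db()].
#' @param p a [pattern()].
#' @return Logical vector over the database's sequences.
#' @export
db_contains <- function(db, p) {
  stopifnot(inherits(db, "sequence_db"), inherits(p, "seq_pattern"))
  cpp_contains_many(db$encoded, encode_pattern(p, db$alphabet))
}

#' Per-class support counts of a pattern
#'
#' @param p a [pattern()].
#' @param db a [sequence_db()].
#' @return `c(n_died, n_survived)`: the number of sequences of each class
#'   containing `p`.
#' @export
count_support <- function(p, db) {
  hit <- db_contains(db, p)
  c(n_died = sum(hit & db$labels == 1L),
    n_survived = sum(hit & db$labels == 0L))
}

#' Read a long-format cohort from CSV
#'
#' Expects a series file with columns `patient_id, day, variable, value`
#' (continuous values; one row per measurement) and an outcomes file with
#' columns `patient_id, outcome` (1 = died, 0 = survived).  Raw values are
#' retained for discretization by [apply_bins()] or [quantile_bins()].
#'
#' @param path path to the series CSV (UTF-8, header row).
#' @param outcomes path to the outcomes CSV.
#' @return A `raw_cohort`: list with elements `data` and `outcomes`.
#' @export
read_long_csv <- function(path, outcomes) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "variable", "value")
  if (!all(need %in% names(dat)))
    stop("series file must have columns: ", paste(need, collapse = ", "))
  out <- utils::read.csv(outcomes, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "outcome") %in% names(out)))
    stop("outcomes file must have columns: patient_id, outcome")
  raw_cohort(dat, out)
}

#' Assemble a raw (continuous) cohort
#'
#' @param data data frame with `patient_id, day, variable, value`.
#' @param outcomes data frame with `patient_id, outcome`.
#' @return A `raw_cohort` object; errors list duplicated
#'   (patient, day, variable) cells and patients without outcome.
#' @export
raw_cohort <- function(data, outcomes) {
  data$patient_id <- as.character(data$patient_id)
  data$day <- as.integer(data$day)
  outcomes$patient_id <- as.character(outcomes$patient_id)
  key <- paste(data$patient_id, data$day, data$variable, sep = "\r")
  if (anyDuplicated(key)) {
    d <- unique(key[duplicated(key)])
    stop("duplicated (patient, day, variable) cells: ",
         paste(gsub("\r", "/", utils::head(d, 5L)), collapse = "; "))
  }
  miss <- setdiff(unique(data$patient_id), outcomes$patient_id)
  if (length(miss))
    stop("patients without outcome: ",
         paste(utils::head(miss, 10L), collapse = ", "))
  if (anyDuplicated(outcomes$patient_id))
    stop("duplicate outcome rows")
  structure(list(data = data, outcomes = outcomes), class = "raw_cohort")
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat("<raw_cohort> ", length(unique(x$data$patient_id)), " patients, ",
      nrow(x$data), " measurements, variables: ",
      paste(sort(unique(x$data$variable)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
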