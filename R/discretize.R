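# Discretization of continuous daily values into ordered-bin items.
#
# A bin specification holds, per variable, a strictly increasing vector of
# finite cut points c_1 < ... < c_k defining k + 1 intervals
# (-Inf, c_1), [c_1, c_2), ..., [c_k, Inf): left-closed/right-open, so a
# value equal to a cut point falls in the upper interval, and bin index 0
# is the lowest interval.  Expert cut points come from a YAML config; an
# unsupervised quantile rule is the pluggable fallback.

#' Create a bin specification
#'
#' @param cuts named list: variable name -> strictly increasing numeric
#'   vector of finite cut points (k cuts define k + 1 bins).
#' @return A `bin_spec` object.
#' @examples
#' bin_spec(list(PH = c(7.35, 7.45)))  # PH_0 acidemia, PH_1 normal, PH_2 alkalemia
#' @export
bin_spec <- function(cuts) {
  stopifnot(is.list(cuts), !is.null(names(cuts)), all(nzchar(names(cuts))))
  for (v in names(cuts)) {
    cc <- cuts[[v]]
    if (!is.numeric(cc) || length(cc) == 0L || anyNA(cc) || any(!is.finite(cc)))
      stop("cut points for '", v, "' must be finite numbers")
    if (any(diff(cc) <= 0))
      stop("cut points for '", v, "' must be strictly increasing")
    cuts[[v]] <- as.numeric(cc)
  }
  structure(list(cuts = cuts,
                 n_bins = vapply(cuts, function(cc) length(cc) + 1L, 1L)),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat("<bin_spec>\n")
  for (v in names(x$cuts))
    cat("  ", v, ": ", x$n_bins[[v]], " bins, cuts ",
        paste(signif(x$cuts[[v]], 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a bin specification as YAML
#'
#' The YAML maps each variable to its list of cut points.
#'
#' @param path file path.
#' @return `read_bin_spec()` returns a [bin_spec()].
#' @export
read_bin_spec <- function(path) {
  bin_spec(yaml::read_yaml(path))
}

#' @rdname read_bin_spec
#' @param spec a [bin_spec()] to serialize.
#' @export
write_bin_spec <- function(spec, path) {
  stopifnot(inherits(spec, "bin_spec"))
  yaml::write_yaml(lapply(spec$cuts, as.numeric), path)
  invisible(path)
}

bin_index <- function(values, cuts) {
  # findInterval with half-open [c_i, c_{i+1}) intervals: index 0 is lowest
  findInterval(values, cuts, left.open = FALSE)
}

#' Discretize a raw cohort into an item sequence database
#'
#' Each measurement `(patient, day, variable, value)` becomes the item
#' `VARIABLE_b` where `b` is the 0-based index of the interval holding
#' `value`.  Non-finite values are skipped with a warning; a variable
#' missing from the spec is an error.  The result is a [sequence_db()]
#' (already-discretized input is rejected: re-binning bin indices is a
#' type error, not a no-op).
#'
#' @param raw a `raw_cohort` from [read_long_csv()] or [simulate_cohort()].
#' @param spec a [bin_spec()] covering every variable present.
#' @return A [sequence_db()].
#' @export
apply_bins <- function(raw, spec) {
  if (inherits(raw, "sequence_db"))
    stop("input is already a discretized sequence_db; re-binning is not allowed")
  stopifnot(inherits(raw, "raw_cohort"), inherits(spec, "bin_spec"))
  dat <- raw$data
  missing_vars <- setdiff(unique(dat$variable), names(spec$cuts))
  if (length(missing_vars))
    stop("variables missing from bin spec: ",
         paste(missing_vars, collapse = ", "))
  bad <- !is.finite(dat$value)
  if (any(bad)) {
    warning(sum(bad), " non-finite values skipped during discretization")
    dat <- dat[!bad, , drop = FALSE]
  }
  bins <- integer(nrow(dat))
  for (v in unique(dat$variable)) {
    sel <- dat$variable == v
    bins[sel] <- bin_index(dat$value[sel], spec$cuts[[v]])
  }
  dat$item <- paste0(dat$variable, "_", bins)

  ids <- raw$outcomes$patient_id
  by_pat <- split(dat[c("day", "item")], factor(dat$patient_id, levels = ids))
  sequences <- lapply(ids, function(pid) {
    rows <- by_pat[[pid]]
    days <- sort(unique(rows$day))
    patient_sequence(pid, days,
                     lapply(days, function(d) rows$item[rows$day == d]))
  })
  labels <- stats::setNames(as.integer(raw$outcomes$outcome), ids)
  sequence_db(sequences, labels)
}

#' Unsupervised quantile bin specification
#'
#' Cut points are placed at the 1/k, ..., (k-1)/k empirical quantiles of
#' each variable (type-7 quantiles), giving approximately equal bin
#' occupancy.  This is the pluggable stand-in for correlation-preserving
#' discretizers: it shares the [bin_spec()] interface, so the miner is
#' agnostic to how cuts were chosen.
#'
#' @param raw a `raw_cohort`.
#' @param k bins per variable, >= 2.
#' @return A [bin_spec()].
#' @export
quantile_bins <- function(raw, k) {
  stopifnot(inherits(raw, "raw_cohort"), k >= 2)
  vals <- split(raw$data$value, raw$data$variable)
  cuts <- list()
  for (v in names(vals)) {
    x <- vals[[v]][is.finite(vals[[v]])]
    if (length(unique(x)) < k)
      stop("too few distinct values to form ", k, " bins for variable '",
           v, "'")
    cc <- unique(stats::quantile(x, probs = seq_len(k - 1) / k,
                                 names = FALSE, type = 7))
    if (length(cc) < k - 1)
      stop("too few distinct values to form ", k, " bins for variable '",
           v, "'")
    cuts[[v]] <- cc
  }
  bin_spec(cuts)
}
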