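# Diagnostic odds ratio statistics on 2x2 pattern-vs-outcome tables.
#
# The table cells follow the diagnostic convention with death as the
# target disorder: tp = died with the pattern, fn = died without it,
# fp = survived with the pattern, tn = survived without it.  The DOR is
# (tp/fn)/(fp/tn); its 95% interval is Miettinen's test-based interval
# DOR^(1 +/- z/chi) with chi the square root of the Mantel-Haenszel
# chi-square (N - 1 scaling).  Tables with a zero cell are corrected
# before any ratio is formed.

#' Construct a 2x2 contingency table for a pattern
#'
#' @param tp died patients containing the pattern.
#' @param fn died patients without the pattern.
#' @param fp survived patients containing the pattern.
#' @param tn survived patients without the pattern.
#' @param corrected logical, whether a continuity correction has been
#'   applied (cells may then be half-integers).
#' @return A `contingency` object.
#' @export
contingency <- function(tp, fn, fp, tn, corrected = FALSE) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(cells) || any(cells < 0))
    stop("contingency cells must be non-negative")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, corrected = corrected),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat("<contingency>", if (x$corrected) "(corrected)" else "", "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("pattern+", "pattern-"),
                              c("died", "survived")))
  print(m)
  invisible(x)
}

#' Continuity correction for zero cells
#'
#' If no cell is zero the table is returned unchanged.  Otherwise the
#' default `"margin"` convention adds 0.5 to each zero cell and subtracts
#' 0.5 from the other cell of the same outcome class, so both class totals
#' are preserved exactly; this is the convention that reproduces the
#' study-style worked values (e.g. DOR 98.05 for a 10/0 split against
#' 87 died / 378 survived).  The `"all"` convention adds 0.5 to all four
#' cells (the naive reading, giving 102.56 on the same table) and is kept
#' for comparison only.
#'
#' @param t a [contingency()] with integer cells.
#' @param method `"margin"` (default) or `"all"`.
#' @return A corrected [contingency()]; errors when an outcome class total
#'   is zero.
#' @export
correct_zero_cells <- function(t, method = c("margin", "all")) {
  stopifnot(inherits(t, "contingency"))
  method <- match.arg(method)
  if (t$tp + t$fn == 0 || t$fp + t$tn == 0)
    stop("an outcome class total is zero; the table is undefined")
  if (all(c(t$tp, t$fn, t$fp, t$tn) > 0)) return(t)
  if (method == "all")
    return(contingency(t$tp + 0.5, t$fn + 0.5, t$fp + 0.5, t$tn + 0.5,
                       corrected = TRUE))
  tp <- t$tp; fn <- t$fn; fp <- t$fp; tn <- t$tn
  if (tp == 0) { tp <- 0.5; fn <- fn - 0.5 }
  else if (fn == 0) { fn <- 0.5; tp <- tp - 0.5 }
  if (fp == 0) { fp <- 0.5; tn <- tn - 0.5 }
  else if (tn == 0) { tn <- 0.5; fp <- fp - 0.5 }
  contingency(tp, fn, fp, tn, corrected = TRUE)
}

#' Diagnostic odds ratio of a table
#'
#' @param t a [contingency()] with all cells positive (apply
#'   [correct_zero_cells()] first).
#' @return `(tp/fn)/(fp/tn)`, in (0, Inf).
#' @export
dor <- function(t) {
  stopifnot(inherits(t, "contingency"))
  if (any(c(t$tp, t$fn, t$fp, t$tn) == 0))
    stop("zero cell: run correct_zero_cells() before dor()")
  (t$tp / t$fn) / (t$fp / t$tn)
}

#' Risk and protection probabilities of a DOR
#'
#' `R = DOR/(DOR + 1)` is the risk-factor probability (> 0.5 iff DOR > 1)
#' and `P = 1 - R` the protection-factor probability.
#'
#' @param dor_value a non-negative DOR.
#' @return `c(R = ..., P = ...)`.
#' @export
risk_protection <- function(dor_value) {
  stopifnot(is.numeric(dor_value), all(dor_value >= 0))
  r <- dor_value / (dor_value + 1)
  c(R = unname(r), P = unname(1 - r))
}

#' Mantel-Haenszel chi-square of a table
#'
#' `chi^2 = (N - 1) (tp tn - fn fp)^2 / [(tp+fp)(fn+tn)(tp+fn)(fp+tn)]`,
#' computed on the (corrected) table with N the total patient count
#' (margin-preserving corrections leave N and all margins unchanged).
#'
#' @param t a [contingency()].
#' @return The non-negative statistic; 0 iff the table is exactly
#'   independent.
#' @export
mh_chisq <- function(t) {
  stopifnot(inherits(t, "contingency"))
  m <- c(t$tp + t$fp, t$fn + t$tn, t$tp + t$fn, t$fp + t$tn)
  if (any(m == 0)) stop("a margin of the table is zero")
  n <- t$tp + t$fn + t$fp + t$tn
  (n - 1) * (t$tp * t$tn - t$fn * t$fp)^2 / prod(m)
}

#' Test-based 95% confidence interval for the DOR
#'
#' Miettinen's interval `DOR^(1 +/- z/chi)` with
#' `chi = sqrt(mh_chisq(t))`, reported sorted ascending; it always
#' contains the point estimate, and excludes 1 exactly when
#' `mh_chisq(t) > z^2`.
#'
#' @param t a [contingency()] (corrected if it had zero cells).
#' @param z normal quantile, 1.96 for 95% confidence.
#' @return `c(low, high)`; errors when `mh_chisq` is 0 (interval undefined
#'   by this method).
#' @export
dor_ci <- function(t, z = 1.96) {
  d <- dor(t)
  chi2 <- mh_chisq(t)
  if (chi2 == 0)
    stop("chi-square is zero: test-based interval undefined at DOR = 1")
  chi <- sqrt(chi2)
  b <- c(d^(1 - z / chi), d^(1 + z / chi))
  c(low = min(b), high = max(b))
}

#' Jumping Emerging Pattern predicate
#'
#' A JEP has support in exactly one class and none in the other.
#'
#' @param n_died_with_p,n_survived_with_p per-class counts of sequences
#'   containing the pattern.
#' @return `TRUE` iff exactly one count is 0; errors when both are 0.
#' @export
is_jep <- function(n_died_with_p, n_survived_with_p) {
  stopifnot(n_died_with_p >= 0, n_survived_with_p >= 0)
  if (n_died_with_p == 0 && n_survived_with_p == 0)
    stop("pattern unsupported in both classes")
  xor(n_died_with_p == 0, n_survived_with_p == 0)
}

#' Clinical rule interestingness measures for a pattern table
#'
#' Computed for the rule "pattern -> died".  Undefined ratios (zero
#' denominators) are reported as `NA`, not as errors.
#'
#' @param t a [contingency()] (uncorrected counts are fine here).
#' @return Named vector: support, confidence, coverage, prevalence,
#'   sensitivity, specificity, accuracy, relative_risk.
#' @export
pattern_measures <- function(t) {
  stopifnot(inherits(t, "contingency"))
  n <- t$tp + t$fn + t$fp + t$tn
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(support = div(t$tp, n),
    confidence = div(t$tp, t$tp + t$fp),
    coverage = div(t$tp + t$fp, n),
    prevalence = div(t$tp + t$fn, n),
    sensitivity = div(t$tp, t$tp + t$fn),
    specificity = div(t$tn, t$tn + t$fp),
    accuracy = div(t$tp + t$tn, n),
    relative_risk = {
      a <- div(t$tp, t$tp + t$fp); b <- div(t$fn, t$fn + t$tn)
      if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
    })
}

#' Pattern statistics table
#'
#' Attaches the full DOR summary to every mined pattern: contingency
#' counts against the database class totals, the (corrected when needed)
#' DOR, risk/protection probabilities, Mantel-Haenszel chi-square, and the
#' test-based 95% interval.  Patterns at DOR exactly 1 (chi-square 0) get
#' `NA` interval bounds.
#'
#' @param mined a `mined_patterns` table from [mine_frequent()].
#' @param correction zero-cell convention passed to
#'   [correct_zero_cells()].
#' @param z normal quantile for the interval.
#' @return A `pattern_stats` data frame with columns `pattern`, `parent`,
#'   `length`, `tp`, `fn`, `fp`, `tn`, `corrected`, `dor`, `R`, `P`,
#'   `chi_mh`, `ci_low`, `ci_high`, `jep`.
#' @export
pattern_stats <- function(mined, correction = c("margin", "all"), z = 1.96) {
  stopifnot(inherits(mined, "mined_patterns"))
  correction <- match.arg(correction)
  tot <- attr(mined, "db_totals")
  n <- nrow(mined)
  out <- data.frame(pattern = mined$pattern, parent = mined$parent,
                    length = mined$length,
                    tp = as.numeric(mined$n_died),
                    fn = tot[["n_died"]] - as.numeric(mined$n_died),
                    fp = as.numeric(mined$n_survived),
                    tn = tot[["n_survived"]] - as.numeric(mined$n_survived),
                    stringsAsFactors = FALSE)
  out$corrected <- FALSE
  out$dor <- out$R <- out$P <- out$chi_mh <- NA_real_
  out$ci_low <- out$ci_high <- NA_real_
  out$jep <- FALSE
  for (i in seq_len(n)) {
    t0 <- contingency(out$tp[i], out$fn[i], out$fp[i], out$tn[i])
    t1 <- correct_zero_cells(t0, correction)
    out$corrected[i] <- t1$corrected
    out$tp[i] <- t1$tp; out$fn[i] <- t1$fn
    out$fp[i] <- t1$fp; out$tn[i] <- t1$tn
    d <- dor(t1)
    rp <- risk_protection(d)
    out$dor[i] <- d; out$R[i] <- rp[["R"]]; out$P[i] <- rp[["P"]]
    out$chi_mh[i] <- mh_chisq(t1)
    if (out$chi_mh[i] > 0) {
      ci <- dor_ci(t1, z)
      out$ci_low[i] <- ci[["low"]]; out$ci_high[i] <- ci[["high"]]
    }
    out$jep[i] <- is_jep(mined$n_died[i], mined$n_survived[i])
  }
  attr(out, "db_totals") <- tot
  class(out) <- c("pattern_stats", "data.frame")
  out
}

#' @export
print.pattern_stats <- function(x, ...) {
  cat("<pattern_stats> ", nrow(x), " patterns\n", sep = "")
  if (nrow(x)) {
    cols <- intersect(c("pattern", "tp", "fp", "dor", "R",
                        "ci_low", "ci_high", "jep"), names(x))
    show <- as.data.frame(x)[cols]
    for (cc in intersect(c("dor", "ci_low", "ci_high"), cols))
      show[[cc]] <- round(show[[cc]], 2)
    if ("R" %in% cols) show$R <- round(show$R, 4)
    print.data.frame(utils::head(show, 10L))
  }
  invisible(x)
}
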