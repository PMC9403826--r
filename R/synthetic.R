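# Synthetic intensive-care-burn-unit cohorts with planted motifs.
#
# The generator emulates the shape of the study cohort: N patients with a
# fixed survivor fraction, D days of V continuous daily variables, each
# discretized into ordered bins.  Ground-truth class-discriminative
# sequential motifs are planted at designed per-class penetrances; all
# other cells are drawn independently and uniformly over the bins.
# Continuous values are then drawn uniformly inside the interval of the
# assigned bin, so discretizing with the companion bin spec recovers the
# intended items exactly.  The generator tests algorithms, not clinical
# realism: there is no autocorrelation, no physiology, no missingness.

ICBU_VARIABLES <- c("INC", "DIUR", "BAL", "PH", "BIC", "BE")

# illustrative clinically-shaped sampling anchors (NOT the study's expert
# bins, which were never published): k bins need k + 1 anchors; interior
# anchors are the bin-spec cut points.
icbu_anchors <- function() {
  list(INC = c(0, 2000, 4000, 7000, 12000, 20000),
       DIUR = c(0, 300, 800, 1500, 2500, 5000),
       BAL = c(-6000, -1000, 0, 1500, 4000, 12000),
       PH = c(6.90, 7.15, 7.30, 7.40, 7.50, 7.70),
       BIC = c(2, 12, 18, 22, 27, 40),
       BE = c(-25, -10, -5, 0, 5, 15))
}

rescale_anchors <- function(anchors, k) {
  lapply(anchors, function(a) {
    if (length(a) == k + 1L) a
    else seq(a[[1L]], a[[length(a)]], length.out = k + 1L)
  })
}

#' Default planted motif: persistent severe metabolic acidosis
#'
#' Low pH together with low bicarbonate on two separate days — a strongly
#' discriminative signature planted in the non-survivor class.
#'
#' @return A [pattern()].
#' @export
default_motif <- function() {
  pattern(c("BIC_0", "PH_0"), c("BIC_0", "PH_0"))
}

#' Simulation configuration
#'
#' Defaults reproduce the study cohort's shape: 465 patients, 81.3%
#' survivors, 6 daily variables over 5 days, 5 bins per variable, and one
#' strong non-survivor motif ([default_motif()]) at penetrance 0.4 among
#' the died and 0.01 among the survived.
#'
#' @param n_patients cohort size.
#' @param survivor_fraction fraction surviving (rounded to a count).
#' @param n_days days of observation.
#' @param variables variable names.
#' @param n_bins bins per variable.
#' @param motifs list of `list(pattern =, p_died =, p_survived =)` with
#'   penetrances in `[0, 1]`.
#' @param mode `"exact"` plants `round(penetrance * class size)` carriers
#'   exactly (reproducible tests); `"binomial"` draws each patient's
#'   carrier flag independently (for interval-coverage studies).
#' @return A `sim_config` list (includes the companion sampling anchors).
#' @export
sim_config <- function(n_patients = 465L, survivor_fraction = 0.813,
                       n_days = 5L, variables = ICBU_VARIABLES,
                       n_bins = 5L,
                       motifs = list(list(pattern = default_motif(),
                                          p_died = 0.4, p_survived = 0.01)),
                       mode = c("exact", "binomial")) {
  mode <- match.arg(mode)
  stopifnot(n_patients >= 2L, n_days >= 1L, n_bins >= 2L,
            survivor_fraction > 0, survivor_fraction < 1,
            length(variables) >= 1L)
  for (m in motifs) {
    stopifnot(inherits(m$pattern, "seq_pattern"),
              m$p_died >= 0, m$p_died <= 1,
              m$p_survived >= 0, m$p_survived <= 1)
    if (length(m$pattern) > n_days)
      stop("motif '", render_pattern(m$pattern),
           "' has more itemsets than there are days")
    f <- item_fields(unlist(m$pattern))
    if (!all(f$variable %in% variables))
      stop("motif uses unknown variables: ",
           paste(setdiff(f$variable, variables), collapse = ", "))
    if (any(f$bin >= n_bins))
      stop("motif bin index exceeds n_bins - 1")
  }
  anchors <- rescale_anchors(
    icbu_anchors()[intersect(names(icbu_anchors()), variables)], n_bins)
  for (v in setdiff(variables, names(anchors)))
    anchors[[v]] <- seq(0, 1, length.out = n_bins + 1L)
  structure(list(n_patients = as.integer(n_patients),
                 survivor_fraction = survivor_fraction,
                 n_days = as.integer(n_days), variables = variables,
                 n_bins = as.integer(n_bins), motifs = motifs,
                 mode = mode, anchors = anchors[variables]),
            class = "sim_config")
}

#' Companion bin specification of a simulation configuration
#'
#' @param cfg a [sim_config()].
#' @return The [bin_spec()] whose cut points are the interior sampling
#'   anchors; [apply_bins()] with it recovers the planted bins exactly.
#' @export
sim_bin_spec <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  bin_spec(lapply(cfg$anchors, function(a) a[-c(1L, length(a))]))
}

#' Simulate a cohort with planted motifs
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the same seed yields an identical cohort.
#' @return A list with `raw` (a `raw_cohort` of continuous values),
#'   `bin_spec` (companion spec), and `ground_truth` (per-motif realized
#'   per-class carrier counts and per-patient carrier flags).
#' @export
simulate_cohort <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(as.integer(seed), {
    n <- cfg$n_patients
    n_surv <- round(cfg$survivor_fraction * n)
    n_died <- n - n_surv
    if (n_died == 0L || n_surv == 0L)
      stop("survivor_fraction leaves a class empty")
    ids <- sprintf("P%04d", seq_len(n))
    died <- logical(n)
    died[sample.int(n, n_died)] <- TRUE

    k <- cfg$n_bins
    nv <- length(cfg$variables)
    bins <- array(sample.int(k, n * cfg$n_days * nv, replace = TRUE) - 1L,
                  dim = c(n, cfg$n_days, nv))
    set_by <- array(0L, dim = dim(bins))  # motif index that wrote the cell

    gt <- list()
    for (mi in seq_along(cfg$motifs)) {
      m <- cfg$motifs[[mi]]
      carriers_d <- pick_carriers(which(died), m$p_died, cfg$mode)
      carriers_s <- pick_carriers(which(!died), m$p_survived, cfg$mode)
      carriers <- c(carriers_d, carriers_s)
      conflict <- FALSE
      for (p in carriers) {
        dsel <- sort(sample.int(cfg$n_days, length(m$pattern)))
        for (j in seq_along(m$pattern)) {
          f <- item_fields(m$pattern[[j]])
          vi <- match(f$variable, cfg$variables)
          prev <- set_by[cbind(p, dsel[j], vi)]
          if (any(prev > 0L & prev < mi &
                    bins[cbind(p, dsel[j], vi)] != f$bin))
            conflict <- TRUE
          bins[cbind(p, dsel[j], vi)] <- f$bin
          set_by[cbind(p, dsel[j], vi)] <- mi
        }
      }
      if (conflict)
        warning("motif ", mi, " overwrote cells planted by an earlier motif")
      flags <- logical(n); flags[carriers] <- TRUE
      gt[[mi]] <- list(pattern = render_pattern(m$pattern),
                       n_carriers_died = length(carriers_d),
                       n_carriers_survived = length(carriers_s),
                       carriers = stats::setNames(flags, ids))
    }

    # continuous values drawn uniformly inside each cell's bin interval
    long <- expand.grid(patient = seq_len(n), day = seq_len(cfg$n_days),
                        vi = seq_len(nv), KEEP.OUT.ATTRS = FALSE)
    b <- bins[as.matrix(long)]
    lo <- hi <- numeric(nrow(long))
    for (vi in seq_len(nv)) {
      a <- cfg$anchors[[vi]]
      sel <- long$vi == vi
      lo[sel] <- a[b[sel] + 1L]
      hi[sel] <- a[b[sel] + 2L]
    }
    raw <- data.frame(patient_id = ids[long$patient], day = long$day,
                      variable = cfg$variables[long$vi],
                      value = stats::runif(nrow(long), lo, hi),
                      stringsAsFactors = FALSE)
    ord <- order(raw$patient_id, raw$day, raw$variable, method = "radix")
    raw <- raw[ord, , drop = FALSE]
    rownames(raw) <- NULL
    outcomes <- data.frame(patient_id = ids,
                           outcome = as.integer(died),
                           stringsAsFactors = FALSE)
    list(raw = raw_cohort(raw, outcomes), bin_spec = sim_bin_spec(cfg),
         ground_truth = gt)
  })
}

pick_carriers <- function(class_idx, penetrance, mode) {
  if (mode == "exact") {
    n_c <- round(penetrance * length(class_idx))
    if (n_c == 0L) return(integer(0))
    sample(class_idx, n_c)
  } else {
    class_idx[stats::runif(length(class_idx)) < penetrance]
  }
}

#' Write a cohort to long-format CSV files
#'
#' Produces `series.csv`, `outcomes.csv` and `bins.yaml` under `dir`,
#' readable back with [read_long_csv()] and [read_bin_spec()].
#'
#' @param cohort result of [simulate_cohort()] or a `raw_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  raw <- if (inherits(cohort, "raw_cohort")) cohort else cohort$raw
  stopifnot(inherits(raw, "raw_cohort"))
  if (nrow(raw$data) == 0L) stop("refusing to write an empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(series = file.path(dir, "series.csv"),
             outcomes = file.path(dir, "outcomes.csv"))
  utils::write.csv(raw$data, paths[["series"]], row.names = FALSE)
  utils::write.csv(raw$outcomes, paths[["outcomes"]], row.names = FALSE)
  if (!inherits(cohort, "raw_cohort") && !is.null(cohort$bin_spec)) {
    paths[["bins"]] <- file.path(dir, "bins.yaml")
    write_bin_spec(cohort$bin_spec, paths[["bins"]])
  }
  invisible(paths)
}
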