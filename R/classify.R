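# Pattern-containment features and interpretable classifiers.
#
# Selected patterns become binary containment features.  Two classifiers
# from the interpretable family are provided natively (no compiled
# C4.5/RIPPER port exists in this stack): an entropy-based decision tree
# with a minimum-leaf constraint, and a RIPPER-family sequential-covering
# rule learner with grow/prune sets, FOIL gain and a minimum rule weight.
# Both are restricted to binary features, which keeps them exact, small
# and deterministic.  Evaluation is pooled stratified k-fold
# cross-validation; the positive class is SURVIVAL (so an uninformative
# majority model on an imbalanced cohort scores sensitivity 100%,
# specificity 0%).

#' Encode pattern-containment features
#'
#' @param db a [sequence_db()].
#' @param patterns a list of [pattern()] objects, a character vector of
#'   pattern strings, or a `pattern_stats` table.
#' @return Binary matrix, patients x patterns (columns in canonical
#'   order); duplicated patterns are dropped with a warning.
#' @export
encode_features <- function(db, patterns) {
  stopifnot(inherits(db, "sequence_db"))
  if (inherits(patterns, "pattern_stats") || is.data.frame(patterns))
    patterns <- patterns$pattern
  if (is.character(patterns)) patterns <- lapply(patterns, parse_pattern)
  if (inherits(patterns, "seq_pattern")) patterns <- list(patterns)
  if (length(patterns) == 0L)
    stop("no patterns to encode")
  keys <- vapply(patterns, render_pattern, "")
  if (anyDuplicated(keys)) {
    warning("duplicated patterns dropped: ",
            paste(unique(keys[duplicated(keys)]), collapse = "; "))
    patterns <- patterns[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }
  ord <- order(keys, method = "radix")
  patterns <- patterns[ord]; keys <- keys[ord]
  m <- vapply(patterns, function(p) as.integer(db_contains(db, p)),
              integer(length(db$sequences)))
  m <- matrix(m, nrow = length(db$sequences),
              dimnames = list(names(db$labels), keys))
  m
}

entropy <- function(n1, n0) {
  n <- n1 + n0
  if (n == 0) return(0)
  p <- c(n1, n0) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Recursive entropy-gain tree on binary features.  `y` is 1 = survived
# (positive class), 0 = died.  Returns nested list nodes.
grow_tree <- function(x, y, min_leaf) {
  n <- length(y)
  leaf <- function() list(type = "leaf", n = n,
                          p_surv = (sum(y) + 1) / (n + 2),
                          majority = as.integer(mean(y) >= 0.5))
  if (n < 2 * min_leaf || length(unique(y)) == 1L || ncol(x) == 0L)
    return(leaf())
  h <- entropy(sum(y), n - sum(y))
  best <- 0; best_j <- 0L
  for (j in seq_len(ncol(x))) {
    on <- x[, j] == 1L
    n1 <- sum(on)
    if (n1 < min_leaf || n - n1 < min_leaf) next
    g <- h - (n1 / n) * entropy(sum(y[on]), n1 - sum(y[on])) -
      ((n - n1) / n) * entropy(sum(y[!on]), (n - n1) - sum(y[!on]))
    if (g > best + 1e-12) { best <- g; best_j <- j }
  }
  if (best_j == 0L || best <= 1e-12) return(leaf())
  on <- x[, best_j] == 1L
  list(type = "split", feature = colnames(x)[best_j], n = n,
       yes = grow_tree(x[on, , drop = FALSE], y[on], min_leaf),
       no = grow_tree(x[!on, , drop = FALSE], y[!on], min_leaf))
}

predict_tree <- function(node, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$type == "leaf") { out[idx] <<- node$p_surv; return(invisible()) }
    on <- x[idx, node$feature] == 1L
    rec(node$yes, idx[on]); rec(node$no, idx[!on])
  }
  rec(node, seq_len(nrow(x)))
  out
}

tree_features <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$feature, tree_features(node$yes), tree_features(node$no)))
}

format_tree <- function(node, indent = "") {
  if (node$type == "leaf")
    return(sprintf("%sleaf: p(survive) = %.3f (n = %d)",
                   indent, node$p_surv, node$n))
  c(sprintf("%scontains [%s]:", indent, node$feature),
    format_tree(node$yes, paste0(indent, "  ")),
    sprintf("%snot contains [%s]:", indent, node$feature),
    format_tree(node$no, paste0(indent, "  ")))
}

# RIPPER-family rule learner.  Learns rules for the minority class
# (death), default class = survival.  A rule is a conjunction of literals
# (feature, value in {0, 1}).
rule_matches <- function(rule, x) {
  hit <- rep(TRUE, nrow(x))
  for (lit in rule) hit <- hit & (x[, lit$feature] == lit$value)
  hit
}

grow_rule <- function(x, y_pos, candidates, active) {
  rule <- list()
  repeat {
    p0 <- sum(y_pos[active]); n0 <- sum(!y_pos[active])
    if (n0 == 0 || p0 == 0) break
    best_gain <- 0; best <- NULL; best_active <- NULL
    for (j in candidates) for (v in c(1L, 0L)) {
      sel <- active & (x[, j] == v)
      p1 <- sum(y_pos[sel])
      if (p1 == 0) next
      n1 <- sum(!y_pos[sel])
      gain <- p1 * (log2(p1 / (p1 + n1)) - log2(p0 / (p0 + n0)))
      if (gain > best_gain + 1e-12) {
        best_gain <- gain
        best <- list(feature = colnames(x)[j], value = v)
        best_active <- sel
      }
    }
    if (is.null(best)) break
    rule[[length(rule) + 1L]] <- best
    active <- best_active
  }
  rule
}

prune_rule <- function(rule, x_pr, y_pos_pr) {
  if (!length(rule)) return(rule)
  worth <- function(r) {
    if (!length(r)) return(-Inf)
    hit <- rule_matches(r, x_pr)
    p <- sum(y_pos_pr[hit]); n <- sum(hit) - p
    if (p + n == 0) return(-Inf)
    (p - n) / (p + n)
  }
  best <- rule; best_w <- worth(rule)
  r <- rule
  while (length(r) > 1L) {
    r <- r[-length(r)]
    w <- worth(r)
    if (w >= best_w) { best <- r; best_w <- w }
  }
  best
}

fit_rules <- function(x, y, min_weight, seed) {
  # y: 1 = survived; rules target death (the minority class)
  y_pos <- y == 0L
  rules <- list()
  remaining <- rep(TRUE, nrow(x))
  split <- local_seed(seed + 1L, stratified_split(y, 2 / 3))
  candidates <- seq_len(ncol(x))
  if (ncol(x) > 0) {
    for (iter in seq_len(50L)) {
      act_grow <- remaining & split
      act_prune <- remaining & !split
      if (sum(y_pos[remaining]) == 0L) break
      rule <- grow_rule(x, y_pos, candidates, act_grow)
      if (!length(rule)) break
      rule <- prune_rule(rule, x[act_prune, , drop = FALSE],
                         y_pos[act_prune])
      hit <- rule_matches(rule, x) & remaining
      p <- sum(y_pos[hit]); n <- sum(hit) - p
      if (sum(hit) < min_weight || p <= n) break
      rules[[length(rules) + 1L]] <-
        list(literals = rule, p = p, n = n,
             death_prob = (p + 1) / (p + n + 2))
      remaining <- remaining & !rule_matches(rule, x)
    }
  }
  default_death <- {
    p <- sum(y_pos[remaining]); n <- sum(remaining) - p
    (p + 1) / (p + n + 2)
  }
  list(rules = rules, default_death = default_death)
}

predict_rules <- function(model, x) {
  death <- rep(model$default_death, nrow(x))
  assigned <- rep(FALSE, nrow(x))
  for (r in model$rules) {
    hit <- rule_matches(r$literals, x) & !assigned
    death[hit] <- r$death_prob
    assigned <- assigned | hit
  }
  1 - death
}

rules_features <- function(model) {
  feats <- unique(unlist(lapply(model$rules, function(r)
    vapply(r$literals, `[[`, "", "feature"))))
  if (is.null(feats)) character(0) else feats
}

format_rules <- function(model) {
  lines <- vapply(model$rules, function(r) {
    lits <- vapply(r$literals, function(l)
      sprintf("%scontains [%s]", if (l$value == 1L) "" else "not ",
              l$feature), "")
    sprintf("IF %s THEN died (%d died / %d survived covered)",
            paste(lits, collapse = " AND "), r$p, r$n)
  }, "")
  c(lines, sprintf("ELSE survived (default, p(death) = %.3f)",
                   model$default_death))
}

# run `expr` under a local RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# stratified random logical split (TRUE with proportion frac per class)
stratified_split <- function(y, frac) {
  out <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    take <- sample(idx, max(1L, round(frac * length(idx))))
    out[take] <- TRUE
  }
  out
}

# stratified fold assignment 1..k
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

auc_mw <- function(score, positive) {
  # Mann-Whitney with ties = 0.5
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train and evaluate a pattern-based survival classifier
#'
#' Fits an interpretable model on binary pattern-containment features and
#' reports pooled stratified k-fold cross-validation metrics.  The
#' positive class is survival: sensitivity is the fraction of survivors
#' recognised, specificity the fraction of non-survivors recognised, so
#' the majority baseline on an imbalanced cohort has sensitivity 100% and
#' specificity 0%.
#'
#' @param fm feature matrix from [encode_features()].
#' @param labels binary outcome vector aligned with rows (1 = died).
#' @param model `"tree"` (entropy-based decision tree) or `"rules"`
#'   (RIPPER-family sequential covering).
#' @param min_leaf_frac minimum fraction of training patients per leaf /
#'   per rule (the 2% interpretability constraint).
#' @param k number of cross-validation folds.
#' @param seed integer seed controlling fold assignment and the rule
#'   learner's grow/prune split.
#' @return An `eval_report` list: `sensitivity`, `specificity`,
#'   `accuracy` (percent), `auc`, `n_patterns`, `total_length`,
#'   `avg_length`, `patterns_used`, `model_text`, `confusion`.
#' @export
train_and_eval <- function(fm, labels, model = c("tree", "rules"),
                           min_leaf_frac = 0.02, k = 10L, seed = 1L) {
  model <- match.arg(model)
  labels <- as.integer(labels)
  stopifnot(nrow(fm) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("both outcome classes are required")
  if (min(table(labels)) < k)
    stop("k exceeds the size of the smallest class")
  y <- 1L - labels  # 1 = survived (positive class)

  fold <- local_seed(seed, stratified_folds(y, k))
  score <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    min_leaf <- max(1L, ceiling(min_leaf_frac * sum(tr)))
    fitted <- if (model == "tree")
      grow_tree(fm[tr, , drop = FALSE], y[tr], min_leaf)
    else
      fit_rules(fm[tr, , drop = FALSE], y[tr], min_leaf, seed + f)
    score[!tr] <- if (model == "tree")
      predict_tree(fitted, fm[!tr, , drop = FALSE])
    else
      predict_rules(fitted, fm[!tr, , drop = FALSE])
  }
  pred_surv <- score >= 0.5
  tp <- sum(pred_surv & y == 1L); fn <- sum(!pred_surv & y == 1L)
  tn <- sum(!pred_surv & y == 0L); fp <- sum(pred_surv & y == 0L)

  min_leaf <- max(1L, ceiling(min_leaf_frac * length(y)))
  final <- if (model == "tree") grow_tree(fm, y, min_leaf)
  else fit_rules(fm, y, min_leaf, seed)
  used <- if (model == "tree") tree_features(final) else rules_features(final)
  lens <- if (length(used))
    vapply(used, function(s) pattern_length(parse_pattern(s)), 0L) else integer(0)

  structure(list(
    model = model,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / length(y),
    auc = auc_mw(score, y == 1L),
    confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
    n_patterns = length(used),
    total_length = sum(lens),
    avg_length = if (length(used)) sum(lens) / length(used) else NA_real_,
    patterns_used = sort(as.character(used), method = "radix"),
    model_text = if (model == "tree") format_tree(final)
    else format_rules(final),
    k = k, seed = seed), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s: sens %.2f%%  spec %.2f%%  acc %.2f%%  AUC %.3f\n",
    x$model, x$sensitivity, x$specificity, x$accuracy, x$auc))
  cat(sprintf("  %d patterns, total length %d, average %.2f\n",
              x$n_patterns, x$total_length,
              if (is.na(x$avg_length)) 0 else x$avg_length))
  cat(x$model_text, sep = "\n")
  invisible(x)
}
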