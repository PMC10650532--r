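# Evaluation protocol: stratified k-fold cross-validation, confusion
# metrics (positive class = ictal, one-vs-rest for 3-class runs), and
# Kruskal-Wallis comparison of per-fold metric values across methods.

#' Stratified k-fold assignment
#'
#' Shuffles indices within each class and deals them round-robin, so
#' every fold's class counts differ by at most one sample per class.
#'
#' @param labels Vector of class labels (each class must have >= k
#'   members).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  assert_scalar_number(k, "k", 2)
  k <- as.integer(k)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    small <- names(counts)[counts < k]
    stop("class(es) ", paste(small, collapse = ", "),
         " have fewer than k = ", k, " members", call. = FALSE)
  }
  folds <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts; positive class is the
#'   seizure (ictal) class.
#' @return A `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  vals <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  vals <- as.integer(vals)
  structure(list(tp = vals[1], fp = vals[2], tn = vals[3], fn = vals[4]),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall of the positive class), specificity,
#' precision and F1, all as percentages. A metric whose denominator is
#' empty is reported as `NA` (undefined), never silently as 0.
#'
#' @param counts A [confusion_counts()].
#' @return A one-row data frame with columns `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1` (percent, `NA` when undefined).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0L) stop("no evaluated samples", call. = FALSE)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- (tp + tn) / total
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  data.frame(accuracy = 100 * acc, sensitivity = 100 * sens,
             specificity = 100 * spec, precision = 100 * prec,
             f1 = 100 * f1)
}

#' Kruskal-Wallis H test across groups
#'
#' Rank-based H with tie correction and a chi-square p-value on `k - 1`
#' degrees of freedom (via [stats::kruskal.test()]). When every
#' observation across all groups is identical the statistic is defined as
#' `H = 0` with `p = 1` (the test's 0/0 tie correction is replaced by
#' this convention).
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("need a total of >= 3 observations", call. = FALSE)
  k <- length(groups)
  if (length(unique(x)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = k - 1L))
  }
  g <- factor(rep(seq_len(k), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Compare cross-validation results with Kruskal-Wallis tests
#'
#' Runs one Kruskal-Wallis test per metric across the methods' per-fold
#' values and flags p-values below `alpha`.
#'
#' @param results List of >= 2 `cv_result` objects (see
#'   [run_pipeline()]), with identical fold counts.
#' @param alpha Significance threshold (default 0.05, uncorrected).
#' @return Data frame with `metric`, `H`, `p_value`, `significant`.
#' @export
compare_methods <- function(results, alpha = 0.05) {
  if (!is.list(results) || length(results) < 2L) {
    stop("need >= 2 cross-validation results to compare", call. = FALSE)
  }
  per_fold <- lapply(results, function(r) {
    stopifnot(inherits(r, "cv_result"))
    r$per_fold
  })
  nf <- vapply(per_fold, nrow, integer(1))
  if (length(unique(nf)) != 1L) {
    stop("methods have mismatched fold counts", call. = FALSE)
  }
  metrics <- c("accuracy", "sensitivity", "specificity", "precision", "f1")
  rows <- lapply(metrics, function(mt) {
    kw <- kruskal_wallis(lapply(per_fold, `[[`, mt))
    data.frame(metric = mt, H = kw$statistic, p_value = kw$p_value,
               significant = kw$p_value < alpha)
  })
  do.call(rbind, rows)
}
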