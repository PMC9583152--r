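#' Draw repeated one-sample-per-drug bootstrap test sets
#'
#' Each repeat draws, for every test drug independently, a single
#' uncertainty-sample index uniformly at random, and the chosen rows form
#' one test set (one row per drug; 16 rows for the reference test split).
#' Draws are independent across repeats; each repeat uses its own seed
#' stream derived from the master seed, so the sequence does not depend
#' on evaluation order and is reproducible.
#'
#' @param bank Feature bank data.frame (see [synth_feature_bank()])
#'   restricted to test-split drugs.
#' @param n_repeats Number of test sets (default 10000).
#' @param seed Master seed.
#' @return Object of class `test_sets`: `drugs`, `n_samples` per drug and
#'   an `n_repeats` x `n_drugs` matrix `idx` of sample indices.
#' @export
make_test_sets <- function(bank, n_repeats = 10000, seed = 1L) {
  if (any(bank$split != "test")) {
    stop("bank must contain only test-split drugs")
  }
  drugs <- unique(bank$drug)
  n_samples <- vapply(drugs, function(d) sum(bank$drug == d), integer(1))
  if (any(n_samples == 0)) {
    stop("drug with zero samples: ", paste(drugs[n_samples == 0], collapse = ", "))
  }
  idx <- matrix(0L, n_repeats, length(drugs),
                dimnames = list(NULL, drugs))
  for (r in seq_len(n_repeats)) {
    idx[r, ] <- with_seed(derive_seed(seed, paste0("testset-", r)),
                          vapply(n_samples, function(k) sample.int(k, 1L),
                                 integer(1)))
  }
  structure(list(drugs = drugs, n_samples = n_samples, idx = idx,
                 n_repeats = n_repeats, seed = seed),
            class = "test_sets")
}

#' One-vs-rest ROC AUC by midranks
#'
#' Rank-based area under the ROC curve of a score for one positive class:
#' the Mann-Whitney U statistic normalised by the number of
#' positive-negative pairs, with ties receiving half credit (midranks).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Item labels.
#' @param positive_class The label treated as positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc_ovr <- function(scores, labels, positive_class) {
  pos <- labels == positive_class
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) {
    stop("single-class input: need both positive and negative items")
  }
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Three-class confusion matrix and diagnostic metrics
#'
#' Builds the 3x3 confusion matrix of predicted vs actual risk labels and,
#' per class one-vs-rest, the counts TP/TN/FP/FN with sensitivity
#' (recall), specificity, precision, the diagnostic likelihood ratios
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`, and the F1
#' score, plus the overall accuracy. A ratio whose denominator is zero is
#' reported as `NA` with a reason code rather than as infinity.
#'
#' @param predicted,actual Risk labels of equal length.
#' @return Object of class `confusion_summary`: `table` (3x3), `per_class`
#'   data.frame, `accuracy`, `n`, `reasons` (named character vector of
#'   zero-division codes).
#' @export
confusion_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  predicted <- as_risk(predicted); actual <- as_risk(actual)
  tab <- table(predicted = predicted, actual = actual)
  n <- length(actual)
  reasons <- character(0)
  per_class <- do.call(rbind, lapply(risk_levels(), function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[cl, ]) - tp
    fn <- sum(tab[, cl]) - tp
    tn <- n - tp - fp - fn
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    lrp <- if (!is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
    lrm <- if (!is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    if (is.na(lrp)) reasons[paste0(cl, ".lr_plus")] <<- "specificity=1"
    if (is.na(lrm)) reasons[paste0(cl, ".lr_minus")] <<- "specificity=0"
    if (is.na(prec)) reasons[paste0(cl, ".precision")] <<- "no predictions"
    data.frame(class = cl, tp = tp, tn = tn, fp = fp, fn = fn,
               sensitivity = sens, specificity = spec, precision = prec,
               lr_plus = lrp, lr_minus = lrm, f1 = f1)
  }))
  structure(list(table = tab, per_class = per_class,
                 accuracy = sum(diag(tab)) / n, n = n, reasons = reasons),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> n = %d, accuracy = %.3f\n", x$n, x$accuracy))
  print(x$per_class[, c("class", "sensitivity", "specificity",
                        "lr_plus", "lr_minus", "f1")], row.names = FALSE)
  invisible(x)
}

#' Repeated bootstrap evaluation of a fitted ordinal classifier
#'
#' For each of `n_repeats` one-sample-per-drug test sets: classify the
#' set with [predict_class()], score each class with its predicted
#' probability, and record overall accuracy plus per-class one-vs-rest
#' AUC and F1 (and likelihood ratios). Per-metric medians, minima and
#' maxima over the repeats are returned; an AUC that is undefined in a
#' repeat (single-class set) becomes a missing cell, never an abort.
#'
#' @param model Converged `olr_fit`.
#' @param bank Feature bank containing the test-split rows of the
#'   model's feature.
#' @param n_repeats Number of repeats (default 10000).
#' @param seed Master seed for the test-set draws.
#' @param feature Feature column scored; defaults to the model's.
#' @return Object of class `repeat_summary` with a `metrics` data.frame
#'   (`metric`, `class`, `median`, `min`, `max`) and `n_repeats`.
#' @export
evaluate_repeats <- function(model, bank, n_repeats = 10000, seed = 1L,
                             feature = model$feature_name) {
  stopifnot(inherits(model, "olr_fit"))
  if (!model$converged) stop("model did not converge")
  bank <- bank[bank$split == "test", , drop = FALSE]
  if (!feature %in% names(bank)) stop("feature '", feature, "' not in bank")
  sets <- make_test_sets(bank, n_repeats = n_repeats, seed = seed)
  drugs <- sets$drugs
  # row lookup: row_id[drug d, sample s] into the bank
  row_id <- lapply(drugs, function(d) which(bank$drug == d))
  x <- bank[[feature]]
  probs <- class_probabilities(model, x)
  pred <- as.integer(predict_class(model, x))
  actual_by_drug <- vapply(row_id, function(ix) {
    as.integer(as_risk(bank$risk[ix[1]]))
  }, integer(1))

  classes <- risk_levels()
  acc <- numeric(n_repeats)
  auc <- matrix(NA_real_, n_repeats, 3, dimnames = list(NULL, classes))
  f1 <- matrix(NA_real_, n_repeats, 3, dimnames = list(NULL, classes))
  lrp <- matrix(NA_real_, n_repeats, 3, dimnames = list(NULL, classes))
  lrm <- matrix(NA_real_, n_repeats, 3, dimnames = list(NULL, classes))
  act_f <- factor(classes[actual_by_drug], levels = classes, ordered = TRUE)
  for (r in seq_len(n_repeats)) {
    rows <- vapply(seq_along(drugs),
                   function(j) row_id[[j]][sets$idx[r, j]], integer(1))
    pr <- factor(classes[pred[rows]], levels = classes, ordered = TRUE)
    cm <- confusion_metrics(pr, act_f)
    acc[r] <- cm$accuracy
    f1[r, ] <- cm$per_class$f1
    lrp[r, ] <- cm$per_class$lr_plus
    lrm[r, ] <- cm$per_class$lr_minus
    for (k in 1:3) {
      if (any(actual_by_drug == k) && any(actual_by_drug != k)) {
        auc[r, k] <- roc_auc_ovr(probs[rows, k], actual_by_drug, k)
      }
    }
  }
  summarise <- function(mat, name) {
    do.call(rbind, lapply(seq_len(ncol(mat)), function(k) {
      v <- mat[, k]
      data.frame(metric = name, class = classes[k],
                 median = stats::median(v, na.rm = TRUE),
                 min = suppressWarnings(min(v, na.rm = TRUE)),
                 max = suppressWarnings(max(v, na.rm = TRUE)))
    }))
  }
  metrics <- rbind(
    data.frame(metric = "accuracy", class = "overall",
               median = stats::median(acc), min = min(acc), max = max(acc)),
    summarise(auc, "auc"), summarise(f1, "f1"),
    summarise(lrp, "lr_plus"), summarise(lrm, "lr_minus"))
  structure(list(feature = feature, n_repeats = n_repeats, metrics = metrics),
            class = "repeat_summary")
}

#' Format a repeat-summary cell as "median (min-max)"
#'
#' @param summary A `repeat_summary`.
#' @param metric,class Cell selector.
#' @param digits Decimal places (default 2).
#' @return Character scalar like `"0.92 (0.75-0.96)"`, or `"-"` for an
#'   empty cell.
#' @export
format_summary_cell <- function(summary, metric, class, digits = 2) {
  row <- summary$metrics[summary$metrics$metric == metric &
                           summary$metrics$class == class, ]
  if (nrow(row) == 0 || !is.finite(row$median)) return("-")
  sprintf(paste0("%.", digits, "f (%.", digits, "f–%.", digits, "f)"),
          row$median, row$min, row$max)
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("<repeat_summary> %s over %d repeats\n", x$feature, x$n_repeats))
  cat("  accuracy:", format_summary_cell(x, "accuracy", "overall"), "\n")
  for (cl in risk_levels()) {
    cat(sprintf("  %-12s AUC %s  F1 %s\n", cl,
                format_summary_cell(x, "auc", cl),
                format_summary_cell(x, "f1", cl)))
  }
  invisible(x)
}

#' Compare one biomarker across two datasets (F test then Welch t)
#'
#' Two-sided variance-ratio F test, followed by the unequal-variance
#' (Welch) two-sample t test with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @return List: `f_statistic`, `f_p`, `t_statistic`, `t_p`.
#' @export
compare_datasets <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs size >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both samples")
  }
  f <- stats::var.test(a, b)
  t <- stats::t.test(a, b, var.equal = FALSE)
  list(f_statistic = unname(f$statistic), f_p = f$p.value,
       t_statistic = unname(t$statistic), t_p = t$p.value)
}
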