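# Deduplicated stratified k-fold cross-validation, per-status metric
# suite, balanced accuracy / macro F aggregates, document-type breakdown,
# patient-overlap audit and extractor comparison.

#' Stratified fold assignment
#'
#' Shuffles items within each class under the seed, then deals them to
#' folds in a single round-robin that continues across classes, so fold
#' sizes differ by at most one both per class and overall. Duplicated
#' normalized keys are a contract violation (deduplicate first): an
#' identical sentence in two folds would leak validation data into
#' training.
#'
#' @param labels Character vector of gold labels.
#' @param keys Normalized sentence keys ([normalize_key()]); must be
#'   unique.
#' @param k Number of folds (default 3).
#' @param seed Integer seed.
#' @return Object of class \code{fold_plan}: integer \code{assignment} in
#'   \code{1:k} per item, plus \code{k} and \code{seed}.
#' @export
make_folds <- function(labels, keys, k = 3L, seed = 1L) {
  n <- length(labels)
  stopifnot(length(keys) == n, k >= 2L)
  if (anyDuplicated(keys)) {
    stop("duplicated normalized keys; deduplicate before folding",
         call. = FALSE)
  }
  cnt <- table(labels)
  small <- names(cnt)[cnt < k]
  if (length(small) > 0L) {
    stop(sprintf("class(es) with fewer than k samples: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  rng <- local_rng(seed)
  assignment <- integer(n)
  pointer <- 0L
  for (cl in sort(names(cnt))) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample(length(idx), length(idx))]
    assignment[idx] <- ((pointer + seq_along(idx) - 1L) %% k) + 1L
    pointer <- (pointer + length(idx)) %% k
  }
  structure(list(assignment = assignment, k = as.integer(k),
                 seed = as.integer(seed)), class = "fold_plan")
}

# One-vs-rest confusion counts per class.
confusion_counts <- function(gold, predicted, classes) {
  n <- length(gold)
  t(vapply(classes, function(cl) {
    tp <- sum(gold == cl & predicted == cl)
    fp <- sum(gold != cl & predicted == cl)
    fn <- sum(gold == cl & predicted != cl)
    c(tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn)
  }, numeric(4)))
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Per-status metrics, balanced accuracy and macro F
#'
#' One-vs-rest counts per class give precision \eqn{TP/(TP+FP)}, recall
#' \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)} and the F-score (their
#' harmonic mean of precision and recall). Aggregates are averaged over
#' the evaluated statuses only:
#' \deqn{BA = \frac{1}{C}\sum_c \frac{recall_c + specificity_c}{2}, \qquad
#'       F_{macro} = \frac{1}{C}\sum_c F_c.}
#' Undefined ratios (0/0) are reported \code{NA} and excluded from
#' aggregates, with \code{has_undefined} flagged — a status with no
#' support is marked not-applicable, never scored 0.
#'
#' @param gold,predicted Character label vectors over the same sentences
#'   (equal length, aligned).
#' @param evaluated_statuses Classes entering the aggregates; default:
#'   every class with at least one gold sample, plus \code{unknown}.
#' @return Object of class \code{metrics_report}: \code{per_class} data
#'   frame, \code{balanced_accuracy}, \code{macro_f},
#'   \code{evaluated_statuses}, \code{has_undefined}, \code{n}.
#' @export
compute_metrics <- function(gold, predicted, evaluated_statuses = NULL) {
  if (length(gold) != length(predicted)) {
    stop("gold and predicted must cover the same sentences", call. = FALSE)
  }
  if (is.null(evaluated_statuses)) {
    evaluated_statuses <- union(sort(unique(gold[gold != "unknown"])),
                                intersect("unknown", c(gold, predicted)))
  }
  classes <- evaluated_statuses
  cc <- confusion_counts(gold, predicted, classes)
  precision <- safe_ratio(cc[, "tp"], cc[, "tp"] + cc[, "fp"])
  recall <- safe_ratio(cc[, "tp"], cc[, "tp"] + cc[, "fn"])
  specificity <- safe_ratio(cc[, "tn"], cc[, "tn"] + cc[, "fp"])
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(!is.na(precision) & !is.na(recall), 0, NA_real_))
  per_class <- data.frame(status = classes, tp = cc[, "tp"], fp = cc[, "fp"],
                          fn = cc[, "fn"], tn = cc[, "tn"],
                          precision = precision, recall = recall,
                          specificity = specificity, f1 = f1,
                          stringsAsFactors = FALSE)
  ba_terms <- (recall + specificity) / 2
  structure(list(per_class = per_class,
                 balanced_accuracy = mean(ba_terms, na.rm = TRUE),
                 macro_f = mean(f1, na.rm = TRUE),
                 evaluated_statuses = classes,
                 has_undefined = anyNA(c(ba_terms, f1)),
                 n = length(gold)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, statuses: %s\n", x$n,
              paste(x$evaluated_statuses, collapse = "/")))
  df <- x$per_class[, c("status", "precision", "recall", "specificity", "f1")]
  df[-1] <- lapply(df[-1], round, 4)
  print(df, row.names = FALSE)
  cat(sprintf("balanced accuracy %.4f, macro F %.4f%s\n",
              x$balanced_accuracy, x$macro_f,
              if (x$has_undefined) " (undefined cells excluded)" else ""))
  invisible(x)
}

#' Cross-validate an extractor backend
#'
#' Runs k train/validate rounds over a stratified, deduplicated fold plan:
#' in each round one fold validates and the rest train. The backend
#' factory receives the training \code{labeled_dataset} and the fold index
#' and returns a fitted \code{status_extractor}; stateless backends
#' (rules, external) simply ignore the training data.
#'
#' @param dataset A [labeled_dataset()].
#' @param backend_factory \code{function(train_dataset, fold)} returning a
#'   \code{status_extractor}.
#' @param k Number of folds.
#' @param seed Integer seed for the fold plan.
#' @return Object of class \code{cv_result}: per-fold
#'   \code{metrics_report}s, \code{macro_f} per fold, \code{mean_macro_f},
#'   \code{sd_macro_f} (sample SD over folds), and the \code{fold_plan}.
#' @export
cross_validate <- function(dataset, backend_factory, k = 3L, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  keep <- dataset$labels %in% dataset$label_set
  sents <- dataset$sentences[keep, , drop = FALSE]
  labels <- dataset$labels[keep]
  plan <- make_folds(labels, normalize_key(sents$text), k = k, seed = seed)
  reports <- vector("list", k)
  macro_f <- numeric(k)
  for (fold in seq_len(k)) {
    val <- plan$assignment == fold
    train_ds <- labeled_dataset(sents[!val, , drop = FALSE], labels[!val],
                                condition = dataset$condition,
                                min_per_class = 1L)
    extractor <- tryCatch(backend_factory(train_ds, fold), error = function(e) {
      stop(sprintf("fold %d: %s", fold, conditionMessage(e)), call. = FALSE)
    })
    pred <- predict(extractor, sents[val, , drop = FALSE])
    reports[[fold]] <- compute_metrics(labels[val], pred$label)
    macro_f[[fold]] <- reports[[fold]]$macro_f
  }
  structure(list(reports = reports, macro_f = macro_f,
                 mean_macro_f = mean(macro_f),
                 sd_macro_f = stats::sd(macro_f),
                 fold_plan = plan, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: macro F %s; mean %.4f (SD %.4f)\n",
              x$k, paste(sprintf("%.4f", x$macro_f), collapse = ", "),
              x$mean_macro_f, x$sd_macro_f))
  invisible(x)
}

#' Per-document-type F-score breakdown
#'
#' Recomputes the per-status F-score within each document-type slice.
#' Combinations with zero gold and zero predicted support are marked
#' \code{NA} (not available), never 0.
#'
#' @param gold,predicted Aligned label vectors.
#' @param doc_types Document type per sentence.
#' @return Data frame (\code{doc_type}, \code{status}, \code{f1},
#'   \code{support}).
#' @export
breakdown_by_doctype <- function(gold, predicted, doc_types) {
  stopifnot(length(gold) == length(predicted),
            length(gold) == length(doc_types))
  statuses <- sort(unique(c(gold, predicted)))
  out <- list()
  for (dt in sort(unique(doc_types))) {
    sel <- doc_types == dt
    cc <- confusion_counts(gold[sel], predicted[sel], statuses)
    for (i in seq_along(statuses)) {
      support <- cc[i, "tp"] + cc[i, "fn"]
      predicted_n <- cc[i, "tp"] + cc[i, "fp"]
      f1 <- if (support + predicted_n == 0) NA_real_ else {
        prec <- safe_ratio(cc[i, "tp"], predicted_n)
        rec <- safe_ratio(cc[i, "tp"], support)
        if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
      }
      out[[length(out) + 1L]] <- data.frame(
        doc_type = dt, status = statuses[[i]], f1 = f1,
        support = as.integer(support), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Audit patient overlap across folds
#'
#' For each fold, the fraction of its validation sentences whose patient
#' also contributes sentences to the corresponding training folds —
#' sentence-level partitioning does not stratify by patient, so related
#' sentences can leak across the split.
#'
#' @param plan A [make_folds()] plan.
#' @param patient_ids Patient id per item, aligned with the plan.
#' @return Numeric vector of per-fold overlap fractions.
#' @export
audit_patient_overlap <- function(plan, patient_ids) {
  stopifnot(inherits(plan, "fold_plan"),
            length(patient_ids) == length(plan$assignment))
  vapply(seq_len(plan$k), function(fold) {
    val <- plan$assignment == fold
    train_patients <- unique(patient_ids[!val])
    if (!any(val)) return(NA_real_)
    mean(patient_ids[val] %in% train_patients)
  }, numeric(1))
}

#' Paired fold-wise comparison of two extractors
#'
#' Two-sided paired t-test on per-fold macro F-scores of two backends
#' evaluated on identical folds (k - 1 degrees of freedom).
#'
#' @param macro_f_a,macro_f_b Per-fold macro F vectors of equal length.
#' @return \code{htest} object from [stats::t.test()].
#' @export
compare_extractors <- function(macro_f_a, macro_f_b) {
  stopifnot(length(macro_f_a) == length(macro_f_b))
  stats::t.test(macro_f_a, macro_f_b, paired = TRUE)
}
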