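# Annotation records, inter-annotator agreement (Cohen's kappa), the
# agreement gate, disagreement extraction, term-driven revision selection
# and annotation-time accounting.

#' Build an annotation record table
#'
#' One record per (sentence, annotator, condition): a status label and the
#' time the decision took.
#'
#' @param sent_id,annotator_id,condition Character vectors.
#' @param label Status labels (see [status_labels()]).
#' @param duration_seconds Nonnegative decision times.
#' @return Data frame with the five fields, validated.
#' @export
annotation_records <- function(sent_id, annotator_id, condition, label,
                               duration_seconds = NA_real_) {
  label <- as.character(label)
  bad <- setdiff(unique(label), status_labels())
  if (length(bad) > 0L) {
    stop(sprintf("invalid status label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.na(duration_seconds) & duration_seconds < 0)) {
    stop("duration_seconds must be nonnegative", call. = FALSE)
  }
  out <- data.frame(sent_id = as.character(sent_id),
                    annotator_id = as.character(annotator_id),
                    condition = as.character(condition),
                    label = label,
                    duration_seconds = as.numeric(duration_seconds),
                    stringsAsFactors = FALSE)
  key <- paste(out$sent_id, out$annotator_id, out$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("at most one record per (sent_id, annotator_id, condition)",
         call. = FALSE)
  }
  out
}

# Align two annotators' records for a condition on an identical sentence
# set; errors list the symmetric difference.
align_records <- function(records_a, records_b, condition) {
  a <- records_a[records_a$condition == condition, , drop = FALSE]
  b <- records_b[records_b$condition == condition, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop(sprintf("no overlapping annotations for condition '%s'", condition),
         call. = FALSE)
  }
  only_a <- setdiff(a$sent_id, b$sent_id)
  only_b <- setdiff(b$sent_id, a$sent_id)
  if (length(only_a) > 0L || length(only_b) > 0L) {
    stop(sprintf(
      "annotators labeled different sentence sets for '%s' (only A: %s; only B: %s)",
      condition,
      paste(utils::head(only_a, 5), collapse = ","),
      paste(utils::head(only_b, 5), collapse = ",")), call. = FALSE)
  }
  b <- b[match(a$sent_id, b$sent_id), , drop = FALSE]
  list(sent_id = a$sent_id, label_a = a$label, label_b = b$label)
}

#' Cohen's kappa between two annotators
#'
#' Chance-corrected agreement \eqn{\kappa = (P_o - P_e) / (1 - P_e)} on the
#' doubly-annotated sentence set of one condition, where \eqn{P_o} is the
#' observed agreement fraction and \eqn{P_e = \sum_l m_A(l)\,m_B(l)} the
#' chance agreement from the annotators' label marginals. When
#' \eqn{P_e = 1} (both annotators degenerate on a single label) kappa is
#' defined as 1 if \eqn{P_o = 1} and 0 otherwise.
#'
#' @param records_a,records_b Annotation record tables of the two
#'   annotators; for \code{condition} they must cover an identical,
#'   non-empty sentence set.
#' @param condition Condition name.
#' @return Object of class \code{agreement_result}: \code{kappa},
#'   \code{po}, \code{pe}, \code{n_items}, and the label-by-label
#'   \code{contingency} table.
#' @export
cohen_kappa <- function(records_a, records_b, condition) {
  al <- align_records(records_a, records_b, condition)
  n <- length(al$sent_id)
  labs <- status_labels()
  tab <- table(factor(al$label_a, levels = labs),
               factor(al$label_b, levels = labs))
  po <- sum(diag(tab)) / n
  pe <- sum((rowSums(tab) / n) * (colSums(tab) / n))
  kappa <- if (pe >= 1) {
    if (po >= 1) 1 else 0
  } else {
    (po - pe) / (1 - pe)
  }
  structure(list(kappa = kappa, po = po, pe = pe, n_items = n,
                 contingency = tab),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> kappa %.4f (Po %.4f, Pe %.4f, n = %d)\n",
              x$kappa, x$po, x$pe, x$n_items))
  invisible(x)
}

#' Agreement gate
#'
#' Annotated data is trusted only when chance-corrected agreement reaches
#' the threshold (boundary inclusive); below it a disagreement-analysis and
#' correction round is required.
#'
#' @param result An [cohen_kappa()] result.
#' @param threshold Kappa threshold in (0, 1]; default 0.8.
#' @return \code{TRUE} (pass) or \code{FALSE} (fail).
#' @export
agreement_gate <- function(result, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  result$kappa >= threshold
}

#' Extract disagreeing items
#'
#' @inheritParams cohen_kappa
#' @return Data frame (\code{sent_id}, \code{label_a}, \code{label_b}) of
#'   exactly the items with unequal labels, input order preserved.
#' @export
find_disagreements <- function(records_a, records_b, condition) {
  al <- align_records(records_a, records_b, condition)
  diff <- al$label_a != al$label_b
  data.frame(sent_id = al$sent_id[diff],
             label_a = al$label_a[diff],
             label_b = al$label_b[diff], stringsAsFactors = FALSE)
}

#' Correction plan from ambiguous terms
#'
#' After a failed agreement gate, disagreement analysis typically yields a
#' list of ambiguous terms clarified in updated guidelines; sentences
#' containing any term are re-annotated.
#'
#' @param ambiguous_terms Non-empty character vector.
#' @param guideline_version Version tag of the updated guidelines.
#' @return Object of class \code{correction_plan}.
#' @export
correction_plan <- function(ambiguous_terms, guideline_version = "v2") {
  if (length(ambiguous_terms) == 0L) {
    stop("ambiguous_terms must be non-empty", call. = FALSE)
  }
  structure(list(ambiguous_terms = as.character(ambiguous_terms),
                 guideline_version = guideline_version),
            class = "correction_plan")
}

#' Select sentences for revision
#'
#' Case-insensitive substring containment of any ambiguous term against
#' whitespace-normalized sentence text; each sentence listed once, in
#' input order.
#'
#' @param sentences Sentence data frame.
#' @param plan A [correction_plan()].
#' @return Character vector of \code{sent_id}s.
#' @export
select_for_revision <- function(sentences, plan) {
  stopifnot(inherits(plan, "correction_plan"))
  norm <- normalize_key(sentences$text)
  hit <- rep(FALSE, length(norm))
  for (term in plan$ambiguous_terms) {
    hit <- hit | stringi::stri_detect_fixed(norm, normalize_key(term))
  }
  sentences$sent_id[hit]
}

#' Annotation-time accounting
#'
#' Mean annotation duration per sentence over all records, and restricted
#' to informative records (label other than \code{unknown}); uninformative
#' sentences are dismissed much faster, biasing the overall mean down.
#'
#' @param records Annotation record table with durations.
#' @return List with \code{mean_all} and \code{mean_informative} (seconds
#'   per sentence; \code{NA} when no informative record exists).
#' @export
annotation_time_summary <- function(records) {
  d <- records$duration_seconds
  if (anyNA(d)) stop("durations must be present", call. = FALSE)
  informative <- records$label != "unknown"
  list(mean_all = mean(d),
       mean_informative = if (any(informative)) mean(d[informative])
                          else NA_real_)
}

#' Apply a correction round
#'
#' Replaces records of the selected sentences with corrected labels and
#' archives the replaced records with the plan's guideline version, so an
#' audit trail of pre-correction annotations is retained.
#'
#' @param records Annotation record table.
#' @param corrected Record table of re-annotated sentences (same fields).
#' @param plan The [correction_plan()] that triggered the revision.
#' @return List with \code{records} (updated) and \code{archived} (the
#'   replaced rows plus a \code{guideline_version} column).
#' @export
apply_corrections <- function(records, corrected, plan) {
  stopifnot(inherits(plan, "correction_plan"))
  key <- function(df) paste(df$sent_id, df$annotator_id, df$condition,
                            sep = "\r")
  replaced <- key(records) %in% key(corrected)
  archived <- records[replaced, , drop = FALSE]
  if (nrow(archived) > 0L) archived$guideline_version <- plan$guideline_version
  list(records = rbind(records[!replaced, , drop = FALSE], corrected),
       archived = archived)
}
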