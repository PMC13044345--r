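# Orchestration of the iterative loop: segmentation, preannotation,
# qualification, kappa-gated annotation ingestion, training,
# cross-validation, stopping rule, and report rendering.

#' Stopping rule for the iterative loop
#'
#' @param macro_f_threshold Stop once mean macro F reaches this value
#'   (default 0.90).
#' @param max_iterations Hard cap on iterations (default 2).
#' @return Object of class \code{stop_rule}.
#' @export
stop_rule <- function(macro_f_threshold = 0.90, max_iterations = 2L) {
  stopifnot(macro_f_threshold > 0, macro_f_threshold <= 1)
  structure(list(macro_f_threshold = macro_f_threshold,
                 max_iterations = as.integer(max_iterations)),
            class = "stop_rule")
}

#' Stop / continue decision
#'
#' Stop once the cross-validated mean macro F reaches the threshold, or
#' (with a warning) once the iteration cap is hit.
#'
#' @param mean_macro_f Mean macro F of the current iteration.
#' @param rule A [stop_rule()].
#' @param iteration Current iteration index.
#' @return \code{TRUE} to stop, \code{FALSE} to continue.
#' @export
should_stop <- function(mean_macro_f, rule, iteration) {
  if (mean_macro_f >= rule$macro_f_threshold) return(TRUE)
  if (iteration >= rule$max_iterations) {
    warning(sprintf(
      "iteration cap (%d) reached with mean macro F %.3f below threshold %.2f",
      rule$max_iterations, mean_macro_f, rule$macro_f_threshold))
    return(TRUE)
  }
  FALSE
}

#' Initialize pipeline state
#'
#' @param condition Condition name.
#' @param preannotator Initial preannotation extractor, normally
#'   [rules_extractor()]; later iterations may replace it with the best
#'   trained extractor.
#' @return Object of class \code{pipeline_state}.
#' @export
pipeline_state <- function(condition, preannotator) {
  stopifnot(inherits(preannotator, "status_extractor"))
  structure(list(condition = condition, iteration = 0L,
                 sentences = NULL, labels = character(),
                 preannotator = preannotator, reports = list(),
                 stopped = FALSE),
            class = "pipeline_state")
}

#' @export
print.pipeline_state <- function(x, ...) {
  cat(sprintf("<pipeline_state> %s, iteration %d, %d annotated sentences%s\n",
              x$condition, x$iteration,
              if (is.null(x$sentences)) 0L else nrow(x$sentences),
              if (x$stopped) " [stopped]" else ""))
  invisible(x)
}

#' Run one pipeline iteration on a synthetic corpus
#'
#' Executes a full pass: sentence segmentation of the corpus documents,
#' preannotation with the current preannotator, reservation of the
#' unbiased control subset and preannotation filtering, simulated double
#' annotation of the newly qualified sentences with a kappa gate (a
#' failing gate triggers a term-driven revision sub-loop when a
#' [correction_plan()] is supplied, and halts otherwise), accumulation of
#' the annotated dataset, deduplicated stratified cross-validation of the
#' trained backend against the rule-based baseline on identical folds,
#' and preannotator upgrade when the trained extractor beats the rules.
#' Human (or here, simulated-human) labels are the only training labels;
#' preannotations are never used as gold.
#'
#' @param state A [pipeline_state()].
#' @param corpus A [generate_corpus()] gold corpus (its gold labels stand
#'   in for the human annotators via [simulate_annotators()]).
#' @param rules The condition's [ruleset()] (rule baseline for the C4
#'   comparison).
#' @param qualify_cfg A [qualify_config()].
#' @param rule The [stop_rule()].
#' @param disagreement_rate Simulated annotator-B flip rate.
#' @param correction Optional [correction_plan()] used when the kappa
#'   gate fails.
#' @param kappa_threshold Agreement gate threshold (default 0.8).
#' @param kappa_subset_fraction Fraction of the batch doubly annotated for
#'   the agreement estimate (default 0.1; at least 20 sentences).
#' @param k Cross-validation folds.
#' @param min_per_class Minimum class support retained for training.
#' @param seed Integer seed for this iteration.
#' @return The updated \code{pipeline_state}; per-iteration reports are
#'   appended under \code{reports}.
#' @export
run_iteration <- function(state, corpus, rules, qualify_cfg, rule,
                          disagreement_rate = 0, correction = NULL,
                          kappa_threshold = 0.8,
                          kappa_subset_fraction = 0.1, k = 3L,
                          min_per_class = 3L, seed = 1L) {
  stopifnot(inherits(state, "pipeline_state"), inherits(corpus, "gold_corpus"))
  condition <- state$condition
  iteration <- state$iteration + 1L
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  # P2: segmentation (documents -> sentences)
  sentences <- segment_corpus(corpus$documents)
  say("P2 segmentation: %d documents -> %d sentences (seed %d)",
      nrow(corpus$documents), nrow(sentences), seed)
  # D1: preannotation with the current preannotator
  pre <- predict(state$preannotator, sentences)
  say("D1 preannotation (%s backend): %d informative",
      state$preannotator$backend, sum(pre$label != "unknown"))
  # D2: control reservation + filtering
  sc <- split_control(sentences, qualify_cfg)
  filtered <- filter_by_preannotation(sc$pool, pre, qualify_cfg)
  qualified <- rbind(sc$control, filtered)
  say("D2 qualification: control %d + filtered %d of pool %d",
      nrow(sc$control), nrow(filtered), nrow(sc$pool))
  # only sentences not yet annotated enter this batch
  if (!is.null(state$sentences)) {
    qualified <- qualified[!(qualified$sent_id %in% state$sentences$sent_id),
                           , drop = FALSE]
  }
  say("M1 batch: %d new sentences", nrow(qualified))
  # M1: simulated double annotation of the batch
  ann <- simulate_annotators(corpus, condition,
                             disagreement_rate = disagreement_rate,
                             statuses = rules$statuses, seed = seed)
  batch_a <- ann$a[ann$a$sent_id %in% qualified$sent_id, , drop = FALSE]
  batch_b <- ann$b[ann$b$sent_id %in% qualified$sent_id, , drop = FALSE]
  # M2: kappa on the doubly-annotated subset
  n_sub <- max(min(nrow(batch_a), 20L),
               ceiling(kappa_subset_fraction * nrow(batch_a)))
  rng <- local_rng(seed + 7L)
  sub_ids <- batch_a$sent_id[rng$sample(nrow(batch_a), n_sub)]
  ka <- cohen_kappa(batch_a[batch_a$sent_id %in% sub_ids, , drop = FALSE],
                    batch_b[batch_b$sent_id %in% sub_ids, , drop = FALSE],
                    condition)
  say("M2 agreement: kappa %.3f on %d doubly-annotated sentences",
      ka$kappa, ka$n_items)
  revised <- FALSE
  if (!agreement_gate(ka, kappa_threshold)) {
    if (is.null(correction)) {
      stop(sprintf(
        paste("kappa %.3f below threshold %.2f and no correction plan",
              "supplied; analyze disagreements, update the guidelines and",
              "re-run with a correction_plan()"),
        ka$kappa, kappa_threshold), call. = FALSE)
    }
    # M3/M4: disagreement-driven revision; corrected labels are the gold
    # (annotator A) labels for the selected sentences
    revise_ids <- select_for_revision(qualified, correction)
    fix <- batch_a$sent_id %in% revise_ids
    corrected <- batch_a[fix, , drop = FALSE]
    corrected$annotator_id <- "annotB"
    batch_b <- apply_corrections(batch_b, corrected, correction)$records
    ka <- cohen_kappa(batch_a[batch_a$sent_id %in% sub_ids, , drop = FALSE],
                      batch_b[batch_b$sent_id %in% sub_ids, , drop = FALSE],
                      condition)
    revised <- TRUE
    say("M3/M4 revision: %d sentences corrected, kappa now %.3f",
        sum(fix), ka$kappa)
    if (!agreement_gate(ka, kappa_threshold)) {
      warning(sprintf(
        "kappa %.3f still below %.2f after revision; extend the ambiguous-term list",
        ka$kappa, kappa_threshold))
    }
  }
  # accumulate the annotated dataset (annotator A's labels are the gold)
  batch_sentences <- qualified
  batch_labels <- batch_a$label[match(qualified$sent_id, batch_a$sent_id)]
  all_sentences <- rbind(state$sentences, batch_sentences)
  all_labels <- c(state$labels, batch_labels)
  ds <- labeled_dataset(all_sentences, all_labels, condition = condition,
                        min_per_class = min_per_class)
  say("C1 dataset: %d unique sentences, classes retained: %s",
      nrow(ds$sentences), paste(ds$label_set, collapse = "/"))
  # C2/C3: cross-validate the trained backend; C4: compare with rules
  cv_linear <- cross_validate(ds, function(train_ds, fold) {
    train_linear(train_ds, seed = seed)
  }, k = k, seed = seed)
  cv_rules <- cross_validate(ds, function(train_ds, fold) {
    rules_extractor(rules)
  }, k = k, seed = seed)
  say("C3 validation: linear macro F %.3f (SD %.3f), rules %.3f (SD %.3f)",
      cv_linear$mean_macro_f, cv_linear$sd_macro_f,
      cv_rules$mean_macro_f, cv_rules$sd_macro_f)
  # preannotator upgrade gate: trained model replaces rules only if it
  # beats them on the same folds
  if (cv_linear$mean_macro_f > cv_rules$mean_macro_f) {
    state$preannotator <- train_linear(ds, seed = seed)
    say("C4: linear extractor becomes the next preannotator")
  } else {
    say("C4: rule-based preannotator retained")
  }
  us_labels <- gold_labels(corpus, condition)[
    corpus$sentences$sent_id %in% sc$control$sent_id]
  ps_labels <- batch_labels[batch_sentences$sent_id %in% filtered$sent_id]
  stop_now <- should_stop(cv_linear$mean_macro_f, rule, iteration)
  say("stop decision: %s (mean macro F %.3f, threshold %.2f)",
      if (stop_now) "stop" else "continue",
      cv_linear$mean_macro_f, rule$macro_f_threshold)
  state$iteration <- iteration
  state$sentences <- all_sentences
  state$labels <- all_labels
  state$stopped <- stop_now
  state$reports[[iteration]] <- list(
    iteration = iteration,
    batch_size = nrow(batch_sentences),
    cumulative_size = length(all_labels),
    kappa = ka, revised = revised,
    distribution = distribution_report(us_labels, ps_labels),
    cv = cv_linear, cv_rules = cv_rules,
    dataset = ds, log = log_lines)
  state
}

#' Check dataset bookkeeping totals
#'
#' Validates a per-iteration status-count table: within each (condition,
#' iteration) row the per-status counts must sum to the stated row total,
#' every condition must share the same per-iteration total, and the grand
#' total must equal the sum of the iteration totals.
#'
#' @param counts Data frame with columns \code{condition},
#'   \code{iteration}, \code{present}, \code{absent}, \code{former},
#'   \code{unknown}, \code{total}.
#' @return List with \code{iteration_totals} (named) and
#'   \code{grand_total}; errors on any inconsistency.
#' @export
check_iteration_totals <- function(counts) {
  status_cols <- c("present", "absent", "former", "unknown")
  row_sums <- rowSums(as.matrix(counts[, status_cols]), na.rm = TRUE)
  bad <- which(row_sums != counts$total)
  if (length(bad) > 0L) {
    stop(sprintf("row %d (%s, iteration %d): statuses sum to %d, total says %d",
                 bad[[1]], counts$condition[[bad[[1]]]],
                 counts$iteration[[bad[[1]]]], row_sums[[bad[[1]]]],
                 counts$total[[bad[[1]]]]), call. = FALSE)
  }
  iters <- sort(unique(counts$iteration))
  iteration_totals <- vapply(iters, function(it) {
    tot <- unique(counts$total[counts$iteration == it])
    if (length(tot) != 1L) {
      stop(sprintf("iteration %d: conditions disagree on the batch total", it),
           call. = FALSE)
    }
    tot
  }, numeric(1))
  names(iteration_totals) <- as.character(iters)
  list(iteration_totals = iteration_totals,
       grand_total = sum(iteration_totals))
}

#' Bundled case-study iteration counts
#'
#' The per-iteration, per-condition status counts of the institutional
#' case study shipped with the package (991 sentences annotated in the
#' first iteration, 11,128 in the second).
#'
#' @return Data frame in the [check_iteration_totals()] layout.
#' @export
iteration_status_counts <- function() {
  utils::read.csv(system.file("extdata", "iteration_counts.csv",
                              package = "medstatus", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Render pipeline reports
#'
#' Materializes the per-iteration reports of a pipeline state as
#' deterministic CSV files plus a Markdown summary: cumulative status
#' counts, control-vs-filtered distribution, best-extractor metrics,
#' per-iteration cross-validation, document-type breakdown and the
#' extractor comparison.
#'
#' @param state A [pipeline_state()] after at least one [run_iteration()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
render_reports <- function(state, out_dir) {
  stopifnot(length(state$reports) > 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  # status counts per iteration (cumulative batches)
  counts <- do.call(rbind, lapply(state$reports, function(r) {
    labs <- r$dataset$labels
    data.frame(condition = state$condition, iteration = r$iteration,
               present = sum(labs == "present"),
               absent = sum(labs == "absent"),
               former = sum(labs == "former"),
               unknown = sum(labs == "unknown"),
               total = length(labs), stringsAsFactors = FALSE)
  }))
  put(counts, "status_counts.csv")
  last <- state$reports[[length(state$reports)]]
  # US / PS distribution of the last iteration
  dist <- last$distribution
  dd <- dist$proportions
  dd$us_prevalence_pct <- dist$prevalence[["us"]]
  dd$ps_prevalence_pct <- dist$prevalence[["ps"]]
  put(dd, "usps_distribution.csv")
  # best-extractor per-status metrics (best CV fold of the last iteration)
  best <- last$cv$reports[[which.max(last$cv$macro_f)]]
  put(best$per_class, "best_metrics.csv")
  put(data.frame(
    macro_f = best$macro_f, balanced_accuracy = best$balanced_accuracy,
    stringsAsFactors = FALSE), "best_aggregates.csv")
  # per-iteration cross-validation
  cv <- do.call(rbind, lapply(state$reports, function(r) {
    data.frame(iteration = r$iteration, n = r$cumulative_size,
               mean_macro_f = r$cv$mean_macro_f,
               sd_macro_f = r$cv$sd_macro_f,
               kappa = r$kappa$kappa, stringsAsFactors = FALSE)
  }))
  put(cv, "cv_by_iteration.csv")
  # doc-type breakdown on the last iteration's folds (pooled validation)
  ds <- last$dataset
  keep <- ds$labels %in% ds$label_set
  sents <- ds$sentences[keep, , drop = FALSE]
  pred <- predict(state$preannotator, sents)
  put(breakdown_by_doctype(ds$labels[keep], pred$label, sents$doc_type),
      "doctype_breakdown.csv")
  # extractor comparison (trained vs rules, identical folds)
  put(data.frame(
    backend = c("linear", "rules"),
    mean_macro_f = c(last$cv$mean_macro_f, last$cv_rules$mean_macro_f),
    sd_macro_f = c(last$cv$sd_macro_f, last$cv_rules$sd_macro_f),
    stringsAsFactors = FALSE), "extractor_comparison.csv")
  # markdown summary
  md <- c(sprintf("# Pipeline report: %s", state$condition), "",
          sprintf("Iterations run: %d; stopped: %s", state$iteration,
                  state$stopped), "",
          unlist(lapply(state$reports, function(r) {
            c(sprintf("## Iteration %d", r$iteration), r$log, "")
          })))
  p <- file.path(out_dir, "report.md")
  writeLines(md, p)
  paths <- c(paths, p)
  invisible(paths)
}
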