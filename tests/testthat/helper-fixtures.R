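# Shared fixtures and independent brute-force oracles.

# Build a minimal sentence table from bare texts.
tiny_sentences <- function(texts, doc_type = "Other",
                           patient_id = "pat1") {
  data.frame(sent_id = sprintf("s%d", seq_along(texts)),
             doc_id = rep_len("doc1", length(texts)),
             patient_id = rep_len(patient_id, length(texts)),
             doc_type = rep_len(doc_type, length(texts)),
             text = texts,
             span_start = seq_along(texts) - 1L,
             span_end = seq_along(texts),
             stringsAsFactors = FALSE)
}

# Independent per-class counting oracle for the metric suite: explicit
# loops, no shared code with compute_metrics.
oracle_metrics <- function(gold, predicted, statuses) {
  out <- list()
  for (cl in statuses) {
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_along(gold)) {
      if (gold[i] == cl && predicted[i] == cl) tp <- tp + 1
      else if (gold[i] != cl && predicted[i] == cl) fp <- fp + 1
      else if (gold[i] == cl && predicted[i] != cl) fn <- fn + 1
      else tn <- tn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec)) {
      if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    } else NA_real_
    out[[cl]] <- c(precision = prec, recall = rec, specificity = spec,
                   f1 = f1, ba_term = (rec + spec) / 2)
  }
  f1s <- vapply(out, function(v) v[["f1"]], numeric(1))
  bas <- vapply(out, function(v) v[["ba_term"]], numeric(1))
  list(per_class = out,
       macro_f = mean(f1s, na.rm = TRUE),
       balanced_accuracy = mean(bas, na.rm = TRUE))
}

# Independent Cohen's kappa oracle: explicit pair counting.
oracle_kappa <- function(a, b) {
  n <- length(a)
  po <- sum(a == b) / n
  labs <- union(a, b)
  pe <- 0
  for (l in labs) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# Dense informative regime (a post-qualification annotation batch) used
# by the training and iteration tests.
smoking_dense_conditions <- function(prevalence = 0.13) {
  list(smoking = list(prevalence = prevalence,
                      status_probs = c(present = 0.507, absent = 0.166,
                                       former = 0.327),
                      family_rate = 0.005))
}

diabetes_dense_conditions <- function(prevalence = 0.30) {
  list(diabetes = list(prevalence = prevalence,
                       status_probs = c(present = 0.6, absent = 0.4),
                       family_rate = 0.02))
}

smoking_corpus <- function(n_documents, seed, cue_noise = 0.10,
                           prevalence = 0.13) {
  generate_corpus(synth_config(
    conditions = smoking_dense_conditions(prevalence),
    cue_noise = cue_noise, duplicate_rate = 0.05,
    n_documents = n_documents,
    n_patients = max(10L, n_documents %/% 5L),
    sentences_per_doc = 8, seed = seed))
}
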