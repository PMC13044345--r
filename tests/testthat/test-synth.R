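test_that("generator limit cases, determinism and infeasible configs", {
  zero <- synth_config(
    conditions = list(smoking = list(prevalence = 0,
                                     status_probs = c(present = 1),
                                     family_rate = 0)),
    n_documents = 20, n_patients = 5, seed = 1)
  gc0 <- generate_corpus(zero)
  expect_true(all(gold_labels(gc0, "smoking") == "unknown"))

  cfg <- synth_config(conditions = smoking_dense_conditions(),
                      n_documents = 30, n_patients = 8, seed = 9)
  expect_identical(generate_corpus(cfg)$sentences,
                   generate_corpus(cfg)$sentences)

  expect_error(synth_config(
    conditions = list(a = list(prevalence = 0.7, status_probs = c(present = 1),
                               family_rate = 0),
                      b = list(prevalence = 0.5, status_probs = c(present = 1),
                               family_rate = 0))), "sum")
  expect_error(synth_config(
    conditions = list(a = list(prevalence = 0.1,
                               status_probs = c(present = 0.5,
                                                absent = 0.4)))),
    "status_probs")
})

test_that("realized informative prevalence stays within binomial tolerance", {
  p <- 0.0075
  cfg <- synth_config(
    conditions = list(smoking = list(prevalence = p,
                                     status_probs = c(present = 0.507,
                                                      absent = 0.166,
                                                      former = 0.327),
                                     family_rate = 0)),
    cue_noise = 0, duplicate_rate = 0, n_documents = 750,
    n_patients = 150, sentences_per_doc = 8, seed = 13)
  gc <- generate_corpus(cfg)
  n <- nrow(gc$sentences)
  realized <- mean(gold_labels(gc, "smoking") != "unknown")
  tol <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(realized - p), tol)
})

test_that("bookkeeping counts equal realized gold counts exactly", {
  corpus <- smoking_corpus(40, seed = 33)
  bk <- corpus$bookkeeping
  gold <- gold_labels(corpus, "smoking")
  for (st in status_labels()) {
    expect_equal(bk$count[bk$condition == "smoking" & bk$status == st],
                 sum(gold == st))
  }
  expect_equal(sum(bk$count[bk$condition == "smoking"]),
               nrow(corpus$sentences))
})

test_that("generated documents segment back into the planted sentences", {
  corpus <- smoking_corpus(25, seed = 44)
  seg <- segment_corpus(corpus$documents)
  expect_identical(seg$sent_id, corpus$sentences$sent_id)
  expect_identical(seg$text, corpus$sentences$text)
  expect_identical(seg$span_start, corpus$sentences$span_start)
})

test_that("duplicate injection exercises deduplication and patient grouping", {
  cfg <- synth_config(conditions = smoking_dense_conditions(),
                      duplicate_rate = 0.3, n_documents = 60,
                      n_patients = 10, seed = 55)
  corpus <- generate_corpus(cfg)
  dd <- deduplicate(corpus$sentences)
  expect_gt(dd$removed_count, 0)
  expect_gt(length(unique(corpus$documents$patient_id)), 1)
  # duplicated text keeps its gold label (same sentence, same status)
  keys <- normalize_key(corpus$sentences$text)
  gold <- gold_labels(corpus, "smoking")
  for (k in unique(keys[duplicated(keys)])) {
    expect_length(unique(gold[keys == k]), 1)
  }
})

test_that("clean cues are exactly rule-recoverable; noise degrades the rules", {
  clean <- smoking_corpus(50, seed = 66, cue_noise = 0)
  rules <- rules_extractor(default_ruleset("smoking"))
  gold_c <- gold_labels(clean, "smoking")
  pred_c <- predict(rules, clean$sentences)$label
  m_c <- compute_metrics(gold_c, pred_c)
  expect_equal(m_c$macro_f, 1)

  noisy <- smoking_corpus(50, seed = 66, cue_noise = 0.3)
  gold_n <- gold_labels(noisy, "smoking")
  pred_n <- predict(rules, noisy$sentences)$label
  expect_lt(compute_metrics(gold_n, pred_n)$macro_f, 1)
})

test_that("sparse statuses are excluded rather than failing the evaluation", {
  cfg <- synth_config(
    conditions = list(copd = list(prevalence = 0.15,
                                  status_probs = c(present = 0.995,
                                                   absent = 0.005),
                                  family_rate = 0)),
    n_documents = 25, n_patients = 8, sentences_per_doc = 8, seed = 77)
  corpus <- generate_corpus(cfg)
  gold <- gold_labels(corpus, "copd")
  expect_lt(sum(gold == "absent"), 3)  # below min_per_class
  ds <- labeled_dataset(corpus$sentences, gold, condition = "copd")
  expect_false("absent" %in% ds$label_set)
  cv <- cross_validate(ds, function(train_ds, fold) {
    rules_extractor(default_ruleset("copd"))
  }, k = 3, seed = 2)
  expect_length(cv$macro_f, 3L)
})

test_that("simulated annotators reproduce the requested disagreement and timing", {
  corpus <- smoking_corpus(40, seed = 88)
  ann0 <- simulate_annotators(corpus, "smoking", disagreement_rate = 0,
                              seed = 4)
  expect_equal(cohen_kappa(ann0$a, ann0$b, "smoking")$kappa, 1)

  # two-status flip model: Po converges to 1 - rate
  cfg2 <- synth_config(
    conditions = list(smoking = list(prevalence = 0.3,
                                     status_probs = c(present = 1),
                                     family_rate = 0)),
    n_documents = 250, n_patients = 50, sentences_per_doc = 8, seed = 5)
  big <- generate_corpus(cfg2)
  ann <- simulate_annotators(big, "smoking", disagreement_rate = 0.2,
                             statuses = c("present", "unknown"), seed = 6)
  res <- cohen_kappa(ann$a, ann$b, "smoking")
  n <- res$n_items
  expect_lt(abs(res$po - 0.8), 3 * sqrt(0.2 * 0.8 / n))

  # duration model: unknown-labeled sentences are dismissed faster
  ann5 <- simulate_annotators(big, "smoking", disagreement_rate = 0,
                              duration_means = c(unknown = 1.5,
                                                 informative = 3.0),
                              seed = 7)
  ts <- annotation_time_summary(ann5$a)
  expect_lt(abs(ts$mean_informative - 3.0) / 3.0, 0.05)
  gold <- gold_labels(big, "smoking")
  expected_all <- mean(ifelse(gold == "unknown", 1.5, 3.0))
  expect_lt(abs(ts$mean_all - expected_all) / expected_all, 0.05)
})
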