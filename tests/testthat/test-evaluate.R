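test_that("stratified folds balance classes and forbid duplicate keys", {
  labs <- rep(c("a", "b", "c"), each = 3)
  keys <- paste0("k", 1:9)
  plan <- make_folds(labs, keys, k = 3, seed = 2)
  for (fold in 1:3) {
    expect_equal(sort(labs[plan$assignment == fold]), c("a", "b", "c"))
  }

  expect_error(make_folds(c("a", "a", "b", "b", "b"),
                          c("k1", "k1", "k2", "k3", "k4"), k = 2, seed = 1),
               "duplicated")
  expect_error(make_folds(c("a", "a", "a", "b"), paste0("k", 1:4),
                          k = 3, seed = 1), "b")

  # 100 samples at proportions (0.7, 0.2, 0.1): per-fold deviation <= 1
  set.seed(61)
  labs2 <- sample(c("maj", "mid", "min"), 100, replace = TRUE,
                  prob = c(.7, .2, .1))
  labs2[1:9] <- rep(c("maj", "mid", "min"), 3)
  keys2 <- paste0("k", 1:100)
  plan2 <- make_folds(labs2, keys2, k = 3, seed = 4)
  for (cl in unique(labs2)) {
    per_fold <- table(factor(plan2$assignment[labs2 == cl], levels = 1:3))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  sizes <- table(factor(plan2$assignment, levels = 1:3))
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(plan2$assignment,
                   make_folds(labs2, keys2, k = 3, seed = 4)$assignment)
  expect_false(identical(plan2$assignment,
                         make_folds(labs2, keys2, k = 3, seed = 5)$assignment))
})

test_that("the metric suite matches hand-built confusion tables", {
  perfect <- compute_metrics(c("p", "a", "u"), c("p", "a", "u"),
                             evaluated_statuses = c("p", "a", "u"))
  expect_true(all(perfect$per_class$f1 == 1))
  expect_equal(perfect$macro_f, 1)
  expect_equal(perfect$balanced_accuracy, 1)

  gold <- c("present", "present", "absent", "unknown")
  pred <- c("present", "absent", "absent", "unknown")
  m <- compute_metrics(gold, pred)
  pc <- m$per_class
  expect_equal(pc$f1[pc$status == "present"], 2 / 3)
  expect_equal(pc$f1[pc$status == "absent"], 2 / 3)
  expect_equal(pc$f1[pc$status == "unknown"], 1)
  expect_equal(m$macro_f, (2 / 3 + 2 / 3 + 1) / 3)
  expect_equal(m$balanced_accuracy, (3 / 4 + 5 / 6 + 1) / 3)

  expect_error(compute_metrics(c("a", "b"), "a"), "same sentences")
})

test_that("the metric suite agrees with the brute-force counting oracle", {
  set.seed(71)
  statuses <- c("present", "absent", "former", "unknown")
  for (i in 1:50) {
    n <- sample(4:60, 1)
    gold <- sample(statuses, n, replace = TRUE)
    pred <- sample(statuses, n, replace = TRUE)
    m <- compute_metrics(gold, pred, evaluated_statuses = statuses)
    o <- oracle_metrics(gold, pred, statuses)
    expect_equal(m$macro_f, o$macro_f, tolerance = 1e-12)
    expect_equal(m$balanced_accuracy, o$balanced_accuracy,
                 tolerance = 1e-12)
    for (cl in statuses) {
      expect_equal(m$per_class$f1[m$per_class$status == cl],
                   unname(o$per_class[[cl]][["f1"]]), tolerance = 1e-12)
    }
  }
})

test_that("aggregates reduce correctly and ignore unsupported statuses", {
  gold <- c("present", "present", "unknown", "unknown")
  pred <- c("present", "unknown", "unknown", "unknown")
  one <- compute_metrics(gold, pred, evaluated_statuses = "present")
  pc <- one$per_class
  expect_equal(one$macro_f, pc$f1[[1]])
  expect_equal(one$balanced_accuracy,
               (pc$recall[[1]] + pc$specificity[[1]]) / 2)

  # adding a status with zero gold-and-predicted support leaves the
  # remaining per-status metrics unchanged
  both <- compute_metrics(gold, pred,
                          evaluated_statuses = c("present", "former"))
  expect_equal(both$per_class[both$per_class$status == "present", ],
               one$per_class, ignore_attr = TRUE)
  expect_true(is.na(both$per_class$f1[both$per_class$status == "former"]))
  expect_true(both$has_undefined)
  expect_equal(both$macro_f, one$macro_f)
})

test_that("cross-validation reports per-fold metrics with mean and SD", {
  corpus <- smoking_corpus(40, seed = 17, cue_noise = 0)
  ds <- labeled_dataset(corpus$sentences, gold_labels(corpus, "smoking"),
                        condition = "smoking")
  cv <- cross_validate(ds, function(train_ds, fold) {
    rules_extractor(default_ruleset("smoking"))
  }, k = 3, seed = 6)
  expect_length(cv$macro_f, 3L)
  expect_equal(cv$mean_macro_f, 1)       # clean cues are rule-recoverable
  expect_equal(cv$sd_macro_f, 0)
  expect_equal(cv$mean_macro_f, mean(cv$macro_f))
  expect_equal(cv$sd_macro_f, stats::sd(cv$macro_f))
})

test_that("document-type breakdown marks unsupported cells not-available", {
  gold <- c("present", "absent", "unknown", "present", "unknown")
  pred <- c("present", "absent", "unknown", "absent", "unknown")
  types <- c("Medical reports", "Medical reports", "Medical reports",
             "Imaging reports", "Imaging reports")
  bd <- breakdown_by_doctype(gold, pred, types)
  # absent has no gold or predicted sample in Medical reports? it has one
  img_absent <- bd$f1[bd$doc_type == "Imaging reports" &
                      bd$status == "absent"]
  expect_equal(img_absent, 0)  # predicted but wrong: defined, not NA
  med <- bd[bd$doc_type == "Medical reports", ]
  expect_equal(med$f1[med$status == "present"], 1)

  # a type-status cell with zero support on both sides is NA
  bd2 <- breakdown_by_doctype(c("present", "unknown"),
                              c("present", "unknown"),
                              c("t1", "t2"))
  expect_true(is.na(bd2$f1[bd2$doc_type == "t2" & bd2$status == "present"]))

  # slice oracle: each populated cell equals a recomputation on the slice
  corpus <- smoking_corpus(30, seed = 23, cue_noise = 0)
  lab <- gold_labels(corpus, "smoking")
  pred2 <- predict(rules_extractor(default_ruleset("smoking")),
                   corpus$sentences)$label
  bd3 <- breakdown_by_doctype(lab, pred2, corpus$sentences$doc_type)
  for (dt in unique(corpus$sentences$doc_type)) {
    sel <- corpus$sentences$doc_type == dt
    m <- compute_metrics(lab[sel], pred2[sel],
                         evaluated_statuses = sort(unique(c(lab, pred2))))
    for (cl in m$per_class$status) {
      cell <- bd3$f1[bd3$doc_type == dt & bd3$status == cl]
      ref <- m$per_class$f1[m$per_class$status == cl]
      if (is.na(ref)) expect_true(is.na(cell)) else expect_equal(cell, ref)
    }
  }
})

test_that("patient-overlap audit counts leaked validation sentences", {
  labs <- rep(c("a", "b"), each = 6)
  keys <- paste0("k", 1:12)
  plan <- make_folds(labs, keys, k = 3, seed = 3)

  # one patient everywhere: full overlap
  expect_equal(audit_patient_overlap(plan, rep("p1", 12)), rep(1, 3))

  # patients partitioned exactly by fold: zero overlap
  by_fold <- paste0("p", plan$assignment)
  expect_equal(audit_patient_overlap(plan, by_fold), rep(0, 3))

  # random assignment versus a hand-counted oracle
  set.seed(81)
  pats <- sample(paste0("p", 1:4), 12, replace = TRUE)
  got <- audit_patient_overlap(plan, pats)
  for (fold in 1:3) {
    val <- plan$assignment == fold
    manual <- mean(pats[val] %in% unique(pats[!val]))
    expect_equal(got[[fold]], manual)
  }
})

test_that("paired fold-wise comparison is a k-1 df paired t-test", {
  a <- c(0.91, 0.93, 0.95)
  b <- c(0.88, 0.90, 0.91)
  ht <- compare_extractors(a, b)
  expect_equal(unname(ht$parameter), 2)
  ref <- stats::t.test(a - b)
  expect_equal(unname(ht$statistic), unname(ref$statistic))
})
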