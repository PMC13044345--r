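kappa_fixture <- function() {
  # 10 items: 4 agree-present, 4 agree-unknown, 2 crossed
  ids <- paste0("s", 1:10)
  a <- annotation_records(ids, "A", "smoking",
                          c(rep("present", 5), rep("unknown", 5)),
                          duration_seconds = 1)
  b <- annotation_records(ids, "B", "smoking",
                          c(rep("present", 4), "unknown",
                            "present", rep("unknown", 4)),
                          duration_seconds = 1)
  list(a = a, b = b)
}

test_that("Cohen's kappa matches the hand-enumerated contingency", {
  fx <- kappa_fixture()
  res <- cohen_kappa(fx$a, fx$b, "smoking")
  expect_equal(res$po, 0.8)
  expect_equal(res$pe, 0.5)
  expect_equal(res$kappa, 0.6)
  expect_equal(res$n_items, 10L)
  expect_equal(sum(res$contingency), 10)
  expect_equal(res$contingency["present", "present"], 4)
  expect_equal(res$contingency["unknown", "unknown"], 4)

  # identical annotations
  same <- cohen_kappa(fx$a, fx$a, "smoking")
  expect_equal(same$kappa, 1)

  # agreement with the independent pair-counting oracle on random fixtures
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    la <- sample(c("present", "absent", "unknown"), n, replace = TRUE)
    lb <- sample(c("present", "absent", "unknown"), n, replace = TRUE)
    ids <- paste0("x", seq_len(n))
    ra <- annotation_records(ids, "A", "c", la, 1)
    rb <- annotation_records(ids, "B", "c", lb, 1)
    expect_equal(cohen_kappa(ra, rb, "c")$kappa, oracle_kappa(la, lb))
  }
})

test_that("kappa of independent annotators tends to zero and is relabeling-invariant", {
  set.seed(21)
  n <- 4000
  la <- sample(c("present", "unknown"), n, replace = TRUE)
  lb <- sample(c("present", "unknown"), n, replace = TRUE)
  ids <- paste0("x", seq_len(n))
  ra <- annotation_records(ids, "A", "c", la, 1)
  rb <- annotation_records(ids, "B", "c", lb, 1)
  expect_lt(abs(cohen_kappa(ra, rb, "c")$kappa), 0.08)  # ~3 binomial SD

  # permuting label names leaves kappa unchanged
  swap <- function(x) ifelse(x == "present", "unknown", "present")
  ra2 <- annotation_records(ids, "A", "c", swap(la), 1)
  rb2 <- annotation_records(ids, "B", "c", swap(lb), 1)
  expect_equal(cohen_kappa(ra2, rb2, "c")$kappa,
               cohen_kappa(ra, rb, "c")$kappa)
})

test_that("degenerate agreement uses the documented Pe = 1 convention", {
  ids <- paste0("s", 1:5)
  all_p <- annotation_records(ids, "A", "c", rep("present", 5), 1)
  all_p_b <- annotation_records(ids, "B", "c", rep("present", 5), 1)
  expect_equal(cohen_kappa(all_p, all_p_b, "c")$kappa, 1)
  mixed_b <- annotation_records(ids, "B", "c",
                                c(rep("present", 4), "absent"), 1)
  res <- cohen_kappa(all_p, mixed_b, "c")
  expect_lt(res$pe, 1)
  expect_true(res$kappa <= 1)
})

test_that("mismatched or empty annotation sets are rejected with the difference listed", {
  fx <- kappa_fixture()
  expect_error(cohen_kappa(fx$a, fx$b[-1, ], "smoking"), "s1")
  expect_error(cohen_kappa(fx$a, fx$b, "diabetes"), "no overlapping")
})

test_that("the agreement gate is boundary-inclusive", {
  res <- list(kappa = 0.57)
  class(res) <- "agreement_result"
  expect_false(agreement_gate(res, 0.8))
  res$kappa <- 0.8
  expect_true(agreement_gate(res, 0.8))
  res$kappa <- 1.0
  expect_true(agreement_gate(res, 0.99))
  expect_error(agreement_gate(res, 0), "threshold")
})

test_that("disagreement extraction returns exactly the crossed items in order", {
  fx <- kappa_fixture()
  d <- find_disagreements(fx$a, fx$b, "smoking")
  expect_equal(d$sent_id, c("s5", "s6"))
  expect_equal(d$label_a, c("present", "unknown"))
  expect_equal(d$label_b, c("unknown", "present"))

  expect_equal(nrow(find_disagreements(fx$a, fx$a, "smoking")), 0L)

  # count identity: disagreements = n * (1 - Po)
  res <- cohen_kappa(fx$a, fx$b, "smoking")
  expect_equal(nrow(d), round(res$n_items * (1 - res$po)))
})

test_that("term-driven revision selection uses normalized substring containment", {
  s <- tiny_sentences(c(
    "Fonction systolique normale",
    "Décompensation avec une fraction d'éjection ventriculaire conservée",
    "Pas d'insuffisance cardiaque",
    "Suivi cardiologique standard",
    "Échographie programmée"))
  plan <- correction_plan("fraction d'éjection")
  expect_equal(select_for_revision(s, plan), "s2")
  expect_length(select_for_revision(s, correction_plan("introuvable")), 0L)
  # overlapping terms select the sentence once
  multi <- correction_plan(c("FRACTION", "éjection"))
  expect_equal(select_for_revision(s, multi), "s2")
  expect_error(correction_plan(character()), "non-empty")
})

test_that("annotation-time accounting separates informative sentences", {
  r <- annotation_records(paste0("s", 1:3), "A", "c",
                          c("unknown", "unknown", "present"),
                          duration_seconds = c(1, 1, 4))
  ts <- annotation_time_summary(r)
  expect_equal(ts$mean_all, 2)
  expect_equal(ts$mean_informative, 4)

  all_unknown <- annotation_records(paste0("s", 1:2), "A", "c",
                                    c("unknown", "unknown"), c(1, 2))
  expect_true(is.na(annotation_time_summary(all_unknown)$mean_informative))

  # lognormal durations: sample means recover the stated means
  set.seed(31)
  n <- 1000
  labs <- sample(c("unknown", "present"), n, replace = TRUE, prob = c(.7, .3))
  sdlog <- 0.5
  mu <- ifelse(labs == "unknown", log(1.5), log(3.0)) - sdlog^2 / 2
  recs <- annotation_records(paste0("s", seq_len(n)), "A", "c", labs,
                             stats::rlnorm(n, mu, sdlog))
  ts2 <- annotation_time_summary(recs)
  expect_lt(abs(ts2$mean_informative - 3.0) / 3.0, 0.05)
  expected_all <- mean(ifelse(labs == "unknown", 1.5, 3.0))
  expect_lt(abs(ts2$mean_all - expected_all) / expected_all, 0.05)
})

test_that("corrections replace records and archive the originals", {
  fx <- kappa_fixture()
  plan <- correction_plan("ambigu", guideline_version = "v2")
  corrected <- annotation_records(c("s5", "s6"), "B", "smoking",
                                  c("present", "unknown"), 1)
  out <- apply_corrections(fx$b, corrected, plan)
  expect_equal(nrow(out$records), 10L)
  expect_equal(nrow(out$archived), 2L)
  expect_equal(unique(out$archived$guideline_version), "v2")
  merged <- out$records[match(fx$a$sent_id, out$records$sent_id), ]
  expect_equal(merged$label, fx$a$label)  # B now agrees everywhere
})
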