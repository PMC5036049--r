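test_that("threshold metrics match a hand confusion matrix", {
  scores <- c(0.9, 0.8, 0.3, 0.6, 0.1, 0.55)
  labels <- c(1, 0, 1, 1, 0, 0)
  m <- threshold_metrics(scores, labels, threshold = 0.5)
  # by hand: tp = {0.9, 0.6}, fp = {0.8, 0.55}, fn = {0.3}, tn = {0.1}
  expect_identical(c(m$tp, m$fp, m$fn, m$tn), c(2L, 2L, 1L, 1L))
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 2 / 4)
  expect_equal(m$f1, 2 * (0.5 * 2 / 3) / (0.5 + 2 / 3))
  expect_equal(m$acc, 3 / 6)
  expect_equal(m$mcc, (2 * 1 - 2 * 1) / sqrt(4 * 3 * 3 * 2))
  expect_error(threshold_metrics(numeric(0), numeric(0)), "empty")
  expect_error(threshold_metrics(1, c(1, 0)), "length mismatch")
})

test_that("degenerate confusion matrices give zero MCC and precision", {
  m <- threshold_metrics(c(0.1, 0.2), c(1, 1), threshold = 0.5)
  expect_equal(m$mcc, 0)
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
})

test_that("rank-based AUC matches pair enumeration including ties", {
  set.seed(12)
  for (trial in 1:8) {
    n <- sample(10:40, 1)
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[n] <- 0
    scores <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
  }
  expect_equal(auc_score(c(1, 2, 3), c(0, 0, 1)), 1)
  expect_equal(auc_score(c(5, 5), c(0, 1)), 0.5)
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")
})

test_that("cross-validation partitions structures and pools every residue", {
  bm <- small_benchmark(n = 6, seed = 19)
  ev <- cross_validate(bm, k = 2, seed = 3)
  expect_s3_class(ev, "cr_evaluation")
  total <- sum(vapply(bm$structures, n_residues, integer(1)))
  expect_identical(nrow(ev$scores), total)
  # each structure lands in exactly one fold
  byf <- unique(ev$scores[, c("structure", "fold")])
  expect_identical(nrow(byf), 6L)
  expect_setequal(unique(ev$scores$fold), 1:2)
  expect_identical(sort(names(ev$pooled_auc)),
                   sort(c("fscore_str", "tscore_str", "fscore_seq",
                          "tscore_seq", "strhunter", "seqhunter", "crhunter")))
  expect_true(all(ev$pooled_auc >= 0 & ev$pooled_auc <= 1))
  # labels match the annotations
  ids <- vapply(bm$structures, function(s) s$id, character(1))
  for (q in seq_along(ids)) {
    sub <- ev$scores[ev$scores$structure == ids[q], ]
    expect_identical(which(sub$label == 1L),
                     as.integer(bm$annotations[[q]]$catalytic_indices))
  }
  expect_error(cross_validate(bm, k = 1), "k must be")
  expect_error(cross_validate(bm, k = 10), "fewer structures")
})

test_that("cross-validation is reproducible for a fixed seed", {
  bm <- small_benchmark(n = 6, seed = 23)
  ev1 <- cross_validate(bm, k = 2, seed = 5)
  ev2 <- cross_validate(bm, k = 2, seed = 5)
  expect_identical(ev1$scores, ev2$scores)
  expect_identical(ev1$pooled_auc, ev2$pooled_auc)
})

test_that("evaluation reports serialize to JSON", {
  bm <- small_benchmark(n = 6, seed = 29)
  ev <- cross_validate(bm, k = 2, seed = 1)
  path <- tempfile(fileext = ".json")
  write_evaluation(ev, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$pooled_auc$crhunter, unname(ev$pooled_auc["crhunter"]))
  expect_equal(rep$k, 2)
  expect_equal(rep$n_residues, nrow(ev$scores))
})
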