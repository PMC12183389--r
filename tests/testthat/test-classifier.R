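test_that("stratified split preserves proportions and is seeded", {
  labels <- factor(rep(c("Normal", "OtherSubtype", "TNBC_no_recur", "TNBC_recur"),
                       c(30, 57, 26, 17)))
  ids <- sprintf("S%03d", 1:130)
  sp <- stratified_split(labels, 0.7, seed = 3, ids = ids)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  expect_lte(abs(length(sp$train_ids) - 91), 2)
  for (cl in levels(labels)) {
    in_cl <- ids[labels == cl]
    n_tr <- sum(sp$train_ids %in% in_cl)
    expect_lte(abs(n_tr - 0.7 * length(in_cl)), 1)
    expect_gt(n_tr, 0)
    expect_gt(sum(sp$test_ids %in% in_cl), 0)
  }
  sp2 <- stratified_split(labels, 0.7, seed = 3, ids = ids)
  expect_identical(sp, sp2)

  expect_error(stratified_split(labels, 1.0), "strictly between")
  expect_error(stratified_split(c("a", "a", "b"), 0.5), "single sample")
  expect_silent(stratified_split(c("a", "a", "b"), 0.5, stratified = FALSE))
})

test_that("classification report matches hand counts and a concordance oracle", {
  truth <- c("A", "A", "A", "A", "B", "B", "B", "B", "C", "C", "C", "C")
  pred <- c("A", "A", "B", "C", "B", "B", "B", "A", "C", "C", "A", "C")
  set.seed(2)
  scores <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("A", "B", "C")))
  rep <- classification_report(truth, pred, scores, classes = c("A", "B", "C"))
  expect_equal(as.numeric(diag(rep$confusion)), c(2, 3, 3))
  expect_equal(rep$accuracy, 8 / 12)
  expect_equal(rep$metrics$tpr, c(2 / 4, 3 / 4, 3 / 4))
  expect_equal(rep$metrics$tpr + rep$metrics$fnr, rep(1, 3))
  expect_equal(as.numeric(rowSums(rep$confusion)),
               as.numeric(table(factor(truth, levels = c("A", "B", "C")))))
  # one-vs-rest AUC against an exhaustive pairwise concordance count
  for (i in 1:3) {
    cl <- c("A", "B", "C")[i]
    pos <- scores[truth == cl, i]
    neg <- scores[truth != cl, i]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(rep$metrics$auc[i], brute, tolerance = 1e-12)
  }
})

test_that("report metrics are invariant to class relabelling and catch bad labels", {
  truth <- c("A", "B", "A", "B", "A")
  pred <- c("A", "B", "B", "B", "A")
  r1 <- classification_report(truth, pred, classes = c("A", "B"))
  swap <- c(A = "Z", B = "Y")
  r2 <- classification_report(unname(swap[truth]), unname(swap[pred]),
                              classes = c("Z", "Y"))
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(sort(r1$metrics$tpr), sort(r2$metrics$tpr))

  # perfect and degenerate predictors
  perf <- classification_report(truth, truth, classes = c("A", "B"))
  expect_equal(perf$accuracy, 1)
  allb <- classification_report(truth, rep("B", 5), classes = c("A", "B"))
  expect_equal(allb$metrics$tpr, c(0, 1))
  expect_error(classification_report(truth, c(pred[-5], "Q"),
                                     classes = c("A", "B")), "Q")
})

test_that("the hybrid classifier learns a small planted cohort end to end", {
  ds <- simulate_cohort(small_sim_config(seed = 21, n_proteins = 30))
  x <- impute_median(ds$intensity)
  hy <- suppressMessages(train_hybrid(
    x, ds$annotations$class, marker_subset = c("ECM1", "MBL2", "BTD", "RAB5C"),
    cnn = list(epochs = 80), seed = 2))
  expect_identical(hy$extractor, "dense")
  # strong planted effects: far better than the majority rate
  expect_gt(hy$report_test$accuracy, 0.6)
  # test metrics never touch training samples
  expect_length(intersect(hy$split$train_ids, hy$split$test_ids), 0)
  expect_equal(sum(hy$report_test$confusion),
               length(hy$split$test_ids))
})

test_that("the convolutional path trains and is deterministic under a seed", {
  ds <- simulate_cohort(small_sim_config(seed = 31, n_proteins = 60))
  x <- impute_median(ds$intensity)
  h1 <- train_hybrid(x, ds$annotations$class, cnn = list(epochs = 15), seed = 5)
  h2 <- train_hybrid(x, ds$annotations$class, cnn = list(epochs = 15), seed = 5)
  expect_identical(h1$extractor, "conv")
  expect_identical(h1$report_test$confusion, h2$report_test$confusion)
  expect_equal(h1$report_test$metrics$auc, h2$report_test$metrics$auc,
               tolerance = 1e-12)
  pr <- predict(h1, x, type = "prob")
  expect_equal(dim(pr), c(44L, 4L))
  expect_equal(unname(rowSums(pr)), rep(1, 44), tolerance = 1e-6)
})

test_that("single-class training data is rejected with the class named", {
  vals <- matrix(rnorm(40, 20), 4)
  x <- tiny_intensity(vals)
  expect_error(train_hybrid(x, rep("Normal", 10)), "Normal")
})
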