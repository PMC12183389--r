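test_that("score_samples is the exact sigmoid of the linear predictor", {
  model <- structure(
    list(markers = c("m1", "m2"), intercept = 0.5,
         coefficients = c(m1 = 1, m2 = -2), excluded = tibble::tibble(),
         separation = FALSE, scale = "log2_intensity"),
    class = "ev_score_model"
  )
  vals <- matrix(c(2, 1), 1, dimnames = list("s1", c("m1", "m2")))
  expect_equal(unname(score_samples(model, vals)),
               1 / (1 + exp(-0.5)), tolerance = 1e-12) # ~0.6225
  zero <- model
  zero$intercept <- 0
  zero$coefficients <- c(m1 = 0, m2 = 0)
  expect_equal(unname(score_samples(zero, vals)), 0.5)
  low <- model
  low$intercept <- -50
  low$coefficients <- c(m1 = 0, m2 = 0)
  expect_lt(unname(score_samples(low, vals)), 1e-12)
  expect_error(score_samples(model, vals[, 1, drop = FALSE]), "m2")
})

test_that("a separable marker gets a positive coefficient and high scores", {
  set.seed(3)
  y <- rep(c(0, 1), each = 30)
  vals <- cbind(sig = y * 3 + rnorm(60, sd = 0.4))
  rownames(vals) <- sprintf("s%02d", 1:60)
  model <- fit_marker_score(vals, y)
  expect_gt(model$coefficients[["sig"]], 0)
  sc <- score_samples(model, vals)
  expect_true(all(sc[y == 1] > 0.5))
})

test_that("pure-noise markers are excluded by the single backward pass", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rep(c(0, 1), each = 150)
    vals <- cbind(strong = y * 2 + rnorm(300, sd = 0.8), noise = rnorm(300))
    rownames(vals) <- sprintf("s%03d", 1:300)
    model <- fit_marker_score(vals, y)
    "noise" %in% model$excluded$marker
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("perfect separation falls back to finite penalised coefficients", {
  y <- rep(c(0, 1), each = 10)
  vals <- cbind(sep = c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1)))
  rownames(vals) <- sprintf("s%02d", 1:20)
  model <- fit_marker_score(vals, y)
  expect_true(model$separation)
  expect_true(is.finite(model$coefficients[["sep"]]))
  expect_gt(model$coefficients[["sep"]], 0)
})

test_that("scores increase in any marker with a positive coefficient", {
  set.seed(6)
  y <- rep(c(0, 1), each = 40)
  vals <- cbind(a = y + rnorm(80, sd = 0.6), b = y + rnorm(80, sd = 0.9))
  rownames(vals) <- sprintf("s%02d", 1:80)
  model <- fit_marker_score(vals, y)
  grid <- cbind(a = seq(-1, 2, length.out = 10), b = 0)
  rownames(grid) <- sprintf("g%02d", 1:10)
  sc <- score_samples(model, grid)
  if (model$coefficients[["a"]] > 0) expect_true(all(diff(sc) > 0))
})

test_that("combination search is exhaustive with exactly one best panel", {
  set.seed(9)
  y <- rep(c(0, 1), each = 40)
  vals <- cbind(good = y * 2 + rnorm(80, sd = 0.7),
                n1 = rnorm(80), n2 = rnorm(80))
  rownames(vals) <- sprintf("s%02d", 1:80)
  combos <- evaluate_combinations(vals, y)
  expect_equal(nrow(combos), 7) # 2^3 - 1
  expect_equal(sum(combos$is_best), 1L)
  expect_true("good" %in% best_combination(combos))
  expect_gte(combos$auc[combos$is_best], max(combos$auc) - 1e-12)

  single <- evaluate_combinations(vals[, "good", drop = FALSE], y)
  expect_equal(nrow(single), 1)
  expect_true(single$is_best)
  expect_error(evaluate_combinations(matrix(rnorm(32), 2,
                                            dimnames = list(NULL, letters[1:16])),
                                     c(0, 1)), "15")
})

test_that("an informative marker is almost always in the best panel", {
  hit <- vapply(1:20, function(s) {
    set.seed(s + 100)
    y <- rep(c(0, 1), each = 40)
    vals <- cbind(good = y * 1.5 + rnorm(80, sd = 0.8), n1 = rnorm(80),
                  n2 = rnorm(80), n3 = rnorm(80))
    rownames(vals) <- sprintf("s%02d", 1:80)
    "good" %in% best_combination(evaluate_combinations(vals, y))
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("control-median normalisation maps control medians to one", {
  tb <- simulate_elisa(n_control = 11, n_case = 15, seed = 3)
  ctrl <- tb$sample_id[tb$group == "control"]
  norm <- normalize_to_control_median(tb, ctrl)
  for (mk in c("ECM1", "MBL2", "BTD", "RAB5C")) {
    expect_equal(median(norm[[mk]][tb$group == "control"]), 1, tolerance = 1e-12)
    expect_equal(norm[[mk]], tb[[mk]] / median(tb[[mk]][tb$group == "control"]),
                 tolerance = 1e-12)
  }
  # idempotent on an already-normalised table
  again <- normalize_to_control_median(norm, ctrl)
  expect_equal(again$ECM1, norm$ECM1, tolerance = 1e-12)

  zero <- tb
  zero$ECM1[tb$group == "control"] <- 0
  expect_error(normalize_to_control_median(zero, ctrl), "ECM1")
})
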