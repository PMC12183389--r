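test_that("two-group test matches the Welch formula and handles edge cases", {
  a <- c(1, 2, 3, 4)
  expect_equal(two_group_test(a, a)$p_value, 1, tolerance = 1e-9)
  expect_equal(two_group_test(a, a)$log2_difference, 0)

  set.seed(2)
  b <- rnorm(20)
  shifted <- b + 1
  res <- two_group_test(shifted, b)
  expect_equal(res$log2_difference, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)

  # independent textbook Welch computation
  set.seed(8)
  x <- rnorm(15, 0, 1)
  y <- rnorm(11, 0.6, 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(var(x) / 15 + var(y) / 11)
  df <- (var(x) / 15 + var(y) / 11)^2 /
    ((var(x) / 15)^2 / 14 + (var(y) / 11)^2 / 10)
  p_ref <- 2 * stats::pt(-abs(t_stat), df)
  expect_equal(two_group_test(x, y)$p_value, p_ref, tolerance = 1e-10)

  expect_error(two_group_test(1, c(1, 2)), ">= 2")
})

test_that("published marker statistics pass the selection rule", {
  tb <- bc_signature_table()
  mbl2 <- tb[tb$protein == "MBL2", ]
  expect_equal(mbl2$fold_change, 6.665)
  flagged <- dep_rule(tb)
  expect_true(flagged$selected[flagged$protein == "MBL2"])
  # a null row is untouched
  expect_false(dep_rule(tibble::tibble(p_value = 0.5, fold_change = 1))$selected)
})

volcano_fixture <- function(seed = 4) {
  set.seed(seed)
  groups <- rep(c("HC", "TNBC"), c(15, 15))
  vals <- matrix(rnorm(20 * 30, 20, 0.5), 20)
  vals[1:3, 16:30] <- vals[1:3, 16:30] + 2    # strong up in TNBC
  vals[4, 16:30] <- vals[4, 16:30] - 2.5      # strong down
  list(x = tiny_intensity(vals), ann = tiny_annotations(groups))
}

test_that("volcano selection equals brute-force thresholding on a toy matrix", {
  fx <- volcano_fixture()
  v <- volcano_select(fx$x, fx$ann, group_a = "TNBC", group_b = "HC")
  m <- as_matrix(fx$x)
  hc <- fx$ann$sample_id[fx$ann$group == "HC"]
  tn <- fx$ann$sample_id[fx$ann$group == "TNBC"]
  for (j in seq_len(nrow(m))) {
    tt <- t.test(m[j, tn], m[j, hc])
    d <- mean(m[j, tn]) - mean(m[j, hc])
    row <- v[v$protein == rownames(m)[j], ]
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(row$log2_difference, d, tolerance = 1e-12)
    expect_identical(row$significant_up, tt$p.value < 0.05 && d > 1)
    expect_identical(row$significant_down, tt$p.value < 0.05 && d < -1)
    expect_equal(row$fold_change, 2^abs(d), tolerance = 1e-12)
  }
  expect_true(all(v$protein[v$significant_up] %in% c("P01", "P02", "P03")))
  expect_identical(v$protein[v$significant_down], "P04")
  expect_false(is.unsorted(v$p_value))
})

test_that("swapping groups negates effects, keeps p, and swaps flags", {
  fx <- volcano_fixture(6)
  a <- volcano_select(fx$x, fx$ann, "TNBC", "HC")
  b <- volcano_select(fx$x, fx$ann, "HC", "TNBC")
  b <- b[match(a$protein, b$protein), ]
  expect_equal(a$log2_difference, -b$log2_difference, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_identical(a$significant_up, b$significant_down)
  expect_identical(a$significant_down, b$significant_up)
})

test_that("tightening thresholds never adds selected proteins", {
  fx <- volcano_fixture(10)
  base <- volcano_select(fx$x, fx$ann, "TNBC", "HC", p_thresh = 0.1,
                         fc_log2_thresh = 0.5)
  tight_p <- volcano_select(fx$x, fx$ann, "TNBC", "HC", p_thresh = 0.01,
                            fc_log2_thresh = 0.5)
  tight_fc <- volcano_select(fx$x, fx$ann, "TNBC", "HC", p_thresh = 0.1,
                             fc_log2_thresh = 1.5)
  sel <- function(v) v$protein[v$significant_up | v$significant_down]
  expect_true(all(sel(tight_p) %in% sel(base)))
  expect_true(all(sel(tight_fc) %in% sel(base)))
})

test_that("proteins with too few observations are skipped with a warning", {
  fx <- volcano_fixture(12)
  m <- as_matrix(fx$x)
  m[5, fx$ann$sample_id[fx$ann$group == "HC"]] <- NA
  x <- tiny_intensity(m)
  expect_warning(v <- volcano_select(x, fx$ann, "TNBC", "HC"), "skipped")
  expect_false("P05" %in% v$protein)
})

test_that("comparison grid is consistent with single-comparison volcano", {
  fx <- volcano_fixture(14)
  grid <- comparison_grid(fx$x, fx$ann,
                          list(main = list(a = "TNBC", b = "HC")),
                          marker_subset = c("P01", "P04", "P07"))
  expect_equal(nrow(grid), 3)
  v <- volcano_select(fx$x, fx$ann, "TNBC", "HC")
  for (p in grid$protein) {
    expect_equal(grid$p_value[grid$protein == p],
                 v$p_value[v$protein == p], tolerance = 1e-12)
  }
  expect_error(comparison_grid(fx$x, fx$ann,
                               list(main = list(a = "TNBC", b = "HC")),
                               marker_subset = "NOPE"), "NOPE")
})
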