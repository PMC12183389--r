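test_that("log2 normalisation is exact and rejects bad input", {
  x <- tiny_intensity(matrix(c(8, 1, 4, NA), 2), scale = "linear")
  y <- normalize_log2(x)
  expect_equal(as_matrix(y)[1, 1], 3)
  expect_equal(as_matrix(y)[2, 1], 0)
  expect_true(is.na(as_matrix(y)[2, 2]))
  expect_identical(intensity_scale(y), "log2")

  vals <- matrix(abs(rnorm(60)) + 0.1, 6)
  z <- tiny_intensity(vals, scale = "linear")
  expect_equal(as_matrix(normalize_log2(z)), log2(as_matrix(z)),
               tolerance = 1e-12)

  bad <- tiny_intensity(matrix(c(1, -2, 3, 4), 2), scale = "linear")
  expect_error(normalize_log2(bad), "P02")
  expect_error(normalize_log2(tiny_intensity(matrix(1:4, 2))), "linear-scale")
})

make_masked_fixture <- function(seed = 1, n_prot = 25, groups = NULL) {
  set.seed(seed)
  groups <- groups %||% rep(c("HC", "Luminal", "HER2", "TNBC"), c(12, 10, 9, 13))
  n <- length(groups)
  vals <- matrix(rnorm(n_prot * n, 20), n_prot)
  vals[matrix(runif(n_prot * n) < 0.35, n_prot)] <- NA
  list(x = tiny_intensity(vals), ann = tiny_annotations(groups))
}

test_that("min-individuals filter matches a brute-force recount and boundaries", {
  # boundary: observed in exactly 10 samples of one group
  groups <- rep(c("HC", "TNBC"), c(12, 8))
  vals <- matrix(rnorm(3 * 20, 20), 3)
  vals[1, 11:20] <- NA          # protein 1: 10 HC, 0 TNBC -> retained at 10
  vals[2, c(1:3, 13:20)] <- NA  # protein 2: 9 HC, 1 TNBC -> dropped
  x <- tiny_intensity(vals)
  ann <- tiny_annotations(groups)
  out <- filter_min_individuals(x, ann, min_n = 10)
  expect_identical(out$protein, c("P01", "P03"))
  expect_error(filter_min_individuals(x, ann, min_n = 0), ">= 1")

  fx <- make_masked_fixture(3)
  out2 <- filter_min_individuals(fx$x, fx$ann, min_n = 5)
  m <- as_matrix(fx$x)
  grp <- fx$ann$group
  keep_brute <- vapply(seq_len(nrow(m)), function(j) {
    any(vapply(unique(grp), function(g) sum(!is.na(m[j, grp == g])) >= 5,
               logical(1)))
  }, logical(1))
  expect_identical(out2$protein, fx$x$protein[keep_brute])
})

test_that("group-presence filter is strict, per-group, and oracle-consistent", {
  # 71% in all groups retained, exactly 70% in one group dropped
  groups <- rep(c("HC", "TNBC"), c(100, 10))
  vals <- matrix(rnorm(2 * 110, 20), 2)
  vals[1, 1:29] <- NA   # 71% HC presence, 100% TNBC -> retained
  vals[2, 1:30] <- NA   # exactly 70% HC -> dropped (strict)
  x <- tiny_intensity(vals)
  ann <- tiny_annotations(groups)
  out <- filter_group_presence(x, ann, min_fraction = 0.7)
  expect_identical(out$protein, "P01")
  rep <- filter_report(out)
  expect_equal(rep$n_input, 2)
  expect_equal(rep$n_output, 1)

  fx <- make_masked_fixture(5)
  out2 <- filter_group_presence(fx$x, fx$ann, min_fraction = 0.5)
  m <- as_matrix(fx$x)
  grp <- fx$ann$group
  keep_brute <- vapply(seq_len(nrow(m)), function(j) {
    all(vapply(unique(grp), function(g) mean(!is.na(m[j, grp == g])) > 0.5,
               logical(1)))
  }, logical(1))
  expect_identical(out2$protein, fx$x$protein[keep_brute])
  expect_error(filter_group_presence(fx$x, fx$ann, min_fraction = 1), "\\[0, 1\\)")
})

test_that("filters are monotone in their thresholds and idempotent", {
  fx <- make_masked_fixture(9, n_prot = 40)
  for (pair in list(c(8, 4), c(6, 3))) {
    strict <- filter_min_individuals(fx$x, fx$ann, min_n = pair[1])
    loose <- filter_min_individuals(fx$x, fx$ann, min_n = pair[2])
    expect_true(all(strict$protein %in% loose$protein))
  }
  strict <- filter_group_presence(fx$x, fx$ann, min_fraction = 0.6)
  loose <- filter_group_presence(fx$x, fx$ann, min_fraction = 0.3)
  expect_true(all(strict$protein %in% loose$protein))

  once <- filter_group_presence(fx$x, fx$ann, min_fraction = 0.4)
  twice <- filter_group_presence(once, fx$ann, min_fraction = 0.4)
  expect_identical(as_matrix(once), as_matrix(twice))
  # filters never alter retained values
  expect_equal(as_matrix(once), as_matrix(fx$x)[once$protein, , drop = FALSE])
})

test_that("median imputation fills exactly the missing cells with row medians", {
  x <- tiny_intensity(matrix(c(1, 3, NA, 5, 5, 5), 2, byrow = TRUE))
  y <- impute_median(x)
  expect_equal(as_matrix(y)[1, 3], 2)
  expect_false(anyNA(as_matrix(y)))

  complete <- tiny_intensity(matrix(rnorm(12), 3))
  expect_identical(as_matrix(impute_median(complete)), as_matrix(complete))

  fx <- make_masked_fixture(21)
  keep <- rowSums(!is.na(as_matrix(fx$x))) > 0
  xk <- fx$x[keep, , drop = FALSE]
  imp <- as_matrix(impute_median(xk))
  m <- as_matrix(xk)
  for (j in seq_len(nrow(m))) {
    med <- median(m[j, ], na.rm = TRUE)
    expect_equal(unname(imp[j, is.na(m[j, ])]),
                 rep(med, sum(is.na(m[j, ]))))
    expect_equal(imp[j, !is.na(m[j, ])], m[j, !is.na(m[j, ])])
  }

  allna <- tiny_intensity(matrix(c(1, NA, 2, NA), 2, byrow = TRUE))
  allna_m <- as_matrix(allna)
  allna_m[2, ] <- NA
  expect_error(impute_median(tiny_intensity(allna_m)), "no observed")
})
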