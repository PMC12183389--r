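test_that("cohort generation is deterministic and respects the configuration", {
  cfg <- small_sim_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as_matrix(a$intensity), as_matrix(b$intensity))
  expect_identical(a$annotations, b$annotations)
  expect_equal(ncol(as_matrix(a$intensity)), sum(cfg$n_per_class))
  expect_equal(nrow(as_matrix(a$intensity)), cfg$n_proteins)
  expect_equal(as.numeric(table(a$annotations$class)), c(12, 14, 10, 8))
})

test_that("default study-scale cohort matches the analysis dimensions", {
  cfg <- sim_config()
  expect_equal(cfg$n_proteins, 985L)
  expect_equal(unname(cfg$n_per_class[c("Normal", "OtherSubtype",
                                        "TNBC_no_recur", "TNBC_recur")]),
               c(30, 57, 26, 17))
  expect_equal(sum(cfg$n_per_class), 130)
})

test_that("realised missingness stays within binomial bounds of the target", {
  r <- 0.15
  ds <- simulate_cohort(small_sim_config(missing_rate = r, n_proteins = 200,
                                         seed = 2))
  m <- as_matrix(ds$intensity)
  n_cells <- length(m)
  expect_lt(abs(mean(is.na(m)) - r), 2 * sqrt(r * (1 - r) / n_cells) + 1e-12)
})

test_that("null cohorts have no systematic class differences", {
  cfg <- small_sim_config(planted = NULL, missing_rate = 0, n_proteins = 30,
                          seed = 7)
  ds <- simulate_cohort(cfg)
  m <- as_matrix(ds$intensity)
  cls <- ds$annotations$class
  for (j in c(1, 15, 30)) {
    mm <- tapply(m[j, ], cls, mean)
    nn <- tapply(m[j, ], cls, length)
    spread <- max(mm) - min(mm)
    expect_lt(spread, 4 * cfg$baseline_sd / sqrt(min(nn)) * 2)
  }
})

test_that("a planted fold change is recovered from a large cohort", {
  fc <- 2.238 # ECM1-scale linear fold change
  planted <- tibble::tibble(protein = "ECM1",
                            OtherSubtype = log2(fc), TNBC_no_recur = log2(fc),
                            TNBC_recur = log2(fc))
  cfg <- sim_config(n_per_class = c(Normal = 200, OtherSubtype = 200,
                                    TNBC_no_recur = 200, TNBC_recur = 200),
                    n_proteins = 10, planted = planted, missing_rate = 0,
                    seed = 13)
  ds <- simulate_cohort(cfg)
  m <- as_matrix(ds$intensity)
  cancer <- ds$annotations$class != "Normal"
  est <- 2^(mean(m["ECM1", cancer]) - mean(m["ECM1", !cancer]))
  expect_lt(abs(est - fc) / fc, 0.10)
})

test_that("planted marker lists are validated", {
  dup <- tibble::tibble(protein = c("A", "A"), OtherSubtype = 1,
                        TNBC_no_recur = 1, TNBC_recur = 1)
  cfg <- small_sim_config(seed = 1)
  cfg$planted <- dup
  expect_error(simulate_cohort(cfg), "Duplicate")
  cfg2 <- small_sim_config(seed = 1)
  cfg2$n_proteins <- 2L # fewer slots than the four default planted markers
  expect_error(simulate_cohort(cfg2), "More planted")
})

test_that("survival generator enforces score range, RFS <= OS and censoring", {
  ds <- simulate_cohort(small_sim_config(seed = 3))
  ids <- ds$annotations$sample_id[ds$annotations$group != "HC"]
  sc <- stats::setNames(rep(c(0.2, 0.8), length.out = length(ids)), ids)
  cfg0 <- small_sim_config(censor_rate = 0, seed = 3)
  ann <- simulate_survival(ds$annotations, sc, cfg0)
  case <- ann$group != "HC"
  expect_true(all(ann$rfs_event[case] == 1)) # no censoring => all events
  expect_true(all(ann$rfs_time[case] <= ann$os_time[case] + 1e-12))
  expect_true(all(is.na(ann$rfs_time[!case])))

  expect_error(simulate_survival(ds$annotations, sc * 2, cfg0), "\\[0, 1\\]")
  expect_error(simulate_survival(ds$annotations, sc[-1], cfg0),
               "No risk score")
  ann2 <- simulate_survival(ds$annotations, sc, cfg0)
  expect_identical(ann, ann2) # deterministic
})

test_that("ELISA panel has the requested shape and planted fold changes", {
  tb <- simulate_elisa(seed = 5)
  expect_equal(nrow(tb), 40)
  expect_equal(sum(tb$group == "control"), 10)

  big <- simulate_elisa(n_control = 200, n_case = 200,
                        fold_changes = c(A = 1, B = 3), seed = 9)
  norm <- normalize_to_control_median(big, big$sample_id[big$group == "control"])
  med_case <- vapply(c("A", "B"), function(k) {
    median(norm[[k]][norm$group == "case"])
  }, numeric(1))
  expect_gt(med_case[["A"]], 0.7)
  expect_lt(med_case[["A"]], 1.4)
  expect_gt(med_case[["B"]], 2.5)
  expect_lt(med_case[["B"]], 3.5)
  expect_error(simulate_elisa(n_control = 0), "positive")
})
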