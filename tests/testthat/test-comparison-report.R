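make_profiles <- function(seed = 1, n_per_group = 9) {
  design <- study_design(n_per_group = n_per_group, seed = seed)
  randomness_profile(standardize(generate_study(design)))
}

test_that("cell summaries have the 2x2 layout and basic invariances", {
  profiles <- make_profiles(seed = 21, n_per_group = 4)
  cells <- summarize_cells(profiles)
  expect_equal(nrow(cells), 4 * 5)
  expect_true(all(cells$n_sequences == 4))
  expect_true(all(cells$sd >= 0))

  # invariant to row order
  shuffled <- profiles[sample(nrow(profiles)), ]
  expect_equal(summarize_cells(shuffled), cells)

  # a cell of identical profiles has zero SD
  const <- profiles
  for (col in c("redundancy", "fpr", "nsq", "coupon", "rep_gap")) {
    const[[col]][const$group == "expert" & const$task == "morra"] <- 1
  }
  cc <- summarize_cells(const)
  expect_true(all(cc$sd[cc$group == "expert" & cc$task == "morra"] == 0))

  # an absent cell is reported as missing, not fabricated
  dropped <- profiles[!(profiles$group == "expert" & profiles$task == "morra"), ]
  cd <- summarize_cells(dropped)
  miss <- cd[cd$group == "expert" & cd$task == "morra", ]
  expect_true(all(miss$n_sequences == 0))
  expect_true(all(is.na(miss$mean)))
})

test_that("the overlap index behaves like a distribution overlap", {
  set.seed(100)
  x <- rnorm(400)
  expect_gt(overlap_index(x, x), 0.99)
  expect_lte(overlap_index(x, x), 1)
  expect_lt(overlap_index(x, x + 100), 0.001)
  # symmetry
  y <- rnorm(300, 1, 2)
  expect_equal(overlap_index(x, y), overlap_index(y, x), tolerance = 1e-6)
  # equivariance under a common affine map
  ov1 <- overlap_index(x, y)
  ov2 <- overlap_index(3 * x - 7, 3 * y - 7)
  expect_equal(ov1, ov2, tolerance = 0.01)
})

test_that("overlap matches the closed form for equal-variance normals", {
  set.seed(200)
  ov <- overlap_index(rnorm(10000), rnorm(10000, mean = 2))
  expect_equal(as.numeric(ov), 2 * pnorm(-1), tolerance = 0.02)
})

test_that("zero-variance samples fall back to discrete mass overlap, flagged", {
  expect_warning(ov <- overlap_index(rep(1, 5), c(1, 1, 2, 2, 2)),
                 "discrete")
  expect_equal(attr(ov, "method"), "discrete")
  expect_equal(as.numeric(ov), 0.4)  # min(1, 2/5)
})

test_that("permutation contrasts are valid and reproducible", {
  x <- c(1.2, 0.7, 1.5, 0.9, 1.1)
  pc <- permutation_contrast(x, x, n_perm = 199, seed = 1)
  expect_equal(pc$observed_diff, 0)
  expect_equal(pc$p_value, 1)

  lo <- rnorm(10, 0, 0.1)
  hi <- rnorm(10, 10, 0.1)
  pc2 <- permutation_contrast(lo, hi, n_perm = 999, seed = 2)
  expect_lte(pc2$p_value, 0.01)
  expect_lt(pc2$observed_diff, 0)

  pc3 <- permutation_contrast(lo, hi, n_perm = 999, seed = 2)
  expect_identical(pc2, pc3)
  expect_error(permutation_contrast(1, c(1, 2), n_perm = 99),
               class = "morrarand_error_input")
})

test_that("permutation p-values are conservative and near-uniform under the null", {
  set.seed(300)
  pvals <- vapply(1:300, function(i) {
    permutation_contrast(rnorm(12), rnorm(12), n_perm = 199)$p_value
  }, numeric(1))
  # type-I error at alpha = 0.05 within Monte-Carlo error of nominal
  expect_lte(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  expect_gte(mean(pvals <= 0.05), 0.05 - 3 * sqrt(0.05 * 0.95 / 300))
  expect_lt(abs(mean(pvals) - 0.5), 0.06)
})

test_that("index correlations flag degenerate columns and find real structure", {
  profiles <- tibble::tibble(
    redundancy = c(1, 2, 3, 4), fpr = c(2, 4, 6, 8), nsq = c(4, 3, 2, 1),
    coupon = c(5, 5, 5, 5), rep_gap = c(1.1, 1.4, 1.2, 1.9)
  )
  expect_warning(ct <- metric_correlations(profiles), "coupon")
  r_rf <- ct$r[ct$index_1 == "redundancy" & ct$index_2 == "fpr"]
  expect_equal(r_rf, 1)
  expect_true(all(is.na(ct$r[ct$index_1 == "coupon" | ct$index_2 == "coupon"])))
  expect_error(metric_correlations(profiles[1:2, ]),
               class = "morrarand_error_input")

  # on synthetic studies, redundancy and pairing bias travel together
  profiles2 <- make_profiles(seed = 33)
  ct2 <- metric_correlations(profiles2)
  expect_gt(ct2$r[ct2$index_1 == "redundancy" & ct2$index_2 == "fpr"], 0)
})

test_that("the full report has the 4-cells x 4-contrasts x 5-indices shape", {
  profiles <- make_profiles(seed = 44, n_per_group = 5)
  rep1 <- build_report(profiles, n_perm = 199, seed = 9)
  expect_s3_class(rep1, "morra_report")
  expect_equal(nrow(rep1$cells), 20)
  expect_equal(nrow(rep1$contrasts), 20)
  expect_equal(sort(unique(rep1$contrasts$type)), c("between", "within"))
  expect_true(all(rep1$contrasts$ov >= 0 & rep1$contrasts$ov <= 1))
  expect_true(all(rep1$contrasts$p_value > 0 & rep1$contrasts$p_value <= 1))

  # deterministic: identical object and byte-identical files on re-run
  rep2 <- build_report(profiles, n_perm = 199, seed = 9)
  expect_equal(rep1, rep2)
  d1 <- withr::local_tempdir()
  write_report(rep1, file.path(d1, "r1"))
  write_report(rep2, file.path(d1, "r2"))
  expect_identical(readLines(file.path(d1, "r1.json")),
                   readLines(file.path(d1, "r2.json")))
  expect_identical(readLines(file.path(d1, "r1.txt")),
                   readLines(file.path(d1, "r2.txt")))
  expect_true(file.exists(file.path(d1, "r1_cells.csv")))
  expect_true(file.exists(file.path(d1, "r1_contrasts.csv")))
})

test_that("a report on a study with an empty cell marks it missing", {
  profiles <- make_profiles(seed = 55, n_per_group = 4)
  dropped <- profiles[!(profiles$group == "expert" & profiles$task == "rngt"), ]
  rep <- build_report(dropped, n_perm = 99, seed = 3)
  affected <- rep$contrasts$ov_method[grepl("rngt", rep$contrasts$contrast) |
                                        rep$contrasts$contrast == "expert: morra vs rngt"]
  expect_true(any(rep$contrasts$ov_method == "missing cell"))
  expect_true(all(is.na(rep$contrasts$ov[rep$contrasts$ov_method == "missing cell"])))
})

test_that("tidy, glance and autoplot expose the report", {
  profiles <- make_profiles(seed = 66, n_per_group = 4)
  rep <- build_report(profiles, n_perm = 99, seed = 4)
  td <- tidy(rep)
  expect_equal(td, rep$contrasts)
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_sequences, nrow(profiles))
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
  expect_s3_class(ggplot2::autoplot(build_payoff_matrix()), "ggplot")
  expect_output(print(rep), "Cell means")
})
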