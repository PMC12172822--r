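test_that("fisher z is atanh with a guarded domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306144334, tolerance = 1e-10)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

make_partition <- function(sizes = c(PM = 3, AT = 3, MPF = 2)) {
  ids <- sprintf("n%02d", seq_len(sum(sizes)))
  tibble::tibble(node_id = ids, subnetwork = rep(names(sizes), sizes))
}

test_that("subnetwork profiles average z values per block", {
  part <- make_partition()
  ids <- part$node_id
  n <- length(ids)

  # uniform matrix: every block mean equals atanh(0.5)
  m <- matrix(0.5, n, n, dimnames = list(ids, ids))
  diag(m) <- 1
  prof <- subnetwork_profile(m, part)
  expect_equal(unlist(prof), rep(atanh(0.5), 6), ignore_attr = TRUE)

  # two-node subnetwork: the within value is that single pair's z
  m2 <- m
  m2["n07", "n08"] <- m2["n08", "n07"] <- 0.31
  expect_equal(subnetwork_profile(m2, part)$within_mpf, atanh(0.31))

  # permuting node order leaves the profile unchanged
  set.seed(3)
  y <- matrix(rnorm(200 * n), 200, n)
  colnames(y) <- ids
  r <- pearson_matrix(y)
  perm <- sample(n)
  expect_equal(subnetwork_profile(r[perm, perm], part),
               subnetwork_profile(r, part))

  # block means stay inside the range of their block's z values
  z <- atanh(r - diag(diag(r)) + diag(0, n))
  prof_r <- subnetwork_profile(r, part)
  pm_ids <- ids[1:3]
  pm_z <- atanh(r[pm_ids, pm_ids][upper.tri(diag(3))])
  expect_gte(prof_r$within_pm, min(pm_z))
  expect_lte(prof_r$within_pm, max(pm_z))

  # r-then-z mode transforms the block average instead
  expect_equal(subnetwork_profile(m2, part, mode = "r_first")$within_mpf,
               atanh(0.31))
  mixed <- m
  mixed["n01", "n02"] <- mixed["n02", "n01"] <- 0.2
  expect_equal(subnetwork_profile(mixed, part, mode = "r_first")$within_pm,
               atanh(mean(c(0.2, 0.5, 0.5))))

  expect_error(subnetwork_profile(m, part[part$subnetwork != "AT", ]),
               "AT is empty")
})

test_that("pooled two-sample t matches hand computation and summaries", {
  # hand example: a = 1,2,3 vs b = 2,3,4 -> t = -1.2247, df = 4
  res <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)

  # identical groups -> t = 0, p = 1
  res0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # swapping groups negates t, p unchanged
  res_sw <- two_sample_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(res_sw$t, -res$t)
  expect_equal(res_sw$p, res$p)

  # summary route identical to raw route for random inputs
  set.seed(10)
  for (i in 1:25) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    raw <- two_sample_t(a, b)
    summ <- t_from_summary(mean(a), sd(a), length(a),
                           mean(b), sd(b), length(b))
    expect_equal(raw$t, summ$t, tolerance = 1e-10)
    expect_equal(raw$p, summ$p, tolerance = 1e-10)
  }

  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
  expect_error(t_from_summary(1, 0, 5, 2, 0, 5), "not both zero")
})

test_that("published group summaries reproduce their printed t statistics", {
  # WAIS vocabulary, CHR (n=9) vs FEP (n=19): t(26) = 2.62
  wais <- t_from_summary(47.00, 10.87, 9, 34.68, 11.92, 19)
  expect_equal(wais$t, 2.62, tolerance = 0.005)
  expect_equal(wais$df, 26)
  expect_lt(wais$p, 0.05)

  # general psychopathology: t(26) = 2.167
  gen <- t_from_summary(33.00, 6.40, 9, 27.47, 6.26, 19)
  expect_equal(gen$t, 2.167, tolerance = 0.005)
  expect_equal(gen$df, 26)
})

test_that("chi-square on 2x2 counts is Pearson without correction", {
  # identical proportions -> statistic 0
  even <- chi_square_counts(matrix(c(10, 20, 10, 20), 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)

  # perfectly separated table -> statistic 20 (hand computation)
  sep <- chi_square_counts(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(sep$statistic, 20)
  expect_equal(sep$df, 1)

  # invariant to row/column swaps
  tab <- matrix(c(12, 5, 7, 9), 2, 2)
  expect_equal(chi_square_counts(tab)$statistic,
               chi_square_counts(tab[2:1, ])$statistic)
  expect_equal(chi_square_counts(tab)$statistic,
               chi_square_counts(tab[, 2:1])$statistic)

  expect_error(chi_square_counts(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "marginal")
})

test_that("group comparisons on identically distributed groups are mostly null", {
  # type-I behaviour: per-measure rejection near the nominal level
  set.seed(42)
  n_cohorts <- 100
  reject <- matrix(FALSE, n_cohorts, 6)
  for (i in seq_len(n_cohorts)) {
    profiles <- tibble::tibble(
      subject_id = sprintf("s%02d", 1:40),
      within_pm = rnorm(40, 0.45, 0.1), within_at = rnorm(40, 0.39, 0.08),
      within_mpf = rnorm(40, 0.59, 0.14), mpf_pm = rnorm(40, 0.35, 0.1),
      pm_at = rnorm(40, 0.27, 0.09), mpf_at = rnorm(40, 0.33, 0.08)
    )
    groups <- tibble::tibble(subject_id = profiles$subject_id,
                             group = rep(c("HC", "PSY"), each = 20))
    cmp <- compare_profiles(profiles, groups, "HC", "PSY")
    reject[i, ] <- cmp$p < 0.05
  }
  # each of the six tests should be non-significant in >= 90% of cohorts
  expect_true(all(colMeans(reject) <= 0.10))
})
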