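test_that("configuration invariants are enforced", {
  expect_error(simulation_config(rho_within = 0.3, rho_between = 0.4),
               "strictly smaller")
  expect_error(simulation_config(rho_within = 1.2), "outside")
  expect_error(simulation_config(n_frames = 1), "outside")
  expect_error(simulation_config(spike_rate = 1.5), "outside")
  cfg <- simulation_config(n_nodes = 60)
  expect_equal(unname(table(cfg$planted_partition)[c("PM", "AT", "MPF", "Other")]),
               c(18L, 22L, 8L, 12L), ignore_attr = TRUE)
})

test_that("motion traces are deterministic with truthful spike records", {
  cfg <- simulation_config(n_subjects = 2, seed = 5)
  m1 <- generate_motion_trace(cfg, 1)
  m2 <- generate_motion_trace(cfg, 1)
  expect_identical(unclass(m1), unclass(m2))
  expect_false(identical(unclass(m1), unclass(generate_motion_trace(cfg, 2))))

  # zero motion settings give an identically-zero trace and zero FD
  cfg0 <- simulation_config(motion_step_sd = 0, spike_rate = 0, seed = 1)
  m0 <- generate_motion_trace(cfg0, 1)
  expect_true(all(m0 == 0))
  expect_true(all(compute_fd(m0)$fd == 0))

  # recorded spike frames show up as FD outliers under the module's oracle
  cfg_sp <- simulation_config(spike_rate = 0.05, spike_magnitude = 2,
                              motion_step_sd = 0.01, seed = 9)
  msp <- generate_motion_trace(cfg_sp, 3)
  spikes <- attr(msp, "spike_frames")
  expect_gt(length(spikes), 0)
  fd <- oracle_fd(msp)
  expect_true(all(fd[spikes] > 0.5))
})

test_that("node series carry the planted correlation structure and tSNR", {
  # independence: rho 0/0 keeps off-diagonal sample correlations near zero
  part <- stats::setNames(rep(c("A", "B"), each = 5), sprintf("n%03d", 1:10))
  cfg0 <- simulation_config(n_subjects = 1, n_nodes = 10,
                            planted_partition = part, rho_within = 0,
                            rho_between = 0, seed = 3)
  s0 <- generate_node_series(cfg0, 1)
  r0 <- cor(s0)
  expect_lt(max(abs(r0[upper.tri(r0)])), 3 / sqrt(cfg0$n_frames))

  # planted blocks: Monte-Carlo over 50 subjects lands within +/- 0.05
  cfg <- simulation_config(n_subjects = 50, n_nodes = 10,
                           planted_partition = part, seed = 21)
  within_r <- between_r <- numeric(50)
  tsnr_all <- numeric(0)
  for (i in 1:50) {
    s <- generate_node_series(cfg, i)
    r <- cor(s)
    same <- outer(part, part, "==")
    diag(same) <- FALSE
    within_r[i] <- mean(r[same])
    between_r[i] <- mean(r[!same & upper.tri(r, diag = FALSE)])
    if (i <= 10) tsnr_all <- c(tsnr_all, compute_tsnr(s)$tsnr)
  }
  expect_lt(abs(mean(within_r) - cfg$rho_within), 0.05)
  expect_lt(abs(mean(between_r) - cfg$rho_between), 0.05)

  # population tSNR = signal_mean / noise_sd (here 100 / 1)
  expect_equal(mean(tsnr_all), 100, tolerance = 2)

  # tSNR 50 example: mean 100, SD 2
  cfg2 <- simulation_config(n_nodes = 10, planted_partition = part,
                            noise_sd = 2, seed = 4)
  expect_equal(mean(compute_tsnr(generate_node_series(cfg2, 1))$tsnr), 50,
               tolerance = 2)

  expect_error(
    generate_node_series(simulation_config(n_nodes = 12, seed = 1,
                                           planted_partition = part)),
    "every node")
})

test_that("cohorts pair every subject with motion, confounds and groups", {
  cfg <- simulation_config(n_subjects = 12, seed = 6)
  coh <- generate_cohort(cfg)
  expect_equal(names(coh$series), names(coh$motion))
  expect_equal(names(coh$series), names(coh$confounds))
  expect_equal(nrow(coh$subjects), 12)
  expect_true(all(c("HC", "CHR", "FEP") %in% coh$subjects$group))
  # symptom scores exist only for patient-group subjects
  expect_true(all(!coh$subjects$has_symptoms[coh$subjects$group == "HC"]))
  # determinism at the cohort level
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$series, coh2$series)
  expect_identical(coh$subjects, coh2$subjects)
})

test_that("symptom generation follows the planted linear model", {
  cfg <- simulation_config(n_subjects = 10, seed = 30, symptom_noise_sd = 0,
                           beta_fd = 0)
  ids <- sprintf("s%03d", 1:10)
  profiles <- tibble::tibble(
    subject_id = ids,
    # small spread keeps the noiseless scores inside the clipping range
    mpf_pm = rnorm(10, 0.35, 0.01), mpf_at = rnorm(10, 0.33, 0.01)
  )
  fd <- tibble::tibble(subject_id = ids, mean_fd = runif(10, 0.1, 0.3))
  sym <- generate_symptoms(cfg, profiles, fd)

  # noiseless case: an exact affine function of the two planted predictors
  fit <- lm(sym$panss_negative ~ profiles$mpf_pm + profiles$mpf_at)
  expect_equal(summary(fit)$r.squared, 1, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[-1]), c(cfg$beta_mpf_pm, cfg$beta_mpf_at),
               tolerance = 1e-6)

  # determinism
  expect_identical(sym, generate_symptoms(cfg, profiles, fd))

  # scores stay inside instrument ranges
  expect_true(all(sym$panss_positive >= 7 & sym$panss_positive <= 49))
  expect_true(all(sym$panss_negative >= 7 & sym$panss_negative <= 49))
  expect_true(all(sym$panss_general >= 16 & sym$panss_general <= 112))

  # misaligned profiles are refused
  expect_error(generate_symptoms(cfg, profiles, fd[1:5, ]), "align")
})

test_that("fixture sets round-trip bit-identically with a complete manifest", {
  cfg <- simulation_config(n_subjects = 3, n_nodes = 12, n_frames = 20,
                           seed = 44)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_fixture_set(coh, dir)

  # manifest lists one series file per subject plus tables and truth
  expect_equal(sum(startsWith(manifest$file, "series_")), 3)
  expect_true(all(file.exists(file.path(dir, manifest$file))))

  back <- read_fixture_set(dir)
  expect_equal(back$series, coh$series, tolerance = 0)
  for (id in names(coh$motion)) {
    expect_equal(unclass(back$motion[[id]]), unclass(coh$motion[[id]]),
                 ignore_attr = TRUE, tolerance = 0)
  }
  # truth record reproduces the planted betas exactly
  expect_equal(back$truth$betas,
               c(mpf_pm = cfg$beta_mpf_pm, mpf_at = cfg$beta_mpf_at,
                 fd = cfg$beta_fd))
  expect_equal(unname(back$truth$planted_partition[names(cfg$planted_partition)]),
               unname(cfg$planted_partition))
})

test_that("sphere extraction inverts volume painting for separated nodes", {
  nodes <- tibble::tibble(
    node_id = c("a", "b", "c"),
    x = c(0, 30, 0), y = c(0, 0, 30), z = c(0, 0, 0), radius = 5
  )
  set.seed(55)
  series <- matrix(rnorm(3 * 12, 100, 2), 12, 3)
  colnames(series) <- nodes$node_id
  vol <- series_to_volume(series, nodes)
  back <- extract_node_series(vol, nodes)
  expect_equal(back, series, tolerance = 1e-12)
  expect_error(extract_node_series(unclass(vol)[, , , , drop = FALSE],
                                   nodes, voxel_mm = NULL), "geometry")
})
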