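test_that("framewise displacement follows the sphere-conversion formula", {
  # constant trace -> all zeros
  m <- matrix(0.3, 10, 6)
  expect_equal(compute_fd(m)$fd, rep(0, 10))

  # hand example: 0.1 mm shift + 0.002 rad pitch -> 0.1 + 50*0.002 = 0.2 mm
  m <- matrix(0, 4, 6)
  m[2, 1] <- 0.1
  m[2, 5] <- 0.002
  fd <- compute_fd(m)$fd
  expect_equal(fd[2], 0.2)
  expect_equal(fd[3], 0.2) # moving back contributes the same differential

  # linearity: doubling every parameter difference doubles fd
  set.seed(4)
  m <- matrix(rnorm(60), 10, 6)
  expect_equal(compute_fd(2 * m)$fd, 2 * compute_fd(m)$fd)

  # offset invariance: adding a constant to any parameter leaves fd unchanged
  m2 <- sweep(m, 2, c(5, -3, 0.4, 0.1, 0, 2), "+")
  expect_equal(compute_fd(m2)$fd, compute_fd(m)$fd)

  # agrees with an element-wise oracle
  expect_equal(compute_fd(m)$fd, oracle_fd(m))

  expect_error(compute_fd(matrix(c(1, NA), 2, 6)), "non-finite")
})

test_that("outlier flagging uses a strict 0.5 mm threshold", {
  fd <- tibble::tibble(frame = 1:4, fd = c(0, 0.2, 0.6, 0.3))
  flags <- flag_outliers(fd)
  expect_equal(which(flags$outlier), 3L) # third frame (0-based index 2)
  expect_equal(ncol(spike_matrix(flags)), 1L)
  expect_equal(spike_matrix(flags)[, 1], c(0, 0, 1, 0))

  # boundary: exactly 0.5 is not flagged; all below -> no spike columns
  fd$fd <- c(0, 0.5, 0.49, 0.1)
  flags <- flag_outliers(fd)
  expect_false(any(flags$outlier))
  expect_equal(ncol(spike_matrix(flags)), 0L)
})

test_that("exclusion decision applies strict 3 mm and 17% rules", {
  mk_trace <- function(n_spikes, n_frames = 185) {
    # isolated +/-0.6 mm steps at every other frame: each step is exactly one
    # FD outlier, and the position never strays past 0.6 mm
    steps <- numeric(n_frames)
    if (n_spikes > 0) {
      frames <- seq(2, by = 2, length.out = n_spikes)
      steps[frames] <- 0.6 * rep_len(c(1, -1), n_spikes)
    }
    m <- matrix(0, n_frames, 6)
    m[, 1] <- cumsum(steps)
    m
  }
  # 32/185 = 0.173 > 0.17 -> excluded; 31/185 = 0.168 -> retained
  expect_true(exclusion_decision(mk_trace(32))$excluded)
  dec31 <- exclusion_decision(mk_trace(31))
  expect_false(dec31$excluded)
  expect_equal(dec31$n_outliers, 31L)

  # zero motion -> retained
  expect_false(exclusion_decision(matrix(0, 20, 6))$excluded)

  # absolute translation above 3 mm relative to the first frame
  m <- matrix(0, 20, 6)
  m[, 2] <- 10 # constant offset: relative displacement is 0
  expect_false(exclusion_decision(m)$excluded)
  m[15, 2] <- 13.5 # 3.5 mm away from the reference frame
  dec <- exclusion_decision(m)
  expect_true(dec$excluded)
  expect_equal(dec$reason, "absolute motion")
})

test_that("exclusion decision matches a brute-force recomputation", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(10:40, 1)
    m <- matrix(rnorm(n * 6, 0, 0.4), n, 6)
    if (i %% 3 == 0) m[sample(n, 1), sample(3, 1)] <- 4
    expect_equal(exclusion_decision(m)$excluded, oracle_excluded(m))
  }
})

test_that("nuisance design has the documented structure", {
  t_frames <- 185
  m <- matrix(rnorm(t_frames * 6, 0, 0.01), t_frames, 6)
  wm <- rnorm(t_frames)
  csf <- rnorm(t_frames)

  # K = floor(2 * 370 * 0.01) = 7 DCT columns; width 1 + 6 + 2 + 7 = 16
  x <- build_design(m, wm, csf, highpass_hz = 0.01, tr_seconds = 2)
  expect_equal(sum(attr(x, "roles") == "dct"), 7L)
  expect_equal(ncol(x), 16L)

  # cutoff 0 disables the basis
  x0 <- build_design(m, wm, csf, highpass_hz = 0, tr_seconds = 2)
  expect_equal(sum(attr(x0, "roles") == "dct"), 0L)

  # spike columns carry exactly one 1
  fd <- tibble::tibble(frame = seq_len(t_frames),
                       fd = c(rep(0, 9), 0.8, rep(0, t_frames - 10)))
  sp <- spike_matrix(flag_outliers(fd))
  xs <- build_design(m, wm, csf, sp, tr_seconds = 2)
  spike_cols <- xs[, attr(xs, "roles") == "spike", drop = FALSE]
  expect_equal(colSums(spike_cols), 1, ignore_attr = TRUE)

  # duplicated confound columns are pruned with a warning
  expect_warning(build_design(m, wm, wm, tr_seconds = 2), "rank-deficient")
  expect_error(build_design(m, wm[-1], csf, tr_seconds = 2), "frame count")
})

test_that("nuisance regression projects out the design", {
  t_frames <- 60
  m <- matrix(rnorm(t_frames * 6, 0, 0.01), t_frames, 6)
  x <- build_design(m, rnorm(t_frames), rnorm(t_frames), tr_seconds = 2)

  # a series equal to a design column has residual 0
  y1 <- x[, 3, drop = FALSE]
  expect_lt(max(abs(regress_nuisance(y1, x))), 1e-10)

  # residuals orthogonal to every column; variance never increases
  y <- matrix(rnorm(t_frames * 5), t_frames, 5)
  res <- regress_nuisance(y, x)
  expect_lt(max(abs(crossprod(x, res))) / max(abs(y)), 1e-8)
  expect_true(all(apply(res, 2, var) <= apply(y, 2, var) + 1e-12))

  # a series orthogonal to all columns passes through unchanged
  y_perp <- res[, 1, drop = FALSE]
  expect_equal(regress_nuisance(y_perp, x), y_perp, tolerance = 1e-10)
})

test_that("spike regressors zero out flagged frames exactly", {
  t_frames <- 80
  m <- matrix(rnorm(t_frames * 6, 0, 0.005), t_frames, 6)
  m[30, 1] <- m[30, 1] + 2 # big spike
  fd <- compute_fd(m)
  flags <- flag_outliers(fd)
  expect_true(any(flags$outlier))
  sp <- spike_matrix(flags)
  x <- build_design(m, rnorm(t_frames), rnorm(t_frames), sp, tr_seconds = 2)
  y <- matrix(rnorm(t_frames * 4, 100, 2), t_frames, 4)
  res <- regress_nuisance(y, x)
  expect_lt(max(abs(res[flags$frame[flags$outlier], ])), 1e-8)
})

test_that("tSNR is mean over SD with an infinite sentinel", {
  set.seed(7)
  y <- matrix(rnorm(4000, 100, 2), 1000, 4)
  tsnr <- compute_tsnr(y)
  expect_equal(tsnr$tsnr, rep(50, 4), tolerance = 0.1)

  # scale invariance
  expect_equal(compute_tsnr(3 * y)$tsnr, compute_tsnr(y)$tsnr)

  # constant series -> sentinel, never "below 50"
  yc <- cbind(y, const = 7)
  t2 <- compute_tsnr(yc)
  expect_equal(t2$tsnr[5], Inf)
})
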