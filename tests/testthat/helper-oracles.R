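# Independent oracles and small fixture builders used across tests.

# Framewise displacement computed element-by-element from its definition,
# independent of the package's vectorized implementation.
oracle_fd <- function(motion, radius = 50) {
  m <- unclass(motion)
  fd <- numeric(nrow(m))
  for (i in 2:nrow(m)) {
    s <- 0
    for (j in 1:3) s <- s + abs(m[i, j] - m[i - 1, j])
    for (j in 4:6) s <- s + radius * abs(m[i, j] - m[i - 1, j])
    fd[i] <- s
  }
  fd
}

# Exclusion rule recomputed from scratch.
oracle_excluded <- function(motion, thr = 0.5, frac = 0.17, abs_thr = 3) {
  m <- unclass(motion)
  fd <- oracle_fd(m)
  n_out <- sum(fd > thr)
  rel <- sweep(m[, 1:3, drop = FALSE], 2, m[1, 1:3])
  max(abs(rel)) > abs_thr || n_out / nrow(m) > frac
}

# Coordinate-descent elastic net solving
#   (1/(2n)) * RSS + lambda * (alpha * ||b||_1 +
#                              (1-alpha)/(2*l2_sd) * ||b||_2^2)
# with an unpenalized intercept, written independently. `l2_sd` expresses
# the ridge term relative to a response scale (1 for the plain objective;
# the population SD of y for the convention the package documents).
cd_elastic_net <- function(x, y, lambda, alpha = 1, l2_sd = 1, tol = 1e-12,
                           maxit = 100000L) {
  n <- nrow(x)
  p <- ncol(x)
  beta <- rep(0, p)
  b0 <- mean(y)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  xsq <- colSums(x^2) / n
  for (it in seq_len(maxit)) {
    beta_old <- beta
    b0 <- mean(y - x %*% beta)
    for (j in seq_len(p)) {
      r_j <- y - b0 - x[, -j, drop = FALSE] %*% beta[-j]
      z <- sum(x[, j] * r_j) / n
      beta[j] <- soft(z, lambda * alpha) /
        (xsq[j] + lambda * (1 - alpha) / l2_sd)
    }
    if (max(abs(beta - beta_old)) < tol) break
  }
  list(beta = beta, intercept = b0)
}

# Random symmetric signed weighted graph on n nodes.
random_signed_graph <- function(n, seed, density = 0.7) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- ifelse(runif(sum(up)) < density, runif(sum(up), -1, 1), 0)
  w[up] <- vals
  w <- w + t(w)
  w
}

# Tiny cohort + planted-partition membership tibble used by several tests.
planted_membership <- function(config) {
  tibble::tibble(node_id = names(config$planted_partition),
                 subnetwork = unname(config$planted_partition))
}
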