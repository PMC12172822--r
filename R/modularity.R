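# Signed weighted modularity and Louvain-style community detection.
#
# The quality function is the resolution-parametrized modularity with the
# asymmetric positive/negative weighting for signed matrices: positive and
# negative parts each get their own configuration-model null, and the
# negative contribution is down-weighted by v- / (v+ + v-), so positive
# weights dominate. With a non-negative matrix this reduces to ordinary
# Newman-Girvan modularity with resolution gamma.

# Generalized modularity matrix M such that Q(labels) = sum over same-
# community pairs (including the diagonal) of M. Diagonal entries of W are
# ignored (no self-loops).
modularity_matrix <- function(w, gamma = 1, negative = c("asym", "zero")) {
  negative <- match.arg(negative)
  if (!is.matrix(w) || nrow(w) != ncol(w)) abort("`w` must be square.")
  if (max(abs(w - t(w))) > 1e-10) abort("`w` must be symmetric.")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  wp <- pmax(w, 0)
  wn <- -pmin(w, 0)
  if (negative == "zero") wn[] <- 0
  vp <- sum(wp)
  vn <- sum(wn)
  m <- matrix(0, nrow(w), ncol(w))
  if (vp > 0) {
    sp <- rowSums(wp)
    m <- m + (wp - gamma * outer(sp, sp) / vp) / vp
  }
  if (vn > 0) {
    sn <- rowSums(wn)
    m <- m - vn / (vp + vn) * (wn - gamma * outer(sn, sn) / vn) / vn
  }
  dimnames(m) <- dimnames(w)
  m
}

#' Signed weighted modularity of a partition
#'
#' Resolution-parametrized modularity Q of a community assignment on a
#' signed weighted matrix, using the asymmetric positive/negative scheme
#' (negative part down-weighted by its total weight share). Self-weights
#' (the diagonal) are ignored.
#'
#' @param w Symmetric numeric matrix of edge weights (may contain negative
#'   entries, e.g. correlations).
#' @param labels Community labels, one per node.
#' @param gamma Resolution parameter (larger values favour more, smaller
#'   communities).
#' @param negative `"asym"` (default) for the asymmetric signed scheme or
#'   `"zero"` to ignore negative weights.
#' @return The scalar Q.
#' @export
modularity_signed <- function(w, labels, gamma = 1, negative = "asym") {
  if (length(labels) != nrow(w)) abort("One label per node is required.")
  m <- modularity_matrix(w, gamma, negative)
  sum(m[outer(labels, labels, "==")])
}

# One Louvain run on a precomputed generalized modularity matrix.
# `init` seeds the first level's community assignment (default singletons);
# random initial partitions across restarts make every local optimum
# reachable by greedy descent. Returns integer labels 1..k (renumbered in
# order of first appearance).
louvain_core <- function(m, init = NULL) {
  n <- nrow(m)
  node_labels <- seq_len(n) # labels on the original nodes
  mm <- m
  first_level <- TRUE
  repeat {
    nn <- nrow(mm)
    lab <- if (first_level && !is.null(init)) as.integer(init) else seq_len(nn)
    first_level <- FALSE
    improved_any <- FALSE
    # local-move phase
    repeat {
      improved <- FALSE
      for (i in sample.int(nn)) {
        x <- mm[i, ]
        x[i] <- 0
        gains <- rowsum(x, lab)
        comms <- as.integer(rownames(gains))
        cur <- lab[i]
        g_cur <- gains[match(cur, comms), 1]
        best <- which.max(gains[, 1])
        g_best <- gains[best, 1]
        if (max(g_best, 0) > g_cur + 1e-12) {
          # a fresh singleton community has gain 0; take it when every
          # existing community (including the current one) is worse
          lab[i] <- if (g_best > 0) comms[best] else max(lab) + 1L
          improved <- TRUE
          improved_any <- TRUE
        }
      }
      if (!improved) break
    }
    lab <- match(lab, unique(lab))
    k <- max(lab)
    if (!improved_any || k == nn) {
      node_labels <- lab[node_labels]
      break
    }
    # aggregation phase
    f <- factor(lab, levels = seq_len(k))
    mm <- rowsum(t(rowsum(mm, f)), f)
    node_labels <- lab[node_labels]
  }
  match(node_labels, unique(node_labels))
}

#' One Louvain community-detection run
#'
#' Greedy modularity optimization (local node moves followed by community
#' aggregation, repeated until no improvement) on a signed weighted matrix,
#' with randomized sweep order driven by `seed`. `restarts` independent runs
#' are performed and the highest-Q partition returned; on an all-zero matrix
#' the single-community degenerate result is flagged.
#'
#' @inheritParams modularity_signed
#' @param seed Integer seed controlling the randomized node orderings.
#' @param restarts Number of random restarts (best of; default 20).
#' @return List with `labels` (integer vector, named by the matrix dimnames
#'   when present), `q` (modularity), `degenerate` (logical).
#' @export
louvain_partition <- function(w, gamma = 1, seed = 1, restarts = 20,
                              negative = "asym") {
  m <- modularity_matrix(w, gamma, negative)
  n <- nrow(m)
  off <- m
  diag(off) <- 0
  if (all(off == 0)) {
    labels <- rep(1L, n)
    names(labels) <- rownames(w)
    return(list(labels = labels,
                q = modularity_signed(w, labels, gamma, negative),
                degenerate = TRUE))
  }
  best_lab <- NULL
  best_q <- -Inf
  diag_q <- sum(diag(m))
  for (r in seq_len(restarts)) {
    lab <- with_seed(derive_seed(seed, 6L, r), {
      # first restart: classic singleton start; later restarts descend from
      # random initial partitions so no local optimum is unreachable
      init <- if (r == 1) NULL else sample.int(n, n, replace = TRUE)
      louvain_core(m, init)
    })
    q <- sum(off[outer(lab, lab, "==")]) + diag_q
    if (q > best_q + 1e-14) {
      best_q <- q
      best_lab <- lab
    }
  }
  names(best_lab) <- rownames(w)
  list(labels = best_lab, q = best_q, degenerate = FALSE)
}

#' Exhaustive-search modularity optimum (small graphs)
#'
#' Enumerates every set partition of the nodes (restricted-growth strings)
#' and returns the partition maximizing the same signed modularity as
#' [louvain_partition()]. Feasible up to ~12 nodes; intended as an
#' independent oracle for validating heuristic community detection.
#'
#' @inheritParams modularity_signed
#' @param max_nodes Safety cap on the enumeration (default 12).
#' @return List with `labels` and `q`.
#' @export
best_partition_exhaustive <- function(w, gamma = 1, negative = "asym",
                                      max_nodes = 12) {
  n <- nrow(w)
  if (n > max_nodes) abort("Exhaustive search is limited to small graphs.")
  m <- modularity_matrix(w, gamma, negative)
  parts <- all_set_partitions(n)
  qs <- vapply(seq_len(nrow(parts)), function(i) {
    lab <- parts[i, ]
    sum(m[outer(lab, lab, "==")])
  }, numeric(1))
  best <- parts[which.max(qs), ]
  names(best) <- rownames(w)
  list(labels = best, q = max(qs))
}

# All set partitions of n elements as restricted-growth strings
# (one row per partition), memoized per n.
partition_cache <- new.env(parent = emptyenv())
all_set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(partition_cache[[key]])) return(partition_cache[[key]])
  rows <- list(1L)
  if (n > 1) {
    for (i in 2:n) {
      rows <- unlist(lapply(rows, function(r) {
        lapply(seq_len(max(r) + 1L), function(c) c(r, c))
      }), recursive = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  partition_cache[[key]] <- out
  out
}

# Optimal injective matching of run communities onto reference communities,
# maximizing total overlap of the contingency table. Exact (permutation
# enumeration over the smaller side) for up to 7 communities, greedy beyond.
match_communities <- function(run_labels, ref_labels) {
  ct <- table(run_labels, ref_labels)
  kr <- nrow(ct)
  kf <- ncol(ct)
  run_ids <- as.integer(rownames(ct))
  ref_ids <- as.integer(colnames(ct))
  map <- rep(NA_integer_, max(run_labels))
  if (min(kr, kf) <= 7 && max(kr, kf) <= 9) {
    if (kr <= kf) {
      perms <- permutations_of(seq_len(kf), kr)
      scores <- vapply(perms, function(p) sum(ct[cbind(seq_len(kr), p)]),
                       numeric(1))
      p <- perms[[which.max(scores)]]
      map[run_ids] <- ref_ids[p]
    } else {
      perms <- permutations_of(seq_len(kr), kf)
      scores <- vapply(perms, function(p) sum(ct[cbind(p, seq_len(kf))]),
                       numeric(1))
      p <- perms[[which.max(scores)]]
      map[run_ids[p]] <- ref_ids
    }
  } else {
    # greedy fallback for many communities
    ctw <- ct
    repeat {
      if (all(ctw < 0)) break
      ij <- arrayInd(which.max(ctw), dim(ctw))
      if (ctw[ij] < 0) break
      map[run_ids[ij[1]]] <- ref_ids[ij[2]]
      ctw[ij[1], ] <- -1
      ctw[, ij[2]] <- -1
      if (all(ctw < 0)) break
    }
  }
  map
}

# All ordered selections (permutations) of `k` elements from `v`.
permutations_of <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i], k - 1)
    out <- c(out, lapply(rest, function(p) c(v[i], p)))
  }
  out
}

#' Consensus community detection over a Louvain ensemble
#'
#' Runs [louvain_partition()] `iterations` times (iteration i uses seed
#' `seed + i` internally), takes the maximum-Q run as the reference
#' partition, matches every run's communities to the reference communities
#' by optimal one-to-one maximal-overlap assignment, and computes each
#' node's stability: the fraction of runs placing it in its matched
#' reference community. Nodes with stability below `stability_threshold`
#' (strictly) are marked removed, mirroring the rule that nodes assigned to
#' a network in less than 40% of iterations are dropped.
#'
#' @inheritParams louvain_partition
#' @param iterations Ensemble size (default 1000).
#' @param stability_threshold Minimum stability fraction (default 0.40).
#' @param restarts Random restarts inside each Louvain run.
#' @return Object of class `partition_ensemble`: list with `consensus`
#'   (tibble `node_id`, `community`, `stability`, `removed`), `assignments`
#'   (iterations x N matrix), `q_values`, `gamma`, `stability_threshold`,
#'   `reference_run`.
#' @export
consensus_partition <- function(w, gamma = 1, iterations = 1000,
                                stability_threshold = 0.40, seed = 1,
                                restarts = 20, negative = "asym") {
  if (iterations < 1) abort("`iterations` must be at least 1.")
  n <- nrow(w)
  assignments <- matrix(NA_integer_, iterations, n)
  q_values <- numeric(iterations)
  for (i in seq_len(iterations)) {
    run <- louvain_partition(w, gamma, seed = seed + i, restarts = restarts,
                             negative = negative)
    assignments[i, ] <- run$labels
    q_values[i] <- run$q
  }
  ref_idx <- which.max(q_values)
  ref <- assignments[ref_idx, ]
  if (length(unique(ref)) < 2) {
    warn("Consensus reference partition has fewer than 2 communities.")
  }
  agree <- matrix(0, iterations, n)
  for (i in seq_len(iterations)) {
    map <- match_communities(assignments[i, ], ref)
    agree[i, ] <- !is.na(map[assignments[i, ]]) &
      map[assignments[i, ]] == ref
  }
  stability <- colMeans(agree)
  ids <- rownames(w)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(n))
  consensus <- tibble::tibble(
    node_id = ids,
    community = ref,
    stability = stability,
    removed = stability < stability_threshold
  )
  structure(list(
    consensus = consensus, assignments = assignments, q_values = q_values,
    gamma = gamma, stability_threshold = stability_threshold,
    reference_run = ref_idx
  ), class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  k <- length(unique(x$consensus$community))
  cat(sprintf(
    "Consensus partition: %d nodes, %d communities (gamma = %g, %d iterations)\n",
    nrow(x$consensus), k, x$gamma, length(x$q_values)))
  cat(sprintf("  max Q = %.4f; %d node(s) below stability %.2f\n",
              max(x$q_values), sum(x$consensus$removed),
              x$stability_threshold))
  invisible(x)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the mean of the two label entropies;
#' 1 for identical partitions (up to relabeling), 0 for independent ones.
#' Pairs where either labeling is `NA` (e.g. removed nodes) are dropped.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have the same length.")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (!length(a)) abort("No overlapping labeled nodes.")
  n <- length(a)
  ct <- table(a, b) / n
  pa <- rowSums(ct)
  pb <- colSums(ct)
  nz <- ct > 0
  mi <- sum(ct[nz] * log(ct[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- (ha + hb) / 2
  if (denom == 0) return(1) # both single-label: identical partitions
  max(0, min(1, mi / denom))
}
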