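# Independent oracles used by the unit and acceptance tests. Each one is a
# deliberately naive computation (enumeration, constrained least squares,
# eigendecomposition) kept separate from the implementation path it checks.

# AUROC by explicit pairwise comparison of every positive-negative pair.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision by a stepwise sweep over distinct score thresholds,
# accumulating (delta recall) x precision.
oracle_auprc <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  recall_prev <- 0
  for (th in thresholds) {
    called <- scores >= th
    precision <- sum(labels[called] == 1) / sum(called)
    recall <- sum(labels[called] == 1) / n_pos
    ap <- ap + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  ap
}

# Global alignment score with linear gap costs (iterative Needleman-Wunsch
# on character vectors), used by the local-alignment oracle below.
oracle_nw_global <- function(a, b, match, mismatch, gap) {
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- -gap * (0:n)
  D[1, ] <- -gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- max(
        D[i, j] + if (a[i] == b[j]) match else mismatch,
        D[i, j + 1] - gap,
        D[i + 1, j] - gap)
    }
  }
  D[n + 1, m + 1]
}

# Smith-Waterman oracle: exhaustive maximum of global alignment scores over
# all substring pairs (O(n^2 m^2) enumerations); linear gaps only.
oracle_sw <- function(seq_a, seq_b, match, mismatch, gap) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  best <- 0
  for (i1 in seq_along(a)) for (i2 in i1:length(a)) {
    for (j1 in seq_along(b)) for (j2 in j1:length(b)) {
      best <- max(best, oracle_nw_global(a[i1:i2], b[j1:j2],
                                         match, mismatch, gap))
    }
  }
  best
}

# Minimizer of ||G - V||_F over {V : sym(X'V) = 0} by explicit linearly
# constrained least squares: project vec(G) onto the null space of the
# constraint matrix.
oracle_tangent_ls <- function(X, G) {
  n <- nrow(X); R <- ncol(X)
  pairs <- which(upper.tri(diag(R), diag = TRUE), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), n * R)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    C <- matrix(0, n, R)
    C[, j] <- C[, j] + X[, i]
    C[, i] <- C[, i] + X[, j]
    A[r, ] <- as.vector(C) / 2
  }
  v <- as.vector(G)
  v_proj <- v - t(A) %*% solve(A %*% t(A), A %*% v)
  matrix(v_proj, n, R)
}

# Rayleigh-quotient test problem on St(n, R): f(X) = tr(X' A X).
rayleigh_problem <- function(A) {
  list(f = function(X) sum(diag(crossprod(X, A %*% X))),
       grad = function(X) 2 * A %*% X,
       optimum = function(R) sum(sort(eigen(A, symmetric = TRUE,
                                            only.values = TRUE)$values)[1:R]))
}

# Central finite difference of f along direction V at X.
fd_directional <- function(f, X, V, h = 1e-5) {
  (f(X + h * V) - f(X - h * V)) / (2 * h)
}

# Small dense network with every score observed, for gradient tests.
toy_network <- function(n_d = 3, n_t = 2, seed = 1) {
  set.seed(seed)
  A <- matrix(rbinom(n_d * n_t, 1, 0.5), n_d, n_t)
  if (sum(A) == 0) A[1, 1] <- 1
  rand_sim <- function(n) {
    S <- matrix(runif(n * n, 0.1, 0.9), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    S
  }
  dti_network(A, rand_sim(n_d), rand_sim(n_t))
}

# Fit validity: non-increasing outer-loss trace and Stiefel feasibility of
# both blocks at every recorded outer iteration.
expect_valid_fit <- function(emb) {
  expect_true(all(diff(emb$trace$loss) <= 1e-10))
  expect_lt(max(emb$trace$stiefel_dev_drugs), 1e-10)
  expect_lt(max(emb$trace$stiefel_dev_targets), 1e-10)
  invisible(emb)
}

# Row-wise label shuffle: independently permutes each drug's target labels,
# destroying the drug-target coupling while preserving per-drug degree.
shuffle_labels <- function(network, seed = 99) {
  A <- network$adjacency
  set.seed(seed)
  A_shuf <- t(apply(A, 1, sample))
  dimnames(A_shuf) <- dimnames(A)
  dti_network(A_shuf, network$sim_drugs, network$sim_targets)
}
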