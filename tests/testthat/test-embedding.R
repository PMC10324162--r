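# The kernel-preserving objective, its gradients, alternating training, and
# out-of-sample embedding.

test_that("gaussian_kernel closed-form values", {
  expect_identical(gaussian_kernel(c(1, 2), c(1, 2), 0.7), 1)
  sigma <- 1.3
  x <- c(0, 0); y <- c(sigma * sqrt(2), 0)
  expect_equal(gaussian_kernel(x, y, sigma), exp(-1), tolerance = 1e-12)
  expect_equal(gaussian_kernel(c(0, 0), c(3, 4), 5), exp(-0.5),
               tolerance = 1e-12)
  expect_error(gaussian_kernel(1, 1, 0), "positive")
  expect_error(gaussian_kernel(c(1, 2), c(1, 2, 3), 1), "mismatch")
})

test_that("objective is a masked sum of squared kernel residuals", {
  # all-NA scores: empty sum
  net <- dti_network(matrix(0, 2, 2),
                     matrix(c(1, NA, NA, 1), 2),
                     matrix(c(1, NA, NA, 1), 2))
  cfg <- embedding_config(R = 2, seed = 1)
  X_d <- random_stiefel(2, 2, seed = 1)
  X_t <- random_stiefel(2, 2, seed = 2)
  expect_identical(kpe_objective(X_d, X_t, net, cfg), 0)

  # a single observed cross pair whose kernel equals the score exactly
  sigma <- 1
  d <- sqrt(-2 * sigma^2 * log(0.9))
  net1 <- dti_network(matrix(c(1, 0), 1, 2),
                      matrix(1, 1, 1),
                      matrix(c(1, NA, NA, 1), 2))
  cfg1 <- embedding_config(R = 1, sigma = sigma, seed = 1)
  expect_equal(kpe_objective(matrix(1, 1, 1),
                             matrix(c(1 - d, 0), 2, 1), net1, cfg1),
               0, tolerance = 1e-14)
})

test_that("objective equals a hand-expanded three-term sum", {
  # 2 drugs, 1 target, R = 2, everything observed
  A <- matrix(c(1, 0), 2, 1)
  sd_ <- matrix(c(1, 0.6, 0.6, 1), 2)
  st_ <- matrix(1, 1, 1)
  net <- dti_network(A, sd_, st_)
  sig <- c(cross = 0.8, drug = 1.1, target = 0.9)
  cfg <- embedding_config(R = 2, sigma = sig, lambda_d = 2, lambda_t = 3,
                          seed = 1)
  X_d <- matrix(c(1, 0, 0, 1), 2, 2)      # identity: a valid St(2,2) point
  X_t <- matrix(c(0.6, 0.8), 1, 2)        # unit row: St(1,2) transpose-wise
  # hand expansion
  k_c1 <- exp(-sum((X_d[1, ] - X_t[1, ])^2) / (2 * sig["cross"]^2))
  k_d <- exp(-sum((X_d[1, ] - X_d[2, ])^2) / (2 * sig["drug"]^2))
  manual <- (0.9 - k_c1)^2 + 2 * (0.6 - k_d)^2  # target self-pair excluded
  expect_equal(kpe_objective(X_d, X_t, net, cfg), unname(manual),
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences (both phases)", {
  net <- toy_network(3, 2, seed = 5)
  cfg <- embedding_config(R = 2, seed = 2)
  X_d <- random_stiefel(3, 2, seed = 3)
  X_t <- random_stiefel(2, 2, seed = 4)

  G_d <- kpe_gradient_drugs(X_d, X_t, net, cfg)
  G_t <- kpe_gradient_targets(X_d, X_t, net, cfg)
  f_d <- function(X) kpe_objective(X, X_t, net, cfg)
  f_t <- function(X) kpe_objective(X_d, X, net, cfg)

  set.seed(6)
  for (k in 1:10) {
    V <- matrix(rnorm(6), 3, 2); V <- V / sqrt(sum(V^2))
    fd <- fd_directional(f_d, X_d, V)
    expect_equal(sum(G_d * V), fd, tolerance = 1e-5 * max(1, abs(fd)))
    W <- matrix(rnorm(4), 2, 2); W <- W / sqrt(sum(W^2))
    fd_t <- fd_directional(f_t, X_t, W)
    expect_equal(sum(G_t * W), fd_t, tolerance = 1e-5 * max(1, abs(fd_t)))
  }
})

test_that("gradient is zero at an exact fit and translation-invariant within domains", {
  # zero-loss configuration: single cross pair at kernel 0.9, no within terms
  sigma <- 1
  d <- sqrt(-2 * sigma^2 * log(0.9))
  net1 <- dti_network(matrix(c(1, 0), 1, 2),
                      matrix(1, 1, 1),
                      matrix(c(1, NA, NA, 1), 2))
  cfg1 <- embedding_config(R = 1, sigma = sigma, lambda_d = 0, lambda_t = 0,
                           seed = 1)
  X_d <- matrix(1, 1, 1)
  X_t <- matrix(c(1 - d, 0), 2, 1)
  expect_lt(max(abs(kpe_gradient_drugs(X_d, X_t, net1, cfg1))), 1e-12)
  expect_lt(max(abs(kpe_gradient_targets(X_d, X_t, net1, cfg1))), 1e-12)

  # within-domain-only loss: pairwise distances are translation invariant,
  # so gradient rows must sum to zero
  net <- toy_network(4, 3, seed = 9)
  net$adjacency[] <- 0   # no cross term
  net <- dti_network(net$adjacency, net$sim_drugs, net$sim_targets)
  cfg <- embedding_config(R = 2, seed = 1)
  G <- kpe_gradient_drugs(random_stiefel(4, 2, seed = 1),
                          random_stiefel(3, 2, seed = 2), net, cfg)
  expect_lt(max(abs(colSums(G))), 1e-12)
})

test_that("kpe_fit is monotone, feasible, deterministic, and obeys outer_iters", {
  sim <- simulate_dti_network(n_drugs = 20, n_targets = 10, r_true = 3,
                              interaction_quantile = 0.1, seed = 2)
  cfg <- embedding_config(R = 3, outer_iters = 4, seed = 5)
  emb <- kpe_fit(sim$network, cfg)
  expect_valid_fit(emb)
  expect_lte(emb$loss, emb$trace$loss[1])

  emb2 <- kpe_fit(sim$network, cfg)
  expect_identical(emb$loss, emb2$loss)
  expect_identical(emb$X_d, emb2$X_d)
  expect_identical(emb$X_t, emb2$X_t)

  cfg1 <- embedding_config(R = 3, outer_iters = 1, seed = 5)
  emb1 <- kpe_fit(sim$network, cfg1)
  expect_identical(nrow(emb1$trace), 2L)  # init row + one outer iteration
  expect_false(is.na(emb1$trace$inner_iters_drugs[2]))
  expect_false(is.na(emb1$trace$inner_iters_targets[2]))
})

test_that("fit recovers a self-consistent planted network (low final loss)", {
  sim <- simulate_dti_network(n_drugs = 20, n_targets = 10, r_true = 3,
                              interaction_quantile = 0.1, seed = 2)
  emb <- kpe_fit(sim$network, embedding_config(R = 3, seed = 5))
  expect_lt(emb$loss, 0.1 * emb$trace$loss[1])
  expect_valid_fit(emb)
})

test_that("training loss improves as R grows toward the planted dimension", {
  # Orthonormal coordinate blocks are NOT nested across R (every extra
  # column carries unit norm and adds inter-point distance), so training
  # loss is not monotone beyond the planted dimensionality; what does hold
  # is that expressiveness improves up to R_true. See the vignette.
  sim <- simulate_dti_network(n_drugs = 20, n_targets = 10, r_true = 3,
                              interaction_quantile = 0.1, seed = 2)
  losses <- vapply(2:3, function(R) {
    kpe_fit(sim$network, embedding_config(R = R, seed = 5))$loss
  }, numeric(1))
  expect_lt(losses[2], losses[1])
})

test_that("isolated objects trigger a loud warning", {
  A <- matrix(0, 3, 2); A[1, 1] <- 1
  sd_ <- diag(3); sd_[sd_ == 0] <- NA    # no observed drug-drug pairs
  sd_[1, 2] <- sd_[2, 1] <- 0.5
  st_ <- matrix(c(1, 0.4, 0.4, 1), 2)
  net <- dti_network(A, sd_, st_)
  cfg <- embedding_config(R = 1, outer_iters = 2, seed = 3)
  expect_warning(emb <- kpe_fit(net, cfg), "no observed scores")
  expect_valid_fit(emb)
})

test_that("embed_new_drug reproduces a training drug from its kernel profile", {
  sim <- simulate_dti_network(n_drugs = 20, n_targets = 10, r_true = 3,
                              interaction_quantile = 0.1, seed = 2)
  emb <- kpe_fit(sim$network, embedding_config(R = 3, seed = 5))
  sigma <- emb$sigma[["drug"]]
  kernel_profile <- function(x) {
    exp(-colSums((t(emb$X_d) - x)^2) / (2 * sigma^2))
  }
  for (i in c(1, 7, 20)) {
    prof <- kernel_profile(emb$X_d[i, ])
    x_star <- embed_new_drug(emb, prof)
    expect_lt(max(abs(kernel_profile(x_star) - prof)), 1e-3)
  }
})

test_that("embed_new_drug degenerate profiles behave as documented", {
  sim <- simulate_dti_network(n_drugs = 12, n_targets = 6, r_true = 2,
                              interaction_quantile = 0.15, seed = 4)
  emb <- kpe_fit(sim$network, embedding_config(R = 2, outer_iters = 5, seed = 1))

  # single observed similarity of 1.0 to drug i forces coincidence
  prof <- rep(NA_real_, 12)
  prof[4] <- 1
  x_star <- embed_new_drug(emb, prof)
  expect_gte(gaussian_kernel(x_star, emb$X_d[4, ], emb$sigma[["drug"]]), 0.999)

  # uniform profile over two drugs lands equidistant from both
  prof2 <- rep(NA_real_, 12)
  prof2[c(2, 9)] <- 0.5
  x2 <- embed_new_drug(emb, prof2)
  expect_equal(sum((x2 - emb$X_d[2, ])^2), sum((x2 - emb$X_d[9, ])^2),
               tolerance = 1e-6)

  expect_error(embed_new_drug(emb, rep(NA_real_, 12)), "no observed")
  expect_error(embed_new_drug(emb, rep(0.5, 5)), "length")
})

test_that("predict_pair_scores ranks exactly as negative Euclidean distance", {
  sim <- simulate_dti_network(n_drugs = 12, n_targets = 6, r_true = 2,
                              interaction_quantile = 0.15, seed = 4)
  emb <- kpe_fit(sim$network, embedding_config(R = 2, outer_iters = 3, seed = 1))

  # drug vector placed exactly on a target row scores 1 for that target
  v <- emb$X_t[3, ]
  s <- predict_pair_scores(v, emb)
  expect_equal(unname(s[1, 3]), 1, tolerance = 1e-12)

  set.seed(10)
  vecs <- matrix(rnorm(10), 5, 2)
  scores <- predict_pair_scores(vecs, emb)
  for (i in 1:5) {
    d2 <- colSums((t(emb$X_t) - vecs[i, ])^2)
    expect_identical(order(scores[i, ], decreasing = TRUE), order(d2))
  }

  empty <- predict_pair_scores(matrix(numeric(0), 0, 2), emb)
  expect_identical(dim(empty), c(0L, 6L))
})
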