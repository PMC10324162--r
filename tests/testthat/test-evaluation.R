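# Fold plans, masking, ranking metrics, cross-validation, novel-pair ranking.

test_that("make_fold_plan partitions drugs into near-equal folds", {
  plan <- make_fold_plan(10, folds = 10, reps = 1, seed = 1)
  expect_length(plan, 10L)
  sizes <- vapply(plan, function(p) length(p$test), integer(1))
  expect_true(all(sizes == 1L))
  expect_setequal(unlist(lapply(plan, `[[`, "test")), 1:10)

  plan2 <- make_fold_plan(54, folds = 10, reps = 10, seed = 2)
  expect_length(plan2, 100L)
  for (r in 1:10) {
    recs <- Filter(function(p) p$replication == r, plan2)
    sizes <- vapply(recs, function(p) length(p$test), integer(1))
    expect_true(all(sizes %in% c(5L, 6L)))
    expect_setequal(unlist(lapply(recs, `[[`, "test")), 1:54)
    for (p in recs) expect_length(intersect(p$test, p$train), 0L)
  }

  expect_identical(make_fold_plan(20, 4, 2, seed = 7),
                   make_fold_plan(20, 4, 2, seed = 7))
  expect_error(make_fold_plan(5, folds = 6), "more folds")
})

test_that("mask_network_for_fold excludes test drugs completely and round-trips", {
  net <- toy_network(5, 3, seed = 11)
  plan <- make_fold_plan(5, folds = 5, reps = 1, seed = 3)
  rec <- plan[[2]]
  sp <- mask_network_for_fold(net, rec)

  expect_identical(dim(sp$train$sim_drugs), c(4L, 4L))
  expect_identical(dim(sp$test_profiles), c(1L, 4L))
  expect_length(intersect(sp$train$drug_ids, sp$test_ids), 0L)

  # reconstruction: merging train + held-out rows reproduces the original
  A <- matrix(0L, 5, 3, dimnames = dimnames(net$adjacency))
  A[rec$train, ] <- sp$train$adjacency
  A[rec$test, ] <- sp$test_labels
  expect_identical(A + 0, net$adjacency + 0)
  S <- net$sim_drugs
  expect_identical(S[rec$train, rec$train], sp$train$sim_drugs)
  expect_identical(S[rec$test, rec$train, drop = FALSE], sp$test_profiles)

  expect_error(mask_network_for_fold(net, list(test = 1:5, train = integer(0))),
               "empty training set")
})

test_that("auroc matches hand counts and the pairwise oracle", {
  expect_identical(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_identical(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "single class")

  set.seed(41)
  for (k in 1:50) {
    n <- sample(5:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_identical(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("auprc matches hand evaluation and the step-integration oracle", {
  expect_identical(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  n <- 8
  s <- seq(1, 0.1, length.out = n)
  l <- c(rep(0, n - 1), 1)             # single positive ranked last
  expect_equal(auprc(s, l), 1 / n, tolerance = 1e-15)
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), (1 + 2 / 3) / 2,
               tolerance = 1e-15)
  expect_error(auprc(c(0.3, 0.2), c(0, 0)), "no positive")

  set.seed(43)
  for (k in 1:50) {
    n <- sample(5:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) next
    expect_equal(auprc(scores, labels), oracle_auprc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under permutation of tied scores", {
  set.seed(47)
  scores <- rep(c(0.3, 0.7), each = 5)
  labels <- c(1, 0, 0, 1, 0, 1, 1, 0, 0, 1)
  perm <- sample(10)
  expect_identical(auroc(scores, labels), auroc(scores[perm], labels[perm]))
  expect_identical(auprc(scores, labels), auprc(scores[perm], labels[perm]))
})

test_that("cross_validate wires folds, metrics and determinism together", {
  sim <- simulate_dti_network(n_drugs = 10, n_targets = 6, r_true = 2,
                              interaction_quantile = 0.2, seed = 6)
  cfg <- embedding_config(R = 2, outer_iters = 3, seed = 1)
  cv <- cross_validate(sim$network, cfg, folds = 2, reps = 1, seed = 5)
  expect_identical(nrow(cv$results), 2L)
  expect_true(all(cv$results$auroc >= 0 & cv$results$auroc <= 1, na.rm = TRUE))
  expect_true(all(cv$results$n_pos + cv$results$n_neg ==
                    5L * 6L))
  cv2 <- cross_validate(sim$network, cfg, folds = 2, reps = 1, seed = 5)
  expect_identical(cv$results, cv2$results)

  # kernel-score ranking and (negative) distance ranking give identical AUROC
  sp <- mask_network_for_fold(sim$network,
                              make_fold_plan(10, 2, 1, seed = 5)[[1]])
  emb <- kpe_fit(sp$train, cfg)
  vecs <- t(vapply(seq_len(nrow(sp$test_profiles)),
                   function(j) embed_new_drug(emb, sp$test_profiles[j, ]),
                   numeric(2)))
  k_scores <- as.vector(predict_pair_scores(vecs, emb))
  d2 <- as.vector(kpembed:::cross_sqdist(vecs, emb$X_t))
  labels <- as.vector(sp$test_labels)
  if (length(unique(labels)) == 2) {
    expect_identical(auroc(k_scores, labels), auroc(-d2, labels))
  }
})

test_that("rank_novel_pairs returns sorted novel pairs only", {
  # hand-built embedding: one non-interacting pair coincides exactly
  A <- matrix(0, 3, 2, dimnames = list(c("d1", "d2", "d3"), c("t1", "t2")))
  A[1, 1] <- 1
  X_d <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  X_t <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)  # t1 == d2 position
  emb <- structure(list(X_d = X_d, X_t = X_t,
                        sigma = c(cross = 1, drug = 1, target = 1),
                        drug_ids = rownames(A), target_ids = colnames(A)),
                   class = "kpe_embedding")
  net <- dti_network(A, diag(3), diag(2))
  res <- rank_novel_pairs(emb, net, k = 3)
  expect_identical(res$drug_id[1], "d2")
  expect_identical(res$target_id[1], "t1")
  expect_identical(res$distance[1], 0)
  expect_true(all(diff(res$distance) >= 0))
  # known interacting pair never appears
  expect_false(any(res$drug_id == "d1" & res$target_id == "t1"))

  # k larger than the number of novel pairs returns all, with a message
  expect_message(all_pairs <- rank_novel_pairs(emb, net, k = 100),
                 "returning all")
  expect_identical(nrow(all_pairs), 5L)
})

test_that("rank_novel_pairs is deterministic under ties", {
  A <- matrix(0, 2, 2, dimnames = list(c("dA", "dB"), c("tA", "tB")))
  X_d <- diag(2)
  X_t <- diag(2)[2:1, ]   # both cross pairs at equal distances
  emb <- structure(list(X_d = X_d, X_t = X_t,
                        sigma = c(cross = 1, drug = 1, target = 1),
                        drug_ids = rownames(A), target_ids = colnames(A)),
                   class = "kpe_embedding")
  net <- dti_network(A, diag(2), diag(2))
  res <- rank_novel_pairs(emb, net, k = 4)
  # ties broken lexicographically by (drug id, target id)
  tied <- res[res$distance == res$distance[1], ]
  expect_identical(tied$drug_id, sort(tied$drug_id))
})
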