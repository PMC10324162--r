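# Drug-wise (cold-start) cross-validation, AUROC/AUPRC, and ranking of
# novel interactions by embedded Euclidean distance.

#' Drug-wise cross-validation fold plan
#'
#' Per replication, a uniformly random partition of the drugs into folds of
#' near-equal size (sizes differ by at most one). The fold RNG stream is
#' local to this function, so plans are reproducible independently of any
#' model-initialization seed.
#'
#' @param n_drugs number of drugs.
#' @param folds number of folds (`<= n_drugs`).
#' @param reps number of replications.
#' @param seed integer seed.
#' @return list of records, each with `replication`, `fold`, `test`
#'   (drug indices) and `train` fields.
#' @export
make_fold_plan <- function(n_drugs, folds = 10L, reps = 10L, seed = 1L) {
  if (folds > n_drugs) {
    stop("more folds than drugs", call. = FALSE)
  }
  with_seed(seed, {
    plan <- list()
    for (r in seq_len(reps)) {
      perm <- sample.int(n_drugs)
      fold_of <- rep(seq_len(folds), length.out = n_drugs)
      for (k in seq_len(folds)) {
        test <- sort(perm[fold_of == k])
        plan[[length(plan) + 1L]] <- list(replication = r, fold = k,
                                          test = test,
                                          train = setdiff(seq_len(n_drugs), test))
      }
    }
    plan
  })
}

#' Hold out the test drugs of one fold
#'
#' Test drugs are excluded from training entirely: their adjacency rows and
#' their similarity rows AND columns are removed from the training network.
#' What remains available at test time is each held-out drug's similarity
#' profile to the training drugs (the input of out-of-sample embedding) and
#' its held-out adjacency row (the labels).
#'
#' @param network a [dti_network()].
#' @param plan_record one element of [make_fold_plan()].
#' @return list with `train` (a [dti_network()] over the training drugs),
#'   `test_profiles` (n_test x n_train similarity matrix), `test_labels`
#'   (n_test x N_t binary matrix) and `test_ids`.
#' @export
mask_network_for_fold <- function(network, plan_record) {
  test <- plan_record$test
  train <- plan_record$train
  if (length(train) == 0L) stop("empty training set", call. = FALSE)
  train_net <- dti_network(
    adjacency = network$adjacency[train, , drop = FALSE],
    sim_drugs = network$sim_drugs[train, train, drop = FALSE],
    sim_targets = network$sim_targets,
    drug_ids = network$drug_ids[train],
    target_ids = network$target_ids)
  list(train = train_net,
       test_profiles = network$sim_drugs[test, train, drop = FALSE],
       test_labels = network$adjacency[test, , drop = FALSE],
       test_ids = network$drug_ids[test])
}

#' Area under the ROC curve
#'
#' Tie-corrected concordance probability (the Mann-Whitney formulation):
#' `P(score_pos > score_neg) + P(score_pos = score_neg) / 2`, computed via
#' mid-ranks, so the result is invariant under permutations of tied scores.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1) of the same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  check_metric_input(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC undefined: labels contain a single class", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration equivalent to average precision: each positive
#' contributes the precision at its rank, divided by the number of
#' positives. Tied scores are handled as a block — every positive in a tied
#' block contributes the precision evaluated at the end of the block — so
#' the result is invariant under permutations of tied scores.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  check_metric_input(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) {
    stop("AUPRC undefined: no positive labels", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # block boundaries: last index of each run of tied scores
  block_end <- which(c(s[-1] != s[-length(s)], TRUE))
  cum_tp <- cumsum(y)
  tp_at_end <- cum_tp[block_end]
  prec_at_end <- tp_at_end / block_end
  tp_in_block <- diff(c(0, tp_at_end))
  sum(tp_in_block * prec_at_end) / n_pos
}

#' @noRd
check_metric_input <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) == 0L) {
    stop("scores and labels must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("scores must be numeric and labels binary, without missing values",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Drug-wise cross-validation of the embedding
#'
#' For each fold of each replication: fit the embedding on the training
#' network (test drugs fully excluded), embed every test drug out-of-sample
#' from its similarity profile to the training drugs, score all test-drug x
#' target pairs with the cross-domain kernel, and compute one AUROC and one
#' AUPRC over the pooled pairs of the fold. Folds whose test pairs contain a
#' single label class yield `NA` metrics, are excluded from the averages,
#' and are reported with a warning.
#'
#' The per-fold model seed is derived deterministically from `config$seed`
#' and the fold indices; the fold-plan seed is separate, so CV plans are
#' stable across model or optimizer changes.
#'
#' @param network a [dti_network()].
#' @param config an [embedding_config()].
#' @param folds,reps protocol size; the published protocol is 10 x 10.
#' @param seed seed of the fold plan.
#' @return list of class `kpe_cv` with `results` (one row per fold:
#'   replication, fold, auroc, auprc, n_pos, n_neg) and `summary` (means and
#'   standard deviations, both over all folds and over replication means).
#' @export
cross_validate <- function(network, config, folds = 10L, reps = 10L,
                           seed = 1L) {
  plan <- make_fold_plan(length(network$drug_ids), folds, reps, seed)
  rows <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    rec <- plan[[i]]
    sp <- mask_network_for_fold(network, rec)
    fold_config <- config
    fold_config$seed <- (config$seed + 7919L * rec$replication +
                           104729L * rec$fold) %% 2147483647L
    emb <- kpe_fit(sp$train, fold_config)
    vecs <- t(vapply(seq_along(rec$test), function(j) {
      embed_new_drug(emb, sp$test_profiles[j, ])
    }, numeric(config$R)))
    scores <- as.vector(predict_pair_scores(vecs, emb))
    labels <- as.vector(sp$test_labels)
    n_pos <- sum(labels == 1)
    n_neg <- sum(labels == 0)
    if (n_pos == 0L || n_neg == 0L) {
      warning(sprintf(
        "replication %d fold %d has a single label class; metrics recorded as NA",
        rec$replication, rec$fold), call. = FALSE)
      roc <- pr <- NA_real_
    } else {
      roc <- auroc(scores, labels)
      pr <- auprc(scores, labels)
    }
    rows[[i]] <- data.frame(replication = rec$replication, fold = rec$fold,
                            auroc = roc, auprc = pr,
                            n_pos = n_pos, n_neg = n_neg)
  }
  results <- do.call(rbind, rows)
  rep_means <- stats::aggregate(results[c("auroc", "auprc")],
                                by = list(replication = results$replication),
                                FUN = mean, na.rm = TRUE)
  summary <- data.frame(
    metric = rep(c("auroc", "auprc"), each = 2),
    over = rep(c("folds", "replication_means"), times = 2),
    mean = c(mean(results$auroc, na.rm = TRUE),
             mean(rep_means$auroc),
             mean(results$auprc, na.rm = TRUE),
             mean(rep_means$auprc)),
    sd = c(stats::sd(results$auroc, na.rm = TRUE),
           stats::sd(rep_means$auroc),
           stats::sd(results$auprc, na.rm = TRUE),
           stats::sd(rep_means$auprc)))
  structure(list(results = results, summary = summary), class = "kpe_cv")
}

#' @export
print.kpe_cv <- function(x, ...) {
  m <- x$summary[x$summary$over == "folds", ]
  cat(sprintf("kpe_cv: %d folds; AUROC %.3f (sd %.3f), AUPRC %.3f (sd %.3f)\n",
              nrow(x$results),
              m$mean[m$metric == "auroc"], m$sd[m$metric == "auroc"],
              m$mean[m$metric == "auprc"], m$sd[m$metric == "auprc"]))
  invisible(x)
}

#' Rank novel interactions by embedded Euclidean distance
#'
#' On an embedding trained on the full network, all drug-target pairs
#' without a known interaction are sorted by ascending Euclidean distance
#' between the embedded points; the closest pairs are the strongest novel
#' candidates. Ties are broken lexicographically by (drug id, target id) so
#' the ranking is fully deterministic.
#'
#' @param emb a [kpe_fit()] result trained on `network`.
#' @param network the [dti_network()] whose known interactions are excluded.
#' @param k number of top-ranked pairs to return (default 25); if fewer
#'   non-interacting pairs exist, all are returned with a message.
#' @return data frame with columns `drug_id`, `target_id`, `distance`,
#'   `rank`.
#' @export
rank_novel_pairs <- function(emb, network, k = 25L) {
  stopifnot(inherits(emb, "kpe_embedding"), inherits(network, "dti_network"))
  if (!identical(emb$drug_ids, network$drug_ids) ||
      !identical(emb$target_ids, network$target_ids)) {
    stop("embedding and network identifier lists differ", call. = FALSE)
  }
  D <- sqrt(cross_sqdist(emb$X_d, emb$X_t))
  novel <- which(network$adjacency == 0, arr.ind = TRUE)
  df <- data.frame(drug_id = network$drug_ids[novel[, 1]],
                   target_id = network$target_ids[novel[, 2]],
                   distance = D[novel])
  ord <- order(df$distance, df$drug_id, df$target_id)
  df <- df[ord, , drop = FALSE]
  if (k > nrow(df)) {
    message(sprintf("only %d non-interacting pairs available; returning all",
                    nrow(df)))
    k <- nrow(df)
  }
  df <- df[seq_len(k), , drop = FALSE]
  df$rank <- seq_len(k)
  rownames(df) <- NULL
  df
}
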