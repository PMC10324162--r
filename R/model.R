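# The embedding core: a kernel-preserving objective over two Stiefel
# manifolds, alternating training, and out-of-sample embedding of unseen
# drugs.
#
# Drugs and targets get coordinate blocks X_d (N_d x R) and X_t (N_t x R),
# each constrained to a Stiefel manifold. The loss sums squared differences
# between observed scores and Gaussian kernel values of the embedded points:
#
#   L = sum_{(i,j) obs} (s_c[i,j] - k(x_i, z_j))^2
#     + lambda_d * sum_{i<j obs} (s_d[i,j] - k(x_i, x_j))^2
#     + lambda_t * sum_{i<j obs} (s_t[i,j] - k(z_i, z_j))^2
#
# with k(x, y) = exp(-||x - y||^2 / (2 sigma^2)) per term. Unobserved (NA)
# entries contribute nothing.

#' Gaussian kernel between two coordinate vectors
#'
#' `exp(-||x - y||^2 / (2 sigma^2))`: strictly decreasing in Euclidean
#' distance, equal to 1 iff the points coincide.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma kernel width, positive.
#' @return kernel value in (0, 1\].
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

#' Pairwise squared Euclidean distances between row sets
#' @noRd
cross_sqdist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

#' Default kernel widths for Stiefel-constrained coordinates
#'
#' Rows of an n x R Stiefel block have squared norms of order R/n, so a
#' fixed width would be scale-inappropriate. Each width is set to the
#' typical (expected, under rotational symmetry) inter-point distance of its
#' term: `sigma^2 = 2R/n` within a domain of size n, and
#' `sigma^2 = R (1/N_d + 1/N_t)` across domains, making the typical kernel
#' exponent 1/2 in all three terms. These are declared package defaults, not
#' literature values; override via `embedding_config(sigma = ...)`.
#'
#' @param n_drugs,n_targets domain sizes.
#' @param R subspace dimensionality.
#' @return named numeric vector with entries `cross`, `drug`, `target`.
#' @export
default_kernel_widths <- function(n_drugs, n_targets, R) {
  c(cross = sqrt(R * (1 / n_drugs + 1 / n_targets)),
    drug = sqrt(2 * R / n_drugs),
    target = sqrt(2 * R / n_targets))
}

#' Configuration of the kernel-preserving embedding
#'
#' @param R subspace dimensionality (>= 1). The published protocol uses 25
#'   for small networks, 10-15 for larger ones, and 2 for visualization.
#' @param sigma kernel widths: `NULL` (derive from block sizes at fit time
#'   via [default_kernel_widths()]), one number (used for all three terms),
#'   or a named vector with entries `cross`, `drug`, `target`.
#' @param lambda_d,lambda_t nonnegative weights of the within-domain terms.
#' @param outer_iters maximum alternating (outer) iterations; default 25.
#' @param outer_tol outer stopping tolerance: training stops early when the
#'   loss improvement is below this for two consecutive outer iterations.
#' @param optimizer [optimizer_options()] for the inner sub-problems; the
#'   default loosens `grad_tol` to 1e-4 as appropriate for the inner solves.
#' @param method inner minimizer: `"lrbfgs"` (default) or
#'   `"steepest_descent"` (the historical baseline).
#' @param interaction_score score assigned to interacting pairs (default 0.9).
#' @param knn optional integer: restrict each within-domain sum to the
#'   symmetrized k-nearest-neighbor graph of the similarity matrix, keeping
#'   only local neighborhood information. `NULL` uses all observed pairs.
#' @param seed integer seed for the random Stiefel initialization.
#' @return list of class `kpe_config`.
#' @export
embedding_config <- function(R,
                             sigma = NULL,
                             lambda_d = 1,
                             lambda_t = 1,
                             outer_iters = 25L,
                             outer_tol = 1e-6,
                             optimizer = optimizer_options(grad_tol = 1e-4),
                             method = c("lrbfgs", "steepest_descent"),
                             interaction_score = 0.9,
                             knn = NULL,
                             seed = 1L) {
  stopifnot(R >= 1, lambda_d >= 0, lambda_t >= 0,
            outer_iters >= 1, outer_tol >= 0)
  if (!is.null(sigma)) {
    if (length(sigma) == 1L && is.null(names(sigma))) {
      sigma <- c(cross = sigma, drug = sigma, target = sigma)
    }
    if (!all(c("cross", "drug", "target") %in% names(sigma)) ||
        any(sigma <= 0)) {
      stop("sigma must be positive, named cross/drug/target (or a single value)",
           call. = FALSE)
    }
    sigma <- sigma[c("cross", "drug", "target")]
  }
  structure(list(R = as.integer(R), sigma = sigma,
                 lambda_d = lambda_d, lambda_t = lambda_t,
                 outer_iters = as.integer(outer_iters),
                 outer_tol = outer_tol,
                 optimizer = optimizer,
                 method = match.arg(method),
                 interaction_score = interaction_score,
                 knn = if (is.null(knn)) NULL else as.integer(knn),
                 seed = as.integer(seed)),
            class = "kpe_config")
}

#' Symmetrized k-nearest-neighbor restriction of an observation mask
#' @noRd
knn_mask <- function(S, mask, k) {
  n <- nrow(S)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- which(mask[i, ])
    if (length(cand) == 0L) next
    ord <- cand[order(S[i, cand], decreasing = TRUE)]
    keep[i, ord[seq_len(min(k, length(ord)))]] <- TRUE
  }
  (keep | t(keep)) & mask
}

#' Assemble the precomputed optimization problem
#' @noRd
kpe_problem <- function(network, config) {
  scores <- score_set(network, config$interaction_score)
  n_d <- length(network$drug_ids)
  n_t <- length(network$target_ids)
  sigma <- config$sigma
  if (is.null(sigma)) sigma <- default_kernel_widths(n_d, n_t, config$R)
  m_d <- scores$m_d
  m_t <- scores$m_t
  if (!is.null(config$knn)) {
    m_d <- knn_mask(scores$s_d, m_d, config$knn)
    m_t <- knn_mask(scores$s_t, m_t, config$knn)
  }
  list(s_c = scores$s_c, m_c = scores$m_c,
       s_d = scores$s_d, m_d = m_d, ut_d = m_d & upper.tri(m_d),
       s_t = scores$s_t, m_t = m_t, ut_t = m_t & upper.tri(m_t),
       sigma = sigma, lambda_d = config$lambda_d, lambda_t = config$lambda_t,
       n_d = n_d, n_t = n_t)
}

#' Kernel matrix between row sets for a given width
#' @noRd
kernel_matrix <- function(X, Y, sigma) {
  exp(-cross_sqdist(X, Y) / (2 * sigma^2))
}

#' Loss of a coordinate pair under a precomputed problem
#' @noRd
problem_loss <- function(X_d, X_t, prob) {
  loss <- 0
  if (any(prob$m_c)) {
    K <- kernel_matrix(X_d, X_t, prob$sigma[["cross"]])
    loss <- loss + sum((prob$s_c[prob$m_c] - K[prob$m_c])^2)
  }
  if (prob$lambda_d > 0 && any(prob$ut_d)) {
    K <- kernel_matrix(X_d, X_d, prob$sigma[["drug"]])
    loss <- loss + prob$lambda_d * sum((prob$s_d[prob$ut_d] - K[prob$ut_d])^2)
  }
  if (prob$lambda_t > 0 && any(prob$ut_t)) {
    K <- kernel_matrix(X_t, X_t, prob$sigma[["target"]])
    loss <- loss + prob$lambda_t * sum((prob$s_t[prob$ut_t] - K[prob$ut_t])^2)
  }
  loss
}

#' Weight matrix 2 (s - k) k / sigma^2 on the observed support
#' @noRd
residual_weights <- function(S, K, mask, sigma) {
  W <- matrix(0, nrow(K), ncol(K))
  W[mask] <- 2 * (S[mask] - K[mask]) * K[mask] / sigma^2
  W
}

#' Ambient gradient of the loss with respect to the drug block
#' @noRd
problem_grad_drugs <- function(X_d, X_t, prob) {
  G <- matrix(0, nrow(X_d), ncol(X_d))
  if (any(prob$m_c)) {
    K <- kernel_matrix(X_d, X_t, prob$sigma[["cross"]])
    W <- residual_weights(prob$s_c, K, prob$m_c, prob$sigma[["cross"]])
    G <- G + rowSums(W) * X_d - W %*% X_t
  }
  if (prob$lambda_d > 0 && any(prob$m_d)) {
    K <- kernel_matrix(X_d, X_d, prob$sigma[["drug"]])
    W <- residual_weights(prob$s_d, K, prob$m_d, prob$sigma[["drug"]])
    G <- G + prob$lambda_d * (rowSums(W) * X_d - W %*% X_d)
  }
  G
}

#' Ambient gradient of the loss with respect to the target block
#' @noRd
problem_grad_targets <- function(X_d, X_t, prob) {
  G <- matrix(0, nrow(X_t), ncol(X_t))
  if (any(prob$m_c)) {
    K <- kernel_matrix(X_d, X_t, prob$sigma[["cross"]])
    W <- residual_weights(prob$s_c, K, prob$m_c, prob$sigma[["cross"]])
    G <- G + colSums(W) * X_t - crossprod(W, X_d)
  }
  if (prob$lambda_t > 0 && any(prob$m_t)) {
    K <- kernel_matrix(X_t, X_t, prob$sigma[["target"]])
    W <- residual_weights(prob$s_t, K, prob$m_t, prob$sigma[["target"]])
    G <- G + prob$lambda_t * (rowSums(W) * X_t - W %*% X_t)
  }
  G
}

#' Kernel-preserving embedding loss
#'
#' The masked sum of squared differences between observed scores and the
#' Gaussian kernel values of the embedded coordinates (see the package
#' vignette for the full expression). Exposed mainly for testing and
#' diagnostics; [kpe_fit()] uses it internally.
#'
#' @param X_d,X_t drug and target coordinate blocks (N x R matrices).
#' @param network a [dti_network()].
#' @param config an [embedding_config()].
#' @return nonnegative scalar loss.
#' @export
kpe_objective <- function(X_d, X_t, network, config) {
  if (anyNA(X_d) || anyNA(X_t)) stop("NaN in coordinates", call. = FALSE)
  problem_loss(X_d, X_t, kpe_problem(network, config))
}

#' Ambient gradients of the embedding loss
#'
#' Gradient of [kpe_objective()] with respect to one coordinate block,
#' holding the other fixed. Each observed pair with score s and kernel value
#' k contributes `2 (s - k) k (x_i - y) / sigma^2` to its row.
#'
#' @inheritParams kpe_objective
#' @return matrix of the same shape as the differentiated block.
#' @export
kpe_gradient_drugs <- function(X_d, X_t, network, config) {
  problem_grad_drugs(X_d, X_t, kpe_problem(network, config))
}

#' @export
#' @rdname kpe_gradient_drugs
kpe_gradient_targets <- function(X_d, X_t, network, config) {
  problem_grad_targets(X_d, X_t, kpe_problem(network, config))
}

#' Fit the kernel-preserving embedding
#'
#' Alternating minimization: starting from random Stiefel points (QR
#' factorization of standard-normal matrices), each outer iteration first
#' minimizes the loss over the drug block with the target block fixed, then
#' over the target block with the drug block fixed, using the configured
#' Riemannian minimizer warm-started from the previous iterate. Training
#' runs for at most `outer_iters` outer iterations and stops early when the
#' loss improvement stays below `outer_tol` for two consecutive outer
#' iterations. The recorded outer-loss trace is non-increasing and both
#' blocks satisfy the Stiefel orthonormality invariant after every outer
#' iteration.
#'
#' Objects with no observed scores at all (isolated drugs or targets) feel
#' no gradient and remain at their random initial positions; a warning
#' reports how many there are.
#'
#' @param network a [dti_network()].
#' @param config an [embedding_config()].
#' @return object of class `kpe_embedding` with elements `X_d`, `X_t`
#'   (coordinate blocks with identifier rownames), `sigma` (kernel widths
#'   used), `loss` (final loss), `trace` (per-outer-iteration data frame),
#'   `config`, `drug_ids`, `target_ids`.
#' @export
kpe_fit <- function(network, config) {
  stopifnot(inherits(network, "dti_network"), inherits(config, "kpe_config"))
  prob <- kpe_problem(network, config)
  if (config$R > min(prob$n_d, prob$n_t)) {
    stop("R exceeds the smaller block size; no Stiefel point exists",
         call. = FALSE)
  }

  iso_d <- sum(rowSums(prob$m_c) == 0 & rowSums(prob$m_d) == 0)
  iso_t <- sum(colSums(prob$m_c) == 0 & rowSums(prob$m_t) == 0)
  if (iso_d + iso_t > 0) {
    warning(sprintf(
      "%d drug(s) and %d target(s) have no observed scores; they stay at their random initial positions",
      iso_d, iso_t), call. = FALSE)
  }

  init <- with_seed(config$seed, {
    list(X_d = random_stiefel(prob$n_d, config$R),
         X_t = random_stiefel(prob$n_t, config$R))
  })
  X_d <- init$X_d
  X_t <- init$X_t

  minimize <- switch(config$method,
                     lrbfgs = lrbfgs_minimize,
                     steepest_descent = steepest_descent_armijo)

  loss <- problem_loss(X_d, X_t, prob)
  trace <- data.frame(iter = 0L, loss = loss,
                      stiefel_dev_drugs = stiefel_deviation(X_d),
                      stiefel_dev_targets = stiefel_deviation(X_t),
                      inner_iters_drugs = NA_integer_,
                      inner_iters_targets = NA_integer_)
  below_tol <- 0L

  for (it in seq_len(config$outer_iters)) {
    res_d <- minimize(function(X) problem_loss(X, X_t, prob),
                      function(X) problem_grad_drugs(X, X_t, prob),
                      X_d, config$optimizer)
    X_d <- res_d$X
    res_t <- minimize(function(X) problem_loss(X_d, X, prob),
                      function(X) problem_grad_targets(X_d, X, prob),
                      X_t, config$optimizer)
    X_t <- res_t$X

    new_loss <- problem_loss(X_d, X_t, prob)
    improvement <- loss - new_loss
    loss <- new_loss
    trace <- rbind(trace, data.frame(
      iter = it, loss = loss,
      stiefel_dev_drugs = stiefel_deviation(X_d),
      stiefel_dev_targets = stiefel_deviation(X_t),
      inner_iters_drugs = res_d$trace$iterations,
      inner_iters_targets = res_t$trace$iterations))

    below_tol <- if (improvement < config$outer_tol) below_tol + 1L else 0L
    if (below_tol >= 2L) break
  }

  rownames(X_d) <- network$drug_ids
  rownames(X_t) <- network$target_ids
  colnames(X_d) <- colnames(X_t) <- sprintf("coord_%d", seq_len(config$R))
  structure(list(X_d = X_d, X_t = X_t,
                 sigma = prob$sigma,
                 loss = loss, trace = trace,
                 config = config,
                 drug_ids = network$drug_ids,
                 target_ids = network$target_ids),
            class = "kpe_embedding")
}

#' @export
print.kpe_embedding <- function(x, ...) {
  cat(sprintf(
    "kpe_embedding: %d drugs + %d targets in %d dimensions; final loss %.6g after %d outer iterations\n",
    nrow(x$X_d), nrow(x$X_t), ncol(x$X_d), x$loss, max(x$trace$iter)))
  invisible(x)
}

#' Out-of-sample embedding of an unseen drug
#'
#' Places a new drug into a trained embedding from its similarity profile to
#' the training drugs alone, without refitting: the coordinates x* minimize
#' `sum_i (sim_i - k(x*, x_i))^2` over observed profile entries, with the
#' drug-domain kernel width. The variable is unconstrained (a single point
#' cannot carry an orthonormality constraint) and is initialized at the
#' similarity-weighted mean of the training-drug coordinates, then refined
#' by BFGS with the analytic gradient. Deterministic given the embedding and
#' the profile.
#'
#' @param emb a fitted [kpe_fit()] object.
#' @param sim_profile numeric vector of similarities to the training drugs,
#'   in \[0, 1\], `NA` allowed for unobserved entries; length must equal the
#'   number of training drugs.
#' @return coordinate vector of length R.
#' @export
embed_new_drug <- function(emb, sim_profile) {
  stopifnot(inherits(emb, "kpe_embedding"))
  if (length(sim_profile) != nrow(emb$X_d)) {
    stop("profile length must equal the number of training drugs",
         call. = FALSE)
  }
  obs <- which(!is.na(sim_profile))
  if (length(obs) == 0L) {
    stop("cannot embed: similarity profile has no observed entries",
         call. = FALSE)
  }
  s <- as.numeric(sim_profile[obs])
  Xo <- emb$X_d[obs, , drop = FALSE]
  sigma <- emb$sigma[["drug"]]

  w <- if (sum(s) > 0) s / sum(s) else rep(1 / length(s), length(s))
  x0 <- as.numeric(crossprod(Xo, w))

  fn <- function(x) {
    k <- exp(-colSums((t(Xo) - x)^2) / (2 * sigma^2))
    sum((s - k)^2)
  }
  gr <- function(x) {
    D <- t(x - t(Xo))                      # rows: x - x_i
    k <- exp(-rowSums(D^2) / (2 * sigma^2))
    colSums(2 * (s - k) * k * D) / sigma^2
  }
  res <- stats::optim(x0, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  as.numeric(res$par)
}

#' Kernel scores between embedded drugs and all targets
#'
#' Entry (i, j) is the cross-domain Gaussian kernel between drug coordinate
#' vector i and target row j of the trained embedding. The kernel is a
#' strictly decreasing function of embedded Euclidean distance, so ranking
#' pairs by these scores is identical to ranking by proximity.
#'
#' @param drug_vecs m x R matrix of drug coordinates (a vector is taken as
#'   one row); m may be 0.
#' @param emb a fitted [kpe_fit()] object.
#' @return m x N_t matrix of scores in (0, 1\].
#' @export
predict_pair_scores <- function(drug_vecs, emb) {
  stopifnot(inherits(emb, "kpe_embedding"))
  if (is.null(dim(drug_vecs))) drug_vecs <- matrix(drug_vecs, nrow = 1L)
  if (ncol(drug_vecs) != ncol(emb$X_t)) {
    stop("coordinate dimension mismatch", call. = FALSE)
  }
  if (nrow(drug_vecs) == 0L) {
    return(matrix(numeric(0), 0L, nrow(emb$X_t),
                  dimnames = list(NULL, emb$target_ids)))
  }
  K <- kernel_matrix(drug_vecs, emb$X_t, emb$sigma[["cross"]])
  colnames(K) <- emb$target_ids
  K
}
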