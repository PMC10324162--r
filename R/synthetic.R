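# Synthetic drug-target networks with a planted low-dimensional kernel
# geometry, so the whole pipeline is testable without downloading the
# curated interaction sets. Defaults emulate the smallest curated network
# (54 drugs, 26 nuclear-receptor targets, 90 known interactions, sparsity
# 93.59%).

#' Generate a synthetic interaction network with planted geometry
#'
#' Latent drug and target coordinates are drawn from a standard normal in
#' `r_true` dimensions, scaled so row norms match those of Stiefel blocks of
#' the same size (expected squared norm `r_true / n`); the model's default
#' kernel widths therefore transfer directly. Similarity matrices are the
#' exact Gaussian kernel matrices of the latent points plus clipped-Gaussian
#' noise, symmetrized, with unit diagonal. The adjacency declares the top
#' `interaction_quantile` fraction of cross-kernel values interacting, so
#' interactions, drug-drug and target-target similarities are all consistent
#' with one latent geometry.
#'
#' @param n_drugs,n_targets domain sizes (defaults: 54 and 26).
#' @param r_true planted latent dimensionality (default 5).
#' @param interaction_quantile fraction of drug-target pairs declared
#'   interacting, in (0, 1); the default 0.0641 reproduces the 90/1404
#'   interaction density of the smallest curated set.
#' @param noise_sd standard deviation of the similarity noise (default 0:
#'   similarities equal the planted kernel values exactly).
#' @param seed integer seed; the draw is fully deterministic given it.
#' @return list with `network` (a [dti_network()]) and `latent` (list of the
#'   true drug and target coordinate matrices).
#' @export
simulate_dti_network <- function(n_drugs = 54L, n_targets = 26L,
                                 r_true = 5L,
                                 interaction_quantile = 0.0641,
                                 noise_sd = 0,
                                 seed = 1L) {
  stopifnot(interaction_quantile > 0, interaction_quantile < 1,
            r_true >= 1, noise_sd >= 0)
  n_inter <- round(interaction_quantile * n_drugs * n_targets)
  if (n_inter < 1) {
    stop("parameters produce zero interactions", call. = FALSE)
  }
  with_seed(seed, {
    U <- matrix(stats::rnorm(n_drugs * r_true, sd = 1 / sqrt(n_drugs)),
                n_drugs, r_true)
    V <- matrix(stats::rnorm(n_targets * r_true, sd = 1 / sqrt(n_targets)),
                n_targets, r_true)
    sigma <- default_kernel_widths(n_drugs, n_targets, r_true)

    noisy_sim <- function(K) {
      if (noise_sd > 0) {
        E <- matrix(stats::rnorm(length(K), sd = noise_sd), nrow(K))
        K <- K + (E + t(E)) / 2
        K[K < 0] <- 0
        K[K > 1] <- 1
      }
      diag(K) <- 1
      K
    }
    sim_d <- noisy_sim(kernel_matrix(U, U, sigma[["drug"]]))
    sim_t <- noisy_sim(kernel_matrix(V, V, sigma[["target"]]))

    K_c <- kernel_matrix(U, V, sigma[["cross"]])
    thr <- sort(as.vector(K_c), decreasing = TRUE)[n_inter]
    adjacency <- (K_c >= thr) + 0

    drug_ids <- sprintf("SD%05d", seq_len(n_drugs))
    target_ids <- sprintf("syn%04d", seq_len(n_targets))
    net <- dti_network(adjacency, sim_d, sim_t,
                       drug_ids = drug_ids, target_ids = target_ids)
    list(network = net, latent = list(drugs = U, targets = V))
  })
}

#' Generate related residue sequences by ancestral mutation
#'
#' One random ancestor sequence is drawn over `alphabet`, and `n`
#' descendants are derived by independent per-site substitution with the
#' given rate (a mutated site receives a uniformly random different
#' letter). Average pairwise alignment similarity between descendants
#' decreases with the mutation rate, which exercises the Smith-Waterman
#' scoring path end-to-end.
#'
#' @param n number of sequences.
#' @param length sequence length.
#' @param mutation_rate per-site substitution probability in \[0, 1\].
#' @param seed integer seed.
#' @param alphabet residue letters; default the 20 amino acids.
#' @return character vector of `n` sequences.
#' @export
simulate_sequences <- function(n, length, mutation_rate, seed = 1L,
                               alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, n >= 1, length >= 1)
  with_seed(seed, {
    ancestor <- sample(alphabet, length, replace = TRUE)
    vapply(seq_len(n), function(i) {
      child <- ancestor
      hit <- stats::runif(length) < mutation_rate
      if (any(hit)) {
        child[hit] <- vapply(ancestor[hit], function(a) {
          sample(setdiff(alphabet, a), 1L)
        }, character(1))
      }
      paste(child, collapse = "")
    }, character(1))
  })
}
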