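# The drug-target interaction network container: a binary adjacency matrix
# plus within-domain similarity matrices with aligned identifier lists.

#' Validate a similarity matrix in place
#'
#' Similarities must be symmetric with unit diagonal and values in [0, 1]
#' (NA allowed as a missingness mask). Asymmetry and off-unit diagonals are
#' tolerated up to 1e-6 (symmetrized / forced with a warning), anything
#' larger is rejected as an un-normalized input.
#' @noRd
validate_similarity <- function(S, what) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) {
    stop(sprintf("%s must be square", what), call. = FALSE)
  }
  asym <- max(abs(S - t(S)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-6) {
    stop(sprintf("%s asymmetric beyond tolerance (max |S - S'| = %.3g)",
                 what, asym), call. = FALSE)
  }
  if (is.finite(asym) && asym > 0) {
    warning(sprintf("%s slightly asymmetric (%.3g); symmetrized", what, asym),
            call. = FALSE)
    S <- (S + t(S)) / 2
  }
  d <- diag(S)
  bad_diag <- which(!is.na(d) & abs(d - 1) > 1e-6)
  if (length(bad_diag) > 0) {
    stop(sprintf("%s diagonal must be 1 (off by more than 1e-6 at index %d)",
                 what, bad_diag[1]), call. = FALSE)
  }
  diag(S)[!is.na(d)] <- 1
  rng <- range(S, na.rm = TRUE)
  if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12) {
    stop(sprintf("%s values must lie in [0, 1]", what), call. = FALSE)
  }
  S[S < 0] <- 0
  S[S > 1] <- 1
  S
}

#' Construct a drug-target interaction network
#'
#' Bundles the three observed matrices: a binary drugs x targets adjacency,
#' a drug-drug chemical similarity matrix and a target-target genomic
#' similarity matrix, with consistent identifier orderings. Similarity
#' matrices may contain `NA` entries, which are treated as unobserved
#' throughout (they contribute nothing to the embedding loss).
#'
#' @param adjacency binary matrix, drugs as rows.
#' @param sim_drugs drug-drug similarity matrix in \[0, 1\].
#' @param sim_targets target-target similarity matrix in \[0, 1\].
#' @param drug_ids,target_ids identifier character vectors; default to the
#'   dimnames of `adjacency` or generated labels.
#' @return an object of class `dti_network`.
#' @export
dti_network <- function(adjacency, sim_drugs, sim_targets,
                        drug_ids = NULL, target_ids = NULL) {
  adjacency <- as.matrix(adjacency)
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1))) {
    stop("adjacency must be strictly binary (0/1)", call. = FALSE)
  }
  n_d <- nrow(adjacency)
  n_t <- ncol(adjacency)
  if (is.null(drug_ids)) {
    drug_ids <- rownames(adjacency)
    if (is.null(drug_ids)) drug_ids <- sprintf("drug_%03d", seq_len(n_d))
  }
  if (is.null(target_ids)) {
    target_ids <- colnames(adjacency)
    if (is.null(target_ids)) target_ids <- sprintf("target_%03d", seq_len(n_t))
  }
  if (length(drug_ids) != n_d || length(target_ids) != n_t) {
    stop("identifier lists inconsistent with adjacency dimensions",
         call. = FALSE)
  }
  if (anyDuplicated(drug_ids) || anyDuplicated(target_ids)) {
    stop("identifiers must be unique", call. = FALSE)
  }
  sim_drugs <- validate_similarity(sim_drugs, "sim_drugs")
  sim_targets <- validate_similarity(sim_targets, "sim_targets")
  if (nrow(sim_drugs) != n_d) {
    stop("sim_drugs dimension does not match the number of drugs",
         call. = FALSE)
  }
  if (nrow(sim_targets) != n_t) {
    stop("sim_targets dimension does not match the number of targets",
         call. = FALSE)
  }
  dimnames(adjacency) <- list(drug_ids, target_ids)
  dimnames(sim_drugs) <- list(drug_ids, drug_ids)
  dimnames(sim_targets) <- list(target_ids, target_ids)
  structure(list(drug_ids = drug_ids,
                 target_ids = target_ids,
                 adjacency = adjacency,
                 sim_drugs = sim_drugs,
                 sim_targets = sim_targets),
            class = "dti_network")
}

#' @export
print.dti_network <- function(x, ...) {
  k <- sum(x$adjacency)
  cat(sprintf(
    "dti_network: %d drugs x %d targets, %d known interactions (sparsity %.2f%%)\n",
    length(x$drug_ids), length(x$target_ids), k,
    dataset_sparsity(length(x$drug_ids), length(x$target_ids), k)))
  invisible(x)
}

#' Masked score matrices entering the embedding loss
#'
#' Builds the cross-domain interaction scores (fixed positive score /
#' `NA`), and carries the within-domain similarity matrices with their
#' observation masks. Within-domain self-pairs (the unit diagonal) are never
#' part of the loss.
#'
#' @param network a [dti_network()].
#' @param interaction_score score assigned to interacting pairs.
#' @return list of class `kpe_score_set` with elements `s_c`, `s_d`, `s_t`
#'   and logical observation masks `m_c`, `m_d`, `m_t`.
#' @export
score_set <- function(network, interaction_score = 0.9) {
  s_c <- build_interaction_scores(network$adjacency, interaction_score)
  s_d <- network$sim_drugs
  s_t <- network$sim_targets
  m_d <- !is.na(s_d)
  diag(m_d) <- FALSE
  m_t <- !is.na(s_t)
  diag(m_t) <- FALSE
  structure(list(s_c = s_c, s_d = s_d, s_t = s_t,
                 m_c = !is.na(s_c), m_d = m_d, m_t = m_t),
            class = "kpe_score_set")
}
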