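# Score construction: cross-domain interaction scores, drug-drug chemical
# similarity (Jaccard over substructure sets), target-target genomic
# similarity (normalized Smith-Waterman), and dataset summary statistics.

#' Interaction scores from a binary adjacency matrix
#'
#' Known interacting pairs receive a fixed score (0.9 by default); all other
#' pairs are left unobserved (`NA`), so they exert no force on the embedding.
#' The mapping is invertible on its observed support: `!is.na(s)` recovers
#' the adjacency.
#'
#' @param adjacency binary drugs x targets matrix (entries 0/1).
#' @param score value assigned to interacting pairs.
#' @return matrix of the same shape with entries `score` or `NA`.
#' @export
build_interaction_scores <- function(adjacency, score = 0.9) {
  adjacency <- as.matrix(adjacency)
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1))) {
    stop("adjacency must be strictly binary (0/1) with no missing values",
         call. = FALSE)
  }
  s <- matrix(NA_real_, nrow(adjacency), ncol(adjacency),
              dimnames = dimnames(adjacency))
  s[adjacency == 1] <- score
  s
}

#' Jaccard (Tanimoto) similarity between two substructure sets
#'
#' `|a intersect b| / |a union b|` over the chemical substructure tokens of
#' two compounds. Symmetric, bounded in \[0, 1\], and 1 for identical sets.
#'
#' @param a,b character vectors of substructure tokens (duplicates ignored).
#' @return similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0L) {
    stop("similarity undefined: both substructure sets are empty",
         call. = FALSE)
  }
  length(intersect(a, b)) / u
}

#' Smith-Waterman scoring parameters
#'
#' @param match,mismatch scores used when no substitution matrix is given.
#' @param gap_open penalty for the first residue of a gap (nonnegative).
#' @param gap_extend penalty for each further residue; equal to `gap_open`
#'   gives linear gap costs. Defaults to `gap_open`.
#' @param substitution optional symmetric named score matrix over the residue
#'   alphabet, or the string `"BLOSUM62"` to use the standard protein matrix
#'   (requires the Biostrings package). Overrides `match`/`mismatch`.
#' @return a list of class `kpe_sw_params`.
#' @export
sw_params <- function(match = 1, mismatch = -1,
                      gap_open = 1, gap_extend = gap_open,
                      substitution = NULL) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  if (identical(substitution, "BLOSUM62")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("the BLOSUM62 substitution matrix requires the Biostrings package",
           call. = FALSE)
    }
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    substitution <- env$BLOSUM62
  }
  if (!is.null(substitution)) {
    substitution <- as.matrix(substitution)
    if (is.null(rownames(substitution)) ||
        !identical(rownames(substitution), colnames(substitution)) ||
        max(abs(substitution - t(substitution))) > 0) {
      stop("substitution matrix must be symmetric with matching row/column names",
           call. = FALSE)
    }
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 substitution = substitution),
            class = "kpe_sw_params")
}

#' Default protein scoring: BLOSUM62 with affine gaps (open 10, extend 1)
#' @export
#' @rdname sw_params
sw_params_protein <- function() {
  sw_params(gap_open = 10, gap_extend = 1, substitution = "BLOSUM62")
}

#' Split a sequence into residues and map them to substitution-score rows
#' @noRd
sw_residues <- function(seq, p, arg) {
  r <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(r) == 0L) stop(sprintf("%s is empty", arg), call. = FALSE)
  if (!is.null(p$substitution)) {
    idx <- match(r, rownames(p$substitution))
    if (anyNA(idx)) {
      stop(sprintf("unknown residue token(s) in %s: %s", arg,
                   paste(unique(r[is.na(idx)]), collapse = ", ")),
           call. = FALSE)
    }
    idx
  } else {
    r
  }
}

#' Smith-Waterman local alignment score
#'
#' Optimal local-alignment score by the Gotoh dynamic program with affine gap
#' costs: a gap of length L costs `gap_open + (L - 1) * gap_extend`, which
#' degenerates to linear costs when the two penalties are equal. The score is
#' nonnegative (the empty alignment is always allowed) and symmetric in its
#' arguments.
#'
#' @param seq_a,seq_b residue strings over the alphabet of `p`.
#' @param p scoring parameters from [sw_params()].
#' @return nonnegative alignment score.
#' @export
smith_waterman <- function(seq_a, seq_b, p = sw_params()) {
  ra <- sw_residues(seq_a, p, "seq_a")
  rb <- sw_residues(seq_b, p, "seq_b")
  n <- length(ra); m <- length(rb)
  subscore <- if (is.null(p$substitution)) {
    function(i, j) if (ra[i] == rb[j]) p$match else p$mismatch
  } else {
    function(i, j) p$substitution[ra[i], rb[j]]
  }
  # H: best local alignment ending at (i, j); E/F: ditto ending in a gap
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F_ <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - p$gap_open,
                               E[i + 1L, j] - p$gap_extend)
      F_[i + 1L, j + 1L] <- max(H[i, j + 1L] - p$gap_open,
                                F_[i, j + 1L] - p$gap_extend)
      h <- max(0,
               H[i, j] + subscore(i, j),
               E[i + 1L, j + 1L],
               F_[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) best <- h
    }
  }
  best
}

#' Normalized Smith-Waterman similarity
#'
#' The local-alignment score scaled by the geometric mean of the two
#' self-alignment scores: `SW(a, b) / sqrt(SW(a, a) * SW(b, b))`. Yields 1
#' for identical sequences and 0 for sequences with no positive-scoring
#' local alignment.
#'
#' @inheritParams smith_waterman
#' @return similarity in \[0, 1\] for standard scoring schemes.
#' @export
normalized_sw <- function(seq_a, seq_b, p = sw_params()) {
  saa <- smith_waterman(seq_a, seq_a, p)
  sbb <- smith_waterman(seq_b, seq_b, p)
  if (saa <= 0 || sbb <= 0) {
    stop("normalization undefined: zero self-alignment score", call. = FALSE)
  }
  smith_waterman(seq_a, seq_b, p) / sqrt(saa * sbb)
}

#' Sparsity of a drug-target interaction network
#'
#' Percentage of drug-target pairs with no known interaction,
#' `100 * (1 - k / (n_drugs * n_targets))`, reported to two decimals. High
#' sparsity is the norm in curated interaction sets and is what makes
#' extracting structure from the similarity spaces worthwhile.
#'
#' @param n_drugs,n_targets,n_interactions nonnegative counts.
#' @return sparsity percentage rounded to two decimals.
#' @export
dataset_sparsity <- function(n_drugs, n_targets, n_interactions) {
  if (n_drugs <= 0 || n_targets <= 0) {
    stop("network must have at least one drug and one target", call. = FALSE)
  }
  if (n_interactions > n_drugs * n_targets) {
    stop("more interactions than drug-target pairs", call. = FALSE)
  }
  round(100 * (1 - n_interactions / (n_drugs * n_targets)), 2)
}
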